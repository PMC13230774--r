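test_that("the generator is deterministic and self-validating", {
  cfg <- sim_config(n_schd = 80L, n_nschd = 80L, n_control = 500L,
                    n_genes = 120L, seed = 5)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1, c2)
  # construction already runs full validation; the TSV round trip must too
  d <- tempfile()
  write_cohort(c1, d)
  c3 <- read_cohort(d)
  expect_equal(nrow(c3$genotypes), nrow(c1$genotypes))
  expect_equal(sort(c3$samples$sample_id), sort(c1$samples$sample_id))
})

test_that("seed is mandatory everywhere randomness enters", {
  expect_error(sim_config(), "seed")
  expect_error(simulate_labeled_scores(), "seed")
  expect_error(simulate_deg_clusters(data.frame(gene_id = "a")), "seed")
})

test_that("empirical AF rarity matches the configured mixture", {
  cfg <- sim_config(n_schd = 50L, n_nschd = 50L, n_control = 300L,
                    n_genes = 800L, rare_weight = 0.9, seed = 6)
  co <- simulate_cohort(cfg)
  rare <- is_rare(co$variants)
  # forced qualifying sites (3 per gene) are always rare; the rest follow
  # the mixture weight, so the overall rate lies a little above 0.9
  n <- length(rare)
  expected_min <- 0.9
  expect_gt(mean(rare), expected_min - 3 * sqrt(0.9 * 0.1 / n))
  expect_lt(mean(rare), 0.99)
  # common variants are common in every present source
  common_af <- co$variants$af_internal[!rare]
  expect_true(all(common_af >= 0.001))
})

test_that("without planted effects carrier rates are balanced per bin", {
  cfg <- sim_config(n_schd = 4000L, n_nschd = 4000L, n_control = 12000L,
                    n_genes = 1000L, seed = 7)
  co <- simulate_cohort(cfg)
  sets <- bins_as_gene_sets(make_constraint_bins(co$genes, "loeuf"))
  case <- co$samples$stratum != "control"
  for (lbl in names(sets)[c(1, 5, 10)]) {
    mac <- per_sample_mac(co, sets[[lbl]], "hcLOF")
    ratio <- mean(mac[case] > 0) / mean(mac[!case] > 0)
    expect_gt(ratio, 0.8)
    expect_lt(ratio, 1.25)
  }
})

test_that("a planted carrier odds ratio is recovered by the logistic
           burden test", {
  planted <- data.frame(target = "bin_1", category = "hcLOF",
                        stratum = "sCHD", or = 2.27)
  cfg <- sim_config(n_schd = 1800L, n_nschd = 500L, n_control = 20000L,
                    n_genes = 1000L, planted_effects = planted, seed = 8)
  co <- simulate_cohort(cfg)
  sets <- bins_as_gene_sets(make_constraint_bins(co$genes, "loeuf"))
  gs <- run_geneset_battery(co, sets["bin_1"], strata = "sCHD",
                            categories = "hcLOF")
  expect_gt(gs$results$odds_ratio, 1.9)
  expect_lt(gs$results$odds_ratio, 2.7)
})

test_that("planting on an unknown target is an error", {
  cfg <- sim_config(n_schd = 20L, n_nschd = 20L, n_control = 50L,
                    n_genes = 50L,
                    planted_effects = data.frame(
                      target = "no_such_set", category = "hcLOF",
                      stratum = "sCHD", or = 2),
                    seed = 9)
  expect_error(simulate_cohort(cfg), "planted target not found")
})

test_that("labelled score sets behave at zero and strong separation", {
  expect_error(simulate_labeled_scores(n_per_class = 0, seed = 1),
               ">= 1")
  null_set <- simulate_labeled_scores(n_per_class = 1000, dprime = 0,
                                      seed = 12)
  rep0 <- select_score_thresholds(null_set)
  expect_false(any(rep0$qualifies))

  strong <- simulate_labeled_scores(n_per_class = 2000, dprime = 3,
                                    seed = 13)
  rep3 <- select_score_thresholds(strong)
  ens <- rep3[rep3$score_name %in% c("cadd", "revel", "mvp"), ]
  expect_true(all(ens$qualifies))
  expect_true(all(ens$auc_constrained > 0.95))
  expect_true(all(ens$auc_nonconstrained > 0.95))
  # the weakly separated extra score is evaluated but rejected
  expect_false(rep3$qualifies[rep3$score_name == "mpc"])
})

test_that("DEG cluster simulation yields 15 labelled sets with controlled
           overlap", {
  genes <- data.frame(gene_id = sprintf("g%04d", 1:1000))
  sets <- simulate_deg_clusters(genes, seed = 14)
  expect_equal(names(sets), paste0("C", 0:14))
  expect_true(all(lengths(sets) == 100L))

  risk <- genes$gene_id[1:100]
  sets2 <- simulate_deg_clusters(genes, risk_genes = risk,
                                 risk_cluster = "C14", seed = 15)
  expect_equal(sort(sets2$C14), sort(risk))
  for (lbl in paste0("C", 0:13)) {
    expect_length(intersect(sets2[[lbl]], risk), 0)
  }
})
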