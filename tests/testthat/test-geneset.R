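test_that("constraint bins partition genes into near-equal deciles", {
  g20 <- data.frame(gene_id = sprintf("g%02d", 1:20),
                    loeuf = seq(0.1, 2, length.out = 20), moeuf = 1)
  b <- make_constraint_bins(g20, "loeuf")
  expect_equal(unname(table(b$bin)), rep(2L, 10), ignore_attr = TRUE)
  expect_equal(b$gene_id[b$bin == 1], c("g01", "g02"))

  # study-scale: 19,923 genes split as 3 x 1993 + 7 x 1992
  big <- data.frame(gene_id = sprintf("g%05d", 1:19923),
                    loeuf = runif(19923), moeuf = 1)
  bb <- make_constraint_bins(big, "loeuf")
  sizes <- as.integer(table(bb$bin))
  expect_true(all(sizes %in% c(1992L, 1993L)))
  expect_equal(sum(sizes), 19923L)
  # partition: every gene with the metric in exactly one bin
  expect_equal(sort(bb$gene_id), sort(big$gene_id))
  expect_false(anyDuplicated(bb$gene_id) > 0)

  # the most constrained gene lands in bin 1
  expect_equal(bb$gene_id[which.min(big$loeuf[match(bb$gene_id,
                                                    big$gene_id)])],
               bb$gene_id[1])
  expect_equal(bb$bin[1], 1L)

  expect_error(make_constraint_bins(
    data.frame(gene_id = "a", loeuf = NA_real_, moeuf = NA_real_),
    "loeuf"), "absent")
})

test_that("per-sample MAC sums dosages over QC-passing rare calls", {
  co <- tiny_cohort()
  mac <- per_sample_mac(co, "G1", "hcLOF")
  # s1: two het calls = 2; s4: hom_alt = 2; s2/c1 fail QC; c2 common
  expect_equal(unname(mac[c("s1", "s2", "s4", "c1", "c2")]),
               c(2L, 0L, 2L, 0L, 0L))
  macx <- per_sample_mac(co, "GX", "hcLOF")
  expect_equal(unname(macx["s3"]), 1L)  # hemizygous dosage 1
  # additivity over disjoint sets
  both <- per_sample_mac(co, c("G1", "GX"), "hcLOF")
  expect_equal(both, mac + macx)
})

test_that("logistic burden test agrees with an independent Newton solver", {
  set.seed(31)
  for (i in 1:50) {
    n <- 200
    mac <- rbinom(n, 3, 0.2)
    x1 <- rnorm(n)
    y <- rbinom(n, 1, plogis(-1 + 0.4 * mac + 0.2 * x1))
    if (length(unique(y)) < 2 || var(mac) == 0) next
    fit <- logistic_geneset_test(mac, y, data.frame(x1 = x1))
    beta <- unname(newton_logistic(cbind(mac, x1), y))
    expect_equal(fit$beta, beta[2], tolerance = 1e-6)
    expect_equal(fit$odds_ratio, exp(beta[2]), tolerance = 1e-6)
    expect_true(fit$ci_low < fit$odds_ratio & fit$odds_ratio < fit$ci_high)
  }
})

test_that("degenerate and single-class inputs are handled explicitly", {
  y <- rep(c(0, 1), each = 20)
  r <- logistic_geneset_test(rep(0, 40), y)
  expect_equal(r$flag, "degenerate")
  expect_true(is.na(r$p))
  expect_error(logistic_geneset_test(rbinom(40, 1, 0.5), rep(1, 40)),
               "single-class")
})

test_that("the battery flags a planted cluster in the right stratum only", {
  planted <- data.frame(target = "risk", category = "hcLOF",
                        stratum = "sCHD", or = 2.5)
  risk_genes <- sprintf("G%05d", 1:100)
  cfg <- sim_config(n_schd = 1800L, n_nschd = 600L, n_control = 20000L,
                    n_genes = 1200L,
                    planted_effects = planted,
                    extra_sets = list(risk = risk_genes),
                    seed = 515)
  co <- simulate_cohort(cfg)
  sets <- simulate_deg_clusters(co, risk_genes = risk_genes,
                                risk_cluster = "C14", seed = 516)
  expect_equal(names(sets), paste0("C", 0:14))
  gs <- run_geneset_battery(co, sets, strata = c("sCHD", "nsCHD"),
                            categories = "hcLOF")
  r <- gs$results
  expect_true(r$significant[r$set_label == "C14" & r$stratum == "sCHD"])
  expect_false(r$significant[r$set_label == "C14" & r$stratum == "nsCHD"])
  # planted odds ratio is recovered in the right ballpark
  or_hat <- r$odds_ratio[r$set_label == "C14" & r$stratum == "sCHD"]
  expect_gt(or_hat, 1.9)
  expect_lt(or_hat, 2.7)
})

test_that("null cohorts show no monotone trend of OR across bins", {
  # counts must be dense enough for stable per-bin estimates: with only a
  # handful of case carrier events per bin, zero-count bins produce
  # extreme negative log-ORs and any size imbalance masquerades as trend
  ors <- NULL
  bins_idx <- NULL
  for (s in 1:20) {
    co <- simulate_cohort(sim_config(
      n_schd = 400L, n_nschd = 150L, n_control = 2500L, n_genes = 500L,
      baseline_carrier_rate = 2e-3, seed = 3000 + s))
    sets <- bins_as_gene_sets(make_constraint_bins(co$genes, "loeuf"))
    gs <- run_geneset_battery(co, sets, strata = "sCHD",
                              categories = "hcLOF")
    ors <- c(ors, gs$results$odds_ratio)
    bins_idx <- c(bins_idx, seq_along(sets))
  }
  keep <- is.finite(ors)
  ct <- suppressWarnings(cor.test(bins_idx[keep], ors[keep],
                                  method = "spearman"))
  expect_gt(ct$p.value, 0.05)
  expect_lt(abs(unname(ct$estimate)), 0.3)
})

test_that("unknown sex is imputed to the majority and counted", {
  co <- tiny_cohort()
  co$samples$sex[1] <- "unknown"
  sets <- list(all = c("G1", "GX"))
  gs <- suppressWarnings(run_geneset_battery(co, sets, strata = "sCHD",
                                             categories = "synonymous"))
  expect_equal(gs$n_sex_imputed, 1L)
})
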