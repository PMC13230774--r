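test_that("genotype QC enforces DP, GQ and the strict het AB rule", {
  gt <- data.frame(
    zygosity = c("het", "hom_alt", "het", "het", "missing", "hemizygous"),
    dp = c(9L, 10L, 30L, 30L, 50L, 15L),
    gq = c(50L, 20L, 60L, 60L, 99L, 40L),
    ab = c(0.5, NA, 0.2, 0.21, 0.5, NA))
  expect_equal(qc_genotype(gt),
               c(FALSE,  # DP 9 < 10
                 TRUE,   # AB rule applies to het only
                 FALSE,  # AB exactly 0.2 fails the strict > 0.2
                 TRUE, FALSE, TRUE))
})

test_that("carrier counting deduplicates, gates on QC and rarity, and
           counts hemizygous X genotypes", {
  co <- tiny_cohort()
  # s1 het at two hcLOF sites counts once; s2 fails DP; s4 is hom_alt
  expect_equal(count_carriers(co, "G1", "hcLOF", "sCHD"), 1L)
  # male hemizygous X carrier
  expect_equal(count_carriers(co, "GX", "hcLOF", "sCHD"), 1L)
  # c1 fails AB = 0.2, c2's variant is common, c4 is a het carrier
  expect_equal(count_carriers(co, "G1", "hcLOF", "control"), 1L)
  expect_equal(count_carriers(co, "G1", "missC", "nsCHD"), 1L)
  expect_equal(count_carriers(co, "G1", "synonymous", "control"), 1L)
  expect_error(count_carriers(co, "NOPE", "hcLOF", "sCHD"),
               "unknown gene_id")
})

test_that("one-sided Fisher burden equals the hypergeometric tail", {
  expect_equal(fisher_burden(3, 100, 0, 100),
               (100 / 200) * (99 / 199) * (98 / 198), tolerance = 1e-12)
  expect_equal(fisher_burden(0, 1818, 5, 52881), 1.0)
  expect_equal(fisher_burden(8, 1818, 0, 52881),
               brute_fisher_tail(8, 1818, 0, 52881), tolerance = 1e-15)
  expect_error(fisher_burden(5, 4, 0, 10), "inconsistent")
  # cross-check against the generic implementation in stats
  for (tab in list(c(3, 50, 1, 60), c(0, 10, 4, 40), c(7, 30, 7, 30))) {
    ft <- fisher.test(matrix(c(tab[1], tab[2] - tab[1],
                               tab[3], tab[4] - tab[3]), 2,
                             byrow = TRUE), alternative = "greater")
    expect_equal(fisher_burden(tab[1], tab[2], tab[3], tab[4]),
                 ft$p.value, tolerance = 1e-12)
  }
})

test_that("adding a case carrier never increases the one-sided p", {
  set.seed(3)
  for (i in 1:100) {
    n_case <- sample(10:200, 1)
    n_ctrl <- sample(10:2000, 1)
    kc <- sample(0:(n_case - 1), 1)
    k0 <- sample(0:n_ctrl, 1)
    expect_lte(fisher_burden(kc + 1, n_case, k0, n_ctrl),
               fisher_burden(kc, n_case, k0, n_ctrl) + 1e-15)
  }
})

test_that("minimal p selection keeps the category label and tie rule", {
  expect_equal(minimal_p(1e-8, 1e-3),
               data.frame(p_min = 1e-8, min_category = "hcLOF",
                          stringsAsFactors = FALSE))
  expect_equal(minimal_p(1, 1)$min_category, "hcLOF")
  expect_equal(minimal_p(0.5, 1e-4),
               data.frame(p_min = 1e-4, min_category = "missC",
                          stringsAsFactors = FALSE))
})

test_that("Bonferroni with the study factor reproduces printed values", {
  cfg <- mt_config()  # 2 x 16,351
  expect_equal(cfg$n_tests, 32702L)
  expect_equal(signif(adjust_bonferroni(9.76e-13, cfg), 3), 3.19e-8)
  expect_equal(adjust_bonferroni(3.15e-5, cfg), 1.0)
  expect_equal(adjust_bonferroni(1.0, cfg), 1.0)
})

test_that("BH step-up matches its brute-force definition", {
  cfg <- mt_config()
  expect_equal(adjust_bh(1e-6, cfg), 1e-6 * 32702)
  set.seed(17)
  for (i in 1:25) {
    k <- sample(1:50, 1)
    p <- 10^runif(k, -8, 0)
    expect_equal(adjust_bh(p, cfg), brute_bh(p, 32702), tolerance = 1e-12)
  }
  expect_error(adjust_bh(rep(0.5, 10), mt_config(n_genes_tested = 2,
                                                 n_categories = 1)),
               "n_tests")
})

test_that("null cohorts give no family-wise error in most runs", {
  hits <- vapply(1:20, function(s) {
    co <- small_sim(seed = 1000 + s, n_case = 150L, n_control = 1200L,
                    n_genes = 250L)
    gb <- run_gene_burden(co)
    sum(gb$results$p_bonferroni < 0.05)
  }, numeric(1))
  expect_gte(mean(hits == 0), 0.95)
})

test_that("a strongly enriched gene attains the smallest minimal p", {
  planted <- data.frame(target = "G00010", category = "hcLOF",
                        stratum = "sCHD", or = 20)
  co <- simulate_cohort(sim_config(
    n_schd = 2000L, n_nschd = 500L, n_control = 20000L, n_genes = 300L,
    planted_effects = planted, seed = 404))
  gb <- run_gene_burden(co)
  r <- gb$results[gb$results$stratum == "sCHD", ]
  expect_equal(r$gene_id[which.min(r$p_min)], "G00010")
  expect_equal(r$min_category[which.min(r$p_min)], "hcLOF")
})

test_that("synonymous burden p-values stay on the calibration track and
           behave conservatively under the null", {
  co <- small_sim(seed = 77, n_case = 200L, n_control = 1500L,
                  n_genes = 300L)
  gb <- run_gene_burden(co)
  expect_false("synonymous" %in% gb$results$min_category)
  p <- gb$synonymous$p[gb$synonymous$stratum == "sCHD"]
  expect_true(all(p > 0 & p <= 1))
  # discrete one-sided tests are stochastically >= uniform: the observed
  # quantiles sit at or above the uniform ones
  qs <- quantile(p, c(0.1, 0.25, 0.5))
  expect_true(all(qs >= c(0.1, 0.25, 0.5) - 0.05))
})

test_that("recessive carriers are homozygotes or unphased compound hets", {
  co <- tiny_cohort()
  rb <- recessive_burden(co)
  r <- rb$results
  # sCHD: s4 is hom_alt and s1 holds two distinct rare hcLOF hets (the
  # unphased compound-het proxy); control: c4 with two distinct hets
  expect_equal(r$carriers_case[r$stratum == "sCHD" & r$gene_id == "G1"], 2L)
  expect_equal(r$carriers_ctrl[r$stratum == "sCHD" & r$gene_id == "G1"], 1L)
  # the single-het missC carrier n1 is not a recessive carrier
  expect_equal(r$carriers_case[r$stratum == "nsCHD" & r$gene_id == "G1"], 0L)
})

test_that("recessive analysis on a null cohort finds nothing significant", {
  co <- small_sim(seed = 2024, n_case = 300L, n_control = 2000L,
                  n_genes = 300L)
  rb <- recessive_burden(co)
  if (nrow(rb$results)) {
    expect_true(all(rb$results$p_bonferroni >= 0.05))
  } else {
    succeed("no recessive carriers arose under the null")
  }
})
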