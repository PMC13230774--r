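mk_var <- function(consequence = "missense", lof_hc = FALSE, cadd = NA,
                   revel = NA, mvp = NA, af = list()) {
  v <- data.frame(chrom = "1", pos = 1L, ref = "A", alt = "G",
                  gene_id = "G", consequence = consequence,
                  lof_hc = lof_hc, cadd = cadd, revel = revel, mvp = mvp,
                  af_internal = NA_real_, af_gnomad_exomes = NA_real_,
                  af_gnomad_genomes = NA_real_, af_rumc = NA_real_,
                  af_inhouse = NA_real_, stringsAsFactors = FALSE)
  for (nm in names(af)) v[[nm]] <- af[[nm]]
  v
}

test_that("hcLOF requires both a LOF consequence and the HC flag", {
  expect_true(is_hclof(mk_var("stop_gained", lof_hc = TRUE)))
  expect_false(is_hclof(mk_var("stop_gained", lof_hc = FALSE)))
  expect_false(is_hclof(mk_var("missense", lof_hc = FALSE)))
  expect_true(is_hclof(mk_var("frameshift", lof_hc = TRUE)))
  expect_true(is_hclof(mk_var("essential_splice", lof_hc = TRUE)))
})

test_that("missC applies the 2-of-3 rule with missing scores failing", {
  cfg <- category_config()
  expect_true(is_missc(mk_var(cadd = 25, revel = 0.61, mvp = 0.10), cfg))
  expect_false(is_missc(mk_var(cadd = 30, revel = 0.40, mvp = 0.50), cfg))
  expect_true(is_missc(mk_var(cadd = NA, revel = 0.9, mvp = 0.9), cfg))
  expect_false(is_missc(mk_var(cadd = NA, revel = NA, mvp = 0.9), cfg))
  # thresholds are inclusive
  expect_true(is_missc(mk_var(cadd = 24, revel = 0.5, mvp = 0), cfg))
  # non-missense never qualifies, whatever the scores
  expect_false(is_missc(mk_var("synonymous", cadd = 99, revel = 1,
                               mvp = 1), cfg))
})

test_that("rarity requires every present AF source below the threshold", {
  cfg <- category_config()
  expect_false(is_rare(mk_var(af = list(af_gnomad_exomes = 0.0015,
                                        af_internal = 0, af_rumc = 0)),
                       cfg))
  expect_true(is_rare(mk_var(), cfg))           # all sources absent
  expect_true(is_rare(mk_var(af = list(af_internal = 0)), cfg))
  expect_false(is_rare(mk_var(af = list(af_internal = 0.002,
                                        af_gnomad_exomes = 0)), cfg))
  # strict inequality at the boundary
  expect_false(is_rare(mk_var(af = list(af_internal = 0.001)), cfg))
})

test_that("every variant maps to exactly one category", {
  expect_equal(as.character(variant_category(
    mk_var("frameshift", lof_hc = TRUE))), "hcLOF")
  expect_equal(as.character(variant_category(mk_var("synonymous"))),
               "synonymous")
  expect_equal(as.character(variant_category(
    mk_var(cadd = 30, revel = 0.1, mvp = 0.1))), "none")
  # property: a partition over many random variants
  set.seed(11)
  n <- 500
  v <- do.call(rbind, replicate(1, mk_var(), simplify = FALSE))
  v <- v[rep(1, n), ]
  v$consequence <- sample(c("stop_gained", "frameshift",
                            "essential_splice", "missense", "synonymous",
                            "other"), n, replace = TRUE)
  v$lof_hc <- v$consequence %in% c("stop_gained", "frameshift",
                                   "essential_splice") &
    runif(n) < 0.5
  v$cadd <- ifelse(runif(n) < 0.2, NA, runif(n, 0, 40))
  v$revel <- ifelse(runif(n) < 0.2, NA, runif(n))
  v$mvp <- ifelse(runif(n) < 0.2, NA, runif(n))
  cats <- variant_category(v)
  expect_false(anyNA(cats))
  expect_true(all(as.character(cats) %in%
                    c("hcLOF", "missC", "synonymous", "none")))
  # mutual exclusivity with the predicates
  expect_equal(cats == "hcLOF", is_hclof(v))
  expect_equal(cats == "missC", is_missc(v) & !is_hclof(v))
})

test_that("raising a score never demotes a missense variant", {
  set.seed(7)
  cfg <- category_config()
  for (i in 1:50) {
    v <- mk_var(cadd = runif(1, 0, 40), revel = runif(1), mvp = runif(1))
    before <- is_missc(v, cfg)
    v2 <- v
    col <- sample(c("cadd", "revel", "mvp"), 1)
    v2[[col]] <- v2[[col]] + runif(1, 0, 20)
    expect_true(is_missc(v2, cfg) >= before)
  }
})

test_that("rank-based AUC matches brute-force pair enumeration", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    path <- runif(n) < 0.4
    if (!any(path) || all(path)) next
    scores <- round(rnorm(n), sample(0:2, 1))  # induce ties
    expect_equal(roc_auc(scores, path), brute_auc(scores, path),
                 tolerance = 1e-12)
  }
})

test_that("score threshold selection reproduces separation and null cases", {
  set.seed(5)
  # perfectly separated: AUC 1 in both strata
  n <- 200
  lab <- rep(c("benign", "pathogenic"), each = n)
  df <- data.frame(label = lab,
                   gene_loeuf = rep_len(c(0.1, 0.8), 2 * n),
                   s = c(runif(n, 0, 1), runif(n, 2, 3)))
  rep1 <- select_score_thresholds(df)
  expect_equal(rep1$auc_constrained, 1)
  expect_equal(rep1$auc_nonconstrained, 1)
  expect_true(rep1$qualifies)

  # labels independent of the score: AUC near 1/2, not qualifying
  df$s <- runif(2 * n)
  df2 <- df[sample(nrow(df)), ]
  df2 <- df2[rep(seq_len(nrow(df2)), 5), ]  # n = 2000
  rep2 <- select_score_thresholds(df2)
  expect_lt(abs(rep2$auc_constrained - 0.5), 0.05)
  expect_lt(abs(rep2$auc_nonconstrained - 0.5), 0.05)
  expect_false(rep2$qualifies)
})

test_that("Youden threshold lands at the equal-variance Gaussian midpoint", {
  set.seed(9)
  n <- 5000
  df <- data.frame(
    label = rep(c("benign", "pathogenic"), each = 2 * n),
    gene_loeuf = rep_len(c(0.1, 0.8), 4 * n),
    s = c(rnorm(2 * n, 0, 1), rnorm(2 * n, 2, 1)))
  rep3 <- select_score_thresholds(df)
  expect_lt(abs(rep3$threshold - 1.0), 0.15)
})

test_that("a single-class stratum is an error naming the stratum", {
  df <- data.frame(label = c("benign", "benign", "pathogenic"),
                   gene_loeuf = c(0.1, 0.8, 0.8),
                   s = c(1, 2, 3))
  expect_error(select_score_thresholds(df), "stratum LOEUF < 0.35")
})
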