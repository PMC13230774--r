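# Independent oracles and hand-built fixtures shared across test files.
# Each oracle is deliberately naive (enumeration / direct definition) and
# never calls the implementation path it checks.

# AUC as the proportion of (pathogenic, benign) pairs correctly ordered,
# ties counting one half, by explicit enumeration over all pairs.
brute_auc <- function(scores, pathogenic) {
  sp <- scores[pathogenic]
  sb <- scores[!pathogenic]
  tot <- 0
  for (a in sp) tot <- tot + sum(a > sb) + 0.5 * sum(a == sb)
  tot / (length(sp) * length(sb))
}

# BH step-up by its definition: rank i gets min over j >= i of
# min(1, p_(j) * n / j), reported in input order.
brute_bh <- function(p, n) {
  o <- order(p)
  ps <- p[o]
  k <- length(p)
  adj <- numeric(k)
  for (i in seq_len(k)) {
    adj[i] <- min(pmin(1, ps[i:k] * n / (i:k)))
  }
  out <- numeric(k)
  out[o] <- adj
  out
}

# One-sided Fisher tail by direct summation of hypergeometric point masses
# over all tables at least as case-enriched as observed.
brute_fisher_tail <- function(kc, n_case, k0, n_ctrl) {
  K <- kc + k0
  kk <- kc:min(K, n_case)
  sum(stats::dhyper(kk, n_case, n_ctrl, K))
}

# Deterministic Newton-Raphson logistic MLE (independent of stats::glm).
newton_logistic <- function(X, y, tol = 1e-12, maxit = 200L) {
  X <- cbind(1, as.matrix(X))
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    grad <- drop(crossprod(X, y - mu))
    H <- crossprod(X * w, X)
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  beta
}

# Hand-built six-teen-call cohort exercising every carrier-counting rule:
# QC gates, per-sample dedup, hemizygous X, hom_alt exclusion from the
# dominant model, compound-het recessive proxy, rarity filtering.
tiny_cohort <- function() {
  variants <- data.frame(
    chrom = c("1", "1", "1", "1", "1", "1", "X"),
    pos = c(101, 102, 103, 104, 105, 106, 501),
    ref = "A", alt = "G",
    gene_id = c(rep("G1", 6), "GX"),
    consequence = c("stop_gained", "frameshift", "missense", "synonymous",
                    "missense", "stop_gained", "stop_gained"),
    lof_hc = c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE),
    cadd = c(NA, NA, 25, NA, 12, NA, NA),
    revel = c(NA, NA, 0.61, NA, 0.1, NA, NA),
    mvp = c(NA, NA, 0.10, NA, 0.2, NA, NA),
    af_internal = c(1e-4, 1e-4, 2e-4, 3e-4, 2e-4, 0.01, 1e-4),
    af_gnomad_exomes = NA_real_, af_gnomad_genomes = NA_real_,
    af_rumc = NA_real_, af_inhouse = NA_real_,
    stringsAsFactors = FALSE)
  vid <- variant_key(variants$chrom, variants$pos, variants$ref,
                     variants$alt)
  g <- function(s, v, z, dp = 40L, gq = 90L, ab = 0.5) {
    data.frame(sample_id = s, variant_id = vid[v], zygosity = z,
               dp = dp, gq = gq, ab = ab, stringsAsFactors = FALSE)
  }
  genotypes <- rbind(
    g("s1", 1, "het"),              # hcLOF carrier, sCHD
    g("s1", 2, "het"),              # same sample, second hcLOF site
    g("s2", 1, "het", dp = 9L),     # fails DP
    g("s3", 7, "hemizygous"),       # male X carrier
    g("s4", 1, "hom_alt", ab = 0.98), # recessive, not dominant
    g("n1", 3, "het"),              # missC carrier, nsCHD
    g("c1", 1, "het", ab = 0.2),    # fails strict AB > 0.2
    g("c2", 6, "het"),              # common variant, filtered by rarity
    g("c3", 4, "het"),              # synonymous carrier, control
    g("c4", 1, "het"),              # first of a compound-het pair
    g("c4", 3, "het"))              # second, distinct variant, same gene
  samples <- data.frame(
    sample_id = c("s1", "s2", "s3", "s4", "n1", "c1", "c2", "c3", "c4"),
    stratum = c("sCHD", "sCHD", "sCHD", "sCHD", "nsCHD",
                "control", "control", "control", "control"),
    sex = c("female", "female", "male", "female", "male",
            "female", "male", "female", "female"),
    pc1 = 0, pc2 = 0, pc3 = 0, pc4 = 0, pc5 = 0,
    stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = c("G1", "GX"), symbol = c("G1", "GX"),
                      chrom = c("1", "X"), loeuf = c(0.2, 0.3),
                      moeuf = c(0.5, 0.4), stringsAsFactors = FALSE)
  chd_cohort(variants, genotypes, samples, genes)
}

# Small null/planted simulated cohorts used by several files.
small_sim <- function(seed, n_case = 200L, n_control = 1500L,
                      n_genes = 300L, planted = NULL) {
  simulate_cohort(sim_config(
    n_schd = n_case, n_nschd = n_case, n_control = n_control,
    n_genes = n_genes, planted_effects = planted, seed = seed))
}
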