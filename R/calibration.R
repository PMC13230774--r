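## Negative-control calibration: genomic inflation lambda and its
## 1000-case/1000-control rescaling, QQ statistics, label-permutation
## nulls, MAF-stratified synonymous diagnostics.

CHISQ1_MEDIAN <- stats::qchisq(0.5, df = 1)  # 0.4549364...

#' Genomic inflation factor lambda_GC
#'
#' Median of the 1-df chi-square quantile transform of the p-values,
#' divided by the theoretical chi-square(1) median.
#'
#' @param p_values numeric vector in (0, 1].
#' @return lambda (1 under a uniform null).
#' @export
lambda_gc <- function(p_values) {
  if (length(p_values) == 0L) stop("empty p-value vector", call. = FALSE)
  stopifnot(all(p_values > 0 & p_values <= 1))
  chi <- stats::qchisq(p_values, df = 1, lower.tail = FALSE)
  stats::median(chi) / CHISQ1_MEDIAN
}

#' Rescale lambda to a 1000-case / 1000-control study
#'
#' `lambda_1000 = 1 + (lambda - 1) * (1/n_case + 1/n_control) /
#' (1/1000 + 1/1000)`. Linear in lambda; equals lambda exactly when both
#' arms are 1000 and fixes lambda = 1.
#'
#' @param lambda observed inflation factor (> 0).
#' @param n_case,n_control analysed arm sizes (>= 1).
#' @return rescaled inflation factor.
#' @export
lambda_1000 <- function(lambda, n_case, n_control) {
  ## lambda = 0 arises for fully degenerate discrete p-vectors (all p = 1)
  stopifnot(lambda >= 0, n_case >= 1, n_control >= 1)
  1 + (lambda - 1) * (1 / n_case + 1 / n_control) / (2 / 1000)
}

#' QQ points for a p-value vector
#'
#' Expected quantiles are `-log10((i - 0.5) / n)` for the ascending
#' observed p-values (convention fixed here and used by the QQ plot).
#'
#' @param p_values numeric vector in (0, 1].
#' @return data.frame `expected`, `observed` (-log10 scale), sorted by
#'   expected.
#' @export
qq_points <- function(p_values) {
  stopifnot(length(p_values) > 0, all(p_values > 0 & p_values <= 1))
  n <- length(p_values)
  obs <- sort(p_values, decreasing = TRUE)
  exp_p <- (n - seq_len(n) + 0.5) / n
  out <- data.frame(expected = -log10(exp_p), observed = -log10(obs))
  out[order(out$expected), , drop = FALSE]
}

## Permute the case/control structure of a cohort. Stratified mode
## reassigns the multiset of stratum labels at random (preserving the
## sCHD/nsCHD split); unstratified mode preserves only the total case
## count, resampling which cases are syndromic.
permute_labels <- function(samples, stratified = TRUE) {
  out <- samples
  if (stratified) {
    out$stratum <- sample(samples$stratum)
  } else {
    is_case <- samples$stratum != "control"
    new_case <- sample(nrow(samples), sum(is_case))
    lab <- rep("control", nrow(samples))
    lab[new_case] <- sample(c("sCHD", "nsCHD"), length(new_case),
                            replace = TRUE)
    out$stratum <- lab
  }
  out
}

#' Label-permutation null for the burden pipeline
#'
#' Re-runs the chosen test statistic pipeline on cohorts whose case/control
#' labels have been permuted (stratified by default: the sCHD/nsCHD split
#' is preserved), and returns the permutation distribution of lambda_GC
#' together with the observed value's empirical percentile. Genotypes and
#' the label multiset are untouched; the whole procedure is reproducible
#' from `seed`.
#'
#' @param cohort a `chd_cohort`.
#' @param test "gene" (per-gene Fisher minimal-P pipeline) or "geneset"
#'   (logistic battery over the supplied `sets`).
#' @param stratum which case stratum's p-values feed lambda ("sCHD" or
#'   "nsCHD"; "aCHD" allowed for test = "geneset").
#' @param category variant category whose p-values are calibrated; default
#'   "synonymous", the negative control.
#' @param sets gene sets for test = "geneset".
#' @param n_perm number of permutations (>= 1).
#' @param seed integer RNG seed (mandatory).
#' @param stratified preserve the sCHD/nsCHD split when permuting.
#' @param cfg a [category_config()].
#' @return object of class `chd_calibration` with fields `lambda_gc`,
#'   `lambda_1000`, `n_case`, `n_control`, `qq_points`,
#'   `permutation_lambdas`, `observed_percentile`, `n_permutations`,
#'   `seed`.
#' @export
permutation_null <- function(cohort, test = c("gene", "geneset"),
                             stratum = "sCHD", category = "synonymous",
                             sets = NULL, n_perm = 100L, seed,
                             stratified = TRUE, cfg = category_config()) {
  test <- match.arg(test)
  stopifnot(n_perm >= 1L)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)

  statistic <- function(co) {
    if (test == "gene") {
      gb <- run_gene_burden(co, cfg)
      if (category == "synonymous") {
        gb$synonymous$p[gb$synonymous$stratum == stratum]
      } else {
        gb$results$p_min[gb$results$stratum == stratum]
      }
    } else {
      if (is.null(sets)) stop("sets required for test = 'geneset'",
                              call. = FALSE)
      gs <- run_geneset_battery(cohort = co, sets = sets,
                                strata = stratum, categories = category,
                                cfg = cfg)
      p <- gs$results$p
      p[!is.na(p)]
    }
  }

  p_obs <- statistic(cohort)
  lam_obs <- lambda_gc(p_obs)
  n_case <- if (stratum == "aCHD") {
    sum(cohort$samples$stratum %in% c("sCHD", "nsCHD"))
  } else {
    sum(cohort$samples$stratum == stratum)
  }
  n_control <- sum(cohort$samples$stratum == "control")

  set.seed(seed)
  lams <- vapply(seq_len(n_perm), function(i) {
    co <- cohort
    co$samples <- permute_labels(cohort$samples, stratified)
    lambda_gc(statistic(co))
  }, numeric(1L))

  structure(list(lambda_gc = lam_obs,
                 lambda_1000 = lambda_1000(lam_obs, n_case, n_control),
                 n_case = n_case, n_control = n_control,
                 qq_points = qq_points(p_obs),
                 permutation_lambdas = lams,
                 observed_percentile = mean(lams <= lam_obs),
                 n_permutations = as.integer(n_perm),
                 seed = seed),
            class = "chd_calibration")
}

#' @export
print.chd_calibration <- function(x, ...) {
  cat("chd_calibration\n")
  cat(sprintf("  lambda_GC = %.4f (lambda_1000 = %.4f; %d cases / %d controls)\n",
              x$lambda_gc, x$lambda_1000, x$n_case, x$n_control))
  cat(sprintf("  %d label permutations: lambda in [%.3f, %.3f], observed at percentile %.2f\n",
              x$n_permutations, min(x$permutation_lambdas),
              max(x$permutation_lambdas), x$observed_percentile))
  invisible(x)
}

#' QQ plot of observed vs expected -log10 p
#'
#' @param x a `chd_calibration`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.chd_calibration <- function(x, ...) {
  qq <- x$qq_points
  lim <- range(c(qq$expected, qq$observed))
  graphics::plot(qq$expected, qq$observed, xlim = lim, ylim = lim,
                 xlab = expression(Expected ~ -log[10](p)),
                 ylab = expression(Observed ~ -log[10](p)),
                 pch = 16, cex = 0.6, ...)
  graphics::abline(0, 1, col = "red", lty = 2)
  graphics::legend("topleft", bty = "n",
                   legend = sprintf("lambda = %.3f", x$lambda_gc))
  invisible(x)
}

#' MAF-stratified synonymous calibration
#'
#' Recomputes the synonymous gene-level burden p-values restricting to
#' variants whose allele frequency falls in each MAF bin, and reports
#' lambda_GC per bin and stratum. A variant's binning frequency is the
#' maximum AF across its present sources (the same quantity the rarity
#' filter bounds); the first bin is closed on the left so AF = 0 singletons
#' are assigned. Empty bins are reported with NA lambda.
#'
#' @param cohort a `chd_cohort`.
#' @param maf_breaks strictly ascending break vector (e.g. `c(0, 1e-4,
#'   1e-3)` gives bins [0, 1e-4] and (1e-4, 1e-3]).
#' @param cfg a [category_config()].
#' @return data.frame `bin`, `maf_low`, `maf_high`, `stratum`,
#'   `n_variants`, `n_genes`, `lambda`.
#' @export
maf_stratified_synonymous <- function(cohort, maf_breaks = c(0, 1e-4, 1e-3),
                                      cfg = category_config()) {
  if (is.unsorted(maf_breaks, strictly = TRUE)) {
    stop("maf_breaks must be strictly ascending", call. = FALSE)
  }
  v <- cohort$variants
  af <- suppressWarnings(
    apply(as.matrix(v[, AF_COLUMNS]), 1L, max, na.rm = TRUE))
  af[!is.finite(af)] <- 0
  syn <- v$consequence == "synonymous"
  bin_of <- cut(af, breaks = maf_breaks, include.lowest = TRUE,
                labels = FALSE)
  n_by_stratum <- table(factor(cohort$samples$stratum, levels = STRATA))
  q <- qualifying_genotypes(cohort, cfg)
  q <- q[q$category == "synonymous" &
           q$zygosity %in% c("het", "hemizygous"), , drop = FALSE]
  q$bin <- bin_of[match(q$variant_id, v$variant_id)]

  out <- list()
  for (b in seq_len(length(maf_breaks) - 1L)) {
    vb <- sum(syn & !is.na(bin_of) & bin_of == b)
    qb <- q[!is.na(q$bin) & q$bin == b, , drop = FALSE]
    genes <- sort(unique(v$gene_id[syn & !is.na(bin_of) & bin_of == b]))
    for (st in c("sCHD", "nsCHD")) {
      lam <- NA_real_
      if (length(genes) && nrow(qb)) {
        u <- qb[!duplicated(paste(qb$sample_id, qb$gene_id)), , drop = FALSE]
        kc <- as.integer(table(factor(u$gene_id[u$stratum == st],
                                      levels = genes)))
        k0 <- as.integer(table(factor(u$gene_id[u$stratum == "control"],
                                      levels = genes)))
        p <- fisher_burden(kc, as.integer(n_by_stratum[[st]]),
                           k0, as.integer(n_by_stratum[["control"]]))
        lam <- lambda_gc(p)
      }
      out[[length(out) + 1L]] <- data.frame(
        bin = b, maf_low = maf_breaks[b], maf_high = maf_breaks[b + 1L],
        stratum = st, n_variants = vb, n_genes = length(genes),
        lambda = lam)
    }
  }
  do.call(rbind, out)
}
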