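## Variant categorisation: hcLOF / missC / synonymous / none, the rarity
## filter, and the ROC machinery used to pick the missense score thresholds.

#' Category configuration for variant classification
#'
#' Defaults encode the ensemble missense rule (a missense variant is
#' constrained, "missC", when at least 2 of CADD >= 24, REVEL >= 0.5,
#' MVP >= 0.8 hold) and the rarity threshold MAF < 0.001 applied to every
#' allele-frequency source. Score thresholds are inclusive; a missing score
#' never counts as passing.
#'
#' @param cadd_threshold,revel_threshold,mvp_threshold score cut-offs.
#' @param min_scores_passing how many of the three scores must pass (1-3).
#' @param rare_maf strict upper bound on every present allele frequency.
#' @return list of class `category_config`.
#' @export
category_config <- function(cadd_threshold = 24, revel_threshold = 0.5,
                            mvp_threshold = 0.8, min_scores_passing = 2L,
                            rare_maf = 0.001) {
  stopifnot(is.finite(cadd_threshold), is.finite(revel_threshold),
            is.finite(mvp_threshold),
            min_scores_passing %in% 1:3,
            is.finite(rare_maf), rare_maf > 0)
  structure(list(cadd_threshold = cadd_threshold,
                 revel_threshold = revel_threshold,
                 mvp_threshold = mvp_threshold,
                 min_scores_passing = as.integer(min_scores_passing),
                 rare_maf = rare_maf),
            class = "category_config")
}

#' High-confidence loss-of-function predicate
#'
#' TRUE iff the consequence is stop_gained, frameshift or essential_splice
#' AND the upstream LOFTEE-style high-confidence flag is set.
#'
#' @param variants variant data.frame (columns `consequence`, `lof_hc`).
#' @return logical vector.
#' @export
is_hclof <- function(variants) {
  variants$consequence %in% LOF_CONSEQUENCES &
    !is.na(variants$lof_hc) & variants$lof_hc
}

#' Constrained-missense (missC) predicate
#'
#' Applies the 2-of-3 ensemble rule over CADD/REVEL/MVP with inclusive
#' thresholds. Non-missense variants are FALSE; missing scores count as not
#' passing.
#'
#' @param variants variant data.frame.
#' @param cfg a [category_config()].
#' @return logical vector.
#' @export
is_missc <- function(variants, cfg = category_config()) {
  pass <- function(x, thr) !is.na(x) & x >= thr
  n_pass <- pass(variants$cadd, cfg$cadd_threshold) +
    pass(variants$revel, cfg$revel_threshold) +
    pass(variants$mvp, cfg$mvp_threshold)
  variants$consequence == "missense" & n_pass >= cfg$min_scores_passing
}

#' Rarity predicate across all allele-frequency sources
#'
#' TRUE iff every present AF (internal plus all external sources) is
#' strictly below `cfg$rare_maf`. Absent sources impose no constraint, so a
#' variant with no AF at all is rare.
#'
#' @inheritParams is_missc
#' @return logical vector.
#' @export
is_rare <- function(variants, cfg = category_config()) {
  rare <- rep(TRUE, nrow(variants))
  for (af in intersect(AF_COLUMNS, names(variants))) {
    v <- variants[[af]]
    rare <- rare & (is.na(v) | v < cfg$rare_maf)
  }
  rare
}

#' Assign each variant to its analysis category
#'
#' Mutually exclusive assignment: hcLOF takes precedence, then missC, then
#' synonymous; anything else is `none`. Rarity is a separate filter (see
#' [is_rare()]), not part of the category.
#'
#' @inheritParams is_missc
#' @return factor with levels hcLOF, missC, synonymous, none.
#' @export
variant_category <- function(variants, cfg = category_config()) {
  out <- rep("none", nrow(variants))
  out[variants$consequence == "synonymous"] <- "synonymous"
  out[is_missc(variants, cfg)] <- "missC"
  out[is_hclof(variants)] <- "hcLOF"
  factor(out, levels = c("hcLOF", "missC", "synonymous", "none"))
}

#' Rank-based (midrank) ROC AUC
#'
#' Equals the proportion of (pathogenic, benign) pairs ordered correctly,
#' counting ties as half.
#'
#' @param scores numeric vector.
#' @param pathogenic logical vector, same length.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, pathogenic) {
  stopifnot(length(scores) == length(pathogenic))
  keep <- is.finite(scores)
  scores <- scores[keep]
  pathogenic <- pathogenic[keep]
  n1 <- sum(pathogenic)
  n0 <- sum(!pathogenic)
  if (n1 == 0L || n0 == 0L) stop("both classes required for AUC",
                                 call. = FALSE)
  r <- rank(scores)  # midranks for ties
  (sum(r[pathogenic]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Youden-optimal threshold
#'
#' Maximises J(t) = sensitivity(t) + specificity(t) - 1 for the rule
#' "call pathogenic when score >= t", over the observed score values.
#' Ties resolve to the smallest qualifying threshold.
#'
#' @inheritParams roc_auc
#' @return the optimal threshold (a score value).
#' @export
youden_threshold <- function(scores, pathogenic) {
  keep <- is.finite(scores)
  scores <- scores[keep]
  pathogenic <- pathogenic[keep]
  thr <- sort(unique(scores))
  n1 <- sum(pathogenic)
  n0 <- sum(!pathogenic)
  if (n1 == 0L || n0 == 0L) stop("both classes required", call. = FALSE)
  ## counts of observations >= t, per class, via reverse cumulative sums
  ord <- order(scores)
  s <- scores[ord]
  p <- pathogenic[ord]
  idx <- findInterval(thr, s, left.open = TRUE) # observations < t
  cum_p <- c(0, cumsum(p))
  cum_n <- c(0, cumsum(!p))
  sens <- (n1 - cum_p[idx + 1L]) / n1
  spec <- cum_n[idx + 1L] / n0
  j <- sens + spec - 1
  thr[which.max(j)]  # first max = smallest threshold
}

#' ROC-based selection of missense score thresholds
#'
#' Reproduces the score-vetting step: for each candidate deleteriousness
#' score, the AUC separating benign from pathogenic missense variants is
#' computed separately in LOF-constrained genes (LOEUF < 0.35) and
#' non-constrained genes (LOEUF >= 0.35). A score qualifies when both AUCs
#' exceed 0.9; its working threshold is the Youden-optimal point on the
#' pooled set. Scores evaluated but not qualifying (e.g. an MPC column) are
#' reported with `qualifies = FALSE` and are never used by
#' [variant_category()].
#'
#' @param labeled data.frame with a `label` column ("benign"/"pathogenic"),
#'   a `gene_loeuf` column, and one numeric column per score.
#' @param scores character vector of score column names; defaults to every
#'   numeric column other than `gene_loeuf`.
#' @param loeuf_cut stratification cut-point (default 0.35).
#' @param auc_min qualification bound on both per-stratum AUCs.
#' @return data.frame with one row per score: `score_name`,
#'   `auc_constrained`, `auc_nonconstrained`, `qualifies`, `threshold`.
#' @export
select_score_thresholds <- function(labeled, scores = NULL,
                                    loeuf_cut = 0.35, auc_min = 0.9) {
  stopifnot(all(c("label", "gene_loeuf") %in% names(labeled)))
  stopifnot(all(labeled$label %in% c("benign", "pathogenic")))
  if (is.null(scores)) {
    num <- vapply(labeled, is.numeric, logical(1L))
    scores <- setdiff(names(labeled)[num], "gene_loeuf")
  }
  pathogenic <- labeled$label == "pathogenic"
  constrained <- labeled$gene_loeuf < loeuf_cut
  out <- lapply(scores, function(s) {
    x <- labeled[[s]]
    keep <- is.finite(x)
    for (stratum in c(TRUE, FALSE)) {
      cls <- pathogenic[keep & constrained == stratum]
      if (length(unique(cls)) < 2L) {
        stop(sprintf(
          "score %s: stratum LOEUF %s %.2f contains a single class",
          s, if (stratum) "<" else ">=", loeuf_cut), call. = FALSE)
      }
    }
    auc_c <- roc_auc(x[constrained], pathogenic[constrained])
    auc_n <- roc_auc(x[!constrained], pathogenic[!constrained])
    data.frame(score_name = s,
               auc_constrained = auc_c,
               auc_nonconstrained = auc_n,
               qualifies = min(auc_c, auc_n) > auc_min,
               threshold = youden_threshold(x, pathogenic),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
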