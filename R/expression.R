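## Bulk developmental-expression profiling: early-stage mean RPKM,
## percentile ranks, and between-gene-set location tests per tissue.

#' Read a long-format expression table
#'
#' Columns: `gene_id`, `tissue`, `stage` (weeks post-conception), `rpkm`.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_expression <- function(path) {
  df <- read_tsv(path, "expression")
  require_columns(df, c("gene_id", "tissue", "stage", "rpkm"), "expression")
  if (any(df$rpkm < 0, na.rm = TRUE)) {
    stop("validation error: negative RPKM values", call. = FALSE)
  }
  df
}

#' Mean early-developmental expression per gene and tissue
#'
#' Arithmetic mean RPKM over samples whose developmental stage lies inside
#' the window (inclusive on both ends); the default window is 4-8 weeks
#' post-conception. Tissues with no in-window sample are omitted with a
#' warning.
#'
#' @param expr long-format expression data.frame ([read_expression()]).
#' @param stage_window numeric length-2 window in weeks post-conception.
#' @return matrix genes x tissues of mean RPKM.
#' @export
mean_early_expression <- function(expr, stage_window = c(4, 8)) {
  stopifnot(length(stage_window) == 2L, stage_window[1] <= stage_window[2])
  inw <- expr$stage >= stage_window[1] & expr$stage <= stage_window[2]
  tissues <- unique(expr$tissue)
  dropped <- setdiff(tissues, unique(expr$tissue[inw]))
  if (length(dropped)) {
    warning("no samples inside the stage window for tissue(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  e <- expr[inw, , drop = FALSE]
  genes <- sort(unique(expr$gene_id))
  keep_t <- setdiff(tissues, dropped)
  out <- matrix(NA_real_, length(genes), length(keep_t),
                dimnames = list(genes, keep_t))
  for (tt in keep_t) {
    m <- tapply(e$rpkm[e$tissue == tt], e$gene_id[e$tissue == tt], mean)
    out[names(m), tt] <- m
  }
  out
}

#' Percentile rank of each gene within a tissue
#'
#' Midrank convention: percentile = 100 * (rank - 0.5) / n, with tied
#' values sharing their midrank; invariant under strictly monotone
#' transforms of the expression values.
#'
#' @param x numeric vector (one tissue's per-gene means), names preserved.
#' @return percentiles in [0, 100].
#' @export
percentile_rank <- function(x) {
  stopifnot(length(x) > 0)
  r <- rank(x, ties.method = "average", na.last = "keep")
  100 * (r - 0.5) / sum(!is.na(x))
}

#' Compare expression percentiles of two gene sets across tissues
#'
#' Two-sided Wilcoxon rank-sum test on the percentile values of the two
#' sets, per tissue, with Bonferroni correction over the tissues tested.
#' The null distribution is exact for combined set sizes up to 20 (no
#' ties), and the normal approximation with continuity correction
#' otherwise.
#'
#' @param percentiles matrix genes x tissues of percentile ranks (e.g.
#'   `apply(mean_early_expression(...), 2, percentile_rank)`).
#' @param set_a,set_b character vectors of gene ids; each must intersect
#'   the matrix rows.
#' @param tissues tissues to test (default: all columns).
#' @return data.frame `tissue`, `n_a`, `n_b`, `statistic`, `p`,
#'   `p_bonferroni`.
#' @export
compare_gene_sets <- function(percentiles, set_a, set_b,
                              tissues = colnames(percentiles)) {
  a <- intersect(set_a, rownames(percentiles))
  b <- intersect(set_b, rownames(percentiles))
  if (length(a) == 0L) stop("set_a has no genes in the matrix",
                            call. = FALSE)
  if (length(b) == 0L) stop("set_b has no genes in the matrix",
                            call. = FALSE)
  out <- lapply(tissues, function(tt) {
    xa <- percentiles[a, tt]
    xb <- percentiles[b, tt]
    xa <- xa[is.finite(xa)]; xb <- xb[is.finite(xb)]
    exact <- (length(xa) + length(xb) <= 20L) &&
      !anyDuplicated(c(xa, xb))
    wt <- suppressWarnings(
      stats::wilcox.test(xa, xb, alternative = "two.sided",
                         exact = exact, correct = TRUE))
    data.frame(tissue = tt, n_a = length(xa), n_b = length(xb),
               statistic = unname(wt$statistic), p = wt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$p_bonferroni <- pmin(1, out$p * length(tissues))
  out
}
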