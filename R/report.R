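## Reporting: the bundled top-genes fixture, Manhattan plot, and
## deterministic table/JSON outputs.

#' Published top-gene burden table (in-package fixture)
#'
#' The printed top-21 gene table of the case-control burden analysis: per
#' gene, the analysis stratum, the category attaining the minimal p
#' (`csq`), heterozygous carrier counts, the printed minimal p-value and
#' its printed BH/Bonferroni adjustments (all with 3 significant digits, as
#' published; 16 sCHD-stratum and 5 nsCHD-stratum genes).
#'
#' @return data.frame with columns `gene`, `stratum`, `csq`, `n_schd`,
#'   `n_nschd`, `n_control`, `p_min`, `p_fdr_printed`, `p_bonf_printed`,
#'   `known_chd`.
#' @export
chd_table1 <- function() {
  path <- system.file("extdata", "table1_burden.tsv", package = "chdburden")
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df
}

#' Format p-values in printed scientific style
#'
#' Three significant digits, upper-case exponent: `9.76E-13`, `1.00E+00`.
#'
#' @param p numeric vector.
#' @return character vector.
#' @export
format_p_sci <- function(p) {
  toupper(formatC(p, format = "e", digits = 2))
}

#' Manhattan-style plot of per-gene burden results
#'
#' Plots -log10 of the per-gene minimal p against genomic order (genes
#' sorted by chromosome, then position), with horizontal reference lines at
#' the raw-p equivalents of Bonferroni significance (`alpha / n_tests`) and
#' of FDR 5% (the largest raw p whose BH-adjusted value is below alpha).
#' Genes without coordinates are dropped with a warning.
#'
#' @param x a `chd_gene_burden` from [run_gene_burden()].
#' @param stratum "sCHD", "nsCHD" or "both" (facet-free overlay).
#' @param ... further arguments passed to [graphics::plot()].
#' @return invisibly, the plotted data.frame (genomic order).
#' @export
plot.chd_gene_burden <- function(x, stratum = "sCHD", ...) {
  r <- x$results
  if (stratum != "both") r <- r[r$stratum == stratum, , drop = FALSE]
  if (nrow(r) == 0L) stop("no burden results to plot", call. = FALSE)
  gi <- x$gene_info
  m <- match(r$gene_id, gi$gene_id)
  if (anyNA(m)) {
    warning(sum(is.na(m)), " gene(s) without coordinates dropped",
            call. = FALSE)
    r <- r[!is.na(m), , drop = FALSE]
    m <- m[!is.na(m)]
  }
  r$chrom <- gi$chrom[m]
  r$pos <- gi$pos[m]
  chrom_order <- c(as.character(1:22), "X", "Y")
  r$chrom_rank <- match(r$chrom, chrom_order)
  r <- r[order(r$chrom_rank, r$pos, r$gene_id), ]
  r$x <- seq_len(nrow(r))

  bonf_line <- -log10(x$mt$alpha / x$mt$n_tests)
  below <- r$p_min[r$p_bh < x$mt$alpha]
  fdr_line <- if (length(below)) -log10(max(below)) else NA_real_

  graphics::plot(r$x, -log10(r$p_min),
                 col = ifelse(r$chrom_rank %% 2 == 0, "grey40", "grey70"),
                 pch = 16, cex = 0.7, xlab = "Genes (genomic order)",
                 ylab = expression(-log[10](italic(P))),
                 ylim = c(0, max(-log10(r$p_min), bonf_line, na.rm = TRUE)
                          * 1.05), ...)
  graphics::abline(h = bonf_line, col = "red", lty = 2)
  if (is.finite(fdr_line)) {
    graphics::abline(h = fdr_line, col = "grey30", lty = 3)
  }
  invisible(r)
}

#' Write deterministic result tables and a calibration report
#'
#' Produces a published-style gene table (`burden_results.tsv`, sorted by
#' minimal p, p-values in 3-significant-digit scientific notation), a
#' gene-set odds-ratio table (`geneset_results.tsv`) and a calibration
#' JSON (`calibration_report.json`). Rerunning on identical inputs yields
#' identical files; results containing NaN p-values are rejected.
#'
#' @param gene_burden a `chd_gene_burden`, or NULL.
#' @param geneset a `chd_geneset_burden`, or NULL.
#' @param calibration a `chd_calibration`, or NULL.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
report_tables <- function(gene_burden = NULL, geneset = NULL,
                          calibration = NULL, dir) {
  if (is.null(gene_burden) && is.null(geneset) && is.null(calibration)) {
    stop("at least one completed analysis is required", call. = FALSE)
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  if (!is.null(gene_burden)) {
    r <- gene_burden$results
    if (any(is.nan(r$p_min))) stop("NaN p-values in burden results",
                                   call. = FALSE)
    r <- r[order(r$p_min, r$gene_id, r$stratum), ]
    out <- data.frame(gene = r$gene_id, stratum = r$stratum,
                      csq_min = r$min_category,
                      carriers_case_lof = r$carriers_case_lof,
                      carriers_ctrl_lof = r$carriers_ctrl_lof,
                      carriers_case_miss = r$carriers_case_miss,
                      carriers_ctrl_miss = r$carriers_ctrl_miss,
                      p_lof = format_p_sci(r$p_lof),
                      p_miss = format_p_sci(r$p_miss),
                      p_min = format_p_sci(r$p_min),
                      p_fdr = format_p_sci(r$p_bh),
                      p_bonferroni = format_p_sci(r$p_bonferroni),
                      stringsAsFactors = FALSE)
    p <- file.path(dir, "burden_results.tsv")
    utils::write.table(out, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(geneset)) {
    r <- geneset$results
    if (any(is.nan(r$p), na.rm = TRUE)) {
      stop("NaN p-values in gene-set results", call. = FALSE)
    }
    r <- r[order(r$category, r$stratum, r$set_label), ]
    r$p <- format_p_sci(r$p)
    r$p_bonferroni <- format_p_sci(r$p_bonferroni)
    for (col in c("beta", "se", "odds_ratio", "ci_low", "ci_high")) {
      r[[col]] <- signif(r[[col]], 4)
    }
    p <- file.path(dir, "geneset_results.tsv")
    utils::write.table(r, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(calibration)) {
    p <- file.path(dir, "calibration_report.json")
    jsonlite::write_json(
      list(lambda_gc = calibration$lambda_gc,
           lambda_1000 = calibration$lambda_1000,
           n_case = calibration$n_case,
           n_control = calibration$n_control,
           n_permutations = calibration$n_permutations,
           seed = calibration$seed,
           observed_percentile = calibration$observed_percentile,
           permutation_lambdas = calibration$permutation_lambdas,
           qq_points = calibration$qq_points),
      p, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p)
  }
  invisible(paths)
}
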