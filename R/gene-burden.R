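## Per-gene carrier counting under genotype QC, one-sided Fisher exact
## burden per variant category and CHD stratum, minimal-P selection, and
## the stratified Bonferroni / Benjamini-Hochberg correction scheme.

#' Genotype quality-control predicate
#'
#' A call is high-confidence when DP >= 10, GQ >= 20 and, for heterozygous
#' calls only, allelic balance strictly > 0.2. Missing zygosity always
#' fails; a missing DP/GQ/AB also fails the corresponding rule.
#'
#' @param genotypes genotype data.frame (`zygosity`, `dp`, `gq`, `ab`).
#' @param min_dp,min_gq,min_het_ab QC bounds.
#' @return logical vector.
#' @export
qc_genotype <- function(genotypes, min_dp = 10L, min_gq = 20L,
                        min_het_ab = 0.2) {
  ok_dp <- !is.na(genotypes$dp) & genotypes$dp >= min_dp
  ok_gq <- !is.na(genotypes$gq) & genotypes$gq >= min_gq
  is_het <- genotypes$zygosity == "het"
  ok_ab <- !is_het | (!is.na(genotypes$ab) & genotypes$ab > min_het_ab)
  called <- !is.na(genotypes$zygosity) & genotypes$zygosity != "missing"
  called & ok_dp & ok_gq & ok_ab
}

## Qualifying genotype records: QC-passing calls at rare variants of a
## classified category, annotated with gene, category, zygosity, stratum.
qualifying_genotypes <- function(cohort, cfg = category_config()) {
  v <- cohort$variants
  keep_v <- is_rare(v, cfg)
  category <- as.character(variant_category(v, cfg))
  g <- cohort$genotypes[qc_genotype(cohort$genotypes), , drop = FALSE]
  m <- match(g$variant_id, v$variant_id)
  out <- data.frame(sample_id = g$sample_id,
                    variant_id = g$variant_id,
                    zygosity = g$zygosity,
                    gene_id = v$gene_id[m],
                    category = category[m],
                    rare = keep_v[m],
                    stringsAsFactors = FALSE)
  out <- out[out$rare & out$category != "none", , drop = FALSE]
  out$stratum <- cohort$samples$stratum[match(out$sample_id,
                                              cohort$samples$sample_id)]
  out
}

#' Count dominant-model carriers for one gene, category and stratum
#'
#' A carrier is a sample in the stratum with at least one QC-passing
#' heterozygous or hemizygous genotype at a rare variant of the category in
#' the gene; each sample counts at most once per (gene, category).
#' Hemizygous male X genotypes count so that X-linked genes remain testable.
#'
#' @param cohort a `chd_cohort`.
#' @param gene_id single gene id (must exist in the gene table).
#' @param category one of "hcLOF", "missC", "synonymous".
#' @param stratum one of "control", "sCHD", "nsCHD".
#' @param cfg a [category_config()].
#' @return integer carrier count.
#' @export
count_carriers <- function(cohort, gene_id, category, stratum,
                           cfg = category_config()) {
  if (!gene_id %in% cohort$genes$gene_id) {
    stop("unknown gene_id: ", gene_id, call. = FALSE)
  }
  q <- qualifying_genotypes(cohort, cfg)
  q <- q[q$gene_id == gene_id & q$category == category &
           q$stratum == stratum &
           q$zygosity %in% c("het", "hemizygous"), , drop = FALSE]
  length(unique(q$sample_id))
}

#' One-sided Fisher exact burden p-value
#'
#' Exact hypergeometric tail probability that the number of case carriers
#' is at least as large as observed, given the carrier totals — i.e. the
#' Fisher exact test of the 2x2 carriers table, one-sided towards
#' enrichment in cases. Vectorised over counts. Returns 1 when there are no
#' case carriers.
#'
#' @param carriers_case,n_case,carriers_ctrl,n_ctrl non-negative integer
#'   vectors; carriers must not exceed the stratum sizes.
#' @return numeric p-values in (0, 1].
#' @export
fisher_burden <- function(carriers_case, n_case, carriers_ctrl, n_ctrl) {
  k <- cbind(carriers_case, n_case, carriers_ctrl, n_ctrl)
  if (any(!is.finite(k)) || any(k < 0) ||
      any(carriers_case > n_case) || any(carriers_ctrl > n_ctrl)) {
    stop("inconsistent carrier counts", call. = FALSE)
  }
  stats::phyper(carriers_case - 1L, n_case, n_ctrl,
                carriers_case + carriers_ctrl, lower.tail = FALSE)
}

#' Minimal p-value across the two discovery categories
#'
#' @param p_lof,p_miss numeric vectors in (0, 1]; a category with no
#'   qualifying variants contributes p = 1.
#' @return data.frame with `p_min` and `min_category`; ties resolve to
#'   hcLOF (the more severe category).
#' @export
minimal_p <- function(p_lof, p_miss) {
  stopifnot(all(p_lof > 0 & p_lof <= 1), all(p_miss > 0 & p_miss <= 1))
  data.frame(p_min = pmin(p_lof, p_miss),
             min_category = ifelse(p_lof <= p_miss, "hcLOF", "missC"),
             stringsAsFactors = FALSE)
}

#' Multiple-testing configuration
#'
#' The correction factor is `n_genes_tested x n_categories` tests (testing
#' hcLOF and missC per gene); the study-scale configuration is
#' 2 x 16,351 = 32,702.
#'
#' @param n_genes_tested number of genes entering the test.
#' @param n_categories number of variant categories tested per gene.
#' @param alpha family-wise significance level.
#' @return list of class `mt_config` with `n_tests` precomputed.
#' @export
mt_config <- function(n_genes_tested = 16351L, n_categories = 2L,
                      alpha = 0.05) {
  stopifnot(n_genes_tested >= 1, n_categories >= 1, alpha > 0, alpha < 1)
  structure(list(n_genes_tested = as.integer(n_genes_tested),
                 n_categories = as.integer(n_categories),
                 n_tests = as.integer(n_genes_tested) *
                   as.integer(n_categories),
                 alpha = alpha),
            class = "mt_config")
}

#' Bonferroni adjustment with a fixed correction factor
#'
#' @param p numeric vector in (0, 1].
#' @param cfg an [mt_config()].
#' @return `min(1, p * n_tests)`, elementwise.
#' @export
adjust_bonferroni <- function(p, cfg = mt_config()) {
  stopifnot(all(p > 0 & p <= 1))
  pmin(1, p * cfg$n_tests)
}

#' Benjamini-Hochberg step-up adjustment with a fixed correction factor
#'
#' Ranks are assigned within the supplied vector (one stratum's gene list,
#' ascending p) but the multiplier uses the study-wide number of tests:
#' the gene at rank i receives `min over j >= i of min(1, p_(j) * n / j)`.
#' This is `stats::p.adjust(p, "BH", n = n_tests)`; output order matches
#' input order.
#'
#' @inheritParams adjust_bonferroni
#' @return adjusted p-values in input order.
#' @export
adjust_bh <- function(p, cfg = mt_config()) {
  stopifnot(all(p > 0 & p <= 1))
  if (cfg$n_tests < length(p)) {
    stop("n_tests smaller than the number of p-values", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH", n = cfg$n_tests)
}

## Shared counting engine: unique carriers per gene x category x stratum.
## `carrier_ids` is a data.frame(sample_id, gene_id, category) of carrier
## events (already deduplicated or not; deduplication happens here).
tabulate_carriers <- function(carrier_ids, strata_of_sample) {
  key <- paste(carrier_ids$sample_id, carrier_ids$gene_id,
               carrier_ids$category, sep = "\r")
  u <- carrier_ids[!duplicated(key), , drop = FALSE]
  u$stratum <- strata_of_sample[u$sample_id]
  u
}

count_table <- function(u, genes, categories) {
  out <- list()
  for (cat in categories) {
    uc <- u[u$category == cat, , drop = FALSE]
    for (st in STRATA) {
      tab <- table(factor(uc$gene_id[uc$stratum == st], levels = genes))
      out[[paste(cat, st, sep = ".")]] <- as.integer(tab)
    }
  }
  df <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  cbind(df, as.data.frame(out, check.names = FALSE))
}

#' Run the per-gene case-control burden analysis
#'
#' For every tested gene and each case stratum (sCHD vs controls, nsCHD vs
#' controls) the one-sided Fisher burden p-value is computed separately for
#' rare hcLOF and rare missC carriers; the per-gene minimal p across the two
#' categories is the study-wide p, adjusted by Bonferroni and per-stratum
#' BH with the fixed factor of `mt$n_tests`. Synonymous-category p-values
#' are computed in parallel and kept on the result for calibration — they
#' never enter the discovery table.
#'
#' A gene is "tested" when it harbours at least one rare hcLOF or missC
#' variant site; genes with no qualifying site contribute no row (this is
#' what makes the tested-gene count smaller than the annotated gene count).
#' By default `mt` is derived from the data as
#' `mt_config(n_genes_tested = <tested genes>)`.
#'
#' @param cohort a `chd_cohort`; both case strata and controls must be
#'   non-empty.
#' @param cfg a [category_config()].
#' @param mt an [mt_config()], or NULL to derive the factor from the data.
#' @return object of class `chd_gene_burden`: list with `results` (one row
#'   per gene x stratum: counts, `p_lof`, `p_miss`, `p_min`,
#'   `min_category`, `p_bh`, `p_bonferroni`), `synonymous` (same layout for
#'   the negative-control category), `counts`, `mt`, `gene_info`.
#' @export
run_gene_burden <- function(cohort, cfg = category_config(), mt = NULL) {
  n_by_stratum <- table(factor(cohort$samples$stratum, levels = STRATA))
  if (any(n_by_stratum == 0L)) {
    stop("empty stratum: ",
         paste(names(n_by_stratum)[n_by_stratum == 0L], collapse = ", "),
         call. = FALSE)
  }
  q <- qualifying_genotypes(cohort, cfg)
  dom <- q[q$zygosity %in% c("het", "hemizygous"), , drop = FALSE]

  v <- cohort$variants
  site_cat <- as.character(variant_category(v, cfg))
  site_rare <- is_rare(v, cfg)
  tested <- sort(unique(v$gene_id[site_rare &
                                    site_cat %in% c("hcLOF", "missC")]))
  syn_genes <- sort(unique(v$gene_id[site_rare & site_cat == "synonymous"]))
  if (length(tested) == 0L) stop("no testable genes", call. = FALSE)
  if (is.null(mt)) mt <- mt_config(n_genes_tested = length(tested))

  strata_of <- stats::setNames(cohort$samples$stratum,
                               cohort$samples$sample_id)
  u <- tabulate_carriers(dom[, c("sample_id", "gene_id", "category")],
                         strata_of)
  counts <- count_table(u, union(tested, syn_genes),
                        c("hcLOF", "missC", "synonymous"))

  one_stratum <- function(case_stratum, genes, categories) {
    n_case <- as.integer(n_by_stratum[[case_stratum]])
    n_ctrl <- as.integer(n_by_stratum[["control"]])
    idx <- match(genes, counts$gene_id)
    ps <- lapply(categories, function(cat) {
      kc <- counts[[paste(cat, case_stratum, sep = ".")]][idx]
      k0 <- counts[[paste(cat, "control", sep = ".")]][idx]
      fisher_burden(kc, n_case, k0, n_ctrl)
    })
    names(ps) <- categories
    ps
  }

  res <- list()
  for (st in c("sCHD", "nsCHD")) {
    ps <- one_stratum(st, tested, c("hcLOF", "missC"))
    mp <- minimal_p(ps$hcLOF, ps$missC)
    idx <- match(tested, counts$gene_id)
    res[[st]] <- data.frame(
      gene_id = tested, stratum = st,
      carriers_case_lof = counts[[paste0("hcLOF.", st)]][idx],
      carriers_ctrl_lof = counts[["hcLOF.control"]][idx],
      carriers_case_miss = counts[[paste0("missC.", st)]][idx],
      carriers_ctrl_miss = counts[["missC.control"]][idx],
      p_lof = ps$hcLOF, p_miss = ps$missC,
      p_min = mp$p_min, min_category = mp$min_category,
      p_bh = adjust_bh(mp$p_min, mt),
      p_bonferroni = adjust_bonferroni(mp$p_min, mt),
      stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, res)
  rownames(results) <- NULL

  syn <- list()
  for (st in c("sCHD", "nsCHD")) {
    ps <- one_stratum(st, syn_genes, "synonymous")
    idx <- match(syn_genes, counts$gene_id)
    syn[[st]] <- data.frame(
      gene_id = syn_genes, stratum = st,
      carriers_case = counts[[paste0("synonymous.", st)]][idx],
      carriers_ctrl = counts[["synonymous.control"]][idx],
      p = ps$synonymous, stringsAsFactors = FALSE)
  }
  synonymous <- do.call(rbind, syn)
  rownames(synonymous) <- NULL

  gene_pos <- stats::aggregate(pos ~ gene_id + chrom, data = v,
                               FUN = stats::median)
  structure(list(results = results, synonymous = synonymous,
                 counts = counts, mt = mt, cfg = cfg,
                 n_by_stratum = n_by_stratum,
                 gene_info = gene_pos),
            class = "chd_gene_burden")
}

#' Recessive (biallelic) burden analysis
#'
#' A recessive carrier is a sample with at least one QC-passing homozygous
#' rare protein-altering (hcLOF or missC) genotype in the gene, or at least
#' two distinct QC-passing rare heterozygous protein-altering variants in
#' the gene — the unphased proxy for compound heterozygosity. Fisher test
#' and correction as in [run_gene_burden()], one pooled protein-altering
#' category.
#'
#' @inheritParams run_gene_burden
#' @return object of class `chd_gene_burden` (recessive flavour: `p_lof` /
#'   `p_miss` collapse to a single `p_min` column per gene x stratum).
#' @export
recessive_burden <- function(cohort, cfg = category_config(), mt = NULL) {
  n_by_stratum <- table(factor(cohort$samples$stratum, levels = STRATA))
  q <- qualifying_genotypes(cohort, cfg)
  q <- q[q$category %in% c("hcLOF", "missC"), , drop = FALSE]
  hom <- q[q$zygosity == "hom_alt", c("sample_id", "gene_id")]
  het <- q[q$zygosity == "het", , drop = FALSE]
  key <- paste(het$sample_id, het$gene_id, het$variant_id, sep = "\r")
  het <- het[!duplicated(key), , drop = FALSE]
  nhet <- stats::aggregate(variant_id ~ sample_id + gene_id, data = het,
                           FUN = length)
  chet <- nhet[nhet$variant_id >= 2L, c("sample_id", "gene_id")]
  carriers <- unique(rbind(hom, chet))
  if (nrow(carriers) == 0L) {
    genes <- character(0)
  } else {
    genes <- sort(unique(carriers$gene_id))
  }
  if (is.null(mt)) {
    mt <- mt_config(n_genes_tested = max(1L, length(genes)),
                    n_categories = 1L)
  }
  if (length(genes) == 0L) {
    empty <- data.frame(gene_id = character(), stratum = character(),
                        carriers_case = integer(), carriers_ctrl = integer(),
                        p_min = numeric(), p_bh = numeric(),
                        p_bonferroni = numeric(), stringsAsFactors = FALSE)
    return(structure(list(results = empty, mt = mt,
                          n_by_stratum = n_by_stratum, recessive = TRUE),
                     class = "chd_gene_burden"))
  }
  carriers$stratum <- cohort$samples$stratum[match(carriers$sample_id,
                                                   cohort$samples$sample_id)]
  res <- list()
  for (st in c("sCHD", "nsCHD")) {
    kc <- as.integer(table(factor(
      carriers$gene_id[carriers$stratum == st], levels = genes)))
    k0 <- as.integer(table(factor(
      carriers$gene_id[carriers$stratum == "control"], levels = genes)))
    p <- fisher_burden(kc, as.integer(n_by_stratum[[st]]),
                       k0, as.integer(n_by_stratum[["control"]]))
    res[[st]] <- data.frame(gene_id = genes, stratum = st,
                            carriers_case = kc, carriers_ctrl = k0,
                            p_min = p,
                            p_bh = adjust_bh(p, mt),
                            p_bonferroni = adjust_bonferroni(p, mt),
                            stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, res)
  rownames(results) <- NULL
  structure(list(results = results, mt = mt, n_by_stratum = n_by_stratum,
                 recessive = TRUE),
            class = "chd_gene_burden")
}

#' @export
print.chd_gene_burden <- function(x, ...) {
  cat("chd_gene_burden",
      if (isTRUE(x$recessive)) "(recessive model)" else "(dominant model)",
      "\n")
  cat(sprintf("  %d gene x stratum tests, correction factor n = %d\n",
              nrow(x$results), x$mt$n_tests))
  sig <- sum(x$results$p_bonferroni < x$mt$alpha)
  fdr <- sum(x$results$p_bh < x$mt$alpha)
  cat(sprintf("  Bonferroni-significant: %d; FDR < %.2g: %d\n",
              sig, x$mt$alpha, fdr))
  top <- x$results[order(x$results$p_min), ]
  print(utils::head(top, 5L), row.names = FALSE)
  invisible(x)
}

#' @export
summary.chd_gene_burden <- function(object, ...) {
  r <- object$results
  out <- list(
    n_tests = nrow(r),
    n_bonferroni_significant = sum(r$p_bonferroni < object$mt$alpha),
    n_fdr_significant = sum(r$p_bh < object$mt$alpha),
    top = utils::head(r[order(r$p_min), ], 10L))
  class(out) <- "summary.chd_gene_burden"
  out
}

#' @export
print.summary.chd_gene_burden <- function(x, ...) {
  cat(sprintf("%d tests; %d Bonferroni-significant, %d at FDR\n",
              x$n_tests, x$n_bonferroni_significant, x$n_fdr_significant))
  print(x$top, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.chd_gene_burden <- function(x, ...) x$results
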