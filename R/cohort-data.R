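## Core domain tables and the validated cohort container.
##
## Conventions: 1-based VCF coordinates; genotype storage is sparse (only
## non-reference calls are stored, absence means hom_ref); missing scores and
## missing allele frequencies are NA, never 0.

#' @keywords internal
CONSEQUENCES <- c("stop_gained", "frameshift", "essential_splice",
                  "missense", "synonymous", "other")

#' @keywords internal
LOF_CONSEQUENCES <- c("stop_gained", "frameshift", "essential_splice")

#' @keywords internal
ZYGOSITIES <- c("hom_ref", "het", "hom_alt", "hemizygous", "missing")

#' @keywords internal
STRATA <- c("control", "sCHD", "nsCHD")

#' @keywords internal
AF_COLUMNS <- c("af_internal", "af_gnomad_exomes", "af_gnomad_genomes",
                "af_rumc", "af_inhouse")

#' Build a variant identifier from VCF-style coordinates
#'
#' @param chrom,pos,ref,alt vectors describing one biallelic variant per
#'   element (1-based position).
#' @return character vector `"chrom:pos:ref:alt"`.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

fail_rows <- function(what, idx, extra = NULL) {
  idx <- utils::head(idx, 5L)
  msg <- sprintf("%s (rows %s)", what, paste(idx, collapse = ", "))
  if (!is.null(extra)) msg <- paste0(msg, "; ", extra)
  stop(msg, call. = FALSE)
}

require_columns <- function(df, cols, table_name) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("schema error in %s: missing column(s) %s",
                 table_name, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

validate_variants <- function(variants) {
  require_columns(variants,
                  c("chrom", "pos", "ref", "alt", "gene_id", "consequence",
                    "lof_hc", AF_COLUMNS),
                  "variants")
  if (!all(c("cadd", "revel", "mvp") %in% names(variants))) {
    stop("schema error in variants: missing column(s) cadd, revel or mvp",
         call. = FALSE)
  }
  bad <- which(!is.finite(variants$pos) | variants$pos < 1)
  if (length(bad)) fail_rows("validation error: pos must be >= 1", bad)
  bad <- which(variants$ref == variants$alt)
  if (length(bad)) fail_rows("validation error: ref must differ from alt", bad)
  bad <- which(!variants$consequence %in% CONSEQUENCES)
  if (length(bad)) {
    fail_rows("validation error: consequence outside the allowed set", bad,
              paste("allowed:", paste(CONSEQUENCES, collapse = ", ")))
  }
  bad <- which(variants$lof_hc &
                 !variants$consequence %in% LOF_CONSEQUENCES)
  if (length(bad)) {
    fail_rows(paste("validation error: lof_hc may be TRUE only for",
                    "stop_gained/frameshift/essential_splice"), bad)
  }
  for (af in AF_COLUMNS) {
    v <- variants[[af]]
    bad <- which(!is.na(v) & (v < 0 | v > 1))
    if (length(bad)) {
      fail_rows(sprintf("validation error: %s outside [0, 1]", af), bad)
    }
  }
  bad <- which(!is.na(variants$revel) &
                 (variants$revel < 0 | variants$revel > 1))
  if (length(bad)) fail_rows("validation error: revel outside [0, 1]", bad)
  bad <- which(!is.na(variants$cadd) & variants$cadd < 0)
  if (length(bad)) fail_rows("validation error: cadd must be >= 0", bad)
  vid <- variant_key(variants$chrom, variants$pos, variants$ref, variants$alt)
  bad <- which(duplicated(vid))
  if (length(bad)) fail_rows("validation error: duplicated variant", bad)
  invisible(variants)
}

validate_samples <- function(samples) {
  require_columns(samples, c("sample_id", "stratum", "sex",
                             paste0("pc", 1:5)), "samples")
  bad <- which(duplicated(samples$sample_id))
  if (length(bad)) fail_rows("validation error: duplicated sample_id", bad)
  bad <- which(!samples$stratum %in% STRATA)
  if (length(bad)) fail_rows("validation error: unknown stratum", bad)
  bad <- which(!samples$sex %in% c("female", "male", "unknown"))
  if (length(bad)) fail_rows("validation error: unknown sex", bad)
  pcs <- as.matrix(samples[, paste0("pc", 1:5)])
  bad <- which(apply(pcs, 1L, function(r) any(!is.finite(r))))
  if (length(bad)) fail_rows("validation error: non-finite ancestry PC", bad)
  invisible(samples)
}

validate_genes <- function(genes) {
  require_columns(genes, c("gene_id", "symbol", "chrom", "loeuf", "moeuf"),
                  "genes")
  bad <- which(duplicated(genes$gene_id))
  if (length(bad)) fail_rows("validation error: duplicated gene_id", bad)
  for (m in c("loeuf", "moeuf")) {
    v <- genes[[m]]
    bad <- which(!is.na(v) & (!is.finite(v) | v <= 0))
    if (length(bad)) {
      fail_rows(sprintf("validation error: %s must be finite and > 0", m), bad)
    }
  }
  invisible(genes)
}

validate_genotypes <- function(genotypes, variants, samples) {
  require_columns(genotypes, c("sample_id", "variant_id", "zygosity",
                               "dp", "gq", "ab"), "genotypes")
  bad <- which(!genotypes$zygosity %in% ZYGOSITIES)
  if (length(bad)) fail_rows("validation error: unknown zygosity", bad)
  bad <- which(!is.na(genotypes$ab) &
                 (genotypes$ab < 0 | genotypes$ab > 1))
  if (length(bad)) fail_rows("validation error: ab outside [0, 1]", bad)
  bad <- which(!is.na(genotypes$dp) & genotypes$dp < 0)
  if (length(bad)) fail_rows("validation error: dp must be >= 0", bad)
  bad <- which(!is.na(genotypes$gq) & genotypes$gq < 0)
  if (length(bad)) fail_rows("validation error: gq must be >= 0", bad)
  vid <- variant_key(variants$chrom, variants$pos, variants$ref, variants$alt)
  bad <- which(!genotypes$variant_id %in% vid)
  if (length(bad)) {
    fail_rows("validation error: genotype references unknown variant", bad,
              paste("first offending id:",
                    genotypes$variant_id[bad[1L]]))
  }
  bad <- which(!genotypes$sample_id %in% samples$sample_id)
  if (length(bad)) {
    fail_rows("validation error: genotype references unknown sample", bad)
  }
  key <- paste(genotypes$sample_id, genotypes$variant_id)
  bad <- which(duplicated(key))
  if (length(bad)) {
    fail_rows("validation error: duplicated (sample_id, variant_id) pair", bad)
  }
  invisible(genotypes)
}

#' Assemble and validate a cohort dataset
#'
#' Bundles the four core tables of a case-control rare-variant study into a
#' single validated container. Genotype storage is sparse: only non-hom_ref
#' calls are stored and carrier logic treats absence as hom_ref.
#'
#' @param variants data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `gene_id`, `consequence`, `lof_hc` (logical), `cadd`, `revel`, `mvp`
#'   and the five allele-frequency columns `af_internal`,
#'   `af_gnomad_exomes`, `af_gnomad_genomes`, `af_rumc`, `af_inhouse`
#'   (NA = source absent).
#' @param genotypes data.frame with `sample_id`, `variant_id`, `zygosity`,
#'   `dp`, `gq`, `ab`.
#' @param samples data.frame with `sample_id`, `stratum`
#'   (control/sCHD/nsCHD), `sex`, `pc1`..`pc5`.
#' @param genes data.frame with `gene_id`, `symbol`, `chrom`, `loeuf`,
#'   `moeuf` (constraint metrics, NA allowed).
#' @return object of class `chd_cohort`: a list of the four validated tables
#'   with a `variant_id` column added to `variants`.
#' @export
chd_cohort <- function(variants, genotypes, samples, genes) {
  variants <- as.data.frame(variants)
  genotypes <- as.data.frame(genotypes)
  samples <- as.data.frame(samples)
  genes <- as.data.frame(genes)
  validate_variants(variants)
  validate_samples(samples)
  validate_genes(genes)
  validate_genotypes(genotypes, variants, samples)
  unknown <- setdiff(unique(variants$gene_id), genes$gene_id)
  if (length(unknown)) {
    stop("validation error: variants reference unknown gene_id(s): ",
         paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
  }
  variants$variant_id <- variant_key(variants$chrom, variants$pos,
                                     variants$ref, variants$alt)
  structure(list(variants = variants, genotypes = genotypes,
                 samples = samples, genes = genes),
            class = "chd_cohort")
}

#' @export
print.chd_cohort <- function(x, ...) {
  tab <- table(factor(x$samples$stratum, levels = STRATA))
  cat("chd_cohort\n")
  cat(sprintf("  samples:   %d (control %d, sCHD %d, nsCHD %d)\n",
              nrow(x$samples), tab[["control"]], tab[["sCHD"]],
              tab[["nsCHD"]]))
  cat(sprintf("  variants:  %d in %d genes\n", nrow(x$variants),
              length(unique(x$variants$gene_id))))
  cat(sprintf("  genotypes: %d non-reference calls\n", nrow(x$genotypes)))
  cat(sprintf("  genes:     %d annotated\n", nrow(x$genes)))
  invisible(x)
}

read_tsv <- function(path, table_name) {
  if (!file.exists(path)) {
    stop(sprintf("file for %s not found: %s", table_name, path),
         call. = FALSE)
  }
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "",
                    check.names = FALSE)
}

#' Read a cohort from a directory of TSV files
#'
#' Expects `variants.tsv`, `genotypes.tsv`, `samples.tsv` and `genes.tsv`
#' (empty cells = missing). `genotypes.tsv` identifies variants by
#' chrom/pos/ref/alt, which are collapsed to a `variant_id` key. All
#' invariants of [chd_cohort()] are enforced; violations raise row-numbered
#' errors.
#'
#' @param paths directory containing the four TSVs, or a named list/vector
#'   with entries `variants`, `genotypes`, `samples`, `genes`.
#' @return a validated `chd_cohort`.
#' @export
read_cohort <- function(paths) {
  if (is.character(paths) && length(paths) == 1L && dir.exists(paths)) {
    paths <- file.path(paths, c(variants = "variants.tsv",
                                genotypes = "genotypes.tsv",
                                samples = "samples.tsv",
                                genes = "genes.tsv"))
    names(paths) <- c("variants", "genotypes", "samples", "genes")
  }
  paths <- as.list(paths)
  variants <- read_tsv(paths$variants, "variants")
  genotypes <- read_tsv(paths$genotypes, "genotypes")
  samples <- read_tsv(paths$samples, "samples")
  genes <- read_tsv(paths$genes, "genes")
  require_columns(variants, "lof_hc", "variants")
  variants$lof_hc <- as.logical(variants$lof_hc)
  require_columns(genotypes, c("chrom", "pos", "ref", "alt"), "genotypes")
  genotypes$variant_id <- variant_key(genotypes$chrom, genotypes$pos,
                                      genotypes$ref, genotypes$alt)
  genotypes <- genotypes[, c("sample_id", "variant_id", "zygosity",
                             "dp", "gq", "ab")]
  chd_cohort(variants, genotypes, samples, genes)
}

#' Write a cohort as a TSV bundle
#'
#' Inverse of [read_cohort()]. Rows are sorted on their natural keys so the
#' output is byte-stable: `read_cohort()` followed by `write_cohort()` is
#' idempotent on the files.
#'
#' @param cohort a `chd_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory path.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "chd_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", na = "",
                       quote = FALSE, row.names = FALSE)
  }
  v <- cohort$variants
  v <- v[order(v$chrom, v$pos, v$ref, v$alt), ]
  wt(v[, setdiff(names(v), "variant_id")], "variants.tsv")
  g <- cohort$genotypes
  parts <- do.call(rbind, strsplit(g$variant_id, ":", fixed = TRUE))
  g2 <- data.frame(sample_id = g$sample_id,
                   chrom = parts[, 1L], pos = as.integer(parts[, 2L]),
                   ref = parts[, 3L], alt = parts[, 4L],
                   zygosity = g$zygosity, dp = g$dp, gq = g$gq, ab = g$ab,
                   stringsAsFactors = FALSE)
  g2 <- g2[order(g2$sample_id, g2$chrom, g2$pos, g2$ref, g2$alt), ]
  wt(g2, "genotypes.tsv")
  s <- cohort$samples[order(cohort$samples$sample_id), ]
  wt(s, "samples.tsv")
  ge <- cohort$genes[order(cohort$genes$gene_id), ]
  wt(ge, "genes.tsv")
  invisible(dir)
}

#' Read a gene-set collection from a long-format TSV
#'
#' The file has two columns, `set_label` and `gene_id`. Gene ids that do not
#' resolve against the supplied gene table are dropped with a warning, per
#' set.
#'
#' @param path TSV path.
#' @param genes gene table of a `chd_cohort` (used to resolve ids); NULL
#'   skips resolution.
#' @return named list of character vectors of gene ids.
#' @export
read_gene_sets <- function(path, genes = NULL) {
  df <- read_tsv(path, "genesets")
  require_columns(df, c("set_label", "gene_id"), "genesets")
  sets <- split(df$gene_id, df$set_label)
  if (!is.null(genes)) {
    sets <- lapply(stats::setNames(names(sets), names(sets)), function(lbl) {
      ids <- sets[[lbl]]
      bad <- setdiff(ids, genes$gene_id)
      if (length(bad)) {
        warning(sprintf("gene set %s: dropping %d unresolvable gene id(s)",
                        lbl, length(bad)), call. = FALSE)
      }
      intersect(ids, genes$gene_id)
    })
  }
  sets
}
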