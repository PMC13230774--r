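## VCF 4.2 import. Annotation itself (VEP/LOFTEE, CADD/REVEL/MVP, external
## AFs) happens upstream; here we only map already-present INFO fields onto
## the variant table via a user-supplied field map.

#' Import annotated variants and genotypes from a VCF file
#'
#' Multi-allelic records are split into biallelic variants (one
#' `AnnotatedVariant` per site x alt); per-allele INFO fields are expected
#' comma-separated in allele order. Genotype DP/GQ are taken from FORMAT;
#' allelic balance is the AB FORMAT field when present, otherwise computed
#' as alt-depth / total depth from AD. A mapped INFO field that is absent
#' from the file yields a warning and NA values, not an error; unparseable
#' genotypes get zygosity `"missing"`.
#'
#' @param vcf_path path to a VCF (plain or bgzipped).
#' @param field_map named list mapping variant columns to INFO keys. Keys
#'   that can be mapped: `gene_id`, `consequence`, `lof_hc`, `cadd`,
#'   `revel`, `mvp`, `af_internal`, `af_gnomad_exomes`, `af_gnomad_genomes`,
#'   `af_rumc`, `af_inhouse`. Unmapped columns are NA (`lof_hc` FALSE,
#'   `gene_id` NA, `consequence` "other").
#' @param sex optional named character vector (sample -> "male"/"female");
#'   when given, male non-reference calls on chromosome X are imported as
#'   hemizygous.
#' @return list with elements `variants` and `genotypes`, ready for
#'   [chd_cohort()].
#' @export
import_vcf <- function(vcf_path, field_map = list(), sex = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("import_vcf requires the vcfR package", call. = FALSE)
  }
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  n_rec <- nrow(fix)
  alt_list <- strsplit(fix$ALT, ",", fixed = TRUE)
  n_alt <- lengths(alt_list)
  rec_idx <- rep.int(seq_len(n_rec), n_alt)     # source record per variant
  allele_idx <- unlist(lapply(n_alt, seq_len))  # 1-based alt index

  info_field <- function(key, per_allele = TRUE) {
    raw <- vcfR::extract.info(vcf, element = key)
    if (all(is.na(raw))) {
      warning(sprintf("INFO field '%s' not found in %s; values set missing",
                      key, basename(vcf_path)), call. = FALSE)
      return(rep(NA_character_, length(rec_idx)))
    }
    if (!per_allele) return(raw[rec_idx])
    pieces <- strsplit(raw, ",", fixed = TRUE)
    mapply(function(rec, k) {
      p <- pieces[[rec]]
      if (length(p) >= k) p[k] else if (length(p) == 1L) p[1L]
      else NA_character_
    }, rec_idx, allele_idx, USE.NAMES = FALSE)
  }

  pull <- function(col) {
    key <- field_map[[col]]
    if (is.null(key)) return(rep(NA_character_, length(rec_idx)))
    info_field(key)
  }

  variants <- data.frame(
    chrom = fix$CHROM[rec_idx],
    pos = as.integer(fix$POS[rec_idx]),
    ref = fix$REF[rec_idx],
    alt = unlist(alt_list),
    stringsAsFactors = FALSE)
  variants$gene_id <- pull("gene_id")
  csq <- pull("consequence")
  csq[is.na(csq) | !csq %in% CONSEQUENCES] <- "other"
  variants$consequence <- csq
  lof <- pull("lof_hc")
  variants$lof_hc <- !is.na(lof) & lof %in% c("1", "true", "TRUE", "HC")
  variants$lof_hc <- variants$lof_hc & variants$consequence %in% LOF_CONSEQUENCES
  for (col in c("cadd", "revel", "mvp", AF_COLUMNS)) {
    val <- pull(col)
    variants[[col]] <- suppressWarnings(as.numeric(val))
  }
  variants$variant_id <- variant_key(variants$chrom, variants$pos,
                                     variants$ref, variants$alt)

  ## genotypes ---------------------------------------------------------------
  samples <- colnames(vcf@gt)[-1L]
  if (length(samples) == 0L) {
    return(list(variants = variants[, setdiff(names(variants), "variant_id")],
                genotypes = data.frame(sample_id = character(),
                                       variant_id = character(),
                                       zygosity = character(),
                                       dp = integer(), gq = integer(),
                                       ab = numeric())))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(vcf, element = "DP",
                                          as.numeric = TRUE))
  gq <- suppressWarnings(vcfR::extract.gt(vcf, element = "GQ",
                                          as.numeric = TRUE))
  ad <- tryCatch(vcfR::extract.gt(vcf, element = "AD"),
                 error = function(e) NULL)

  out <- vector("list", length(rec_idx))
  for (vi in seq_along(rec_idx)) {
    rec <- rec_idx[vi]
    k <- allele_idx[vi]
    gts <- gt[rec, ]
    alleles <- strsplit(gsub("|", "/", gts, fixed = TRUE), "/", fixed = TRUE)
    n_match <- vapply(alleles, function(a) sum(a == as.character(k)),
                      integer(1L))
    n_called <- vapply(alleles, function(a) sum(a != "." & nzchar(a)),
                       integer(1L))
    zyg <- ifelse(is.na(gts) | n_called == 0L, "missing",
           ifelse(n_match == 0L, "hom_ref",
           ifelse(n_called == 1L, "hemizygous",
           ifelse(n_match >= 2L, "hom_alt", "het"))))
    ab <- rep(NA_real_, length(samples))
    if (!is.null(ad)) {
      ad_parts <- strsplit(ad[rec, ], ",", fixed = TRUE)
      ab <- vapply(ad_parts, function(p) {
        d <- suppressWarnings(as.numeric(p))
        if (length(d) <= k || anyNA(d) || sum(d) == 0) NA_real_
        else d[k + 1L] / sum(d)
      }, numeric(1L))
    }
    if (!is.null(sex)) {
      chrx <- variants$chrom[vi] %in% c("X", "chrX")
      male <- !is.na(sex[samples]) & sex[samples] == "male"
      hemi <- chrx & male & zyg %in% c("het", "hom_alt")
      zyg[hemi] <- "hemizygous"
    }
    keep <- zyg != "hom_ref"
    if (!any(keep)) next
    out[[vi]] <- data.frame(
      sample_id = samples[keep],
      variant_id = variants$variant_id[vi],
      zygosity = zyg[keep],
      dp = as.integer(round(dp[rec, keep])),
      gq = as.integer(round(gq[rec, keep])),
      ab = ab[keep],
      stringsAsFactors = FALSE)
  }
  genotypes <- do.call(rbind, out[!vapply(out, is.null, logical(1L))])
  if (is.null(genotypes)) {
    genotypes <- data.frame(sample_id = character(), variant_id = character(),
                            zygosity = character(), dp = integer(),
                            gq = integer(), ab = numeric())
  }
  rownames(genotypes) <- NULL
  list(variants = variants[, setdiff(names(variants), "variant_id")],
       genotypes = genotypes)
}
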