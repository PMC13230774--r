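## Fully in-silico cohort generation with the statistical structure the
## burden analyses assume: constraint-distributed genes, rare variants with
## score triplets and multi-source AFs, sparse genotypes with QC fields,
## and carrier-probability effects plantable per constraint bin, gene set
## or single gene, per variant category and CHD stratum.

#' Simulation configuration
#'
#' Defaults reproduce the study conditions: 1818 syndromic and 2929
#' non-syndromic CHD cases against 52,881 controls, 19,923 protein-coding
#' genes with log-normal LOEUF/MOEUF constraint metrics, a rare/common AF
#' mixture below/above MAF 0.001, class-conditional Gaussian score
#' triplets, and genotype quality fields (negative-binomial depth,
#' discretised-Gaussian GQ, Beta heterozygous allelic balance). Effects are
#' planted on the per-gene carrier probability: for a planted
#' `(target, category, stratum, or)` the carrier probability in that
#' stratum's cases is the baseline rate shifted by `log(or)` on the
#' log-odds scale.
#'
#' @param n_schd,n_nschd,n_control stratum sizes.
#' @param n_genes number of protein-coding genes.
#' @param frac_chrx fraction of genes placed on chromosome X.
#' @param loeuf_meanlog,loeuf_sdlog,moeuf_meanlog,moeuf_sdlog log-normal
#'   parameters of the constraint metrics.
#' @param metric_missing_rate fraction of genes lacking each metric.
#' @param variants_per_gene named vector: Poisson means for extra LOF /
#'   missense / synonymous sites per gene (one qualifying site of each
#'   category is always guaranteed).
#' @param lof_hc_rate probability a LOF-consequence site carries the
#'   high-confidence flag.
#' @param missense_damaging_rate fraction of missense sites drawn from the
#'   damaging score profile.
#' @param score_missing_rate per-score missingness among missense sites.
#' @param rare_weight mixture weight of the rare AF component.
#' @param rare_af_max upper bound of the rare component (below the rarity
#'   threshold even after per-source jitter).
#' @param common_af_range AF range of the common component.
#' @param af_source_missing_rate missingness per external AF source.
#' @param baseline_carrier_rate per-gene per-category carrier probability.
#' @param hom_alt_rate fraction of carrier genotypes that are homozygous.
#' @param dp_size,dp_mu negative-binomial read-depth parameters.
#' @param gq_mean,gq_sd genotype-quality parameters (clamped to 0..99).
#' @param ab_shape1,ab_shape2 Beta parameters of heterozygous allelic
#'   balance.
#' @param planted_effects NULL or data.frame with columns `target`
#'   (a gene_id, `"bin_k"` / `"moeuf_bin_k"`, or a name in `extra_sets`),
#'   `category`, `stratum` ("sCHD", "nsCHD" or "aCHD"), `or`.
#' @param extra_sets named list of gene-id vectors usable as plant targets.
#' @param pc_confounding shift added to PC1 of cases (0 = no confounding).
#' @param seed integer RNG seed; mandatory.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_schd = 1818L, n_nschd = 2929L, n_control = 52881L,
                       n_genes = 19923L, frac_chrx = 0.03,
                       loeuf_meanlog = log(0.8), loeuf_sdlog = 0.6,
                       moeuf_meanlog = log(0.9), moeuf_sdlog = 0.4,
                       metric_missing_rate = 0.02,
                       variants_per_gene = c(lof = 1, missense = 2,
                                             synonymous = 1.5),
                       lof_hc_rate = 0.85,
                       missense_damaging_rate = 0.4,
                       score_missing_rate = 0.05,
                       rare_weight = 0.9, rare_af_max = 5e-4,
                       common_af_range = c(2e-3, 5e-2),
                       af_source_missing_rate = 0.1,
                       baseline_carrier_rate = 1e-3,
                       hom_alt_rate = 0.02,
                       dp_size = 20, dp_mu = 60,
                       gq_mean = 80, gq_sd = 15,
                       ab_shape1 = 20, ab_shape2 = 20,
                       planted_effects = NULL,
                       extra_sets = NULL,
                       pc_confounding = 0,
                       seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(n_schd >= 1, n_nschd >= 1, n_control >= 1, n_genes >= 10,
            baseline_carrier_rate > 0, baseline_carrier_rate < 1,
            rare_weight >= 0, rare_weight <= 1,
            hom_alt_rate >= 0, hom_alt_rate <= 1)
  if (!is.null(planted_effects)) {
    planted_effects <- as.data.frame(planted_effects)
    stopifnot(all(c("target", "category", "stratum", "or") %in%
                    names(planted_effects)))
    stopifnot(all(planted_effects$or > 0),
              all(planted_effects$category %in%
                    c("hcLOF", "missC", "synonymous")),
              all(planted_effects$stratum %in% c("sCHD", "nsCHD", "aCHD")))
  }
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))

sim_genes <- function(cfg) {
  n <- cfg$n_genes
  ids <- sprintf("G%05d", seq_len(n))
  chrom <- ifelse(stats::runif(n) < cfg$frac_chrx, "X",
                  as.character(sample(1:22, n, replace = TRUE)))
  loeuf <- stats::rlnorm(n, cfg$loeuf_meanlog, cfg$loeuf_sdlog)
  moeuf <- stats::rlnorm(n, cfg$moeuf_meanlog, cfg$moeuf_sdlog)
  loeuf[stats::runif(n) < cfg$metric_missing_rate] <- NA
  moeuf[stats::runif(n) < cfg$metric_missing_rate] <- NA
  data.frame(gene_id = ids, symbol = ids, chrom = chrom,
             loeuf = loeuf, moeuf = moeuf, stringsAsFactors = FALSE)
}

## score profiles for missense variants; "damaging" variants tend to pass
## the 2-of-3 ensemble rule, "benign" ones tend to fail it
sim_missense_scores <- function(n, damaging) {
  cadd <- ifelse(damaging, stats::rnorm(n, 30, 3), stats::rnorm(n, 15, 5))
  revel <- ifelse(damaging, stats::rnorm(n, 0.75, 0.12),
                  stats::rnorm(n, 0.25, 0.12))
  mvp <- ifelse(damaging, stats::rnorm(n, 0.85, 0.08),
                stats::rnorm(n, 0.40, 0.15))
  data.frame(cadd = pmax(0, cadd),
             revel = clamp(revel, 0, 1),
             mvp = clamp(mvp, 0, 1))
}

sim_variants <- function(cfg, genes) {
  n_g <- nrow(genes)
  n_lof <- 1L + stats::rpois(n_g, cfg$variants_per_gene[["lof"]])
  n_mis <- 1L + stats::rpois(n_g, cfg$variants_per_gene[["missense"]])
  n_syn <- 1L + stats::rpois(n_g, cfg$variants_per_gene[["synonymous"]])
  counts <- n_lof + n_mis + n_syn
  gidx <- rep.int(seq_len(n_g), counts)
  n_v <- length(gidx)

  ## per-gene variant ordering: LOF block, then missense, then synonymous;
  ## the first of each block is the guaranteed qualifying site
  offset <- sequence(counts)
  block <- unlist(mapply(function(a, b, c) {
    rep(c("lof", "mis", "syn"), c(a, b, c))
  }, n_lof, n_mis, n_syn, SIMPLIFY = FALSE), use.names = FALSE)
  first <- unlist(mapply(function(a, b, c) {
    x <- rep(FALSE, a + b + c)
    x[c(1L, a + 1L, a + b + 1L)] <- TRUE
    x
  }, n_lof, n_mis, n_syn, SIMPLIFY = FALSE), use.names = FALSE)

  consequence <- character(n_v)
  consequence[block == "lof"] <- sample(LOF_CONSEQUENCES,
                                        sum(block == "lof"), replace = TRUE)
  consequence[block == "mis"] <- "missense"
  consequence[block == "syn"] <- "synonymous"

  lof_hc <- rep(FALSE, n_v)
  is_lof <- block == "lof"
  lof_hc[is_lof] <- stats::runif(sum(is_lof)) < cfg$lof_hc_rate
  lof_hc[is_lof & first] <- TRUE

  cadd <- revel <- mvp <- rep(NA_real_, n_v)
  is_mis <- block == "mis"
  n_mis_tot <- sum(is_mis)
  damaging <- stats::runif(n_mis_tot) < cfg$missense_damaging_rate
  sc <- sim_missense_scores(n_mis_tot, damaging)
  for (col in c("cadd", "revel", "mvp")) {
    sc[[col]][stats::runif(n_mis_tot) < cfg$score_missing_rate] <- NA
  }
  ## guaranteed missC site per gene: scores always present and passing
  forced <- first[is_mis]
  nf <- sum(forced)
  sc$cadd[forced] <- stats::runif(nf, 25, 35)
  sc$revel[forced] <- stats::runif(nf, 0.55, 0.95)
  sc$mvp[forced] <- stats::runif(nf, 0.82, 0.95)
  cadd[is_mis] <- sc$cadd
  revel[is_mis] <- sc$revel
  mvp[is_mis] <- sc$mvp

  rare <- stats::runif(n_v) < cfg$rare_weight
  rare[first] <- TRUE
  base_af <- ifelse(rare, stats::runif(n_v, 0, cfg$rare_af_max),
                    stats::runif(n_v, cfg$common_af_range[1],
                                 cfg$common_af_range[2]))
  afs <- lapply(stats::setNames(AF_COLUMNS, AF_COLUMNS), function(src) {
    af <- base_af * stats::runif(n_v, 0.8, 1.2)
    if (src != "af_internal") {
      af[stats::runif(n_v) < cfg$af_source_missing_rate] <- NA
    }
    clamp(af, 0, 1)
  })

  gene_start <- (seq_len(n_g) - 1L) * 100000L + 1L
  pos <- gene_start[gidx] + offset
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_v, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L),
                character(1L), USE.NAMES = FALSE)

  v <- data.frame(chrom = genes$chrom[gidx], pos = pos, ref = ref,
                  alt = alt, gene_id = genes$gene_id[gidx],
                  consequence = consequence, lof_hc = lof_hc,
                  cadd = cadd, revel = revel, mvp = mvp,
                  stringsAsFactors = FALSE)
  for (src in AF_COLUMNS) v[[src]] <- afs[[src]]
  v
}

resolve_target <- function(target, genes, cfg) {
  if (target %in% genes$gene_id) return(target)
  if (grepl("^bin_[0-9]+$", target)) {
    bins <- make_constraint_bins(genes, "loeuf")
    k <- as.integer(sub("bin_", "", target))
    ids <- bins$gene_id[bins$bin == k]
    if (length(ids)) return(ids)
  }
  if (grepl("^moeuf_bin_[0-9]+$", target)) {
    bins <- make_constraint_bins(genes, "moeuf")
    k <- as.integer(sub("moeuf_bin_", "", target))
    ids <- bins$gene_id[bins$bin == k]
    if (length(ids)) return(ids)
  }
  if (!is.null(cfg$extra_sets) && target %in% names(cfg$extra_sets)) {
    return(intersect(cfg$extra_sets[[target]], genes$gene_id))
  }
  stop("planted target not found: ", target, call. = FALSE)
}

#' Simulate a full case-control cohort
#'
#' Generates samples (stratum, sex, standard-normal ancestry PCs), genes
#' with constraint metrics, annotated variants and sparse genotypes with
#' quality fields, honouring any planted carrier-probability effects.
#' Carriers are drawn per gene x category x stratum as Binomial counts and
#' assigned one qualifying variant each, so the cost scales with the number
#' of carriers rather than samples x variants. The result passes
#' [chd_cohort()] validation unmodified and is byte-reproducible from the
#' seed.
#'
#' @param cfg a [sim_config()].
#' @return a validated `chd_cohort`.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)

  n_tot <- cfg$n_control + cfg$n_schd + cfg$n_nschd
  stratum <- rep(c("control", "sCHD", "nsCHD"),
                 c(cfg$n_control, cfg$n_schd, cfg$n_nschd))
  samples <- data.frame(
    sample_id = sprintf("S%06d", seq_len(n_tot)),
    stratum = stratum,
    sex = sample(c("female", "male"), n_tot, replace = TRUE),
    stringsAsFactors = FALSE)
  pcs <- matrix(stats::rnorm(n_tot * 5L), n_tot, 5L)
  if (cfg$pc_confounding != 0) {
    pcs[, 1L] <- pcs[, 1L] + cfg$pc_confounding * (stratum != "control")
  }
  colnames(pcs) <- paste0("pc", 1:5)
  samples <- cbind(samples, as.data.frame(pcs))

  genes <- sim_genes(cfg)
  variants <- sim_variants(cfg, genes)
  variants$variant_id <- variant_key(variants$chrom, variants$pos,
                                     variants$ref, variants$alt)

  ## qualifying variant pool per gene x category, by the pipeline's own
  ## classification under default thresholds
  ccfg <- category_config()
  cat_v <- as.character(variant_category(variants, ccfg))
  rare_v <- is_rare(variants, ccfg)
  pool_cat <- ifelse(rare_v & cat_v != "none", cat_v, "none")

  ## carrier probability per gene x category x stratum
  categories <- c("hcLOF", "missC", "synonymous")
  base <- cfg$baseline_carrier_rate
  p_arr <- array(base, dim = c(nrow(genes), 3L, 3L),
                 dimnames = list(genes$gene_id, categories, STRATA))
  if (!is.null(cfg$planted_effects)) {
    for (i in seq_len(nrow(cfg$planted_effects))) {
      pe <- cfg$planted_effects[i, ]
      ids <- resolve_target(pe$target, genes, cfg)
      strata <- if (pe$stratum == "aCHD") c("sCHD", "nsCHD") else pe$stratum
      p_arr[ids, pe$category, strata] <-
        stats::plogis(stats::qlogis(base) + log(pe$or))
    }
  }

  idx_by_stratum <- split(seq_len(n_tot), stratum)
  male <- samples$sex == "male"
  is_x <- stats::setNames(genes$chrom == "X", genes$gene_id)

  rows <- list()
  for (cat in categories) {
    vpool <- split(which(pool_cat == cat), variants$gene_id[pool_cat == cat])
    for (st in STRATA) {
      pool_samples <- idx_by_stratum[[st]]
      n_st <- length(pool_samples)
      p_g <- p_arr[, cat, st]
      k_g <- stats::rbinom(length(p_g), n_st, p_g)
      hit <- which(k_g > 0L)
      if (!length(hit)) next
      carrier_sample <- unlist(lapply(hit, function(g) {
        pool_samples[sample.int(n_st, k_g[g])]
      }), use.names = FALSE)
      gene_of <- rep(genes$gene_id[hit], k_g[hit])
      carrier_variant <- unlist(lapply(hit, function(g) {
        vp <- vpool[[genes$gene_id[g]]]
        if (is.null(vp)) integer(0)
        else vp[sample.int(length(vp), k_g[g], replace = TRUE)]
      }), use.names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_idx = carrier_sample, variant_idx = carrier_variant,
        gene_id = gene_of, stringsAsFactors = FALSE)
    }
  }
  carr <- do.call(rbind, rows)
  n_c <- nrow(carr)

  zyg <- ifelse(stats::runif(n_c) < cfg$hom_alt_rate, "hom_alt", "het")
  hemi <- is_x[carr$gene_id] & male[carr$sample_idx]
  zyg[hemi] <- "hemizygous"
  dp <- stats::rnbinom(n_c, size = cfg$dp_size, mu = cfg$dp_mu)
  gq <- as.integer(clamp(round(stats::rnorm(n_c, cfg$gq_mean, cfg$gq_sd)),
                         0, 99))
  ab <- rep(NA_real_, n_c)
  het <- zyg == "het"
  ab[het] <- stats::rbeta(sum(het), cfg$ab_shape1, cfg$ab_shape2)
  ab[!het] <- stats::rbeta(sum(!het), 45, 5)

  genotypes <- data.frame(
    sample_id = samples$sample_id[carr$sample_idx],
    variant_id = variants$variant_id[carr$variant_idx],
    zygosity = zyg, dp = as.integer(dp), gq = gq,
    ab = round(ab, 4), stringsAsFactors = FALSE)
  genotypes <- genotypes[!duplicated(paste(genotypes$sample_id,
                                           genotypes$variant_id)), ]
  genotypes <- genotypes[order(genotypes$sample_id,
                               genotypes$variant_id), ]
  rownames(genotypes) <- NULL

  chd_cohort(variants[, setdiff(names(variants), "variant_id")],
             genotypes, samples, genes)
}

#' Simulate a labelled benign/pathogenic score table
#'
#' Stand-in for a curated ClinVar-style missense set used by
#' [select_score_thresholds()]: class-conditional, mutually correlated
#' CADD/REVEL/MVP (and optionally MPC) triplets driven by a shared latent
#' deleteriousness axis with separation `dprime`, plus gene LOEUF values
#' spanning both constraint strata.
#'
#' @param n_per_class variants per label (>= 1).
#' @param dprime latent class separation in SD units (0 = no signal).
#' @param include_mpc add an `mpc` column with weaker separation (the
#'   candidate score the vetting step is expected to reject at moderate
#'   dprime).
#' @param seed RNG seed (mandatory).
#' @return data.frame with `label`, `gene_loeuf` and score columns.
#' @export
simulate_labeled_scores <- function(n_per_class = 1000L, dprime = 2,
                                    include_mpc = TRUE, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (n_per_class < 1L) stop("n_per_class must be >= 1", call. = FALSE)
  set.seed(seed)
  n <- 2L * n_per_class
  label <- rep(c("benign", "pathogenic"), each = n_per_class)
  z <- stats::rnorm(n, mean = ifelse(label == "pathogenic", dprime, 0))
  ## alternate constrained / non-constrained genes within each label so
  ## both LOEUF strata always contain both classes
  constrained <- rep_len(c(TRUE, FALSE), n)
  loeuf <- ifelse(constrained, stats::runif(n, 0.05, 0.34),
                  stats::runif(n, 0.36, 1.6))
  out <- data.frame(
    label = label,
    gene_loeuf = loeuf,
    cadd = pmax(0, 18 + 4 * z + stats::rnorm(n, 0, 2)),
    revel = clamp(0.4 + 0.12 * z + stats::rnorm(n, 0, 0.06), 0, 1),
    mvp = clamp(0.55 + 0.12 * z + stats::rnorm(n, 0, 0.07), 0, 1),
    stringsAsFactors = FALSE)
  if (include_mpc) {
    out$mpc <- pmax(0, 1 + 0.3 * z + stats::rnorm(n, 0, 0.8))
  }
  out
}

#' Simulate differentially-expressed-gene cluster sets
#'
#' Builds 15 possibly-overlapping gene sets labelled C0..C14 mimicking the
#' per-cell-cluster DEG lists of an embryonic-heart single-cell atlas. When
#' `risk_genes` is given, the named `risk_cluster` draws `risk_overlap` of
#' its members from those genes and every other cluster avoids them, so
#' planted burden effects propagate to exactly one cluster.
#'
#' @param genes gene table (or a `chd_cohort`).
#' @param n_clusters number of clusters (default 15).
#' @param cluster_size genes per cluster.
#' @param risk_genes optional gene ids carrying planted effects.
#' @param risk_cluster label receiving the overlap (default "C14").
#' @param risk_overlap fraction of the risk cluster drawn from
#'   `risk_genes`.
#' @param seed RNG seed (mandatory).
#' @return named list C0..C14 of gene-id vectors.
#' @export
simulate_deg_clusters <- function(genes, n_clusters = 15L,
                                  cluster_size = 100L,
                                  risk_genes = NULL,
                                  risk_cluster = "C14",
                                  risk_overlap = 1,
                                  seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (inherits(genes, "chd_cohort")) genes <- genes$genes
  ids <- genes$gene_id
  if (length(ids) < cluster_size) {
    stop("n_genes smaller than the requested cluster size", call. = FALSE)
  }
  set.seed(seed)
  labels <- paste0("C", seq_len(n_clusters) - 1L)
  safe <- if (is.null(risk_genes)) ids else setdiff(ids, risk_genes)
  sets <- lapply(labels, function(lbl) {
    if (!is.null(risk_genes) && lbl == risk_cluster) {
      k <- min(round(risk_overlap * cluster_size), length(risk_genes))
      c(sample(risk_genes, k),
        if (cluster_size > k) sample(safe, cluster_size - k))
    } else {
      sample(safe, min(cluster_size, length(safe)))
    }
  })
  stats::setNames(sets, labels)
}

#' Simulate a long-format bulk expression table
#'
#' Log-normal RPKM across tissues and developmental stages, with an
#' optional mean shift (in SD units of log expression) planted for a gene
#' set in selected tissues — the structure needed to exercise
#' [mean_early_expression()], [percentile_rank()] and
#' [compare_gene_sets()].
#'
#' @param gene_ids character vector of genes.
#' @param tissues tissue labels.
#' @param stages weeks-post-conception sampling points.
#' @param shift_genes,shift_tissues,shift_sd planted upward shift.
#' @param seed RNG seed (mandatory).
#' @return data.frame `gene_id`, `tissue`, `stage`, `rpkm`.
#' @export
simulate_expression <- function(gene_ids,
                                tissues = c("heart", "kidney", "brain",
                                            "liver"),
                                stages = c(4, 5, 6, 7, 8, 9),
                                shift_genes = NULL, shift_tissues = NULL,
                                shift_sd = 1, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  set.seed(seed)
  grid <- expand.grid(gene_id = gene_ids, tissue = tissues, stage = stages,
                      stringsAsFactors = FALSE)
  ## between-gene log-expression SD 1 dominates the per-observation noise
  ## (0.5), so shift_sd is effectively in between-gene SD units; baselines
  ## are drawn per gene x tissue so tissues are exchangeable under the null
  mu <- matrix(stats::rnorm(length(gene_ids) * length(tissues), 2, 1),
               length(gene_ids), length(tissues),
               dimnames = list(gene_ids, tissues))
  lg <- mu[cbind(grid$gene_id, grid$tissue)] +
    stats::rnorm(nrow(grid), 0, 0.5)
  if (!is.null(shift_genes)) {
    hit <- grid$gene_id %in% shift_genes &
      grid$tissue %in% (shift_tissues %||% tissues)
    lg[hit] <- lg[hit] + shift_sd
  }
  grid$rpkm <- exp(lg)
  grid
}

`%||%` <- function(a, b) if (is.null(a)) b else a
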