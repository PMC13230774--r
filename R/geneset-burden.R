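## Gene-set burden: LOEUF/MOEUF constraint decile bins, per-sample minor
## allele counts (MAC) aggregated over a gene set, and the covariate-
## adjusted logistic burden test per set x CHD stratum x variant category.

#' Bin genes into constraint deciles
#'
#' Genes carrying the chosen constraint metric are sorted ascending (ties
#' broken by gene_id for determinism) and split into `n_bins` contiguous
#' groups of near-equal size (sizes differ by at most one; the first bins
#' take the remainder). Bin 1 holds the lowest metric values, i.e. the most
#' constrained genes. Genes lacking the metric are unassigned.
#'
#' @param genes gene table (`gene_id`, `loeuf`, `moeuf`).
#' @param metric "loeuf" or "moeuf".
#' @param n_bins number of bins (default 10).
#' @return object of class `constraint_bins`: data.frame `gene_id`, `bin`
#'   with attributes `metric` and `n_bins`.
#' @export
make_constraint_bins <- function(genes, metric = c("loeuf", "moeuf"),
                                 n_bins = 10L) {
  metric <- match.arg(metric)
  x <- genes[[metric]]
  keep <- !is.na(x)
  if (!any(keep)) stop("metric ", metric, " absent for all genes",
                       call. = FALSE)
  ids <- genes$gene_id[keep]
  x <- x[keep]
  if (length(ids) < n_bins) {
    stop("fewer genes with ", metric, " than bins", call. = FALSE)
  }
  ord <- order(x, ids)
  n <- length(ids)
  base <- n %/% n_bins
  extra <- n %% n_bins
  sizes <- rep(base, n_bins) + c(rep(1L, extra), rep(0L, n_bins - extra))
  bin <- rep(seq_len(n_bins), times = sizes)
  out <- data.frame(gene_id = ids[ord], bin = bin, stringsAsFactors = FALSE)
  structure(out, metric = metric, n_bins = as.integer(n_bins),
            class = c("constraint_bins", "data.frame"))
}

#' Turn a constraint binning into a named gene-set list
#'
#' @param bins a [make_constraint_bins()] result.
#' @return named list `bin_1` .. `bin_k` of gene-id vectors.
#' @export
bins_as_gene_sets <- function(bins) {
  stopifnot(inherits(bins, "constraint_bins"))
  sets <- split(bins$gene_id, bins$bin)
  names(sets) <- paste0("bin_", names(sets))
  sets
}

#' Per-sample minor allele count over a gene set
#'
#' Sums allele dosage (het = 1, hom_alt = 2, hemizygous = 1) over
#' QC-passing genotypes at rare variants of the given category within the
#' set's genes.
#'
#' @param cohort a `chd_cohort`.
#' @param gene_set character vector of gene ids.
#' @param category "hcLOF", "missC" or "synonymous".
#' @param cfg a [category_config()].
#' @return named integer vector over all cohort samples (zeros included).
#' @export
per_sample_mac <- function(cohort, gene_set, category,
                           cfg = category_config()) {
  q <- qualifying_genotypes(cohort, cfg)
  q <- q[q$category == category & q$gene_id %in% gene_set, , drop = FALSE]
  dosage <- c(het = 1L, hom_alt = 2L, hemizygous = 1L)[q$zygosity]
  dosage[is.na(dosage)] <- 0L
  mac <- stats::setNames(rep(0L, nrow(cohort$samples)),
                         cohort$samples$sample_id)
  if (nrow(q)) {
    agg <- rowsum(as.integer(dosage), group = q$sample_id)
    mac[rownames(agg)] <- as.integer(agg[, 1L])
  }
  mac
}

#' Logistic gene-set burden test
#'
#' Maximum-likelihood logistic regression of case/control status on the
#' per-sample MAC, adjusting for the supplied covariates (the five ancestry
#' PCs and sex in the standard battery). The Wald z p-value on the MAC
#' coefficient is reported with `OR = exp(beta)` and a 95% Wald CI.
#' Degenerate inputs (no MAC variation), non-convergence and
#' quasi-separation are flagged on the result instead of silently reported.
#'
#' @param mac numeric vector of per-sample minor allele counts.
#' @param status logical/0-1 case indicator (both classes required).
#' @param covariates optional numeric matrix or data.frame, rows aligned
#'   with `mac`; rank-deficient columns are dropped with a warning.
#' @return one-row data.frame: `beta`, `se`, `odds_ratio`, `ci_low`,
#'   `ci_high`, `p`, `flag` ("" when clean).
#' @export
logistic_geneset_test <- function(mac, status, covariates = NULL) {
  status <- as.integer(status)
  if (length(unique(status)) < 2L) {
    stop("single-class response: both cases and controls required",
         call. = FALSE)
  }
  if (min(table(status)) < 2L) {
    stop("need at least 2 samples per class", call. = FALSE)
  }
  empty <- function(flag) {
    data.frame(beta = NA_real_, se = NA_real_, odds_ratio = NA_real_,
               ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
               flag = flag, stringsAsFactors = FALSE)
  }
  if (stats::var(mac) == 0) return(empty("degenerate"))
  dat <- data.frame(.status = status, .mac = as.numeric(mac))
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    dat <- cbind(dat, covariates)
  }
  fit <- suppressWarnings(
    stats::glm(.status ~ ., data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100L)))
  alias <- is.na(stats::coef(fit))
  if (any(alias)) {
    warning("dropped rank-deficient covariate column(s): ",
            paste(names(stats::coef(fit))[alias], collapse = ", "),
            call. = FALSE)
  }
  cf <- summary(fit)$coefficients
  if (!".mac" %in% rownames(cf)) return(empty("degenerate"))
  beta <- cf[".mac", "Estimate"]
  se <- cf[".mac", "Std. Error"]
  flag <- ""
  if (!fit$converged) flag <- "non_convergence"
  if (se > 10 || abs(beta) > 15) {
    flag <- paste0(flag, if (nzchar(flag)) "+", "quasi_separation")
  }
  data.frame(beta = beta, se = se, odds_ratio = exp(beta),
             ci_low = exp(beta - 1.96 * se),
             ci_high = exp(beta + 1.96 * se),
             p = 2 * stats::pnorm(-abs(beta / se)),
             flag = flag, stringsAsFactors = FALSE)
}

encode_sex <- function(sex) {
  known <- sex[sex != "unknown"]
  majority <- if (length(known) && mean(known == "male") > 0.5) "male"
              else "female"
  imputed <- sex == "unknown"
  sex[imputed] <- majority
  list(x = as.numeric(sex == "male"), n_imputed = sum(imputed))
}

#' Run the gene-set burden battery
#'
#' One logistic burden test per (gene set, CHD stratum) within each variant
#' category, adjusting for the five ancestry PCs and sex. `aCHD` pools the
#' sCHD and nsCHD cases. The per-category family-wise Bonferroni factor is
#' `#sets x #strata` (45 for the 15 single-cell DEG clusters across three
#' strata). Unknown sex is imputed to the cohort majority (counted on the
#' result); the synonymous category serves as the negative control.
#'
#' @param cohort a `chd_cohort`.
#' @param sets named list of gene-id vectors (e.g. [bins_as_gene_sets()] or
#'   [read_gene_sets()] output).
#' @param strata subset of c("aCHD", "sCHD", "nsCHD").
#' @param categories subset of c("hcLOF", "missC", "synonymous").
#' @param cfg a [category_config()].
#' @param alpha family-wise level for the significance flag.
#' @return object of class `chd_geneset_burden`: data.frame with one row
#'   per set x stratum x category (`beta`, `se`, `odds_ratio`, `ci_low`,
#'   `ci_high`, `p`, `p_bonferroni`, `n_tests_family`, `significant`,
#'   `flag`).
#' @export
run_geneset_battery <- function(cohort, sets,
                                strata = c("aCHD", "sCHD", "nsCHD"),
                                categories = c("hcLOF", "missC",
                                               "synonymous"),
                                cfg = category_config(), alpha = 0.05) {
  stopifnot(is.list(sets), !is.null(names(sets)), all(nzchar(names(sets))))
  strata <- match.arg(strata, several.ok = TRUE)
  categories <- match.arg(categories, several.ok = TRUE)
  smp <- cohort$samples
  sex <- encode_sex(smp$sex)
  covars <- cbind(as.matrix(smp[, paste0("pc", 1:5)]), sex = sex$x)
  family_n <- length(sets) * length(strata)

  case_mask <- list(aCHD = smp$stratum %in% c("sCHD", "nsCHD"),
                    sCHD = smp$stratum == "sCHD",
                    nsCHD = smp$stratum == "nsCHD")
  ctrl <- smp$stratum == "control"

  rows <- list()
  for (cat in categories) {
    macs <- lapply(sets, function(g) per_sample_mac(cohort, g, cat, cfg))
    for (lbl in names(sets)) {
      for (st in strata) {
        keep <- ctrl | case_mask[[st]]
        r <- logistic_geneset_test(macs[[lbl]][keep],
                                   case_mask[[st]][keep],
                                   covars[keep, , drop = FALSE])
        r <- cbind(data.frame(set_label = lbl, stratum = st,
                              category = cat, stringsAsFactors = FALSE), r)
        rows[[length(rows) + 1L]] <- r
      }
    }
  }
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p * family_n)
  out$n_tests_family <- family_n
  out$significant <- !is.na(out$p_bonferroni) & out$p_bonferroni < alpha
  rownames(out) <- NULL
  structure(list(results = out, family_n = family_n, alpha = alpha,
                 n_sex_imputed = sex$n_imputed),
            class = "chd_geneset_burden")
}

#' @export
print.chd_geneset_burden <- function(x, ...) {
  cat("chd_geneset_burden\n")
  cat(sprintf("  %d tests; per-category Bonferroni family n = %d (alpha %.3g)\n",
              nrow(x$results), x$family_n, x$alpha))
  sig <- x$results[x$results$significant, , drop = FALSE]
  cat(sprintf("  significant set x stratum x category combinations: %d\n",
              nrow(sig)))
  if (nrow(sig)) {
    print(sig[order(sig$p),
              c("set_label", "stratum", "category", "odds_ratio",
                "ci_low", "ci_high", "p", "p_bonferroni")],
          row.names = FALSE)
  }
  invisible(x)
}

#' @export
as.data.frame.chd_geneset_burden <- function(x, ...) x$results
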