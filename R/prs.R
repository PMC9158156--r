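#' Read a PRS weight table
#'
#' Tab-separated with columns `variant_id`, `risk_allele`, `weight`
#' (log-odds per risk allele), `imputation_r2` and `is_apoe_region`. With no
#' path, the packaged synthetic 35-variant table
#' (`prs_weights_synthetic.tsv`, realistic-magnitude placeholder weights at
#' genome-wide significant AD loci) is read.
#'
#' @param path Path to a weights TSV, or `NULL` for the packaged table.
#' @return Validated data.frame.
#' @export
read_prs_weights <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "prs_weights_synthetic.tsv",
                        package = "famalz")
  w <- read.delim(path, stringsAsFactors = FALSE)
  needed <- c("variant_id", "risk_allele", "weight", "imputation_r2",
              "is_apoe_region")
  if (!all(needed %in% names(w)))
    stop("weights table needs columns: ", paste(needed, collapse = ", "))
  if (any(!is.finite(w$weight))) stop("weights must be finite")
  if (any(w$imputation_r2 < 0 | w$imputation_r2 > 1))
    stop("imputation_r2 must be in [0, 1]")
  w$is_apoe_region <- as.logical(w$is_apoe_region)
  w
}

#' Compute raw polygenic risk scores
#'
#' Weighted dosage sum per sample:
#' \eqn{\mathrm{PRS} = \sum_k d_k w_k} over the retained variants —
#' non-APOE-region variants with imputation quality `imputation_r2 >=
#' min_r2`. APOE-region variants never enter the PRS (APOE risk is scored
#' separately on the same scale). A missing dosage skips that term for that
#' sample and is recorded in the audit.
#'
#' @param dosages Numeric matrix, samples x variants (allele dosages in
#'   `[0, 2]`, hard calls or imputed fractions), with column names matching
#'   `weights$variant_id`.
#' @param weights Weight table (see [read_prs_weights()]).
#' @param min_r2 Imputation-quality gate (default 0.3 for imputed sequence
#'   dosages; use 0.6 for array-genotyped sources).
#' @return Named numeric vector of raw scores with attribute `"audit"`:
#'   list(`n_variants_used`, `dropped_low_r2`, `dropped_apoe`,
#'   `missing_dosage` = per-sample skipped-term counts).
#' @export
compute_prs <- function(dosages, weights, min_r2 = 0.3) {
  dosages <- as.matrix(dosages)
  keep <- !weights$is_apoe_region & weights$imputation_r2 >= min_r2
  used <- weights[keep, , drop = FALSE]
  missing_cols <- setdiff(used$variant_id, colnames(dosages))
  if (length(missing_cols))
    stop("dosage columns missing for weight variants: ",
         paste(head(missing_cols, 5), collapse = ", "))
  d <- dosages[, used$variant_id, drop = FALSE]
  if (any(d < 0 | d > 2, na.rm = TRUE))
    stop("dosages must lie in [0, 2]")
  n_miss <- rowSums(is.na(d))
  d[is.na(d)] <- 0  # missing dosage: term skipped for that sample
  prs <- as.numeric(d %*% used$weight)
  names(prs) <- rownames(dosages)
  attr(prs, "audit") <- list(
    n_variants_used = nrow(used),
    dropped_low_r2 = sum(!weights$is_apoe_region &
                           weights$imputation_r2 < min_r2),
    dropped_apoe = sum(weights$is_apoe_region),
    missing_dosage = n_miss
  )
  prs
}

#' Centre risk scores on a population-control mean
#'
#' Subtracts the mean raw score of a population-based control set, so that 0
#' is the population average and `exp(score)` is an odds ratio relative to
#' it.
#'
#' @param prs_raw Numeric vector of raw scores.
#' @param control_scores Raw scores of the population control set
#'   (non-empty).
#' @return `prs_raw - mean(control_scores)`, names preserved.
#' @export
scale_to_population <- function(prs_raw, control_scores) {
  if (!length(control_scores)) stop("control score set must be non-empty")
  prs_scaled <- as.numeric(prs_raw) - mean(control_scores)
  names(prs_scaled) <- names(prs_raw)
  prs_scaled
}

#' APOE risk model
#'
#' Per-allele log-odds effects for the two APOE-defining SNPs and the
#' population-mean offset that places scores on the same
#' population-centred scale as the PRS: each e4 allele adds `effect_e4`
#' (+1.20), each e2 allele adds `effect_e2` (-0.47), and the population mean
#' is subtracted so that the e3e3 genotype scores `-population_mean_offset`
#' (-0.36 by default, the offset implied by an e4-rich control population).
#'
#' @param effect_e4,effect_e2 Per-allele log-odds effects.
#' @param population_mean_offset Population-mean APOE risk subtracted from
#'   every score; recomputable from a control set as the mean unscaled risk.
#' @return List of class `apoe_model`.
#' @export
apoe_model <- function(effect_e4 = 1.20, effect_e2 = -0.47,
                       population_mean_offset = 0.36) {
  structure(list(effect_e4 = effect_e4, effect_e2 = effect_e2,
                 population_mean_offset = population_mean_offset),
            class = "apoe_model")
}

#' Population-scaled APOE risk of a diplotype
#'
#' `risk = effect_e4 * n(e4) + effect_e2 * n(e2) - offset`, so with the
#' default model e3e3 scores -0.36, e3e4 scores 0.84 and e4e4 scores 2.04.
#' Missing genotypes propagate as `NA`.
#'
#' @param genotype Character vector of diplotypes written as allele digit
#'   pairs: `"22"`, `"23"`, `"24"`, `"33"`, `"34"`, `"44"` (order
#'   irrelevant), or `NA`.
#' @param model An [apoe_model()].
#' @return Numeric vector of scaled log-odds risks.
#' @export
apoe_risk <- function(genotype, model = apoe_model()) {
  gt <- as.character(genotype)
  known <- c("22", "23", "24", "33", "34", "44", "32", "42", "43")
  bad <- setdiff(unique(gt[!is.na(gt)]), known)
  if (length(bad))
    stop("unknown APOE genotype(s): ", paste(bad, collapse = ", "))
  n4 <- vapply(strsplit(gt, ""), function(a) sum(a == "4"), numeric(1))
  n2 <- vapply(strsplit(gt, ""), function(a) sum(a == "2"), numeric(1))
  out <- model$effect_e4 * n4 + model$effect_e2 * n2 -
    model$population_mean_offset
  out[is.na(gt)] <- NA_real_
  names(out) <- names(genotype)
  out
}

#' Family-averaged risk over affected members
#'
#' The per-family score is the arithmetic mean of the scores of its affected
#' members; unaffected relatives are excluded. Families whose affected
#' members all lack scores get `NA` with a warning.
#'
#' @param scores Named numeric vector of per-sample scores (PRS or APOE
#'   risk, population-scaled).
#' @param phenotypes data.frame with `sample_id`, `family_id`, `status`
#'   (statuses `EOAD`/`LOAD`/`MCI`/`AD` count as affected).
#' @return Named numeric vector of per-family means.
#' @export
family_average <- function(scores, phenotypes) {
  aff <- phenotypes[is_affected(phenotypes$status) &
                      !is.na(phenotypes$family_id), , drop = FALSE]
  vals <- scores[aff$sample_id]
  means <- tapply(vals, aff$family_id, mean, na.rm = TRUE)
  if (any(is.nan(means))) {
    warning("family with no scored affected member: ",
            paste(names(means)[is.nan(means)], collapse = ", "))
    means[is.nan(means)] <- NA_real_
  }
  out <- as.numeric(means)
  names(out) <- names(means)
  out
}

#' Convert a population-scaled log-odds effect to an odds ratio
#'
#' @param beta Numeric log-odds effect(s).
#' @return `exp(beta)`: 0 maps to OR 1, 1 to OR 2.72.
#' @export
beta_to_or <- function(beta) exp(beta)
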