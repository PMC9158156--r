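#' Gene-level ordinal rare-variant burden test
#'
#' For each gene and each cumulative CADD stratum (stratum `s` keeps variants
#' with CADD >= `s`; `"none"` keeps all), builds a dominant carrier indicator
#' (>= 1 qualifying allele), and fits a proportional-odds model of the
#' ordered outcome (control < LOAD < EOAD) on the carrier indicator plus the
#' ancestry principal components. Genes with fewer carriers than
#' `min_carriers`, or with no carriers or all carriers, are skipped with a
#' reason. The burden coefficient is tested two-sided (Wald); under complete
#' separation the p-value falls back to a likelihood-ratio test against the
#' covariates-only model. p-values are Benjamini-Hochberg adjusted across
#' all tests performed in the call.
#'
#' @param variant_carriers Long data.frame of qualifying calls: one row per
#'   (sample, variant) with columns `sample_id`, `unit` (gene symbol or
#'   variant id), `cadd` (may be `NA`; `NA` only qualifies in the `"none"`
#'   stratum).
#' @param labels Named (by sample id) outcome vector/factor with levels
#'   among control, LOAD, EOAD; or unnamed and aligned with `pcs` rows.
#' @param pcs Numeric matrix of covariates (samples x PCs), rownames
#'   matching label names when named.
#' @param min_carriers Minimum carrier count (default 10 for genes).
#' @param cadd_strata Numeric CADD thresholds (default `c(15, 20, 25, 30)`);
#'   use `"none"`/`NA` entries for the unstratified analysis.
#' @return List with `results` (data.frame `unit`, `cadd_stratum`,
#'   `n_carriers`, `beta`, `se`, `p`, `q`, `or_`, `separation`) and
#'   `skipped` (data.frame `unit`, `cadd_stratum`, `reason`).
#' @export
gene_burden <- function(variant_carriers, labels, pcs,
                        min_carriers = 10L,
                        cadd_strata = c(15, 20, 25, 30)) {
  burden_core(variant_carriers, labels, pcs, min_carriers, cadd_strata)
}

#' Variant-level ordinal burden test
#'
#' Same contract as [gene_burden()] with the unit being a single variant and
#' a minimum of 5 carriers.
#'
#' @inheritParams gene_burden
#' @export
variant_burden <- function(variant_carriers, labels, pcs,
                           min_carriers = 5L,
                           cadd_strata = c(15, 20, 25, 30)) {
  burden_core(variant_carriers, labels, pcs, min_carriers, cadd_strata)
}

burden_core <- function(variant_carriers, labels, pcs, min_carriers,
                        cadd_strata) {
  stopifnot(all(c("sample_id", "unit") %in% names(variant_carriers)))
  if (!"cadd" %in% names(variant_carriers))
    variant_carriers$cadd <- NA_real_
  labels <- order_labels(labels)
  samples <- names(labels)
  if (is.null(samples)) {
    samples <- rownames(pcs) %||% sprintf("s%d", seq_along(labels))
    names(labels) <- samples
  }
  pcs <- as.matrix(pcs)
  if (!is.null(rownames(pcs))) pcs <- pcs[samples, , drop = FALSE]
  if (nrow(pcs) != length(labels))
    stop("pcs must have one row per labelled sample")
  null_fit <- NULL
  res <- list(); skip <- list()
  strata <- if (is.null(cadd_strata) || !length(cadd_strata)) NA else
    cadd_strata
  for (s in strata) {
    s_name <- if (is.na(suppressWarnings(as.numeric(s)))) "none" else
      as.character(s)
    vc <- variant_carriers
    if (s_name != "none")
      vc <- vc[!is.na(vc$cadd) & vc$cadd >= as.numeric(s), , drop = FALSE]
    carriers_by_unit <- split(vc$sample_id, vc$unit)
    for (unit in names(carriers_by_unit)) {
      carrier <- as.integer(samples %in% carriers_by_unit[[unit]])
      nc <- sum(carrier)
      if (nc < min_carriers) {
        skip[[length(skip) + 1L]] <- data.frame(
          unit = unit, cadd_stratum = s_name,
          reason = sprintf("fewer than %d carriers (%d)", min_carriers, nc),
          stringsAsFactors = FALSE)
        next
      }
      if (nc == length(samples)) {
        skip[[length(skip) + 1L]] <- data.frame(
          unit = unit, cadd_stratum = s_name, reason = "all samples carry",
          stringsAsFactors = FALSE)
        next
      }
      fit <- fit_proportional_odds(labels, cbind(carrier = carrier, pcs))
      beta <- fit$beta[["carrier"]]
      se <- fit$se[["carrier"]]
      pval <- fit$p_wald[["carrier"]]
      if (fit$separation || !is.finite(se)) {
        # likelihood-ratio fallback against the covariates-only model
        if (is.null(null_fit))
          null_fit <- fit_proportional_odds(labels, pcs)
        lr <- 2 * (fit$logLik - null_fit$logLik)
        pval <- pchisq(max(lr, 0), df = 1, lower.tail = FALSE)
      }
      res[[length(res) + 1L]] <- data.frame(
        unit = unit, cadd_stratum = s_name, n_carriers = nc,
        beta = beta, se = se, p = pval, or_ = exp(beta),
        separation = fit$separation, stringsAsFactors = FALSE)
    }
  }
  results <- if (length(res)) do.call(rbind, res) else
    data.frame(unit = character(), cadd_stratum = character(),
               n_carriers = integer(), beta = numeric(), se = numeric(),
               p = numeric(), or_ = numeric(), separation = logical(),
               stringsAsFactors = FALSE)
  results$q <- adjust_fdr(results$p)
  results <- results[, c("unit", "cadd_stratum", "n_carriers", "beta", "se",
                         "p", "q", "or_", "separation")]
  rownames(results) <- NULL
  skipped <- if (length(skip)) do.call(rbind, skip) else
    data.frame(unit = character(), cadd_stratum = character(),
               reason = character(), stringsAsFactors = FALSE)
  list(results = results, skipped = skipped)
}

# Coerce an outcome vector to the ordered factor control < LOAD < EOAD,
# keeping only the levels present.
order_labels <- function(labels) {
  nm <- names(labels)
  if (is.factor(labels)) labels <- as.character(labels)
  bad <- setdiff(unique(labels), c("control", "LOAD", "EOAD"))
  if (length(bad))
    stop("unknown outcome label(s): ", paste(bad, collapse = ", "))
  out <- factor(labels, levels = c("control", "LOAD", "EOAD"),
                ordered = TRUE)
  out <- droplevels(out)
  names(out) <- nm
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up BH adjustment with monotonicity enforcement (wraps
#' `stats::p.adjust(method = "BH")`). An empty input returns an empty
#' vector.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same length and order as `p`.
#' @export
adjust_fdr <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must be in [0, 1]")
  p.adjust(p, method = "BH")
}
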