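#' Read a family summary table
#'
#' Loads the per-family summary used by the subgroup statistics and the
#' actionability categorizer. With no path, the packaged 36-family reference
#' fixture is read (per family: number of patients, mean onset age,
#' pathogenic-variant and VUS gene if any, population-scaled family APOE
#' risk and PRS, and whether any affected member is an e4e4 homozygote).
#'
#' @param path Path to a TSV, or `NULL` for the packaged fixture.
#' @return data.frame with columns `family_id`, `n_patients`, `onset_age`,
#'   `pv_gene`, `vus_gene`, `apoe_risk`, `prs`, `has_e44`, plus derived
#'   logicals `has_pv`, `has_vus`.
#' @export
read_family_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "table1_families.tsv", package = "famalz")
  d <- read.delim(path, stringsAsFactors = FALSE)
  for (col in c("pv_gene", "vus_gene"))
    d[[col]] <- ifelse(is.na(d[[col]]), "", d[[col]])
  d$has_pv <- nzchar(d$pv_gene)
  d$has_vus <- nzchar(d$vus_gene)
  d$has_e44 <- as.logical(d$has_e44)
  d
}

#' Compare family PRS between two groups (unpaired t-test)
#'
#' Group means and sample standard deviations with a two-sided unpaired
#' t-test. The default is the classic pooled-variance test
#' (`var_equal = TRUE`), matching standard reporting practice for
#' family-subgroup PRS comparisons; Welch's correction is available with
#' `var_equal = FALSE`. A group of size 1 yields means but `p = NA`.
#'
#' @param summaries Family summary data.frame (see [read_family_table()]).
#' @param group Logical vector (one element per family) or vector of
#'   `family_id`s defining the first group; the rest form the second.
#' @param value Column compared (default `"prs"`).
#' @param var_equal Pooled-variance (default) vs Welch.
#' @return List: `n`, `mean`, `sd` (each length 2: group, rest),
#'   `statistic`, `p`.
#' @export
subgroup_compare_prs <- function(summaries, group, value = "prs",
                                 var_equal = TRUE) {
  g <- as_group(summaries, group)
  x <- summaries[[value]][g]
  y <- summaries[[value]][!g]
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  out <- list(n = c(length(x), length(y)),
              mean = c(mean(x), mean(y)),
              sd = c(sd(x), sd(y)),
              statistic = NA_real_, p = NA_real_)
  if (length(x) > 1 && length(y) > 1) {
    tt <- t.test(x, y, var.equal = var_equal)
    out$statistic <- unname(tt$statistic)
    out$p <- tt$p.value
  }
  out
}

#' Compare family APOE risk between two groups (Mann-Whitney U)
#'
#' Two-sided Mann-Whitney U test using the tie-corrected normal
#' approximation with continuity correction, on the family-averaged APOE
#' risk.
#'
#' @inheritParams subgroup_compare_prs
#' @param value Column compared (default `"apoe_risk"`).
#' @return List: `n`, `mean`, `sd`, `U` (the Mann-Whitney statistic for
#'   group vs rest), `p`.
#' @export
subgroup_compare_apoe <- function(summaries, group, value = "apoe_risk") {
  g <- as_group(summaries, group)
  x <- summaries[[value]][g]
  y <- summaries[[value]][!g]
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
  list(n = c(length(x), length(y)),
       mean = c(mean(x), mean(y)),
       sd = c(sd(x), sd(y)),
       U = unname(wt$statistic), p = wt$p.value)
}

#' Spearman correlation between family APOE risk and PRS
#'
#' Rank correlation with average ranks for ties; the asymptotic two-sided
#' p-value is used (family-level scores are heavily tied after rounding, so
#' an exact permutation null is unavailable).
#'
#' @param summaries Family summary data.frame.
#' @param exclude_pv Drop families with a pathogenic variant first
#'   (default `TRUE`).
#' @return List: `rho`, `p`, `n`.
#' @export
correlate_apoe_prs <- function(summaries, exclude_pv = TRUE) {
  d <- if (exclude_pv) summaries[!summaries$has_pv, , drop = FALSE] else
    summaries
  if (nrow(d) < 3) stop("need at least 3 families")
  ct <- suppressWarnings(cor.test(d$apoe_risk, d$prs, method = "spearman",
                                  exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = nrow(d))
}

#' Assign families to clinical actionability categories
#'
#' Per family, genetic flags are raised for: a pathogenic variant (`PV`), a
#' variant of uncertain significance (`VUS`), at least one affected e4e4
#' homozygote (`APOE`), and an elevated family PRS
#' (`PRS`, `prs >= prs_flag_threshold`). The category is then:
#' \itemize{
#'   \item `monogenic` — the PV flag is set (genetic cause identified,
#'     reportable);
#'   \item `risk_factors` — no PV but at least one other flag (possible
#'     polygenic/multifactorial etiology, not clinically actionable);
#'   \item `unresolved` — no flags (candidates for further genetic
#'     work-up).
#' }
#'
#' @param summaries Family summary data.frame (see [read_family_table()]).
#' @param prs_flag_threshold Family-PRS flagging threshold (default 0.45).
#' @return data.frame `family_id`, `flags` (comma-separated), `category`
#'   (factor monogenic/risk_factors/unresolved).
#' @export
categorize <- function(summaries, prs_flag_threshold = 0.45) {
  f_pv <- summaries$has_pv
  f_vus <- summaries$has_vus
  f_apoe <- summaries$has_e44
  f_prs <- summaries$prs >= prs_flag_threshold
  flags <- mapply(function(a, b, c_, d) {
    paste(c("PV", "VUS", "APOE", "PRS")[c(a, b, c_, d)], collapse = ",")
  }, f_pv, f_vus, f_apoe, f_prs)
  category <- ifelse(f_pv, "monogenic",
                     ifelse(f_vus | f_apoe | f_prs, "risk_factors",
                            "unresolved"))
  data.frame(
    family_id = summaries$family_id,
    flags = unname(flags),
    category = factor(category, levels = c("monogenic", "risk_factors",
                                           "unresolved")),
    stringsAsFactors = FALSE
  )
}

#' Full subgroup comparison report
#'
#' Recomputes the standard subgroup table on a family summary: APOE risk and
#' PRS means/SDs and group-vs-rest p-values for all families, families with
#' any pathogenic variant, APP/PSEN1 families, VUS families, and the
#' low (< 1, no PV) / high (> 2) APOE-risk strata. APOE comparisons use the
#' Mann-Whitney U test, PRS comparisons the unpaired t-test.
#'
#' @param summaries Family summary data.frame.
#' @param var_equal Passed to [subgroup_compare_prs()].
#' @return data.frame: one row per (measure, subgroup) with `n`, `mean`,
#'   `sd`, `p_vs_rest` (NA for the all-families row).
#' @export
table3_report <- function(summaries, var_equal = TRUE) {
  groups <- list(
    all = rep(TRUE, nrow(summaries)),
    pathogenic_variant = summaries$has_pv,
    app_psen1 = summaries$pv_gene %in% c("APP", "PSEN1"),
    vus = summaries$has_vus,
    low_apoe_no_pv = !summaries$has_pv & summaries$apoe_risk < 1,
    high_apoe = summaries$apoe_risk > 2
  )
  rows <- list()
  for (measure in c("apoe_risk", "prs")) {
    for (gname in names(groups)) {
      g <- groups[[gname]]
      if (gname == "all") {
        rows[[length(rows) + 1L]] <- data.frame(
          measure = measure, subgroup = gname, n = sum(g),
          mean = mean(summaries[[measure]]), sd = sd(summaries[[measure]]),
          p_vs_rest = NA_real_, stringsAsFactors = FALSE)
        next
      }
      if (measure == "apoe_risk" && gname %in% c("low_apoe_no_pv",
                                                 "high_apoe")) next
      if (sum(g) == 0 || sum(!g) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          measure = measure, subgroup = gname, n = sum(g),
          mean = if (sum(g)) mean(summaries[[measure]][g]) else NA_real_,
          sd = if (sum(g) > 1) sd(summaries[[measure]][g]) else NA_real_,
          p_vs_rest = NA_real_, stringsAsFactors = FALSE)
        next
      }
      cmp <- if (measure == "apoe_risk")
        subgroup_compare_apoe(summaries, g) else
          subgroup_compare_prs(summaries, g, var_equal = var_equal)
      rows[[length(rows) + 1L]] <- data.frame(
        measure = measure, subgroup = gname, n = cmp$n[1],
        mean = cmp$mean[1], sd = cmp$sd[1], p_vs_rest = cmp$p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

as_group <- function(summaries, group) {
  if (is.logical(group)) {
    stopifnot(length(group) == nrow(summaries))
    return(group)
  }
  summaries$family_id %in% group
}

#' Round half away from zero
#'
#' Display rounding used in the per-family reports (0.005 -> 0.01,
#' -0.005 -> -0.01), unlike base R's round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 2) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}
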