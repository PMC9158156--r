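#' Filtering criteria for family-based rare-variant segregation analysis
#'
#' The four conjunctive stages of the family filter: call quality
#' (quality-by-depth), functional consequence (coding or near-splice),
#' population rarity (gnomAD allele frequency) and within-family segregation
#' (heterozygous in every affected member, homozygous reference in every
#' unaffected member).
#'
#' @param min_qd Minimum quality-by-depth (inclusive; default 5).
#' @param consequence_whitelist Coding consequence classes accepted
#'   unconditionally.
#' @param splice_window Splice-region window in bp from the nearest
#'   exon-intron junction (default 2).
#' @param max_maf Maximum gnomAD allele frequency, exclusive (default 0.001,
#'   i.e. MAF < 0.1%).
#' @param use_nfe If `TRUE`, filter on the non-Finnish-European gnomAD
#'   frequency instead of the total.
#' @return A list of class `filter_criteria`.
#' @export
filter_criteria <- function(min_qd = 5,
                            consequence_whitelist = c("missense", "nonsense",
                                                      "frameshift", "splice"),
                            splice_window = 2, max_maf = 0.001,
                            use_nfe = FALSE) {
  if (min_qd <= 0 || splice_window < 0 || max_maf <= 0)
    stop("filter thresholds must be positive")
  structure(list(min_qd = min_qd,
                 consequence_whitelist = consequence_whitelist,
                 splice_window = splice_window, max_maf = max_maf,
                 use_nfe = isTRUE(use_nfe)),
            class = "filter_criteria")
}

#' Restrict a cohort's variants to one family
#'
#' Subsets the genotype columns to the family members and keeps only records
#' with at least one non-reference call among them (the per-family view of
#' the cohort VCF).
#'
#' @param variants Annotation data.frame (one row per variant, see
#'   [plant_rare_variants()] for the schema).
#' @param geno Genotype matrix, variants x samples (0/1/2, `NA`), rownames
#'   matching `variants$variant_id`.
#' @param members Character vector of the family's sample ids; every member
#'   must be a genotype column, otherwise an error names the missing sample.
#' @return List of class `family_view`: `variants` and `geno` restricted to
#'   the family.
#' @export
build_family_view <- function(variants, geno, members) {
  missing <- setdiff(members, colnames(geno))
  if (length(missing))
    stop("family member(s) missing from cohort genotypes: ",
         paste(missing, collapse = ", "))
  g <- geno[, members, drop = FALSE]
  carried <- rowSums(g > 0, na.rm = TRUE) > 0
  structure(list(variants = variants[carried, , drop = FALSE],
                 geno = g[carried, , drop = FALSE]),
            class = "family_view")
}

#' Apply the four-stage segregation filter to a family view
#'
#' The stages are conjunctive, so the surviving set does not depend on their
#' order; the per-stage audit counts do (each stage counts removals among the
#' variants still standing). Stage predicates:
#' \itemize{
#'   \item `qd`: quality-by-depth >= `min_qd`; a missing QD passes
#'     (absence of evidence).
#'   \item `consequence`: class in the coding whitelist, or a
#'     splice/intronic record within `splice_window` bp of an exon-intron
#'     junction; a missing class fails (coding cannot be confirmed).
#'   \item `maf`: gnomAD allele frequency < `max_maf`; missing frequency
#'     passes (novel variants are absent from gnomAD).
#'   \item `segregation`: heterozygous in every affected member (a missing
#'     affected call fails) and homozygous reference in every unaffected
#'     member (a missing unaffected call is not held against the variant).
#' }
#'
#' @param view A [build_family_view()] result.
#' @param affected Sample ids of the family's affected members.
#' @param unaffected Sample ids of unaffected members (may be empty).
#' @param criteria A [filter_criteria()].
#' @param stage_order Permutation of `c("qd", "consequence", "maf",
#'   "segregation")` controlling audit attribution only.
#' @return List of class `filter_result`: `survivors` (a `family_view` of
#'   passing variants) and `audit` (data.frame `stage`, `n_in`, `n_removed`,
#'   `n_out`).
#' @export
apply_filters <- function(view, affected, unaffected = character(0),
                          criteria = filter_criteria(),
                          stage_order = c("qd", "consequence", "maf",
                                          "segregation")) {
  stopifnot(inherits(view, "family_view"),
            setequal(stage_order, c("qd", "consequence", "maf",
                                    "segregation")))
  v <- view$variants
  g <- view$geno
  pass <- list()
  pass$qd <- is.na(v$qd) | v$qd >= criteria$min_qd
  csq <- v$consequence_class
  coding <- csq %in% setdiff(criteria$consequence_whitelist,
                             c("splice", "intronic"))
  near_splice <- csq %in% c("splice", "intronic") &
    ((csq == "splice" & is.na(v$splice_distance)) |
       (!is.na(v$splice_distance) &
          v$splice_distance <= criteria$splice_window))
  pass$consequence <- !is.na(csq) & (coding | near_splice)
  af <- if (criteria$use_nfe) v$af_gnomad_nfe else v$af_gnomad_total
  pass$maf <- is.na(af) | af < criteria$max_maf
  ga <- g[, intersect(affected, colnames(g)), drop = FALSE]
  if (ncol(ga) < length(affected))
    stop("affected member(s) missing from family view genotypes: ",
         paste(setdiff(affected, colnames(g)), collapse = ", "))
  het_all_aff <- rowSums(ga == 1L, na.rm = TRUE) == length(affected) &
    rowSums(is.na(ga)) == 0
  gu <- g[, intersect(unaffected, colnames(g)), drop = FALSE]
  homref_unaff <- rowSums(gu != 0L, na.rm = TRUE) == 0
  pass$segregation <- het_all_aff & homref_unaff
  remaining <- rep(TRUE, nrow(v))
  audit <- data.frame(stage = stage_order, n_in = NA_integer_,
                      n_removed = NA_integer_, n_out = NA_integer_,
                      stringsAsFactors = FALSE)
  for (s in seq_along(stage_order)) {
    p <- pass[[stage_order[s]]]
    audit$n_in[s] <- sum(remaining)
    removed <- remaining & !p
    audit$n_removed[s] <- sum(removed)
    remaining <- remaining & p
    audit$n_out[s] <- sum(remaining)
  }
  structure(list(
    survivors = structure(list(variants = v[remaining, , drop = FALSE],
                               geno = g[remaining, , drop = FALSE]),
                          class = "family_view"),
    audit = audit
  ), class = "filter_result")
}
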