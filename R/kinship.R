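#' Pairwise kinship coefficient from biallelic genotypes
#'
#' Robust within-family moment estimator of the kinship coefficient from
#' alternate-allele counts (Manichaikul-style, as implemented by
#' `vcftools --relatedness2`):
#' \deqn{\phi = \frac{N_{het,het} - 2 N_{opp.hom}}{N_{het}^{(i)} + N_{het}^{(j)}}}
#' where all counts are taken over sites non-missing in both samples.
#' A sample paired with itself (or its duplicate) scores exactly 0.5.
#'
#' @param genotypes_i,genotypes_j Integer vectors of 0/1/2 calls (`NA` =
#'   missing). If both are named, the shared (intersecting) site names are
#'   used; an empty intersection is an error.
#' @param maf_filter Sites with minor allele frequency <= `maf_filter` are
#'   excluded (the common-variant restriction). Frequency is taken from `af`
#'   when given (e.g. computed once over the whole cohort), otherwise from
#'   the pair itself.
#' @param af Optional per-site alternate-allele frequencies aligned to the
#'   (shared) sites.
#' @return A list of class `kinship_estimate`: `phi`, `n_het_het`,
#'   `n_opp_hom`, `n_het_i`, `n_het_j`, `n_sites` (usable sites), `low_sites`
#'   (fewer than 100 usable sites) and `degree` (see [classify_degree()]).
#'   `phi` is `NaN` when the denominator is zero.
#' @export
kinship_pair <- function(genotypes_i, genotypes_j, maf_filter = 0.05,
                         af = NULL) {
  if (!is.null(names(genotypes_i)) && !is.null(names(genotypes_j))) {
    shared <- intersect(names(genotypes_i), names(genotypes_j))
    if (!length(shared))
      stop("samples share no sites: disjoint site sets")
    if (!is.null(af) && !is.null(names(af))) af <- af[shared]
    genotypes_i <- genotypes_i[shared]
    genotypes_j <- genotypes_j[shared]
  } else if (length(genotypes_i) != length(genotypes_j)) {
    stop("unnamed genotype vectors must have equal length")
  }
  if (is.null(af)) {
    af <- colMeans(rbind(genotypes_i, genotypes_j), na.rm = TRUE) / 2
  }
  maf <- pmin(af, 1 - af)
  keep <- !is.na(maf) & maf > maf_filter
  gi <- genotypes_i[keep]; gj <- genotypes_j[keep]
  use <- !is.na(gi) & !is.na(gj)  # pairwise-complete sites
  gi <- gi[use]; gj <- gj[use]
  n_het_i <- sum(gi == 1L)
  n_het_j <- sum(gj == 1L)
  n_het_het <- sum(gi == 1L & gj == 1L)
  n_opp_hom <- sum((gi == 0L & gj == 2L) | (gi == 2L & gj == 0L))
  denom <- n_het_i + n_het_j
  phi <- if (denom == 0) NaN else (n_het_het - 2 * n_opp_hom) / denom
  est <- list(phi = phi, n_het_het = n_het_het, n_opp_hom = n_opp_hom,
              n_het_i = n_het_i, n_het_j = n_het_j, n_sites = sum(use),
              low_sites = sum(use) < 100,
              degree = as.character(classify_degree(phi)))
  class(est) <- "kinship_estimate"
  est
}

#' Kinship estimates for all sample pairs of a genotype matrix
#'
#' Allele frequencies for the common-variant filter are computed once over
#' the whole sample set (all rows of `geno`), then [kinship_pair()] is
#' applied to every pair with pairwise-complete site deletion.
#'
#' @param geno Integer matrix, samples x sites (0/1/2, `NA` missing), with
#'   rownames.
#' @param maf_filter Minor-allele-frequency exclusion threshold
#'   (default 0.05, i.e. keep sites with MAF > 5%).
#' @return data.frame with one row per unordered pair: `sample_i`,
#'   `sample_j`, `n_sites`, `phi`, `degree`, `low_sites`.
#' @export
kinship_all <- function(geno, maf_filter = 0.05) {
  stopifnot(is.matrix(geno), !is.null(rownames(geno)))
  af <- colMeans(geno, na.rm = TRUE) / 2
  ids <- rownames(geno)
  if (length(ids) < 2)
    return(data.frame(sample_i = character(), sample_j = character(),
                      n_sites = integer(), phi = numeric(),
                      degree = character(), low_sites = logical()))
  pairs <- utils::combn(ids, 2)
  res <- apply(pairs, 2, function(p) {
    e <- kinship_pair(geno[p[1], ], geno[p[2], ], maf_filter = maf_filter,
                      af = af)
    data.frame(sample_i = p[1], sample_j = p[2], n_sites = e$n_sites,
               phi = e$phi, degree = e$degree, low_sites = e$low_sites,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Classify a kinship coefficient into a relationship degree
#'
#' Uses the standard powers-of-two inference bands
#' (2^-3/2 ... 2^-9/2): duplicate/MZ above 0.354, 1st degree in
#' (0.177, 0.354], 2nd in (0.0884, 0.177], 3rd in (0.0442, 0.0884],
#' otherwise unrelated. `NaN`/`NA` coefficients are classified `"unknown"`.
#'
#' @param phi Numeric vector of kinship coefficients.
#' @return Factor with levels `duplicate/MZ`, `1st`, `2nd`, `3rd`,
#'   `unrelated`, `unknown`.
#' @export
classify_degree <- function(phi) {
  out <- ifelse(is.na(phi), "unknown",
         ifelse(phi > 0.354, "duplicate/MZ",
         ifelse(phi > 0.177, "1st",
         ifelse(phi > 0.0884, "2nd",
         ifelse(phi > 0.0442, "3rd", "unrelated")))))
  factor(out, levels = c("duplicate/MZ", "1st", "2nd", "3rd", "unrelated",
                         "unknown"))
}

#' Cluster samples into family units from pairwise kinship
#'
#' Builds a graph with an edge for every pair whose inferred degree is at
#' least as close as `max_degree`; connected components containing at least
#' two affected samples become families (a cohort needs two or more patients
#' per family). Components failing the two-patient rule are discarded.
#' Family ids are deterministic: components are ordered by their
#' lexicographically smallest member id.
#'
#' @param estimates data.frame from [kinship_all()] (needs `sample_i`,
#'   `sample_j`, `degree`).
#' @param phenotypes data.frame with `sample_id` and `status`; statuses
#'   `EOAD`, `LOAD`, `MCI` and `AD` count as affected.
#' @param max_degree Closest-to-furthest edge rule: `"1st"`, `"2nd"`
#'   (default) or `"3rd"`.
#' @return data.frame `family_id`, `sample_id`, `role`
#'   (`affected`/`unaffected`).
#' @export
cluster_families <- function(estimates, phenotypes, max_degree = "2nd") {
  rank <- c("duplicate/MZ" = 0, "1st" = 1, "2nd" = 2, "3rd" = 3)
  if (!max_degree %in% names(rank)[-1])
    stop("max_degree must be one of '1st', '2nd', '3rd'")
  keep <- !is.na(rank[estimates$degree]) &
    rank[estimates$degree] <= rank[[max_degree]]
  samples <- sort(unique(phenotypes$sample_id))
  g <- igraph::graph_from_data_frame(
    estimates[keep, c("sample_i", "sample_j"), drop = FALSE],
    directed = FALSE, vertices = data.frame(name = samples)
  )
  comp <- igraph::components(g)
  membership <- split(names(comp$membership), comp$membership)
  membership <- membership[order(vapply(membership, min, character(1)))]
  affected <- phenotypes$sample_id[is_affected(phenotypes$status)]
  out <- list(); fid <- 0L
  for (members in membership) {
    if (sum(members %in% affected) < 2) next
    fid <- fid + 1L
    out[[fid]] <- data.frame(
      family_id = sprintf("FAM%02d", fid),
      sample_id = sort(members),
      role = ifelse(sort(members) %in% affected, "affected", "unaffected"),
      stringsAsFactors = FALSE
    )
  }
  if (!length(out))
    return(data.frame(family_id = character(), sample_id = character(),
                      role = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Affection-status rule shared by clustering and segregation filtering:
# mild cognitive impairment counts as affected.
is_affected <- function(status) {
  status %in% c("EOAD", "LOAD", "MCI", "AD")
}
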