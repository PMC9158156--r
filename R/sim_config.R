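#' Default per-family simulation plan for a 36-family EOAD cohort
#'
#' Returns the per-family plan used by [sim_config()] when no explicit plan is
#' given and `n_families = 36`. It mirrors the composition of a familial EOAD
#' cohort of 36 small pedigrees (77 patients): eight families carry a planted
#' pathogenic panel variant (APP, GRN, five PSEN1, a truncating SORL1), eight
#' carry a panel variant of uncertain significance, family sizes are 2-4
#' affected (one family of four, three of three), four families include one
#' unaffected elderly relative, and the APOE genotype mix reproduces the
#' family-averaged APOE risk spectrum of such a cohort (seven families fully
#' segregating for e4e4, eighteen with at least one e4e4 carrier, a single e2
#' carrier).
#'
#' @return A data.frame with one row per family: `family_id`, `n_affected`,
#'   `n_unaffected_elderly`, `structure` ("sibship" or "avuncular"),
#'   `planted_kind` ("pathogenic_panel", "vus_panel" or "none"),
#'   `planted_gene`, `planted_consequence`, `planted_cadd`, `planted_db`
#'   (database-pathogenic flag) and `apoe` (comma-separated APOE diplotypes
#'   assigned to the affected members in order).
#' @export
default_family_plan <- function() {
  pv <- c("APP", "GRN", "PSEN1", "PSEN1", "PSEN1", "PSEN1", "PSEN1", "SORL1")
  vus <- c("ABCA7", "BIN1", "CR1", "FERMT2", "MADD", "PRNP", "SORL1", "SQSTM1")
  vus_csq <- c("missense", "missense", "missense", "missense", "frameshift",
               "missense", "missense", "nonsense")
  vus_cadd <- c(23.9, 24.6, 24, 18.8, NA, 23.4, 18.2, 35)
  pv_csq <- c("missense", "frameshift", rep("missense", 5), "frameshift")
  pv_cadd <- c(34, NA, 25.6, 34, 33, 25.6, 33, NA)
  # db_pathogenic: the truncating SORL1 variant is novel (absent from
  # databases); it is classified pathogenic through the high-penetrance-PTV
  # rule instead.
  pv_db <- c(rep(TRUE, 7), FALSE)
  apoe <- c(
    "34,33", "34,33", "34,23", "33,33", "33,33", "34,34", "34,33", "34,44",
    "44,44", "34,44", "34,44", "44,44", "44,44", "34,33", "34,44", "34,34",
    "34,44", "44,44,44,44", "34,44", "34,44", "44,44", "44,44", "34,44",
    "34,44", "44,44,34", "44,34,34", "44,44",
    "33,33", "34,34,33", "33,33", "34,34", "33,33", "34,34", "34,33",
    "34,33", "34,34"
  )
  n_aff <- rep(2L, 36)
  n_aff[18] <- 4L
  n_aff[c(25, 26, 29)] <- 3L
  elderly <- integer(36)
  elderly[c(12, 18, 19, 30)] <- 1L
  data.frame(
    family_id = sprintf("F%02d", 1:36),
    n_affected = n_aff,
    n_unaffected_elderly = elderly,
    structure = ifelse(1:36 %% 3 == 0, "avuncular", "sibship"),
    planted_kind = c(rep("pathogenic_panel", 8), rep("vus_panel", 8),
                     rep("none", 20)),
    planted_gene = c(pv, vus, rep(NA_character_, 20)),
    planted_consequence = c(pv_csq, vus_csq, rep(NA_character_, 20)),
    planted_cadd = c(pv_cadd, vus_cadd, rep(NA_real_, 20)),
    planted_db = c(pv_db, rep(FALSE, 8), rep(NA, 20)),
    apoe = apoe,
    stringsAsFactors = FALSE
  )
}

#' Build a synthetic-cohort simulation configuration
#'
#' Collects and validates every knob of the synthetic-cohort generator. The
#' defaults are the study conditions the package is designed around: a
#' 36-family cohort following [default_family_plan()], 76 background rare
#' variants per family (the post-filter scale seen in real familial exome
#' data), common-SNP allele frequencies above 5%, a replication case-control
#' set of 833 EOAD / 521 LOAD / 6949 controls with 10 ancestry principal
#' components, and a population control panel of 980 individuals for risk
#' scaling.
#'
#' @param n_families Number of families to simulate.
#' @param family_plan Optional data.frame as returned by
#'   [default_family_plan()]. When `NULL` and `n_families == 36` the default
#'   plan is used; otherwise a plan is generated from `family_size_range`.
#' @param family_size_range Length-2 integer vector, (min, max) affected
#'   members per family when no plan is given. The minimum must be >= 2:
#'   a family needs at least two patients.
#' @param n_common_snps Number of unlinked common SNPs used for kinship.
#' @param common_maf_range Allele-frequency interval, within (0, 0.5], from
#'   which common-SNP founder frequencies are drawn.
#' @param n_background_rare Background rare variants per family; each violates
#'   exactly one of the four segregation-filter stages (for filter audits).
#' @param novel_plan Optional data.frame planting novel-gene candidate
#'   structure with columns `gene`, `type` ("shared_variant" for one identical
#'   variant across families, "gene_multi" for distinct variants in the same
#'   gene), `families` (comma-separated family ids) and `cadd`.
#' @param include_cousins If `TRUE`, each family's pedigree contributes one
#'   genotyped unaffected first cousin (a 3rd-degree relative of the affected
#'   sibship), so that the cohort contains 3rd-degree truth pairs.
#' @param n_singletons Number of unrelated affected singletons added to the
#'   cohort (they must never form a family).
#' @param duplicate_samples Number of sampled individuals re-emitted as exact
#'   genotype duplicates (suffix `_dup`), e.g. to test duplicate detection.
#' @param missing_rate Genotype missingness rate applied to emitted calls.
#' @param n_prs_snps Number of independent PRS SNPs (dosage loci).
#' @param replication_sizes Named integer vector `c(EOAD=, LOAD=, control=)`
#'   giving the target composition of the unrelated replication cohort.
#' @param n_pcs Number of ancestry principal components simulated for the
#'   replication cohort.
#' @param n_population_controls Size of the population-based control panel
#'   used to centre PRS and APOE risk.
#' @param seed Integer seed; identical configurations with identical seeds
#'   yield identical cohorts.
#' @return An object of class `famalz_config` (a validated list).
#' @export
sim_config <- function(n_families = 36,
                       family_plan = NULL,
                       family_size_range = c(2L, 4L),
                       n_common_snps = 10000L,
                       common_maf_range = c(0.05, 0.5),
                       n_background_rare = 76L,
                       novel_plan = NULL,
                       include_cousins = FALSE,
                       n_singletons = 0L,
                       duplicate_samples = 0L,
                       missing_rate = 0,
                       n_prs_snps = 35L,
                       replication_sizes = c(EOAD = 833L, LOAD = 521L,
                                             control = 6949L),
                       n_pcs = 10L,
                       n_population_controls = 980L,
                       seed = 1L) {
  stopifnot(length(family_size_range) == 2, length(common_maf_range) == 2)
  if (family_size_range[1] < 2)
    stop("family_size_range minimum must be >= 2: families need >= 2 affected")
  if (family_size_range[2] < family_size_range[1])
    stop("family_size_range must be (min, max) with min <= max")
  counts <- c(n_families, n_common_snps, n_background_rare, n_singletons,
              duplicate_samples, n_prs_snps, replication_sizes, n_pcs,
              n_population_controls)
  if (any(counts < 0)) stop("all counts must be >= 0")
  if (common_maf_range[1] <= 0 || common_maf_range[2] > 0.5 ||
      common_maf_range[1] > common_maf_range[2])
    stop("common_maf_range must lie within (0, 0.5]")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  if (is.null(family_plan)) {
    if (n_families == 36) {
      family_plan <- default_family_plan()
    } else {
      # deterministic generated plan: sizes cycle through the range,
      # structures alternate, no planted variants unless asked for
      sizes <- family_size_range[1] +
        (seq_len(n_families) - 1L) %% (family_size_range[2] -
                                         family_size_range[1] + 1L)
      apoe_pool <- c("34,33", "33,33", "34,34", "44,44", "34,44", "44,34")
      family_plan <- data.frame(
        family_id = sprintf("F%02d", seq_len(n_families)),
        n_affected = as.integer(sizes),
        n_unaffected_elderly = rep(0L, n_families),
        structure = ifelse(seq_len(n_families) %% 2 == 0,
                           "avuncular", "sibship"),
        planted_kind = "none",
        planted_gene = NA_character_,
        planted_consequence = NA_character_,
        planted_cadd = NA_real_,
        planted_db = NA,
        apoe = vapply(sizes, function(k) {
          paste(rep(apoe_pool, length.out = k), collapse = ",")
        }, character(1)),
        stringsAsFactors = FALSE
      )
    }
  }
  if (nrow(family_plan) != n_families)
    stop("family_plan must have one row per family")
  if (any(family_plan$n_affected < 2))
    stop("every family must have >= 2 affected members")
  if (!is.null(novel_plan)) {
    needed <- c("gene", "type", "families", "cadd")
    if (!all(needed %in% names(novel_plan)))
      stop("novel_plan needs columns: ", paste(needed, collapse = ", "))
    fams <- unlist(strsplit(novel_plan$families, ","))
    unknown <- setdiff(trimws(fams), family_plan$family_id)
    if (length(unknown))
      stop("novel_plan references unknown family id(s): ",
           paste(unknown, collapse = ", "))
  }
  structure(list(
    n_families = as.integer(n_families),
    family_plan = family_plan,
    family_size_range = as.integer(family_size_range),
    n_common_snps = as.integer(n_common_snps),
    common_maf_range = as.numeric(common_maf_range),
    n_background_rare = as.integer(n_background_rare),
    novel_plan = novel_plan,
    include_cousins = isTRUE(include_cousins),
    n_singletons = as.integer(n_singletons),
    duplicate_samples = as.integer(duplicate_samples),
    missing_rate = as.numeric(missing_rate),
    n_prs_snps = as.integer(n_prs_snps),
    replication_sizes = replication_sizes,
    n_pcs = as.integer(n_pcs),
    n_population_controls = as.integer(n_population_controls),
    seed = as.integer(seed)
  ), class = "famalz_config")
}
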