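#' Run the full family-genetics pipeline on a synthetic cohort
#'
#' Orchestrates every stage end to end: cohort simulation, pairwise kinship
#' and family clustering, per-family segregation filtering, panel screening
#' and variant classification, novel-gene prioritization (optionally
#' followed by a replication burden test on a simulated unrelated cohort),
#' PRS and APOE risk scoring with population scaling and family averaging,
#' subgroup statistics and actionability categorization. Deterministic
#' given `config$seed`.
#'
#' @param config A [sim_config()].
#' @param max_degree Family clustering edge rule (see [cluster_families()]).
#' @param panel Gene panel (default: packaged dementia panel).
#' @param criteria Filtering criteria ([filter_criteria()]).
#' @param prs_flag_threshold Family-PRS flagging threshold for
#'   [categorize()].
#' @param literature_flags Named logical vector for
#'   [prioritize_novel()].
#' @param blacklist Blacklisted variant ids for [prioritize_novel()].
#' @param do_replication If `TRUE` and candidate genes were selected,
#'   simulate a replication cohort and run [gene_burden()] on it.
#' @return List of class `famalz_report`: `stage_counts`, `kinship`,
#'   `families`, `filter_audits`, `survivors`, `classified`,
#'   `prioritization`, `replication` (or `NULL`), `profiles` (per-sample
#'   risk), `summaries` (per recovered family), `categories`,
#'   `category_counts`, `subgroups` (the [table3_report()]), and `truth`.
#' @export
run_pipeline <- function(config = sim_config(),
                         max_degree = "2nd",
                         panel = read_gene_panel(),
                         criteria = filter_criteria(),
                         prs_flag_threshold = 0.45,
                         literature_flags = logical(0),
                         blacklist = character(0),
                         do_replication = FALSE) {
  cohort <- simulate_cohort(config)
  phen <- cohort$phenotypes
  # 1. relatedness
  kin <- kinship_all(cohort$common_geno)
  families <- cluster_families(kin, phen, max_degree = max_degree)
  fam_ids <- unique(families$family_id)
  # 2. per-family segregation filtering
  audits <- list(); surv <- list()
  for (fid in fam_ids) {
    members <- families$sample_id[families$family_id == fid]
    st <- phen$status[match(members, phen$sample_id)]
    affected <- members[is_affected(st)]
    unaffected <- setdiff(members, affected)
    view <- build_family_view(cohort$variants, cohort$var_geno, members)
    flt <- apply_filters(view, affected, unaffected, criteria = criteria)
    audits[[fid]] <- flt$audit
    if (nrow(flt$survivors$variants)) {
      s <- flt$survivors$variants
      s$family_id <- fid
      surv[[fid]] <- s
    }
  }
  survivors <- if (length(surv)) do.call(rbind, surv) else
    data.frame(variant_id = character(), gene = character(),
               family_id = character(), stringsAsFactors = FALSE)
  rownames(survivors) <- NULL
  # 3. panel screen + classification
  survivors <- screen_panel(survivors, panel)
  classified <- classify_variants(survivors)
  panel_path <- classified$panel_member & classified$label == "pathogenic"
  solved <- unique(classified$family_id[panel_path])
  vus_fams <- unique(classified$family_id[classified$panel_member &
                                            classified$label == "VUS"])
  # 4. novel-gene prioritization (non-panel survivors)
  nonpanel <- classified[!classified$panel_member,
                         c("family_id", "variant_id", "gene", "cadd")]
  prio <- prioritize_novel(nonpanel, solved_families = solved,
                           blacklist = blacklist,
                           literature_flags = literature_flags)
  # 5. optional replication burden test on an unrelated simulated cohort
  replication <- NULL
  if (do_replication && nrow(prio$selected)) {
    rep_cohort <- simulate_replication_cohort(
      config, n_genes = nrow(prio$selected), beta = 0)
    colnames(rep_cohort$carriers) <- prio$selected$gene
    carrier_long <- which(rep_cohort$carriers == 1L, arr.ind = TRUE)
    vc <- data.frame(
      sample_id = sprintf("r%05d", carrier_long[, 1]),
      unit = colnames(rep_cohort$carriers)[carrier_long[, 2]],
      cadd = NA_real_, stringsAsFactors = FALSE)
    labels <- setNames(as.character(rep_cohort$labels),
                       sprintf("r%05d", seq_along(rep_cohort$labels)))
    rownames(rep_cohort$pcs) <- names(labels)
    replication <- gene_burden(vc, labels, rep_cohort$pcs,
                               cadd_strata = NULL)
  }
  # 6. risk scoring
  prs_raw <- compute_prs(cohort$prs$dosages, cohort$weights)
  ctrl_raw <- compute_prs(cohort$prs$control, cohort$weights)
  prs_scaled <- scale_to_population(prs_raw, ctrl_raw)
  apoe_scaled <- apoe_risk(phen$apoe)
  names(apoe_scaled) <- phen$sample_id
  fam_phen <- phen
  fam_phen$family_id <- families$family_id[match(fam_phen$sample_id,
                                                 families$sample_id)]
  fam_prs <- family_average(prs_scaled, fam_phen)
  fam_apoe <- family_average(apoe_scaled, fam_phen)
  profiles <- data.frame(
    sample_id = phen$sample_id,
    family_id = fam_phen$family_id,
    prs_raw = unname(prs_raw[phen$sample_id]),
    prs_scaled = unname(prs_scaled[phen$sample_id]),
    apoe_scaled = unname(apoe_scaled),
    stringsAsFactors = FALSE
  )
  # 7. per-family summary + categorization
  summaries <- data.frame(family_id = fam_ids, stringsAsFactors = FALSE)
  aff_only <- fam_phen[is_affected(fam_phen$status) &
                         !is.na(fam_phen$family_id), ]
  summaries$n_patients <- as.integer(table(aff_only$family_id)[fam_ids])
  summaries$onset_age <- as.numeric(
    tapply(aff_only$onset_age, aff_only$family_id, mean)[fam_ids])
  pv_gene <- vapply(fam_ids, function(f) {
    g <- classified$gene[panel_path & classified$family_id == f]
    if (length(g)) paste(sort(unique(g)), collapse = ";") else ""
  }, character(1))
  vus_gene <- vapply(fam_ids, function(f) {
    g <- classified$gene[classified$panel_member &
                           classified$label == "VUS" &
                           classified$family_id == f]
    if (length(g)) paste(sort(unique(g)), collapse = ";") else ""
  }, character(1))
  summaries$pv_gene <- unname(pv_gene)
  summaries$vus_gene <- unname(vus_gene)
  summaries$has_pv <- nzchar(summaries$pv_gene)
  summaries$has_vus <- nzchar(summaries$vus_gene)
  summaries$apoe_risk <- unname(fam_apoe[fam_ids])
  summaries$prs <- unname(fam_prs[fam_ids])
  summaries$has_e44 <- vapply(fam_ids, function(f) {
    any(aff_only$apoe[aff_only$family_id == f] == "44", na.rm = TRUE)
  }, logical(1))
  categories <- categorize(summaries, prs_flag_threshold)
  subgroups <- table3_report(summaries)
  stage_counts <- list(
    n_samples = nrow(phen),
    n_common_snps = ncol(cohort$common_geno),
    n_rare_variants = nrow(cohort$variants),
    n_families_recovered = length(fam_ids),
    n_filter_survivors = nrow(survivors),
    n_panel_hits = sum(classified$panel_member),
    n_pathogenic = sum(classified$label == "pathogenic"),
    n_vus = sum(classified$label == "VUS" & classified$panel_member),
    n_solved_families = length(solved),
    n_vus_families = length(vus_fams),
    n_candidate_genes = nrow(prio$selected),
    category_counts = table(categories$category)
  )
  structure(list(stage_counts = stage_counts, kinship = kin,
                 families = families, filter_audits = audits,
                 survivors = survivors, classified = classified,
                 prioritization = prio, replication = replication,
                 profiles = profiles, summaries = summaries,
                 categories = categories,
                 category_counts = table(categories$category),
                 subgroups = subgroups, truth = cohort$truth),
            class = "famalz_report")
}

#' @export
print.famalz_report <- function(x, ...) {
  sc <- x$stage_counts
  cat("famalz pipeline report\n")
  cat(sprintf("  samples: %d  families recovered: %d\n",
              sc$n_samples, sc$n_families_recovered))
  cat(sprintf("  filter survivors: %d  panel hits: %d (PV %d, VUS %d)\n",
              sc$n_filter_survivors, sc$n_panel_hits, sc$n_pathogenic,
              sc$n_vus))
  cat(sprintf("  candidate genes: %d\n", sc$n_candidate_genes))
  cat("  categories:",
      paste(names(sc$category_counts), as.integer(sc$category_counts),
            sep = "=", collapse = "  "), "\n")
  invisible(x)
}
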