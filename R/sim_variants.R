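#' Plant annotated rare variants into the simulated families
#'
#' Emits, per family, one fully segregating planted variant when the family
#' plan asks for one (heterozygous in every affected member, homozygous
#' reference elsewhere, gnomAD AF < 0.001, QD >= 5, coding consequence),
#' `config$n_background_rare` background variants each violating exactly one
#' of the four segregation-filter stages (tags `fail_qd`,
#' `fail_consequence`, `fail_maf`, `fail_segregation`, cycling), and any
#' cross-family novel-gene candidate structure requested in
#' `config$novel_plan`. Every emission is recorded in the truth table.
#'
#' @param pedigree A [simulate_pedigree()] result.
#' @param config The corresponding [sim_config()].
#' @return List with `variants` (annotation data.frame, one row per variant),
#'   `geno` (integer matrix variants x sampled individuals, 0/1/2) and
#'   `truth` (data.frame `variant_id`, `family_id`, `kind`, `tag`, `gene`).
#' @export
plant_rare_variants <- function(pedigree, config) {
  stopifnot(inherits(pedigree, "famalz_pedigree"))
  set.seed(config$seed + 2L)
  ped <- pedigree$ped
  plan <- config$family_plan
  sampled <- ped$id[ped$sampled]
  aff_of <- function(fam) ped$id[ped$sampled & ped$role == "affected" &
                                   !is.na(ped$family_id) &
                                   ped$family_id == fam]
  bases <- c("A", "C", "G", "T")
  counter <- 0L
  new_coords <- function() {
    counter <<- counter + 1L
    list(chrom = as.character(1L + (counter - 1L) %% 22L),
         pos = 1000000L + 997L * counter,
         ref = bases[1L + (counter - 1L) %% 4L],
         alt = bases[1L + counter %% 4L])
  }
  rare_af <- function(n) {
    af <- round(runif(n, 0, 5e-4), 6)
    af[runif(n) < 0.5] <- 0
    af
  }
  vrows <- list(); grows <- list(); trows <- list()
  add_variant <- function(id, fam, kind, tag, gene, consequence, cadd, db,
                          qd, af, splice_distance = NA_real_,
                          predictors = c("damaging", "damaging", "damaging"),
                          coords = new_coords(), carriers, hom_ref_rest = TRUE,
                          geno_override = NULL) {
    vrows[[length(vrows) + 1L]] <<- data.frame(
      variant_id = id, chrom = coords$chrom, pos = coords$pos,
      ref = coords$ref, alt = coords$alt, qd = qd, gene = gene,
      consequence_class = consequence, splice_distance = splice_distance,
      af_gnomad_total = af, af_gnomad_nfe = af,
      cadd = cadd, sift = predictors[1], polyphen2 = predictors[2],
      muttaster = predictors[3], db_pathogenic = db,
      stringsAsFactors = FALSE
    )
    g <- if (is.null(geno_override)) {
      setNames(rep(0L, length(sampled)), sampled)
    } else geno_override
    if (is.null(geno_override)) g[carriers] <- 1L
    grows[[length(grows) + 1L]] <<- g
    trows[[length(trows) + 1L]] <<- data.frame(
      variant_id = id, family_id = fam, kind = kind,
      tag = if (is.null(tag)) NA_character_ else tag, gene = gene,
      stringsAsFactors = FALSE
    )
  }
  # planted panel variants
  for (i in seq_len(nrow(plan))) {
    if (plan$planted_kind[i] == "none") next
    fam <- plan$family_id[i]
    aff <- aff_of(fam)
    if (!length(aff)) stop("plan references family with no affected: ", fam)
    add_variant(
      id = paste0(fam, "_planted"), fam = fam,
      kind = paste0("planted_", sub("_panel", "", plan$planted_kind[i])),
      tag = NULL, gene = plan$planted_gene[i],
      consequence = plan$planted_consequence[i],
      cadd = plan$planted_cadd[i], db = isTRUE(plan$planted_db[i]),
      qd = round(runif(1, 10, 40), 2), af = rare_af(1),
      carriers = aff
    )
  }
  # novel-gene candidate structure shared across families
  if (!is.null(config$novel_plan)) {
    np <- config$novel_plan
    for (i in seq_len(nrow(np))) {
      fams <- trimws(strsplit(np$families[i], ",")[[1]])
      unknown <- setdiff(fams, plan$family_id)
      if (length(unknown))
        stop("novel_plan references unknown family id(s): ",
             paste(unknown, collapse = ", "))
      if (np$type[i] == "shared_variant") {
        coords <- new_coords()
        add_variant(
          id = paste0("NV_", np$gene[i]), fam = paste(fams, collapse = ";"),
          kind = "novel", tag = NULL, gene = np$gene[i],
          consequence = "missense", cadd = np$cadd[i], db = FALSE,
          qd = round(runif(1, 10, 40), 2), af = rare_af(1), coords = coords,
          carriers = unlist(lapply(fams, aff_of))
        )
      } else {
        for (fam in fams) {
          add_variant(
            id = paste0("NV_", np$gene[i], "_", fam), fam = fam,
            kind = "novel", tag = NULL, gene = np$gene[i],
            consequence = "missense", cadd = np$cadd[i], db = FALSE,
            qd = round(runif(1, 10, 40), 2), af = rare_af(1),
            carriers = aff_of(fam)
          )
        }
      }
    }
  }
  # tagged background variants: each violates exactly one filter stage
  tags <- c("fail_qd", "fail_consequence", "fail_maf", "fail_segregation")
  for (i in seq_len(nrow(plan))) {
    fam <- plan$family_id[i]
    aff <- aff_of(fam)
    n_bg <- config$n_background_rare
    if (n_bg < 1) next
    for (b in seq_len(n_bg)) {
      tag <- tags[1L + (b - 1L) %% 4L]
      qd <- round(runif(1, 10, 40), 2)
      af <- rare_af(1)
      consequence <- sample(c("missense", "nonsense", "frameshift"), 1)
      splice_distance <- NA_real_
      geno_override <- NULL
      if (tag == "fail_qd") qd <- round(runif(1, 0.5, 4.9), 2)
      if (tag == "fail_maf") af <- round(runif(1, 0.002, 0.05), 4)
      if (tag == "fail_consequence") {
        consequence <- sample(c("synonymous", "intronic"), 1)
        if (consequence == "intronic")
          splice_distance <- sample(3:60, 1)
      }
      if (tag == "fail_segregation") {
        geno_override <- setNames(rep(0L, length(sampled)), sampled)
        if (length(aff) > 1) geno_override[aff[-1]] <- 1L
        # first affected stays homozygous reference -> not het in all affected
      }
      add_variant(
        id = sprintf("%s_bg%04d", fam, b), fam = fam, kind = "background",
        tag = tag, gene = sprintf("BGENE%03d_%s", b, fam),
        consequence = consequence, splice_distance = splice_distance,
        cadd = round(runif(1, 0, 30), 1), db = FALSE, qd = qd, af = af,
        predictors = sample(c("damaging", "tolerated", "NA"), 3,
                            replace = TRUE),
        carriers = aff, geno_override = geno_override
      )
    }
  }
  if (!length(vrows)) {
    return(list(
      variants = make_empty_variants(),
      geno = matrix(integer(0), 0, length(sampled),
                    dimnames = list(NULL, sampled)),
      truth = data.frame(variant_id = character(), family_id = character(),
                         kind = character(), tag = character(),
                         gene = character(), stringsAsFactors = FALSE)))
  }
  variants <- do.call(rbind, vrows)
  geno <- do.call(rbind, grows)
  rownames(geno) <- variants$variant_id
  truth <- do.call(rbind, trows)
  rownames(variants) <- rownames(truth) <- NULL
  list(variants = variants, geno = geno, truth = truth)
}

make_empty_variants <- function() {
  data.frame(variant_id = character(), chrom = character(), pos = integer(),
             ref = character(), alt = character(), qd = numeric(),
             gene = character(), consequence_class = character(),
             splice_distance = numeric(), af_gnomad_total = numeric(),
             af_gnomad_nfe = numeric(), cadd = numeric(), sift = character(),
             polyphen2 = character(), muttaster = character(),
             db_pathogenic = logical(), stringsAsFactors = FALSE)
}

#' Assign APOE diplotypes to the simulated cohort
#'
#' Affected members receive, in order, the genotypes listed in the family
#' plan's `apoe` field (e.g. `"34,44"`); sampled unaffected relatives and
#' unrelated singletons draw from a background mix dominated by e3e3/e3e4.
#'
#' @inheritParams plant_rare_variants
#' @return Named character vector of diplotypes (`"33"`, `"34"`, ...) over
#'   sampled individuals.
#' @export
simulate_apoe <- function(pedigree, config) {
  set.seed(config$seed + 3L)
  ped <- pedigree$ped
  plan <- config$family_plan
  out <- setNames(rep(NA_character_, sum(ped$sampled)), ped$id[ped$sampled])
  for (i in seq_len(nrow(plan))) {
    fam <- plan$family_id[i]
    aff <- ped$id[ped$sampled & ped$role == "affected" &
                    !is.na(ped$family_id) & ped$family_id == fam]
    gts <- trimws(strsplit(plan$apoe[i], ",")[[1]])
    out[aff] <- rep(gts, length.out = length(aff))
  }
  rest <- names(out)[is.na(out)]
  out[rest] <- sample(c("33", "34", "44"), length(rest),
                      replace = TRUE, prob = c(0.65, 0.30, 0.05))
  out
}

#' Simulate PRS dosages for the cohort and a population control panel
#'
#' PRS loci are unlinked common SNPs (allele frequencies uniform on
#' 0.1-0.5) transmitted through the pedigrees; the control panel of
#' `config$n_population_controls` unrelated individuals is drawn from
#' Hardy-Weinberg at the same frequencies and is used to centre scores on the
#' population mean.
#'
#' @inheritParams plant_rare_variants
#' @param weights A PRS weight table (see [read_prs_weights()]); dosage
#'   columns are named by its `variant_id`.
#' @return List with `dosages` (sampled individuals x loci), `control`
#'   (controls x loci) and `maf`.
#' @export
simulate_prs_dosages <- function(pedigree, config, weights) {
  set.seed(config$seed + 4L)
  n <- nrow(weights)
  maf <- runif(n, 0.1, 0.5)
  geno <- transmit_genotypes(pedigree$ped, maf)
  sampled <- pedigree$ped$id[pedigree$ped$sampled]
  dosages <- geno[sampled, , drop = FALSE]
  colnames(dosages) <- weights$variant_id
  control <- matrix(rbinom(config$n_population_controls * n, 2L,
                           rep(maf, each = config$n_population_controls)),
                    nrow = config$n_population_controls,
                    dimnames = list(NULL, weights$variant_id))
  list(dosages = dosages, control = control, maf = maf)
}

#' Simulate a complete synthetic cohort
#'
#' Runs the full generator: pedigrees, common-SNP genotypes, planted and
#' background rare variants, APOE diplotypes and PRS dosages (with a
#' population control panel), and collects the phenotype table and truth
#' record.
#'
#' @param config A [sim_config()].
#' @param weights Optional PRS weight table; defaults to the packaged
#'   synthetic 35-variant table when `config$n_prs_snps == 35`, otherwise a
#'   generated table of that size.
#' @return An object of class `famalz_cohort`: list with `config`,
#'   `pedigree`, `common_geno` (sampled x SNP matrix), `variants`,
#'   `var_geno` (variant x sample matrix), `phenotypes`, `apoe`,
#'   `prs` (dosages + control panel), `weights` and `truth`.
#' @export
simulate_cohort <- function(config = sim_config(), weights = NULL) {
  stopifnot(inherits(config, "famalz_config"))
  pedigree <- simulate_pedigree(config)
  geno <- simulate_genotypes(pedigree, config)
  rare <- plant_rare_variants(pedigree, config)
  apoe <- simulate_apoe(pedigree, config)
  if (is.null(weights)) {
    if (config$n_prs_snps == 35L) {
      weights <- read_prs_weights()
    } else {
      set.seed(config$seed + 5L)
      weights <- data.frame(
        variant_id = sprintf("prs%03d", seq_len(config$n_prs_snps)),
        risk_allele = sample(c("A", "C", "G", "T"), config$n_prs_snps,
                             replace = TRUE),
        weight = round(runif(config$n_prs_snps, 0.03, 0.25), 4),
        imputation_r2 = round(runif(config$n_prs_snps, 0.6, 0.99), 2),
        is_apoe_region = FALSE,
        stringsAsFactors = FALSE
      )
    }
  }
  prs <- simulate_prs_dosages(pedigree, config, weights)
  sampled <- attr(geno, "sampled")
  ped <- pedigree$ped
  base <- sub("_dup$", "", sampled)
  mi <- match(base, ped$id)
  phenotypes <- data.frame(
    sample_id = sampled,
    family_id = ped$family_id[mi],
    status = ifelse(ped$role[mi] == "affected", ped$status[mi],
                    ifelse(ped$role[mi] == "singleton", "EOAD",
                           "unaffected")),
    onset_age = ped$onset_age[mi],
    apoe = unname(apoe[base]),
    stringsAsFactors = FALSE
  )
  # extend rare-variant and PRS genotypes to duplicate samples
  dup <- sampled[grepl("_dup$", sampled)]
  if (length(dup)) {
    src <- sub("_dup$", "", dup)
    vg <- rare$geno[, src, drop = FALSE]
    colnames(vg) <- dup
    rare$geno <- cbind(rare$geno, vg)
    dd <- prs$dosages[src, , drop = FALSE]
    rownames(dd) <- dup
    prs$dosages <- rbind(prs$dosages, dd)
  }
  prs_true <- as.numeric(prs$dosages[, weights$variant_id, drop = FALSE] %*%
                           weights$weight)
  common <- geno[sampled, , drop = FALSE]
  attr(common, "maf") <- attr(geno, "maf")
  truth <- list(
    degrees = pedigree$truth_degrees,
    planted = rare$truth,
    families = stats::na.omit(unique(
      phenotypes[, c("family_id", "sample_id")])),
    apoe = as.list(apoe),
    prs_true = setNames(as.list(prs_true), rownames(prs$dosages))
  )
  structure(list(config = config, pedigree = pedigree, common_geno = common,
                 variants = rare$variants, var_geno = rare$geno,
                 phenotypes = phenotypes, apoe = apoe, prs = prs,
                 weights = weights, truth = truth),
            class = "famalz_cohort")
}
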