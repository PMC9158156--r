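#' Simulate family pedigrees and their truth record
#'
#' Builds one three-generation pedigree per family: a grandparental founder
#' couple, two parental siblings (each with an unrelated founder spouse), an
#' affected sibship under one parent and a first cousin under the other. With
#' `structure = "sibship"` the affected members are the sibship (all pairs
#' 1st degree); with `"avuncular"` one affected is the parental sibling (an
#' avuncular, 2nd-degree relative of the sibship). Every affected pair is
#' therefore 1st or 2nd degree. The optional unaffected elderly relative is
#' the grandmother; the optional genotyped cousin provides 3rd-degree pairs.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `famalz_pedigree` with elements:
#'   \describe{
#'     \item{ped}{data.frame of all pedigree members: `id`, `family_id`,
#'       `father`, `mother` (`NA` for founders), `sampled` (emitted in the
#'       cohort), `status` (`EOAD`/`LOAD`/`unaffected`), `onset_age`, `role`.}
#'     \item{truth_degrees}{data.frame of true pairwise relationship degrees
#'       (`sample_i`, `sample_j`, `phi_true`, `degree`) for all sampled
#'       within-family pairs; cross-family pairs are unrelated by
#'       construction.}
#'   }
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "famalz_config"))
  set.seed(config$seed)
  plan <- config$family_plan
  rows <- list()
  for (i in seq_len(nrow(plan))) {
    fam <- plan$family_id[i]
    k <- plan$n_affected[i]
    struct <- plan$structure[i]
    n_sibs <- if (struct == "avuncular") k - 1L else k
    if (n_sibs < 1L) n_sibs <- 1L
    pid <- function(x) ifelse(is.na(x), NA_character_, paste0(fam, "_", x))
    members <- data.frame(
      id = pid(c("GF", "GM", "P1", "P2", "S1", "S2",
                 paste0("A", seq_len(n_sibs)), "C1")),
      family_id = fam,
      father = pid(c(NA, NA, "GF", "GF", NA, NA,
                     rep("P1", n_sibs), "P2")),
      mother = pid(c(NA, NA, "GM", "GM", NA, NA,
                     rep("S1", n_sibs), "S2")),
      stringsAsFactors = FALSE
    )
    affected_ids <- pid(paste0("A", seq_len(n_sibs)))
    if (struct == "avuncular") affected_ids <- c(affected_ids, pid("P2"))
    members$role <- "relative"
    members$role[members$id %in% affected_ids] <- "affected"
    sampled <- affected_ids
    if (plan$n_unaffected_elderly[i] >= 1L) {
      members$role[members$id == pid("GM")] <- "elderly_unaffected"
      sampled <- c(sampled, pid("GM"))
    }
    if (config$include_cousins && !(pid("C1") %in% affected_ids)) {
      members$role[members$id == pid("C1")] <- "cousin_unaffected"
      sampled <- c(sampled, pid("C1"))
    }
    members$sampled <- members$id %in% sampled
    onset <- round(pmin(pmax(rnorm(length(affected_ids), 63, 6), 42), 80), 1)
    onset[1] <- min(onset[1], 69)  # inclusion rule: >=1 patient with onset <70
    members$onset_age <- NA_real_
    members$onset_age[match(affected_ids, members$id)] <- onset
    members$status <- "unrelated"
    members$status[members$id %in% affected_ids] <-
      ifelse(onset < 70, "EOAD", "LOAD")
    members$status[members$sampled & !(members$id %in% affected_ids)] <-
      "unaffected"
    members$onset_age[members$role == "elderly_unaffected"] <-
      round(runif(sum(members$role == "elderly_unaffected"), 76, 90))
    rows[[i]] <- members
  }
  ped <- do.call(rbind, rows)
  if (config$n_singletons > 0) {
    sing <- data.frame(
      id = sprintf("U%02d", seq_len(config$n_singletons)),
      family_id = NA_character_,
      father = NA_character_, mother = NA_character_,
      role = "singleton", sampled = TRUE,
      onset_age = round(pmin(pmax(
        rnorm(config$n_singletons, 63, 6), 42), 80), 1),
      status = "EOAD",
      stringsAsFactors = FALSE
    )
    ped <- rbind(ped, sing[, names(ped)])
  }
  rownames(ped) <- NULL
  truth <- truth_degrees(ped)
  structure(list(ped = ped, truth_degrees = truth, config = config),
            class = "famalz_pedigree")
}

# Exact pedigree kinship by the classic recursion: members must be ordered
# parents-before-children (guaranteed by the generator, validated here).
pedigree_kinship_matrix <- function(members) {
  n <- nrow(members)
  idx <- setNames(seq_len(n), members$id)
  K <- matrix(0, n, n, dimnames = list(members$id, members$id))
  for (i in seq_len(n)) {
    f <- members$father[i]; m <- members$mother[i]
    fi <- if (!is.na(f)) idx[[f]] else NA_integer_
    mi <- if (!is.na(m)) idx[[m]] else NA_integer_
    if ((!is.na(fi) && fi >= i) || (!is.na(mi) && mi >= i))
      stop("pedigree is cyclic or not ordered parents-before-children")
    for (j in seq_len(i - 1L)) {
      kij <- 0
      if (!is.na(fi)) kij <- kij + 0.5 * K[fi, j]
      if (!is.na(mi)) kij <- kij + 0.5 * K[mi, j]
      K[i, j] <- K[j, i] <- kij
    }
    K[i, i] <- if (!is.na(fi) && !is.na(mi)) 0.5 * (1 + K[fi, mi]) else 0.5
  }
  K
}

# True relationship degree for every sampled within-family pair.
truth_degrees <- function(ped) {
  fams <- unique(ped$family_id[!is.na(ped$family_id)])
  out <- list()
  for (fam in fams) {
    members <- ped[!is.na(ped$family_id) & ped$family_id == fam, ]
    K <- pedigree_kinship_matrix(members)
    s <- members$id[members$sampled]
    if (length(s) < 2) next
    pairs <- utils::combn(s, 2)
    phi <- K[cbind(pairs[1, ], pairs[2, ])]
    out[[fam]] <- data.frame(
      sample_i = pairs[1, ], sample_j = pairs[2, ],
      family_id = fam, phi_true = phi,
      degree = as.character(classify_degree(phi)),
      stringsAsFactors = FALSE
    )
  }
  if (!length(out)) {
    return(data.frame(sample_i = character(), sample_j = character(),
                      family_id = character(), phi_true = numeric(),
                      degree = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
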