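#' Screen variants against a dementia gene panel
#'
#' @param variants Annotation data.frame with a `gene` column.
#' @param panel Character vector of panel gene symbols.
#' @return `variants` with an added logical `panel_member` column.
#' @export
screen_panel <- function(variants, panel) {
  if (!length(panel)) {
    variants$panel_member <- rep(FALSE, nrow(variants))
    return(variants)
  }
  variants$panel_member <- variants$gene %in% panel
  variants
}

#' Classify filtered variants as pathogenic, VUS or likely benign
#'
#' Operationalises a clinical-style triage of rare segregating variants:
#' \enumerate{
#'   \item \strong{pathogenic} if flagged as definitely pathogenic in
#'     curated databases, or if truncating (nonsense/frameshift) in a gene
#'     where protein-truncating variants are established as highly penetrant
#'     (default `SORL1`, `GRN`) — this covers novel truncating alleles
#'     absent from databases;
#'   \item otherwise \strong{likely benign} if predicted tolerated by at
#'     least two of the three in-silico tools (SIFT, PolyPhen2,
#'     MutationTaster) and/or the scaled CADD score is below 10;
#'   \item otherwise \strong{VUS}. Variants with no usable predictor calls
#'     and no CADD score are VUS with rationale "insufficient evidence".
#' }
#' The pathogenic rule is evaluated before the benign rule.
#'
#' @param variants Annotation data.frame (columns `gene`,
#'   `consequence_class`, `cadd`, `sift`, `polyphen2`, `muttaster`,
#'   `db_pathogenic`).
#' @param ptv_genes Genes whose truncating variants are treated as
#'   pathogenic.
#' @return `variants` with added `label` (factor: pathogenic, VUS,
#'   likely_benign) and `rationale` (character) columns; every row gets
#'   exactly one label.
#' @export
classify_variants <- function(variants, ptv_genes = c("SORL1", "GRN")) {
  n <- nrow(variants)
  preds <- cbind(variants$sift, variants$polyphen2, variants$muttaster)
  preds[preds == "NA"] <- NA
  n_tol <- rowSums(preds == "tolerated", na.rm = TRUE)
  n_called <- rowSums(!is.na(preds))
  db <- variants$db_pathogenic %in% TRUE
  ptv <- variants$consequence_class %in% c("nonsense", "frameshift") &
    variants$gene %in% ptv_genes
  cadd_low <- !is.na(variants$cadd) & variants$cadd < 10
  benign <- n_tol >= 2 | cadd_low
  no_evidence <- n_called == 0 & is.na(variants$cadd)
  label <- rep("VUS", n)
  rationale <- rep("neither pathogenic nor benign rule fired", n)
  rationale[no_evidence] <- "insufficient evidence"
  label[benign] <- "likely_benign"
  rationale[benign & n_tol >= 2 & !cadd_low] <-
    "tolerated by >=2 of 3 prediction tools"
  rationale[benign & cadd_low & !(n_tol >= 2)] <- "CADD < 10"
  rationale[benign & cadd_low & n_tol >= 2] <-
    "tolerated by >=2 of 3 prediction tools; CADD < 10"
  label[ptv] <- "pathogenic"
  rationale[ptv] <- "truncating variant in high-penetrance-PTV gene"
  label[db] <- "pathogenic"
  rationale[db] <- "definite pathogenic in curated databases"
  rationale[db & ptv] <-
    "definite pathogenic in curated databases; truncating in high-penetrance-PTV gene"
  variants$label <- factor(label,
                           levels = c("pathogenic", "VUS", "likely_benign"))
  variants$rationale <- rationale
  variants
}

#' Prioritize novel candidate genes shared across families
#'
#' Applies the cross-family selection rules to the per-family filter
#' survivors in genes outside the dementia panel, after removing families
#' with a confirmed monogenic cause:
#' \itemize{
#'   \item `shared_variant_2plus`: one identical variant
#'     (chrom+pos+ref+alt) carried by two or more families;
#'   \item `gene_3plus_families`: a gene with qualifying variants in three
#'     or more distinct families;
#'   \item `gene_2fam_cadd15_lit`: a gene with variants in exactly two
#'     families, CADD > 15 in both, and a literature link to
#'     dementia/neurodegeneration.
#' }
#' Rules are reported in that precedence order. Variants matching the
#' blacklist (known false-positive calls) are flagged; a candidate that no
#' longer satisfies its rule once blacklisted support is removed is excluded
#' from the selected set but returned with `blacklist_flag = TRUE`.
#'
#' @param survivors data.frame of per-family non-panel filter survivors:
#'   columns `family_id`, `variant_id`, `gene`, `cadd`.
#' @param solved_families Family ids with a confirmed monogenic cause
#'   (removed before prioritization).
#' @param blacklist Optional character vector of blacklisted `variant_id`s.
#' @param literature_flags Named logical vector: per-gene literature link to
#'   dementia/neurodegeneration (missing genes count as `FALSE`).
#' @return List with `candidates` (data.frame `gene`, `rule`,
#'   `n_families`, `families`, `variant_ids`, `blacklist_flag`; selected
#'   candidates have `blacklist_flag = FALSE`), `selected` (the clean
#'   subset) and `counts` (named selections per rule).
#' @export
prioritize_novel <- function(survivors, solved_families = character(0),
                             blacklist = character(0),
                             literature_flags = logical(0)) {
  sv <- survivors[!survivors$family_id %in% solved_families, , drop = FALSE]
  lit <- function(gene) isTRUE(unname(literature_flags[gene])[1])
  pick <- function(d) {
    # selection rules on one support set; returns per-gene rule or NA
    genes <- unique(d$gene)
    vapply(genes, function(g) {
      dg <- d[d$gene == g, , drop = FALSE]
      shared <- any(vapply(split(dg$family_id, dg$variant_id),
                           function(f) length(unique(f)) >= 2, logical(1)))
      n_fam <- length(unique(dg$family_id))
      if (shared) return("shared_variant_2plus")
      if (n_fam >= 3) return("gene_3plus_families")
      if (n_fam == 2 && lit(g)) {
        max_cadd <- tapply(dg$cadd, dg$family_id, max, na.rm = TRUE)
        if (all(is.finite(max_cadd)) && all(max_cadd > 15))
          return("gene_2fam_cadd15_lit")
      }
      NA_character_
    }, character(1))
  }
  full_rules <- pick(sv)
  clean <- sv[!sv$variant_id %in% blacklist, , drop = FALSE]
  clean_rules <- pick(clean)
  cand_genes <- names(full_rules)[!is.na(full_rules)]
  if (!length(cand_genes)) {
    empty <- data.frame(gene = character(), rule = character(),
                        n_families = integer(), families = character(),
                        variant_ids = character(), blacklist_flag = logical(),
                        stringsAsFactors = FALSE)
    return(list(candidates = empty, selected = empty,
                counts = c(shared_variant_2plus = 0L,
                           gene_3plus_families = 0L,
                           gene_2fam_cadd15_lit = 0L)))
  }
  rows <- lapply(cand_genes, function(g) {
    ok <- g %in% names(clean_rules) && !is.na(clean_rules[[g]])
    d <- if (ok) clean[clean$gene == g, , drop = FALSE] else
      sv[sv$gene == g, , drop = FALSE]
    data.frame(
      gene = g,
      rule = if (ok) clean_rules[[g]] else full_rules[[g]],
      n_families = length(unique(d$family_id)),
      families = paste(sort(unique(d$family_id)), collapse = ";"),
      variant_ids = paste(sort(unique(d$variant_id)), collapse = ";"),
      blacklist_flag = !ok,
      stringsAsFactors = FALSE
    )
  })
  candidates <- do.call(rbind, rows)
  candidates <- candidates[order(candidates$gene), , drop = FALSE]
  rownames(candidates) <- NULL
  selected <- candidates[!candidates$blacklist_flag, , drop = FALSE]
  counts <- table(factor(selected$rule,
                         levels = c("shared_variant_2plus",
                                    "gene_3plus_families",
                                    "gene_2fam_cadd15_lit")))
  list(candidates = candidates, selected = selected,
       counts = c(counts))
}

#' Read a gene panel file
#'
#' One gene symbol per line; blank lines and `#` comments ignored. With no
#' path, the packaged dementia panel is read.
#'
#' @param path Path to a panel file, or `NULL` for the packaged panel.
#' @return Character vector of gene symbols.
#' @export
read_gene_panel <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "dementia_panel.txt", package = "famalz")
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}
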