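test_that("panel screening partitions by gene membership", {
  v <- make_variants(3, gene = c("PSEN1", "NOVELG", "GRN"))
  panel <- read_gene_panel()
  out <- screen_panel(v, panel)
  expect_equal(out$panel_member, c(TRUE, FALSE, TRUE))
  none <- screen_panel(v, character(0))
  expect_false(any(none$panel_member))
})

test_that("classification rules fire in the documented order", {
  v <- make_variants(8,
    gene = c("GRN", "SORL1", "SQSTM1", "ABCA7", "CR1", "MADD", "BIN1",
             "PRNP"),
    consequence_class = c("frameshift", "frameshift", "nonsense",
                          "missense", "missense", "frameshift", "missense",
                          "missense"),
    db_pathogenic = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                      FALSE),
    cadd = c(NA, NA, 35, 22, 9, NA, 24, 23),
    sift = c("NA", "NA", "damaging", "tolerated", "damaging", "NA",
             "damaging", "tolerated"),
    polyphen2 = c("NA", "NA", "damaging", "tolerated", "damaging", "NA",
                  "damaging", "damaging"),
    muttaster = c("NA", "NA", "damaging", "damaging", "damaging", "NA",
                  "damaging", "damaging"))
  out <- classify_variants(v)
  lab <- setNames(as.character(out$label), v$gene)
  # database-pathogenic frameshift -> pathogenic
  expect_equal(lab[["GRN"]], "pathogenic")
  # novel truncating variant in a high-penetrance-PTV gene -> pathogenic
  expect_equal(lab[["SORL1"]], "pathogenic")
  # truncating in a gene outside the PTV set stays VUS
  expect_equal(lab[["SQSTM1"]], "VUS")
  # two tools tolerated -> likely benign even at CADD 22 (and/or rule)
  expect_equal(lab[["ABCA7"]], "likely_benign")
  # CADD < 10 -> likely benign even with damaging calls
  expect_equal(lab[["CR1"]], "likely_benign")
  # no predictors, no CADD -> VUS with insufficient-evidence rationale
  expect_equal(lab[["MADD"]], "VUS")
  expect_equal(out$rationale[v$gene == "MADD"], "insufficient evidence")
  expect_equal(lab[["BIN1"]], "VUS")
  # one tolerated call is not enough for the benign rule
  expect_equal(lab[["PRNP"]], "VUS")
  # label totality: exactly one label each, rationale non-empty
  expect_false(any(is.na(out$label)))
  expect_true(all(nzchar(out$rationale)))
})

test_that("the PTV gene set is configurable", {
  v <- make_variants(1, gene = "SQSTM1", consequence_class = "nonsense",
                     cadd = 35)
  expect_equal(as.character(classify_variants(v)$label), "VUS")
  expect_equal(as.character(
    classify_variants(v, ptv_genes = c("SQSTM1"))$label), "pathogenic")
})

surv <- function(...) {
  d <- data.frame(..., stringsAsFactors = FALSE)
  names(d) <- c("family_id", "variant_id", "gene", "cadd")[seq_along(d)]
  d
}

test_that("the three prioritization rules select as specified", {
  sv <- rbind(
    surv(c("F1", "F2"), c("vA", "vA"), c("G1", "G1"), c(12, 12)),
    surv(c("F1", "F2", "F3"), c("vB1", "vB2", "vB3"), rep("G2", 3),
         c(10, 11, 12)),
    surv(c("F1", "F2"), c("vC1", "vC2"), c("G3", "G3"), c(16, 18)),
    surv(c("F1", "F2"), c("vD1", "vD2"), c("G4", "G4"), c(16, 14)),
    surv(c("F1", "F2"), c("vE1", "vE2"), c("G5", "G5"), c(16, 18)))
  out <- prioritize_novel(sv, literature_flags = c(G3 = TRUE, G4 = TRUE,
                                                   G5 = FALSE))
  rules <- setNames(out$selected$rule, out$selected$gene)
  expect_equal(rules[["G1"]], "shared_variant_2plus")
  expect_equal(rules[["G2"]], "gene_3plus_families")
  expect_equal(rules[["G3"]], "gene_2fam_cadd15_lit")
  expect_false("G4" %in% out$selected$gene)  # CADD 14 in one family
  expect_false("G5" %in% out$selected$gene)  # no literature link
  expect_equal(unname(out$counts), c(1L, 1L, 1L))
})

test_that("solved families are excluded before prioritization", {
  sv <- surv(c("F1", "F2"), c("vA", "vA"), c("G1", "G1"), c(20, 20))
  expect_equal(prioritize_novel(sv)$selected$gene, "G1")
  expect_equal(nrow(prioritize_novel(sv,
                                     solved_families = "F2")$selected), 0L)
})

test_that("blacklisted support is flagged and removes failing candidates", {
  sv <- rbind(surv(c("F1", "F2"), c("vA", "vA"), c("G1", "G1"), c(20, 20)),
              surv(c("F1", "F2", "F3"), c("vB1", "vB2", "vB3"),
                   rep("G2", 3), c(20, 20, 20)))
  out <- prioritize_novel(sv, blacklist = "vA")
  expect_false("G1" %in% out$selected$gene)
  g1 <- out$candidates[out$candidates$gene == "G1", ]
  expect_true(g1$blacklist_flag)
  # G2 loses one family's variant but still qualifies via the other rule?
  out2 <- prioritize_novel(sv, blacklist = "vB3")
  expect_false("G2" %in% out2$selected$gene)  # down to 2 families, no lit
  out3 <- prioritize_novel(sv, blacklist = "vB3",
                           literature_flags = c(G2 = TRUE))
  expect_equal(out3$selected$rule[out3$selected$gene == "G2"],
               "gene_2fam_cadd15_lit")
})

test_that("prioritization is monotone in supporting families", {
  base <- surv(c("F1", "F2"), c("vA", "vA"), c("G1", "G1"), c(20, 20))
  more <- rbind(base, surv("F3", "vA2", "G1", 20))
  sel_base <- prioritize_novel(base)$selected$gene
  sel_more <- prioritize_novel(more)$selected$gene
  expect_true(all(sel_base %in% sel_more))
})

test_that("planted novel-gene structure is recovered exactly from a cohort", {
  novel <- data.frame(
    gene = c("NOVA", "NOVB", "NOVC"),
    type = c("shared_variant", "gene_multi", "gene_multi"),
    families = c("F01,F02", "F01,F02,F03", "F02,F03"),
    cadd = c(22, 18, 25), stringsAsFactors = FALSE)
  cfg <- sim_config(n_families = 3, novel_plan = novel,
                    n_common_snps = 100, n_background_rare = 8, seed = 61)
  co <- simulate_cohort(cfg)
  phen <- co$phenotypes
  sv <- list()
  for (fid in c("F01", "F02", "F03")) {
    members <- phen$sample_id[phen$family_id %in% fid]
    aff_m <- members[phen$status[match(members, phen$sample_id)] %in%
                       c("EOAD", "LOAD", "MCI")]
    view <- build_family_view(co$variants, co$var_geno, members)
    s <- apply_filters(view, aff_m,
                       setdiff(members, aff_m))$survivors$variants
    if (nrow(s)) sv[[fid]] <- data.frame(family_id = fid, s)
  }
  sv <- do.call(rbind, sv)
  panel <- read_gene_panel()
  sv <- screen_panel(sv, panel)
  out <- prioritize_novel(
    sv[!sv$panel_member, c("family_id", "variant_id", "gene", "cadd")],
    literature_flags = c(NOVC = TRUE))
  expect_setequal(out$selected$gene, c("NOVA", "NOVB", "NOVC"))
  truth_novel <- unique(co$truth$planted$gene[
    co$truth$planted$kind == "novel"])
  expect_setequal(out$selected$gene, truth_novel)
  # unknown family in the plan is rejected
  bad <- novel; bad$families[1] <- "F01,F09"
  expect_error(sim_config(n_families = 3, novel_plan = bad), "F09")
})
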