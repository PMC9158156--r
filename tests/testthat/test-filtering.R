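fam <- c("p1", "p2", "u1")
aff <- c("p1", "p2")

view_of <- function(variants, geno) {
  structure(list(variants = variants, geno = geno), class = "family_view")
}

seg_geno <- function(variants) {
  g <- make_geno(variants, fam)
  g[, "u1"] <- 0L
  g
}

test_that("family view keeps only records carried by the family and validates members", {
  v <- make_variants(3)
  g <- make_geno(v, c(fam, "other"))
  g[1, fam] <- 0L            # hom-ref in all members -> excluded
  g[2, ] <- 0L; g[2, "p1"] <- 1L  # het in one member -> included
  view <- build_family_view(v, g, fam)
  expect_setequal(view$variants$variant_id, c("v002", "v003"))
  expect_equal(colnames(view$geno), fam)
  expect_error(build_family_view(v, g, c(fam, "ghost")), "ghost")
})

test_that("QD and MAF boundaries are respected; missing annotations follow policy", {
  v <- make_variants(6,
    qd = c(4.9, 5.0, NA, 20, 20, 20),
    af_gnomad_total = c(0, 0, 0, 0.002, NA, 0.001),
    consequence_class = c(rep("missense", 5), NA))
  res <- apply_filters(view_of(v, seg_geno(v)), aff, "u1")
  ids <- res$survivors$variants$variant_id
  expect_false("v001" %in% ids)  # QD 4.9 removed
  expect_true("v002" %in% ids)   # QD 5.0 retained (inclusive)
  expect_true("v003" %in% ids)   # missing QD passes
  expect_false("v004" %in% ids)  # AF 0.002 removed
  expect_true("v005" %in% ids)   # missing AF passes (novel variant)
  expect_false("v006" %in% ids)  # missing consequence fails
  aud <- res$audit
  expect_equal(aud$n_removed[aud$stage == "qd"], 1L)
  # v006 (AF at the 0.001 boundary) falls at the earlier consequence stage
  expect_equal(aud$n_removed[aud$stage == "consequence"], 1L)
  expect_equal(aud$n_removed[aud$stage == "maf"], 1L)
})

test_that("consequence stage accepts coding and near-splice, rejects the rest", {
  v <- make_variants(6,
    consequence_class = c("missense", "synonymous", "splice", "splice",
                          "intronic", "intronic"),
    splice_distance = c(NA, NA, 2, NA, 2, 3))
  res <- apply_filters(view_of(v, seg_geno(v)), aff, "u1")
  expect_setequal(res$survivors$variants$variant_id,
                  c("v001", "v003", "v004", "v005"))
})

test_that("segregation requires het in all affected (MCI included) and ref in unaffected", {
  v <- make_variants(5)
  g <- seg_geno(v)
  g[2, "p2"] <- 0L       # not het in all affected
  g[3, "u1"] <- 1L       # unaffected carries
  g[4, "p1"] <- NA       # missing affected call fails
  g[5, "u1"] <- NA       # missing unaffected call is not held against it
  res <- apply_filters(view_of(v, g), aff, "u1")
  expect_setequal(res$survivors$variants$variant_id, c("v001", "v005"))
})

test_that("stage order changes audit attribution but never the survivor set", {
  cfg <- tiny_config(seed = 55)
  co <- simulate_cohort(cfg)
  members <- co$truth$families$sample_id[
    co$truth$families$family_id == "F01"]
  aff_m <- co$phenotypes$sample_id[
    co$phenotypes$family_id %in% "F01" &
      co$phenotypes$status %in% c("EOAD", "LOAD", "MCI")]
  view <- build_family_view(co$variants, co$var_geno, members)
  orders <- list(c("qd", "consequence", "maf", "segregation"),
                 c("segregation", "maf", "consequence", "qd"),
                 c("maf", "qd", "segregation", "consequence"))
  sets <- lapply(orders, function(o)
    sort(apply_filters(view, aff_m, setdiff(members, aff_m),
                       stage_order = o)$survivors$variants$variant_id))
  expect_identical(sets[[1]], sets[[2]])
  expect_identical(sets[[1]], sets[[3]])
})

test_that("filtering is idempotent and monotone in thresholds", {
  cfg <- tiny_config(seed = 56)
  co <- simulate_cohort(cfg)
  members <- co$truth$families$sample_id[
    co$truth$families$family_id == "F02"]
  aff_m <- co$phenotypes$sample_id[
    co$phenotypes$family_id %in% "F02" &
      co$phenotypes$status %in% c("EOAD", "LOAD", "MCI")]
  unaff <- setdiff(members, aff_m)
  view <- build_family_view(co$variants, co$var_geno, members)
  once <- apply_filters(view, aff_m, unaff)
  twice <- apply_filters(once$survivors, aff_m, unaff)
  expect_identical(twice$survivors$variants, once$survivors$variants)
  expect_equal(sum(twice$audit$n_removed), 0L)
  for (crit in list(filter_criteria(min_qd = 10),
                    filter_criteria(max_maf = 1e-5),
                    filter_criteria(consequence_whitelist = "missense"))) {
    tighter <- apply_filters(view, aff_m, unaff, criteria = crit)
    expect_true(all(tighter$survivors$variants$variant_id %in%
                      once$survivors$variants$variant_id))
  }
})

test_that("audit counts match the planted violation tags exactly", {
  cfg <- tiny_config(seed = 57)  # 8 background variants: 2 per tag
  co <- simulate_cohort(cfg)
  truth <- co$truth$planted
  for (fid in c("F01", "F02")) {
    members <- co$truth$families$sample_id[
      co$truth$families$family_id == fid]
    aff_m <- co$phenotypes$sample_id[
      co$phenotypes$family_id %in% fid &
        co$phenotypes$status %in% c("EOAD", "LOAD", "MCI")]
    view <- build_family_view(co$variants, co$var_geno, members)
    res <- apply_filters(view, aff_m, setdiff(members, aff_m))
    tags <- table(truth$tag[truth$family_id == fid &
                              truth$kind == "background"])
    aud <- res$audit
    expect_equal(aud$n_removed[aud$stage == "qd"],
                 unname(tags[["fail_qd"]]))
    expect_equal(aud$n_removed[aud$stage == "consequence"],
                 unname(tags[["fail_consequence"]]))
    expect_equal(aud$n_removed[aud$stage == "maf"],
                 unname(tags[["fail_maf"]]))
    expect_equal(aud$n_removed[aud$stage == "segregation"],
                 unname(tags[["fail_segregation"]]))
    planted_id <- truth$variant_id[truth$family_id == fid &
                                     grepl("^planted", truth$kind)]
    expect_identical(res$survivors$variants$variant_id, planted_id)
  }
})

test_that("NFE frequency filtering is available behind a flag", {
  v <- make_variants(2, af_gnomad_total = c(0, 0.002),
                     af_gnomad_nfe = c(0.002, 0))
  res_tot <- apply_filters(view_of(v, seg_geno(v)), aff, "u1")
  res_nfe <- apply_filters(view_of(v, seg_geno(v)), aff, "u1",
                           criteria = filter_criteria(use_nfe = TRUE))
  expect_equal(res_tot$survivors$variants$variant_id, "v001")
  expect_equal(res_nfe$survivors$variants$variant_id, "v002")
})
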