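test_that("pedigree truth degrees match relationship definitions", {
  # two siblings -> 1st degree; avuncular pair -> 2nd degree
  plan <- default_family_plan()[1:2, ]
  plan$structure <- c("sibship", "avuncular")
  plan$n_affected <- c(2L, 2L)
  cfg <- sim_config(n_families = 2, family_plan = plan, n_common_snps = 10,
                    seed = 11)
  ped <- simulate_pedigree(cfg)
  td <- ped$truth_degrees
  sibs <- td[td$family_id == "F01", ]
  expect_equal(nrow(sibs), 1L)
  expect_equal(sibs$degree, "1st")
  expect_equal(sibs$phi_true, 0.25)
  avunc <- td[td$family_id == "F02", ]
  expect_equal(avunc$degree, "2nd")
  expect_equal(avunc$phi_true, 0.125)
})

test_that("cousins are 3rd-degree truth pairs and every affected pair is close", {
  cfg <- sim_config(n_families = 3, include_cousins = TRUE, seed = 12,
                    n_common_snps = 10)
  ped <- simulate_pedigree(cfg)
  td <- ped$truth_degrees
  expect_true(any(td$degree == "3rd"))
  expect_equal(unique(td$phi_true[td$degree == "3rd"]), 0.0625)
  aff <- ped$ped$id[ped$ped$role == "affected"]
  both_aff <- td[td$sample_i %in% aff & td$sample_j %in% aff, ]
  expect_true(all(both_aff$degree %in% c("1st", "2nd")))
})

test_that("family size below two affected is rejected", {
  expect_error(sim_config(family_size_range = c(1, 3)), ">= 2")
})

test_that("identical seeds give identical cohorts, different seeds differ", {
  a <- simulate_cohort(tiny_config(seed = 42))
  b <- simulate_cohort(tiny_config(seed = 42))
  d <- simulate_cohort(tiny_config(seed = 43))
  expect_identical(a$common_geno, b$common_geno)
  expect_identical(a$variants, b$variants)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$prs$dosages, b$prs$dosages)
  expect_false(identical(a$common_geno, d$common_geno))
})

test_that("genotype transmission is Mendelian-consistent and Hardy-Weinberg at founders", {
  cfg <- sim_config(n_families = 2, n_common_snps = 10000,
                    common_maf_range = c(0.5, 0.5), seed = 13)
  ped <- simulate_pedigree(cfg)
  g <- simulate_genotypes(ped, cfg)
  # exhaustive Mendelian check: child allele counts reachable from parents
  pd <- ped$ped
  for (i in which(!is.na(pd$father))) {
    gc <- g[pd$id[i], ]; gf <- g[pd$father[i], ]; gm <- g[pd$mother[i], ]
    min_child <- (gf == 2) + (gm == 2)
    max_child <- 2 - ((gf == 0) + (gm == 0))
    expect_true(all(gc >= min_child & gc <= max_child))
  }
  # heterozygosity 0.5 +/- 0.02 at MAF 0.5 over 10,000 sites
  founder <- pd$id[is.na(pd$father)][1]
  expect_lt(abs(mean(g[founder, ] == 1) - 0.5), 0.02)
})

test_that("duplicate-sample mode emits identical calls", {
  cfg <- tiny_config(duplicate_samples = 1, seed = 14)
  co <- simulate_cohort(cfg)
  dup <- grep("_dup$", co$phenotypes$sample_id, value = TRUE)
  expect_length(dup, 1L)
  src <- sub("_dup$", "", dup)
  expect_identical(co$common_geno[dup, ], co$common_geno[src, ])
  expect_identical(unname(co$var_geno[, dup]), unname(co$var_geno[, src]))
})

test_that("planted variants segregate and background variants carry their tag", {
  cfg <- tiny_config(seed = 15)
  co <- simulate_cohort(cfg)
  truth <- co$truth$planted
  phen <- co$phenotypes
  planted <- truth[grepl("^planted", truth$kind), ]
  for (i in seq_len(nrow(planted))) {
    v <- co$variants[co$variants$variant_id == planted$variant_id[i], ]
    aff <- phen$sample_id[phen$family_id %in% planted$family_id[i] &
                            phen$status %in% c("EOAD", "LOAD")]
    expect_true(all(co$var_geno[planted$variant_id[i], aff] == 1L))
    expect_lt(v$af_gnomad_total, 0.001)
    expect_gte(v$qd, 5)
    expect_true(v$consequence_class %in% c("missense", "nonsense",
                                           "frameshift"))
  }
  bg <- truth[truth$kind == "background", ]
  expect_equal(nrow(bg), cfg$n_background_rare * cfg$n_families)
  expect_setequal(unique(bg$tag),
                  c("fail_qd", "fail_consequence", "fail_maf",
                    "fail_segregation"))
})

test_that("null replication cohort has label-independent carriers; strong effects order them", {
  cfg <- sim_config(replication_sizes = c(EOAD = 3000, LOAD = 3000,
                                          control = 4000), seed = 16)
  null <- simulate_replication_cohort(cfg, n_genes = 1, carrier_freq = 0.1,
                                      beta = 0, seed = 21)
  freq0 <- tapply(null$carriers[, 1], null$labels, mean)
  expect_true(all(abs(freq0 - 0.1) < 0.02))
  eff <- simulate_replication_cohort(cfg, n_genes = 1, carrier_freq = 0.1,
                                     beta = 2, seed = 22)
  freq <- tapply(eff$carriers[, 1], eff$labels, mean)
  expect_true(freq[["EOAD"]] > freq[["LOAD"]])
  expect_true(freq[["LOAD"]] > freq[["control"]])
  # zero genes requested -> empty carrier table
  none <- simulate_replication_cohort(cfg, n_genes = 0, seed = 23)
  expect_equal(ncol(none$carriers), 0L)
})

test_that("write/read round-trips the cohort losslessly", {
  cfg <- tiny_config(n_singletons = 1, duplicate_samples = 1, seed = 17)
  co <- simulate_cohort(cfg)
  d <- withr::local_tempdir()
  paths <- write_cohort(co, d)
  expect_true(all(file.exists(paths)))
  rt <- read_cohort(d)
  v1 <- co$variants[order(co$variants$variant_id), ]
  v2 <- rt$variants[order(rt$variants$variant_id), names(v1)]
  rownames(v1) <- rownames(v2) <- NULL
  v2$pos <- as.integer(v2$pos)
  expect_equal(v2, v1, tolerance = 1e-8)
  ord <- co$phenotypes$sample_id
  expect_identical(unname(rt$var_geno[rownames(co$var_geno), ord]),
                   unname(co$var_geno[, ord]))
  expect_identical(unname(unclass(rt$common_geno[ord, ])),
                   unname(co$common_geno[ord, ]))
  expect_equal(rt$phenotypes, co$phenotypes)
  expect_identical(unname(rt$dosages[ord, ]),
                   unname(co$prs$dosages[ord, colnames(rt$dosages)]))
  # header declares every INFO key used in the body
  lines <- readLines(paths[["vcf"]])
  body <- lines[!startsWith(lines, "#")]
  info_field <- vapply(strsplit(body, "\t"), `[[`, character(1), 8)
  info_keys <- unique(sub("=.*", "", unlist(strsplit(info_field, ";"))))
  info_keys <- setdiff(info_keys, ".")
  declared <- sub("^##INFO=<ID=([^,]+),.*", "\\1",
                  grep("^##INFO", lines, value = TRUE))
  expect_true(all(info_keys %in% declared))
})

test_that("an empty cohort still writes a valid header-only VCF", {
  cfg <- sim_config(n_families = 2, n_common_snps = 0,
                    n_background_rare = 0, seed = 18)
  co <- simulate_cohort(cfg)
  co$variants <- co$variants[0, ]
  co$var_geno <- co$var_geno[0, , drop = FALSE]
  d <- withr::local_tempdir()
  paths <- write_cohort(co, d)
  lines <- readLines(paths[["vcf"]])
  expect_equal(lines[1], "##fileformat=VCFv4.2")
  expect_true(all(startsWith(lines, "#")))
})

test_that("unwritable output path errors", {
  co <- simulate_cohort(tiny_config(seed = 19))
  expect_error(write_cohort(co, "/proc/nonexistent/xyz"), "cannot create")
})
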