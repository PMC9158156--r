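sim_ordinal <- function(n = 600, beta = 0.8, carrier_freq = 0.15,
                        n_pcs = 3, seed = 1) {
  cfg <- sim_config(replication_sizes = c(
    EOAD = round(n * 0.15), LOAD = round(n * 0.1),
    control = n - round(n * 0.15) - round(n * 0.1)), n_pcs = n_pcs)
  simulate_replication_cohort(cfg, n_genes = 1,
                              carrier_freq = carrier_freq, beta = beta,
                              seed = seed)
}

test_that("the cumulative-logit fit matches the MASS::polr oracle", {
  skip_if_not_installed("MASS")
  rc <- sim_ordinal(seed = 71)
  x <- cbind(carrier = rc$carriers[, 1], rc$pcs)
  fit <- fit_proportional_odds(rc$labels, x)
  d <- data.frame(y = rc$labels, x)
  or <- MASS::polr(y ~ ., data = d, Hess = TRUE)
  expect_equal(unname(fit$beta), unname(coef(or)), tolerance = 1e-4)
  expect_equal(unname(fit$alpha), unname(or$zeta), tolerance = 1e-4)
  expect_equal(fit$logLik, as.numeric(logLik(or)), tolerance = 1e-8)
  expect_equal(unname(fit$se),
               unname(sqrt(diag(vcov(or))[seq_along(fit$beta)])),
               tolerance = 1e-3)
  expect_true(fit$converged)
})

test_that("two-level collapse equals the binary-logistic MLE within 1e-6", {
  rc <- sim_ordinal(seed = 72)
  keep <- rc$labels != "LOAD"
  y2 <- droplevels(rc$labels[keep])
  x2 <- cbind(carrier = rc$carriers[keep, 1], rc$pcs[keep, ])
  fit <- fit_proportional_odds(y2, x2)
  gfit <- glm(I(y2 == "EOAD") ~ x2, family = binomial)
  expect_lt(max(abs(fit$beta - coef(gfit)[-1])), 1e-6)
})

test_that("degenerate designs are handled: constant x, reversed labels, nesting", {
  rc <- sim_ordinal(seed = 73)
  const <- fit_proportional_odds(rc$labels,
                                 cbind(z = rep(2, length(rc$labels))))
  expect_equal(unname(const$beta), 0)
  expect_equal(unname(const$p_wald), 1)
  # reversing the outcome order flips the coefficient sign exactly
  x <- cbind(carrier = rc$carriers[, 1], rc$pcs)
  fwd <- fit_proportional_odds(rc$labels, x)
  rev_y <- factor(as.character(rc$labels),
                  levels = rev(levels(rc$labels)), ordered = TRUE)
  bwd <- fit_proportional_odds(rev_y, x)
  expect_equal(unname(bwd$beta), -unname(fwd$beta), tolerance = 1e-6)
  # the fitted model never scores below its own null
  null <- fit_proportional_odds(rc$labels, NULL)
  expect_gte(fwd$logLik, null$logLik)
  expect_error(fit_proportional_odds(factor(rep("a", 5))), "two outcome")
})

test_that("carrier minima gate gene- and variant-level results", {
  set.seed(74)
  n <- 400
  samples <- sprintf("s%03d", 1:n)
  labels <- setNames(sample(c("control", "LOAD", "EOAD"), n, TRUE,
                            prob = c(0.7, 0.15, 0.15)), samples)
  pcs <- matrix(rnorm(n * 2), n, dimnames = list(samples, c("PC1", "PC2")))
  vc <- data.frame(
    sample_id = c(samples[1:9], samples[1:10], samples[1:4], samples[1:5]),
    unit = c(rep("gene9", 9), rep("gene10", 10), rep("var4", 4),
             rep("var5", 5)),
    cadd = 20, stringsAsFactors = FALSE)
  g <- gene_burden(vc[vc$unit %in% c("gene9", "gene10"), ], labels, pcs,
                   cadd_strata = NULL)
  expect_false("gene9" %in% g$results$unit)
  expect_true("gene10" %in% g$results$unit)
  expect_equal(g$skipped$unit, "gene9")
  v <- variant_burden(vc[vc$unit %in% c("var4", "var5"), ], labels, pcs,
                      cadd_strata = NULL)
  expect_false("var4" %in% v$results$unit)
  expect_true("var5" %in% v$results$unit)
})

test_that("CADD strata are cumulative and qualify carriers accordingly", {
  set.seed(75)
  n <- 300
  samples <- sprintf("s%03d", 1:n)
  labels <- setNames(sample(c("control", "EOAD"), n, TRUE,
                            prob = c(0.8, 0.2)), samples)
  pcs <- matrix(rnorm(n), n, dimnames = list(samples, "PC1"))
  # 30 carriers at CADD 16, 15 more at CADD 26
  vc <- data.frame(sample_id = samples[1:45], unit = "geneX",
                   cadd = c(rep(16, 30), rep(26, 15)),
                   stringsAsFactors = FALSE)
  out <- gene_burden(vc, labels, pcs, cadd_strata = c(15, 20, 25, 30))
  res <- out$results
  expect_equal(res$n_carriers[res$cadd_stratum == "15"], 45L)
  expect_equal(res$n_carriers[res$cadd_stratum == "20"], 15L)
  expect_equal(res$n_carriers[res$cadd_stratum == "25"], 15L)
  expect_false("30" %in% res$cadd_stratum)  # no carriers at CADD >= 30
  expect_true(all(res$q >= res$p - 1e-12))
  expect_equal(res$or_, exp(res$beta))
})

test_that("a strong planted enrichment toward EOAD yields a positive burden", {
  rc <- sim_ordinal(n = 1500, beta = 1.5, seed = 76)
  samples <- sprintf("s%04d", seq_along(rc$labels))
  labels <- setNames(as.character(rc$labels), samples)
  rownames(rc$pcs) <- samples
  vc <- data.frame(sample_id = samples[rc$carriers[, 1] == 1],
                   unit = "geneY", cadd = 25, stringsAsFactors = FALSE)
  out <- gene_burden(vc, labels, rc$pcs, cadd_strata = NULL)
  expect_gt(out$results$beta, 0)
  expect_lt(out$results$p, 0.01)
})

test_that("BH adjustment reproduces hand-computed q-values", {
  expect_equal(adjust_fdr(0.03), 0.03)
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(adjust_fdr(rep(1, 5)), rep(1, 5))
  expect_identical(adjust_fdr(numeric(0)), numeric(0))
  # a hand-worked staggered example: step-up with monotonicity
  p <- c(0.005, 0.04, 0.03, 0.8)
  expect_equal(adjust_fdr(p), c(0.02, 0.0533333333333333, 0.0533333333333333,
                                0.8), tolerance = 1e-10)
  expect_error(adjust_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})
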