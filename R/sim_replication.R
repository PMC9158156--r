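#' Simulate an unrelated EOAD/LOAD/control replication cohort
#'
#' Generates per-gene rare-variant carrier indicators and an ordinal disease
#' outcome under a cumulative-logit (proportional-odds) model with the
#' ordering control < LOAD < EOAD, so a positive effect enriches carriers
#' towards EOAD. Carrier status is drawn first (independent Bernoulli per
#' gene), then the outcome from
#' `P(Y <= k | x) = plogis(alpha_k - x'beta)` with cutpoints chosen so that
#' under the null the expected group sizes match `config$replication_sizes`.
#' Ancestry principal components are independent standard normals.
#'
#' @param config A [sim_config()]; `replication_sizes` gives the target
#'   EOAD/LOAD/control composition and `n_pcs` the number of covariates.
#' @param n_genes Number of genes (carrier columns) to simulate.
#' @param carrier_freq Carrier probability per gene (scalar or length
#'   `n_genes`).
#' @param beta True ordinal log-odds effect per gene (scalar recycled or
#'   length `n_genes`); `beta = 0` gives a null cohort in which carrier
#'   frequency is independent of the outcome.
#' @param seed Optional seed overriding `config$seed + 6`.
#' @return List with `carriers` (n x n_genes 0/1 matrix, columns
#'   `gene001`...), `labels` (ordered factor control < LOAD < EOAD), `pcs`
#'   (n x n_pcs matrix) and `beta` (the true effects used).
#' @export
simulate_replication_cohort <- function(config, n_genes = 1L,
                                        carrier_freq = 0.02, beta = 0,
                                        seed = NULL) {
  stopifnot(inherits(config, "famalz_config"))
  set.seed(if (is.null(seed)) config$seed + 6L else seed)
  sizes <- config$replication_sizes
  if (any(sizes < 0)) stop("replication_sizes must be >= 0")
  n <- sum(sizes)
  beta <- rep_len(beta, n_genes)
  carrier_freq <- rep_len(carrier_freq, n_genes)
  if (n == 0L || n_genes == 0L) {
    return(list(
      carriers = matrix(0L, n, n_genes,
                        dimnames = list(NULL,
                                        sprintf("gene%03d",
                                                seq_len(n_genes)))),
      labels = factor(character(), levels = c("control", "LOAD", "EOAD"),
                      ordered = TRUE),
      pcs = matrix(numeric(), n, config$n_pcs), beta = beta))
  }
  carriers <- vapply(seq_len(n_genes),
                     function(j) rbinom(n, 1L, carrier_freq[j]),
                     integer(n))
  carriers <- matrix(carriers, nrow = n,
                     dimnames = list(NULL, sprintf("gene%03d",
                                                   seq_len(n_genes))))
  # cutpoints from the target composition: control < LOAD < EOAD
  p <- c(sizes[["control"]], sizes[["LOAD"]], sizes[["EOAD"]]) / n
  alpha <- qlogis(cumsum(p)[1:2])
  eta <- as.numeric(carriers %*% beta)
  u <- qlogis(runif(n))  # standard-logistic latent
  y <- 1L + (u > alpha[1] - eta) + (u > alpha[2] - eta)
  labels <- factor(c("control", "LOAD", "EOAD")[y],
                   levels = c("control", "LOAD", "EOAD"), ordered = TRUE)
  pcs <- matrix(rnorm(n * config$n_pcs), n,
                dimnames = list(NULL, sprintf("PC%d",
                                              seq_len(config$n_pcs))))
  list(carriers = carriers, labels = labels, pcs = pcs, beta = beta)
}
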