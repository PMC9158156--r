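#' Simulate unlinked biallelic genotypes through the pedigrees
#'
#' Founders are drawn from Hardy-Weinberg proportions at per-site allele
#' frequencies sampled uniformly from `config$common_maf_range`; non-founders
#' receive one allele from each parent, chosen uniformly at heterozygous
#' sites. Sites are unlinked. Genotypes are coded as alternate-allele counts
#' (0/1/2, `NA` = missing).
#'
#' @param pedigree A [simulate_pedigree()] result.
#' @param config The [sim_config()] used to build the pedigree.
#' @return Integer matrix, all pedigree members x sites (rownames are member
#'   ids, including `_dup` duplicates when configured). The site allele
#'   frequencies are attached as attribute `"maf"`, and the emitted
#'   (`sampled`) ids as attribute `"sampled"`. Missingness
#'   (`config$missing_rate`) is applied to sampled individuals only.
#' @export
simulate_genotypes <- function(pedigree, config) {
  stopifnot(inherits(pedigree, "famalz_pedigree"))
  set.seed(config$seed + 1L)
  maf <- runif(config$n_common_snps, config$common_maf_range[1],
               config$common_maf_range[2])
  geno <- transmit_genotypes(pedigree$ped, maf)
  sampled <- pedigree$ped$id[pedigree$ped$sampled]
  if (config$duplicate_samples > 0) {
    dup_src <- head(sampled, config$duplicate_samples)
    dup <- geno[dup_src, , drop = FALSE]
    rownames(dup) <- paste0(dup_src, "_dup")
    geno <- rbind(geno, dup)
    sampled <- c(sampled, rownames(dup))
  }
  if (config$missing_rate > 0) {
    sub <- geno[sampled, , drop = FALSE]
    miss <- matrix(runif(length(sub)) < config$missing_rate, nrow(sub))
    sub[miss] <- NA_integer_
    geno[sampled, ] <- sub
  }
  attr(geno, "maf") <- maf
  attr(geno, "sampled") <- sampled
  geno
}

# Drop genotypes down the pedigree: founders Hardy-Weinberg at `maf`,
# children one uniformly-transmitted allele per parent. `ped` must be ordered
# parents-before-children (checked).
transmit_genotypes <- function(ped, maf) {
  n_sites <- length(maf)
  geno <- matrix(NA_integer_, nrow(ped), n_sites,
                 dimnames = list(ped$id, NULL))
  idx <- setNames(seq_len(nrow(ped)), ped$id)
  draw_allele <- function(g) {
    as.integer(g == 2L | (g == 1L & runif(n_sites) < 0.5))
  }
  for (i in seq_len(nrow(ped))) {
    f <- ped$father[i]; m <- ped$mother[i]
    if (is.na(f) && is.na(m)) {
      geno[i, ] <- rbinom(n_sites, 2L, maf)
    } else {
      fi <- idx[[f]]; mi <- idx[[m]]
      if (fi >= i || mi >= i)
        stop("pedigree is cyclic or not ordered parents-before-children")
      geno[i, ] <- draw_allele(geno[fi, ]) + draw_allele(geno[mi, ])
    }
  }
  geno
}
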