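# Small configurations shared across test files. Sizes are deliberately
# tiny; statistical checks that need scale set their own.

tiny_config <- function(n_families = 2, seed = 101, ...) {
  sim_config(n_families = n_families, n_common_snps = 200,
             n_background_rare = 8,
             replication_sizes = c(EOAD = 60, LOAD = 40, control = 200),
             seed = seed, ...)
}

# a minimal annotated-variant data.frame with overridable fields
make_variants <- function(n = 1, ...) {
  v <- data.frame(
    variant_id = sprintf("v%03d", seq_len(n)),
    chrom = "1", pos = 1000L + seq_len(n), ref = "A", alt = "G",
    qd = 20, gene = "GENE1", consequence_class = "missense",
    splice_distance = NA_real_, af_gnomad_total = 0,
    af_gnomad_nfe = 0, cadd = 25, sift = "damaging",
    polyphen2 = "damaging", muttaster = "damaging",
    db_pathogenic = FALSE, stringsAsFactors = FALSE
  )
  over <- list(...)
  for (nm in names(over)) v[[nm]] <- over[[nm]]
  v
}

# genotype matrix helper: variants x samples from a list of named vectors
make_geno <- function(variants, samples, default = 1L) {
  g <- matrix(default, nrow(variants), length(samples),
              dimnames = list(variants$variant_id, samples))
  g
}
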