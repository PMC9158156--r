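#' Write a simulated cohort in the pipeline's input formats
#'
#' Emits, under `dir`:
#' \itemize{
#'   \item `cohort.vcf` — VCF v4.2 with one record per common kinship SNP
#'     and per annotated rare variant (INFO keys `QD`, `GENE`, `CSQ_CLASS`,
#'     `SPLICE_DIST`, `AF_GNOMAD`, `AF_GNOMAD_NFE`, `CADD`, `SIFT`,
#'     `POLYPHEN2`, `MUTTASTER`, flag `DB_PATH`), `GT` genotypes for every
#'     sampled individual;
#'   \item `phenotypes.tsv` — `sample_id`, `family_id`, `status`,
#'     `onset_age`, `apoe`;
#'   \item `prs_weights.tsv` — the weight table used;
#'   \item `prs_dosages.tsv` — samples x PRS-locus dosage matrix;
#'   \item `truth.json` — the truth record (pair degrees, planted variants,
#'     APOE diplotypes, true PRS).
#' }
#' Files round-trip losslessly through [read_cohort()].
#'
#' @param cohort A [simulate_cohort()] object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "famalz_cohort"))
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", dir)
  samples <- cohort$phenotypes$sample_id
  paths <- c(vcf = file.path(dir, "cohort.vcf"),
             phenotypes = file.path(dir, "phenotypes.tsv"),
             weights = file.path(dir, "prs_weights.tsv"),
             dosages = file.path(dir, "prs_dosages.tsv"),
             truth = file.path(dir, "truth.json"))
  # --- VCF ---
  fmt_num <- function(x) ifelse(is.na(x), NA, sprintf("%.6g", x))
  gt_code <- c("0/0", "0/1", "1/1")
  gt_of <- function(g) ifelse(is.na(g), "./.", gt_code[g + 1L])
  common <- cohort$common_geno
  n_common <- ncol(common)
  rows <- character(0)
  if (n_common > 0) {
    idx <- seq_len(n_common)
    gt <- apply(common[samples, , drop = FALSE], 1, gt_of)
    gt <- matrix(gt, nrow = n_common)  # sites x samples
    rows <- paste(
      as.character(1L + (idx - 1L) %% 22L), 20000000L + 13L * idx,
      sprintf("snp%05d", idx), "A", "G", ".", "PASS", ".", "GT",
      apply(gt, 1, paste, collapse = "\t"),
      sep = "\t")
  }
  v <- cohort$variants
  if (!is.null(v) && nrow(v) > 0) {
    info <- vapply(seq_len(nrow(v)), function(i) {
      kv <- c(QD = fmt_num(v$qd[i]), GENE = v$gene[i],
              CSQ_CLASS = v$consequence_class[i],
              SPLICE_DIST = if (is.na(v$splice_distance[i])) NA else
                as.character(v$splice_distance[i]),
              AF_GNOMAD = fmt_num(v$af_gnomad_total[i]),
              AF_GNOMAD_NFE = fmt_num(v$af_gnomad_nfe[i]),
              CADD = fmt_num(v$cadd[i]),
              SIFT = v$sift[i], POLYPHEN2 = v$polyphen2[i],
              MUTTASTER = v$muttaster[i])
      kv <- kv[!is.na(kv)]
      s <- paste(names(kv), kv, sep = "=", collapse = ";")
      if (isTRUE(v$db_pathogenic[i])) s <- paste0(s, ";DB_PATH")
      s
    }, character(1))
    g <- cohort$var_geno[, samples, drop = FALSE]
    gt <- matrix(gt_of(g), nrow = nrow(v))
    rows <- c(rows, paste(
      v$chrom, v$pos, v$variant_id, v$ref, v$alt, ".", "PASS", info, "GT",
      apply(gt, 1, paste, collapse = "\t"),
      sep = "\t"))
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=famalz synthetic cohort generator",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CSQ_CLASS,Number=1,Type=String,Description=\"Consequence class\">",
    "##INFO=<ID=SPLICE_DIST,Number=1,Type=Integer,Description=\"Distance to nearest exon-intron junction (bp)\">",
    "##INFO=<ID=AF_GNOMAD,Number=1,Type=Float,Description=\"gnomAD total allele frequency\">",
    "##INFO=<ID=AF_GNOMAD_NFE,Number=1,Type=Float,Description=\"gnomAD non-Finnish European allele frequency\">",
    "##INFO=<ID=CADD,Number=1,Type=Float,Description=\"Scaled CADD score\">",
    "##INFO=<ID=SIFT,Number=1,Type=String,Description=\"SIFT call\">",
    "##INFO=<ID=POLYPHEN2,Number=1,Type=String,Description=\"PolyPhen2 call\">",
    "##INFO=<ID=MUTTASTER,Number=1,Type=String,Description=\"MutationTaster call\">",
    "##INFO=<ID=DB_PATH,Number=0,Type=Flag,Description=\"Definite pathogenic in curated databases\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(header, rows), paths[["vcf"]])
  # --- tables ---
  write.table(cohort$phenotypes, paths[["phenotypes"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(cohort$weights, paths[["weights"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  dos <- data.frame(sample_id = rownames(cohort$prs$dosages),
                    cohort$prs$dosages, check.names = FALSE)
  write.table(dos, paths[["dosages"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(cohort$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(paths)
}

#' Read a cohort VCF into annotation table and genotype matrices
#'
#' Records carrying a `GENE` INFO key are treated as annotated rare
#' variants; all other records are plain (common) SNPs used for kinship.
#' Genotypes are recoded to alternate-allele counts.
#'
#' @param path Path to a VCF (v4.2) file.
#' @return List: `variants` (annotation data.frame in the
#'   [plant_rare_variants()] schema), `var_geno` (variants x samples),
#'   `common_geno` (samples x common sites, columns named by VCF ID),
#'   `samples`.
#' @export
read_cohort_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  n <- nrow(fix)
  empty <- list(
    variants = data.frame(), var_geno = matrix(integer(0), 0, 0),
    common_geno = matrix(integer(0), 0, 0), samples = character(0))
  if (is.null(n) || n == 0) return(empty)
  gt_raw <- vcfR::extract.gt(vcf)
  geno <- matrix(NA_integer_, nrow(gt_raw), ncol(gt_raw),
                 dimnames = dimnames(gt_raw))
  geno[gt_raw %in% c("0/0", "0|0")] <- 0L
  geno[gt_raw %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  geno[gt_raw %in% c("1/1", "1|1")] <- 2L
  info <- vcf@fix[, "INFO"]
  has_gene <- grepl("(^|;)GENE=", info)
  samples <- colnames(geno)
  info_chr <- function(key, rows) {
    pat <- paste0("(^|;)", key, "=[^;]*")
    x <- info[rows]
    out <- rep(NA_character_, length(x))
    hit <- grepl(pat, x)
    out[hit] <- sub(paste0("^;?", key, "="), "",
                    regmatches(x, regexpr(pat, x)))
    out
  }
  info_num <- function(key, rows) as.numeric(info_chr(key, rows))
  variants <- data.frame()
  var_geno <- matrix(integer(0), 0, length(samples),
                     dimnames = list(NULL, samples))
  if (any(has_gene)) {
    variants <- data.frame(
      variant_id = fix$ID[has_gene],
      chrom = fix$CHROM[has_gene],
      pos = as.integer(fix$POS[has_gene]),
      ref = fix$REF[has_gene], alt = fix$ALT[has_gene],
      qd = info_num("QD", has_gene),
      gene = info_chr("GENE", has_gene),
      consequence_class = info_chr("CSQ_CLASS", has_gene),
      splice_distance = info_num("SPLICE_DIST", has_gene),
      af_gnomad_total = info_num("AF_GNOMAD", has_gene),
      af_gnomad_nfe = info_num("AF_GNOMAD_NFE", has_gene),
      cadd = info_num("CADD", has_gene),
      sift = info_chr("SIFT", has_gene),
      polyphen2 = info_chr("POLYPHEN2", has_gene),
      muttaster = info_chr("MUTTASTER", has_gene),
      db_pathogenic = grepl("(^|;)DB_PATH(;|$)", info[has_gene]),
      stringsAsFactors = FALSE
    )
    var_geno <- geno[has_gene, , drop = FALSE]
    rownames(var_geno) <- variants$variant_id
  }
  common_geno <- t(geno[!has_gene, , drop = FALSE])
  colnames(common_geno) <- fix$ID[!has_gene]
  list(variants = variants, var_geno = var_geno, common_geno = common_geno,
       samples = samples)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing `cohort.vcf`, `phenotypes.tsv`,
#'   `prs_weights.tsv`, `prs_dosages.tsv` and `truth.json`.
#' @return List: the [read_cohort_vcf()] fields plus `phenotypes`,
#'   `weights`, `dosages` (matrix) and `truth`.
#' @export
read_cohort <- function(dir) {
  vcf <- read_cohort_vcf(file.path(dir, "cohort.vcf"))
  phenotypes <- read.delim(file.path(dir, "phenotypes.tsv"),
                           stringsAsFactors = FALSE,
                           colClasses = c(apoe = "character"))
  weights <- read_prs_weights(file.path(dir, "prs_weights.tsv"))
  dos <- read.delim(file.path(dir, "prs_dosages.tsv"), check.names = FALSE,
                    stringsAsFactors = FALSE)
  dosages <- as.matrix(dos[, -1, drop = FALSE])
  rownames(dosages) <- dos$sample_id
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  c(vcf, list(phenotypes = phenotypes, weights = weights, dosages = dosages,
              truth = truth))
}
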