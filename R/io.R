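#' Tab-separated interchange helpers
#'
#' Canonical tabular dialect for all pipeline outputs: tab-separated,
#' header row, UTF-8, `"."` for missing values, no quoting or row names.
#'
#' @param x Data.frame to write.
#' @param path File path.
#' @return `write_tsv` returns `path` invisibly; `read_tsv` the data.frame.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, na.strings = c(".", "NA"), check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Write genotype dosages as PLINK-style additive text
#'
#' Minimal `.raw`-style dialect: columns `FID`, `IID`, then one
#' `SNP_ALLELE` column per variant holding the 0/1/2 count of the named
#' (effect) allele.
#'
#' @param genotypes List with `dosage` and `info` as produced by
#'   [simulate_genotypes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_raw <- function(genotypes, path) {
  dos <- genotypes$dosage; info <- genotypes$info
  ids <- rownames(dos)
  if (is.null(ids)) ids <- sprintf("S%05d", seq_len(nrow(dos)))
  df <- data.frame(FID = ids, IID = ids, stringsAsFactors = FALSE)
  cols <- paste0(info$snp, "_", info$a1)
  for (j in seq_along(cols)) df[[cols[j]]] <- dos[, j]
  write_tsv(df, path)
}

#' Read genotype dosages
#'
#' Reads additive dosages either from PLINK-style `.raw` text (`FID`,
#' `IID`, optional `PAT`/`MAT`/`SEX`/`PHENOTYPE`, then `SNP_ALLELE`
#' columns) or from a VCF (dosage = ALT-allele count parsed from `GT`,
#' via the vcfR package). Missing genotypes are mean-imputed per SNP and
#' the imputation count is reported.
#'
#' @param path Input file.
#' @param format `"raw"` or `"vcf"`.
#' @return List with `dosage` (n x m numeric matrix, subject row names,
#'   SNP column names), `info` (`snp`, `chr`, `pos`, `a1`, `a2` where
#'   available) and attribute `n_imputed`.
#' @export
read_genotypes <- function(path, format = c("raw", "vcf")) {
  format <- match.arg(format)
  if (format == "raw") .read_raw(path) else .read_vcf(path)
}

.impute_means <- function(dos) {
  n_imp <- sum(is.na(dos))
  if (n_imp > 0) {
    for (j in seq_len(ncol(dos))) {
      miss <- is.na(dos[, j])
      if (any(miss)) dos[miss, j] <- mean(dos[!miss, j])
    }
    message("mean-imputed ", n_imp, " missing genotype call(s)")
  }
  list(dosage = dos, n_imputed = n_imp)
}

.read_raw <- function(path) {
  df <- read_tsv(path)
  if (!all(c("FID", "IID") %in% names(df)[1:2]))
    stop("malformed .raw header: first columns must be FID, IID")
  snp_cols <- setdiff(names(df),
                      c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"))
  if (!length(snp_cols)) stop("no SNP columns found")
  if (!all(grepl("_[ACGT]$", snp_cols)))
    stop("malformed SNP_ALLELE column name(s): ",
         paste(utils::head(snp_cols[!grepl("_[ACGT]$", snp_cols)], 3),
               collapse = ", "))
  snp <- sub("_[ACGT]$", "", snp_cols)
  a1 <- sub("^.*_", "", snp_cols)
  dos <- as.matrix(df[snp_cols])
  if (!all(dos %in% c(0, 1, 2, NA)))
    stop("dosages must be 0/1/2 or missing")
  colnames(dos) <- snp
  rownames(dos) <- as.character(df$IID)
  imp <- .impute_means(dos)
  structure(list(dosage = imp$dosage,
                 info = data.frame(snp = snp, chr = NA_integer_,
                                   pos = NA_integer_, a1 = a1,
                                   a2 = NA_character_,
                                   stringsAsFactors = FALSE)),
            n_imputed = imp$n_imputed)
}

.read_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  alt_count <- function(s) {
    if (is.na(s)) return(NA_real_)
    a <- strsplit(s, "[/|]")[[1]]
    if (any(a == ".")) return(NA_real_)
    sum(a == "1")
  }
  dos <- t(apply(gt, 1, function(r) vapply(r, alt_count, numeric(1))))
  if (ncol(gt) == 1L) dos <- t(dos)
  dos <- t(dos) # subjects x snps
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  info <- data.frame(snp = fix$ID, chr = fix$CHROM,
                     pos = as.integer(fix$POS),
                     a1 = fix$ALT, a2 = fix$REF, stringsAsFactors = FALSE)
  colnames(dos) <- info$snp
  imp <- .impute_means(dos)
  structure(list(dosage = imp$dosage, info = info),
            n_imputed = imp$n_imputed)
}

#' Write genotypes as a minimal VCF
#'
#' Emits an uncompressed VCFv4.2 text file with `GT` genotypes derived
#' from the 0/1/2 ALT-allele dosages (`0/0`, `0/1`, `1/1`).
#'
#' @inheritParams write_raw
#' @export
write_vcf <- function(genotypes, path) {
  dos <- genotypes$dosage; info <- genotypes$info
  ids <- rownames(dos)
  if (is.null(ids)) ids <- sprintf("S%05d", seq_len(nrow(dos)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", ids), collapse = "\t")),
             con)
  gt_of <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(dos))) {
    gts <- ifelse(is.na(dos[, j]), "./.", gt_of[dos[, j] + 1L])
    writeLines(paste(c(info$chr[j], info$pos[j], info$snp[j], info$a2[j],
                       info$a1[j], ".", "PASS", ".", "GT", gts),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a PRS weight table
#'
#' Expects GWAS summary-statistics style columns `SNP`, `A1` (effect
#' allele) and `BETA` (case-insensitive; `effect_allele`/`beta` synonyms
#' accepted).
#'
#' @param path TSV file path.
#' @return Data.frame with `snp`, `effect_allele`, `beta`.
#' @export
read_prs_weights <- function(path) {
  df <- read_tsv(path)
  nm <- tolower(names(df))
  pick <- function(cands) {
    i <- which(nm %in% cands)[1]
    if (is.na(i)) stop("PRS weight file lacks column: ",
                       paste(cands, collapse = "/"))
    df[[i]]
  }
  out <- data.frame(snp = as.character(pick(c("snp", "id"))),
                    effect_allele = as.character(pick(c("a1",
                                                        "effect_allele"))),
                    beta = as.numeric(pick(c("beta", "effect"))),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$snp)) stop("duplicated SNP ids in weight file")
  if (!all(out$effect_allele %in% c("A", "C", "G", "T")))
    stop("effect alleles must be A/C/G/T")
  out
}

#' Read a gene-location table
#'
#' NCBI gene-loc style TSV with columns `gene`, `chr`, `start`, `end`
#' (1-based closed intervals).
#'
#' @param path TSV file path.
#' @return Data.frame with those four columns.
#' @export
read_gene_locations <- function(path) {
  df <- read_tsv(path)
  need <- c("gene", "chr", "start", "end")
  if (!all(need %in% tolower(names(df))))
    stop("gene-location file must have columns gene, chr, start, end")
  names(df) <- tolower(names(df))
  df[need]
}

#' Read / write GMT gene-set files
#'
#' GMT lines are `set-name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path GMT file path.
#' @param sets Named list of character vectors (for writing).
#' @param descriptions Optional character vector of set descriptions.
#' @return `read_gmt` returns a named list of gene-id vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) stop("malformed GMT line(s): need name, description, genes")
  stats::setNames(lapply(parts, function(p) p[-(1:2)]),
                  vapply(parts, `[`, character(1), 1L))
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  writeLines(vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1)), path)
  invisible(path)
}

#' Write a simulated cohort to disk
#'
#' FFQ and covariates as TSV, genotypes as PLINK-style `.raw` text, the
#' phenotype as TSV, and the ground-truth configuration (seed, planted
#' weights, coefficients and effects) as a JSON sidecar for provenance.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(cohort$ffq, file.path(dir, "ffq.tsv"))
  write_tsv(cohort$covariates, file.path(dir, "covariates.tsv"))
  if (!is.null(cohort$genotypes))
    write_raw(cohort$genotypes, file.path(dir, "genotypes.raw"))
  write_tsv(data.frame(subject_id = cohort$ffq$subject_id,
                       phenotype = as.integer(cohort$phenotype)),
            file.path(dir, "phenotype.tsv"))
  cfg <- cohort$config
  jsonlite::write_json(
    list(seed = cfg$seed, n_subjects = cfg$n_subjects,
         case_fraction = cfg$case_fraction, n_snps = cfg$n_snps,
         maf_range = cfg$maf_range,
         true_item_weights = cfg$true_item_weights,
         true_group_coefs = cfg$true_group_coefs,
         interaction_effects = as.list(cfg$interaction_effects),
         covariate_effects = as.list(cfg$covariate_effects)),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
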