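# PLINK 1 binary genotype codec.
#
# Internal orientation throughout the package is loci x individuals (an m x n
# integer matrix of reference-allele dosages in {0, 1, 2}, NA for missing),
# with rownames = locus ids and colnames = individual ids.  The BED format is
# SNP-major: per locus, individuals are packed 4 per byte, 2 bits each,
# least-significant bits first.  Two-bit codes: 00 = homozygous A1 (dosage 2),
# 01 = missing, 10 = heterozygous (1), 11 = homozygous A2 (0).

BED_MAGIC <- as.raw(c(0x6c, 0x1b, 0x01))

# 256 x 4 lookup: byte value -> dosages of the 4 packed individuals (NA = missing)
.bed_decode_table <- local({
  code2dosage <- c(2L, NA_integer_, 1L, 0L)  # codes 0,1,2,3
  b <- 0:255
  tab <- cbind(
    code2dosage[bitwAnd(b, 3L) + 1L],
    code2dosage[bitwAnd(bitwShiftR(b, 2L), 3L) + 1L],
    code2dosage[bitwAnd(bitwShiftR(b, 4L), 3L) + 1L],
    code2dosage[bitwAnd(bitwShiftR(b, 6L), 3L) + 1L]
  )
  tab
})

#' Validate a genotype matrix
#'
#' Checks that a dosage matrix is a valid loci-by-individuals genotype matrix:
#' integer-valued entries in \{0, 1, 2\} (NA allowed for missing), with
#' optional row (locus) and column (individual) names.
#'
#' @param X Numeric matrix, m loci x n individuals.
#' @return `X`, invisibly, as an integer matrix.
#' @export
validate_genotypes <- function(X) {
  if (!is.matrix(X))
    stop("genotypes must be a matrix (loci x individuals)")
  vals <- X[!is.na(X)]
  if (length(vals) && !all(vals %in% c(0, 1, 2)))
    stop("non-missing genotype dosages must be in {0, 1, 2}")
  storage.mode(X) <- "integer"
  invisible(X)
}

#' Write genotypes to a PLINK 1 BED/BIM/FAM fileset
#'
#' Writes the m x n dosage matrix in SNP-major BED v1.00 format together with
#' matching BIM and FAM text files.  Simulated data uses synthetic allele
#' labels A (counted allele, A1) and B, chromosome 1, and sequential 1-based
#' positions.
#'
#' @param X Genotype matrix (loci x individuals), dosages in \{0,1,2\}, NA missing.
#' @param path_prefix Output path prefix; `.bed`, `.bim`, `.fam` are appended.
#' @param annotation Optional data frame with one row per individual; columns
#'   `sex` ("male"/"female"/"unknown" or 1/2/0) and `phenotype` are used if
#'   present.
#' @return The path prefix, invisibly.
#' @export
write_genotypes <- function(X, path_prefix, annotation = NULL) {
  X <- validate_genotypes(X)
  m <- nrow(X)
  n <- ncol(X)
  if (n < 1L) stop("need at least one individual")
  locus_ids <- rownames(X)
  if (is.null(locus_ids))
    locus_ids <- paste0("snp", seq_len(m), recycle0 = TRUE)
  ind_ids <- colnames(X)
  if (is.null(ind_ids)) ind_ids <- paste0("ind", seq_len(n))

  # dosage -> 2-bit code; pack 4 individuals per byte, LSB first
  dosage2code <- function(x) {
    code <- integer(length(x))
    code[is.na(x)] <- 1L
    code[!is.na(x) & x == 2L] <- 0L
    code[!is.na(x) & x == 1L] <- 2L
    code[!is.na(x) & x == 0L] <- 3L
    code
  }
  bpl <- ceiling(n / 4)  # bytes per locus
  payload <- raw(0)
  if (m > 0L) {
    codes <- matrix(0L, nrow = 4L * bpl, ncol = m)
    codes[seq_len(n), ] <- dosage2code(as.integer(t(X)))
    dim(codes) <- c(4L, bpl * m)
    bytes <- codes[1L, ] + 4L * codes[2L, ] + 16L * codes[3L, ] + 64L * codes[4L, ]
    payload <- as.raw(bytes)
  }
  con <- file(paste0(path_prefix, ".bed"), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(BED_MAGIC, con)
  writeBin(payload, con)

  bim <- data.frame(chr = rep(1L, m), id = locus_ids, posg = rep(0L, m),
                    pos = seq_len(m), alt = rep("A", m), ref = rep("B", m))
  utils::write.table(bim, paste0(path_prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)

  sex_code <- rep(0L, n)
  pheno <- rep(-9, n)
  if (!is.null(annotation)) {
    if (!is.null(annotation$sex)) {
      s <- annotation$sex
      sex_code <- if (is.numeric(s)) as.integer(s)
        else c(male = 1L, female = 2L, unknown = 0L)[as.character(s)]
      sex_code[is.na(sex_code)] <- 0L
    }
    if (!is.null(annotation$phenotype)) pheno <- annotation$phenotype
  }
  fam <- data.frame(fid = ind_ids, iid = ind_ids, pat = 0L, mat = 0L,
                    sex = sex_code, pheno = pheno)
  utils::write.table(fam, paste0(path_prefix, ".fam"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path_prefix)
}

#' Read genotypes from a PLINK 1 BED/BIM/FAM fileset
#'
#' Reads a SNP-major PLINK 1 binary fileset into a loci-by-individuals dosage
#' matrix counting the A1 allele, with the missing code mapped to NA.
#'
#' @param path_prefix Path prefix of the `.bed`/`.bim`/`.fam` triplet.
#' @return A list with elements `X` (m x n integer matrix, rownames = locus
#'   ids, colnames = individual ids), `bim` and `fam` (data frames).
#' @export
read_genotypes <- function(path_prefix) {
  bed_path <- paste0(path_prefix, ".bed")
  bim_path <- paste0(path_prefix, ".bim")
  fam_path <- paste0(path_prefix, ".fam")
  for (p in c(bed_path, bim_path, fam_path))
    if (!file.exists(p)) stop("missing file: ", p)

  bim <- utils::read.table(bim_path, sep = "\t", header = FALSE,
                           col.names = c("chr", "id", "posg", "pos", "alt", "ref"),
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  fam <- utils::read.table(fam_path, sep = "\t", header = FALSE,
                           col.names = c("fid", "iid", "pat", "mat", "sex", "pheno"),
                           colClasses = c("character", "character", "character",
                                          "character", "integer", "numeric"))
  m <- nrow(bim)
  n <- nrow(fam)
  raw_all <- readBin(bed_path, "raw", n = file.info(bed_path)$size)
  if (length(raw_all) < 3L || !identical(raw_all[1:3], BED_MAGIC))
    stop("not a PLINK 1 SNP-major BED file (bad magic bytes): ", bed_path)
  bpl <- ceiling(n / 4)
  expected <- 3L + m * bpl
  if (length(raw_all) != expected)
    stop(sprintf("truncated or oversized BED file: expected %d bytes, found %d",
                 expected, length(raw_all)))
  X <- matrix(integer(0), nrow = m, ncol = n)
  if (m > 0L && n > 0L) {
    idx <- as.integer(raw_all[-(1:3)]) + 1L
    vals <- t(.bed_decode_table[idx, , drop = FALSE])  # 4 x (bpl*m)
    dim(vals) <- c(4L * bpl, m)
    X <- t(vals[seq_len(n), , drop = FALSE])
  }
  dimnames(X) <- list(bim$id, fam$iid)
  list(X = X, bim = bim, fam = fam)
}

#' Write a symmetric matrix (kinship/coancestry) as TSV
#'
#' @param K Square symmetric matrix with individual ids as dimnames.
#' @param path Output file.
#' @export
write_kinship_tsv <- function(K, path) {
  ids <- rownames(K)
  if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(K)))
  df <- data.frame(id = ids, K, check.names = FALSE)
  colnames(df) <- c("id", ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a symmetric matrix written by [write_kinship_tsv()]
#' @param path Input TSV file.
#' @return Numeric matrix with dimnames.
#' @export
read_kinship_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  K <- as.matrix(df[, -1, drop = FALSE])
  rownames(K) <- df[[1]]
  K
}
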