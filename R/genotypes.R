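#' Construct a genotype matrix
#'
#' Container for biallelic SNP genotypes coded as minor-allele counts.
#' Rows are SNPs, columns are patients; cells are 0, 1, 2 or `NA`
#' (missing). Per-SNP metadata carries the rs identifier, GRCh37-style
#' 1-based position and the minor/major alleles.
#'
#' @param codes Integer matrix, SNPs x patients, values in `{0, 1, 2, NA}`.
#' @param snps Data frame with columns `snp_id`, `chrom`, `pos`,
#'   `allele_minor`, `allele_major`; one row per row of `codes`.
#' @param patients Character vector of patient identifiers, one per column
#'   of `codes`.
#' @return An object of class `genotype_matrix` with elements `codes`
#'   (named integer matrix), `snps` (tibble) and `patients`.
#' @examples
#' gm <- genotype_matrix(
#'   codes = rbind(rs1 = c(0L, 1L, 2L)),
#'   snps = data.frame(snp_id = "rs1", chrom = "1", pos = 100L,
#'                     allele_minor = "A", allele_major = "G"),
#'   patients = c("P1", "P2", "P3")
#' )
#' @export
genotype_matrix <- function(codes, snps, patients) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  snps <- tibble::as_tibble(snps)
  patients <- as.character(patients)
  req <- c("snp_id", "chrom", "pos", "allele_minor", "allele_major")
  if (!all(req %in% names(snps))) {
    stop_curescan(paste0("snp metadata must have columns: ",
                         paste(req, collapse = ", ")), "curescan_bad_input")
  }
  if (nrow(codes) != nrow(snps) || ncol(codes) != length(patients)) {
    stop_curescan("codes dimensions do not match snps x patients",
                  "curescan_dim_mismatch")
  }
  if (anyDuplicated(snps$snp_id)) {
    stop_curescan("duplicated snp_id in metadata", "curescan_bad_input")
  }
  bad <- !is.na(codes) & !(codes %in% 0:2)
  if (any(bad)) {
    stop_curescan(sprintf("non-{0,1,2,NA} genotype code at SNP '%s'",
                          snps$snp_id[which(bad, arr.ind = TRUE)[1, 1]]),
                  "curescan_bad_code")
  }
  if (any(snps$allele_minor == snps$allele_major)) {
    stop_curescan("allele_minor equals allele_major for some SNP",
                  "curescan_bad_input")
  }
  dimnames(codes) <- list(snps$snp_id, patients)
  structure(list(codes = codes, snps = snps, patients = patients),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d SNPs x %d patients (%.1f%% missing)\n",
              nrow(x$codes), ncol(x$codes),
              100 * mean(is.na(x$codes))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$codes)

#' @describeIn genotype_matrix long-format tibble
#'   (`snp_id`, `patient_id`, `code`).
#' @param x A `genotype_matrix`.
#' @param ... Unused.
#' @export
as_tibble.genotype_matrix <- function(x, ...) {
  tibble::tibble(
    snp_id = rep(rownames(x$codes), times = ncol(x$codes)),
    patient_id = rep(colnames(x$codes), each = nrow(x$codes)),
    code = as.integer(x$codes)
  )
}

# orient codes so they count the minor allele in this sample; flips rows
# whose counted-allele frequency exceeds 0.5 and swaps the allele labels
orient_to_minor <- function(codes, snps) {
  freq <- rowMeans(codes, na.rm = TRUE) / 2
  flip <- !is.na(freq) & freq > 0.5
  if (any(flip)) {
    codes[flip, ] <- 2L - codes[flip, , drop = FALSE]
    tmp <- snps$allele_minor[flip]
    snps$allele_minor[flip] <- snps$allele_major[flip]
    snps$allele_major[flip] <- tmp
  }
  list(codes = codes, snps = snps)
}

#' Read genotypes from PLINK bed/bim/fam or a wide TSV
#'
#' Two dialects are supported. `"tsv"` is a wide table whose first five
#' columns are `snp_id`, `chrom`, `pos`, `a1`, `a2`, followed by one
#' column per patient; cells count copies of the `a1` allele (0, 1, 2 or
#' `NA`). `"plink"` is the binary PLINK 1 triplet (`.bed` SNP-major with
#' its `.bim`/`.fam` companions); codes count the A1 allele. In either
#' case, if the counted allele is not the minor allele in this sample the
#' codes are flipped (`2 - x`) and the allele labels swapped, so the
#' returned matrix always holds minor-allele counts.
#'
#' @param path For `"tsv"`, the TSV file; for `"plink"`, the `.bed` file
#'   or the common prefix of the triplet.
#' @param format `"auto"` (by extension), `"tsv"` or `"plink"`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "tsv", "plink")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path) || file.exists(paste0(path, ".bed")))
      "plink" else "tsv"
  }
  if (format == "tsv") read_genotypes_tsv(path) else read_genotypes_plink(path)
}

read_genotypes_tsv <- function(path) {
  if (!file.exists(path)) stop_curescan(paste0("no such file: ", path),
                                        "curescan_io")
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  meta_cols <- c("snp_id", "chrom", "pos", "a1", "a2")
  if (ncol(tab) < 6L || !identical(names(tab)[1:5], meta_cols)) {
    stop_curescan("wide TSV must start with columns snp_id, chrom, pos, a1, a2",
                  "curescan_io")
  }
  patients <- names(tab)[-(1:5)]
  raw <- as.matrix(tab[, -(1:5), drop = FALSE])
  raw[raw %in% c("NA", "")] <- NA
  bad <- !is.na(raw) & !(raw %in% c("0", "1", "2"))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop_curescan(sprintf("unparseable genotype code '%s' at SNP '%s', patient '%s'",
                          raw[bad][1], tab$snp_id[idx[1]], patients[idx[2]]),
                  "curescan_bad_code")
  }
  codes <- matrix(as.integer(raw), nrow = nrow(tab))
  if (any(nchar(tab$a1) != 1L | nchar(tab$a2) != 1L)) {
    i <- which(nchar(tab$a1) != 1L | nchar(tab$a2) != 1L)[1]
    stop_curescan(sprintf("non-biallelic record at SNP '%s'", tab$snp_id[i]),
                  "curescan_bad_input")
  }
  snps <- tibble::tibble(snp_id = tab$snp_id, chrom = tab$chrom,
                         pos = as.integer(tab$pos),
                         allele_minor = tab$a1, allele_major = tab$a2)
  o <- orient_to_minor(codes, snps)
  genotype_matrix(o$codes, o$snps, patients)
}

read_genotypes_plink <- function(path) {
  prefix <- sub("\\.bed$", "", path)
  bed <- paste0(prefix, ".bed"); bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) {
    if (!file.exists(f)) stop_curescan(paste0("missing PLINK file: ", f),
                                       "curescan_io")
  }
  bim_tab <- utils::read.table(bim, header = FALSE, colClasses = "character")
  if (ncol(bim_tab) != 6L) stop_curescan("malformed .bim file", "curescan_io")
  names(bim_tab) <- c("chrom", "snp_id", "cm", "pos", "a1", "a2")
  fam_tab <- utils::read.table(fam, header = FALSE, colClasses = "character")
  patients <- fam_tab[[2]]
  n <- length(patients); m <- nrow(bim_tab)
  raw <- readBin(bed, what = "raw", n = file.size(bed))
  if (length(raw) < 3L ||
      !identical(as.integer(raw[1:3]), c(0x6cL, 0x1bL, 0x01L))) {
    stop_curescan("not a SNP-major PLINK .bed file (bad magic bytes)",
                  "curescan_io")
  }
  bps <- ceiling(n / 4)  # bytes per SNP
  if (length(raw) - 3L != bps * m) {
    stop_curescan(sprintf(".bed size inconsistent with %d SNPs x %d samples",
                          m, n), "curescan_dim_mismatch")
  }
  # decode lookup: byte value -> 4 two-bit genotypes; PLINK coding
  # 00=2 copies of A1, 10=1 copy, 11=0 copies, 01=missing
  lut <- sapply(0:255, function(b) {
    g <- integer(4)
    for (k in 0:3) {
      two <- bitwAnd(bitwShiftR(b, 2L * k), 3L)
      g[k + 1] <- c(2L, NA_integer_, 1L, 0L)[two + 1L]
    }
    g
  })  # 4 x 256
  body <- as.integer(raw[-(1:3)])
  geno <- lut[, body + 1L]                       # 4 x (bps*m)
  dim(geno) <- c(4L * bps, m)
  codes <- t(geno[seq_len(n), , drop = FALSE])   # m x n
  snps <- tibble::tibble(snp_id = bim_tab$snp_id, chrom = bim_tab$chrom,
                         pos = as.integer(bim_tab$pos),
                         allele_minor = bim_tab$a1, allele_major = bim_tab$a2)
  if (any(nchar(snps$allele_minor) != 1L | nchar(snps$allele_major) != 1L)) {
    i <- which(nchar(snps$allele_minor) != 1L |
                 nchar(snps$allele_major) != 1L)[1]
    stop_curescan(sprintf("non-biallelic record at SNP '%s'", snps$snp_id[i]),
                  "curescan_bad_input")
  }
  o <- orient_to_minor(codes, snps)
  genotype_matrix(o$codes, o$snps, patients)
}

#' Write genotypes to a wide TSV or PLINK bed/bim/fam
#'
#' Inverse of [read_genotypes()] for both dialects. Codes are written as
#' counts of `allele_minor` (A1 in the PLINK triplet).
#'
#' @param gm A [genotype_matrix()].
#' @param path Output TSV path, or PLINK prefix (no extension) for
#'   `format = "plink"`.
#' @param format `"tsv"` or `"plink"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path, format = c("tsv", "plink")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- data.frame(snp_id = gm$snps$snp_id, chrom = gm$snps$chrom,
                      pos = gm$snps$pos, a1 = gm$snps$allele_minor,
                      a2 = gm$snps$allele_major, check.names = FALSE)
    tab <- cbind(tab, as.data.frame(gm$codes, check.names = FALSE))
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  n <- length(gm$patients); m <- nrow(gm$codes)
  writeLines(paste(gm$snps$chrom, gm$snps$snp_id, 0, gm$snps$pos,
                   gm$snps$allele_minor, gm$snps$allele_major, sep = "\t"),
             paste0(path, ".bim"))
  writeLines(paste(gm$patients, gm$patients, 0, 0, 0, -9, sep = "\t"),
             paste0(path, ".fam"))
  bps <- ceiling(n / 4)
  con <- file(paste0(path, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  # code -> two-bit field: 2->00, 1->10, 0->11, NA->01
  two_bits <- function(x) {
    out <- integer(length(x))
    out[is.na(x)] <- 1L
    out[!is.na(x) & x == 1L] <- 2L
    out[!is.na(x) & x == 0L] <- 3L
    out  # x == 2 stays 0
  }
  for (i in seq_len(m)) {
    g <- two_bits(gm$codes[i, ])
    length(g) <- 4L * bps          # pad with 0 (= code 2) then mask below
    g[is.na(g)] <- 0L
    gm4 <- matrix(g, nrow = 4L)
    bytes <- gm4[1, ] + bitwShiftL(gm4[2, ], 2L) +
      bitwShiftL(gm4[3, ], 4L) + bitwShiftL(gm4[4, ], 6L)
    writeBin(as.raw(bytes), con)
  }
  invisible(path)
}
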