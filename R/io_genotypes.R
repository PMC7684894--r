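#' Read genotypes from standard formats
#'
#' Supported formats: VCF 4.x (`GT` field, diploid, biallelic records),
#' PLINK binary (`.bed`/`.bim`/`.fam`, pass the path with or without the
#' `.bed` extension), and a plain whitespace-delimited dosage matrix with a
#' header row of sample identifiers (optionally preceded by the variant
#' metadata columns `id chrom pos ref alt`, one variant per row).
#'
#' Dosages are counts of the alternate allele; missing genotypes become
#' `NA`; variant order is preserved. For PLINK files the A1 allele of the
#' `.bim` file is taken as the counted (alt) allele.
#'
#' @param path input file path.
#' @param format one of `"vcf"`, `"plink_bed"`, `"matrix"`.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("vcf", "plink_bed", "matrix")) {
  format <- match.arg(format)
  switch(format,
         vcf = read_vcf_genotypes(path),
         plink_bed = read_plink(path),
         matrix = read_matrix_genotypes(path))
}

read_vcf_genotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("malformed VCF '", path, "': ",
                                         conditionMessage(e)))
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("VCF '", path, "' contains no variant records")
  multi <- grepl(",", fix$ALT %||% "")
  if (any(multi))
    stop("multi-allelic record not supported (record ", which(multi)[1L],
         ", id ", fix$ID[which(multi)[1L]], ")")
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("VCF '", path, "' has no GT field")
  dos <- apply(gt, c(1, 2), decode_gt)
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  variants <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                         id = ids, ref = fix$REF, alt = fix$ALT,
                         stringsAsFactors = FALSE)
  genotype_matrix(t(dos), samples = colnames(gt), variants = variants)
}

# "0/1", "0|1", "./." -> alt-allele count; anything non-diploid is an error.
decode_gt <- function(x) {
  if (is.na(x) || x %in% c("./.", ".|.", ".")) return(NA_real_)
  al <- strsplit(x, "[/|]")[[1L]]
  if (length(al) != 2L)
    stop("non-diploid genotype '", x, "' is not supported")
  if (any(al == ".")) return(NA_real_)
  a <- suppressWarnings(as.integer(al))
  if (anyNA(a) || any(a > 1L))
    stop("genotype '", x, "' is not biallelic diploid")
  sum(a)
}

#' Write genotypes to a minimal VCF 4.2 text file
#'
#' @param g a [genotype_matrix()].
#' @param path output path (plain text).
#' @export
write_vcf_genotypes <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=mlrgwas",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", g$samples), collapse = "\t")), con)
  code <- c("0/0", "0/1", "1/1")
  for (j in seq_len(nrow(g$variants))) {
    d <- g$dosages[, j]
    gt <- ifelse(is.na(d), "./.", code[d + 1L])
    writeLines(paste(c(g$variants$chrom[j], g$variants$pos[j], g$variants$id[j],
                       g$variants$ref[j], g$variants$alt[j], ".", "PASS", ".",
                       "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Write / read the plain dosage-matrix format
#'
#' One variant per row; header row holds the variant metadata column names
#' followed by the sample identifiers; missing dosages written as `NA`.
#'
#' @param g a [genotype_matrix()].
#' @param path file path.
#' @export
write_matrix_genotypes <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  tab <- cbind(g$variants[, c("id", "chrom", "pos", "ref", "alt")],
               as.data.frame(t(g$dosages)))
  names(tab) <- c("id", "chrom", "pos", "ref", "alt", g$samples)
  write.table(tab, path, quote = FALSE, sep = " ", row.names = FALSE)
  invisible(path)
}

read_matrix_genotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- tryCatch(read.table(path, header = TRUE, check.names = FALSE,
                             stringsAsFactors = FALSE),
                  error = function(e) stop("malformed dosage matrix '", path,
                                           "': ", conditionMessage(e)))
  meta_cols <- c("id", "chrom", "pos", "ref", "alt")
  if (all(meta_cols %in% names(tab)[1:5])) {
    variants <- tab[, meta_cols]
    dos <- as.matrix(tab[, -(1:5), drop = FALSE])
  } else {
    variants <- NULL
    dos <- as.matrix(tab)
  }
  if (!is.numeric(dos))
    stop("malformed dosage matrix '", path, "': non-numeric dosage entries")
  g <- t(dos)
  rownames(g) <- colnames(dos)
  genotype_matrix(g, samples = colnames(dos), variants = variants)
}

# ---- PLINK .bed/.bim/.fam ---------------------------------------------------

plink_prefix <- function(path) sub("\\.bed$", "", path)

#' Write genotypes as a PLINK binary fileset
#'
#' Writes `.bed` (variant-major), `.bim` and `.fam`. The counted (alt)
#' allele is written as A1.
#'
#' @param g a [genotype_matrix()].
#' @param prefix path prefix (without extension).
#' @export
write_plink <- function(g, prefix) {
  stopifnot(inherits(g, "genotype_matrix"))
  prefix <- plink_prefix(prefix)
  n <- length(g$samples)
  write.table(data.frame(g$variants$chrom, g$variants$id, 0, g$variants$pos,
                         g$variants$alt, g$variants$ref),
              paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  write.table(data.frame(g$samples, g$samples, 0, 0, 0, -9),
              paste0(prefix, ".fam"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  # 2-bit codes, variant-major: 00 = hom A1 (dosage 2), 10 = het,
  # 11 = hom A2 (dosage 0), 01 = missing; 4 samples per byte, LSB first.
  code <- function(d) {
    if (is.na(d)) return(1L)
    c(3L, 2L, 0L)[d + 1L]
  }
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  nb <- ceiling(n / 4)
  for (j in seq_len(nrow(g$variants))) {
    codes <- vapply(g$dosages[, j], code, integer(1))
    codes <- c(codes, rep(0L, 4 * nb - n))
    byte <- codes[seq(1, length(codes), 4)] +
      4L * codes[seq(2, length(codes), 4)] +
      16L * codes[seq(3, length(codes), 4)] +
      64L * codes[seq(4, length(codes), 4)]
    writeBin(as.raw(byte), con)
  }
  invisible(prefix)
}

read_plink <- function(path) {
  prefix <- plink_prefix(path)
  bed <- paste0(prefix, ".bed")
  for (f in paste0(prefix, c(".bed", ".bim", ".fam")))
    if (!file.exists(f)) stop("file not found: ", f)
  bim <- read.table(paste0(prefix, ".bim"), header = FALSE,
                    stringsAsFactors = FALSE,
                    col.names = c("chrom", "id", "cm", "pos", "a1", "a2"))
  fam <- read.table(paste0(prefix, ".fam"), header = FALSE,
                    stringsAsFactors = FALSE)
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(bed, what = "raw", n = file.size(bed))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("malformed .bed file '", bed, "': bad magic bytes")
  if (raw[3] != as.raw(0x01))
    stop("sample-major .bed files are not supported")
  nb <- ceiling(n / 4)
  if (length(raw) != 3 + nb * m)
    stop("malformed .bed file '", bed, "': expected ", 3 + nb * m,
         " bytes, found ", length(raw))
  body <- as.integer(raw[-(1:3)])
  # unpack the four 2-bit fields of every byte
  codes <- rbind(body %% 4L, (body %/% 4L) %% 4L,
                 (body %/% 16L) %% 4L, (body %/% 64L) %% 4L)
  lookup <- c(2, NA, 1, 0) # code 0,1,2,3 -> dosage of A1
  dos <- matrix(NA_real_, n, m)
  for (j in seq_len(m)) {
    cj <- codes[, ((j - 1) * nb + 1):(j * nb)]
    dos[, j] <- lookup[cj[seq_len(n)] + 1L]
  }
  variants <- data.frame(chrom = as.character(bim$chrom), pos = bim$pos,
                         id = bim$id, ref = bim$a2, alt = bim$a1,
                         stringsAsFactors = FALSE)
  genotype_matrix(dos, samples = as.character(fam[[2]]), variants = variants)
}

#' Read a phenotype/covariate table
#'
#' Delimited text with a header; the first column is the sample identifier.
#'
#' @param path file path.
#' @return a data frame, sample IDs in the first column (character).
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  tab[[1]] <- as.character(tab[[1]])
  tab
}
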