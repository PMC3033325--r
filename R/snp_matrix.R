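#' SNP matrix container
#'
#' Builds a validated individuals-by-markers matrix of discrete SNP codes.
#' Unphased genotypes are coded 0/1/2 (minor-allele dosage), phased haplotypes
#' 0/1 (one row per haplotype). The missing sentinel `-1` is tolerated on
#' construction and must be removed by [impute_missing()] before model
#' learning.
#'
#' @param values integer matrix, individuals in rows, markers in columns.
#' @param coding `"genotype_012"` or `"haplotype_01"`.
#' @param marker_names optional character vector of unique marker names;
#'   defaults to existing column names or `SNP1..SNPp`.
#' @param positions optional non-decreasing integer base-pair positions
#'   (1-based).
#' @param chromosome optional chromosome label.
#' @return An object of class `snp_matrix`: the integer matrix with coding and
#'   marker metadata attached as attributes.
#' @examples
#' x <- snp_matrix(matrix(c(0L, 1L, 2L, 0L, 1L, 1L), nrow = 3),
#'                 coding = "genotype_012")
#' dim(x)
#' @export
snp_matrix <- function(values, coding = c("genotype_012", "haplotype_01"),
                       marker_names = NULL, positions = NULL,
                       chromosome = NULL) {
  coding <- match.arg(coding)
  if (!is.matrix(values)) values <- as.matrix(values)
  if (nrow(values) == 0L || ncol(values) == 0L) {
    abort("SNP matrix must have at least one individual and one marker")
  }
  storage.mode(values) <- "integer"
  dom <- snp_domain(coding)
  bad <- which(!(values %in% c(-1L, dom)))
  if (length(bad)) {
    i <- ((bad[1] - 1L) %% nrow(values)) + 1L
    j <- ((bad[1] - 1L) %/% nrow(values)) + 1L
    abort(sprintf(
      "value %s at row %d, column %d outside domain {%s} for coding '%s'",
      values[bad[1]], i, j, paste(dom, collapse = ","), coding
    ))
  }
  if (is.null(marker_names)) {
    marker_names <- colnames(values)
    if (is.null(marker_names)) marker_names <- paste0("SNP", seq_len(ncol(values)))
  }
  if (length(marker_names) != ncol(values) || anyDuplicated(marker_names)) {
    abort("marker_names must be unique and match the number of columns")
  }
  if (!is.null(positions)) {
    positions <- as.integer(positions)
    if (length(positions) != ncol(values) || any(positions < 1L) ||
        is.unsorted(positions)) {
      abort("positions must be 1-based, non-decreasing, one per marker")
    }
  }
  colnames(values) <- marker_names
  structure(values,
    coding = coding, positions = positions, chromosome = chromosome,
    class = c("snp_matrix", "matrix", "array")
  )
}

snp_domain <- function(coding) {
  if (coding == "genotype_012") 0:2 else 0:1
}

#' @export
print.snp_matrix <- function(x, ...) {
  cat(sprintf(
    "<snp_matrix> %d individuals x %d markers, coding %s%s\n",
    nrow(x), ncol(x), attr(x, "coding"),
    if (anyNA(x) || any(x == -1L)) sprintf(" (%d missing cells)", sum(x == -1L)) else ""
  ))
  invisible(x)
}

#' @export
`[.snp_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) {
    pos <- attr(x, "positions")
    if (!is.null(pos) && !missing(j)) pos <- pos[j]
    snp_matrix(out,
      coding = attr(x, "coding"), marker_names = colnames(out),
      positions = pos, chromosome = attr(x, "chromosome")
    )
  } else {
    out
  }
}

#' @method as_tibble snp_matrix
#' @export
as_tibble.snp_matrix <- function(x, ...) {
  tibble::as_tibble(unclass(x), .name_repair = "minimal")
}

#' Impute missing SNP codes to the per-marker mode
#'
#' Replaces every `-1` cell with the most frequent observed code of its marker
#' (ties broken toward the smaller code) and reports how many cells were
#' filled. Downstream estimators assume complete categorical data.
#'
#' @param x an [snp_matrix()].
#' @return The completed `snp_matrix`.
#' @export
impute_missing <- function(x) {
  stopifnot(inherits(x, "snp_matrix"))
  n_missing <- sum(x == -1L)
  if (n_missing > 0L) {
    for (j in seq_len(ncol(x))) {
      miss <- x[, j] == -1L
      if (any(miss)) x[miss, j] <- int_mode(unclass(x)[, j])
    }
    inform(sprintf("imputed %d missing cells to per-marker modes", n_missing))
  }
  x
}

#' Read a SNP matrix from a tab-separated file
#'
#' Expects a header row of marker names and one row of integer codes per
#' individual. `-1` marks a missing value.
#'
#' @param path file path.
#' @param coding `"genotype_012"` or `"haplotype_01"`.
#' @return An [snp_matrix()].
#' @export
read_snp_matrix <- function(path, coding = c("genotype_012", "haplotype_01")) {
  coding <- match.arg(coding)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- read.delim(path, header = TRUE, check.names = FALSE,
                   colClasses = "character")
  if (nrow(df) == 0L || ncol(df) == 0L) abort("empty SNP matrix file")
  vals <- suppressWarnings(matrix(as.integer(as.matrix(df)),
                                  nrow = nrow(df), ncol = ncol(df)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1]
    i <- ((bad - 1L) %% nrow(vals)) + 1L
    j <- ((bad - 1L) %/% nrow(vals)) + 1L
    abort(sprintf(
      "malformed cell '%s' at data row %d, column '%s' in %s",
      as.matrix(df)[i, j], i, colnames(df)[j], path
    ))
  }
  dom <- snp_domain(coding)
  out_dom <- which(!(vals %in% c(-1L, dom)))
  if (length(out_dom)) {
    bad <- out_dom[1]
    i <- ((bad - 1L) %% nrow(vals)) + 1L
    j <- ((bad - 1L) %/% nrow(vals)) + 1L
    abort(sprintf(
      "value %s at data row %d, column '%s' outside domain {%s}",
      vals[bad], i, colnames(df)[j], paste(dom, collapse = ",")
    ))
  }
  snp_matrix(vals, coding = coding, marker_names = colnames(df))
}

#' Write a SNP matrix to a tab-separated file
#'
#' @param x an [snp_matrix()].
#' @param path output path.
#' @export
write_snp_matrix <- function(x, path) {
  stopifnot(inherits(x, "snp_matrix"))
  write.table(unclass(x), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read marker metadata (name, chromosome, position)
#'
#' Sidecar TSV with columns `name`, `chromosome`, `position` (1-based bp).
#'
#' @param path file path.
#' @return A tibble with one row per marker.
#' @export
read_marker_metadata <- function(path) {
  df <- read.delim(path, header = TRUE, check.names = FALSE)
  need <- c("name", "chromosome", "position")
  if (!all(need %in% colnames(df))) {
    abort("marker metadata needs columns name, chromosome, position")
  }
  if (any(df$position < 1L)) abort("positions must be >= 1")
  tibble::as_tibble(df[need])
}

#' Extract a SNP matrix from a VCF file
#'
#' Reads GT fields from biallelic sites. With `phased = FALSE` each site
#' becomes a 0/1/2 dosage per individual; with `phased = TRUE` every
#' individual contributes two haplotype rows in 0/1 and all genotypes must be
#' phased (`|` separator). Non-biallelic sites are skipped and counted.
#'
#' @param path VCF path (plain or bgzipped).
#' @param phased logical.
#' @return An [snp_matrix()]; the number of skipped sites is attached as
#'   attribute `n_skipped`.
#' @export
read_vcf_matrix <- function(path, phased = FALSE) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("package vcfR is required to read VCF files")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- v@fix[, "ALT"]
  ref <- v@fix[, "REF"]
  biallelic <- !is.na(alt) & !grepl(",", alt) & nchar(ref) >= 1L
  n_skipped <- sum(!biallelic)
  if (n_skipped > 0L) {
    inform(sprintf("skipped %d non-biallelic sites", n_skipped))
  }
  gt <- vcfR::extract.gt(v[biallelic, ], element = "GT")
  ids <- v@fix[biallelic, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(
    v@fix[biallelic, "CHROM"], ":", v@fix[biallelic, "POS"]
  )[is.na(ids) | ids == "."]
  pos <- as.integer(v@fix[biallelic, "POS"])
  chrom <- unique(v@fix[biallelic, "CHROM"])
  chrom <- if (length(chrom) == 1L) chrom else NULL
  if (phased) {
    if (any(grepl("/", gt), na.rm = TRUE)) {
      abort("unphased genotype encountered with phased = TRUE")
    }
    a1 <- suppressWarnings(as.integer(sub("\\|.*", "", gt)))
    a2 <- suppressWarnings(as.integer(sub(".*\\|", "", gt)))
    a1[is.na(a1)] <- -1L
    a2[is.na(a2)] <- -1L
    vals <- matrix(0L, nrow = 2L * ncol(gt), ncol = nrow(gt))
    vals[seq(1L, nrow(vals), by = 2L), ] <- t(a1)
    vals[seq(2L, nrow(vals), by = 2L), ] <- t(a2)
    coding <- "haplotype_01"
  } else {
    alleles <- gsub("[^01]", "", gsub("[|/]", "", gt))
    dose <- nchar(gsub("0", "", alleles))
    dose[is.na(gt) | gt %in% c(".", "./.", ".|.")] <- -1L
    vals <- t(matrix(as.integer(dose), nrow = nrow(gt)))
    coding <- "genotype_012"
  }
  ord <- order(pos)
  out <- snp_matrix(vals[, ord, drop = FALSE],
    coding = coding, marker_names = ids[ord],
    positions = pos[ord], chromosome = chrom
  )
  attr(out, "n_skipped") <- n_skipped
  out
}
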