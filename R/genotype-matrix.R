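#' Construct a genotype matrix
#'
#' Samples by ordered biallelic markers, calls coded as alt-allele dosage
#' (0, 1, 2) with `NA` for missing. Markers must be strictly increasing in
#' base-pair position within each chromosome (GRCh37-style 1-based
#' coordinates).
#'
#' @param calls numeric matrix, samples x markers, values in
#'   `{0, 1, 2, NA}`. Row names are sample ids if `sample_ids` is missing.
#' @param markers data.frame with columns `id`, `chrom`, `bp`, optional
#'   `a1`, `a2` (allele labels) and `ref_maf` (reference-population minor
#'   allele frequency in `[0, 1]`).
#' @param sample_ids character vector of sample ids.
#' @return object of class `genotype_matrix`: a list with elements `calls`,
#'   `markers`, `sample_ids`.
#' @export
genotype_matrix <- function(calls, markers, sample_ids = rownames(calls)) {
  calls <- as.matrix(calls)
  if (is.null(sample_ids)) stop("sample ids are required")
  if (nrow(calls) != length(sample_ids))
    stop("calls rows do not match sample ids")
  req <- c("id", "chrom", "bp")
  if (!all(req %in% names(markers))) stop("markers need columns id, chrom, bp")
  if (ncol(calls) != nrow(markers))
    stop("calls columns do not match marker count")
  ok <- is.na(calls) | calls %in% c(0, 1, 2)
  if (!all(ok)) stop("genotype calls must be 0, 1, 2 or NA")
  if (any(markers$bp < 1)) stop("marker bp must be >= 1")
  markers$bp <- as.integer(markers$bp)
  markers$chrom <- as.character(markers$chrom)
  for (ch in unique(markers$chrom)) {
    bp <- markers$bp[markers$chrom == ch]
    if (is.unsorted(bp, strictly = TRUE))
      stop("markers not strictly increasing in bp on chromosome ", ch)
  }
  if (!is.null(markers$ref_maf) &&
      any(!is.na(markers$ref_maf) &
          (markers$ref_maf < 0 | markers$ref_maf > 1)))
    stop("ref_maf outside [0, 1]")
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  rownames(markers) <- NULL
  dimnames(calls) <- list(as.character(sample_ids), markers$id)
  structure(list(calls = calls, markers = markers,
                 sample_ids = as.character(sample_ids)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d markers (%s)\n",
              length(x$sample_ids), nrow(x$markers),
              paste(unique(x$markers$chrom), collapse = ",")))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix
#'
#' @param gm a [genotype_matrix].
#' @param samples sample ids (or logical/integer index) to keep.
#' @param markers marker ids (or logical/integer index) to keep; order of
#'   the stored markers is preserved.
#' @return a [genotype_matrix].
#' @export
subset_genotypes <- function(gm, samples = NULL, markers = NULL) {
  si <- if (is.null(samples)) seq_along(gm$sample_ids) else
    if (is.character(samples)) match(samples, gm$sample_ids) else samples
  if (anyNA(si)) stop("unknown sample id")
  mi <- if (is.null(markers)) seq_len(nrow(gm$markers)) else
    if (is.character(markers)) match(markers, gm$markers$id) else markers
  if (anyNA(mi)) stop("unknown marker id")
  if (is.logical(mi)) mi <- which(mi)
  mi <- sort(mi)
  genotype_matrix(gm$calls[si, mi, drop = FALSE],
                  gm$markers[mi, , drop = FALSE],
                  gm$sample_ids[si])
}

#' Read / write a TSV dosage matrix
#'
#' Plain-text dialect: the first four columns are `id`, `chrom`, `bp`,
#' `ref_maf` (one row per marker, `ref_maf` may be `NA`), followed by one
#' column per sample holding dosages 0/1/2 or `NA`.
#'
#' @param path file path.
#' @return a [genotype_matrix].
#' @export
read_dosage_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  meta <- c("id", "chrom", "bp", "ref_maf")
  if (!all(meta %in% names(df)[1:4])) stop("dosage TSV lacks marker columns")
  samples <- setdiff(names(df), meta)
  calls <- t(as.matrix(df[samples]))
  genotype_matrix(calls, df[meta], samples)
}

#' @param gm a [genotype_matrix].
#' @rdname read_dosage_tsv
#' @export
write_dosage_tsv <- function(gm, path) {
  mk <- gm$markers
  if (is.null(mk$ref_maf)) mk$ref_maf <- NA_real_
  out <- cbind(mk[c("id", "chrom", "bp", "ref_maf")],
               as.data.frame(t(gm$calls), check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write PLINK text .ped/.map genotype files
#'
#' `.map` holds chrom, marker id, genetic distance, bp; `.ped` holds the six
#' FAM columns followed by two allele columns per marker (`0 0` = missing).
#' Alleles are reported as `A`/`B` with `B` the alternate (dosage-counted)
#' allele unless the markers table provides labels.
#'
#' @param prefix path prefix; `<prefix>.ped` and `<prefix>.map` are used.
#' @param ref_maf optional numeric vector of reference MAFs to attach to
#'   the markers (recycled from the `.map` file order).
#' @return `read_ped_map` returns a list with elements `genotypes`
#'   (a [genotype_matrix]) and `pedigree` (a [pedigree]).
#' @export
read_ped_map <- function(prefix, ref_maf = NULL) {
  map <- utils::read.table(paste0(prefix, ".map"), header = FALSE,
                           stringsAsFactors = FALSE)
  names(map) <- c("chrom", "id", "cm", "bp")[seq_len(ncol(map))]
  ped <- utils::read.table(paste0(prefix, ".ped"), header = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  nmark <- nrow(map)
  if (ncol(ped) != 6 + 2 * nmark)
    stop(".ped column count does not match .map marker count")
  fam <- ped[, 1:6]
  names(fam) <- c("family", "id", "father", "mother", "sex", "affection")
  a1 <- as.matrix(ped[, 6 + 2 * seq_len(nmark) - 1, drop = FALSE])
  a2 <- as.matrix(ped[, 6 + 2 * seq_len(nmark), drop = FALSE])
  # dosage of the B allele; "0" on either slot means missing
  calls <- (a1 == "B") + (a2 == "B")
  calls[a1 == "0" | a2 == "0"] <- NA
  markers <- data.frame(id = map$id, chrom = as.character(map$chrom),
                        bp = map$bp, stringsAsFactors = FALSE)
  if (!is.null(ref_maf)) markers$ref_maf <- ref_maf
  list(genotypes = genotype_matrix(calls, markers, fam$id),
       pedigree = pedigree(fam))
}

#' @param gm a [genotype_matrix].
#' @param ped a [pedigree] covering the samples of `gm`.
#' @rdname read_ped_map
#' @export
write_ped_map <- function(gm, ped, prefix) {
  mk <- gm$markers
  utils::write.table(
    data.frame(mk$chrom, mk$id, 0, mk$bp),
    paste0(prefix, ".map"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  ped <- ped[match(gm$sample_ids, ped$id), ]
  sex <- c(male = 1L, female = 2L, unknown = 0L)[ped$sex]
  aff <- c(unaffected = 1L, CD = 2L, UC = 3L, unknown = 0L)[ped$affection]
  g <- gm$calls
  n <- nrow(g)
  allele_cols <- matrix("", n, 2 * ncol(g))
  a1 <- ifelse(is.na(g), "0", ifelse(g >= 1, "B", "A"))
  a2 <- ifelse(is.na(g), "0", ifelse(g == 2, "B", "A"))
  allele_cols[, seq(1, 2 * ncol(g), by = 2)] <- a1
  allele_cols[, seq(2, 2 * ncol(g), by = 2)] <- a2
  out <- cbind(ped$family, ped$id,
               ifelse(is.na(ped$father), "0", ped$father),
               ifelse(is.na(ped$mother), "0", ped$mother),
               sex, aff, allele_cols)
  utils::write.table(out, paste0(prefix, ".ped"), sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}
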