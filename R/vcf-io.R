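#' Read exome variants from VCF plus an annotation table
#'
#' Reads a VCF (v4.x) with `GT:AD:GQ` genotype fields via `vcfR`. The
#' site-level VQSR dialect: a `FILTER` value of `PASS` sets the pass flag;
#' an `INFO` key `TRANCHE=<percent>` carries the truth-tranche sensitivity.
#' Functional annotations and population frequencies are joined from a TSV
#' keyed by `chrom`, `pos`, `ref`, `alt` with columns `gene`,
#' `consequence`, `sift`, `polyphen`, `cadd` and one `maf_<population>`
#' column per reference population (empty/NA = absent from that data set).
#'
#' @param vcf_path path to the VCF file.
#' @param ann_path optional path to the annotation TSV.
#' @return a [variant_set].
#' @export
read_vcf_variants <- function(vcf_path, ann_path = NULL) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  info <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                     id = fix$ID, ref = fix$REF, alt = fix$ALT,
                     stringsAsFactors = FALSE)
  info$pass <- !is.na(fix$FILTER) & fix$FILTER == "PASS"
  tr <- vcfR::extract.info(v, "TRANCHE", as.numeric = TRUE)
  info$tranche <- if (is.null(tr)) NA_real_ else as.numeric(tr)

  gt_raw <- vcfR::extract.gt(v, element = "GT")
  gt <- matrix(NA_real_, nrow(gt_raw), ncol(gt_raw),
               dimnames = dimnames(gt_raw))
  clean <- gsub("\\|", "/", gt_raw)
  gt[clean == "0/0"] <- 0
  gt[clean %in% c("0/1", "1/0")] <- 1
  gt[clean == "1/1"] <- 2
  gq <- vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE)
  ad <- vcfR::extract.gt(v, element = "AD")
  split_ad <- function(k) {
    out <- suppressWarnings(
      as.numeric(vapply(strsplit(ad, ","), function(x)
        if (length(x) >= k) x[k] else NA_character_, character(1))))
    matrix(out, nrow(ad), ncol(ad), dimnames = dimnames(ad))
  }
  ad_ref <- split_ad(1); ad_alt <- split_ad(2)

  if (!is.null(ann_path)) {
    ann <- utils::read.table(ann_path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, check.names = FALSE)
    key_v <- paste(info$chrom, info$pos, info$ref, info$alt)
    key_a <- paste(ann$chrom, ann$pos, ann$ref, ann$alt)
    idx <- match(key_v, key_a)
    for (col in setdiff(names(ann), c("chrom", "pos", "ref", "alt")))
      info[[col]] <- ann[[col]][idx]
  }
  variant_set(info, gt, gq, ad_ref, ad_alt)
}

#' Write a variant set as VCF
#'
#' Minimal VCF v4.2 writer with `GT:AD:GQ` genotype fields and the
#' `TRANCHE` INFO dialect consumed by [read_vcf_variants()]. Uncompressed
#' text output.
#'
#' @param vs a [variant_set].
#' @param path output path.
#' @export
write_variant_vcf <- function(vs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  samples <- colnames(vs$gt)
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=TRANCHE,Number=1,Type=Float,Description=\"VQSR truth tranche sensitivity (percent)\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")), con)
  info <- vs$info
  gt_str <- c("0/0", "0/1", "1/1")
  for (i in seq_len(nrow(info))) {
    flt <- if (isTRUE(info$pass[i])) "PASS" else "."
    inf <- if (is.na(info$tranche[i])) "."
           else sprintf("TRANCHE=%.6g", info$tranche[i])
    cells <- vapply(samples, function(s) {
      g <- vs$gt[i, s]
      gs <- if (is.na(g)) "./." else gt_str[g + 1]
      ad <- if (is.null(vs$ad_ref) || is.na(vs$ad_ref[i, s])) "."
            else sprintf("%d,%d", vs$ad_ref[i, s], vs$ad_alt[i, s])
      gq <- if (is.null(vs$gq) || is.na(vs$gq[i, s])) "."
            else as.character(vs$gq[i, s])
      paste(gs, ad, gq, sep = ":")
    }, character(1))
    id <- if (is.null(info$id) || is.na(info$id[i])) "." else info$id[i]
    writeLines(paste(c(info$chrom[i], info$pos[i], id, info$ref[i],
                       info$alt[i], ".", flt, inf, "GT:AD:GQ", cells),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Write the variant annotation TSV consumed by [read_vcf_variants()]
#'
#' @param vs a [variant_set] whose `info` carries annotation columns.
#' @param path output path.
#' @export
write_variant_annotation <- function(vs, path) {
  cols <- intersect(c("chrom", "pos", "ref", "alt", "gene", "consequence",
                      "sift", "polyphen", "cadd",
                      grep("^maf_", names(vs$info), value = TRUE)),
                    names(vs$info))
  utils::write.table(vs$info[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
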