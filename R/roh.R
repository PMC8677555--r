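#' ROH detection parameters
#'
#' Defaults mirror a stringent homozygosity-mapping setup for
#' consanguineous families: a run must span at least 1 Mb and contain at
#' least 50 homozygous markers, heterozygous calls are not tolerated inside
#' a run (silently erasing them is the classic source of false ROH in
#' low-density regions), missing calls neither break a run nor count
#' towards its marker number, and only common markers (reference MAF >
#' 0.05) are used as input.
#'
#' @param min_snps minimum number of homozygous markers in a run.
#' @param min_length_bp minimum run length, `end_bp - start_bp`.
#' @param het_tolerance number of heterozygous calls tolerated inside a run.
#' @param max_missing_run maximum number of consecutive missing calls
#'   allowed inside a run before it is split (`Inf` = unlimited).
#' @param input_maf_min markers with `ref_maf` at or below this value are
#'   excluded from the scan (when `ref_maf` is available).
#' @param require_identity for case-shared regions, require all cases to
#'   carry the same homozygous genotype at every counted marker.
#' @return list of class `roh_params`.
#' @export
roh_params <- function(min_snps = 50, min_length_bp = 1e6,
                       het_tolerance = 0, max_missing_run = Inf,
                       input_maf_min = 0.05, require_identity = TRUE) {
  if (min_snps < 1 || min_length_bp < 1) stop("invalid ROH thresholds")
  structure(list(min_snps = min_snps, min_length_bp = min_length_bp,
                 het_tolerance = het_tolerance,
                 max_missing_run = max_missing_run,
                 input_maf_min = input_maf_min,
                 require_identity = require_identity),
            class = "roh_params")
}

# drop markers at or below the common-MAF input threshold (when known)
roh_input_markers <- function(gm, p) {
  maf <- gm$markers$ref_maf
  if (is.null(maf)) return(gm)
  keep <- is.na(maf) | maf > p$input_maf_min
  if (all(keep)) gm else subset_genotypes(gm, markers = which(keep))
}

# Maximal-run scan over one chromosome.
# g: codes 0/2 homozygous, 1 heterozygous (or identity breaker), NA missing.
# Returns data.frame(start_idx, end_idx, n_markers) of maximal runs bounded
# by homozygous calls containing at most `het_tolerance` heterozygous calls
# and no gap of more than `max_missing_run` consecutive missing calls;
# thresholds are applied by the caller.
roh_scan_chrom <- function(g, p) {
  n <- length(g)
  obs <- which(!is.na(g))
  if (!length(obs)) return(NULL)
  # hard breaks where a missing gap exceeds max_missing_run
  gap <- diff(obs) - 1L
  brk <- which(gap > p$max_missing_run)
  seg_start <- obs[c(1L, brk + 1L)]
  seg_end <- obs[c(brk, length(obs))]
  out <- vector("list", length(seg_start))
  t <- p$het_tolerance
  for (s in seq_along(seg_start)) {
    lo <- seg_start[s]; hi <- seg_end[s]
    idx <- obs[obs >= lo & obs <= hi]
    hets <- idx[g[idx] == 1]
    k <- length(hets)
    bounds_l <- c(lo, hets + 1L)    # candidate left edges (after each het)
    bounds_r <- c(hets - 1L, hi)    # candidate right edges (before each het)
    if (k <= t) {
      wins <- cbind(lo, hi)
    } else {
      i <- 0:(k - t)
      wins <- cbind(bounds_l[i + 1L], bounds_r[i + t + 1L])
    }
    res <- apply(wins, 1, function(w) {
      inwin <- idx[idx >= w[1] & idx <= w[2]]
      hom <- inwin[g[inwin] != 1]
      if (!length(hom)) return(NULL)
      c(start_idx = hom[1], end_idx = hom[length(hom)],
        n_markers = length(hom))
    }, simplify = FALSE)
    out[[s]] <- do.call(rbind, res)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(NULL)
  res <- unique(as.data.frame(res))
  # trimming to homozygous boundaries can nest one candidate window inside
  # another; only maximal windows are runs
  res <- res[order(res$start_idx, -res$end_idx), , drop = FALSE]
  max_end <- cummax(c(-1L, res$end_idx))[seq_len(nrow(res))]
  res[res$end_idx > max_end, , drop = FALSE]
}

roh_regions_df <- function(chrom = character(), start_bp = integer(),
                           end_bp = integer(), n_markers = integer(),
                           members = list()) {
  out <- data.frame(chrom = chrom, start_bp = start_bp, end_bp = end_bp,
                    length_bp = end_bp - start_bp, n_markers = n_markers,
                    stringsAsFactors = FALSE)
  out$members <- members
  class(out) <- c("roh_regions", "data.frame")
  out
}

#' Detect runs of homozygosity for one sample
#'
#' Scans each chromosome for maximal runs of homozygous calls. A
#' heterozygous call terminates a run unless the number of heterozygous
#' calls already inside it is within `p$het_tolerance`; missing calls
#' neither terminate a run nor count towards its marker number (unless a
#' gap exceeds `p$max_missing_run`). Region boundaries are the first and
#' last homozygous markers of the run, the region length is
#' `end_bp - start_bp`, and runs are kept only when they contain at least
#' `p$min_snps` homozygous markers and span at least `p$min_length_bp`.
#'
#' @param gm a [genotype_matrix] with markers sorted by position.
#' @param sample sample id.
#' @param p a [roh_params].
#' @return a `roh_regions` data.frame with columns `chrom`, `start_bp`,
#'   `end_bp`, `length_bp`, `n_markers` and a list-column `members`.
#' @export
detect_roh <- function(gm, sample, p = roh_params()) {
  gm <- roh_input_markers(gm, p)
  if (!(sample %in% gm$sample_ids)) stop("unknown sample: ", sample)
  g <- gm$calls[sample, ]
  scan_regions(g, gm$markers, p, members = list(sample))
}

# shared scan -> thresholded regions across chromosomes
scan_regions <- function(g, markers, p, members) {
  parts <- list()
  for (ch in unique(markers$chrom)) {
    sel <- which(markers$chrom == ch)
    runs <- roh_scan_chrom(g[sel], p)
    if (is.null(runs) || !nrow(runs)) next
    start_bp <- markers$bp[sel[runs$start_idx]]
    end_bp <- markers$bp[sel[runs$end_idx]]
    keep <- runs$n_markers >= p$min_snps &
      (end_bp - start_bp) >= p$min_length_bp
    if (!any(keep)) next
    parts[[ch]] <- roh_regions_df(
      chrom = rep(ch, sum(keep)), start_bp = start_bp[keep],
      end_bp = end_bp[keep], n_markers = runs$n_markers[keep],
      members = rep(members, sum(keep)))
  }
  if (!length(parts)) return(roh_regions_df())
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  class(out) <- c("roh_regions", "data.frame")
  out
}

#' Case-shared identical runs of homozygosity
#'
#' Genetic-homogeneity scan: a marker contributes to a shared run only when
#' every case is homozygous for the same allele there. A heterozygous call
#' in any case, or homozygosity for opposite alleles between cases, breaks
#' the run (subject to `p$het_tolerance`); a marker missing in any case is
#' treated as missing. Length and marker-count thresholds are the same as
#' in [detect_roh()].
#'
#' @param gm a [genotype_matrix].
#' @param case_ids two or more sample ids.
#' @param p a [roh_params].
#' @return a `roh_regions` data.frame; `members` holds the case set.
#' @export
shared_identical_regions <- function(gm, case_ids, p = roh_params()) {
  if (length(case_ids) < 2) stop("need at least two cases")
  if (!all(case_ids %in% gm$sample_ids)) stop("unknown case id")
  gm <- roh_input_markers(gm, p)
  calls <- gm$calls[case_ids, , drop = FALSE]
  any_het <- colSums(calls == 1, na.rm = TRUE) > 0
  n_obs <- colSums(!is.na(calls))
  discord <- apply(calls, 2, function(x) {
    x <- x[!is.na(x)]
    length(unique(x[x != 1])) > 1
  })
  g <- rep(NA_real_, ncol(calls))
  g[any_het | discord] <- 1                    # breaker
  all_hom_same <- !any_het & !discord & n_obs == length(case_ids)
  g[all_hom_same] <- 2                         # counted homozygous marker
  scan_regions(g, gm$markers, p, members = list(case_ids))
}

#' Annotate regions with overlapping control ROH
#'
#' For each case-shared region, lists the unaffected controls that possess
#' an ROH (detected with the same parameters) overlapping it by at least
#' `overlap_frac` of the case-region length. With `exclude = TRUE`, regions
#' with any listed control are dropped, the variant of homozygosity mapping
#' that does not allow for incomplete penetrance.
#'
#' @param regions a `roh_regions` data.frame.
#' @param gm a [genotype_matrix] containing the controls.
#' @param controls control sample ids.
#' @param p a [roh_params].
#' @param overlap_frac minimum overlap as a fraction of the case region.
#' @param exclude drop regions with any control overlap.
#' @return `regions` with a `control_overlaps` list-column (and possibly
#'   fewer rows when `exclude = TRUE`).
#' @export
annotate_control_overlap <- function(regions, gm, controls,
                                     p = roh_params(), overlap_frac = 0.5,
                                     exclude = FALSE) {
  ctrl_roh <- lapply(controls, function(s) detect_roh(gm, s, p))
  names(ctrl_roh) <- controls
  regions$control_overlaps <- lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    hit <- vapply(controls, function(s) {
      cr <- ctrl_roh[[s]]
      cr <- cr[cr$chrom == r$chrom, , drop = FALSE]
      if (!nrow(cr)) return(FALSE)
      ov <- pmin(cr$end_bp, r$end_bp) - pmax(cr$start_bp, r$start_bp)
      any(ov >= overlap_frac * r$length_bp)
    }, logical(1))
    controls[hit]
  })
  if (exclude)
    regions <- regions[lengths(regions$control_overlaps) == 0, , drop = FALSE]
  regions
}

#' Fraction of the genome within runs of homozygosity
#'
#' Sum of ROH lengths divided by the covered autosomal extent (per
#' chromosome, last marker position minus first marker position).
#'
#' @param gm a [genotype_matrix] of autosomal markers.
#' @param sample sample id.
#' @param p a [roh_params].
#' @return fraction in `[0, 1]`.
#' @export
genome_roh_fraction <- function(gm, sample, p = roh_params()) {
  gm <- roh_input_markers(gm, p)
  if (nrow(gm$markers) == 0) stop("empty marker panel")
  covered <- sum(tapply(gm$markers$bp, gm$markers$chrom,
                        function(x) max(x) - min(x)))
  if (covered <= 0) stop("marker panel covers no extent")
  regions <- scan_regions(gm$calls[sample, ], gm$markers, p, list(sample))
  sum(regions$length_bp) / covered
}

#' Annotate regions with protein-coding genes
#'
#' A gene is listed when its interval intersects the region
#' `[start_bp, end_bp]` (1-based inclusive coordinates on the same build).
#'
#' @param regions a `roh_regions` data.frame.
#' @param genes data.frame with columns `symbol`, `chrom`, `start_bp`,
#'   `end_bp` (1-based inclusive), e.g. from [read_gene_bed()].
#' @return `regions` with a `genes` list-column of gene symbols.
#' @export
genes_in_regions <- function(regions, genes) {
  if (nrow(regions) == 0) { regions$genes <- list(); return(regions) }
  rr <- GenomicRanges::GRanges(regions$chrom,
          IRanges::IRanges(regions$start_bp, regions$end_bp))
  gg <- GenomicRanges::GRanges(genes$chrom,
          IRanges::IRanges(genes$start_bp, genes$end_bp))
  hits <- GenomicRanges::findOverlaps(rr, gg)
  regions$genes <- lapply(seq_len(nrow(regions)), function(i)
    genes$symbol[S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]])
  regions
}

#' Annotate regions with GWAS top SNPs
#'
#' @param regions a `roh_regions` data.frame.
#' @param top_snps data.frame with columns `id`, `chrom`, `bp`; an empty
#'   frame marks every region as containing no GWAS locus.
#' @return `regions` with a `gwas_hits` list-column of SNP ids.
#' @export
gwas_loci_in_regions <- function(regions, top_snps) {
  regions$gwas_hits <- lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    if (is.null(top_snps) || nrow(top_snps) == 0) return(character(0))
    top_snps$id[top_snps$chrom == r$chrom &
                top_snps$bp >= r$start_bp & top_snps$bp <= r$end_bp]
  })
  regions
}

#' Read gene intervals from a BED file
#'
#' BED input is 0-based half-open; intervals are converted to 1-based
#' inclusive coordinates, the convention used for all reported regions.
#'
#' @param path BED file with a name column holding the gene symbol.
#' @return data.frame with columns `symbol`, `chrom`, `start_bp`, `end_bp`.
#' @export
read_gene_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(symbol = gr$name,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start_bp = GenomicRanges::start(gr),  # already 1-based
             end_bp = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Write regions as BED
#'
#' Regions are stored 1-based inclusive and written 0-based half-open.
#'
#' @param regions a `roh_regions` data.frame.
#' @param path output path.
#' @param names optional name column.
#' @export
write_roh_bed <- function(regions, path,
                          names = paste0("roh_", seq_len(nrow(regions)))) {
  gr <- GenomicRanges::GRanges(regions$chrom,
          IRanges::IRanges(regions$start_bp, regions$end_bp), name = names)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Flat summary table of annotated regions
#'
#' One row per region with list-columns collapsed to comma-separated
#' strings (`"None"` when empty, `"No IBD GWAS loci"` for absent GWAS
#' hits), mirroring a homozygosity-mapping report table.
#'
#' @param regions a `roh_regions` data.frame.
#' @return plain data.frame suitable for `write.table`.
#' @export
roh_table <- function(regions) {
  collapse <- function(col, empty) {
    if (is.null(regions[[col]])) return(rep(empty, nrow(regions)))
    vapply(regions[[col]], function(x)
      if (length(x)) paste(x, collapse = ", ") else empty, character(1))
  }
  data.frame(chrom = regions$chrom, start_bp = regions$start_bp,
             end_bp = regions$end_bp,
             length_mb = round(regions$length_bp / 1e6, 1),
             n_markers = regions$n_markers,
             members = collapse("members", ""),
             control_overlaps = collapse("control_overlaps", "None"),
             gwas_hits = collapse("gwas_hits", "No IBD GWAS loci"),
             genes = collapse("genes", "None"),
             stringsAsFactors = FALSE)
}
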