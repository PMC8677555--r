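#' Exact 2x2 association test
#'
#' Odds ratio as the raw cross-product `(a*d)/(b*c)` and a one-sided
#' (enrichment-direction) P-value as the upper hypergeometric tail
#' `P(X >= a)` conditioned on the table margins. Zero-cell convention: no
#' continuity correction; `b*c == 0` gives `Inf` (flagged), `a*d == 0`
#' gives 0.
#'
#' @param a,b,c,d non-negative cell counts; `a` is the overlap cell whose
#'   enrichment is tested.
#' @return list of class `enrichment_result` with elements `table`,
#'   `odds_ratio`, `zero_cell`, `p_one_sided`.
#' @examples
#' exact_2x2(3, 17, 700, 18808)$odds_ratio  # 4.74
#' @export
exact_2x2 <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0)) stop("negative counts")
  if (sum(counts) == 0) stop("all-zero table")
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * c)
  p <- stats::phyper(a - 1, m = a + c, n = b + d, k = a + b,
                     lower.tail = FALSE)
  structure(list(table = counts, odds_ratio = or,
                 zero_cell = (b * c == 0) || (a * d == 0),
                 p_one_sided = p),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("2x2 exact test: OR %.3g, one-sided P %.3g (a=%d b=%d c=%d d=%d)\n",
              x$odds_ratio, x$p_one_sided, x$table["a"], x$table["b"],
              x$table["c"], x$table["d"]))
  invisible(x)
}

#' Gene-set enrichment of ROH gene content
#'
#' Tests whether a gene list is over-represented among the genes contained
#' in case-shared ROH: `a` = list genes inside ROH, `b` = list genes
#' outside, `c` = other ROH genes, `d` = remainder of the genome universe.
#'
#' @param roh_genes character vector of genes contained in the ROH.
#' @param list_genes character vector, the gene list of interest.
#' @param genome_gene_total size of the protein-coding gene universe.
#' @return an `enrichment_result` (see [exact_2x2()]).
#' @export
roh_gene_enrichment <- function(roh_genes, list_genes, genome_gene_total) {
  roh_genes <- unique(roh_genes); list_genes <- unique(list_genes)
  if (genome_gene_total < length(union(roh_genes, list_genes)))
    stop("gene universe smaller than observed gene sets")
  a <- length(intersect(roh_genes, list_genes))
  b <- length(setdiff(list_genes, roh_genes))
  c_ <- length(setdiff(roh_genes, list_genes))
  d <- genome_gene_total - a - b - c_
  exact_2x2(a, b, c_, d)
}

#' Homozygous variant burden per sibling
#'
#' Counts homozygous-alternate variants per sibling within frequency /
#' damaging strata. Burden comparisons are restricted to full siblings
#' because siblings are expected to share an equal fraction of their
#' genome in the homozygous state; the sibship is verified against the
#' pedigree.
#'
#' @param vs a [variant_set].
#' @param sib_ids ids of two or more full siblings.
#' @param ped a [pedigree].
#' @param populations populations for the frequency classes.
#' @param t a [filter_thresholds].
#' @return data.frame with one row per sibling and columns `any`,
#'   `uncommon` (uncommon or rarer), `rare` (rare or rarer),
#'   `rare_damaging`.
#' @export
sibling_homozygous_burden <- function(vs, sib_ids, ped, populations,
                                      t = filter_thresholds()) {
  pa <- ped[sib_ids, "father"]; ma <- ped[sib_ids, "mother"]
  if (anyNA(pa) || length(unique(pa)) != 1 || length(unique(ma)) != 1)
    stop("ids are not full siblings")
  cls <- frequency_class(vs, populations, t)
  dmg <- is_damaging(vs, t)
  counts <- t(vapply(sib_ids, function(s) {
    hom <- !is.na(vs$gt[, s]) & vs$gt[, s] == 2
    c(any = sum(hom),
      uncommon = sum(hom & cls <= "uncommon"),
      rare = sum(hom & cls <= "rare"),
      rare_damaging = sum(hom & cls <= "rare" & dmg))
  }, numeric(4)))
  data.frame(sibling = sib_ids, counts, row.names = NULL,
             stringsAsFactors = FALSE)
}
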