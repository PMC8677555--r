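#' Array QC thresholds
#'
#' Defaults follow common practice for family SNP-array QC: samples dropped
#' if missing more than 5% of SNPs, markers dropped if missing in more than
#' 5% of samples or deviating from Hardy-Weinberg equilibrium at
#' P < 5e-8, and "common" defined as MAF > 0.05.
#'
#' @param max_sample_missing maximum tolerated per-sample missing fraction.
#' @param max_marker_missing maximum tolerated per-marker missing fraction.
#' @param hwe_alpha HWE exact-test significance level for marker removal.
#' @param common_maf MAF above which a variant counts as common.
#' @return list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(max_sample_missing = 0.05,
                          max_marker_missing = 0.05,
                          hwe_alpha = 5e-8,
                          common_maf = 0.05) {
  vals <- c(max_sample_missing, max_marker_missing, hwe_alpha, common_maf)
  if (any(vals <= 0 | vals >= 1)) stop("thresholds must be in (0, 1)")
  structure(list(max_sample_missing = max_sample_missing,
                 max_marker_missing = max_marker_missing,
                 hwe_alpha = hwe_alpha, common_maf = common_maf),
            class = "qc_thresholds")
}

#' Remove samples by genotype missingness
#'
#' Applied before any marker filter: a sample is removed when its fraction
#' of missing calls exceeds `t$max_sample_missing`.
#'
#' @param gm a [genotype_matrix].
#' @param t a [qc_thresholds].
#' @return list with elements `genotypes` (filtered matrix) and `removed`
#'   (ids of dropped samples).
#' @export
filter_samples_by_missingness <- function(gm, t = qc_thresholds()) {
  if (length(gm$sample_ids) == 0 || nrow(gm$markers) == 0)
    stop("empty genotype matrix")
  frac <- rowMeans(is.na(gm$calls))
  drop <- frac > t$max_sample_missing
  if (all(drop)) stop("all samples removed by missingness filter")
  list(genotypes = subset_genotypes(gm, samples = which(!drop)),
       removed = gm$sample_ids[drop])
}

#' Hardy-Weinberg exact test
#'
#' Exact conditional test on the heterozygote count: given the observed
#' allele counts, every possible heterozygote count has a conditional
#' probability under Hardy-Weinberg equilibrium; the two-sided P-value is
#' the sum of the probabilities of all configurations no more probable than
#' the observed one (probability-mass ordering).
#'
#' @param n_AA,n_Aa,n_aa genotype counts (reference homozygote,
#'   heterozygote, alternate homozygote).
#' @return the exact two-sided P-value.
#' @examples
#' hwe_exact_test(10, 0, 0)  # monomorphic: 1
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("negative genotype counts")
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("no genotypes")
  m <- 2 * min(n_AA, n_aa) + n_Aa       # minor allele count
  hets <- seq(m %% 2, min(m, 2 * n - m), by = 2)
  # log P(h hets | n, m) = log [ n! / (h! nr! nc!) * 2^h ] - log C(2n, m)
  lp <- lgamma(n + 1) - lgamma(hets + 1) - lgamma((m - hets) / 2 + 1) -
    lgamma(n - (m + hets) / 2 + 1) + hets * log(2) -
    (lgamma(2 * n + 1) - lgamma(m + 1) - lgamma(2 * n - m + 1))
  p <- exp(lp - max(lp)); p <- p / sum(p)
  p_obs <- p[hets == n_Aa]
  min(1, sum(p[p <= p_obs * (1 + 1e-9)]))
}

# per-marker genotype counts -> HWE P-values for a call matrix
hwe_pvalues <- function(calls) {
  apply(calls, 2, function(g) {
    g <- g[!is.na(g)]
    if (!length(g)) return(NA_real_)
    hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2))
  })
}

#' Remove markers by missingness, HWE deviation, and duplicate ids
#'
#' Applied after the sample filter. Markers are removed when missing in more
#' than `t$max_marker_missing` of samples or when the HWE exact test
#' ([hwe_exact_test()]) rejects at `t$hwe_alpha`. Markers whose id
#' duplicates an earlier marker are dropped, keeping the first occurrence.
#'
#' @param gm a [genotype_matrix] (sample filter already applied).
#' @param t a [qc_thresholds].
#' @param ped optional [pedigree]; with `hwe_samples = "founders"` the HWE
#'   test is computed on founder samples only.
#' @param hwe_samples `"all"` (default, one-shot array QC) or `"founders"`.
#' @return list with elements `genotypes` and `removed` (data.frame of
#'   marker id and reason).
#' @export
filter_markers <- function(gm, t = qc_thresholds(), ped = NULL,
                           hwe_samples = c("all", "founders")) {
  hwe_samples <- match.arg(hwe_samples)
  dup <- duplicated(gm$markers$id)
  frac <- colMeans(is.na(gm$calls))
  hwe_calls <- gm$calls
  if (hwe_samples == "founders") {
    if (is.null(ped)) stop("hwe_samples=\"founders\" requires a pedigree")
    keep <- gm$sample_ids %in% ped$id[is_founder(ped)]
    hwe_calls <- gm$calls[keep, , drop = FALSE]
  }
  hwe_p <- hwe_pvalues(hwe_calls)
  drop_miss <- frac > t$max_marker_missing
  drop_hwe <- !is.na(hwe_p) & hwe_p < t$hwe_alpha
  drop <- dup | drop_miss | drop_hwe
  reason <- ifelse(dup, "duplicate_id",
            ifelse(drop_miss, "missingness",
            ifelse(drop_hwe, "hwe", NA)))
  removed <- data.frame(id = gm$markers$id[drop], reason = reason[drop],
                        stringsAsFactors = FALSE)
  list(genotypes = subset_genotypes(gm, markers = which(!drop)),
       removed = removed)
}

#' Infer sample sex from X-chromosome homozygosity
#'
#' Uses the homozygosity rate of common markers on the X chromosome
#' (pseudoautosomal regions excluded by the caller): males are expected to
#' appear homozygous at essentially every X marker. A sample is called male
#' when the rate is at least `male_min`, female when at most `female_max`,
#' and ambiguous in between.
#'
#' @param gm_x a [genotype_matrix] restricted to non-PAR X markers with
#'   `ref_maf` above the common-MAF threshold.
#' @param t a [qc_thresholds] (used to validate the marker MAFs if present).
#' @param male_min,female_max homozygosity-rate cutoffs.
#' @return data.frame with columns `sample_id`, `x_homozygosity_rate`,
#'   `inferred_sex`.
#' @export
infer_sex <- function(gm_x, t = qc_thresholds(),
                      male_min = 0.9, female_max = 0.8) {
  if (nrow(gm_x$markers) == 0) stop("no qualifying X markers")
  if (!is.null(gm_x$markers$ref_maf) &&
      any(gm_x$markers$ref_maf <= t$common_maf, na.rm = TRUE))
    stop("infer_sex expects common markers (ref_maf > common_maf) only")
  rate <- apply(gm_x$calls, 1, function(g) {
    g <- g[!is.na(g)]
    if (!length(g)) return(NA_real_)
    mean(g != 1)
  })
  sex <- ifelse(is.na(rate), "ambiguous",
         ifelse(rate >= male_min, "male",
         ifelse(rate <= female_max, "female", "ambiguous")))
  data.frame(sample_id = gm_x$sample_ids, x_homozygosity_rate = rate,
             inferred_sex = sex, row.names = NULL, stringsAsFactors = FALSE)
}

#' Robust pairwise kinship estimate from genotypes
#'
#' Within-family robust estimator based on shared heterozygosity and
#' opposite-homozygote counts:
#' \deqn{\hat\phi = \frac{N_{Aa,Aa} - 2 N_{AA,aa}}{N_{Aa}(i) + N_{Aa}(j)}}
#' where \eqn{N_{Aa,Aa}} is the number of markers at which both samples are
#' heterozygous, \eqn{N_{AA,aa}} the number at which they are homozygous for
#' opposite alleles, and \eqn{N_{Aa}(\cdot)} each sample's heterozygote
#' count over the shared non-missing markers. This estimator is robust to
#' population structure and requires no external allele frequencies.
#'
#' @param gi,gj dosage vectors over the same markers (0/1/2/NA).
#' @return estimated kinship (can be negative for unrelated pairs).
#' @export
kinship_estimate <- function(gi, gj) {
  ok <- !is.na(gi) & !is.na(gj)
  gi <- gi[ok]; gj <- gj[ok]
  het_i <- sum(gi == 1); het_j <- sum(gj == 1)
  if (het_i + het_j == 0) return(NA_real_)
  n_hh <- sum(gi == 1 & gj == 1)
  n_opp <- sum((gi == 0 & gj == 2) | (gi == 2 & gj == 0))
  (n_hh - 2 * n_opp) / (het_i + het_j)
}

# relationship degree class from a kinship value (powers-of-two boundaries)
kinship_degree <- function(phi) {
  cut(phi, breaks = c(-Inf, 2^-4.5, 2^-3.5, 2^-2.5, 2^-1.5, Inf),
      labels = c("unrelated", "third", "second", "first", "duplicate"),
      right = TRUE)
}

#' Verify pedigree relatedness against genotypes
#'
#' For every pair of genotyped pedigree members, compares the expected
#' kinship from the pedigree ([kinship_coefficient()]) with the robust
#' genotype-based estimate ([kinship_estimate()]). A pair is flagged
#' discordant when the two values fall in different relationship-degree
#' classes (boundaries at 2^-1.5, 2^-2.5, 2^-3.5, 2^-4.5, the conventional
#' inference ranges for duplicate/1st/2nd/3rd degree).
#'
#' @param gm a [genotype_matrix].
#' @param ped a [pedigree].
#' @param min_markers minimum shared non-missing markers per pair.
#' @return data.frame with columns `id1`, `id2`, `expected_kinship`,
#'   `observed_kinship`, `expected_degree`, `observed_degree`, `discordant`.
#' @export
verify_relatedness <- function(gm, ped, min_markers = 100) {
  ids <- intersect(gm$sample_ids, ped$id)
  if (length(ids) < 2) stop("fewer than two genotyped pedigree members")
  res <- expected_kinship_pairs(ped, ids)
  obs <- mapply(function(a, b) {
    ga <- gm$calls[a, ]; gb <- gm$calls[b, ]
    if (sum(!is.na(ga) & !is.na(gb)) < min_markers)
      stop("fewer than ", min_markers, " informative markers for pair ",
           a, ", ", b)
    kinship_estimate(ga, gb)
  }, res$id1, res$id2)
  res$observed_kinship <- as.numeric(obs)
  res$expected_degree <- as.character(kinship_degree(res$expected_kinship))
  res$observed_degree <- as.character(kinship_degree(res$observed_kinship))
  res$discordant <- res$expected_degree != res$observed_degree
  res
}

#' Array-exome genotype concordance
#'
#' Fraction of agreeing calls among sample/position pairs present in both
#' the array genotype matrix and an exome variant set, counting only calls
#' non-missing in both. Dosages are compared directly, so both data sets
#' must count the same allele.
#'
#' @param gm a [genotype_matrix].
#' @param vs a [variant_set].
#' @return fraction in `[0, 1]`.
#' @export
genotype_concordance <- function(gm, vs) {
  samples <- intersect(gm$sample_ids, colnames(vs$gt))
  key_gm <- paste(gm$markers$chrom, gm$markers$bp)
  key_vs <- paste(vs$info$chrom, vs$info$pos)
  shared <- intersect(key_gm, key_vs)
  if (!length(shared) || !length(samples))
    stop("no overlapping sample/position pairs")
  mi <- match(shared, key_gm); vi <- match(shared, key_vs)
  g1 <- gm$calls[samples, mi, drop = FALSE]
  g2 <- t(vs$gt[vi, samples, drop = FALSE])
  ok <- !is.na(g1) & !is.na(g2)
  if (!any(ok)) stop("no overlapping non-missing calls")
  sum(g1[ok] == g2[ok]) / sum(ok)
}
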