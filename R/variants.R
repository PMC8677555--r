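consequence_levels <- c("frameshift", "stop_gained", "stop_lost",
                        "start_lost", "splice_acceptor", "splice_donor",
                        "missense", "synonymous", "intronic", "other")
lof_consequences <- consequence_levels[1:6]
sift_levels <- c("deleterious", "deleterious_lc", "tolerated",
                 "tolerated_lc", "unknown")
polyphen_levels <- c("probably_damaging", "possibly_damaging", "benign",
                     "unknown")
freq_levels <- c("very_rare", "rare", "uncommon", "common")

#' Exome variant set
#'
#' Container for exome variants with per-sample genotype metrics. Genotypes
#' are alt-allele dosages (0/1/2, `NA` = no-call); `gq`, `ad_ref`, `ad_alt`
#' are per-call Genotype Quality and allele depths. Population minor allele
#' frequencies live in `info` columns named `maf_<population>`; `NA` means
#' the variant does not exist in that data set.
#'
#' @param info data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, and optionally `id`, `vtype` (`"snp"`/`"indel"`, derived from
#'   allele lengths when absent), `pass` (logical site-level pass flag),
#'   `tranche` (VQSR truth-tranche sensitivity, percent), `gene`,
#'   `consequence`, `sift`, `polyphen`, `cadd`, and `maf_*` columns.
#' @param gt integer matrix, variants x samples.
#' @param gq,ad_ref,ad_alt matrices of the same shape (optional).
#' @return object of class `variant_set`.
#' @export
variant_set <- function(info, gt, gq = NULL, ad_ref = NULL, ad_alt = NULL) {
  info <- as.data.frame(info, stringsAsFactors = FALSE)
  if (!all(c("chrom", "pos", "ref", "alt") %in% names(info)))
    stop("info needs columns chrom, pos, ref, alt")
  if (any(info$pos < 1)) stop("pos must be >= 1")
  info$pos <- as.integer(info$pos)
  info$chrom <- as.character(info$chrom)
  if (is.null(info$vtype))
    info$vtype <- ifelse(nchar(info$ref) == 1 & nchar(info$alt) == 1,
                         "snp", "indel")
  if (is.null(info$pass)) info$pass <- FALSE
  if (is.null(info$tranche)) info$tranche <- NA_real_
  for (col in c("consequence", "sift", "polyphen")) {
    lv <- switch(col, consequence = consequence_levels, sift = sift_levels,
                 polyphen = polyphen_levels)
    if (!is.null(info[[col]]) && !all(info[[col]] %in% lv))
      stop("invalid ", col, " value")
  }
  maf_cols <- grep("^maf_", names(info), value = TRUE)
  for (col in maf_cols)
    if (any(!is.na(info[[col]]) & (info[[col]] < 0 | info[[col]] > 1)))
      stop("MAF outside [0, 1] in ", col)
  gt <- as.matrix(gt)
  if (nrow(gt) != nrow(info)) stop("gt rows do not match info")
  if (is.null(colnames(gt))) stop("gt needs sample column names")
  shape_ok <- function(m) is.null(m) || all(dim(m) == dim(gt))
  if (!shape_ok(gq) || !shape_ok(ad_ref) || !shape_ok(ad_alt))
    stop("gq/ad matrices must match gt shape")
  if (!is.null(ad_ref) && any(ad_ref < 0, na.rm = TRUE)) stop("negative depth")
  if (!is.null(ad_alt) && any(ad_alt < 0, na.rm = TRUE)) stop("negative depth")
  rownames(info) <- NULL
  structure(list(info = info, gt = gt, gq = gq,
                 ad_ref = ad_ref, ad_alt = ad_alt),
            class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("variant_set: %d variants x %d samples\n",
              nrow(x$info), ncol(x$gt)))
  invisible(x)
}

#' Subset a variant set by row index
#'
#' @param vs a [variant_set].
#' @param idx logical or integer row index.
#' @return a [variant_set].
#' @export
subset_variants <- function(vs, idx) {
  pick <- function(m) if (is.null(m)) NULL else m[idx, , drop = FALSE]
  variant_set(vs$info[idx, , drop = FALSE], pick(vs$gt), pick(vs$gq),
              pick(vs$ad_ref), pick(vs$ad_alt))
}

#' Variant filter thresholds
#'
#' Defaults encode a conservative post-calling exome filter: SNPs kept at
#' VQSR truth tranche <= 99.5 and indels <= 99.0; genotypes no-called when
#' GQ < 30, when a heterozygous call's allele balance deviates from 50:50
#' (chi-squared P < 0.001), or when a het/hom-alt call has fewer than 3
#' alternate reads; variants dropped at a no-call rate of 0.25 or more.
#' `cadd_damaging` is the CADD phred score above which a missense variant
#' counts as predicted deleterious. `class_bounds` are the upper bounds of
#' the very-rare / rare / uncommon frequency classes, each half-open
#' `[lower, upper)`, with MAF at or above the last bound classed common.
#'
#' @param snp_tranche_max,indel_tranche_max VQSR sensitivity ceilings.
#' @param min_gq minimum Genotype Quality.
#' @param ab_p_min minimum allele-balance chi-squared P for het calls.
#' @param min_alt_depth minimum alternate-allele read depth.
#' @param max_no_call_rate variants with a no-call fraction at or above
#'   this are removed.
#' @param cadd_damaging CADD phred threshold (strict `>`).
#' @param class_bounds named numeric upper bounds for very_rare/rare/
#'   uncommon.
#' @return list of class `filter_thresholds`.
#' @export
filter_thresholds <- function(snp_tranche_max = 99.5,
                              indel_tranche_max = 99.0,
                              min_gq = 30, ab_p_min = 0.001,
                              min_alt_depth = 3, max_no_call_rate = 0.25,
                              cadd_damaging = 20,
                              class_bounds = c(very_rare = 0.001,
                                               rare = 0.01,
                                               uncommon = 0.05)) {
  if (is.unsorted(class_bounds, strictly = TRUE))
    stop("class bounds must be increasing")
  structure(list(snp_tranche_max = snp_tranche_max,
                 indel_tranche_max = indel_tranche_max,
                 min_gq = min_gq, ab_p_min = ab_p_min,
                 min_alt_depth = min_alt_depth,
                 max_no_call_rate = max_no_call_rate,
                 cadd_damaging = cadd_damaging,
                 class_bounds = class_bounds),
            class = "filter_thresholds")
}

#' Site-level VQSR tranche filter
#'
#' Retains variants flagged pass, SNPs with truth tranche at or below
#' `t$snp_tranche_max`, and indels at or below `t$indel_tranche_max`.
#' Variants with neither a pass flag nor a tranche annotation are dropped.
#'
#' @param vs a [variant_set].
#' @param t a [filter_thresholds].
#' @return filtered [variant_set].
#' @export
site_filter <- function(vs, t = filter_thresholds()) {
  info <- vs$info
  ceiling_ <- ifelse(info$vtype == "snp", t$snp_tranche_max,
                     t$indel_tranche_max)
  keep <- info$pass | (!is.na(info$tranche) & info$tranche <= ceiling_)
  subset_variants(vs, keep)
}

#' Allele-balance test probability
#'
#' Chi-squared goodness-of-fit of the ref/alt read depths against 50:50 on
#' one degree of freedom: the statistic is `(ref - alt)^2 / (ref + alt)`
#' and the upper-tail probability is returned.
#'
#' @param ref_depth,alt_depth read depths (vectorised).
#' @return upper-tail probabilities.
#' @export
allele_balance_p <- function(ref_depth, alt_depth) {
  tot <- ref_depth + alt_depth
  if (any(tot <= 0, na.rm = TRUE)) stop("zero total read depth")
  stats::pchisq((ref_depth - alt_depth)^2 / tot, df = 1, lower.tail = FALSE)
}

#' Per-genotype quality filter
#'
#' Sets failing calls to no-call (`NA`): any call with GQ below `t$min_gq`
#' (or missing GQ), heterozygous calls whose allele balance fails
#' [allele_balance_p()] at `t$ab_p_min`, and heterozygous or
#' homozygous-alternate calls with fewer than `t$min_alt_depth` alternate
#' reads. Other calls are unchanged.
#'
#' `genotype_filter` applies the rule to a whole [variant_set];
#' `filter_genotype_call` is the vectorised per-call primitive.
#'
#' @param gt dosage calls (0/1/2/NA).
#' @param gq,ref_depth,alt_depth per-call metrics.
#' @param t a [filter_thresholds].
#' @return `filter_genotype_call`: filtered dosage vector;
#'   `genotype_filter`: a [variant_set] with `gt` updated.
#' @export
filter_genotype_call <- function(gt, gq, ref_depth, alt_depth,
                                 t = filter_thresholds()) {
  out <- gt
  fail <- is.na(gq) | gq < t$min_gq
  het <- !is.na(gt) & gt == 1
  ab <- rep(1, length(gt))
  has_depth <- !is.na(ref_depth) & !is.na(alt_depth) &
    (ref_depth + alt_depth) > 0
  ab[has_depth] <- allele_balance_p(ref_depth[has_depth],
                                    alt_depth[has_depth])
  fail <- fail | (het & (!has_depth | ab < t$ab_p_min))
  carrier <- !is.na(gt) & gt >= 1
  fail <- fail | (carrier & (is.na(alt_depth) | alt_depth < t$min_alt_depth))
  out[!is.na(gt) & fail] <- NA
  out
}

#' @param vs a [variant_set] with `gq`, `ad_ref`, `ad_alt` present.
#' @rdname filter_genotype_call
#' @export
genotype_filter <- function(vs, t = filter_thresholds()) {
  if (is.null(vs$gq) || is.null(vs$ad_ref) || is.null(vs$ad_alt))
    stop("genotype_filter needs gq and allele depths")
  gt <- vs$gt
  for (j in seq_len(ncol(gt)))
    gt[, j] <- filter_genotype_call(gt[, j], vs$gq[, j], vs$ad_ref[, j],
                                    vs$ad_alt[, j], t)
  vs$gt <- gt
  vs
}

#' No-call-rate filter
#'
#' Removes variants whose fraction of no-call genotypes is at or above
#' `t$max_no_call_rate` (i.e. only variants with a no-call rate strictly
#' below the threshold are retained). Apply after [genotype_filter()].
#'
#' @param vs a [variant_set].
#' @param t a [filter_thresholds].
#' @return filtered [variant_set].
#' @export
no_call_filter <- function(vs, t = filter_thresholds()) {
  rate <- rowMeans(is.na(vs$gt))
  subset_variants(vs, rate < t$max_no_call_rate)
}

#' Population frequency class
#'
#' Classifies each variant as `very_rare`, `rare`, `uncommon` or `common`
#' per population (class bounds half-open: MAF exactly 0.01 is uncommon,
#' exactly 0.05 is common) and combines across the required populations by
#' taking the least-rare class: the frequency thresholds must be satisfied
#' in every population, and an absent MAF counts as 0 (the variant does not
#' exist in that data set).
#'
#' @param vs a [variant_set].
#' @param populations population names; `maf_<name>` columns must exist.
#' @param t a [filter_thresholds].
#' @return ordered factor with levels very_rare < rare < uncommon < common.
#' @export
frequency_class <- function(vs, populations, t = filter_thresholds()) {
  cols <- paste0("maf_", populations)
  miss <- setdiff(cols, names(vs$info))
  if (length(miss)) stop("missing MAF columns: ", paste(miss, collapse = ", "))
  maf <- as.matrix(vs$info[cols])
  maf[is.na(maf)] <- 0
  cls <- apply(maf, c(1, 2), function(x) findInterval(x, t$class_bounds) + 1L)
  cls <- matrix(cls, nrow = nrow(maf))
  combined <- apply(cls, 1, max)
  factor(freq_levels[combined], levels = freq_levels, ordered = TRUE)
}

#' Predicted-damaging classification
#'
#' A variant is damaging when its consequence is protein-truncating or
#' splice-disrupting (frameshift, stop gained/lost, start lost, splice
#' acceptor/donor); a missense variant is damaging when predicted
#' deleterious by any model: SIFT deleterious (low-confidence calls count
#' as their base class), PolyPhen probably or possibly damaging, or CADD
#' phred strictly above `t$cadd_damaging`. All other consequences are not
#' damaging regardless of scores.
#'
#' @param vs a [variant_set] with `consequence`, `sift`, `polyphen`,
#'   `cadd` columns.
#' @param t a [filter_thresholds].
#' @return logical vector.
#' @export
is_damaging <- function(vs, t = filter_thresholds()) {
  info <- vs$info
  lof <- info$consequence %in% lof_consequences
  mis <- info$consequence == "missense"
  sift_del <- info$sift %in% c("deleterious", "deleterious_lc")
  poly_del <- info$polyphen %in% c("probably_damaging", "possibly_damaging")
  cadd_del <- !is.na(info$cadd) & info$cadd > t$cadd_damaging
  lof | (mis & (sift_del | poly_del | cadd_del))
}

#' Homozygous damaging candidates in the proband
#'
#' After quality filtering, selects variants that are homozygous-alternate
#' in the proband, predicted damaging, and of uncommon or lower combined
#' frequency class.
#'
#' @param vs a filtered [variant_set].
#' @param proband sample id.
#' @param populations populations for the dual-frequency rule.
#' @param t a [filter_thresholds].
#' @return a [variant_set] whose `info` gains a `freq_class` column.
#' @export
proband_candidates <- function(vs, proband, populations,
                               t = filter_thresholds()) {
  if (!(proband %in% colnames(vs$gt))) stop("proband not genotyped")
  cls <- frequency_class(vs, populations, t)
  keep <- !is.na(vs$gt[, proband]) & vs$gt[, proband] == 2 &
    is_damaging(vs, t) & cls != "common"
  out <- subset_variants(vs, keep)
  out$info$freq_class <- as.character(cls[keep])
  out
}

#' Family segregation rule
#'
#' @param required_hom_cases `"all"` or a minimum count of homozygous
#'   affected cases (e.g. 2 of 3 affected siblings).
#' @param exclude_if_hom_controls drop variants homozygous in controls.
#' @param control_mode with exclusion on, drop when `"any"` control or a
#'   `"majority"` of controls is homozygous-alternate.
#' @return list of class `segregation_rule`.
#' @export
segregation_rule <- function(required_hom_cases = "all",
                             exclude_if_hom_controls = FALSE,
                             control_mode = c("any", "majority")) {
  control_mode <- match.arg(control_mode)
  structure(list(required_hom_cases = required_hom_cases,
                 exclude_if_hom_controls = exclude_if_hom_controls,
                 control_mode = control_mode),
            class = "segregation_rule")
}

#' Segregation filter with control-homozygote annotation
#'
#' Keeps variants homozygous-alternate in at least the required number of
#' affected cases and annotates each with its homozygous-control count as
#' `"x/n"`. With `rule$exclude_if_hom_controls`, variants homozygous in
#' any (or a majority of) controls are dropped.
#'
#' @param vs a [variant_set] (typically from [proband_candidates()]).
#' @param rule a [segregation_rule].
#' @param case_ids,ctrl_ids sample ids of affected cases and unaffected
#'   family controls.
#' @return a [variant_set] whose `info` gains a `hom_controls` column.
#' @export
segregation_filter <- function(vs, rule, case_ids, ctrl_ids) {
  unknown <- setdiff(c(case_ids, ctrl_ids), colnames(vs$gt))
  if (length(unknown)) stop("unknown ids: ", paste(unknown, collapse = ", "))
  hom_cases <- rowSums(vs$gt[, case_ids, drop = FALSE] == 2, na.rm = TRUE)
  req <- if (identical(rule$required_hom_cases, "all")) length(case_ids)
         else rule$required_hom_cases
  if (req > length(case_ids)) stop("required count exceeds case set")
  hom_ctrl <- rowSums(vs$gt[, ctrl_ids, drop = FALSE] == 2, na.rm = TRUE)
  keep <- hom_cases >= req
  if (rule$exclude_if_hom_controls) {
    lim <- if (rule$control_mode == "any") 0 else length(ctrl_ids) / 2
    keep <- keep & hom_ctrl <= lim
  }
  out <- subset_variants(vs, keep)
  out$info$hom_controls <- sprintf("%d/%d", hom_ctrl[keep], length(ctrl_ids))
  out
}

#' Infer whether a deceased parent could be homozygous
#'
#' For an unavailable parent, homozygosity for the alternate allele is
#' excluded when any genotyped descendant is homozygous for the reference
#' allele (such a descendant must have received a reference allele from
#' that parent).
#'
#' @param offspring_gt dosage calls of the genotyped descendants at one
#'   variant (`NA` ignored).
#' @return `"hom_alt_excluded"` or `"hom_alt_possible"`.
#' @export
parent_genotype_constraint <- function(offspring_gt) {
  g <- offspring_gt[!is.na(offspring_gt)]
  if (!length(g)) stop("no informative offspring genotypes")
  if (any(g == 0)) "hom_alt_excluded" else "hom_alt_possible"
}

#' Screen samples for a panel of known risk variants
#'
#' @param vs a [variant_set].
#' @param panel data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `label`.
#' @return data.frame, one row per panel variant, with a `label` column
#'   and one column per sample holding `hom_ref`/`het`/`hom_alt`/
#'   `no_call`, or `absent` when the variant is not in the call set.
#' @export
known_variant_screen <- function(vs, panel) {
  samples <- colnames(vs$gt)
  if (nrow(panel) == 0)
    return(data.frame(label = character(0), stringsAsFactors = FALSE))
  key_vs <- paste(vs$info$chrom, vs$info$pos, vs$info$ref, vs$info$alt)
  key_p <- paste(panel$chrom, panel$pos, panel$ref, panel$alt)
  idx <- match(key_p, key_vs)
  code <- c("hom_ref", "het", "hom_alt")
  rows <- lapply(seq_along(idx), function(i) {
    if (is.na(idx[i])) return(rep("absent", length(samples)))
    g <- vs$gt[idx[i], samples]
    ifelse(is.na(g), "no_call", code[g + 1])
  })
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- samples
  cbind(data.frame(label = panel$label, stringsAsFactors = FALSE), out)
}

#' Run the full variant prioritisation cascade
#'
#' Fixed-order cascade: site tranche filter, per-genotype quality filter,
#' no-call-rate filter, then selection of homozygous damaging
#' uncommon-or-rarer candidates in the proband and the family segregation
#' filter. The cascade is idempotent: re-applying it to its own output
#' changes nothing.
#'
#' @param vs a raw [variant_set].
#' @param proband proband sample id.
#' @param case_ids,ctrl_ids affected and unaffected sample ids.
#' @param populations populations for the dual-frequency rule.
#' @param rule a [segregation_rule].
#' @param t a [filter_thresholds].
#' @return a [variant_set] of prioritised candidates.
#' @export
prioritise_variants <- function(vs, proband, case_ids, ctrl_ids,
                                populations,
                                rule = segregation_rule(),
                                t = filter_thresholds()) {
  vs <- site_filter(vs, t)
  vs <- genotype_filter(vs, t)
  vs <- no_call_filter(vs, t)
  vs <- proband_candidates(vs, proband, populations, t)
  segregation_filter(vs, rule, case_ids, ctrl_ids)
}

#' Candidate summary table
#'
#' Flat per-variant report (gene, consequence, predictions, MAFs,
#' frequency class, homozygous-control counts) for writing as TSV.
#'
#' @param vs a prioritised [variant_set].
#' @return data.frame.
#' @export
candidate_table <- function(vs) {
  info <- vs$info
  cols <- intersect(c("chrom", "pos", "id", "ref", "alt", "gene",
                      "consequence", "sift", "polyphen", "cadd",
                      grep("^maf_", names(info), value = TRUE),
                      "freq_class", "hom_controls"), names(info))
  info[cols]
}
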