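#' Synthetic data configuration
#'
#' Controls the synthetic SNP-array generator. The `"fast"` profile places
#' 20,000 markers on four chromosomes, sized for tests; the `"paper"`
#' profile emulates a genotyping array scale of 250,000 autosomal markers
#' on the 22 GRCh37 autosomes. Marker minor-allele frequencies are drawn
#' uniformly on `maf_range` (array content is biased to common variants);
#' genotype error and missingness default to 0.2%, typical post-QC array
#' rates.
#'
#' @param n_markers total marker count.
#' @param chrom_lengths data.frame with `chrom`, `length_bp` (and
#'   optionally `length_cM`).
#' @param maf_range range of marker reference MAFs.
#' @param genotype_error_rate per-call probability of a miscalled
#'   genotype.
#' @param missing_rate per-call probability of a no-call.
#' @param seed RNG seed; output is fully determined by the seed.
#' @param profile shortcut setting `n_markers` and `chrom_lengths`.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_markers = NULL, chrom_lengths = NULL,
                         maf_range = c(0.05, 0.5),
                         genotype_error_rate = 0.002,
                         missing_rate = 0.002, seed = 1,
                         profile = c("fast", "paper")) {
  profile <- match.arg(profile)
  if (is.null(chrom_lengths))
    chrom_lengths <- if (profile == "paper") grch37_autosomes() else
      data.frame(chrom = c("1", "2", "3", "4"),
                 length_bp = c(150e6, 120e6, 90e6, 60e6),
                 stringsAsFactors = FALSE)
  if (is.null(n_markers)) n_markers <- if (profile == "paper") 250000 else 20000
  rates <- c(genotype_error_rate, missing_rate)
  if (any(rates < 0 | rates >= 1)) stop("rates must be in [0, 1)")
  if (n_markers < 1) stop("n_markers must be >= 1")
  structure(list(n_markers = as.integer(n_markers),
                 chrom_lengths = chrom_lengths, maf_range = maf_range,
                 genotype_error_rate = genotype_error_rate,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "synth_config")
}

#' Planted structure specification
#'
#' @param chrom,start_bp,end_bp region to plant.
#' @param carriers sample ids forced to carry the structure.
#' @param mode `"shared_identical_roh"` (carriers made identically
#'   homozygous across all in-region markers) or `"hom_alt_variant"`.
#' @return list of class `plant_spec`.
#' @export
plant_spec <- function(chrom, start_bp, end_bp, carriers,
                       mode = c("shared_identical_roh", "hom_alt_variant")) {
  mode <- match.arg(mode)
  if (end_bp <= start_bp) stop("plant region end before start")
  structure(list(chrom = as.character(chrom), start_bp = start_bp,
                 end_bp = end_bp, carriers = carriers, mode = mode),
            class = "plant_spec")
}

ped_from_rows <- function(family, rows, proband = NULL) {
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- c("id", "father", "mother", "sex", "affection")
  df$family <- family
  p <- pedigree(df[c("family", "id", "father", "mother", "sex",
                     "affection")], proband = proband)
  attr(p, "note") <- "reconstruction"
  p
}

#' Reconstructed study-family pedigrees
#'
#' Returns four synthetic pedigree reconstructions of consanguineous
#' multiplex IBD families, labelled by ancestry group: `AJ` (three affected
#' CD siblings of first-cousin parents, two deceased unaffected siblings
#' represented through their genotyped descendants), `DR` (a five/six
#' generation family in which the affected uncle III-2 is modelled as the
#' offspring of a first-cousin mating and proband V-1 descends from two of
#' his siblings), `AM-CD` (two affected brothers, first-cousin parents)
#' and `AM-UC` (two affected sisters, an affected aunt, first-cousin
#' parents). These are reconstructions for simulation and testing, not
#' ground-truth topologies; each carries `attr(., "note") ==
#' "reconstruction"`.
#'
#' @return named list of [pedigree] objects.
#' @export
family_fixtures <- function() {
  aj <- ped_from_rows("AJ", list(
    c("I-1", 0, 0, "male", "unaffected"),
    c("I-2", 0, 0, "female", "unaffected"),
    c("II-1", "I-1", "I-2", "male", "unaffected"),
    c("II-2", "I-1", "I-2", "female", "unaffected"),
    c("II-3", 0, 0, "female", "unaffected"),
    c("II-4", 0, 0, "male", "unaffected"),
    c("III-1", "II-1", "II-3", "male", "unaffected"),
    c("III-2", "II-4", "II-2", "female", "unaffected"),
    c("IV-1", "III-1", "III-2", "male", "CD"),
    c("IV-2", "III-1", "III-2", "male", "CD"),
    c("IV-3", "III-1", "III-2", "female", "CD"),
    c("IV-4", "III-1", "III-2", "male", "unaffected"),
    c("IV-5", "III-1", "III-2", "female", "unaffected"),
    c("IV-10", 0, 0, "female", "unaffected"),
    c("IV-11", 0, 0, "male", "unaffected"),
    c("V-1", "IV-4", "IV-10", "male", "unaffected"),
    c("V-2", "IV-4", "IV-10", "female", "unaffected"),
    c("V-3", "IV-11", "IV-5", "male", "unaffected"),
    c("V-4", "IV-11", "IV-5", "female", "unaffected")), proband = "IV-1")

  dr <- ped_from_rows("DR", list(
    c("0-1", 0, 0, "male", "unaffected"),
    c("0-2", 0, 0, "female", "unaffected"),
    c("I-1", "0-1", "0-2", "male", "unaffected"),
    c("I-2", "0-1", "0-2", "female", "unaffected"),
    c("I-3", 0, 0, "female", "unaffected"),
    c("I-4", 0, 0, "male", "unaffected"),
    c("II-1", "I-1", "I-3", "male", "unaffected"),
    c("II-2", "I-4", "I-2", "female", "unaffected"),
    c("III-1", "II-1", "II-2", "female", "unaffected"),
    c("III-2", "II-1", "II-2", "male", "CD"),
    c("III-3", "II-1", "II-2", "male", "UC"),
    c("III-10", 0, 0, "male", "unaffected"),
    c("III-11", 0, 0, "female", "unaffected"),
    c("IV-1", "III-10", "III-1", "female", "UC"),
    c("IV-2", "III-3", "III-11", "male", "unaffected"),
    c("V-1", "IV-2", "IV-1", "female", "CD")), proband = "V-1")

  am_cd <- ped_from_rows("AM-CD", list(
    c("III-1", 0, 0, "male", "unaffected"),
    c("III-2", 0, 0, "female", "unaffected"),
    c("IV-3", "III-1", "III-2", "male", "unaffected"),
    c("IV-4", "III-1", "III-2", "female", "unaffected"),
    c("IV-5", 0, 0, "female", "unaffected"),
    c("IV-6", 0, 0, "male", "unaffected"),
    c("IV-1", "IV-3", "IV-5", "male", "unaffected"),
    c("IV-2", "IV-6", "IV-4", "female", "unaffected"),
    c("V-1", "IV-1", "IV-2", "male", "CD"),
    c("V-2", "IV-1", "IV-2", "male", "unaffected"),
    c("V-3", "IV-1", "IV-2", "male", "CD"),
    c("V-4", "IV-1", "IV-2", "female", "unaffected")), proband = "V-1")

  am_uc <- ped_from_rows("AM-UC", list(
    c("III-1", 0, 0, "male", "unaffected"),
    c("III-2", 0, 0, "female", "unaffected"),
    c("IV-7", "III-1", "III-2", "male", "unaffected"),
    c("IV-8", "III-1", "III-2", "female", "unaffected"),
    c("IV-9", "III-1", "III-2", "female", "unaffected"),
    c("IV-13", "III-1", "III-2", "female", "unaffected"),
    c("IV-16", "III-1", "III-2", "female", "CD"),
    c("IV-10", 0, 0, "female", "unaffected"),
    c("IV-11", 0, 0, "male", "unaffected"),
    c("IV-12", 0, 0, "male", "unaffected"),
    c("IV-1", "IV-7", "IV-10", "male", "unaffected"),
    c("IV-2", "IV-11", "IV-8", "female", "unaffected"),
    c("V-1", "IV-1", "IV-2", "female", "UC"),
    c("V-2", "IV-1", "IV-2", "male", "unaffected"),
    c("V-3", "IV-1", "IV-2", "female", "unaffected"),
    c("V-5", "IV-1", "IV-2", "female", "UC"),
    c("V-9", "IV-12", "IV-9", "male", "unaffected"),
    c("V-10", "IV-12", "IV-9", "female", "unaffected")), proband = "V-1")

  list("AJ" = aj, "DR" = dr, "AM-CD" = am_cd, "AM-UC" = am_uc)
}

# marker panel: counts proportional to chromosome length, positions
# uniform, MAFs uniform on cfg$maf_range
synth_marker_panel <- function(cfg) {
  cl <- cfg$chrom_lengths
  n_per <- pmax(1L, round(cfg$n_markers * cl$length_bp / sum(cl$length_bp)))
  parts <- lapply(seq_len(nrow(cl)), function(i) {
    bp <- sort(sample.int(cl$length_bp[i], n_per[i]))
    data.frame(id = sprintf("rs%s_%d", cl$chrom[i], seq_len(n_per[i])),
               chrom = cl$chrom[i], bp = bp,
               ref_maf = round(stats::runif(n_per[i], cfg$maf_range[1],
                                            cfg$maf_range[2]), 4),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, parts)
}

#' Generate family SNP-array genotypes with planted structures
#'
#' Founder haplotype alleles are drawn independently per marker from the
#' marker MAF (so founders conform to Hardy-Weinberg equilibrium);
#' inheritance runs through one gene-dropping replicate with recombination,
#' so relatives share realistic identity-by-descent segments and offspring
#' of consanguineous matings carry genuine autozygous runs. Planted
#' `shared_identical_roh` regions then force the designated carriers to be
#' identically homozygous at every in-region marker, with the markers
#' immediately flanking the region made heterozygous in carriers so that
#' the planted marker boundaries are exactly the boundaries a run detector
#' reports; genotype error and missingness are applied afterwards
#' everywhere outside planted regions.
#' Output is fully determined by `cfg$seed`.
#'
#' @param ped a [pedigree].
#' @param cfg a [synth_config].
#' @param plants list of [plant_spec] objects.
#' @return a [genotype_matrix]; the plant truth (marker indices per plant)
#'   is attached as `attr(., "plants")`.
#' @export
generate_family_genotypes <- function(ped, cfg = synth_config(),
                                      plants = list()) {
  set.seed(cfg$seed)
  markers <- synth_marker_panel(cfg)
  map <- genetic_map(cfg$chrom_lengths)
  st <- drop_once(ped, map)
  n_hap <- 2L * sum(is_founder(ped))
  n_ind <- nrow(ped)
  calls <- matrix(NA_real_, n_ind, nrow(markers),
                  dimnames = list(ped$id, markers$id))
  for (ch in unique(markers$chrom)) {
    sel <- which(markers$chrom == ch)
    pos_cM <- bp_to_cM(map, ch, markers$bp[sel])
    alleles <- matrix(stats::rbinom(n_hap * length(sel), 1,
                                    rep(markers$ref_maf[sel],
                                        each = n_hap)),
                      n_hap, length(sel))
    for (id in ped$id) {
      s <- st$state[[ch]][[id]]
      l1 <- s$h1$lab[findInterval(pos_cM, s$h1$end, left.open = TRUE) + 1L]
      l2 <- s$h2$lab[findInterval(pos_cM, s$h2$end, left.open = TRUE) + 1L]
      calls[id, sel] <- alleles[cbind(l1, seq_along(sel))] +
        alleles[cbind(l2, seq_along(sel))]
    }
  }
  protected <- matrix(FALSE, n_ind, nrow(markers),
                      dimnames = list(ped$id, markers$id))
  truth <- list()
  for (pl in plants) {
    if (pl$mode != "shared_identical_roh") next
    j <- which(markers$chrom == pl$chrom & markers$bp >= pl$start_bp &
               markers$bp <= pl$end_bp)
    if (!length(j)) stop("plant region contains no markers")
    hap <- stats::rbinom(length(j), 1, markers$ref_maf[j])
    for (s in pl$carriers) calls[s, j] <- 2 * hap
    protected[pl$carriers, j] <- TRUE
    # delimit the run: the markers flanking the planted region are made
    # heterozygous in carriers so the planted boundaries are the detected
    # boundaries
    on_chrom <- which(markers$chrom == pl$chrom)
    flank <- c(max(on_chrom[on_chrom < j[1]], -Inf),
               min(on_chrom[on_chrom > j[length(j)]], Inf))
    flank <- flank[is.finite(flank)]
    if (length(flank)) {
      for (s in pl$carriers) calls[s, flank] <- 1
      protected[pl$carriers, flank] <- TRUE
    }
    truth[[length(truth) + 1]] <- list(spec = pl, marker_idx = j,
                                       start_bp = markers$bp[j[1]],
                                       end_bp = markers$bp[j[length(j)]])
  }
  if (cfg$genotype_error_rate > 0) {
    err <- matrix(stats::runif(length(calls)) < cfg$genotype_error_rate,
                  n_ind) & !protected
    shift <- matrix(sample(1:2, length(calls), replace = TRUE), n_ind)
    calls[err] <- (calls[err] + shift[err]) %% 3
  }
  if (cfg$missing_rate > 0) {
    mis <- matrix(stats::runif(length(calls)) < cfg$missing_rate,
                  n_ind) & !protected
    calls[mis] <- NA
  }
  gm <- genotype_matrix(calls, markers, ped$id)
  attr(gm, "plants") <- truth
  gm
}

decoy_types <- c("site_tranche", "low_gq", "allele_balance",
                 "low_alt_depth", "high_no_call", "common_population",
                 "not_damaging", "not_homozygous", "hom_in_controls")

#' Generate an annotated exome variant table with planted candidates
#'
#' Builds a synthetic [variant_set] in which planted candidate variants
#' satisfy every stage of the prioritisation cascade (site pass, clean
#' genotypes, homozygous-alternate in the designated cases, predicted
#' damaging, below-5% MAF in both reference populations) while each decoy
#' violates exactly one named criterion:
#'
#' * `site_tranche` - SNP tranche above the sensitivity ceiling;
#' * `low_gq` - proband Genotype Quality below 30;
#' * `allele_balance` - heterozygous proband call with skewed depths;
#' * `low_alt_depth` - homozygous proband call with < 3 alternate reads;
#' * `high_no_call` - no-call rate at or above 0.25;
#' * `common_population` - common (MAF >= 0.05) in the second reference
#'   population only (the dual-population rule must reject it);
#' * `not_damaging` - missense tolerated/benign with low CADD;
#' * `not_homozygous` - heterozygous in the proband;
#' * `hom_in_controls` - also homozygous in family controls.
#'
#' Background variants with a realistic mix of consequences and frequency
#' classes are added around them.
#'
#' @param ped a [pedigree].
#' @param cfg a [synth_config] (its `seed` drives generation).
#' @param planted list of lists with elements `gene`, `chrom`, `pos`,
#'   `cases` (sample ids made homozygous-alternate).
#' @param decoys character vector of decoy types (see above), or a list of
#'   lists with elements `type` and optionally `chrom`, `pos`, `gene`.
#' @param n_background number of background variants.
#' @param populations names of the two reference populations.
#' @return list with elements `variants` (a [variant_set]) and `truth`
#'   (data.frame of planted/decoy roles keyed by variant id).
#' @export
generate_variant_table <- function(ped, cfg = synth_config(),
                                   planted = list(), decoys = character(),
                                   n_background = 200,
                                   populations = c("gnomad", "gmev")) {
  set.seed(cfg$seed + 1L)
  samples <- ped$id
  proband <- attr(ped, "proband")
  if (is.null(proband)) proband <- samples[1]
  cases <- affected_ids(ped)
  controls <- control_ids(ped)
  if (is.character(decoys)) decoys <- lapply(decoys, function(x) list(type = x))

  rows <- list(); mats <- list(); truth <- list()
  add <- function(info_row, gt, gq, adr, ada, role) {
    rows[[length(rows) + 1]] <<- info_row
    mats[[length(mats) + 1]] <<- list(gt = gt, gq = gq, adr = adr, ada = ada)
    truth[[length(truth) + 1]] <<- data.frame(id = info_row$id, role = role,
                                              stringsAsFactors = FALSE)
  }
  n_s <- length(samples)
  clean_metrics <- function(gt) {
    gq <- rep(99, n_s)
    adr <- ifelse(gt == 2, 0L, ifelse(gt == 1, 15L, 30L))
    ada <- ifelse(gt == 2, 30L, ifelse(gt == 1, 15L, 0L))
    adr[is.na(gt)] <- 0L; ada[is.na(gt)] <- 0L
    list(gq = gq, adr = adr, ada = ada)
  }
  base_info <- function(id, gene, chrom, pos, consequence = "missense",
                        sift = "deleterious", polyphen = "probably_damaging",
                        cadd = 28, maf1 = 0.004, maf2 = 0.003,
                        tranche = 99.0, pass = FALSE) {
    info <- data.frame(chrom = as.character(chrom), pos = pos, id = id,
                       ref = "A", alt = "G", pass = pass, tranche = tranche,
                       gene = gene, consequence = consequence, sift = sift,
                       polyphen = polyphen, cadd = cadd,
                       stringsAsFactors = FALSE)
    info[[paste0("maf_", populations[1])]] <- maf1
    info[[paste0("maf_", populations[2])]] <- maf2
    info
  }
  candidate_gt <- function(hom_ids) {
    gt <- rep(0, n_s)
    names(gt) <- samples
    gt[hom_ids] <- 2
    # parents of homozygotes carry one copy where genotyped
    for (s in hom_ids) {
      for (par in c(ped[s, "father"], ped[s, "mother"]))
        if (!is.na(par) && gt[par] == 0) gt[par] <- 1
    }
    gt
  }

  for (k in seq_along(planted)) {
    pl <- planted[[k]]
    gt <- candidate_gt(pl$cases)
    m <- clean_metrics(gt)
    add(base_info(sprintf("planted_%d", k), pl$gene, pl$chrom, pl$pos),
        gt, m$gq, m$adr, m$ada, "planted")
  }

  for (k in seq_along(decoys)) {
    d <- decoys[[k]]
    if (!(d$type %in% decoy_types)) stop("unknown decoy type: ", d$type)
    chrom <- if (is.null(d$chrom)) "1" else d$chrom
    pos <- if (is.null(d$pos)) 5e6 + 1000 * k else d$pos
    gene <- if (is.null(d$gene)) sprintf("DECOY%d", k) else d$gene
    gt <- candidate_gt(intersect(c(proband, cases), samples))
    info <- base_info(sprintf("decoy_%s_%d", d$type, k), gene, chrom, pos)
    m <- clean_metrics(gt)
    if (d$type == "site_tranche") {
      info$tranche <- 99.6
    } else if (d$type == "low_gq") {
      m$gq[samples == proband] <- 25
    } else if (d$type == "allele_balance") {
      gt[proband] <- 1
      m$adr[samples == proband] <- 28L
      m$ada[samples == proband] <- 3L
    } else if (d$type == "low_alt_depth") {
      m$adr[samples == proband] <- 0L
      m$ada[samples == proband] <- 2L
    } else if (d$type == "high_no_call") {
      n_nc <- ceiling(0.25 * n_s)
      nc <- setdiff(samples, c(proband, cases))[seq_len(n_nc)]
      gt[nc] <- NA
    } else if (d$type == "common_population") {
      info[[paste0("maf_", populations[2])]] <- 0.08
    } else if (d$type == "not_damaging") {
      info$sift <- "tolerated"; info$polyphen <- "benign"; info$cadd <- 5
    } else if (d$type == "not_homozygous") {
      gt[proband] <- 1
      m <- clean_metrics(gt)
    } else if (d$type == "hom_in_controls") {
      gt[controls] <- 2
      m <- clean_metrics(gt)
    }
    add(info, gt, m$gq, m$adr, m$ada, d$type)
  }

  csq_pool <- c("synonymous", "intronic", "missense", "other")
  for (k in seq_len(n_background)) {
    maf <- stats::runif(1, 0, 0.3)
    p_alt <- maf
    gt <- stats::rbinom(n_s, 2, p_alt)
    names(gt) <- samples
    m <- clean_metrics(gt)
    info <- base_info(sprintf("bg_%d", k), sprintf("BG%d", k),
                      sample(c("1", "2", "3", "4"), 1),
                      10e6 + 500 * k,
                      consequence = sample(csq_pool, 1),
                      sift = "tolerated", polyphen = "benign",
                      cadd = round(stats::runif(1, 0, 15), 2),
                      maf1 = round(maf, 4), maf2 = round(maf, 4),
                      tranche = 99.0)
    add(info, gt, m$gq, m$adr, m$ada, "background")
  }

  info <- do.call(rbind, rows)
  gt <- do.call(rbind, lapply(mats, function(m) m$gt))
  gq <- do.call(rbind, lapply(mats, function(m) m$gq))
  adr <- do.call(rbind, lapply(mats, function(m) m$adr))
  ada <- do.call(rbind, lapply(mats, function(m) m$ada))
  colnames(gt) <- colnames(gq) <- colnames(adr) <- colnames(ada) <- samples
  ord <- order(info$chrom, info$pos)
  vs <- variant_set(info[ord, ], gt[ord, , drop = FALSE],
                    gq[ord, , drop = FALSE], adr[ord, , drop = FALSE],
                    ada[ord, , drop = FALSE])
  list(variants = vs, truth = do.call(rbind, truth))
}
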