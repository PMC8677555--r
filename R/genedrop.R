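#' Genetic maps
#'
#' A genetic map records, per chromosome, the physical length in bp and the
#' genetic length in cM, with a uniform recombination rate along each
#' chromosome (piecewise-linear overall). The default map covers the 22
#' GRCh37 autosomes at 1 cM per Mb.
#'
#' @param chrom_lengths data.frame with columns `chrom`, `length_bp` and
#'   optionally `length_cM` (default `length_bp * cM_per_Mb / 1e6`).
#' @param cM_per_Mb uniform rate used when `length_cM` is absent.
#' @return data.frame of class `genetic_map` with columns `chrom`,
#'   `length_bp`, `length_cM`.
#' @export
genetic_map <- function(chrom_lengths, cM_per_Mb = 1) {
  df <- as.data.frame(chrom_lengths, stringsAsFactors = FALSE)
  if (is.null(df$length_cM)) df$length_cM <- df$length_bp * cM_per_Mb / 1e6
  if (any(df$length_cM <= 0)) stop("chromosome genetic length must be > 0")
  df$chrom <- as.character(df$chrom)
  class(df) <- c("genetic_map", "data.frame")
  df
}

#' GRCh37 autosome lengths
#'
#' Physical lengths (bp) of chromosomes 1-22 on GRCh37/hg19.
#'
#' @return data.frame with columns `chrom`, `length_bp`.
#' @export
grch37_autosomes <- function() {
  data.frame(
    chrom = as.character(1:22),
    length_bp = c(249250621, 243199373, 198022430, 191154276, 180915260,
                  171115067, 159138663, 146364022, 141213431, 135534747,
                  135006516, 133851895, 115169878, 107349540, 102531392,
                  90354753, 81195210, 78077248, 59128983, 63025520,
                  48129895, 51304566),
    stringsAsFactors = FALSE)
}

#' @rdname genetic_map
#' @export
default_genetic_map <- function() genetic_map(grch37_autosomes())

#' Convert physical to genetic coordinates (and back)
#'
#' Linear within each chromosome between (1 bp, 0 cM) and
#' (`length_bp`, `length_cM`).
#'
#' @param map a [genetic_map].
#' @param chrom chromosome name.
#' @param bp,cM positions to convert.
#' @return numeric positions.
#' @export
bp_to_cM <- function(map, chrom, bp) {
  row <- map[map$chrom == chrom, ]
  if (nrow(row) != 1) stop("chromosome not in map: ", chrom)
  bp * row$length_cM / row$length_bp
}

#' @rdname bp_to_cM
#' @export
cM_to_bp <- function(map, chrom, cM) {
  row <- map[map$chrom == chrom, ]
  if (nrow(row) != 1) stop("chromosome not in map: ", chrom)
  cM * row$length_bp / row$length_cM
}

#' Gene-drop configuration
#'
#' @param n_reps number of gene-dropping replicates.
#' @param seed RNG seed; a single seeded generator drives all replicates in
#'   sequence, so a run with fewer replicates reproduces a prefix of a
#'   longer run.
#' @param window optional list/vector `(chrom, start_cM, end_cM)`;
#'   `start_cM == end_cM` queries a point locus.
#' @return list of class `drop_config`.
#' @export
drop_config <- function(n_reps = 10000, seed = 1, window = NULL) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  if (!is.null(window)) {
    window <- list(chrom = as.character(window[[1]]),
                   start_cM = as.numeric(window[[2]]),
                   end_cM = as.numeric(window[[3]]))
    if (window$end_cM < window$start_cM) stop("window end before start")
  }
  structure(list(n_reps = as.integer(n_reps), seed = as.integer(seed),
                 window = window), class = "drop_config")
}

# haplotype representation: list(end, lab) where `end` are increasing
# segment right-endpoints in cM (last == chromosome length) and `lab`
# founder-haplotype labels; segment i covers (end[i-1], end[i]].
new_hap <- function(end, lab) list(end = end, lab = lab)

merge_hap_runs <- function(end, lab) {
  n <- length(lab)
  if (n > 1) {
    keep <- c(lab[-1] != lab[-n], TRUE)
    end <- end[keep]; lab <- lab[keep]
  }
  new_hap(end, lab)
}

#' Simulate one gamete from a parental haplotype pair
#'
#' Haldane (no-interference) model: the crossover count is Poisson with
#' mean equal to the chromosome length in Morgans, breakpoints are uniform
#' in genetic distance, and the starting haplotype is chosen with
#' probability 1/2. The returned haplotype tiles the chromosome.
#'
#' @param h1,h2 parental haplotypes: lists with elements `end` (increasing
#'   segment endpoints in cM, last equal to the chromosome length) and
#'   `lab` (integer founder-haplotype labels).
#' @param length_cM chromosome genetic length.
#' @return a haplotype in the same representation.
#' @export
simulate_gamete <- function(h1, h2, length_cM) {
  src <- if (stats::runif(1) < 0.5) 1L else 2L
  k <- stats::rpois(1L, length_cM / 100)
  if (k == 0L) return(if (src == 1L) h1 else h2)
  cuts <- sort(stats::runif(k, 0, length_cM))
  haps <- list(h1, h2)
  ends <- numeric(0); labs <- integer(0)
  lo <- 0
  for (b in c(cuts, length_cM)) {
    if (b > lo) {
      h <- haps[[src]]
      i1 <- findInterval(lo, h$end) + 1L            # first end > lo
      i2 <- findInterval(b, h$end, left.open = TRUE) + 1L  # first end >= b
      e <- h$end[i1:i2]
      e[length(e)] <- b
      ends <- c(ends, e); labs <- c(labs, h$lab[i1:i2])
    }
    src <- 3L - src
    lo <- b
  }
  merge_hap_runs(ends, labs)
}

# one gene-dropping replicate: founder haplotypes labelled 1..2F, every
# non-founder built from its parents' gametes in generation order
drop_once <- function(ped, map, chroms = map$chrom) {
  ids <- ped$id
  founder <- is_founder(ped)
  hap_label <- matrix(NA_integer_, nrow(ped), 2, dimnames = list(ids, NULL))
  hap_label[founder, 1] <- 2L * seq_len(sum(founder)) - 1L
  hap_label[founder, 2] <- 2L * seq_len(sum(founder))
  ord <- ids[order(attr(ped, "depth"))]
  state <- lapply(setNames(chroms, chroms), function(ch) {
    L <- map$length_cM[map$chrom == ch]
    chrom_state <- vector("list", length(ids))
    names(chrom_state) <- ids
    for (id in ord) {
      if (founder[ids == id]) {
        chrom_state[[id]] <- list(h1 = new_hap(L, hap_label[id, 1]),
                                  h2 = new_hap(L, hap_label[id, 2]))
      } else {
        fa <- state_parent(chrom_state, ped[id, "father"])
        mo <- state_parent(chrom_state, ped[id, "mother"])
        chrom_state[[id]] <- list(h1 = simulate_gamete(fa$h1, fa$h2, L),
                                  h2 = simulate_gamete(mo$h1, mo$h2, L))
      }
    }
    chrom_state
  })
  structure(list(state = state, founder_labels = hap_label),
            class = "founder_label_state")
}

state_parent <- function(chrom_state, pid) {
  s <- chrom_state[[pid]]
  if (is.null(s)) stop("missing parent state for ", pid)
  s
}

#' Gene dropping through a pedigree
#'
#' Simulates meioses with recombination ([simulate_gamete()]) through the
#' pedigree, assigning two distinct founder-haplotype labels to every
#' founder and transmitting label segments to descendants. Intended for
#' small replicate counts when the full per-individual states are wanted;
#' summaries over many replicates (e.g.
#' [shared_autozygosity_probability()]) loop internally without storing
#' states.
#'
#' @param ped a [pedigree].
#' @param map a [genetic_map].
#' @param cfg a [drop_config]; `cfg$n_reps` replicate states are returned.
#' @param chroms chromosomes to simulate (default: all autosomes in the
#'   map).
#' @return list of `founder_label_state` replicates; each holds
#'   `state[[chrom]][[id]]$h1/h2` haplotypes and the founder label matrix.
#' @export
gene_drop <- function(ped, map = default_genetic_map(), cfg = drop_config(),
                      chroms = map$chrom) {
  set.seed(cfg$seed)
  lapply(seq_len(cfg$n_reps), function(r) drop_once(ped, map, chroms))
}

# labels seen in (a, b) on a haplotype; a == b queries the point a
hap_labels_window <- function(hap, a, b) {
  if (a == b) {
    i <- findInterval(a, hap$end, left.open = TRUE) + 1L
    return(hap$lab[min(i, length(hap$lab))])
  }
  prev <- c(0, hap$end[-length(hap$end)])
  unique(hap$lab[hap$end > a & prev < b])
}

# is every haplotype single-labelled across the window with all labels
# equal (strict) / per-individual equal (relaxed)?
window_autozygous <- function(st, ids, window, relaxed) {
  chrom_state <- st$state[[window$chrom]]
  labs <- lapply(ids, function(id) {
    s <- chrom_state[[id]]
    list(hap_labels_window(s$h1, window$start_cM, window$end_cM),
         hap_labels_window(s$h2, window$start_cM, window$end_cM))
  })
  if (any(vapply(labs, function(l) length(l[[1]]) != 1 ||
                 length(l[[2]]) != 1, logical(1))))
    return(FALSE)
  per_ind <- vapply(labs, function(l) {
    if (l[[1]] != l[[2]]) NA_integer_ else l[[1]]
  }, integer(1))
  if (anyNA(per_ind)) return(FALSE)
  if (relaxed) TRUE else length(unique(per_ind)) == 1
}

#' Probability of shared identical autozygosity across a window
#'
#' Monte-Carlo estimate, over gene-dropping replicates, of the probability
#' that the given individuals are identically homozygous by descent across
#' an entire genomic window: in the strict (default) mode all of their
#' allele copies must carry the same single founder-haplotype label across
#' the window; in the relaxed mode each individual only needs to be
#' autozygous, possibly to different founders. With a single id (or a pair
#' of identical ids) and a zero-length window this estimates the
#' point-locus autozygosity probability, which converges to the pedigree
#' inbreeding coefficient.
#'
#' Only the chromosome carrying the window is simulated: under the
#' no-interference model chromosomes segregate independently, so the
#' estimator is unchanged.
#'
#' @param ped a [pedigree].
#' @param ids one or two individual ids.
#' @param cfg a [drop_config] whose `window` is set.
#' @param map a [genetic_map].
#' @param relaxed use the relaxed definition (see above).
#' @return list with `estimate`, `se` (binomial Monte-Carlo standard
#'   error), `hits`, `n_reps`.
#' @export
shared_autozygosity_probability <- function(ped, ids, cfg,
                                            map = default_genetic_map(),
                                            relaxed = FALSE) {
  if (is.null(cfg$window)) stop("cfg$window is required")
  if (!all(ids %in% ped$id)) stop("id not in pedigree")
  if (!(cfg$window$chrom %in% map$chrom)) stop("window chromosome not in map")
  L <- map$length_cM[map$chrom == cfg$window$chrom]
  if (cfg$window$end_cM > L) stop("window beyond chromosome end")
  ids <- unique(ids)
  set.seed(cfg$seed)
  hits <- 0L
  for (r in seq_len(cfg$n_reps)) {
    st <- drop_once(ped, map, chroms = cfg$window$chrom)
    if (window_autozygous(st, ids, cfg$window, relaxed)) hits <- hits + 1L
  }
  p <- hits / cfg$n_reps
  list(estimate = p, se = sqrt(p * (1 - p) / cfg$n_reps),
       hits = hits, n_reps = cfg$n_reps)
}

#' Realized inbreeding of one individual in a replicate
#'
#' Fraction of the simulated genome (in cM) where the individual's two
#' haplotypes carry the same founder label; averaged over replicates this
#' converges to the pedigree inbreeding coefficient.
#'
#' @param st a `founder_label_state` from [gene_drop()].
#' @param id individual id.
#' @return fraction in `[0, 1]`.
#' @export
realized_inbreeding <- function(st, id) {
  tot <- 0; auto <- 0
  for (chrom_state in st$state) {
    s <- chrom_state[[id]]
    ends <- sort(unique(c(s$h1$end, s$h2$end)))
    prev <- c(0, ends[-length(ends)])
    mids <- (prev + ends) / 2
    l1 <- s$h1$lab[findInterval(mids, s$h1$end, left.open = TRUE) + 1L]
    l2 <- s$h2$lab[findInterval(mids, s$h2$end, left.open = TRUE) + 1L]
    tot <- tot + ends[length(ends)]
    auto <- auto + sum((ends - prev)[l1 == l2])
  }
  auto / tot
}
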