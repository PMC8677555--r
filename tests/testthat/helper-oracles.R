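# Independent brute-force oracles used to freeze expected values.

# Exact kinship by exhaustive enumeration of inheritance vectors: every
# non-founder has two binary meiosis choices; phi(i, j) is the average over
# all 4^m assignments of the probability that one randomly drawn allele
# from each individual is the same founder allele.
oracle_kinship_enum <- function(ped, i, j) {
  ids <- ped$id
  fa <- setNames(ped$father, ids)
  mo <- setNames(ped$mother, ids)
  nf <- ids[order(attr(ped, "depth"))]
  nf <- nf[!is.na(fa[nf])]
  m <- length(nf)
  stopifnot(m <= 8)  # 4^8 = 65536 assignments
  founders <- ids[is.na(fa[ids])]
  lab <- matrix(NA_integer_, length(ids), 2, dimnames = list(ids, NULL))
  lab[founders, 1] <- 2 * seq_along(founders) - 1
  lab[founders, 2] <- 2 * seq_along(founders)
  total <- 0
  for (v in 0:(4^m - 1)) {
    bits <- (v %/% 4^(seq_len(m) - 1)) %% 4
    l <- lab
    for (k in seq_len(m)) {
      id <- nf[k]
      pat <- bits[k] %% 2; mat <- bits[k] %/% 2
      l[id, 1] <- l[fa[[id]], pat + 1]
      l[id, 2] <- l[mo[[id]], mat + 1]
    }
    total <- total + mean(outer(l[i, ], l[j, ], "=="))
  }
  total / 4^m
}

# Exact HWE P-value by enumerating every placement of the minor alleles
# among the 2n ordered allele slots (all placements equally likely given
# the allele counts); diploids are consecutive slot pairs.
oracle_hwe_enum <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  minor <- 2 * min(n_AA, n_aa) + n_Aa
  slots <- 2 * n
  placements <- utils::combn(slots, minor)
  het_of <- function(cols) {
    x <- logical(slots); x[cols] <- TRUE
    sum(x[seq(1, slots, 2)] != x[seq(2, slots, 2)])
  }
  hets <- apply(placements, 2, het_of)
  tab <- table(hets) / ncol(placements)
  p_obs <- tab[as.character(n_Aa)]
  sum(tab[tab <= p_obs * (1 + 1e-9)])
}

# Brute-force ROH scan: every homozygous-bounded window with at most
# `het_tolerance` heterozygous calls, kept only if maximal and passing the
# marker-count and length thresholds. O(n^2), panels <= ~500 markers.
oracle_roh_bruteforce <- function(g, bp, p) {
  n <- length(g)
  hom <- which(!is.na(g) & g != 1)
  is_het <- !is.na(g) & g == 1
  chet <- cumsum(is_het)
  nhet <- function(i, j) chet[j] - chet[i]  # hets strictly inside (i, j]
  valid <- function(i, j) nhet(i, j) - is_het[j] <= p$het_tolerance
  cand <- list()
  for (i in hom) for (j in hom[hom >= i]) {
    if (!valid(i, j)) next
    cand[[length(cand) + 1]] <- c(i, j)
  }
  keep <- vapply(cand, function(w) {
    left <- hom[hom < w[1]]
    right <- hom[hom > w[2]]
    (!length(left) || !valid(max(left), w[2])) &&
      (!length(right) || !valid(w[1], min(right)))
  }, logical(1))
  cand <- cand[keep]
  res <- lapply(cand, function(w) {
    nm <- sum(!is.na(g[w[1]:w[2]]) & g[w[1]:w[2]] != 1)
    if (nm >= p$min_snps && (bp[w[2]] - bp[w[1]]) >= p$min_length_bp)
      data.frame(start_bp = bp[w[1]], end_bp = bp[w[2]], n_markers = nm)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) data.frame(start_bp = integer(0), end_bp = integer(0),
                               n_markers = integer(0))
  else unique(out[order(out$start_bp), , drop = FALSE])
}

# One-sided hypergeometric P by explicit enumeration over all tables with
# the observed margins.
oracle_hypergeom_enum <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; N <- a + b + c + d
  avals <- max(0, r1 + c1 - N):min(r1, c1)
  probs <- choose(c1, avals) * choose(N - c1, r1 - avals) / choose(N, r1)
  sum(probs[avals >= a])
}
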