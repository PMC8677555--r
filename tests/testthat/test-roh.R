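# dosage run helpers: 0/2 homozygous, 1 het, NA missing
run_calls <- function(...) matrix(c(...), nrow = 1,
                                  dimnames = list("s1", NULL))

test_that("a clean homozygous run is detected with exact boundaries", {
  n <- 60
  bp <- seq(10e6, by = 25000, length.out = n)  # spans 1.475 Mb
  gm <- gm_from_calls(run_calls(rep(2, n)), bp = bp)
  r <- detect_roh(gm, "s1")
  expect_equal(nrow(r), 1)
  expect_equal(r$start_bp, bp[1])
  expect_equal(r$end_bp, bp[n])
  expect_equal(r$n_markers, n)
  expect_equal(r$length_bp, bp[n] - bp[1])
})

test_that("embedded heterozygous calls break runs at zero tolerance", {
  # 49 homozygous markers + 2 embedded hets across >1 Mb: the classic
  # false-ROH artefact; with strict settings no region is emitted
  g <- rep(2, 51); g[c(17, 34)] <- 1
  bp <- seq(5e6, by = 30000, length.out = 51)
  gm <- gm_from_calls(run_calls(g), bp = bp)
  expect_equal(nrow(detect_roh(gm, "s1", roh_params(min_snps = 50))), 0)
  # erasing hets (tolerance 2) manufactures the false region
  lax <- detect_roh(gm, "s1", roh_params(min_snps = 49, het_tolerance = 2))
  expect_equal(nrow(lax), 1)
  expect_equal(lax$n_markers, 49)
})

test_that("length and marker-count thresholds both gate detection", {
  # 120 homozygous markers in only 0.8 Mb: marker count passes, length fails
  bp <- seq(1e6, by = 6700, length.out = 120)
  gm <- gm_from_calls(run_calls(rep(0, 120)), bp = bp)
  expect_equal(nrow(detect_roh(gm, "s1")), 0)
  expect_equal(nrow(detect_roh(gm, "s1", roh_params(min_length_bp = 5e5))), 1)
})

test_that("missing calls neither break runs nor count as markers", {
  g <- rep(2, 60); g[c(10, 30, 31)] <- NA
  bp <- seq(1e6, by = 25000, length.out = 60)
  gm <- gm_from_calls(run_calls(g), bp = bp)
  r <- detect_roh(gm, "s1", roh_params(min_snps = 50))
  expect_equal(nrow(r), 1)
  expect_equal(r$n_markers, 57)
  # a long missing gap splits the run when max_missing_run is set
  r2 <- detect_roh(gm, "s1", roh_params(min_snps = 10, min_length_bp = 1e5,
                                        max_missing_run = 1))
  expect_equal(nrow(r2), 2)
})

test_that("scan equals the brute-force all-substrings oracle", {
  set.seed(8)
  p_list <- list(roh_params(min_snps = 5, min_length_bp = 2e5),
                 roh_params(min_snps = 5, min_length_bp = 2e5,
                            het_tolerance = 1),
                 roh_params(min_snps = 3, min_length_bp = 1e5,
                            het_tolerance = 2))
  for (rep in 1:8) {
    n <- sample(80:300, 1)
    g <- sample(c(0, 1, 2, NA), n, replace = TRUE,
                prob = c(0.35, 0.2, 0.35, 0.1))
    bp <- sort(sample.int(5e6, n)) + 1e6
    gm <- gm_from_calls(matrix(g, 1, dimnames = list("s1", NULL)), bp = bp)
    for (p in p_list) {
      got <- detect_roh(gm, "s1", p)
      want <- oracle_roh_bruteforce(g, bp, p)
      got <- got[order(got$start_bp, got$end_bp), ]
      want <- want[order(want$start_bp, want$end_bp), ]
      expect_equal(nrow(got), nrow(want))
      expect_equal(got$start_bp, want$start_bp)
      expect_equal(got$end_bp, want$end_bp)
      expect_equal(got$n_markers, want$n_markers)
    }
  }
})

test_that("every emitted region satisfies its own thresholds", {
  set.seed(13)
  p <- roh_params(min_snps = 8, min_length_bp = 3e5, het_tolerance = 1)
  for (rep in 1:5) {
    g <- sample(c(0, 1, 2, NA), 400, replace = TRUE,
                prob = c(0.4, 0.1, 0.4, 0.1))
    gm <- gm_from_calls(matrix(g, 1, dimnames = list("s1", NULL)),
                        bp = sort(sample.int(8e6, 400)))
    r <- detect_roh(gm, "s1", p)
    if (nrow(r)) {
      expect_true(all(r$n_markers >= p$min_snps))
      expect_true(all(r$length_bp >= p$min_length_bp))
      expect_true(all(r$end_bp > r$start_bp))
    }
  }
})

test_that("raising thresholds never adds regions (monotonicity)", {
  set.seed(21)
  g <- sample(c(0, 1, 2), 500, replace = TRUE, prob = c(0.45, 0.1, 0.45))
  gm <- gm_from_calls(matrix(g, 1, dimnames = list("s1", NULL)),
                      bp = sort(sample.int(9e6, 500)))
  loose <- detect_roh(gm, "s1", roh_params(min_snps = 5, min_length_bp = 1e5))
  for (ms in c(8, 15)) for (ml in c(2e5, 5e5)) {
    tight <- detect_roh(gm, "s1", roh_params(min_snps = ms,
                                             min_length_bp = ml))
    expect_lte(nrow(tight), nrow(loose))
    key <- function(d) paste(d$start_bp, d$end_bp)
    expect_true(all(key(tight) %in% key(loose)))
  }
})

test_that("shared regions require identical homozygous genotypes", {
  n <- 55
  bp <- seq(1e6, by = 25000, length.out = n)
  both_hom <- rbind(a = rep(2, n), b = rep(2, n))
  gm <- gm_from_calls(both_hom, bp = bp)
  r <- shared_identical_regions(gm, c("a", "b"))
  expect_equal(nrow(r), 1)
  expect_equal(r$members[[1]], c("a", "b"))

  # opposite homozygotes at an internal marker split the run
  opp <- both_hom; opp["b", 28] <- 0
  r2 <- shared_identical_regions(gm_from_calls(opp, bp = bp), c("a", "b"))
  expect_equal(nrow(r2), 0)

  expect_error(shared_identical_regions(gm, "a"), "at least two")
})

test_that("restricting the case set can recover a region lost to a third case", {
  n <- 60
  bp <- seq(1e6, by = 25000, length.out = n)
  calls <- rbind(a = rep(2, n), b = rep(2, n), c = rep(2, n))
  calls["c", 30] <- 1  # third case heterozygous inside
  gm <- gm_from_calls(calls, bp = bp)
  expect_equal(nrow(shared_identical_regions(gm, c("a", "b", "c"))), 0)
  pair <- shared_identical_regions(gm, c("a", "b"))
  expect_equal(nrow(pair), 1)
})

test_that("shared regions are contained in each case's own ROH", {
  fx <- family_fixtures()
  gm <- generate_family_genotypes(
    fx$"AM-CD", synth_config(seed = 17),
    plants = list(plant_spec("3", 20e6, 23e6, c("V-1", "V-3"))))
  p <- roh_params(min_snps = 20, min_length_bp = 5e5)
  shared <- shared_identical_regions(gm, c("V-1", "V-3"), p)
  expect_gt(nrow(shared), 0)
  for (s in c("V-1", "V-3")) {
    own <- detect_roh(gm, s, p)
    for (i in seq_len(nrow(shared))) {
      hit <- own$chrom == shared$chrom[i] &
        own$start_bp <= shared$start_bp[i] & own$end_bp >= shared$end_bp[i]
      expect_true(any(hit), label = paste("containment", s, i))
    }
  }
})

test_that("control overlap annotation lists and optionally excludes", {
  n <- 60
  bp <- seq(1e6, by = 25000, length.out = n)
  calls <- rbind(case1 = rep(2, n), case2 = rep(2, n),
                 ctrl_hom = rep(2, n), ctrl_het = rep(c(1, 0), n / 2))
  gm <- gm_from_calls(calls, bp = bp)
  r <- shared_identical_regions(gm, c("case1", "case2"))
  ann <- annotate_control_overlap(r, gm, c("ctrl_hom", "ctrl_het"))
  expect_equal(ann$control_overlaps[[1]], "ctrl_hom")
  excl <- annotate_control_overlap(r, gm, c("ctrl_hom"), exclude = TRUE)
  expect_equal(nrow(excl), 0)
  none <- annotate_control_overlap(r, gm, c("ctrl_het"))
  expect_equal(length(none$control_overlaps[[1]]), 0)
  expect_equal(roh_table(none)$control_overlaps, "None")
})

test_that("genome ROH fraction matches trivial cases and pedigree F", {
  n <- 100
  bp <- seq(1, by = 101010, length.out = n)  # ~10 Mb chromosome
  het <- gm_from_calls(matrix(rep(1, n), 1, dimnames = list("s1", NULL)),
                       bp = bp)
  expect_equal(genome_roh_fraction(het, "s1"), 0)
  hom <- gm_from_calls(matrix(rep(2, n), 1, dimnames = list("s1", NULL)),
                       bp = bp)
  expect_equal(genome_roh_fraction(hom, "s1", roh_params(min_snps = 50)), 1)

  # offspring of first cousins: mean fraction over seeds ~ F = 1/16
  fc <- make_first_cousins()
  fr <- vapply(1:6, function(s) {
    gm <- generate_family_genotypes(fc, synth_config(
      n_markers = 12000, seed = s, genotype_error_rate = 0,
      missing_rate = 0))
    genome_roh_fraction(gm, "kid", roh_params(min_snps = 25,
                                              min_length_bp = 5e5))
  }, numeric(1))
  expect_lt(abs(mean(fr) - 1 / 16), 0.025)
})

test_that("gene and GWAS-locus annotation respects interval boundaries", {
  r <- structure(data.frame(chrom = "16", start_bp = 48846170,
                            end_bp = 51468005,
                            length_bp = 51468005 - 48846170,
                            n_markers = 359, stringsAsFactors = FALSE),
                 class = c("roh_regions", "data.frame"))
  r$members <- list(c("V-1", "III-2"))
  genes <- data.frame(
    symbol = c("inside", "spanning", "abutting_after", "before"),
    chrom = "16",
    start_bp = c(49000000, 48000000, 51468006, 40000000),
    end_bp = c(49100000, 52000000, 51600000, 41000000),
    stringsAsFactors = FALSE)
  out <- genes_in_regions(r, genes)
  expect_setequal(out$genes[[1]], c("inside", "spanning"))

  snps <- data.frame(id = c("rs_mid", "rs_before"), chrom = "16",
                     bp = c(50000000, 48846169), stringsAsFactors = FALSE)
  out2 <- gwas_loci_in_regions(out, snps)
  expect_equal(out2$gwas_hits[[1]], "rs_mid")
  empty <- gwas_loci_in_regions(out, snps[0, ])
  expect_equal(length(empty$gwas_hits[[1]]), 0)
  expect_equal(roh_table(empty)$gwas_hits, "No IBD GWAS loci")
})

test_that("region counting matches a planted 13-of-20 gene panel", {
  r <- structure(data.frame(chrom = "16", start_bp = 48846170,
                            end_bp = 51468005,
                            length_bp = 51468005 - 48846170,
                            n_markers = 359, stringsAsFactors = FALSE),
                 class = c("roh_regions", "data.frame"))
  r$members <- list("V-1")
  set.seed(4)
  inside <- data.frame(symbol = sprintf("IN%d", 1:13), chrom = "16",
                       start_bp = round(seq(48.9e6, 51.3e6, length.out = 13)))
  outside <- data.frame(symbol = sprintf("OUT%d", 1:7), chrom = "16",
                        start_bp = seq(20e6, 40e6, length.out = 7))
  genes <- rbind(inside, outside)
  genes$end_bp <- genes$start_bp + 5e4
  out <- genes_in_regions(r, genes)
  expect_equal(length(out$genes[[1]]), 13)
  expect_true(all(grepl("^IN", out$genes[[1]])))
})

test_that("BED round trip converts between half-open and inclusive", {
  genes <- data.frame(symbol = c("g1", "g2"), chrom = c("1", "2"),
                      start_bp = c(1001, 5001), end_bp = c(2000, 9000),
                      stringsAsFactors = FALSE)
  gr <- GenomicRanges::GRanges(genes$chrom,
          IRanges::IRanges(genes$start_bp, genes$end_bp), name = genes$symbol)
  path <- tempfile(fileext = ".bed")
  rtracklayer::export(gr, path, format = "BED")
  bed_lines <- read.table(path, sep = "\t")
  expect_equal(bed_lines$V2, c(1000, 5000))  # 0-based starts on disk
  back <- read_gene_bed(path)
  expect_equal(back$start_bp, genes$start_bp)
  expect_equal(back$end_bp, genes$end_bp)
})
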