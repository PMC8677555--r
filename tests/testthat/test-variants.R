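mini_vs <- function(info_extra = list(), gt = NULL, samples = c("p", "s"),
                    n = 1) {
  info <- data.frame(chrom = "1", pos = seq_len(n) * 100, ref = "A",
                     alt = "G", consequence = "missense",
                     sift = "deleterious", polyphen = "benign", cadd = NA,
                     gene = "G1", maf_gnomad = 0.004, maf_gmev = 0.004,
                     pass = FALSE, tranche = 99.0, stringsAsFactors = FALSE)
  for (nm in names(info_extra)) info[[nm]] <- info_extra[[nm]]
  if (is.null(gt)) gt <- matrix(2, n, length(samples),
                                dimnames = list(NULL, samples))
  variant_set(info, gt)
}

test_that("site filter honours tranche ceilings and pass flags", {
  info <- data.frame(chrom = "1", pos = 1:4, ref = c("A", "A", "AT", "A"),
                     alt = c("G", "G", "A", "G"),
                     tranche = c(99.6, 99.5, 99.0, NA),
                     pass = c(FALSE, FALSE, FALSE, TRUE),
                     stringsAsFactors = FALSE)
  vs <- variant_set(info, matrix(0, 4, 1, dimnames = list(NULL, "s")))
  kept <- site_filter(vs)$info
  expect_equal(kept$pos, 2:4)  # 99.6 SNP dropped; indel at 99.0 kept (<=)
  # no tranche, no pass flag -> dropped
  vs2 <- variant_set(data.frame(chrom = "1", pos = 9, ref = "A", alt = "G",
                                stringsAsFactors = FALSE),
                     matrix(0, 1, 1, dimnames = list(NULL, "s")))
  expect_equal(nrow(site_filter(vs2)$info), 0)
})

test_that("allele balance P matches the 1-df chi-squared closed form", {
  expect_equal(allele_balance_p(10, 10), 1)
  # (30, 0): chi2 = 30, far below 0.001
  expect_lt(allele_balance_p(30, 0), 0.001)
  expect_equal(allele_balance_p(30, 0),
               stats::pchisq(30, 1, lower.tail = FALSE))
  # (18, 7): chi2 = 4.84, P ~ 0.028 -> passes
  expect_gt(allele_balance_p(18, 7), 0.001)
  expect_equal(allele_balance_p(18, 7),
               stats::pchisq((18 - 7)^2 / 25, 1, lower.tail = FALSE))
  expect_error(allele_balance_p(0, 0), "zero total")
})

test_that("genotype filter no-calls failing calls and leaves the rest", {
  t <- filter_thresholds()
  expect_true(is.na(filter_genotype_call(1, gq = 29, 15, 15, t)))
  expect_true(is.na(filter_genotype_call(2, gq = 99, 0, 2, t)))
  expect_equal(filter_genotype_call(0, gq = 99, 30, 0, t), 0)
  expect_equal(filter_genotype_call(1, gq = 35, 14, 16, t), 1)
  # het with extreme allele imbalance
  expect_true(is.na(filter_genotype_call(1, gq = 99, 40, 3, t)))
  # hom-ref ignores alt-depth rule
  expect_equal(filter_genotype_call(0, gq = 99, 10, 0, t), 0)
})

test_that("no-call-rate filter keeps variants strictly below 0.25", {
  gt <- rbind(c(rep(NA, 3), rep(0, 7)),   # 0.30 -> dropped
              c(rep(NA, 2), rep(0, 8)),   # 0.20 -> kept
              rep(0, 10))                 # kept
  colnames(gt) <- paste0("s", 1:10)
  info <- data.frame(chrom = "1", pos = 1:3, ref = "A", alt = "G",
                     stringsAsFactors = FALSE)
  out <- no_call_filter(variant_set(info, gt))
  expect_equal(out$info$pos, 2:3)
})

test_that("frequency class applies the dual-population least-rare rule", {
  vs <- mini_vs(list(maf_gnomad = c(0.0054, NA, 0.0072, 0.06, 0.015),
                     maf_gmev = c(0.0044, NA, 0.0146, 0.001, NA)), n = 5)
  cls <- frequency_class(vs, c("gnomad", "gmev"))
  expect_equal(as.character(cls),
               c("rare", "very_rare", "uncommon", "common", "uncommon"))
  # boundary points: 0.01 is uncommon, 0.05 is common, 0.001 is rare
  vb <- mini_vs(list(maf_gnomad = c(0.01, 0.05, 0.001),
                     maf_gmev = c(0, 0, 0)), n = 3)
  expect_equal(as.character(frequency_class(vb, c("gnomad", "gmev"))),
               c("uncommon", "common", "rare"))
})

test_that("frequency class is monotone in any population MAF", {
  set.seed(3)
  for (k in 1:40) {
    m1 <- runif(1, 0, 0.1); m2 <- runif(1, 0, 0.1)
    bump <- runif(1, 0, 0.05)
    a <- mini_vs(list(maf_gnomad = m1, maf_gmev = m2))
    b <- mini_vs(list(maf_gnomad = m1 + bump, maf_gmev = m2))
    expect_gte(as.integer(frequency_class(b, c("gnomad", "gmev"))),
               as.integer(frequency_class(a, c("gnomad", "gmev"))))
  }
})

test_that("damaging classification follows consequence and predictor gates", {
  dmg <- function(...) is_damaging(mini_vs(list(...)))
  expect_true(dmg(consequence = "stop_gained", sift = "unknown",
                  polyphen = "unknown"))                    # LoF gate
  expect_true(dmg(sift = "tolerated", polyphen = "benign", cadd = 23.9))
  expect_true(dmg(sift = "deleterious_lc", polyphen = "benign",
                  cadd = 3.083))                            # SIFT LC counts
  expect_true(dmg(sift = "tolerated", polyphen = "possibly_damaging",
                  cadd = 1))
  expect_false(dmg(sift = "tolerated", polyphen = "benign", cadd = 19))
  expect_false(dmg(consequence = "synonymous", cadd = 25))  # consequence gate
  expect_false(dmg(sift = "tolerated", polyphen = "benign", cadd = 20))
})

test_that("every reported prioritised variant is damaging and sub-common", {
  vs <- reported_variant_fixture()
  expect_equal(nrow(vs$info), 19)
  expect_true(all(is_damaging(vs)))
  cls <- frequency_class(vs, c("gnomad", "pop"))
  expect_true(all(cls <= "uncommon"))
  # spot-check classes against the printed MAFs
  byg <- setNames(as.character(cls), vs$info$gene)
  expect_equal(byg[["C5"]], "rare")
  expect_equal(byg[["DENND3"]], "very_rare")
  expect_equal(byg[["PTGS1"]], "uncommon")  # rarer population cannot rescue
  expect_equal(byg[["DMBT1"]], "uncommon")
})

test_that("proband candidate selection needs hom-alt, damaging, sub-common", {
  gt <- matrix(c(2, 1, 2, 2), 4, 1, dimnames = list(NULL, "p"))
  vs <- mini_vs(list(maf_gnomad = c(0.004, 0.004, 0.004, 0.06),
                     maf_gmev = 0.004,
                     sift = c("deleterious", "deleterious", "tolerated",
                              "deleterious"),
                     polyphen = "benign", cadd = c(NA, NA, 3, NA)),
                gt = gt, samples = "p", n = 4)
  out <- proband_candidates(vs, "p", c("gnomad", "gmev"))
  expect_equal(out$info$pos, 100)   # het, not-damaging, common all excluded
  expect_equal(out$info$freq_class, "rare")
  expect_error(proband_candidates(vs, "zz", c("gnomad", "gmev")),
               "not genotyped")
})

test_that("segregation filter counts case and control homozygotes", {
  gt <- rbind(c(2, 2, 0, 0, 0),
              c(2, 1, 0, 0, 0),
              c(2, 2, 2, 0, 0))
  colnames(gt) <- c("sib1", "sib2", "ctrl1", "ctrl2", "ctrl3")
  info <- data.frame(chrom = "1", pos = 1:3, ref = "A", alt = "G",
                     stringsAsFactors = FALSE)
  vs <- variant_set(info, gt)
  all_rule <- segregation_rule("all")
  out <- segregation_filter(vs, all_rule, c("sib1", "sib2"),
                            c("ctrl1", "ctrl2", "ctrl3"))
  expect_equal(out$info$pos, c(1, 3))
  expect_equal(out$info$hom_controls, c("0/3", "1/3"))
  # 2-of-3 rule
  gt2 <- rbind(c(2, 2, 1, 0), c(2, 1, 1, 0))
  colnames(gt2) <- c("a", "b", "c", "ctrl")
  vs2 <- variant_set(info[1:2, ], gt2)
  out2 <- segregation_filter(vs2, segregation_rule(2), c("a", "b", "c"),
                             "ctrl")
  expect_equal(out2$info$pos, 1)
  # control exclusion
  out3 <- segregation_filter(vs, segregation_rule(
    "all", exclude_if_hom_controls = TRUE), c("sib1", "sib2"),
    c("ctrl1", "ctrl2", "ctrl3"))
  expect_equal(out3$info$pos, 1)
  expect_error(segregation_filter(vs, all_rule, "nope", "ctrl1"), "unknown")
})

test_that("deceased-parent homozygosity is excluded by a hom-ref descendant", {
  expect_equal(parent_genotype_constraint(c(0, 1)), "hom_alt_excluded")
  expect_equal(parent_genotype_constraint(c(1, 1)), "hom_alt_possible")
  expect_equal(parent_genotype_constraint(2), "hom_alt_possible")
  expect_equal(parent_genotype_constraint(c(NA, 0)), "hom_alt_excluded")
  expect_error(parent_genotype_constraint(NA), "no informative")
})

test_that("known-variant screen reports genotypes or absence", {
  gt <- matrix(c(2, 0, 1, NA), 2, 2,
               dimnames = list(NULL, c("case", "ctrl")))
  info <- data.frame(chrom = c("2", "2"), pos = c(100, 200), ref = "A",
                     alt = "G", stringsAsFactors = FALSE)
  vs <- variant_set(info, gt)
  panel <- data.frame(chrom = "2", pos = c(100, 999), ref = "A", alt = "G",
                      label = c("T300A_like", "absent_one"),
                      stringsAsFactors = FALSE)
  out <- known_variant_screen(vs, panel)
  expect_equal(out$case, c("hom_alt", "absent"))
  expect_equal(out$ctrl, c("het", "absent"))
  expect_equal(nrow(known_variant_screen(vs, panel[0, ])), 0)
})

test_that("a planted risk-panel variant is homozygous in cases and carriers", {
  # 3 cases + 5 controls homozygous, mirroring a common risk allele
  samples <- c(paste0("case", 1:3), paste0("ctrl", 1:7))
  gt <- matrix(0, 1, 10, dimnames = list(NULL, samples))
  gt[1, c(1:3, 4:8)] <- 2
  vs <- variant_set(data.frame(chrom = "2", pos = 234183368, ref = "A",
                               alt = "G", stringsAsFactors = FALSE), gt)
  panel <- data.frame(chrom = "2", pos = 234183368, ref = "A", alt = "G",
                      label = "T300A", stringsAsFactors = FALSE)
  out <- known_variant_screen(vs, panel)
  expect_equal(sum(out[1, -1] == "hom_alt"), 8)
})

test_that("the filter cascade is idempotent", {
  fx <- family_fixtures()
  sim <- generate_variant_table(
    fx$"AM-CD", synth_config(seed = 2),
    planted = list(list(gene = "CAND1", chrom = "2", pos = 1e6,
                        cases = c("V-1", "V-3"))),
    decoys = c("site_tranche", "low_gq", "not_damaging"),
    n_background = 60)
  t <- filter_thresholds()
  once <- no_call_filter(genotype_filter(site_filter(sim$variants, t), t), t)
  twice <- no_call_filter(genotype_filter(site_filter(once, t), t), t)
  expect_identical(once$info, twice$info)
  expect_identical(once$gt, twice$gt)
})
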