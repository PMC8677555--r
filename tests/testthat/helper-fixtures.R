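# Small pedigrees and genotype builders shared across tests.

ped_df <- function(...) {
  rows <- list(...)
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- c("id", "father", "mother", "sex", "affection")
  df$family <- "T"
  df[c("family", "id", "father", "mother", "sex", "affection")]
}

make_trio <- function() {
  pedigree(ped_df(c("dad", 0, 0, "male", "unaffected"),
                  c("mum", 0, 0, "female", "unaffected"),
                  c("kid", "dad", "mum", "male", "CD")))
}

# 4 grandparents, 2 sib parents of the cousins, the cousin couple, a child
make_first_cousins <- function() {
  pedigree(ped_df(
    c("g1", 0, 0, "male", "unaffected"),
    c("g2", 0, 0, "female", "unaffected"),
    c("p1", "g1", "g2", "male", "unaffected"),
    c("p2", "g1", "g2", "female", "unaffected"),
    c("s1", 0, 0, "female", "unaffected"),
    c("s2", 0, 0, "male", "unaffected"),
    c("c1", "p1", "s1", "male", "unaffected"),
    c("c2", "s2", "p2", "female", "unaffected"),
    c("kid", "c1", "c2", "male", "CD")))
}

# two sibships intermarrying: c1/c2 are double first cousins
make_double_first_cousins <- function() {
  pedigree(ped_df(
    c("af", 0, 0, "male", "unaffected"),
    c("am", 0, 0, "female", "unaffected"),
    c("bf", 0, 0, "male", "unaffected"),
    c("bm", 0, 0, "female", "unaffected"),
    c("a1", "af", "am", "male", "unaffected"),
    c("a2", "af", "am", "female", "unaffected"),
    c("b1", "bf", "bm", "female", "unaffected"),
    c("b2", "bf", "bm", "male", "unaffected"),
    c("c1", "a1", "b1", "male", "unaffected"),
    c("c2", "b2", "a2", "female", "unaffected"),
    c("kid", "c1", "c2", "female", "CD")))
}

# one-chromosome genotype matrix from a dosage matrix (samples x markers)
gm_from_calls <- function(calls, chrom = "1", bp = NULL, ref_maf = 0.3) {
  n <- ncol(calls)
  if (is.null(bp)) bp <- seq(1e6, by = 2e4, length.out = n)
  if (is.null(rownames(calls)))
    rownames(calls) <- paste0("s", seq_len(nrow(calls)))
  genotype_matrix(calls,
                  data.frame(id = paste0("m", seq_len(n)), chrom = chrom,
                             bp = bp, ref_maf = ref_maf,
                             stringsAsFactors = FALSE))
}

# reported prioritised-variant rows re-encoded as a variant_set fixture
reported_variant_fixture <- function() {
  path <- system.file("extdata", "prioritised_variants_reported.tsv",
                      package = "consangmap")
  tab <- read.table(path, header = TRUE, sep = "\t", na.strings = "-",
                    stringsAsFactors = FALSE)
  info <- data.frame(chrom = as.character(tab$chrom),
                     pos = seq_len(nrow(tab)) * 1000, ref = "A", alt = "G",
                     id = tab$rsid, gene = tab$gene,
                     consequence = tab$consequence, sift = tab$sift,
                     polyphen = tab$polyphen, cadd = tab$cadd,
                     maf_gnomad = tab$maf_gnomad, maf_pop = tab$maf_pop,
                     pass = TRUE, stringsAsFactors = FALSE)
  gt <- matrix(2, nrow(tab), 1, dimnames = list(NULL, "proband"))
  variant_set(info, gt)
}
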