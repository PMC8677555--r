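---
title: "Homozygosity mapping and variant prioritisation in consanguineous IBD families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homozygosity mapping and variant prioritisation in consanguineous IBD families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(consangmap)
```

## The analysis problem

Families with several cases of inflammatory bowel disease (IBD) and known
consanguinity are a natural place to look for rare, high-impact recessive
variation: recent inbreeding produces long runs of homozygosity (ROH), and a
recessive risk allele inherited through both sides of a consanguineous loop
will sit inside an ROH that is *shared and identical* among affected
relatives. `consangmap` implements the full desk side of such a study as
composable, testable pieces:

1. pedigree representation with exact kinship/inbreeding coefficients;
2. SNP-array quality control;
3. detection of ROH and of case-shared identical ROH, with control-overlap,
   gene and GWAS-locus annotation;
4. gene-dropping simulation with recombination, to ask how surprising an
   observed shared autozygous region is under the pedigree;
5. exome variant quality filtering and homozygous-candidate prioritisation;
6. exact 2x2 enrichment of ROH gene content against gene lists;
7. a synthetic-data generator so that every stage can be exercised
   end-to-end without any external download.

No genotype data from the motivating study design are distributed: all
bundled family structures are explicitly labelled reconstructions and all
genotypes are simulated.

## Pedigrees, kinship, inbreeding

A `pedigree` is a validated directed acyclic graph with sex, a three-state
affection phenotype (`CD`/`UC`/`unaffected`) so case sets can be restricted
by IBD subtype, and PLINK-FAM file dialect (`0` = absent parent; phenotype
column `1/2/3` = unaffected/CD/UC). The kinship coefficient
$\varphi(i,j)$ — the probability that one allele drawn from each individual
is identical by descent (IBD) — is computed by the classical recursion on
parents with founders assumed mutually unrelated and non-inbred:
$\varphi(i,i) = \tfrac12(1+F_i)$ and
$\varphi(i,j) = \tfrac12\{\varphi(i, \mathrm{fa}(j)) +
\varphi(i, \mathrm{mo}(j))\}$, descending always on the individual with the
larger generation depth so consanguineous loops terminate. The inbreeding
coefficient is $F_i = \varphi(\mathrm{fa}(i), \mathrm{mo}(i))$. The test
suite checks the recursion against an exhaustive inheritance-vector
enumeration oracle on small pedigrees (first cousins, double first
cousins).

Deeper relatedness than the recorded pedigree is modelled by *adding
ancestors*, never by assigning founder kinship — this mirrors the
"hypothetical pedigree" device used for the Druze reconstruction below.

## Array quality control

Defaults (`qc_thresholds()`): samples removed at >5% missingness *before*
markers are filtered; markers removed at >5% missingness, duplicate-id
(first kept), or Hardy–Weinberg exact-test $P < 5\times10^{-8}$. The HWE
test is the exact conditional test on the heterozygote count with
two-sided probability-mass ordering; it is validated against a
combinatorial enumeration oracle. HWE is computed on all retained samples
by default (a founders-only mode exists) — with a handful of small
families either choice is defensible and the threshold is so extreme that
only genotyping artefacts are caught.

Sex is inferred from the X-chromosome homozygosity rate of common markers
(males ≈ 1): `male` at rate ≥ 0.9, `female` at ≤ 0.8, `ambiguous` in the
deliberate gap between the cutoffs.

Relatedness is verified with a robust within-family estimator built from
shared heterozygosity and opposite homozygotes,
$$\hat\varphi = \frac{N_{Aa,Aa} - 2N_{AA,aa}}{N_{Aa}(i)+N_{Aa}(j)},$$
which needs no external allele frequencies and is robust to population
structure. A pair is flagged when expected and observed kinship fall in
different relationship-degree classes (boundaries $2^{-1.5}\dots2^{-4.5}$).
Caveat: the estimator assumes outbred individuals; strongly inbred pairs
have depressed heterozygosity and can be flagged spuriously, which is
worth knowing when reading reports for deeply consanguineous families.

## ROH detection and homozygosity mapping

The scan (`detect_roh`) operates on common markers (reference MAF > 0.05)
sorted by position and reports maximal runs of homozygous calls:

* a heterozygous call terminates a run unless the running heterozygote
  count stays within `het_tolerance`, which defaults to **0** — silently
  erasing isolated heterozygous calls is exactly how false ROH appear in
  marker-sparse regions, so error tolerance is explicit and off by
  default;
* missing calls neither terminate a run nor count toward its marker
  number; an optional `max_missing_run` splits runs across long no-call
  gaps (a guard for low-density regions);
* region boundaries are the first/last homozygous markers; region length
  is `end_bp - start_bp` (this is the arithmetic that reproduces reported
  region sizes, e.g. 51,468,005 − 48,846,170 → 2.6 Mb);
* a run is kept only with ≥ 50 homozygous markers *and* ≥ 1 Mb span. The
  50-marker floor is what rejects the classic artefact of a 49-marker
  "run" containing two erased heterozygous calls.

Case-shared mapping (`shared_identical_regions`) enforces genetic
homogeneity: a marker counts only when *every* case is homozygous for the
*same* allele; a heterozygous call in any case or opposite homozygotes
between cases breaks the run. Case sets are free parameters, so
subtype-restricted runs (CD-only, UC-only, all-IBD) and leave-one-out runs
are one-liners. The scan is verified against a brute-force all-substrings
oracle on panels up to 500 markers, and every emitted region is asserted
against its own thresholds.

Control overlap lists any unaffected control whose own ROH (same detector,
same parameters) covers ≥ 50% of a case region's length — the overlap
fraction is a config knob, since "overlapping" is not otherwise pinned
down — with an exclusion mode for analyses that do not allow incomplete
penetrance. Gene annotation treats BED input as 0-based half-open and
reports 1-based inclusive GRCh37-convention coordinates throughout.

## Gene dropping

Meioses are simulated under the Haldane (no-interference) model: the
crossover count on a chromosome is Poisson with mean equal to its genetic
length in Morgans and breakpoints are uniform in cM. The model choice is
deliberate: it is the standard neutral choice and is analytically
checkable (e.g. the non-recombinant gamete probability on 100 cM is
$e^{-1}$). The default map is uniform 1 cM/Mb over GRCh37 autosome
lengths; sex chromosomes are excluded; a user map can override either
lengths or rates.

Founders receive two distinct haplotype labels each; `gene_drop`
transmits label segments through the pedigree.
`shared_autozygosity_probability` estimates the probability that a set of
individuals is *identically homozygous by descent* across a window: in
the strict (default) reading all four allele copies of a pair carry the
same single founder-haplotype label across the entire window; a relaxed
mode (each individual autozygous, possibly to different founders) is
available for sensitivity analysis. Only the chromosome carrying the
window is simulated — chromosomes segregate independently under the
model, so this changes nothing but runtime. A single seeded generator
drives the replicates sequentially, so a shorter run reproduces a prefix
of a longer run, and a fixed seed gives bit-identical replicates.

Cross-module parameter recovery: the point-locus autozygosity probability
from simulation must converge to the path-counting inbreeding coefficient
for any pedigree; the tests check first cousins (1/16) and double first
cousins (1/8) within three Monte-Carlo standard errors at 10,000
replicates.

### The Druze family reconstruction

The bundled `DR` pedigree is a *reconstruction* (the published pedigree is
anonymised): the affected uncle III-2 is modelled as the offspring of a
first-cousin mating — the one structural statement available — and the
proband V-1 descends from two of III-2's siblings, making her parents
first cousins within the same loop. This yields $F(\text{III-2}) = 1/16$
and $F(\text{V-1}) = 9/128$ and keeps the recorded relations (V-1 proband,
IV-1 affected mother, III-2/III-3 affected generation-III relatives). On
this reconstruction, 10,000 gene-dropping replicates put the probability
that V-1 and III-2 are identically homozygous across a 1 cM window at the
approximate NOD2 position of chromosome 16 at roughly 0.004 — the same
order as the reported estimate on the true (unpublished) pedigree, and the
quantity `scripts/acceptance.R` recomputes. Exact agreement cannot be
expected from a reconstruction; order-of-magnitude agreement plus exact
point-locus/F agreement is the designed acceptance bar.

## Exome variant prioritisation

The cascade is order-fixed and idempotent:

1. **site filter** — VQSR truth tranche ≤ 99.5 (SNPs) / ≤ 99.0 (indels),
   consumed as a `TRANCHE` INFO annotation or a `PASS` flag (VQSR itself
   is never recomputed);
2. **genotype filter** — calls set to no-call when GQ < 30, when a
   heterozygous call's allele balance fails a 1-df chi-squared test at
   $P < 0.001$, or when a het/hom-alt call has < 3 alternate reads;
3. **no-call filter** — variants kept only below a 0.25 no-call rate;
4. **candidate selection** — homozygous-alternate in the proband,
   predicted damaging, and uncommon or rarer in *all* required reference
   populations;
5. **segregation** — homozygous in all affected siblings (or a stated
   minimum such as 2 of 3), with control-homozygote counts annotated and
   an optional control-based exclusion.

Decisions where the conventions were genuinely open: frequency-class
bounds are half-open (`[0.001, 0.01)` rare, `[0.01, 0.05)` uncommon, MAF
≥ 0.05 common) so boundary points are assigned deterministically; an
absent MAF means "not present in that data set" and counts as 0; the
combined class across populations is the *least rare* one (a rarer second
population can never rescue a variant); SIFT low-confidence calls count as
their base class; PolyPhen "possibly damaging" counts as deleterious
(this is the deliberately permissive any-model stance); CADD > 20 is
strict. For unavailable (deceased) parents,
`parent_genotype_constraint` excludes homozygosity whenever any genotyped
descendant is homozygous reference. Manual curation steps (protein
function, expression) are represented as user-supplied annotation joins,
not automated.

## Enrichment

`exact_2x2` reports the raw cross-product odds ratio (the convention that
reproduces published table arithmetic) and a one-sided upper
hypergeometric tail P, conditioned on margins — one-sided because the
question is enrichment; there is no multiple-testing correction by
design. The default gene universe is 19,528 protein-coding genes
(solving 703 genes ≈ 3.6% of the universe), overridable. Zero-cell odds
ratios report 0 or ∞ with a flag rather than a continuity correction.
Null calibration is tested: with the gene list placed uniformly at
random, $P < 0.05$ occurs in ≈ 5% of replicates within the discreteness
of the hypergeometric. Burden comparisons of homozygous-variant counts
are restricted to full siblings (equal expected autozygous fraction), and
the sibship is verified against the pedigree.

## The synthetic-data generator

`generate_family_genotypes` emulates a family SNP-array experiment:
markers LD-free with MAFs uniform on [0.05, 0.5], founder alleles drawn
per marker (hence Hardy–Weinberg-conforming founders), inheritance via
one gene-dropping replicate so relatives share realistic IBD segments and
consanguineous offspring carry genuine autozygous runs, then planted
case-shared ROH, then 0.2% genotype error and 0.2% missingness outside
planted regions. The markers immediately flanking a planted region are
made heterozygous in carriers so the planted marker boundaries are
exactly what a detector reports — this is what makes the round-trip
("every planted structure is recovered, exactly") a testable contract.
What it does *not* emulate: linkage disequilibrium (the ROH scan is
run-based and the published analysis did not model LD), intensity-level
artefacts, batch effects, mutation or selection. Passing tests therefore
demonstrate correctness of the detectors and filters under the stated
model, not robustness to LD-induced identity-by-state runs — which is
precisely why the 50-marker/1 Mb thresholds exist in the scan itself.

`generate_variant_table` builds annotated exome tables in which planted
candidates satisfy every cascade stage and each decoy violates exactly
one named criterion (tranche, GQ, allele balance, alternate depth,
no-call rate, single-population commonness, non-damaging prediction,
non-homozygous proband, control homozygosity), so each filter stage is
pinned by a decoy that only it can reject.

## Problem sizes and runtime choices

Tests run on the `fast` profile: 20,000 markers over four chromosomes
(150/120/90/60 Mb), 12–19-member pedigrees, 10,000 gene-drop replicates
for probability checks, 2,000 replicates for calibration checks; a
`paper` profile (250,000 markers, 22 GRCh37 autosomes) is available for
array-scale runs. These sizes were chosen so that each statistical check
has Monte-Carlo error well inside its assertion tolerance.

## Known limitations

* The kinship-verification degree classes assume outbred pairs; deeply
  inbred pairs may be flagged discordant without a sample swap.
* The genetic map is uniform per chromosome; recombination hot/cold spots
  are not modelled, so window probabilities at specific loci inherit the
  1 cM/Mb approximation.
* The bundled family pedigrees are reconstructions; quantities that
  depend on exact topology (notably the shared-autozygosity probability)
  are reproduced to order of magnitude, not to the digit.
* Array/exome concordance compares dosages directly and assumes both
  data sets count the same allele.
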