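---
title: "Modelling thelytoky, triploidy and ploidy inference in honey bees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling thelytoky, triploidy and ploidy inference in honey bees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(capensim)
```

## Scope and biology

Honey bees are haplodiploid: males develop from unfertilized (haploid)
eggs, females from fertilized (diploid) eggs, with sex decided by allelic
composition at the complementary sex determiner (*csd*). The Cape honey
bee *A. m. capensis* adds thelytoky to this repertoire: unfertilized eggs
can restore diploidy by fusing two products of meiosis and develop as
females. When queens of this subspecies are narcotised with CO~2~ during
instrumental insemination, a further composite arises: the thelytokous
fusion nucleus is itself fertilized, producing viable triploid females
that carry two maternal alleles and one paternal allele at informative
microsatellite loci. Triploid queens in turn lay eggs through a triploid
meiosis whose products are mostly aneuploid-prone and rarely hatch, with
tetraploid daughters among the survivors.

`capensim` implements both directions of this reasoning as testable code:
a forward simulator from founder genotypes to brood (with truth labels),
and the inference pipeline that recovers ploidy, fertilization status,
laying origin and paternity from observed allele sets and flow-cytometry
histograms.

## The meiosis model

Each chromosome is a genetic map anchored at the centromere; a locus sits
at `centromere_distance` Morgans. The germ cell duplicates each homolog
into sister chromatids; crossovers exchange the allele block distal to a
uniformly drawn point between one chromatid of each homolog; meiosis I
separates centromere pairs (independent assortment per chromosome) and
meiosis II separates sisters. Products are reported in linear tetrad
order `[peripheral-1, central-1, central-2, peripheral-2]`, the two
central pronuclei descending from opposite meiosis-I poles — the geometry
implied by "fusion of the two central pronuclei". Eggs are laid arrested
in anaphase I in vivo; the simulator completes meiosis atomically at egg
formation, since nothing downstream depends on the arrested state.

Crossover counts per chromosome are Poisson. The default mean is `2L`
for a chromosome of map length `L` (each crossover involves two of four
chromatids, so a gamete accumulates `L` Morgans on average, keeping the
nominal map honest); a fixed mean and an obligate (>= 1) mode are
available. Positions are uniform on the map and there is no chiasma
interference — the simplest model consistent with a recombination-driven
loss-of-heterozygosity (LOH) argument. No map positions are published for
the marker panel, so positions are free parameters, defaulting to 0.2 M,
and each locus sits on its own chromosome to avoid unmodelled linkage.

Central fusion merges the two central products. Because they carry
non-sister centromeres, a heterozygous locus at the centromere always
stays heterozygous, while LOH rises with distance and approaches 1/3
under free recombination: once recombination fully randomises which of
the four chromatids (two carrying each allele) ends up in each tetrad
position, the central pair is a uniform draw of two chromatids from the
four, and 2 of the 6 possible pairs are homozygous. The test suite checks
the simulated limit against exactly this enumeration (an exhaustive
chromatid-assignment oracle), and `loh_rate()` exposes the curve:

```{r loh}
loh_rate(0, n = 2000, seed = 1)    # 0 at the centromere
loh_rate(5, n = 50000, seed = 2)   # ~1/3 under free recombination
```

## Triploid meiosis

For a triploid germ cell we model meiosis I as segregating two homologs
to one pole and one to the other so that, after duplication, the daughter
cells are tetraploid and diploid; meiosis II is then reductional in both,
yielding two diploid and two haploid products with one central pronucleus
of each ploidy. Two choices were genuinely open:

* **Which homolog is the singleton** is drawn uniformly and independently
  per chromosome — trivalent pairing subtleties are not modelled.
* **Polarity is coherent across chromosomes**: the singleton always
  segregates to the same pole. Without this, every product would be a
  per-chromosome mixture of one and two copies — aneuploid almost surely —
  whereas the model this simulator implements predicts whole-genome
  haploid and diploid oocytes in equal numbers, which is what unfused
  eggs show (`triploid_unfused_haploid_fraction` ~ 0.5 in the acceptance
  output). The messier alternative is available explicitly through
  `apply_disjunction_errors()`, which moves a chromatid copy between
  products with a per-chromosome probability, conserving total copies and
  flagging aneuploidy — the "unbalanced karyotype" hypothesis for why
  most of a triploid queen's eggs fail.

## Egg formation

`make_egg()` composes meiotic products and sperm under eight modes:
arrhenotoky, ordinary fertilization, central-fusion thelytoky, thelytoky
followed by fertilization, one maternal pronucleus with two sperm of
different fathers, a two-zygote diploid mosaic (the two terminal
pronuclei each fertilized by a different sperm cell), androgenesis (a
sperm-only clone), and the triploid-queen egg. Notes on the choices:

* Which maternal pronucleus survives in single-pronucleus modes is
  uniform over the four — no published evidence favours a position.
* Thelytoky-then-fertilization is modelled sequentially (fusion nucleus,
  then sperm). A simultaneous three-nucleus fusion is genotypically
  identical, so only one mechanism is implemented.
* Polyspermy is fixed at two sperm for the two-sperm mode; higher counts
  are not modelled.
* Every drone's sperm are identical (drones are haploid), so a mosaic
  whose two zygotes involve the same father shows at most one paternal
  allele per locus and is genotypically indistinguishable from a
  triploid — the confounding that motivates flow cytometry.

For the triploid queen, `triploid_egg_policy()` sets the per-egg fates.
`fusion_prob` defaults to 0.2: among a triploid queen's unfertilized
drone-cell eggs, roughly a fifth are triploid (fusion nuclei) and the
rest unfused oocytes, and this single observed ratio is the only
constraint the data put on the fusion rate. Fertilization is
cell-type-specific (`p_fert_worker = 0.85`, `p_fert_drone = 0.05`),
reflecting that queens fertilize eggs laid in worker cells and withhold
sperm in drone cells, imperfectly in both directions. An optional second
thelytoky route — fusion of the two haploid pronuclei into a diploid
nucleus — is provided but off by default; it is one candidate explanation
for the observed excess of diploid over haploid unfused eggs, which the
primary model leaves unexplained.

## Sex and viability

`determine_sex()` is ploidy-neutral: two distinct csd alleles make a
female at any ploidy; a single csd copy a male; two or more identical
copies a diploid male. Mosaics are sexed per cell line and the egg is
female if any line is.

`viability_policy()` keeps the two non-exclusive failure hypotheses
switchable: `require_balanced_karyotype` kills aneuploid eggs,
`remove_diploid_males` emulates worker policing, and `class_viability` is
a per-class Bernoulli hatch probability (a calibration, not a mechanism —
no rates are published). The diploid-queen default is 0.93, the observed
hatch of control queens. `triploid_queen_viability()` sets fertilized
triploid eggs to 0 (none survive to pupation even though triploidy per se
is viable), tetraploids to 0.12 and unfertilized triploids to 0.05; with
the default egg-fate mix this yields an expected worker-cell hatch of
~0.022, matching the observed ~2%.

## The classifier

`call_class()` reproduces the genotype-based reasoning, with thresholds
in `call_thresholds()`:

* **Origin.** Alleles carried by neither the queen nor any father are
  foreign; foreign alleles at >= 2 loci mean worker-laid (one locus is
  written off as genotyping error).
* **Fertilization.** Unambiguously paternal alleles at
  `paternal_evidence_loci` (default 1) loci call "yes". A record with no
  paternal allele anywhere and at least one locus whose alleles are all
  strictly maternal calls "no" — a fertilized individual must carry a
  paternal or shared allele at every locus. Shared (queen-and-father)
  alleles never decide on their own; such records stay ambiguous.
* **Ploidy.** Three distinct alleles at >= `min_loci_multiallele`
  (default 2) loci raise the call to 3.
  (Requiring three alleles at four or more of seven loci, as done when
  choosing cytometry specimens, is a deliberately conservative filter, not
  a calling threshold.)
  Tetraploidy is called only on direct evidence: a locus with four
  distinct alleles, or three maternally-attributable alleles in a
  fertilized individual (a triploid oocyte's three maternal alleles plus
  a shared paternal one); otherwise the lower ploidy wins (parsimony —
  the separation rule at partially informative loci is not published, so
  this heuristic is ours). With no multi-allele locus, one locus with two
  alleles makes the individual at least diploid, so thelytokous diploids
  with LOH at some loci are never demoted to haploid; all-single-allele
  records are haploid if unfertilized, androgenic clones if purely
  paternal, diploid if maternal alleles coexist with paternal evidence.

Limits worth knowing: a diploid mosaic pooled in a whole-body extract is
confounded with a triploid (resolved by cytometry, below), and complete
LOH at *every* locus can mask a fertilized fusion nucleus as an ordinary
fertilized egg — at the default 0.2 M map distance this costs roughly
3 in 10^6 classifications; the same mechanism can make a thelytokous
diploid read as a haploid at individual loci. Dropout only removes
evidence;
a property test asserts confident calls never increase as loci blank out.

## Flow cytometry

`synthesize_histogram()` draws nucleus fluorescence from a Gaussian
mixture with component means `k * c1_mean` (DNA content scales with
ploidy class C1–C4) and coefficient of variation `cv` per peak; tissue
presets encode that brain reads at organismal ploidy while thorax
autopolyploidises. `call_peaks()` gates each event to its nearest
expected peak against a haploid (C1) calibration intensity, retaining it
within a half-width of 0.25 *of the peak mean*. The half-width scales
with the peak because peak spread does too: a fixed-width gate truncates
the broader C3/C4 peaks and biases the called fractions; with
proportional gates the composition is recovered within ±0.03 at
cv = 0.05 and 20,000 events. Nearest-peak assignment keeps gates
disjoint. Debris, doublets and S-phase populations beyond a C4 component
are not modelled, and binary FCS parsing is out of scope (event lists
come and go as CSV). Group comparison of called fractions uses a
Wilcoxon rank-sum test plus a bootstrap CI on the mean difference; the
published nested GLM is deliberately not reproduced.

## Statistics and reporting conventions

`chisq_contingency()` is Pearson's test without continuity correction
(expected counts from marginal products; df = (r-1)(c-1)), with a
Monte-Carlo option for sparse tables. `colony_proportions()` reports the
*unweighted* mean of per-colony percentages — with counts 1/18, 2/20,
6/18, 1/18 this gives 14%, whereas pooling would give 15.6% — and
integer-rounded headline figures alongside exact values. Two rounding
quirks are intentional: 1/18 = 5.6% (a printed "5" is a truncation), and
193/208 = 92.8% at one decimal (a printed "92.7" likewise).
`viability_summary()` is plain `100 * hatched / scored` at one decimal.

## What the synthetic data does and does not show

The generator emulates: multi-allelic microsatellite panels (6–9 loci,
one per chromosome), founder genotypes with or without shared
queen/father alleles, per-locus dropout, tissue-specific genotyping of
mosaics, worker-laid contamination, and cross designs matching
single-drone reciprocal crosses, four-drone inseminations and the
triploid-queen colony. It does not model microsatellite mutation or
stutter, null alleles (beyond symmetric dropout), linked loci, colony
demography or development timing. Passing the round-trip tests therefore
shows the *logic* of the classifier is faithful to the simulator's
genetics; on real data, allele-calling artefacts absent from the
simulation would add error the tests cannot see.

## Problem sizes and numerical choices

The checked properties run at: 50,000 fusions for the LOH limit
(tolerance ±0.01 against the enumeration oracle), 10,000 triploid-queen
eggs for the 1:1 oocyte ratio (binomial test, alpha 0.001) and the egg-fate
mixture (chi-square goodness of fit), 1,000 eggs for the
simulate-classify round trip, 1,000 meioses for copy conservation,
20,000 events per cytometry sample, and 100 random tables for the
chi-square oracle at 1e-9. Free recombination is realised as a marker
5 Morgans from the centromere (about ten crossovers per bivalent), where
the simulated LOH sits within half a percent of 1/3. Ties in the
classifier resolve toward "ambiguous", never toward a guess; degenerate
inputs (empty genomes, zero marginals, zero eggs) raise errors or produce
empty-but-valid outputs rather than silent defaults.
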