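# capensim

Cytogenetic simulation and inference for unusual reproduction in honey
bees (*Apis mellifera*), built around the biology of the Cape honey bee
*A. m. capensis*, whose queens and workers can reproduce thelytokously:
unfertilized eggs develop into females after two products of meiosis fuse.

The package is for researchers interpreting microsatellite and
flow-cytometry data from honey bee crosses in which ploidy is in play —
triploid workers arising when a thelytokous fusion nucleus is itself
fertilized, triploid queens laying mostly inviable eggs, tetraploid brood,
diploid mosaics, androgenesis and worker-laid contamination. It provides:

* a forward simulator of meiosis (diploid **and** triploid germ cells)
  with crossovers, tetrad geometry, central fusion and disjunction errors;
* egg formation under every relevant mode, with true class labels;
* csd-based sex determination and configurable viability filtering;
* the inference side: per-locus allele-origin assignment, ploidy /
  fertilization / origin calls, paternity assignment and brood tables;
* synthetic DAPI flow-cytometry histograms with C1–C4 peak calling;
* the summary statistics used to report such crosses (contingency
  chi-square, hatch percentages, per-colony three-allele proportions).

## The model in brief

Honey bee meiosis produces a linear tetrad of four pronuclei. Writing the
positions `[P1, C1 | C2, P2]`, the two central pronuclei `C1`, `C2`
descend from opposite meiosis-I poles. In arrhenotoky a single pronucleus
survives (haploid male); in fertilization it fuses with one sperm; in
thelytoky by **central fusion** `C1 + C2` restore diploidy. Because the
fused pronuclei carry non-sister centromeres, a locus at genetic distance
*d* (Morgans) from its centromere loses heterozygosity only through
recombination: LOH(*d*) rises from 0 at *d* = 0 towards 1/3 under free
recombination. Crossovers are Poisson per chromosome (mean `2L` for map
length `L` by default), with uniform positions and no interference.

A triploid queen's germ cell is modelled as a meiosis-I division into one
tetraploid and one diploid daughter (two homologs to one pole, one to the
other, the singleton chosen at random per chromosome), followed by a
reductional meiosis II: the tetrad is `{2n, 2n, 1n, 1n}` with one central
pronucleus of each ploidy. Unfused eggs are therefore haploid or diploid
in equal numbers; central fusion gives a triploid nucleus, and
fertilization adds one more genome: `1n+sperm -> 2n`, `2n+sperm -> 3n`
(two maternal + one paternal allele per locus), `3n+sperm -> 4n`.

Sex follows the complementary sex determiner (*csd*): two distinct csd
alleles at any ploidy make a female; hemizygotes are males; csd
homozygotes are diploid males, removed by workers.

## Worked example

A diploid queen inseminated by a single unrelated drone, laying 200
worker-cell eggs of which 14% are fertilized thelytokous fusion nuclei:

```r
library(capensim)
panel <- make_panel(n_loci = 7, seed = 11)        # A8 ... Ap43 + csd
cross <- make_founders(panel, n_drones = 1, seed = 12)
mix <- mode_mixture(c(FERTILIZED = 0.86, THELYTOKY_THEN_FERTILIZED = 0.14))
eggs <- simulate_brood(cross$queen, cross$drones, mix, 200, panel, seed = 13)

queen_gt  <- genotype_of(cross$queen, panel)
father_gt <- lapply(cross$drones, genotype_of, panel = panel)
calls <- lapply(eggs, function(e) {
  call_class(observe_genotype(e, panel), queen_gt, father_gt)
})
subset(tabulate_classes(calls), count > 0)
#>   stage   cell_type         class_label count total
#> 3   egg worker_cell triploid_fertilized    33   200
#> 4   egg worker_cell  diploid_fertilized   167   200
```

The classifier recovers 33 triploids (two maternal alleles plus one
paternal allele at multiple loci) among 167 ordinary diploid fertilized
eggs — 16.5% three-allele progeny in this simulated colony. A single
triploid egg looks like this:

```r
egg <- make_egg(cross$queen, cross$drones, "THELYTOKY_THEN_FERTILIZED",
                panel = panel, seed = 15)
genotype_of(egg$cell_lines[[1]], panel)[1:2]
#> $A8
#> [1] 133 136 159     # two maternal alleles + one paternal
#> $A29
#> [1] 138 144 161
```

Thelytokous offspring lose maternal heterozygosity only where
recombination separates a locus from its centromere:

```r
loh_rate(0.2, n = 5000, seed = 14)   # locus 0.2 Morgans out
#> [1] 0.154
loh_rate(0,   n = 5000, seed = 14)   # at the centromere
#> [1] 0
```

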