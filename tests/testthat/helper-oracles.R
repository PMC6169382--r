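# Independent oracles, kept free of the implementation paths they check.

# Central-fusion homozygosity by exhaustive enumeration of
# chromatid-to-position assignments. Chromatids 1,2 (pole A sisters) and
# 3,4 (pole B sisters) carry two copies each of alleles "a" and "b".
# At the centromere the alleles stay with their homolog (sisters identical);
# under free recombination every placement of the two "a" copies on the
# four chromatids is equally likely. The central pair takes one chromatid
# from each pole.
oracle_central_fusion_loh <- function(free_recombination) {
  arrangements <- if (free_recombination) {
    utils::combn(4L, 2L, simplify = FALSE)   # positions of the "a" copies
  } else {
    list(c(1L, 2L))                          # sisters keep homolog alleles
  }
  hom <- 0L
  tot <- 0L
  for (aa in arrangements) {
    al <- rep("b", 4L)
    al[aa] <- "a"
    for (c1 in 1:2) {
      for (c2 in 3:4) {
        tot <- tot + 1L
        if (al[c1] == al[c2]) hom <- hom + 1L
      }
    }
  }
  hom / tot
}

# Brute-force Pearson chi-square from first principles.
oracle_chisq <- function(tab) {
  tab <- as.matrix(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# Multiset of alleles at one locus across a list of genomes.
allele_multiset <- function(genomes, chromosome, locus_id) {
  out <- integer(0)
  for (g in genomes) {
    for (cd in g$chromatids[[chromosome]]) {
      i <- match(locus_id, names(cd$alleles))
      if (!is.na(i)) out <- c(out, cd$alleles[[i]])
    }
  }
  sort(out)
}
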