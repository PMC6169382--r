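# Small panels and founders used across tests.

tiny_panel <- function(n_loci = 2L, distance = 0.2,
                       alleles_per_locus = 10L) {
  loci <- lapply(seq_len(n_loci), function(i) {
    marker_locus(paste0("L", i), i, distance,
                 alleles = 100L + seq_len(alleles_per_locus))
  })
  marker_panel(loci, csd_locus("csd", n_loci + 1L, distance, 1:8),
               chromosome_count = n_loci + 1L)
}

# Genome with a fixed allele vector (one per copy) at every locus.
fixed_genome <- function(panel, alleles_by_copy, founder = "q") {
  founder_genome(panel, length(alleles_by_copy), founder = founder,
                 allele_pick = function(loc, p) alleles_by_copy)
}

# Per-locus observed-distinct-allele counts split by parental origin.
origin_counts <- function(egg, panel, queen_gt, father_gts) {
  rec <- observe_genotype(egg, panel)
  org <- assign_allele_origin(rec, queen_gt, father_gts)
  list(
    max_maternal = max(vapply(org, function(o) {
      sum(o %in% c("maternal", "shared"))
    }, integer(1))),
    max_paternal = max(vapply(org, function(o) {
      sum(o == "paternal")
    }, integer(1)))
  )
}
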