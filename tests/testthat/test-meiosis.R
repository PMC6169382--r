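panel1 <- tiny_panel(n_loci = 1L, distance = 0)   # locus at the centromere

het_queen <- function(panel, alleles = c(101L, 102L)) {
  founder_genome(panel, 2L, founder = "queen",
                 allele_pick = function(loc, p) {
                   if (inherits(loc, "csd_locus")) 1:2 else alleles
                 })
}

test_that("homozygous germ cells give four identical products", {
  panel <- tiny_panel(distance = 0.3)
  germ <- fixed_genome(panel, c(5L, 5L))
  set.seed(1)
  for (i in 1:20) {
    tet <- perform_meiosis(germ, panel, crossover_model(2))
    for (pr in tet$products) {
      expect_identical(allele_set_at(pr, "L1", panel), 5L)
      expect_identical(allele_set_at(pr, "L2", panel), 5L)
    }
  }
})

test_that("central products always differ at a centromeric heterozygous locus", {
  germ <- het_queen(panel1)
  set.seed(2)
  for (i in 1:200) {
    tet <- perform_meiosis(germ, panel1, crossover_model(3))
    a1 <- allele_set_at(tet$products[[2]], "L1", panel1)
    a2 <- allele_set_at(tet$products[[3]], "L1", panel1)
    expect_false(identical(a1, a2))
  }
  # matches the exhaustive chromatid-assignment oracle: LOH 0 at centromere
  expect_identical(oracle_central_fusion_loh(free_recombination = FALSE), 0)
  expect_identical(loh_rate(0, n = 500, seed = 3), 0)
})

test_that("chromatid copies are conserved across the tetrad", {
  panel <- tiny_panel(distance = 0.4)
  set.seed(4)
  for (i in 1:1000) {
    germ <- founder_genome(panel, 2L, founder = "queen")
    xo <- crossover_model(sample(c(NA, 0, 1, 3), 1),
                          obligate_crossover = i %% 2 == 0)
    tet <- perform_meiosis(germ, panel, xo)
    for (chr in seq_along(germ$chromatids)) {
      expect_identical(
        allele_multiset(tet$products, chr, c("L1", "L2", "csd")[chr]),
        rep(allele_multiset(list(germ), chr, c("L1", "L2", "csd")[chr]),
            each = 2)
      )
    }
  }
})

test_that("obligate crossover keeps two copies of each allele", {
  panel <- tiny_panel(n_loci = 1L, distance = 0.2)
  germ <- het_queen(panel)
  set.seed(5)
  for (i in 1:100) {
    tet <- perform_meiosis(germ, panel,
                           crossover_model(obligate_crossover = TRUE))
    expect_identical(allele_multiset(tet$products, 1L, "L1"),
                     c(101L, 101L, 102L, 102L))
  }
})

test_that("central-fusion LOH rises with centromere distance toward 1/3", {
  r0 <- loh_rate(0, n = 2000, seed = 6)
  r_mid <- loh_rate(0.3, n = 4000, seed = 6)
  r_far <- loh_rate(2, n = 4000, seed = 6)
  expect_identical(r0, 0)
  expect_gt(r_mid, r0)
  expect_gt(r_far, r_mid)
  # free recombination limit against the enumeration oracle
  expect_equal(oracle_central_fusion_loh(free_recombination = TRUE), 1 / 3)
  expect_equal(loh_rate(5, n = 8000, seed = 7),
               oracle_central_fusion_loh(TRUE), tolerance = 0.03)
})

test_that("central fusion of a homozygous mother is homozygous everywhere", {
  panel <- tiny_panel(distance = 0.3)
  germ <- fixed_genome(panel, c(9L, 9L))
  set.seed(8)
  for (i in 1:20) {
    fus <- central_fusion(perform_meiosis(germ, panel, crossover_model(2)))
    expect_identical(ploidy_of(fus), 2L)
    expect_identical(allele_set_at(fus, "L1", panel), 9L)
    expect_identical(allele_set_at(fus, "L2", panel), 9L)
  }
})

test_that("meiosis rejects germ cells of the wrong ploidy", {
  panel <- tiny_panel()
  expect_error(perform_meiosis(fixed_genome(panel, c(1L, 2L, 3L)), panel),
               "diploid")
  expect_error(triploid_meiosis(fixed_genome(panel, c(1L, 2L)), panel),
               "triploid")
})

test_that("triploid meiosis yields {1,1,2,2} products conserving 6 copies", {
  panel <- tiny_panel(distance = 0.3)
  set.seed(9)
  for (i in 1:200) {
    germ <- fixed_genome(panel, c(101L, 102L, 103L))
    tet <- triploid_meiosis(germ, panel)
    ploidies <- vapply(tet$products, function(g) ploidy_of(g), integer(1))
    expect_identical(sort(ploidies), c(1L, 1L, 2L, 2L))
    # central products descend from opposite poles: one diploid, one haploid
    expect_identical(sort(ploidies[2:3]), c(1L, 2L))
    for (chr in 1:2) {
      ms <- allele_multiset(tet$products, chr, paste0("L", chr))
      expect_length(ms, 6L)
      expect_identical(ms, rep(c(101L, 102L, 103L), each = 2))
    }
  }
})

test_that("diploid products of triploid meiosis carry non-sister chromosomes", {
  panel <- tiny_panel(distance = 0.3)
  germ <- fixed_genome(panel, c(101L, 102L, 103L))
  set.seed(10)
  for (i in 1:100) {
    tet <- triploid_meiosis(germ, panel, crossover_model(0))
    for (k in 1:2) {   # the two diploid products
      for (id in c("L1", "L2")) {
        expect_length(allele_set_at(tet$products[[k]], id, panel), 2L)
      }
    }
  }
})

test_that("disjunction errors conserve copies and flag aneuploidy", {
  panel <- tiny_panel(distance = 0.2)
  germ <- het_queen(panel)
  set.seed(11)
  tet <- perform_meiosis(germ, panel)

  same <- apply_disjunction_errors(tet, 0)
  expect_identical(same, tet)

  # rate 1: every chromosome moves exactly one copy
  bad <- apply_disjunction_errors(tet, 1)
  for (chr in seq_along(germ$chromatids)) {
    counts <- vapply(bad$products,
                     function(p) length(p$chromatids[[chr]]), integer(1))
    expect_identical(sum(counts), 4L)
    expect_identical(sort(counts), c(0L, 1L, 1L, 2L))
  }
  expect_true(any(vapply(bad$products, `[[`, logical(1), "aneuploid_flag")))

  # allele content is conserved
  for (chr in 1:2) {
    expect_identical(
      allele_multiset(bad$products, chr, paste0("L", chr)),
      allele_multiset(tet$products, chr, paste0("L", chr))
    )
  }
})

test_that("balanced-tetrad fraction matches the binomial expectation", {
  # 16 chromosomes at error rate 0.05: P(untouched) = 0.95^16 ~ 0.44
  panel <- make_panel(n_loci = 2, chromosome_count = 16, seed = 12)
  germ <- founder_genome(panel, 2L, founder = "queen")
  set.seed(13)
  tet <- perform_meiosis(germ, panel)
  n <- 10000L
  balanced <- 0L
  for (i in seq_len(n)) {
    pert <- apply_disjunction_errors(tet, 0.05)
    ok <- all(vapply(pert$products, function(p) {
      identical(ploidy_of(p), 1L)
    }, logical(1)))
    if (ok) balanced <- balanced + 1L
  }
  expected <- 0.95^16
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(balanced / n - expected), 4 * se)
  expect_error(apply_disjunction_errors(tet, 1.5), "error_rate")
})
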