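# Signature tests use loci at the centromere so that tetrad geometry alone
# fixes the genotypic signature (LOH robustness is tested separately).
sig_panel <- tiny_panel(n_loci = 3L, distance = 0)

test_that("sperm are clonal copies of the drone", {
  f <- make_founders(sig_panel, 1, seed = 1)
  s1 <- sample_sperm(f$drones[[1]])
  s2 <- sample_sperm(f$drones[[1]])
  expect_identical(s1, s2)
  expect_identical(genotype_of(s1, sig_panel),
                   genotype_of(f$drones[[1]], sig_panel))
  expect_error(sample_sperm(f$queen), "haploid")

  # single-drone cross: every offspring shares the paternal allele
  qgt <- genotype_of(f$queen, sig_panel)
  set.seed(2)
  for (i in 1:50) {
    egg <- make_egg(f$queen, f$drones, "FERTILIZED", panel = sig_panel)
    gt <- genotype_of(egg$cell_lines[[1]], sig_panel)
    for (id in names(gt)) {
      expect_true(genotype_of(f$drones[[1]], sig_panel)[[id]] %in% gt[[id]])
    }
  }
})

test_that("fertilization adds one ploidy level per sperm", {
  panel <- sig_panel
  f <- make_founders(panel, 2, seed = 3)
  sperm <- sample_sperm(f$drones[[1]])
  set.seed(4)
  tet <- perform_meiosis(f$queen, panel)
  expect_identical(ploidy_of(fertilize(tet$products[[1]], list(sperm))), 2L)
  expect_identical(ploidy_of(fertilize(central_fusion(tet), list(sperm))), 3L)
  f3 <- make_founders(panel, 1, queen_ploidy = 3, seed = 5)
  tet3 <- triploid_meiosis(f3$queen, panel)
  expect_identical(ploidy_of(fertilize(central_fusion(tet3), list(sperm))),
                   4L)
  expect_error(fertilize(tet$products[[1]], list()), "non-empty")
  expect_error(fertilize(tet$products[[1]], list(f$queen)), "haploid")
})

test_that("each mode leaves its unique genotypic signature", {
  f <- make_founders(sig_panel, 4, seed = 6)
  qgt <- genotype_of(f$queen, sig_panel)
  fgts <- lapply(f$drones, genotype_of, panel = sig_panel)
  # mode -> (ploidy, max maternal alleles, max paternal alleles, cell lines)
  expected <- list(
    ARRHENOTOKY = c(1, 1, 0, 1),
    FERTILIZED = c(2, 1, 1, 1),
    THELYTOKY = c(2, 2, 0, 1),
    THELYTOKY_THEN_FERTILIZED = c(3, 2, 1, 1),
    TWO_SPERM_ONE_MATERNAL = c(3, 1, 2, 1),
    ANDROGENESIS = c(1, 0, 1, 1)
  )
  set.seed(7)
  for (mode in names(expected)) {
    for (i in 1:1000) {
      egg <- make_egg(f$queen, f$drones, mode, panel = sig_panel)
      oc <- origin_counts(egg, sig_panel, qgt, fgts)
      got <- c(ploidy_of(egg$cell_lines[[1]]), oc$max_maternal,
               oc$max_paternal, length(egg$cell_lines))
      expect_identical(got, as.integer(expected[[mode]]),
                       label = paste(mode, paste(got, collapse = ",")))
    }
  }
  # signatures are pairwise distinct
  expect_identical(anyDuplicated(expected), 0L)
})

test_that("mosaic eggs carry two diploid cell lines with pooled 2+2 alleles", {
  f <- make_founders(sig_panel, 4, seed = 8)
  qgt <- genotype_of(f$queen, sig_panel)
  fgts <- lapply(f$drones, genotype_of, panel = sig_panel)
  set.seed(9)
  for (i in 1:200) {
    egg <- make_egg(f$queen, f$drones, "MOSAIC_TWO_ZYGOTES",
                    panel = sig_panel)
    expect_length(egg$cell_lines, 2L)
    for (l in egg$cell_lines) expect_identical(ploidy_of(l), 2L)
    oc <- origin_counts(egg, sig_panel, qgt, fgts)  # pooled whole-body read
    expect_identical(oc$max_maternal, 2L)
    expect_lte(oc$max_paternal, 2L)
    expect_gte(oc$max_paternal, 1L)
  }
})

test_that("unfertilized eggs never carry paternal alleles", {
  f <- make_founders(sig_panel, 4, seed = 10)
  f3 <- make_founders(sig_panel, 1, queen_ploidy = 3, seed = 11)
  drone_alleles <- unlist(lapply(f$drones, genotype_of, panel = sig_panel))
  set.seed(12)
  for (i in 1:200) {
    mode <- sample(c("ARRHENOTOKY", "THELYTOKY"), 1)
    egg <- make_egg(f$queen, f$drones, mode, panel = sig_panel)
    expect_false(egg$fertilized)
    expect_length(egg$sperm_donors, 0L)
    gt <- unlist(genotype_of(egg$cell_lines[[1]], sig_panel))
    expect_length(intersect(gt, drone_alleles), 0L)
  }
  d3 <- unlist(lapply(f3$drones, genotype_of, panel = sig_panel))
  for (i in 1:200) {
    egg <- make_egg(f3$queen, f3$drones, "TRIPLOID_QUEEN_EGG",
                    panel = sig_panel,
                    tq = triploid_egg_policy(p_fert_worker = 0.5))
    if (egg$fertilized) next
    gt <- unlist(genotype_of(egg$cell_lines[[1]], sig_panel))
    expect_length(intersect(gt, d3), 0L)
  }
})

test_that("triploid-queen egg fates follow f : (1-f)/2 : (1-f)/2", {
  f3 <- make_founders(sig_panel, 0, queen_ploidy = 3, seed = 13)
  fprob <- 0.5
  set.seed(14)
  n <- 10000L
  classes <- character(n)
  for (i in seq_len(n)) {
    egg <- make_egg(f3$queen, list(), "TRIPLOID_QUEEN_EGG",
                    panel = sig_panel,
                    tq = triploid_egg_policy(fusion_prob = fprob))
    classes[i] <- egg$true_class
  }
  counts <- c(sum(classes == "triploid_unfertilized"),
              sum(classes == "haploid"),
              sum(classes == "diploid_unfertilized"))
  expect_identical(sum(counts), n)
  gof <- chisq.test(counts, p = c(fprob, (1 - fprob) / 2, (1 - fprob) / 2))
  expect_gt(gof$p.value, 0.001)
  # unfused oocytes split 1:1 haploid:diploid
  bt <- binom.test(counts[2], counts[2] + counts[3])
  expect_gt(bt$p.value, 0.001)
})

test_that("brood mixtures reproduce their mode frequencies", {
  f <- make_founders(sig_panel, 1, seed = 15)
  mix <- mode_mixture(c(THELYTOKY_THEN_FERTILIZED = 0.14, FERTILIZED = 0.86))
  eggs <- simulate_brood(f$queen, f$drones, mix, 2000, sig_panel, seed = 16)
  tri <- mean(vapply(eggs, `[[`, character(1), "true_class") ==
                "triploid_fertilized")
  expect_lt(abs(tri - 0.14), 0.02)

  all_fert <- simulate_brood(f$queen, f$drones,
                             mode_mixture(c(FERTILIZED = 1)), 100,
                             sig_panel, seed = 17)
  expect_true(all(vapply(all_fert, `[[`, character(1), "true_class") ==
                    "diploid_fertilized"))
})

test_that("drone-cell eggs of a triploid queen are mostly unfertilized", {
  f3 <- make_founders(sig_panel, 1, queen_ploidy = 3, seed = 18)
  mix <- mode_mixture(c(TRIPLOID_QUEEN_EGG = 1))
  eggs <- simulate_brood(f3$queen, f3$drones, mix,
                         c(drone_cell = 200), sig_panel, seed = 19)
  expect_lt(mean(vapply(eggs, `[[`, logical(1), "fertilized")), 0.5)
})

test_that("mode preconditions are enforced", {
  f <- make_founders(sig_panel, 1, seed = 20)
  f3 <- make_founders(sig_panel, 1, queen_ploidy = 3, seed = 21)
  expect_error(make_egg(f$queen, f$drones, "TWO_SPERM_ONE_MATERNAL",
                        panel = sig_panel), "distinct drones")
  expect_error(make_egg(f$queen, f$drones, "TRIPLOID_QUEEN_EGG",
                        panel = sig_panel), "triploid queen")
  expect_error(make_egg(f3$queen, f3$drones, "THELYTOKY",
                        panel = sig_panel), "diploid queen")
  expect_error(make_egg(f$queen, list(), "FERTILIZED", panel = sig_panel),
               "drone")
  expect_error(mode_mixture(c(FERTILIZED = 0.5)), "sum to 1")
})
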