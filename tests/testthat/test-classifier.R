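# A 7-locus informative setting used throughout.
cls_panel <- make_panel(n_loci = 7, seed = 101)
cls_f <- make_founders(cls_panel, 4, seed = 102)
cls_qgt <- genotype_of(cls_f$queen, cls_panel)
cls_fgt <- lapply(cls_f$drones, genotype_of, panel = cls_panel)

rec_from <- function(calls, id = "x", stage = "egg",
                     cell_type = "worker_cell") {
  full <- lapply(names(cls_qgt), function(nm) integer(0))
  names(full) <- names(cls_qgt)
  full[names(calls)] <- calls
  genotype_record(id, full, stage = stage, cell_type = cell_type)
}

test_that("allele origins are labelled maternal/paternal/shared/foreign", {
  queen <- list(A = c(5L, 7L), B = c(1L, 2L))
  father <- list(list(A = 9L, B = 1L))
  org <- assign_allele_origin(list(A = c(5L, 7L, 9L), B = integer(0)),
                              queen, father)
  expect_identical(unname(org$A), c("maternal", "maternal", "paternal"))
  expect_length(org$B, 0L)
  org2 <- assign_allele_origin(list(A = 5L, B = 1L), queen,
                               list(list(A = 5L, B = 2L)))
  expect_identical(unname(org2$A), "shared")
  org3 <- assign_allele_origin(list(A = 11L, B = 1L), queen, father)
  expect_identical(unname(org3$A), "foreign")
  expect_error(assign_allele_origin(list(C = 1L), queen, father), "absent")
})

test_that("observed genotypes match the genome at zero dropout", {
  set.seed(1)
  egg <- make_egg(cls_f$queen, cls_f$drones, "THELYTOKY_THEN_FERTILIZED",
                  panel = cls_panel)
  egg$id <- "e1"
  rec <- observe_genotype(egg, cls_panel, dropout_rate = 0)
  expect_identical(rec$calls, genotype_of(egg$cell_lines[[1]], cls_panel))
  expect_identical(rec$individual_id, "e1")
})

test_that("tissues of a uniform individual give identical genotypes", {
  set.seed(2)
  egg <- make_egg(cls_f$queen, cls_f$drones, "THELYTOKY_THEN_FERTILIZED",
                  panel = cls_panel)
  egg$id <- "e2"
  hind <- observe_genotype(egg, cls_panel, tissue = "hind-leg")
  front <- observe_genotype(egg, cls_panel, tissue = "front-leg")
  expect_identical(hind$calls, front$calls)
  # a mosaic of two identical cell lines also reads identically per tissue
  egg$cell_lines <- c(egg$cell_lines, egg$cell_lines)
  h2 <- observe_genotype(egg, cls_panel, tissue = "hind-leg")
  f2 <- observe_genotype(egg, cls_panel, tissue = "front-leg")
  expect_identical(h2$calls, f2$calls)
})

test_that("dropout produces the binomially expected missingness", {
  set.seed(3)
  egg <- make_egg(cls_f$queen, cls_f$drones, "FERTILIZED", panel = cls_panel)
  egg$id <- "e3"
  miss <- vapply(seq_len(10000L), function(i) {
    rec <- observe_genotype(egg, cls_panel, dropout_rate = 0.1)
    sum(lengths(rec$calls) == 0L)
  }, integer(1))
  expect_lt(abs(mean(miss) - 0.7), 0.05)
})

test_that("class calls follow the genotype taxonomy", {
  q <- cls_qgt
  # three alleles (2 maternal + 1 paternal) at 5 of 7 loci -> triploid fert
  ids <- names(q)
  calls <- lapply(ids, function(id) q[[id]][1:2])
  names(calls) <- ids
  for (id in ids[1:5]) calls[[id]] <- c(calls[[id]], cls_fgt[[1]][[id]])
  cc <- call_class(rec_from(calls), q, cls_fgt)
  expect_identical(cc$class_label, "triploid_fertilized")
  expect_identical(cc$ploidy_call, 3L)
  expect_identical(cc$fertilized_call, "yes")

  # only maternal alleles, 2 distinct at several loci -> diploid unfert
  calls2 <- lapply(ids, function(id) q[[id]][1:2])
  names(calls2) <- ids
  cc2 <- call_class(rec_from(calls2), q, cls_fgt)
  expect_identical(cc2$class_label, "diploid_unfertilized")

  # foreign alleles at several loci -> worker laid
  calls3 <- lapply(ids, function(id) 9999L)
  names(calls3) <- ids
  cc3 <- call_class(rec_from(calls3, cell_type = "drone_cell"), q, cls_fgt)
  expect_identical(cc3$origin_call, "worker_laid")
  expect_identical(cc3$class_label, "unclassifiable")

  # fewer typed loci than required -> unclassifiable
  calls4 <- list(A8 = q$A8[1:2], A29 = q$A29[1:2])
  cc4 <- call_class(rec_from(calls4), q, cls_fgt)
  expect_identical(cc4$class_label, "unclassifiable")

  # a single foreign allele is tolerated as genotyping error
  calls5 <- lapply(ids, function(id) q[[id]][1:2])
  names(calls5) <- ids
  calls5[[1]] <- 9999L
  cc5 <- call_class(rec_from(calls5), q, cls_fgt)
  expect_identical(cc5$origin_call, "queen_laid")
})

test_that("LOH never downgrades a thelytokous diploid to haploid", {
  q <- cls_qgt
  ids <- names(q)
  # LOH at all but one locus
  calls <- lapply(ids, function(id) q[[id]][1])
  names(calls) <- ids
  calls[[ids[4]]] <- q[[ids[4]]][1:2]
  cc <- call_class(rec_from(calls), q, cls_fgt)
  expect_identical(cc$class_label, "diploid_unfertilized")
  expect_identical(cc$ploidy_call, 2L)
  # complete homozygosity with no paternal evidence reads as haploid
  calls_all <- lapply(ids, function(id) q[[id]][1])
  names(calls_all) <- ids
  cc2 <- call_class(rec_from(calls_all), q, cls_fgt)
  expect_identical(cc2$class_label, "haploid")
})

test_that("more dropout never increases confident calls", {
  set.seed(4)
  eggs <- lapply(1:80, function(i) {
    m <- sample(c("FERTILIZED", "THELYTOKY_THEN_FERTILIZED", "THELYTOKY"), 1)
    egg <- make_egg(cls_f$queen, cls_f$drones, m, panel = cls_panel)
    egg$id <- paste0("e", i)
    egg
  })
  recs <- lapply(eggs, observe_genotype, panel = cls_panel)
  confident <- function(recs) {
    sum(vapply(recs, function(r) {
      cc <- call_class(r, cls_qgt, cls_fgt)
      cc$class_label != "unclassifiable"
    }, logical(1)))
  }
  n0 <- confident(recs)
  # nested masking: each step blanks additional loci in the same records
  recs1 <- lapply(recs, function(r) {
    drop <- sample(names(r$calls), 2)
    r$calls[drop] <- list(integer(0))
    r
  })
  recs2 <- lapply(recs1, function(r) {
    keep <- names(r$calls)[lengths(r$calls) > 0]
    drop <- sample(keep, min(3, length(keep)))
    r$calls[drop] <- list(integer(0))
    r
  })
  n1 <- confident(recs1)
  n2 <- confident(recs2)
  expect_lte(n1, n0)
  expect_lte(n2, n1)
})

test_that("paternity is assigned uniquely in an informative 4-drone cross", {
  set.seed(5)
  for (i in 1:300) {
    egg <- make_egg(cls_f$queen, cls_f$drones, "FERTILIZED",
                    panel = cls_panel)
    egg$id <- "p"
    rec <- observe_genotype(egg, cls_panel)
    expect_identical(paternity_assign(rec, cls_qgt, cls_fgt),
                     egg$sperm_donors)
  }
  # two fathers with identical panel genotypes are indistinguishable
  twins <- list(d1 = cls_fgt[[1]], d2 = cls_fgt[[1]])
  egg <- make_egg(cls_f$queen, cls_f$drones[1], "FERTILIZED",
                  panel = cls_panel)
  egg$id <- "p2"
  rec <- observe_genotype(egg, cls_panel)
  expect_identical(paternity_assign(rec, cls_qgt, twins), "ambiguous")
  expect_error(paternity_assign(rec, cls_qgt, cls_fgt[1]), ">= 2")
})

test_that("tabulation matches truth on a clean simulated brood", {
  tab0 <- tabulate_classes(list())
  expect_identical(nrow(tab0), 0L)

  set.seed(6)
  mix <- mode_mixture(c(FERTILIZED = 0.6, THELYTOKY_THEN_FERTILIZED = 0.2,
                        THELYTOKY = 0.2))
  eggs <- simulate_brood(cls_f$queen, cls_f$drones, mix, 150, cls_panel,
                         seed = 7)
  recs <- lapply(eggs, observe_genotype, panel = cls_panel)
  calls <- lapply(recs, call_class, queen = cls_qgt, fathers = cls_fgt)
  tab <- tabulate_classes(calls)
  truth_tab <- table(vapply(eggs, `[[`, character(1), "true_class"))
  for (lab in names(truth_tab)) {
    expect_identical(tab$count[tab$class_label == lab],
                     as.integer(truth_tab[[lab]]))
  }
  expect_identical(sum(tab$count), 150L)
  expect_true(all(tab$total == 150L))
})

test_that("genotype tables round-trip through CSV", {
  set.seed(8)
  eggs <- lapply(1:5, function(i) {
    egg <- make_egg(cls_f$queen, cls_f$drones, "FERTILIZED",
                    panel = cls_panel)
    egg$id <- paste0("egg_", i)
    egg
  })
  recs <- lapply(eggs, observe_genotype, panel = cls_panel,
                 dropout_rate = 0.2)
  path <- tempfile(fileext = ".csv")
  write_genotypes(recs, path)
  back <- read_genotypes(path, panel = cls_panel)
  expect_identical(length(back), length(recs))
  for (i in seq_along(recs)) {
    b <- back[[recs[[i]]$individual_id]]
    expect_identical(b$calls, recs[[i]]$calls)
    expect_identical(b$stage, recs[[i]]$stage)
    expect_identical(b$cell_type, recs[[i]]$cell_type)
  }
})
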