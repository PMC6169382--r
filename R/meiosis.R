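#' Crossover model
#'
#' Crossovers per chromosome are Poisson-distributed. With
#' `mean_crossovers = NA` (default) the mean is `2 * L` where `L` is the
#' genetic length of the chromosome in Morgans (the most distal locus), so
#' that each meiotic product carries on average `L` crossovers, consistent
#' with the map distances. `obligate_crossover` forces at least one
#' crossover on chromosomes that carry loci. Crossover positions are uniform
#' on the map; there is no chiasma interference.
#'
#' @param mean_crossovers Mean crossovers per chromosome bivalent
#'   (>= 0), or `NA` for the map-length default.
#' @param obligate_crossover Force >= 1 crossover per mapped chromosome.
#' @return An object of class `crossover_model`.
#' @export
crossover_model <- function(mean_crossovers = NA_real_,
                            obligate_crossover = FALSE) {
  if (!is.na(mean_crossovers)) {
    stopifnot(is.numeric(mean_crossovers), mean_crossovers >= 0)
  }
  structure(list(mean_crossovers = mean_crossovers,
                 obligate_crossover = isTRUE(obligate_crossover)),
            class = "crossover_model")
}

# Tetrad position labels, in order. central-1 and central-2 descend from
# opposite meiosis-I poles; this is the classical linear tetrad geometry
# behind the "two central pronuclei".
TETRAD_POSITIONS <- c("peripheral-1", "central-1", "central-2",
                      "peripheral-2")

new_meiotic_tetrad <- function(products) {
  structure(list(products = products, positions = TETRAD_POSITIONS),
            class = "meiotic_tetrad")
}

#' @export
print.meiotic_tetrad <- function(x, ...) {
  p <- vapply(x$products, function(g) {
    pl <- ploidy_of(g)
    if (identical(pl, "aneuploid")) "aneu" else as.character(pl)
  }, character(1))
  cat("meiotic_tetrad: ploidies [", paste(p, collapse = ", "), "] at [",
      paste(x$positions, collapse = ", "), "]\n")
  invisible(x)
}

# Swap alleles (and their origin labels) distal to map position u between
# two chromatids. `loci` is the data.frame(id, distance) for the chromosome.
swap_distal <- function(cd_a, cd_b, loci, u) {
  distal <- loci$id[loci$distance > u]
  if (length(distal) == 0L) return(list(cd_a, cd_b))
  tmp_a <- cd_a$alleles[distal]
  tmp_o <- cd_a$origins[distal]
  cd_a$alleles[distal] <- cd_b$alleles[distal]
  cd_a$origins[distal] <- cd_b$origins[distal]
  cd_b$alleles[distal] <- tmp_a
  cd_b$origins[distal] <- tmp_o
  list(cd_a, cd_b)
}

n_crossovers <- function(xo, L) {
  if (L <= 0) return(0L)
  m <- if (is.na(xo$mean_crossovers)) 2 * L else xo$mean_crossovers
  n <- stats::rpois(1L, m)
  if (xo$obligate_crossover && n == 0L) n <- 1L
  n
}

#' Meiosis of a diploid germ cell
#'
#' Simulates one complete meiosis. Each homolog is duplicated into sister
#' chromatids; crossovers exchange allele blocks distal to a uniformly drawn
#' point between one chromatid of each homolog; meiosis I separates the two
#' centromere pairs to opposite poles (independently per chromosome) and
#' meiosis II separates sisters. The four haploid products are returned in
#' tetrad order, so "central" pronuclei (one from each meiosis-I pole) are
#' well-defined. Eggs are laid arrested in anaphase I in vivo; here meiosis
#' completes atomically at egg formation.
#'
#' @param germ Diploid [cell_genome()].
#' @param panel [marker_panel()] giving locus map positions.
#' @param xo [crossover_model()].
#' @param seed Optional integer seed.
#' @return A `meiotic_tetrad` of four haploid [cell_genome()] products.
#' @export
perform_meiosis <- function(germ, panel, xo = crossover_model(),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!identical(ploidy_of(germ), 2L)) stop("germ cell must be diploid")
  by_chr <- panel_loci_by_chromosome(panel)
  nchr <- length(germ$chromatids)
  prods <- replicate(4L, vector("list", nchr), simplify = FALSE)
  for (i in seq_len(nchr)) {
    homs <- germ$chromatids[[i]]
    # sister chromatids: 1,2 from homolog A; 3,4 from homolog B
    cds <- list(homs[[1L]], homs[[1L]], homs[[2L]], homs[[2L]])
    loci <- by_chr[[i]]
    L <- if (is.null(loci)) 0 else max(loci$distance)
    for (k in seq_len(n_crossovers(xo, L))) {
      u <- stats::runif(1L, 0, L)
      a <- sample.int(2L, 1L)
      b <- 2L + sample.int(2L, 1L)
      sw <- swap_distal(cds[[a]], cds[[b]], loci, u)
      cds[[a]] <- sw[[1L]]
      cds[[b]] <- sw[[2L]]
    }
    # meiosis I: independent assortment of which homolog pair goes to the
    # first secondary oocyte; meiosis II: random sister orientation
    first_A <- sample(c(TRUE, FALSE), 1L)
    cell1 <- if (first_A) cds[1:2] else cds[3:4]
    cell2 <- if (first_A) cds[3:4] else cds[1:2]
    cell1 <- cell1[sample.int(2L)]
    cell2 <- cell2[sample.int(2L)]
    # positions: [P1, C1 | C2, P2]; products 1,2 from cell 1, 3,4 from cell 2
    prods[[1L]][[i]] <- list(cell1[[1L]])
    prods[[2L]][[i]] <- list(cell1[[2L]])
    prods[[3L]][[i]] <- list(cell2[[1L]])
    prods[[4L]][[i]] <- list(cell2[[2L]])
  }
  new_meiotic_tetrad(lapply(prods, new_cell_genome))
}

#' Meiosis of a triploid germ cell
#'
#' Model for egg formation in a triploid queen: after chromosome
#' duplication, meiosis I segregates two homologs to one pole and one to the
#' other, producing one tetraploid and one diploid daughter cell; meiosis II
#' is reductional in both, yielding two diploid and two haploid products.
#' Which homolog is the singleton is drawn uniformly and independently per
#' chromosome, but the singleton always segregates to the same pole, so the
#' tetrad product ploidies are genome-wide `{2, 2, 1, 1}` (positions
#' `[peripheral-1, central-1]` diploid, `[central-2, peripheral-2]`
#' haploid). Copy conservation: 6 chromatids per chromosome across the four
#' products. The two diploid products carry non-sister chromosomes, up to
#' exchange by recombination in meiosis I.
#'
#' @inheritParams perform_meiosis
#' @param germ Triploid [cell_genome()].
#' @return A `meiotic_tetrad` with two diploid and two haploid products.
#' @export
triploid_meiosis <- function(germ, panel, xo = crossover_model(),
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!identical(ploidy_of(germ), 3L)) stop("germ cell must be triploid")
  by_chr <- panel_loci_by_chromosome(panel)
  nchr <- length(germ$chromatids)
  prods <- replicate(4L, vector("list", nchr), simplify = FALSE)
  for (i in seq_len(nchr)) {
    homs <- germ$chromatids[[i]]
    # sisters: (1,2) homolog 1, (3,4) homolog 2, (5,6) homolog 3
    cds <- list(homs[[1L]], homs[[1L]], homs[[2L]], homs[[2L]],
                homs[[3L]], homs[[3L]])
    loci <- by_chr[[i]]
    L <- if (is.null(loci)) 0 else max(loci$distance)
    for (k in seq_len(n_crossovers(xo, L))) {
      u <- stats::runif(1L, 0, L)
      hp <- sample.int(3L, 2L)   # two distinct homologs
      a <- (hp[1L] - 1L) * 2L + sample.int(2L, 1L)
      b <- (hp[2L] - 1L) * 2L + sample.int(2L, 1L)
      sw <- swap_distal(cds[[a]], cds[[b]], loci, u)
      cds[[a]] <- sw[[1L]]
      cds[[b]] <- sw[[2L]]
    }
    # meiosis I: singleton homolog drawn per chromosome; it always goes to
    # the haploid pole (cell 2), so pole ploidies are coherent genome-wide
    s <- sample.int(3L, 1L)
    sing <- cds[(s - 1L) * 2L + 1:2]
    pair_idx <- setdiff(1:3, s)
    duo <- lapply(pair_idx, function(h) cds[(h - 1L) * 2L + 1:2])
    # meiosis II in the tetraploid cell: sisters of each homolog separate,
    # one to each product, orientation random and independent per homolog
    o1 <- sample.int(2L)
    o2 <- sample.int(2L)
    prods[[1L]][[i]] <- list(duo[[1L]][[o1[1L]]], duo[[2L]][[o2[1L]]])
    prods[[2L]][[i]] <- list(duo[[1L]][[o1[2L]]], duo[[2L]][[o2[2L]]])
    # meiosis II in the diploid cell: one sister each
    o3 <- sample.int(2L)
    prods[[3L]][[i]] <- list(sing[[o3[1L]]])
    prods[[4L]][[i]] <- list(sing[[o3[2L]]])
  }
  new_meiotic_tetrad(lapply(prods, new_cell_genome))
}

#' Central fusion of the two central pronuclei
#'
#' Merges the two central products of a tetrad (one from each meiosis-I
#' pole) into a single fusion nucleus: diploid after diploid meiosis,
#' triploid (2n central + 1n central) after triploid meiosis. Because the
#' fused pronuclei carry non-sister centromeres, heterozygosity is retained
#' at the centromere and lost distally only through recombination.
#'
#' @param tetrad A `meiotic_tetrad`.
#' @return A [cell_genome()] merging central-1 and central-2.
#' @export
central_fusion <- function(tetrad) {
  stopifnot(inherits(tetrad, "meiotic_tetrad"))
  merge_genomes(tetrad$products[[2L]], tetrad$products[[3L]])
}

# Concatenate chromatid lists of two or more genomes.
merge_genomes <- function(...) {
  gs <- list(...)
  nchr <- length(gs[[1L]]$chromatids)
  chroms <- vector("list", nchr)
  for (i in seq_len(nchr)) {
    chroms[[i]] <- do.call(c, lapply(gs, function(g) g$chromatids[[i]]))
  }
  new_cell_genome(chroms)
}

#' Disjunction errors
#'
#' Perturbs a tetrad to emulate errors in chromosome disjunction during
#' meiosis: independently per chromosome, with probability `error_rate`,
#' one chromatid copy is moved from one product to another (both drawn
#' uniformly), yielding eggs with varying or missing chromosome copies.
#' Total copy number per chromosome is conserved; affected products are
#' re-flagged for aneuploidy.
#'
#' @param tetrad A `meiotic_tetrad`.
#' @param error_rate Probability of a disjunction error per chromosome,
#'   in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return A `meiotic_tetrad`.
#' @export
apply_disjunction_errors <- function(tetrad, error_rate, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(tetrad, "meiotic_tetrad"))
  if (!is.numeric(error_rate) || error_rate < 0 || error_rate > 1) {
    stop("error_rate must be in [0, 1]")
  }
  if (error_rate == 0) return(tetrad)
  chroms <- lapply(tetrad$products, `[[`, "chromatids")
  nchr <- length(chroms[[1L]])
  for (i in seq_len(nchr)) {
    if (stats::runif(1L) >= error_rate) next
    counts <- vapply(chroms, function(p) length(p[[i]]), integer(1))
    donors <- which(counts > 0L)
    d <- if (length(donors) == 1L) donors else sample(donors, 1L)
    r <- sample(setdiff(1:4, d), 1L)
    k <- sample.int(counts[d], 1L)
    moved <- chroms[[d]][[i]][[k]]
    chroms[[d]][[i]] <- chroms[[d]][[i]][-k]
    chroms[[r]][[i]] <- c(chroms[[r]][[i]], list(moved))
  }
  new_meiotic_tetrad(lapply(chroms, new_cell_genome))
}

#' Loss-of-heterozygosity rate under central fusion
#'
#' Convenience simulator: a queen heterozygous at a single marker at the
#' given centromere distance produces `n` thelytokous (central fusion)
#' offspring; returns the fraction homozygous at the marker. LOH is 0 at the
#' centromere and approaches 1/3 under free recombination.
#'
#' @param distance Centromere distance of the marker, Morgans.
#' @param n Number of simulated fusions.
#' @param xo [crossover_model()].
#' @param seed Optional integer seed.
#' @return Fraction of fusion nuclei homozygous at the marker.
#' @export
loh_rate <- function(distance, n = 10000L, xo = crossover_model(),
                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  panel <- marker_panel(
    list(marker_locus("M1", 1L, distance, alleles = 1:2)),
    csd_locus("csd", 2L, 0.2, alleles = 1:6),
    chromosome_count = 2L
  )
  queen <- founder_genome(panel, 2L, founder = "queen",
                          allele_pick = function(loc, p) {
                            if (loc$id == "M1") 1:2 else c(1L, 2L)
                          })
  hom <- 0L
  for (k in seq_len(n)) {
    fus <- central_fusion(perform_meiosis(queen, panel, xo))
    if (length(allele_set_at(fus, panel$loci[["M1"]])) == 1L) hom <- hom + 1L
  }
  hom / n
}
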