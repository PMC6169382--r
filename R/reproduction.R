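#' Reproduction modes
#'
#' The egg-formation mechanisms modelled by [make_egg()]:
#' \describe{
#'   \item{ARRHENOTOKY}{one surviving pronucleus develops as a haploid male.}
#'   \item{FERTILIZED}{one pronucleus fuses with one sperm: diploid female.}
#'   \item{THELYTOKY}{the two central pronuclei fuse: diploid female,
#'     unfertilized.}
#'   \item{THELYTOKY_THEN_FERTILIZED}{a thelytokous fusion nucleus is
#'     fertilized by one sperm: triploid, two maternal + one paternal allele
#'     per locus.}
#'   \item{TWO_SPERM_ONE_MATERNAL}{one pronucleus fuses with two sperm of
#'     different fathers: triploid, one maternal + two paternal alleles.}
#'   \item{MOSAIC_TWO_ZYGOTES}{the two terminal pronuclei each fuse with a
#'     different sperm cell: two diploid cell lines in one individual.}
#'   \item{ANDROGENESIS}{a sperm nucleus alone develops: haploid clone of
#'     the sperm donor.}
#'   \item{TRIPLOID_QUEEN_EGG}{triploid meiosis, then a per-egg fate: a
#'     triploid central-fusion nucleus, or an unfused haploid or diploid
#'     oocyte, fertilized or not according to the cell-type policy.}
#' }
#' @export
REPRODUCTION_MODES <- c("ARRHENOTOKY", "FERTILIZED", "THELYTOKY",
                        "THELYTOKY_THEN_FERTILIZED",
                        "TWO_SPERM_ONE_MATERNAL", "MOSAIC_TWO_ZYGOTES",
                        "ANDROGENESIS", "TRIPLOID_QUEEN_EGG")

#' True class labels
#'
#' The brood-item taxonomy used both as simulation truth and as classifier
#' output (plus `"unclassifiable"` on the inference side).
#' @export
CLASS_LABELS <- c("haploid", "diploid_unfertilized", "diploid_fertilized",
                  "triploid_unfertilized", "triploid_fertilized",
                  "tetraploid_fertilized")

class_from_state <- function(ploidy, fertilized) {
  if (identical(ploidy, "aneuploid")) return("aneuploid")
  key <- paste0(ploidy, if (fertilized) "F" else "U")
  switch(key,
         "1U" = "haploid", "1F" = "haploid",
         "2U" = "diploid_unfertilized", "2F" = "diploid_fertilized",
         "3U" = "triploid_unfertilized", "3F" = "triploid_fertilized",
         "4F" = "tetraploid_fertilized",
         "unclassifiable")
}

new_egg_outcome <- function(cell_lines, mode, cell_type, fertilized,
                            sperm_donors, true_class, laid_by = "queen",
                            id = NA_character_) {
  structure(
    list(id = id, cell_lines = cell_lines, mode = mode,
         cell_type = cell_type, fertilized = fertilized,
         sperm_donors = sperm_donors, true_class = true_class,
         laid_by = laid_by, sex = NA_character_, viable = NA),
    class = "egg_outcome"
  )
}

#' @export
print.egg_outcome <- function(x, ...) {
  cat("egg_outcome:", x$mode, "in", x$cell_type, "->", x$true_class,
      sprintf("(%d cell line%s%s)\n", length(x$cell_lines),
              if (length(x$cell_lines) > 1L) "s" else "",
              if (x$fertilized) {
                paste0(", sperm: ", paste(x$sperm_donors, collapse = "+"))
              } else ", unfertilized"))
  invisible(x)
}

#' Sample a sperm cell from a drone
#'
#' Drones are haploid, so all sperm of one drone are genetically identical:
#' the sperm genome is a copy of the drone genome.
#'
#' @param drone Haploid [cell_genome()].
#' @return A haploid [cell_genome()] (copy of the drone).
#' @export
sample_sperm <- function(drone) {
  if (!identical(ploidy_of(drone), 1L)) stop("drone must be haploid")
  drone
}

#' Fertilize an oocyte
#'
#' Merges an oocyte pronucleus with one or more haploid sperm nuclei.
#' The resulting ploidy is the oocyte ploidy plus the number of sperm.
#'
#' @param oocyte A [cell_genome()].
#' @param sperm_list Non-empty list of haploid [cell_genome()] sperm.
#' @return Merged [cell_genome()].
#' @export
fertilize <- function(oocyte, sperm_list) {
  if (!is.list(sperm_list) || length(sperm_list) == 0L) {
    stop("sperm_list must be a non-empty list")
  }
  for (s in sperm_list) {
    if (!identical(ploidy_of(s), 1L)) stop("sperm must be haploid")
  }
  do.call(merge_genomes, c(list(oocyte), sperm_list))
}

#' Egg-fate policy for a triploid queen
#'
#' Per-egg fates downstream of triploid meiosis. With probability
#' `fusion_prob` the two central pronuclei (one diploid, one haploid) fuse
#' into a triploid nucleus; otherwise one central pronucleus survives
#' unfused, haploid or diploid with equal probability. An optional secondary
#' thelytoky route, fusion of the two haploid pronuclei into a diploid
#' nucleus, is off by default. Eggs are then fertilized with a
#' cell-type-specific probability: worker-cell eggs usually fertilized,
#' drone-cell eggs usually not.
#'
#' @param fusion_prob Probability of central fusion (default 0.2, the
#'   triploid share of unfertilized drone-cell eggs in the observed brood
#'   of a triploid queen).
#' @param p_fert_worker Fertilization probability in worker cells
#'   (default 0.85).
#' @param p_fert_drone Fertilization probability in drone cells
#'   (default 0.05).
#' @param haploid_pair_fusion_prob Probability (given no central fusion)
#'   that the two haploid pronuclei fuse into a diploid nucleus (default 0).
#' @return An object of class `triploid_egg_policy`.
#' @export
triploid_egg_policy <- function(fusion_prob = 0.2, p_fert_worker = 0.85,
                                p_fert_drone = 0.05,
                                haploid_pair_fusion_prob = 0) {
  probs <- c(fusion_prob, p_fert_worker, p_fert_drone,
             haploid_pair_fusion_prob)
  stopifnot(all(probs >= 0), all(probs <= 1))
  structure(list(fusion_prob = fusion_prob, p_fert_worker = p_fert_worker,
                 p_fert_drone = p_fert_drone,
                 haploid_pair_fusion_prob = haploid_pair_fusion_prob),
            class = "triploid_egg_policy")
}

drone_ids <- function(drones) {
  ids <- names(drones)
  if (is.null(ids) || any(!nzchar(ids))) {
    ids <- paste0("d", seq_along(drones))
  }
  ids
}

#' Form one egg
#'
#' Runs the meiosis and nuclear-fusion steps appropriate to the requested
#' reproduction mode and returns a truth-labelled egg. Diploid queens
#' support every mode except `TRIPLOID_QUEEN_EGG`, which requires a triploid
#' queen.
#'
#' @param queen Queen [cell_genome()] (diploid, or triploid for
#'   `TRIPLOID_QUEEN_EGG`).
#' @param drones Named list of haploid drone [cell_genome()]s (may be
#'   empty for unfertilized modes).
#' @param mode One of [REPRODUCTION_MODES].
#' @param cell_type `"worker_cell"` or `"drone_cell"`.
#' @param panel [marker_panel()].
#' @param xo [crossover_model()].
#' @param tq [triploid_egg_policy()] used by `TRIPLOID_QUEEN_EGG`.
#' @param disjunction_error_rate Per-chromosome disjunction error
#'   probability applied to the tetrad (default 0).
#' @param seed Optional integer seed.
#' @return An `egg_outcome`.
#' @export
make_egg <- function(queen, drones = list(), mode, cell_type = "worker_cell",
                     panel, xo = crossover_model(),
                     tq = triploid_egg_policy(),
                     disjunction_error_rate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mode <- match.arg(mode, REPRODUCTION_MODES)
  cell_type <- match.arg(cell_type, c("worker_cell", "drone_cell"))
  qp <- ploidy_of(queen)
  if (mode == "TRIPLOID_QUEEN_EGG") {
    if (!identical(qp, 3L)) stop("TRIPLOID_QUEEN_EGG needs a triploid queen")
  } else if (mode != "ANDROGENESIS" && !identical(qp, 2L)) {
    stop("mode ", mode, " needs a diploid queen")
  }
  ids <- drone_ids(drones)
  need_sperm <- !(mode %in% c("ARRHENOTOKY", "THELYTOKY"))
  if (need_sperm && mode != "TRIPLOID_QUEEN_EGG" && length(drones) == 0L) {
    stop("mode ", mode, " needs at least one drone")
  }
  one_sperm <- function() {
    k <- if (length(drones) == 1L) 1L else sample.int(length(drones), 1L)
    list(sperm = sample_sperm(drones[[k]]), id = ids[k])
  }

  tetrad <- NULL
  if (mode != "ANDROGENESIS") {
    tetrad <- if (mode == "TRIPLOID_QUEEN_EGG") {
      triploid_meiosis(queen, panel, xo)
    } else {
      perform_meiosis(queen, panel, xo)
    }
    if (disjunction_error_rate > 0) {
      tetrad <- apply_disjunction_errors(tetrad, disjunction_error_rate)
    }
  }
  # which maternal pronucleus survives in single-pronucleus modes is drawn
  # uniformly from the four products
  surviving <- function() tetrad$products[[sample.int(4L, 1L)]]

  switch(mode,
    ARRHENOTOKY = {
      g <- surviving()
      new_egg_outcome(list(g), mode, cell_type, FALSE, character(0),
                      class_from_state(ploidy_of(g), FALSE))
    },
    FERTILIZED = {
      s <- one_sperm()
      g <- fertilize(surviving(), list(s$sperm))
      new_egg_outcome(list(g), mode, cell_type, TRUE, s$id,
                      class_from_state(ploidy_of(g), TRUE))
    },
    THELYTOKY = {
      g <- central_fusion(tetrad)
      new_egg_outcome(list(g), mode, cell_type, FALSE, character(0),
                      class_from_state(ploidy_of(g), FALSE))
    },
    THELYTOKY_THEN_FERTILIZED = {
      # modelled sequentially; simultaneous fusion of the three nuclei is
      # genotypically identical
      s <- one_sperm()
      g <- fertilize(central_fusion(tetrad), list(s$sperm))
      new_egg_outcome(list(g), mode, cell_type, TRUE, s$id,
                      class_from_state(ploidy_of(g), TRUE))
    },
    TWO_SPERM_ONE_MATERNAL = {
      if (length(unique(ids)) < 2L) {
        stop("TWO_SPERM_ONE_MATERNAL needs >= 2 distinct drones")
      }
      k <- sample.int(length(drones), 2L)
      g <- fertilize(surviving(),
                     lapply(drones[k], sample_sperm))
      new_egg_outcome(list(g), mode, cell_type, TRUE, ids[k],
                      class_from_state(ploidy_of(g), TRUE))
    },
    MOSAIC_TWO_ZYGOTES = {
      # the two terminal pronuclei each fuse with a different sperm cell
      # (possibly from the same father: a drone's sperm are identical)
      s1 <- one_sperm()
      s2 <- one_sperm()
      l1 <- fertilize(tetrad$products[[1L]], list(s1$sperm))
      l2 <- fertilize(tetrad$products[[4L]], list(s2$sperm))
      new_egg_outcome(list(l1, l2), mode, cell_type, TRUE,
                      unique(c(s1$id, s2$id)),
                      class_from_state(ploidy_of(l1), TRUE))
    },
    ANDROGENESIS = {
      s <- one_sperm()
      new_egg_outcome(list(s$sperm), mode, cell_type, TRUE, s$id,
                      class_from_state(1L, TRUE))
    },
    TRIPLOID_QUEEN_EGG = {
      fate <- stats::runif(1L)
      if (fate < tq$fusion_prob) {
        g <- central_fusion(tetrad)
      } else if (stats::runif(1L) < tq$haploid_pair_fusion_prob) {
        g <- merge_genomes(tetrad$products[[3L]], tetrad$products[[4L]])
      } else {
        # unfused oocyte: one of the two central pronuclei survives,
        # diploid (central-1) or haploid (central-2) with equal probability
        g <- tetrad$products[[sample(c(2L, 3L), 1L)]]
      }
      p_fert <- if (cell_type == "worker_cell") tq$p_fert_worker else
        tq$p_fert_drone
      fert <- length(drones) > 0L && stats::runif(1L) < p_fert
      donors <- character(0)
      if (fert) {
        s <- one_sperm()
        g <- fertilize(g, list(s$sperm))
        donors <- s$id
      }
      new_egg_outcome(list(g), mode, cell_type, fert, donors,
                      class_from_state(ploidy_of(g), fert))
    }
  )
}

#' Mode mixture
#'
#' Per-cell-type probabilities over reproduction modes.
#'
#' @param worker_cell Named numeric vector of mode probabilities summing
#'   to 1.
#' @param drone_cell Likewise; defaults to `worker_cell`.
#' @return An object of class `mode_mixture`.
#' @export
mode_mixture <- function(worker_cell, drone_cell = worker_cell) {
  check <- function(p, what) {
    if (is.null(names(p)) || !all(names(p) %in% REPRODUCTION_MODES)) {
      stop(what, ": names must be reproduction modes")
    }
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop(what, ": probabilities must be >= 0 and sum to 1")
    }
    p
  }
  structure(list(worker_cell = check(worker_cell, "worker_cell"),
                 drone_cell = check(drone_cell, "drone_cell")),
            class = "mode_mixture")
}

#' Simulate a brood
#'
#' Draws eggs per cell type with modes from the mixture. Optionally injects
#' worker-laid contamination: eggs laid by unrelated simulated workers
#' (arrhenotokous by default), which carry alleles foreign to the
#' queen/father pair.
#'
#' @param queen Queen [cell_genome()].
#' @param drones Named list of haploid drone genomes.
#' @param mixture A [mode_mixture()].
#' @param n_eggs Named vector, e.g. `c(worker_cell = 100, drone_cell = 50)`;
#'   a single unnamed number means worker cells only.
#' @param panel [marker_panel()].
#' @param xo [crossover_model()].
#' @param tq [triploid_egg_policy()].
#' @param worker_laid_rate Probability an egg is worker-laid (default 0).
#' @param n_laying_workers Number of unrelated laying workers simulated when
#'   `worker_laid_rate > 0` (default 3).
#' @param disjunction_error_rate Passed to [make_egg()].
#' @param seed Optional integer seed (single seed for the whole brood).
#' @return List of `egg_outcome` objects with ids `egg_0001, ...`.
#' @export
simulate_brood <- function(queen, drones, mixture, n_eggs, panel,
                           xo = crossover_model(),
                           tq = triploid_egg_policy(),
                           worker_laid_rate = 0, n_laying_workers = 3L,
                           disjunction_error_rate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(mixture, "mode_mixture"))
  if (is.null(names(n_eggs))) {
    n_eggs <- c(worker_cell = as.integer(n_eggs[1L]))
  }
  layers <- NULL
  if (worker_laid_rate > 0) {
    layers <- lapply(seq_len(n_laying_workers), function(i) {
      founder_genome(panel, 2L, founder = paste0("laying_worker_", i))
    })
  }
  out <- list()
  k <- 0L
  for (ct in names(n_eggs)) {
    probs <- mixture[[ct]]
    for (j in seq_len(n_eggs[[ct]])) {
      k <- k + 1L
      if (!is.null(layers) && stats::runif(1L) < worker_laid_rate) {
        w <- layers[[sample.int(length(layers), 1L)]]
        egg <- make_egg(w, list(), "ARRHENOTOKY", ct, panel, xo)
        egg$laid_by <- attr(w, "founder")
      } else {
        mode <- sample(names(probs), 1L, prob = probs)
        egg <- make_egg(queen, drones, mode, ct, panel, xo, tq = tq,
                        disjunction_error_rate = disjunction_error_rate)
      }
      egg$id <- sprintf("egg_%04d", k)
      out[[k]] <- egg
    }
  }
  out
}
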