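# Default microsatellite locus names used across the three cross designs.
DEFAULT_LOCUS_NAMES <- c("A8", "A29", "A79", "A88", "A113", "B124", "Ap43",
                         "A14", "A107", "HB-THE-03")

# Derive a sub-stream seed so founder draws, brood, viability and dropout
# can be re-run in isolation from one top-level seed.
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 1000003 * k) %% .Machine$integer.max)
}

#' Make a synthetic marker panel
#'
#' Loci are named after the standard honey bee microsatellites, placed on
#' distinct chromosomes (avoiding unmodelled linkage) at a common default
#' centromere distance; each locus gets a random alphabet of
#' `alleles_per_locus` distinct integer labels in a microsatellite fragment
#' size range. The csd locus gets at least six alleles and its own
#' chromosome.
#'
#' @param n_loci Number of marker loci (default 7, the worker-typing panel).
#' @param alleles_per_locus Alphabet size per locus (default 8).
#' @param centromere_distance Map position of every locus, Morgans
#'   (default 0.2).
#' @param chromosome_count Karyotype size (default 16).
#' @param csd_alleles csd alphabet size (default 12, min 6).
#' @param seed Optional integer seed.
#' @return A [marker_panel()].
#' @export
make_panel <- function(n_loci = 7L, alleles_per_locus = 8L,
                       centromere_distance = 0.2, chromosome_count = 16L,
                       csd_alleles = 12L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_loci >= 1L, alleles_per_locus >= 1L, csd_alleles >= 6L,
            n_loci + 1L <= chromosome_count)
  nm <- if (n_loci <= length(DEFAULT_LOCUS_NAMES)) {
    DEFAULT_LOCUS_NAMES[seq_len(n_loci)]
  } else {
    c(DEFAULT_LOCUS_NAMES,
      paste0("L", seq_len(n_loci - length(DEFAULT_LOCUS_NAMES))))
  }
  loci <- lapply(seq_len(n_loci), function(i) {
    marker_locus(nm[i], chromosome = i,
                 centromere_distance = centromere_distance,
                 alleles = sort(sample(100:400, alleles_per_locus)))
  })
  csd <- csd_locus("csd", chromosome = n_loci + 1L,
                   centromere_distance = centromere_distance,
                   alleles = seq_len(csd_alleles))
  marker_panel(loci, csd, chromosome_count = chromosome_count)
}

#' Make founder genomes for a cross
#'
#' With `informative = TRUE` (default) founders receive disjoint alleles:
#' the queen is fully heterozygous and every drone carries a private allele
#' at every locus, so every reproduction mode leaves a distinct genotypic
#' signature. Requires alphabets of at least `queen_ploidy + n_drones`
#' alleles. With `informative = FALSE` alleles are drawn uniformly, allowing
#' shared queen/father alleles as in real crosses.
#'
#' @param panel A [marker_panel()].
#' @param n_drones Number of drones.
#' @param queen_ploidy 2 (default) or 3 for a triploid queen.
#' @param informative Disjoint founder alleles (default TRUE).
#' @param seed Optional integer seed.
#' @return List with `queen` ([cell_genome()]) and `drones` (named list).
#' @export
make_founders <- function(panel, n_drones = 1L, queen_ploidy = 2L,
                          informative = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  need <- queen_ploidy + n_drones
  if (informative) {
    loci <- panel_all_loci(panel)
    short <- vapply(loci, function(l) length(l$alleles) < need, logical(1))
    if (any(short)) {
      stop("informative founders need >= ", need, " alleles per locus")
    }
    queen <- founder_genome(panel, queen_ploidy, founder = "queen",
                            allele_pick = function(loc, p) loc$alleles[1:p])
    drones <- lapply(seq_len(n_drones), function(i) {
      founder_genome(panel, 1L, founder = paste0("d", i),
                     allele_pick = function(loc, p) {
                       loc$alleles[queen_ploidy + i]
                     })
    })
  } else {
    queen <- founder_genome(panel, queen_ploidy, founder = "queen")
    drones <- lapply(seq_len(n_drones), function(i) {
      founder_genome(panel, 1L, founder = paste0("d", i))
    })
  }
  if (n_drones > 0L) names(drones) <- paste0("d", seq_len(n_drones))
  list(queen = queen, drones = drones)
}

#' Cross design
#'
#' Presets for the three cross designs:
#'
#' * Experiment 1: a diploid queen inseminated with a single unrelated
#'   drone (reciprocal single-drone crosses); worker-cell brood is mostly
#'   ordinary fertilized eggs with a minority of fertilized thelytokous
#'   fusion nuclei (triploids) at `triploid_rate` (default 0.14, the mean
#'   per-colony three-allele proportion).
#' * Experiment 2: a diploid queen inseminated with four unrelated drones;
#'   same mixture, default `triploid_rate` 0.065 (the 5-8 percent observed).
#' * Experiment 3: a triploid queen inseminated with a single drone; every
#'   egg follows the triploid-queen meiosis, fertilized per cell type.
#'
#' @param experiment 1, 2 or 3.
#' @param n_eggs Named vector of eggs per cell type; defaults per
#'   experiment (20 worker-cell pupae-scale for 1; 200 for 2; 186 worker +
#'   48 drone eggs for 3).
#' @param triploid_rate Fraction of `THELYTOKY_THEN_FERTILIZED` eggs for
#'   experiments 1-2.
#' @param n_loci Panel size; defaults 7 (experiments 1-2) or 6
#'   (experiment 3's queen-typing panel).
#' @param tq [triploid_egg_policy()] for experiment 3.
#' @param informative Disjoint founder alleles (default TRUE).
#' @return An object of class `cross_design`.
#' @export
cross_design <- function(experiment, n_eggs = NULL, triploid_rate = NULL,
                         n_loci = NULL, tq = triploid_egg_policy(),
                         informative = TRUE) {
  stopifnot(experiment %in% 1:3)
  experiment <- as.integer(experiment)
  if (experiment == 3L) {
    queen_ploidy <- 3L
    n_drones <- 1L
    if (is.null(n_eggs)) n_eggs <- c(worker_cell = 186L, drone_cell = 48L)
    if (is.null(n_loci)) n_loci <- 6L
    mixture <- mode_mixture(c(TRIPLOID_QUEEN_EGG = 1))
  } else {
    queen_ploidy <- 2L
    n_drones <- if (experiment == 2L) 4L else 1L
    if (is.null(triploid_rate)) {
      triploid_rate <- if (experiment == 2L) 0.065 else 0.14
    }
    if (is.null(n_eggs)) {
      n_eggs <- c(worker_cell = if (experiment == 2L) 200L else 20L)
    }
    if (is.null(n_loci)) n_loci <- 7L
    mixture <- mode_mixture(c(FERTILIZED = 1 - triploid_rate,
                              THELYTOKY_THEN_FERTILIZED = triploid_rate))
  }
  structure(list(experiment = experiment, queen_ploidy = queen_ploidy,
                 n_drones = n_drones, n_eggs = n_eggs,
                 triploid_rate = triploid_rate, n_loci = n_loci,
                 mixture = mixture, tq = tq, informative = informative),
            class = "cross_design")
}

#' Build founders and mixture for a design
#'
#' @param design A [cross_design()].
#' @param panel A [marker_panel()].
#' @param seed Optional integer seed.
#' @return List with `queen`, `drones`, `mixture`.
#' @export
build_cross <- function(design, panel, seed = NULL) {
  stopifnot(inherits(design, "cross_design"))
  f <- make_founders(panel, design$n_drones, design$queen_ploidy,
                     informative = design$informative, seed = seed)
  list(queen = f$queen, drones = f$drones, mixture = design$mixture)
}

#' Write a class table TSV
#'
#' The brood-ploidy summary layout: stage, cell type, class, count, total.
#'
#' @param tab Output of [tabulate_classes()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_class_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run a full synthetic experiment
#'
#' End-to-end driver: build founders, lay the brood, apply csd sex
#' determination and the viability policy, genotype eggs (and surviving
#' pupae), classify every record against the parental genotypes, and write
#' all artifacts to `out_dir`: `panel.csv`, `parents.csv` (queen + drone
#' genotypes), `genotypes.csv`, `truth.csv`, `class_calls.csv` and
#' `class_table.tsv`. Output is byte-identical under identical seeds; the
#' truth file supports round-trip scoring.
#'
#' @param design A [cross_design()].
#' @param seed Integer seed (expanded into independent sub-streams for
#'   founders, brood, viability and genotyping).
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing.
#' @param panel Optional [marker_panel()]; default built from the design.
#' @param thresholds [call_thresholds()].
#' @param policy [viability_policy()]; default per experiment (triploid
#'   queens get [triploid_queen_viability()]).
#' @param xo [crossover_model()].
#' @param dropout_rate Per-locus genotyping dropout (default 0).
#' @param worker_laid_rate Worker-laid contamination rate (default 0).
#' @return List with `panel`, `queen`, `drones`, `eggs`, `records`,
#'   `calls`, `truth` (data.frame), `table` (class table) and `paths`.
#' @export
run_experiment <- function(design, seed = 1L, out_dir = NULL, panel = NULL,
                           thresholds = call_thresholds(), policy = NULL,
                           xo = crossover_model(), dropout_rate = 0,
                           worker_laid_rate = 0) {
  stopifnot(inherits(design, "cross_design"))
  if (is.null(panel)) {
    panel <- make_panel(n_loci = design$n_loci, seed = sub_seed(seed, 0L))
  }
  if (is.null(policy)) {
    policy <- if (design$experiment == 3L) triploid_queen_viability()
              else viability_policy()
  }
  cross <- build_cross(design, panel, seed = sub_seed(seed, 1L))
  eggs <- simulate_brood(cross$queen, cross$drones, cross$mixture,
                         design$n_eggs, panel, xo = xo, tq = design$tq,
                         worker_laid_rate = worker_laid_rate,
                         seed = sub_seed(seed, 2L))
  set.seed(sub_seed(seed, 3L))
  eggs <- lapply(eggs, apply_viability, policy = policy, panel = panel)

  set.seed(sub_seed(seed, 4L))
  records <- list()
  for (egg in eggs) {
    records[[length(records) + 1L]] <-
      observe_genotype(egg, panel, dropout_rate = dropout_rate,
                       stage = "egg")
    if (isTRUE(egg$viable)) {
      pupa <- egg
      pupa$id <- paste0(egg$id, "_pupa")
      records[[length(records) + 1L]] <-
        observe_genotype(pupa, panel, dropout_rate = dropout_rate,
                         stage = "pupa")
    }
  }

  queen_gt <- genotype_of(cross$queen, panel)
  father_gts <- lapply(cross$drones, genotype_of, panel = panel)
  calls <- lapply(records, call_class, queen = queen_gt,
                  fathers = father_gts, thresholds = thresholds)
  tab <- tabulate_classes(calls)

  truth <- if (length(eggs)) {
    data.frame(
      egg_id = vapply(eggs, `[[`, character(1), "id"),
      cell_type = vapply(eggs, `[[`, character(1), "cell_type"),
      stage = "egg",
      true_mode = vapply(eggs, `[[`, character(1), "mode"),
      true_class = vapply(eggs, `[[`, character(1), "true_class"),
      ploidy = vapply(eggs, function(e) {
        as.character(ploidy_of(e$cell_lines[[1L]]))
      }, character(1)),
      laid_by = vapply(eggs, `[[`, character(1), "laid_by"),
      sex = vapply(eggs, `[[`, character(1), "sex"),
      viable = vapply(eggs, `[[`, logical(1), "viable"),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(egg_id = character(0), cell_type = character(0),
               stage = character(0), true_mode = character(0),
               true_class = character(0), ploidy = character(0),
               laid_by = character(0), sex = character(0),
               viable = logical(0))
  }

  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      panel = file.path(out_dir, "panel.csv"),
      parents = file.path(out_dir, "parents.csv"),
      genotypes = file.path(out_dir, "genotypes.csv"),
      truth = file.path(out_dir, "truth.csv"),
      class_calls = file.path(out_dir, "class_calls.csv"),
      class_table = file.path(out_dir, "class_table.tsv")
    )
    write_panel(panel, paths$panel)
    parent_recs <- c(
      list(genotype_record("queen", queen_gt, stage = "adult",
                           cell_type = "worker_cell")),
      lapply(names(father_gts), function(id) {
        genotype_record(id, father_gts[[id]], stage = "adult",
                        cell_type = "drone_cell")
      })
    )
    write_genotypes(parent_recs, paths$parents)
    if (length(records)) {
      write_genotypes(records, paths$genotypes)
      write_class_calls(calls, paths$class_calls)
    } else {
      writeLines("individual_id,stage,cell_type,tissue,locus_id,alleles",
                 paths$genotypes)
      writeLines(paste("individual_id,stage,cell_type,ploidy_call",
                       "fertilized_call,origin_call,class_label",
                       "supporting_loci", sep = ","), paths$class_calls)
    }
    utils::write.csv(truth, paths$truth, row.names = FALSE, quote = FALSE)
    write_class_table(tab, paths$class_table)
  }

  list(panel = panel, queen = cross$queen, drones = cross$drones,
       eggs = eggs, records = records, calls = calls, truth = truth,
       table = tab, paths = paths)
}
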