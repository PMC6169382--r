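#' Sex determination at csd
#'
#' Complementary sex determination: an embryo carrying at least two distinct
#' csd alleles develops as a female, whatever its ploidy; a hemizygote
#' (single csd copy) is a male; a diploid or higher embryo whose csd alleles
#' are all identical is a diploid male (removed by workers at the first
#' larval instar).
#'
#' @param genome A [cell_genome()].
#' @param panel A [marker_panel()] (its csd locus is used).
#' @return One of `"female"`, `"male"`, `"diploid_male"`.
#' @export
determine_sex <- function(genome, panel) {
  csd <- panel$csd
  cds <- genome$chromatids[[csd$chromosome]]
  alleles <- integer(0)
  for (cd in cds) {
    i <- match(csd$id, names(cd$alleles))
    if (!is.na(i)) alleles <- c(alleles, cd$alleles[[i]])
  }
  if (length(alleles) == 0L) stop("genome carries no csd allele")
  if (length(unique(alleles)) >= 2L) return("female")
  if (length(alleles) == 1L) "male" else "diploid_male"
}

#' Viability policy
#'
#' Filters applied to eggs after sex determination. Two non-exclusive
#' hypotheses for low egg viability are switchable: karyotype imbalance
#' (`require_balanced_karyotype` kills aneuploid eggs) and per-class hatch
#' probabilities (`class_viability`). `remove_diploid_males` emulates worker
#' policing of csd homozygotes. Default class viabilities are calibrated to
#' the observed hatch rates of a triploid queen's brood (worker-cell hatch
#' ~0.021) and diploid control queens (~0.93).
#'
#' @param require_balanced_karyotype Kill aneuploid eggs (default TRUE).
#' @param remove_diploid_males Kill csd-homozygous diploid males
#'   (default TRUE).
#' @param class_viability Named probabilities of surviving the egg stage
#'   per true class; unlisted classes default to 1.
#' @return An object of class `viability_policy`.
#' @export
viability_policy <- function(require_balanced_karyotype = TRUE,
                             remove_diploid_males = TRUE,
                             class_viability = c(
                               haploid = 0.93,
                               diploid_unfertilized = 0.93,
                               diploid_fertilized = 0.93,
                               triploid_unfertilized = 0.93,
                               triploid_fertilized = 0.93,
                               tetraploid_fertilized = 0.93)) {
  if (any(class_viability < 0) || any(class_viability > 1)) {
    stop("class viabilities must be in [0, 1]")
  }
  structure(list(require_balanced_karyotype = require_balanced_karyotype,
                 remove_diploid_males = remove_diploid_males,
                 class_viability = class_viability),
            class = "viability_policy")
}

#' Viability policy for a triploid queen's brood
#'
#' Preset reproducing the observed pattern: triploid fertilized eggs
#' effectively inviable, tetraploids and unfertilized triploids rarely
#' viable, consistent with worker-cell hatch around 2 percent.
#'
#' @param ... Overrides passed to [viability_policy()].
#' @return A `viability_policy`.
#' @export
triploid_queen_viability <- function(...) {
  viability_policy(class_viability = c(
    haploid = 0.0,
    diploid_unfertilized = 0.0,
    diploid_fertilized = 0.0,
    triploid_unfertilized = 0.05,
    triploid_fertilized = 0.0,
    tetraploid_fertilized = 0.12), ...)
}

#' Apply sex determination and viability filters to an egg
#'
#' Determines sex per cell line (a mosaic is female if any line is female)
#' and sets `viable`: FALSE if the karyotype filter rejects an aneuploid
#' egg or the diploid-male filter rejects a csd homozygote, otherwise a
#' Bernoulli draw from the class viability.
#'
#' @param egg An `egg_outcome`.
#' @param policy A [viability_policy()].
#' @param panel A [marker_panel()].
#' @param seed Optional integer seed.
#' @return The egg with `sex` and `viable` set.
#' @export
apply_viability <- function(egg, policy, panel, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(egg, "egg_outcome"), inherits(policy, "viability_policy"))
  sexes <- vapply(egg$cell_lines, determine_sex, character(1), panel = panel)
  egg$sex <- if (any(sexes == "female")) "female" else sexes[[1L]]
  aneu <- any(vapply(egg$cell_lines, function(g) {
    identical(ploidy_of(g), "aneuploid")
  }, logical(1)))
  if (policy$require_balanced_karyotype && aneu) {
    egg$viable <- FALSE
    return(egg)
  }
  if (policy$remove_diploid_males && egg$sex == "diploid_male") {
    egg$viable <- FALSE
    return(egg)
  }
  p <- policy$class_viability[egg$true_class]
  if (is.na(p)) p <- 1
  egg$viable <- stats::runif(1L) < p
  egg
}

#' Read and write viability policy YAML
#'
#' The file maps class labels to viability probabilities, with optional
#' boolean keys `require_balanced_karyotype` and `remove_diploid_males`.
#'
#' @param path File path.
#' @param policy A [viability_policy()] (for writing).
#' @return `read_viability_policy()` returns a `viability_policy`;
#'   `write_viability_policy()` returns `path` invisibly.
#' @export
read_viability_policy <- function(path) {
  y <- yaml::read_yaml(path)
  cv <- y$class_viability
  viability_policy(
    require_balanced_karyotype = isTRUE(y$require_balanced_karyotype),
    remove_diploid_males = isTRUE(y$remove_diploid_males),
    class_viability = unlist(cv)
  )
}

#' @rdname read_viability_policy
#' @export
write_viability_policy <- function(policy, path) {
  yaml::write_yaml(list(
    require_balanced_karyotype = policy$require_balanced_karyotype,
    remove_diploid_males = policy$remove_diploid_males,
    class_viability = as.list(policy$class_viability)
  ), path)
  invisible(path)
}
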