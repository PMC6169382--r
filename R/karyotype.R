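#' Marker locus
#'
#' A microsatellite locus with a position on the genetic map, expressed as a
#' distance from the centromere in Morgans, and an alphabet of integer allele
#' labels (fragment sizes are treated as opaque labels; no mutation model).
#'
#' @param id Short text label, e.g. `"A8"`.
#' @param chromosome Integer chromosome index (>= 1).
#' @param centromere_distance Genetic distance from the centromere in
#'   Morgans (>= 0). Default 0.2.
#' @param alleles Integer vector of allowed allele labels (>= 1, unique).
#' @return An object of class `marker_locus`.
#' @export
marker_locus <- function(id, chromosome, centromere_distance = 0.2,
                         alleles) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  chromosome <- as.integer(chromosome)
  stopifnot(length(chromosome) == 1L, chromosome >= 1L)
  stopifnot(is.numeric(centromere_distance), length(centromere_distance) == 1L,
            centromere_distance >= 0)
  alleles <- as.integer(alleles)
  if (length(alleles) < 1L) stop("locus '", id, "' needs at least one allele")
  if (anyDuplicated(alleles)) {
    stop("allele labels must be unique within locus '", id, "'")
  }
  structure(
    list(id = id, chromosome = chromosome,
         centromere_distance = centromere_distance, alleles = alleles),
    class = "marker_locus"
  )
}

#' Complementary sex determiner (csd) locus
#'
#' The csd locus has the same shape as a marker locus but is singled out
#' because allelic composition at csd decides sex: heterozygotes develop as
#' females, hemizygotes as males and homozygous diploids (or higher ploidies
#' with all-identical csd alleles) as diploid males.
#'
#' @inheritParams marker_locus
#' @return An object of class `c("csd_locus", "marker_locus")`.
#' @export
csd_locus <- function(id = "csd", chromosome = 3L, centromere_distance = 0.2,
                      alleles) {
  x <- marker_locus(id, chromosome, centromere_distance, alleles)
  class(x) <- c("csd_locus", class(x))
  x
}

#' Marker panel
#'
#' An ordered set of marker loci plus exactly one csd locus, on a karyotype
#' of `chromosome_count` chromosomes (default 16, the honey bee karyotype).
#'
#' @param loci List of [marker_locus()] objects with unique ids.
#' @param csd A [csd_locus()].
#' @param chromosome_count Number of chromosomes (default 16).
#' @return An object of class `marker_panel`.
#' @export
marker_panel <- function(loci, csd, chromosome_count = 16L) {
  stopifnot(is.list(loci), length(loci) >= 1L)
  if (!all(vapply(loci, inherits, logical(1), "marker_locus"))) {
    stop("'loci' must be a list of marker_locus objects")
  }
  if (!inherits(csd, "csd_locus")) stop("'csd' must be a csd_locus")
  chromosome_count <- as.integer(chromosome_count)
  ids <- vapply(loci, `[[`, character(1), "id")
  if (anyDuplicated(c(ids, csd$id))) stop("locus ids must be unique")
  chrs <- vapply(c(loci, list(csd)), `[[`, integer(1), "chromosome")
  if (any(chrs > chromosome_count)) {
    stop("locus chromosome index exceeds chromosome_count")
  }
  names(loci) <- ids
  structure(
    list(loci = loci, csd = csd, chromosome_count = chromosome_count),
    class = "marker_panel"
  )
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("marker_panel:", length(x$loci), "marker loci + csd locus '",
      x$csd$id, "' on ", x$chromosome_count, " chromosomes\n", sep = "")
  for (loc in x$loci) {
    cat(sprintf("  %-8s chr %2d  %.3f M  %d alleles\n", loc$id,
                loc$chromosome, loc$centromere_distance,
                length(loc$alleles)))
  }
  cat(sprintf("  %-8s chr %2d  %.3f M  %d alleles (csd)\n", x$csd$id,
              x$csd$chromosome, x$csd$centromere_distance,
              length(x$csd$alleles)))
  invisible(x)
}

# All loci of the panel (markers + csd) as one named list.
panel_all_loci <- function(panel) {
  c(panel$loci, stats::setNames(list(panel$csd), panel$csd$id))
}

# Named list chromosome -> data.frame(id, distance) of loci on it.
panel_loci_by_chromosome <- function(panel) {
  loci <- panel_all_loci(panel)
  out <- vector("list", panel$chromosome_count)
  for (loc in loci) {
    out[[loc$chromosome]] <- rbind(
      out[[loc$chromosome]],
      data.frame(id = loc$id, distance = loc$centromere_distance,
                 stringsAsFactors = FALSE)
    )
  }
  out
}

#' Chromatid
#'
#' One chromatid: a chromosome copy carrying allele labels at the loci that
#' map to that chromosome, a per-locus founder-origin label, and the founder
#' origin of its centromere (crossovers move distal alleles, and their
#' origins, between chromatids but never the centromere label).
#'
#' @param chromosome Integer chromosome index.
#' @param alleles Named integer vector, names are locus ids on this
#'   chromosome. May be empty for marker-free chromosomes.
#' @param centromere_origin Founder label, e.g. `"queen"` or `"d1"`.
#' @param origins Optional named character vector of per-locus founder
#'   labels; defaults to `centromere_origin` at every locus.
#' @return An object of class `chromatid`.
#' @export
chromatid <- function(chromosome, alleles = integer(0),
                      centromere_origin = "unknown", origins = NULL) {
  chromosome <- as.integer(chromosome)
  if (length(alleles) && is.null(names(alleles))) {
    stop("'alleles' must be named by locus id")
  }
  alleles <- stats::setNames(as.integer(alleles), names(alleles))
  if (is.null(origins)) {
    origins <- stats::setNames(rep(centromere_origin, length(alleles)),
                               names(alleles))
  }
  structure(
    list(chromosome = chromosome, alleles = alleles,
         origins = origins, centromere_origin = centromere_origin),
    class = "chromatid"
  )
}

#' Cell genome
#'
#' A multiset of chromatids per chromosome. Ploidy is the uniform copy
#' number across chromosomes; if copy numbers differ the genome is flagged
#' aneuploid. Realized individuals in this system range from haploid drones
#' to tetraploid workers.
#'
#' @param chromatids A list of length `chromosome_count`; element `i` is a
#'   list of [chromatid()] objects for chromosome `i`.
#' @param founder Optional founder label attached as an attribute.
#' @return An object of class `cell_genome`.
#' @export
cell_genome <- function(chromatids, founder = NULL) {
  stopifnot(is.list(chromatids), length(chromatids) >= 1L)
  counts <- lengths(chromatids)
  for (i in seq_along(chromatids)) {
    for (cd in chromatids[[i]]) {
      if (!inherits(cd, "chromatid")) stop("non-chromatid element")
      if (cd$chromosome != i) {
        stop("chromatid on chromosome ", cd$chromosome,
             " stored under index ", i)
      }
    }
  }
  uniform <- length(unique(counts)) == 1L
  g <- structure(
    list(chromatids = chromatids,
         ploidy = if (uniform) counts[[1L]] else NA_integer_,
         aneuploid_flag = !uniform),
    class = "cell_genome"
  )
  if (!is.null(founder)) attr(g, "founder") <- founder
  g
}

# Internal fast constructor: skips per-chromatid checks (hot path in the
# meiosis simulator).
new_cell_genome <- function(chromatids, founder = NULL) {
  counts <- lengths(chromatids)
  uniform <- length(unique(counts)) == 1L
  g <- structure(
    list(chromatids = chromatids,
         ploidy = if (uniform) counts[[1L]] else NA_integer_,
         aneuploid_flag = !uniform),
    class = "cell_genome"
  )
  if (!is.null(founder)) attr(g, "founder") <- founder
  g
}

#' @export
print.cell_genome <- function(x, ...) {
  p <- ploidy_of(x)
  cat("cell_genome:", length(x$chromatids), "chromosomes, ploidy",
      if (identical(p, "aneuploid")) "aneuploid" else p, "\n")
  invisible(x)
}

#' Ploidy of a genome
#'
#' @param genome A [cell_genome()].
#' @return The uniform chromatid copy number (integer), or the string
#'   `"aneuploid"` when copy numbers differ across chromosomes.
#' @export
ploidy_of <- function(genome) {
  stopifnot(inherits(genome, "cell_genome"))
  counts <- lengths(genome$chromatids)
  if (length(counts) == 0L || all(counts == 0L)) stop("empty genome")
  if (length(unique(counts)) == 1L) counts[[1L]] else "aneuploid"
}

#' Observed allele set at a locus
#'
#' The deduplicated set of allele labels a genome carries at one locus.
#' Its size never exceeds the ploidy.
#'
#' @param genome A [cell_genome()].
#' @param locus A [marker_locus()] or a locus id together with `panel`.
#' @param panel Optional [marker_panel()] used to resolve a locus id.
#' @return Sorted integer vector of distinct allele labels (possibly empty
#'   if the locus was untyped on every chromatid).
#' @export
allele_set_at <- function(genome, locus, panel = NULL) {
  if (is.character(locus)) {
    if (is.null(panel)) stop("provide 'panel' to resolve a locus id")
    all_loci <- panel_all_loci(panel)
    if (!locus %in% names(all_loci)) stop("unknown locus id '", locus, "'")
    locus <- all_loci[[locus]]
  }
  stopifnot(inherits(locus, "marker_locus"))
  cds <- genome$chromatids[[locus$chromosome]]
  out <- integer(0)
  for (cd in cds) {
    i <- match(locus$id, names(cd$alleles))
    if (!is.na(i)) out <- c(out, cd$alleles[[i]])
  }
  sort(unique(out))
}

# Full genotype: named list locus id -> sorted distinct alleles.
#' Genotype of a genome over a panel
#'
#' @param genome A [cell_genome()].
#' @param panel A [marker_panel()].
#' @param include_csd Include the csd locus (default FALSE: microsatellite
#'   genotyping does not read csd).
#' @return Named list, locus id -> sorted integer vector of alleles.
#' @export
genotype_of <- function(genome, panel, include_csd = FALSE) {
  loci <- if (include_csd) panel_all_loci(panel) else panel$loci
  lapply(loci, function(loc) allele_set_at(genome, loc))
}

#' Random founder genome
#'
#' Draws a genome of the requested ploidy with alleles sampled uniformly
#' (with replacement) from each locus alphabet. Chromatids exist for every
#' chromosome of the karyotype, including marker-free ones.
#'
#' @param panel A [marker_panel()].
#' @param ploidy Integer >= 1.
#' @param founder Founder label stored on every chromatid.
#' @param allele_pick Optional function(locus, ploidy) returning the alleles
#'   for each chromatid copy; defaults to uniform sampling.
#' @return A [cell_genome()].
#' @export
founder_genome <- function(panel, ploidy = 2L, founder = "founder",
                           allele_pick = NULL) {
  ploidy <- as.integer(ploidy)
  stopifnot(ploidy >= 1L)
  loci <- panel_all_loci(panel)
  # per locus: vector of `ploidy` alleles (one per copy)
  picks <- lapply(loci, function(loc) {
    if (is.null(allele_pick)) {
      sample(loc$alleles, ploidy, replace = TRUE)
    } else {
      as.integer(allele_pick(loc, ploidy))
    }
  })
  chroms <- vector("list", panel$chromosome_count)
  for (i in seq_len(panel$chromosome_count)) {
    here <- loci[vapply(loci, function(l) l$chromosome == i, logical(1))]
    chroms[[i]] <- lapply(seq_len(ploidy), function(k) {
      al <- vapply(here, function(l) picks[[l$id]][k], integer(1))
      names(al) <- names(here)
      chromatid(i, al, centromere_origin = founder)
    })
  }
  new_cell_genome(chroms, founder = founder)
}

#' Read and write panel definition files
#'
#' CSV with columns `locus_id,chromosome,centromere_distance_M,alleles`
#' (alleles semicolon-separated integers). The csd locus is the row whose
#' `locus_id` is `"csd"`.
#'
#' @param path File path.
#' @param panel A [marker_panel()] (for writing).
#' @param chromosome_count Karyotype size used when reading (default 16).
#' @return `read_panel()` returns a [marker_panel()]; `write_panel()`
#'   returns `path` invisibly.
#' @export
read_panel <- function(path, chromosome_count = 16L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("locus_id", "chromosome", "centromere_distance_M", "alleles")
  if (!all(need %in% names(df))) {
    stop("panel file must have columns ", paste(need, collapse = ","))
  }
  parse_alleles <- function(s) as.integer(strsplit(s, ";", fixed = TRUE)[[1]])
  is_csd <- df$locus_id == "csd"
  if (sum(is_csd) != 1L) stop("panel file must contain exactly one csd row")
  loci <- lapply(which(!is_csd), function(i) {
    marker_locus(df$locus_id[i], df$chromosome[i],
                 df$centromere_distance_M[i], parse_alleles(df$alleles[i]))
  })
  i <- which(is_csd)
  marker_panel(loci,
               csd_locus("csd", df$chromosome[i],
                         df$centromere_distance_M[i],
                         parse_alleles(df$alleles[i])),
               chromosome_count = chromosome_count)
}

#' @rdname read_panel
#' @export
write_panel <- function(panel, path) {
  loci <- panel_all_loci(panel)
  df <- data.frame(
    locus_id = vapply(loci, `[[`, character(1), "id"),
    chromosome = vapply(loci, `[[`, integer(1), "chromosome"),
    centromere_distance_M =
      vapply(loci, `[[`, numeric(1), "centromere_distance"),
    alleles = vapply(loci, function(l) paste(l$alleles, collapse = ";"),
                     character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
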