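#' Genotype record
#'
#' Observed per-locus allele sets for one individual, as produced by
#' microsatellite genotyping of one tissue (or of the whole body, which
#' pools the cell lines of a mosaic). An empty allele set means the locus
#' failed to amplify.
#'
#' @param individual_id Identifier.
#' @param calls Named list, locus id -> integer vector of observed alleles
#'   (deduplicated; `integer(0)` = missing).
#' @param stage `"egg"`, `"pupa"` or `"adult"`.
#' @param cell_type `"worker_cell"` or `"drone_cell"`.
#' @param tissue Optional tissue label (e.g. `"hind-leg"`).
#' @return An object of class `genotype_record`.
#' @export
genotype_record <- function(individual_id, calls, stage = "egg",
                            cell_type = "worker_cell", tissue = NA_character_) {
  stopifnot(is.list(calls))
  calls <- lapply(calls, function(a) sort(unique(as.integer(a))))
  structure(list(individual_id = individual_id, stage = stage,
                 cell_type = cell_type, tissue = tissue, calls = calls),
            class = "genotype_record")
}

as_calls <- function(x) {
  if (inherits(x, "genotype_record")) x$calls
  else if (inherits(x, "cell_genome")) stop("pass genotype_of(genome, panel)")
  else x
}

#' Simulated genotyping of an egg
#'
#' Reads the allele sets of an egg's genome over the marker panel, with
#' per-locus dropout. With `tissue = NULL` the whole body is extracted and
#' a mosaic's cell lines are pooled; a named tissue samples a single cell
#' line, chosen reproducibly from the tissue label so repeat PCRs of the
#' same tissue agree.
#'
#' @param egg An `egg_outcome`.
#' @param panel A [marker_panel()].
#' @param dropout_rate Per-locus missingness probability in `[0, 1)`.
#' @param tissue Optional tissue label.
#' @param stage Developmental stage recorded (default the egg's own use).
#' @param seed Optional integer seed.
#' @return A [genotype_record()].
#' @export
observe_genotype <- function(egg, panel, dropout_rate = 0, tissue = NULL,
                             stage = "egg", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(dropout_rate >= 0, dropout_rate < 1)
  lines <- egg$cell_lines
  if (is.null(tissue)) {
    gts <- lapply(lines, genotype_of, panel = panel)
    calls <- lapply(names(panel$loci), function(id) {
      sort(unique(unlist(lapply(gts, `[[`, id))))
    })
    names(calls) <- names(panel$loci)
    tissue_lab <- NA_character_
  } else {
    # stable tissue -> cell line mapping: the same tissue of the same
    # individual always yields the same line
    k <- (sum(utf8ToInt(tissue)) %% length(lines)) + 1L
    calls <- genotype_of(lines[[k]], panel)
    tissue_lab <- tissue
  }
  if (dropout_rate > 0) {
    drop <- stats::runif(length(calls)) < dropout_rate
    calls[drop] <- list(integer(0))
  }
  genotype_record(egg$id, calls, stage = stage, cell_type = egg$cell_type,
                  tissue = tissue_lab)
}

#' Assign parental origin to observed alleles
#'
#' Labels each observed allele at each locus: `maternal` if carried by the
#' queen only, `paternal` if carried by at least one father only, `shared`
#' if carried by both, `foreign` if carried by neither (the signature of
#' worker-laid brood).
#'
#' @param rec A [genotype_record()] (or a plain calls list).
#' @param queen Queen genotype: named list locus -> alleles.
#' @param fathers List of father genotypes in the same shape.
#' @return Named list, locus id -> named character vector
#'   (names = allele labels).
#' @export
assign_allele_origin <- function(rec, queen, fathers) {
  calls <- as_calls(rec)
  queen <- as_calls(queen)
  if (length(fathers) == 0L) stop("at least one father genotype required")
  fathers <- lapply(fathers, as_calls)
  out <- list()
  for (id in names(calls)) {
    obs <- calls[[id]]
    if (length(obs) == 0L) {
      out[[id]] <- stats::setNames(character(0), character(0))
      next
    }
    if (is.null(queen[[id]])) {
      stop("locus '", id, "' absent from the queen genotype")
    }
    pat_pool <- sort(unique(unlist(lapply(fathers, `[[`, id))))
    lab <- vapply(obs, function(a) {
      in_q <- a %in% queen[[id]]
      in_f <- a %in% pat_pool
      if (in_q && in_f) "shared"
      else if (in_q) "maternal"
      else if (in_f) "paternal"
      else "foreign"
    }, character(1))
    out[[id]] <- stats::setNames(lab, obs)
  }
  out
}

#' Calling thresholds
#'
#' @param min_loci_multiallele Loci with >= 3 distinct alleles required to
#'   raise a ploidy call above 2 (default 2).
#' @param min_loci_typed Minimum typed loci for any call (default 4).
#' @param paternal_evidence_loci Loci with an unambiguously paternal allele
#'   required to call fertilization (default 1).
#' @return An object of class `call_thresholds`.
#' @export
call_thresholds <- function(min_loci_multiallele = 2L, min_loci_typed = 4L,
                            paternal_evidence_loci = 1L) {
  v <- c(min_loci_multiallele, min_loci_typed, paternal_evidence_loci)
  stopifnot(all(v >= 1L))
  structure(list(min_loci_multiallele = as.integer(min_loci_multiallele),
                 min_loci_typed = as.integer(min_loci_typed),
                 paternal_evidence_loci = as.integer(paternal_evidence_loci)),
            class = "call_thresholds")
}

new_class_call <- function(individual_id, ploidy_call, fertilized_call,
                           origin_call, class_label, supporting_loci,
                           stage = NA_character_, cell_type = NA_character_) {
  structure(list(individual_id = individual_id, ploidy_call = ploidy_call,
                 fertilized_call = fertilized_call,
                 origin_call = origin_call, class_label = class_label,
                 supporting_loci = supporting_loci, stage = stage,
                 cell_type = cell_type),
            class = "class_call")
}

#' @export
print.class_call <- function(x, ...) {
  cat(sprintf("class_call %s: %s (ploidy %s, fertilized %s, origin %s, %d loci)\n",
              x$individual_id, x$class_label, as.character(x$ploidy_call),
              x$fertilized_call, x$origin_call, x$supporting_loci))
  invisible(x)
}

#' Classify an individual from its genotype
#'
#' Reproduces the genotype-based reasoning used to interpret the crosses:
#'
#' * origin: alleles foreign to the queen/father pair at >= 2 loci mean the
#'   individual is worker-laid (one locus is not trusted, to guard against
#'   genotyping error);
#' * fertilization: called yes when unambiguously paternal alleles appear at
#'   enough loci; called no when some typed locus carries only strictly
#'   maternal alleles and no paternal allele appears anywhere; otherwise
#'   ambiguous (shared alleles never decide on their own);
#' * ploidy: >= `min_loci_multiallele` loci with three distinct alleles
#'   raise the call to 3; a tetraploid is called only when some locus shows
#'   four distinct alleles, or three distinct maternally-attributable
#'   alleles in a fertilized individual (a triploid oocyte's three maternal
#'   alleles plus a shared paternal one) -- otherwise the lower ploidy is
#'   preferred (parsimony). With no multi-allele loci, any locus retaining
#'   two alleles makes the individual at least diploid, so thelytokous
#'   diploids with loss of heterozygosity at some loci are never called
#'   haploid; an individual with a single allele everywhere is haploid if
#'   unfertilized (or a purely paternal androgenic clone), diploid if a
#'   maternal allele coexists with paternal evidence.
#'
#' Fewer than `min_loci_typed` typed loci, or contradictory evidence, gives
#' `unclassifiable`; ties are resolved toward ambiguity, never guessed.
#'
#' @param rec A [genotype_record()].
#' @param queen Queen genotype (named list locus -> alleles).
#' @param fathers List of father genotypes.
#' @param thresholds A [call_thresholds()].
#' @return A `class_call`.
#' @export
call_class <- function(rec, queen, fathers, thresholds = call_thresholds()) {
  calls <- as_calls(rec)
  iid <- if (inherits(rec, "genotype_record")) rec$individual_id else NA
  stage <- if (inherits(rec, "genotype_record")) rec$stage else NA
  ct <- if (inherits(rec, "genotype_record")) rec$cell_type else NA
  typed <- names(calls)[lengths(calls) > 0L]
  if (length(typed) < thresholds$min_loci_typed) {
    return(new_class_call(iid, "ambiguous", "ambiguous", "ambiguous",
                          "unclassifiable", length(typed), stage, ct))
  }
  org <- assign_allele_origin(rec, queen, fathers)

  n_distinct <- vapply(typed, function(id) length(calls[[id]]), integer(1))
  has_foreign <- vapply(typed, function(id) any(org[[id]] == "foreign"),
                        logical(1))
  has_paternal <- vapply(typed, function(id) any(org[[id]] == "paternal"),
                         logical(1))
  has_shared <- vapply(typed, function(id) any(org[[id]] == "shared"),
                       logical(1))
  has_strict_maternal <- vapply(typed, function(id) any(org[[id]] == "maternal"),
                                logical(1))
  maternal_only <- vapply(typed, function(id) all(org[[id]] == "maternal"),
                          logical(1))
  all_maternal_attrib <- vapply(typed, function(id) {
    all(org[[id]] %in% c("maternal", "shared"))
  }, logical(1))

  origin_call <- if (sum(has_foreign) >= 2L) "worker_laid" else "queen_laid"
  if (origin_call == "worker_laid") {
    return(new_class_call(iid, "ambiguous", "ambiguous", "worker_laid",
                          "unclassifiable", sum(has_foreign), stage, ct))
  }

  fertilized_call <-
    if (sum(has_paternal) >= thresholds$paternal_evidence_loci) "yes"
    else if (!any(has_paternal) && any(maternal_only)) "no"
    else "ambiguous"

  loci3 <- sum(n_distinct >= 3L)
  loci2 <- sum(n_distinct == 2L)
  fert <- fertilized_call == "yes"

  if (loci3 >= thresholds$min_loci_multiallele) {
    evidence4 <- any(n_distinct >= 4L) ||
      (fert && any(n_distinct == 3L & all_maternal_attrib))
    ploidy_call <- if (evidence4) 4L else 3L
    supporting <- loci3
  } else if (loci2 >= 1L) {
    ploidy_call <- 2L
    supporting <- loci2
  } else {
    # single allele at every typed locus
    if (fertilized_call == "no") {
      ploidy_call <- 1L
      supporting <- length(typed)
    } else if (fert && !any(has_strict_maternal) && !any(has_shared)) {
      ploidy_call <- 1L   # androgenic clone: purely paternal
      supporting <- length(typed)
    } else if (fert && any(has_strict_maternal)) {
      ploidy_call <- 2L   # 1 maternal + 1 shared paternal at every locus
      supporting <- sum(has_strict_maternal)
    } else {
      ploidy_call <- "ambiguous"
      supporting <- 0L
    }
  }

  class_label <-
    if (identical(ploidy_call, "ambiguous") || fertilized_call == "ambiguous") {
      "unclassifiable"
    } else {
      class_from_state(ploidy_call, fert)
    }
  new_class_call(iid, ploidy_call, fertilized_call, origin_call,
                 class_label, supporting, stage, ct)
}

#' Assign paternity
#'
#' Finds the unique father compatible with the offspring genotype: at every
#' typed locus the father must share at least one allele with the offspring
#' and must carry every allele that cannot be attributed to the queen.
#'
#' @param rec A [genotype_record()].
#' @param queen Queen genotype.
#' @param fathers Named list of >= 2 father genotypes.
#' @return The compatible father's id, or `"ambiguous"` when none or
#'   several are compatible.
#' @export
paternity_assign <- function(rec, queen, fathers) {
  if (length(fathers) < 2L) stop("paternity needs >= 2 candidate fathers")
  calls <- as_calls(rec)
  queen <- as_calls(queen)
  ids <- names(fathers)
  if (is.null(ids)) ids <- paste0("d", seq_along(fathers))
  typed <- names(calls)[lengths(calls) > 0L]
  ok <- vapply(fathers, function(f) {
    f <- as_calls(f)
    for (id in typed) {
      obs <- calls[[id]]
      if (length(intersect(obs, f[[id]])) == 0L) return(FALSE)
      nonmat <- setdiff(obs, queen[[id]])
      if (!all(nonmat %in% f[[id]])) return(FALSE)
    }
    TRUE
  }, logical(1))
  if (sum(ok) == 1L) ids[ok] else "ambiguous"
}

#' Tabulate class calls
#'
#' Counts class labels per stage x cell-type stratum, in the layout of a
#' brood-ploidy summary table: one row per stratum and class, with the
#' canonical class order (tetraploid fertilized down to haploid, then
#' unclassifiable) and per-stratum totals.
#'
#' @param calls List of `class_call` objects (or a data.frame with columns
#'   `stage`, `cell_type`, `class_label`).
#' @return A data.frame with columns `stage`, `cell_type`, `class_label`,
#'   `count`, `total` (stratum total).
#' @export
tabulate_classes <- function(calls) {
  order_lab <- c("tetraploid_fertilized", "triploid_unfertilized",
                 "triploid_fertilized", "diploid_fertilized",
                 "diploid_unfertilized", "haploid", "unclassifiable")
  if (is.data.frame(calls)) {
    df <- calls
  } else {
    df <- data.frame(
      stage = vapply(calls, function(x) as.character(x$stage), character(1)),
      cell_type = vapply(calls, function(x) as.character(x$cell_type),
                         character(1)),
      class_label = vapply(calls, `[[`, character(1), "class_label"),
      stringsAsFactors = FALSE
    )
  }
  if (nrow(df) == 0L) {
    return(data.frame(stage = character(0), cell_type = character(0),
                      class_label = character(0), count = integer(0),
                      total = integer(0)))
  }
  strata <- unique(df[, c("stage", "cell_type")])
  out <- do.call(rbind, lapply(seq_len(nrow(strata)), function(i) {
    sub <- df[df$stage == strata$stage[i] & df$cell_type == strata$cell_type[i], ]
    counts <- vapply(order_lab, function(l) sum(sub$class_label == l),
                     integer(1))
    data.frame(stage = strata$stage[i], cell_type = strata$cell_type[i],
               class_label = order_lab, count = counts,
               total = nrow(sub), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Read and write genotype tables
#'
#' CSV with columns `individual_id,stage,cell_type,tissue,locus_id,alleles`
#' (alleles semicolon-separated integers; empty = missing). One row per
#' individual x locus.
#'
#' @param path File path.
#' @param records List of [genotype_record()] (for writing).
#' @param panel Optional [marker_panel()]: when given, loci absent from a
#'   record are filled in as missing.
#' @return `read_genotypes()` returns a named list of `genotype_record`;
#'   `write_genotypes()` returns `path` invisibly.
#' @export
read_genotypes <- function(path, panel = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("individual_id", "stage", "cell_type", "tissue", "locus_id",
            "alleles")
  if (!all(need %in% names(df))) {
    stop("genotype file must have columns ", paste(need, collapse = ","))
  }
  loci_template <- if (is.null(panel)) NULL else names(panel$loci)
  split_ids <- split(seq_len(nrow(df)), df$individual_id)
  out <- lapply(split_ids, function(rows) {
    sub <- df[rows, ]
    calls <- lapply(sub$alleles, function(s) {
      if (is.na(s) || !nzchar(s)) integer(0)
      else as.integer(strsplit(s, ";", fixed = TRUE)[[1]])
    })
    names(calls) <- sub$locus_id
    if (!is.null(loci_template)) {
      missing <- setdiff(loci_template, names(calls))
      for (m in missing) calls[[m]] <- integer(0)
      calls <- calls[loci_template]
    }
    tis <- sub$tissue[1L]
    genotype_record(sub$individual_id[1L], calls, stage = sub$stage[1L],
                    cell_type = sub$cell_type[1L],
                    tissue = if (nzchar(tis)) tis else NA_character_)
  })
  out[unique(df$individual_id)]
}

#' @rdname read_genotypes
#' @export
write_genotypes <- function(records, path) {
  rows <- do.call(rbind, lapply(records, function(r) {
    data.frame(
      individual_id = r$individual_id,
      stage = r$stage,
      cell_type = r$cell_type,
      tissue = if (is.na(r$tissue)) "" else r$tissue,
      locus_id = names(r$calls),
      alleles = vapply(r$calls, paste, character(1), collapse = ";"),
      stringsAsFactors = FALSE
    )
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write class calls to CSV
#'
#' @param calls List of `class_call` objects.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_class_calls <- function(calls, path) {
  df <- data.frame(
    individual_id = vapply(calls, function(x) as.character(x$individual_id),
                           character(1)),
    stage = vapply(calls, function(x) as.character(x$stage), character(1)),
    cell_type = vapply(calls, function(x) as.character(x$cell_type),
                       character(1)),
    ploidy_call = vapply(calls, function(x) as.character(x$ploidy_call),
                         character(1)),
    fertilized_call = vapply(calls, `[[`, character(1), "fertilized_call"),
    origin_call = vapply(calls, `[[`, character(1), "origin_call"),
    class_label = vapply(calls, `[[`, character(1), "class_label"),
    supporting_loci = vapply(calls, function(x) as.integer(x$supporting_loci),
                             integer(1)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
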