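#' Ploidy composition
#'
#' Fractions of nuclei in the DNA-content classes C1 (haploid) through C4
#' (tetraploid, typically dividing cells). Fractions must be non-negative
#' and sum to 1.
#'
#' @param fractions Named numeric vector over a subset of `C1..C4`.
#' @return Named numeric vector of length 4 (class `ploidy_composition`).
#' @export
ploidy_composition <- function(fractions) {
  full <- c(C1 = 0, C2 = 0, C3 = 0, C4 = 0)
  if (is.null(names(fractions)) || !all(names(fractions) %in% names(full))) {
    stop("fractions must be named with C1..C4")
  }
  full[names(fractions)] <- fractions
  if (any(full < 0) || abs(sum(full) - 1) > 1e-8) {
    stop("fractions must be >= 0 and sum to 1")
  }
  structure(full, class = "ploidy_composition")
}

#' Synthetic DAPI fluorescence sample
#'
#' Draws nucleus fluorescence intensities from a Gaussian mixture whose
#' component k has mean `k * c1_mean` (DNA content scales linearly with
#' ploidy) and standard deviation `cv * k * c1_mean`. A synthetic stand-in
#' for cytometer event lists; intensities are truncated to be positive.
#'
#' @param composition A [ploidy_composition()] (or named fractions).
#' @param n_events Number of nuclei (>= 100 recommended for calling).
#' @param c1_mean Mean intensity of the haploid (C1) peak, arbitrary units.
#' @param cv Coefficient of variation of each peak, in (0, 0.3].
#' @param tissue `"brain"` or `"thorax"`.
#' @param individual_id Identifier.
#' @param seed Optional integer seed.
#' @return An object of class `cytometry_sample`: list with `events`,
#'   `tissue`, `individual_id`.
#' @export
synthesize_histogram <- function(composition, n_events = 20000L,
                                 c1_mean = 100, cv = 0.05,
                                 tissue = "brain", individual_id = NA,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!inherits(composition, "ploidy_composition")) {
    composition <- ploidy_composition(composition)
  }
  stopifnot(cv > 0, cv <= 0.3, n_events >= 1L, c1_mean > 0)
  k <- sample(1:4, n_events, replace = TRUE, prob = as.numeric(composition))
  ev <- stats::rnorm(n_events, mean = k * c1_mean, sd = cv * k * c1_mean)
  while (any(ev <= 0)) {
    bad <- which(ev <= 0)
    ev[bad] <- stats::rnorm(length(bad), mean = k[bad] * c1_mean,
                            sd = cv * k[bad] * c1_mean)
  }
  structure(list(events = ev, tissue = tissue,
                 individual_id = individual_id),
            class = "cytometry_sample")
}

#' Tissue presets
#'
#' Compositions emulating the observed histograms: brain tissue reads at
#' the organismal ploidy; the thorax undergoes autopolyploidization (a
#' haploid drone's thorax reads mostly diploid). A small C4 component
#' represents dividing cells.
#'
#' @param ploidy Organismal ploidy (1, 2 or 3).
#' @param tissue `"brain"` or `"thorax"`.
#' @return A [ploidy_composition()].
#' @export
tissue_composition <- function(ploidy, tissue = c("brain", "thorax")) {
  tissue <- match.arg(tissue)
  stopifnot(ploidy %in% 1:3)
  fr <- switch(paste(ploidy, tissue),
    "1 brain"  = c(C1 = 0.90, C2 = 0.10),
    "1 thorax" = c(C1 = 0.05, C2 = 0.90, C4 = 0.05),
    "2 brain"  = c(C2 = 0.90, C4 = 0.10),
    "2 thorax" = c(C2 = 0.75, C4 = 0.25),
    "3 brain"  = c(C2 = 0.05, C3 = 0.90, C4 = 0.05),
    "3 thorax" = c(C2 = 0.05, C3 = 0.75, C4 = 0.20)
  )
  ploidy_composition(fr)
}

#' Call C1-C4 peak fractions
#'
#' Nearest-expected-peak gating against a haploid (C1) calibration
#' intensity, mirroring the standards-based approach: each event is
#' assigned to the `k * c1_reference` peak (k in 1..4) it is nearest to,
#' and retained only within a gate around that peak whose half-width scales
#' with the peak mean (`gate_halfwidth_frac * k * c1_reference`), because
#' peak spread is proportional to DNA content; out-of-gate events are
#' discarded and fractions are computed over retained events. Nearest-peak
#' assignment makes the gates disjoint by construction.
#'
#' @param sample A `cytometry_sample`.
#' @param c1_reference C1 calibration intensity (from a haploid standard).
#' @param gate_halfwidth_frac Gate half-width as a fraction of the peak
#'   mean, in (0, 0.5) (default 0.25, separating adjacent integer-ploidy
#'   peaks up to cv of about 0.08 without truncating the broader
#'   high-ploidy peaks).
#' @return A [ploidy_composition()] with attributes `n_retained` and
#'   `n_total`.
#' @export
call_peaks <- function(sample, c1_reference, gate_halfwidth_frac = 0.25) {
  stopifnot(inherits(sample, "cytometry_sample"), c1_reference > 0,
            gate_halfwidth_frac > 0, gate_halfwidth_frac < 0.5)
  ev <- sample$events
  k <- pmin(pmax(round(ev / c1_reference), 1L), 4L)
  keep <- abs(ev - k * c1_reference) <=
    gate_halfwidth_frac * k * c1_reference
  n_ret <- sum(keep)
  if (n_ret < 100L) {
    stop("fewer than 100 events retained within the gates")
  }
  counts <- tabulate(k[keep], nbins = 4L)
  out <- ploidy_composition(stats::setNames(counts / n_ret,
                                            paste0("C", 1:4)))
  attr(out, "n_retained") <- n_ret
  attr(out, "n_total") <- length(ev)
  out
}

#' Compare ploidy compositions between groups
#'
#' Per tissue, compares the called C3 and C2 fractions between two groups
#' of bees (typically two-allele vs three-allele individuals) with a
#' two-sided Wilcoxon rank-sum test plus a bootstrap confidence interval on
#' the difference of group means.
#'
#' @param calls A data.frame with columns `individual_id`, `tissue`,
#'   `group`, `C1`, `C2`, `C3`, `C4` (one row per bee x tissue).
#' @param n_boot Bootstrap replicates (default 2000).
#' @param seed Optional integer seed for the bootstrap.
#' @return A data.frame with one row per tissue x component: group means,
#'   mean difference (group2 - group1), bootstrap 95% CI and Wilcoxon p.
#' @export
compare_groups <- function(calls, n_boot = 2000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  need <- c("individual_id", "tissue", "group", "C2", "C3")
  stopifnot(all(need %in% names(calls)))
  groups <- sort(unique(calls$group))
  if (length(groups) != 2L) stop("exactly two groups required")
  out <- list()
  for (tis in unique(calls$tissue)) {
    sub <- calls[calls$tissue == tis, ]
    for (comp in c("C2", "C3")) {
      x <- sub[[comp]][sub$group == groups[1L]]
      y <- sub[[comp]][sub$group == groups[2L]]
      if (length(x) < 2L || length(y) < 2L) {
        stop("need >= 2 bees per group (tissue ", tis, ")")
      }
      diffs <- replicate(n_boot, {
        mean(sample(y, replace = TRUE)) - mean(sample(x, replace = TRUE))
      })
      p <- if (length(unique(c(x, y))) == 1L) {
        1   # degenerate: all values tied, no evidence of separation
      } else {
        suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))$p.value
      }
      out[[length(out) + 1L]] <- data.frame(
        tissue = tis, component = comp,
        group1 = groups[1L], group2 = groups[2L],
        mean1 = mean(x), mean2 = mean(y),
        mean_diff = mean(y) - mean(x),
        ci_lo = stats::quantile(diffs, 0.025, names = FALSE),
        ci_hi = stats::quantile(diffs, 0.975, names = FALSE),
        p_value = p,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Read and write cytometry event CSVs
#'
#' One row per event: `individual_id,tissue,intensity`. Binary FCS parsing
#' is out of scope; export event lists to CSV upstream.
#'
#' @param path File path.
#' @param samples List of `cytometry_sample` (for writing).
#' @return `read_cytometry()` returns a list of `cytometry_sample` (one per
#'   individual x tissue); `write_cytometry()` returns `path` invisibly.
#' @export
read_cytometry <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual_id", "tissue", "intensity")
  if (!all(need %in% names(df))) {
    stop("cytometry file must have columns ", paste(need, collapse = ","))
  }
  key <- paste(df$individual_id, df$tissue, sep = "\r")
  lapply(split(seq_len(nrow(df)), key), function(rows) {
    structure(list(events = df$intensity[rows],
                   tissue = df$tissue[rows[1L]],
                   individual_id = df$individual_id[rows[1L]]),
              class = "cytometry_sample")
  })
}

#' @rdname read_cytometry
#' @export
write_cytometry <- function(samples, path) {
  df <- do.call(rbind, lapply(samples, function(s) {
    data.frame(individual_id = s$individual_id, tissue = s$tissue,
               intensity = s$events, stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
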