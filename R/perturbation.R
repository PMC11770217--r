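#' Randomly subsample annotation regions
#'
#' Keeps `floor(fraction * N)` regions per replicate, sampled without
#' replacement; used to check that enrichment results do not hinge on
#' any small subset of regions.
#'
#' @param annot An annotation [interval_set()].
#' @param fraction Fraction of regions kept (default 0.9).
#' @param n_reps Number of replicates (default 3).
#' @param seed Optional integer seed.
#' @return A list of `n_reps` interval sets.
#' @export
subsample_regions <- function(annot, fraction = 0.9, n_reps = 3,
                              seed = NULL) {
  stopifnot(fraction > 0, fraction <= 1, n_reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(annot)
  keep_n <- floor(fraction * n)
  lapply(seq_len(n_reps), function(r) {
    keep <- sort(sample.int(n, keep_n))
    interval_set(annot[keep, , drop = FALSE], iv_genome(annot),
                 merged = is_merged(annot))
  })
}

#' Shrink or extend every region's ends
#'
#' Moves each region's two ends inward (`shrink`) or outward (`extend`)
#' by `round(end_fraction * length)` of that region's own length
#' (rounded half-up), so the total length changes by about twice the
#' end fraction. Extension is clamped to chromosome bounds; shrinking
#' never reduces a region below 1 bp (a region too short to shrink
#' collapses to a 1-bp interval at its midpoint).
#'
#' @param annot An annotation [interval_set()].
#' @param end_fraction Per-end displacement as a fraction of region
#'   length, in (0, 0.5) (default 0.05).
#' @param direction `"shrink"` or `"extend"`.
#' @param genome A [genome_define()] object (for clamping).
#' @return An [interval_set()] (not flagged merged: extension can create
#'   overlaps).
#' @export
resize_regions <- function(annot, end_fraction = 0.05,
                           direction = c("shrink", "extend"),
                           genome = iv_genome(annot)) {
  direction <- match.arg(direction)
  stopifnot(end_fraction > 0, end_fraction < 0.5)
  if (nrow(annot) == 0) return(interval_set(annot, genome))
  len <- annot$end - annot$start
  delta <- floor(end_fraction * len + 0.5)  # round half-up
  if (direction == "extend") {
    lens <- genome$length[match(annot$chrom, genome$chrom)]
    ns <- pmax(annot$start - delta, 0)
    ne <- pmin(annot$end + delta, lens)
  } else {
    ns <- annot$start + delta
    ne <- annot$end - delta
    bad <- ne - ns < 1
    if (any(bad)) {
      mid <- floor((annot$start[bad] + annot$end[bad]) / 2)
      ns[bad] <- mid
      ne[bad] <- mid + 1
    }
  }
  interval_set(
    tibble::tibble(chrom = annot$chrom, start = ns, end = ne,
                   name = annot$name),
    genome
  )
}

#' Annotation robustness study
#'
#' Reruns the enrichment pipeline for every trait under perturbed
#' versions of an annotation — random 90% region subsamples, 5%-per-end
#' shrinking, and 5%-per-end extension — and reports the Pearson
#' correlation of the perturbed enrichment estimates (and of the
#' `-log10` p-values) with the original run. Background placements are
#' driven by per-trait seeds that are identical across perturbations,
#' so the correlations reflect the annotation change only.
#'
#' @param element_sets Named list of element sets (already size
#'   filtered upstream or filtered here via `min_set_size`).
#' @param annot The original annotation (merged).
#' @param genome A [genome_define()] object.
#' @param annot_id Label reported in the output.
#' @param modes Subset of `c("identity", "subsample90", "shrink5",
#'   "extend5")`.
#' @param fraction Subsample fraction (default 0.9).
#' @param subsample_reps Subsample replicates (default 3).
#' @param end_fraction Per-end resize fraction (default 0.05).
#' @param n_reps Background replicates per trait run.
#' @param seed Integer seed (per-trait seeds derive from it).
#' @param min_set_size Size filter passed to [run_enrichment()].
#' @return A tibble with one row per (mode, replicate): `annot_id`,
#'   `mode`, `replicate`, `pearson_r_enrichment`, `pearson_r_logp`,
#'   `n_traits`. The original per-trait results are in the `original`
#'   attribute.
#' @export
perturbation_study <- function(element_sets, annot, genome,
                               annot_id = "annot",
                               modes = c("subsample90", "shrink5", "extend5"),
                               fraction = 0.9, subsample_reps = 3,
                               end_fraction = 0.05, n_reps = 1000, seed = 1,
                               min_set_size = 50) {
  modes <- match.arg(modes,
                     c("identity", "subsample90", "shrink5", "extend5"),
                     several.ok = TRUE)
  run_one <- function(a) {
    run_enrichment(element_sets, stats::setNames(list(a), annot_id), genome,
                   n_reps = n_reps, seed = seed, min_set_size = min_set_size)
  }
  orig <- run_one(annot)
  if (nrow(orig) < 3) {
    warning("fewer than 3 traits passed the size filter; correlations skipped")
  }
  variants <- list()
  if ("identity" %in% modes) {
    variants[["identity.1"]] <- annot
  }
  if ("subsample90" %in% modes) {
    subs <- subsample_regions(annot, fraction = fraction,
                              n_reps = subsample_reps, seed = seed)
    for (r in seq_along(subs)) {
      variants[[sprintf("subsample90.%d", r)]] <- merge_intervals(subs[[r]])
    }
  }
  if ("shrink5" %in% modes) {
    variants[["shrink5.1"]] <-
      merge_intervals(resize_regions(annot, end_fraction, "shrink", genome))
  }
  if ("extend5" %in% modes) {
    variants[["extend5.1"]] <-
      merge_intervals(resize_regions(annot, end_fraction, "extend", genome))
  }
  rows <- purrr::imap(variants, function(a, label) {
    parts <- strsplit(label, ".", fixed = TRUE)[[1]]
    pert <- run_one(a)
    ok <- nrow(orig) >= 3 && nrow(pert) == nrow(orig)
    degenerate <- nrow(a) < 2
    cor_exact <- function(x, y) {
      if (identical(x, y)) return(1)
      if (anyNA(x) || anyNA(y)) return(NA_real_)
      if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
      stats::cor(x, y)
    }
    r_enr <- if (ok) cor_exact(orig$I_percent, pert$I_percent) else NA_real_
    r_logp <- if (ok) cor_exact(-log10(orig$p), -log10(pert$p)) else NA_real_
    tibble::tibble(
      annot_id = annot_id, mode = parts[1],
      replicate = as.integer(parts[2]),
      pearson_r_enrichment = r_enr, pearson_r_logp = r_logp,
      n_traits = nrow(orig), degenerate = degenerate
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "original") <- orig
  out
}
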