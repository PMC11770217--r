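#' Percent-difference overlap enrichment
#'
#' The enrichment statistic `I`: the signed percent difference between a
#' trait's observed overlap with an annotation and the mean overlap of
#' the random background, `(observed - mean(bg)) / mean(bg) * 100`.
#' Positive values mean more overlap than expected. Scale-invariant:
#' multiplying all overlaps by a positive constant leaves `I` unchanged.
#'
#' @param observed Observed overlap (intersections per bp, or a raw
#'   count — as long as `bg_overlaps` is on the same scale).
#' @param bg_overlaps Numeric vector of background overlap values.
#' @return Signed percentage.
#' @export
enrichment_percent <- function(observed, bg_overlaps) {
  m <- mean(bg_overlaps)
  if (!is.finite(m) || m <= 0) {
    stop("enrichment undefined: mean background overlap is 0", call. = FALSE)
  }
  (observed - m) / m * 100
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement, preserving the
#' input order. Inputs must be valid p-values in (0, 1].
#'
#' @param pvalues Numeric vector of p-values.
#' @return Adjusted q-values in the same order.
#' @export
adjust_bh <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues <= 0 | pvalues > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Run the overlap-enrichment test for one trait and one annotation
#'
#' Composes the pipeline for a single trait x annotation pair: observed
#' overlap of the element set, a length-matched background
#' ([build_background()]), the Weibull upper-tail p-value, and the
#' percent-difference enrichment on both the per-bp statistic (primary)
#' and the raw overlap count. Deterministic under a fixed seed.
#'
#' @param es An element set that has passed [filter_min_size()].
#' @param annot A merged annotation [interval_set()].
#' @param genome A [genome_define()] object.
#' @param annot_id Label for the annotation column.
#' @param n_reps Background replicates (default 1000).
#' @param seed Optional integer seed for the background.
#' @param mode Overlap counting mode, see [count_overlapping()].
#' @return A one-row tibble: `trait_id`, `annot_id`, `set_size`,
#'   `n_input_hits`, `observed_count`, `observed_ipbp`, `bg_mean_count`,
#'   `bg_mean_ipbp`, `I_percent`, `I_percent_count`, `p`, `fit_note`.
#' @export
run_trait <- function(es, annot, genome, annot_id = "annot", n_reps = 1000,
                      seed = NULL, mode = "element") {
  stopifnot(!is_rejected(es))
  obs_count <- count_overlapping(es, annot, mode = mode)
  obs_ipbp <- obs_count / total_bp(es)
  bg <- build_background(es, annot, genome, n_reps = n_reps, seed = seed,
                         mode = mode)
  p <- weibull_pvalue(bg, obs_ipbp)
  p <- min(max(p, .Machine$double.xmin), 1)
  I_ipbp <- if (mean(bg$values) > 0)
    enrichment_percent(obs_ipbp, bg$values) else NA_real_
  I_count <- if (mean(bg$counts) > 0)
    enrichment_percent(obs_count, bg$counts) else NA_real_
  tibble::tibble(
    trait_id = trait_id(es),
    annot_id = annot_id,
    set_size = nrow(es),
    n_input_hits = attr(es, "n_input_hits") %||% NA_integer_,
    observed_count = obs_count,
    observed_ipbp = obs_ipbp,
    bg_mean_count = mean(bg$counts),
    bg_mean_ipbp = mean(bg$values),
    I_percent = I_ipbp,
    I_percent_count = I_count,
    p = p,
    fit_note = bg$fit_note
  )
}

#' Run a batch of traits against a batch of annotations
#'
#' Applies the size filter, runs [run_trait()] for every passing trait x
#' annotation pair, and BH-adjusts p-values across the whole batch (one
#' FDR family per invocation; set `fdr_family = "per_annotation"` to
#' adjust within each annotation instead). Background placements depend
#' only on the trait's length bins and its derived seed (`seed` + trait
#' index), so each trait reuses identical random placements across
#' annotations — which is also what makes perturbation comparisons
#' reflect annotation changes only.
#'
#' @param element_sets Named list of element sets (names are trait ids;
#'   unnamed lists fall back to each set's own `trait_id`).
#' @param annotations Named list of merged annotation interval sets.
#' @param genome A [genome_define()] object.
#' @param n_reps Background replicates per trait.
#' @param seed Integer seed; trait i uses `seed + i`.
#' @param min_set_size Minimum element-set size (default 50).
#' @param fdr_family `"batch"` or `"per_annotation"`.
#' @param mode Overlap counting mode.
#' @return A tibble with one row per passing trait x annotation plus a
#'   `q` column; rejected traits are recorded in the `rejected`
#'   attribute (tibble of trait_id, size).
#' @export
run_enrichment <- function(element_sets, annotations, genome, n_reps = 1000,
                           seed = 1, min_set_size = 50,
                           fdr_family = c("batch", "per_annotation"),
                           mode = "element") {
  fdr_family <- match.arg(fdr_family)
  if (is.null(names(annotations))) {
    names(annotations) <- paste0("annot", seq_along(annotations))
  }
  ids <- names(element_sets)
  if (is.null(ids)) ids <- vapply(element_sets, trait_id, "")

  rejected <- list()
  rows <- list()
  for (i in seq_along(element_sets)) {
    es <- element_sets[[i]]
    fes <- filter_min_size(es, min_set_size = min_set_size)
    if (is_rejected(fes)) {
      rejected[[length(rejected) + 1]] <-
        tibble::tibble(trait_id = ids[i], size = fes$size)
      next
    }
    for (a in names(annotations)) {
      row <- run_trait(fes, annotations[[a]], genome, annot_id = a,
                       n_reps = n_reps, seed = seed + i, mode = mode)
      row$trait_id <- ids[i]
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      trait_id = character(), annot_id = character(), set_size = integer(),
      n_input_hits = integer(), observed_count = integer(),
      observed_ipbp = numeric(), bg_mean_count = numeric(),
      bg_mean_ipbp = numeric(), I_percent = numeric(),
      I_percent_count = numeric(), p = numeric(), fit_note = character(),
      q = numeric()
    )
  }
  if (nrow(out) > 0) {
    if (fdr_family == "batch") {
      out$q <- adjust_bh(out$p)
    } else {
      out <- out |>
        dplyr::group_by(.data$annot_id) |>
        dplyr::mutate(q = adjust_bh(.data$p)) |>
        dplyr::ungroup()
    }
  }
  attr(out, "rejected") <- dplyr::bind_rows(rejected)
  out
}

#' Rank concordance between two methods' enrichment tables
#'
#' Each table is independently converted to within-table ranks of its
#' enrichment values; rows are then paired on (trait_id, annot_id) and
#' the paired rank differences tested with a two-sided Wilcoxon
#' signed-rank test (zero differences dropped, ties mid-ranked; exact
#' null for up to 25 informative pairs, normal approximation with
#' continuity correction above). Identical rankings are a degenerate
#' outcome reported with p = 1.
#'
#' Note what this test can and cannot see: both rank vectors are
#' permutations of `1..n`, so the paired differences always sum to
#' zero. The test rejects only when the disagreement is asymmetric (a
#' few large displacements against many small opposite ones); a
#' perfectly reversed ranking produces symmetric differences and a
#' p-value near 1.
#'
#' @param a,b Tibbles with columns `trait_id`, `annot_id`,
#'   `enrichment`.
#' @return A one-row tibble: `statistic`, `p_value`, `n_pairs`,
#'   `degenerate`.
#' @export
rank_concordance <- function(a, b) {
  req <- c("trait_id", "annot_id", "enrichment")
  stopifnot(all(req %in% names(a)), all(req %in% names(b)))
  a <- tibble::as_tibble(a)
  b <- tibble::as_tibble(b)
  a$.rank <- rank(a$enrichment)
  b$.rank <- rank(b$enrichment)
  paired <- dplyr::inner_join(
    dplyr::select(a, "trait_id", "annot_id", rank_a = ".rank"),
    dplyr::select(b, "trait_id", "annot_id", rank_b = ".rank"),
    by = c("trait_id", "annot_id")
  )
  n <- nrow(paired)
  if (n == 0) stop("no paired rows between the two tables", call. = FALSE)
  if (n < 6) warning("fewer than 6 paired rows; test is underpowered")
  d <- paired$rank_a - paired$rank_b
  if (all(d == 0)) {
    return(tibble::tibble(statistic = NA_real_, p_value = 1, n_pairs = n,
                          degenerate = TRUE))
  }
  n_nonzero <- sum(d != 0)
  wt <- suppressWarnings(stats::wilcox.test(
    paired$rank_a, paired$rank_b, paired = TRUE,
    exact = n_nonzero <= 25, correct = TRUE
  ))
  tibble::tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
                 n_pairs = n, degenerate = FALSE)
}

#' Read a method-results table
#'
#' Generic TSV with columns `trait_id`, `annot_id`, `enrichment`, and
#' optionally `se` and `p`. Alternatively, `format = "sldsc"` reads a
#' partitioned-heritability `.results` layout (columns `Category`,
#' `Enrichment`, `Enrichment_std_error`, `Enrichment_p`), one file per
#' trait, with `trait` supplied by the caller.
#'
#' @param path Path to the TSV.
#' @param format `"generic"` or `"sldsc"`.
#' @param trait Trait id for `"sldsc"` format files.
#' @return A tibble with columns `trait_id`, `annot_id`, `enrichment`,
#'   `se`, `p` (missing optional columns are `NA`).
#' @export
read_results_table <- function(path, format = c("generic", "sldsc"),
                               trait = NULL) {
  format <- match.arg(format)
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (format == "sldsc") {
    if (is.null(trait)) stop("trait id required for sldsc format",
                             call. = FALSE)
    need <- c("Category", "Enrichment")
    if (!all(need %in% names(x))) {
      stop("not a partitioned-heritability results layout: ", path,
           call. = FALSE)
    }
    return(tibble::tibble(
      trait_id = trait,
      annot_id = as.character(x$Category),
      enrichment = as.numeric(x$Enrichment),
      se = if ("Enrichment_std_error" %in% names(x))
        as.numeric(x$Enrichment_std_error) else NA_real_,
      p = if ("Enrichment_p" %in% names(x))
        as.numeric(x$Enrichment_p) else NA_real_
    ))
  }
  req <- c("trait_id", "annot_id", "enrichment")
  if (!all(req %in% names(x))) {
    stop("results table needs columns trait_id, annot_id, enrichment: ",
         path, call. = FALSE)
  }
  tibble::tibble(
    trait_id = as.character(x$trait_id),
    annot_id = as.character(x$annot_id),
    enrichment = as.numeric(x$enrichment),
    se = if ("se" %in% names(x)) as.numeric(x$se) else NA_real_,
    p = if ("p" %in% names(x)) as.numeric(x$p) else NA_real_
  )
}

#' Write a results table with stable formatting
#'
#' Stable column order and fixed 6-decimal formatting for doubles, so a
#' rerun under the same seed is byte-identical.
#'
#' @param tbl A results tibble (e.g. from [run_enrichment()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(tbl, path) {
  fmt <- lapply(tbl, function(col) {
    if (is.double(col)) sprintf("%.6f", col) else as.character(col)
  })
  lines <- c(paste(names(tbl), collapse = "\t"),
             if (nrow(tbl)) do.call(paste, c(fmt, sep = "\t")))
  writeLines(lines, path)
  invisible(path)
}
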