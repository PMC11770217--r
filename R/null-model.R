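#' Decile length bins for an element set
#'
#' Gene lengths are strongly non-normal, so length matching works on
#' deciles: elements are sorted by length and split into 10 contiguous
#' index groups (group k gets items `floor((k-1)N/10) .. floor(kN/10)-1`;
#' ties stay in sorted order), and each group is summarised by its count
#' and arithmetic-mean length rounded to the nearest bp.
#'
#' @param es A non-empty element set (or any [interval_set()]).
#' @param n_bins Number of quantile groups (default 10).
#' @return A tibble with columns `bin`, `n`, `mean_length`; `sum(n)`
#'   equals the element-set size and `mean_length` is nondecreasing.
#' @export
make_length_bins <- function(es, n_bins = 10) {
  if (nrow(es) == 0) stop("cannot bin an empty element set", call. = FALSE)
  len <- sort(es$end - es$start)
  n <- length(len)
  lo <- floor((seq_len(n_bins) - 1) * n / n_bins)
  hi <- floor(seq_len(n_bins) * n / n_bins)
  tibble::tibble(
    bin = seq_len(n_bins),
    n = as.integer(hi - lo),
    mean_length = vapply(seq_len(n_bins), function(k) {
      if (hi[k] == lo[k]) return(NA_real_)
      round(mean(len[(lo[k] + 1):hi[k]]))
    }, numeric(1))
  )
}

# uniform random placement of intervals with fixed lengths (internal);
# chromosome chosen with probability proportional to the number of valid
# start positions (len - l + 1), start uniform on [0, len - l]
place_random_intervals <- function(lengths, genome) {
  K <- nrow(genome)
  chrom_idx <- integer(length(lengths))
  starts <- numeric(length(lengths))
  for (l in unique(lengths)) {
    sel <- which(lengths == l)
    w <- pmax(genome$length - l + 1, 0)
    if (all(w == 0)) {
      stop(sprintf("element length %d exceeds every chromosome", l),
           call. = FALSE)
    }
    idx <- if (K == 1) rep(1L, length(sel)) else
      sample.int(K, length(sel), replace = TRUE, prob = w)
    chrom_idx[sel] <- idx
    span <- genome$length[idx] - l + 1
    starts[sel] <- floor(stats::runif(length(sel)) * span)
    starts[sel] <- pmin(starts[sel], genome$length[idx] - l)
  }
  tibble::tibble(chrom = genome$chrom[chrom_idx], start = starts,
                 end = starts + lengths)
}

#' Sample one length-matched random element set
#'
#' For every length bin, draws `n` intervals of exactly the bin's mean
#' length, placed uniformly at random over the genome (chromosome chosen
#' with probability proportional to the number of valid start positions).
#' Random background intervals may overlap each other and real genes; no
#' regions are masked.
#'
#' @param bins A tibble from [make_length_bins()].
#' @param genome A [genome_define()] object.
#' @param seed Optional integer seed for reproducibility.
#' @return An [interval_set()] with `sum(bins$n)` intervals.
#' @export
sample_background_set <- function(bins, genome, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lengths <- rep(bins$mean_length[bins$n > 0], bins$n[bins$n > 0])
  interval_set(place_random_intervals(lengths, genome), genome)
}

#' Intersections per base pair
#'
#' The pipeline's test statistic: the number of elements overlapping the
#' annotation divided by the element set's total base-pair length.
#'
#' @param elements A non-empty [interval_set()].
#' @param annot A merged annotation [interval_set()].
#' @param mode Overlap counting mode, see [count_overlapping()].
#' @return Non-negative float.
#' @export
intersections_per_bp <- function(elements, annot, mode = "element") {
  tbp <- total_bp(elements)
  if (tbp == 0) stop("intersections_per_bp undefined: total_bp is 0",
                     call. = FALSE)
  count_overlapping(elements, annot, mode = mode) / tbp
}

#' Build the length-matched background distribution
#'
#' Generates `n_reps` random element sets matched to the trait's length
#' deciles, computes each set's intersections per bp against the
#' annotation, and fits a two-parameter Weibull to the positive values
#' by maximum likelihood (moment-based initialisation). Zero replicates
#' are excluded from the fit (Weibull support is x > 0); when more than
#' half the replicates are zero, or the fit fails (e.g. a degenerate
#' constant background), p-values fall back to the empirical rank and
#' `fit_note` records why.
#'
#' All replicates are drawn from one seeded stream in a single
#' vectorised pass, so a fixed seed reproduces the background exactly.
#'
#' @param es The trait's element set.
#' @param annot A merged annotation [interval_set()].
#' @param genome A [genome_define()] object.
#' @param n_reps Number of background replicates (default 1000).
#' @param seed Optional integer seed.
#' @param mode Overlap counting mode, see [count_overlapping()].
#' @return A `background_dist` object: list with `values` (per-replicate
#'   intersections per bp), `counts`, `shape`, `scale`, `n_zero`,
#'   `n_reps`, `bg_total_bp`, `fit_note`, `seed`.
#' @export
build_background <- function(es, annot, genome, n_reps = 1000, seed = NULL,
                             mode = "element") {
  stopifnot(n_reps >= 2)
  if (!is.null(seed)) set.seed(seed)
  bins <- make_length_bins(es)
  lengths <- rep(bins$mean_length[bins$n > 0], bins$n[bins$n > 0])
  m <- length(lengths)
  bg_total_bp <- sum(lengths)

  all_iv <- place_random_intervals(rep(lengths, n_reps), genome)
  rep_id <- rep(seq_len(n_reps), each = m)
  gr <- GenomicRanges::GRanges(
    seqnames = factor(all_iv$chrom, levels = genome$chrom),
    ranges = IRanges::IRanges(start = all_iv$start + 1, end = all_iv$end)
  )
  if (nrow(annot) > 0) {
    hit <- GenomicRanges::countOverlaps(gr, as_gr(annot), minoverlap = 1L)
    if (mode == "element") hit <- as.integer(hit > 0L)
    counts <- as.numeric(tapply(hit, rep_id, sum))
  } else {
    counts <- rep(0, n_reps)
  }
  values <- counts / bg_total_bp
  n_zero <- sum(values == 0)

  shape <- scale <- NA_real_
  fit_note <- "weibull"
  pos <- values[values > 0]
  if (n_zero > n_reps / 2) {
    fit_note <- sprintf("empirical fallback: %d/%d replicates zero",
                        n_zero, n_reps)
  } else if (length(pos) < 2 || stats::sd(pos) == 0) {
    fit_note <- "empirical fallback: degenerate constant background"
  } else {
    fit <- fit_weibull_mle(pos)
    if (anyNA(fit)) {
      fit_note <- "empirical fallback: weibull MLE failed"
    } else {
      shape <- fit[["shape"]]
      scale <- fit[["scale"]]
      if (n_zero > 0) {
        fit_note <- sprintf("weibull (excluding %d zero replicates)", n_zero)
      }
    }
  }
  structure(
    list(values = values, counts = counts, shape = shape, scale = scale,
         n_zero = n_zero, n_reps = n_reps, bg_total_bp = bg_total_bp,
         fit_note = fit_note, seed = seed),
    class = "background_dist"
  )
}

#' @export
print.background_dist <- function(x, ...) {
  cat(sprintf(
    "<background_dist> %d replicates, mean %.3g intersections/bp, %s\n",
    x$n_reps, mean(x$values),
    if (is.finite(x$shape))
      sprintf("Weibull(shape %.3f, scale %.3g)", x$shape, x$scale)
    else x$fit_note))
  invisible(x)
}

#' Two-parameter Weibull maximum-likelihood fit
#'
#' MLE with moment-based initialisation (no location shift), used for
#' the background null. Because the Weibull family is scale-equivariant
#' (`cX ~ Weibull(k, c * lambda)`), the sample is fitted on a
#' median-rescaled axis so that the tiny intersections-per-bp values do
#' not underflow the optimiser, and the scale estimate is mapped back.
#'
#' @param x Strictly positive sample.
#' @return Named vector `c(shape =, scale =)`, or `NA`s if the fit
#'   fails.
#' @export
fit_weibull_mle <- function(x) {
  stopifnot(all(x > 0))
  s0 <- stats::median(x)
  fit <- tryCatch(
    suppressWarnings(fitdistrplus::fitdist(x / s0, "weibull")),
    error = function(e) NULL
  )
  if (is.null(fit) || any(!is.finite(fit$estimate)) ||
      any(fit$estimate <= 0)) {
    return(c(shape = NA_real_, scale = NA_real_))
  }
  c(shape = unname(fit$estimate["shape"]),
    scale = unname(fit$estimate["scale"]) * s0)
}

#' Upper-tail p-value against the background null
#'
#' With a successful Weibull fit, `P(X >= observed) =
#' exp(-(observed/scale)^shape)`, which is 1 at 0 and strictly
#' decreasing. When the fit fell back, the empirical rank p-value
#' `(1 + #{values >= observed}) / (n_reps + 1)` is used.
#'
#' @param bg A `background_dist` from [build_background()].
#' @param observed Observed intersections per bp (must be >= 0).
#' @return p-value in (0, 1].
#' @export
weibull_pvalue <- function(bg, observed) {
  stopifnot(inherits(bg, "background_dist"))
  if (!is.finite(observed) || observed < 0) {
    stop("observed statistic must be >= 0", call. = FALSE)
  }
  if (is.finite(bg$shape) && is.finite(bg$scale)) {
    exp(-(observed / bg$scale)^bg$shape)
  } else {
    (1 + sum(bg$values >= observed)) / (bg$n_reps + 1)
  }
}

#' Persist / restore a background distribution
#'
#' The replicate values go to a two-column TSV (`replicate`, `value`)
#' and the fit parameters and seed to a JSON sidecar (`<path>.json`),
#' enabling exact reruns.
#'
#' @param bg A `background_dist`.
#' @param path TSV output path.
#' @return `path` ([write_background()]) or a `background_dist`
#'   ([read_background()]).
#' @export
write_background <- function(bg, path) {
  readr::write_tsv(
    tibble::tibble(replicate = seq_along(bg$values), value = bg$values),
    path, progress = FALSE
  )
  meta <- bg[c("shape", "scale", "n_zero", "n_reps", "bg_total_bp",
               "fit_note", "seed")]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_background
#' @export
read_background <- function(path) {
  vals <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(
    list(values = vals$value, counts = NULL,
         shape = meta$shape %||% NA_real_, scale = meta$scale %||% NA_real_,
         n_zero = meta$n_zero, n_reps = meta$n_reps,
         bg_total_bp = meta$bg_total_bp, fit_note = meta$fit_note,
         seed = meta$seed),
    class = "background_dist"
  )
}
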