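#' Interval tables
#'
#' All genomic regions in this package are plain tibbles with columns
#' `chrom`, `start`, `end` (BED convention: 0-based half-open) and an
#' optional `name`. [interval_set()] validates a data frame against a
#' genome definition, sorts it deterministically, and tags it with the
#' genome so downstream set operations can refuse to mix builds.
#'
#' @param x A data frame with columns `chrom`, `start`, `end` and
#'   optionally `name`.
#' @param genome A [genome_define()] object.
#' @param merged Logical; `TRUE` asserts that no two intervals on the
#'   same chromosome overlap or abut (set by [merge_intervals()]).
#' @return A sorted tibble of class `interval_set` with attributes
#'   `genome` and `merged`.
#' @examples
#' g <- genome_define(c(chr1 = 1000))
#' interval_set(data.frame(chrom = "chr1", start = c(10, 2), end = c(20, 5)), g)
#' @export
interval_set <- function(x, genome, merged = FALSE) {
  stopifnot(inherits(genome, "genome_def"))
  x <- tibble::as_tibble(x)
  req <- c("chrom", "start", "end")
  if (!all(req %in% names(x))) {
    stop("interval table needs columns chrom, start, end", call. = FALSE)
  }
  if (!"name" %in% names(x)) x$name <- NA_character_
  x <- x[, c("chrom", "start", "end", "name")]
  x$chrom <- as.character(x$chrom)
  x$start <- as.numeric(x$start)
  x$end <- as.numeric(x$end)
  x$name <- as.character(x$name)

  unknown <- setdiff(unique(x$chrom), genome$chrom)
  if (length(unknown)) {
    stop("unknown chromosome(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(x) > 0) {
    if (any(x$start != floor(x$start)) || any(x$end != floor(x$end))) {
      stop("interval coordinates must be integers", call. = FALSE)
    }
    if (any(x$start < 0) || any(x$start >= x$end)) {
      stop("invalid interval: require 0 <= start < end", call. = FALSE)
    }
    lens <- genome$length[match(x$chrom, genome$chrom)]
    if (any(x$end > lens)) {
      bad <- which(x$end > lens)[1]
      stop(sprintf("interval %s:%d-%d exceeds chromosome length %d",
                   x$chrom[bad], x$start[bad], x$end[bad], lens[bad]),
           call. = FALSE)
    }
  }
  ord <- order(match(x$chrom, genome$chrom), x$start, x$end, method = "radix")
  x <- x[ord, , drop = FALSE]
  out <- structure(x, genome = genome, merged = isTRUE(merged),
                   class = c("interval_set", class(tibble::tibble())))
  # cache the GRanges form: S4 construction dominates small-input set
  # operations, and every op needs it
  attr(out, ".gr") <- build_gr(out)
  out
}

#' @rdname interval_set
#' @export
iv_genome <- function(x) attr(x, "genome")

#' @rdname interval_set
#' @export
is_merged <- function(x) isTRUE(attr(x, "merged"))

#' Total base pairs covered by an interval table
#'
#' Sum of interval lengths. Only equal to the covered footprint when the
#' set is merged.
#'
#' @param x An [interval_set()].
#' @return Numeric scalar.
#' @export
total_bp <- function(x) {
  if (nrow(x) == 0) return(0)
  sum(x$end - x$start)
}

# ---- GRanges bridge (internal) ---------------------------------------------

build_gr <- function(x) {
  g <- iv_genome(x)
  sl <- stats::setNames(g$length, g$chrom)
  GenomicRanges::GRanges(
    seqnames = factor(x$chrom, levels = g$chrom),
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end),
    seqlengths = sl
  )
}

as_gr <- function(x) {
  cached <- attr(x, ".gr")
  if (!is.null(cached) && length(cached) == nrow(x)) return(cached)
  build_gr(x)
}

gr_to_iv <- function(gr, genome, merged = FALSE) {
  interval_set(
    tibble::tibble(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1,
      end = GenomicRanges::end(gr)
    ),
    genome, merged = merged
  )
}

check_same_build <- function(a, b) {
  ba <- genome_build(iv_genome(a))
  bb <- genome_build(iv_genome(b))
  if (!identical(ba, bb)) {
    stop(sprintf("genome build mismatch: '%s' vs '%s'", ba, bb), call. = FALSE)
  }
  invisible(TRUE)
}

# ---- BED I/O ----------------------------------------------------------------

#' Read a BED3+ file into an interval table
#'
#' Tab-separated, no header, at least three columns; a fourth column is
#' kept as the interval name and further columns are ignored. Coordinates
#' are 0-based half-open and validated against the genome: malformed
#' lines raise an error naming the line, intervals beyond chromosome
#' bounds or on unknown chromosomes raise an error.
#'
#' @param path Path to a BED file.
#' @param genome A [genome_define()] object.
#' @return An [interval_set()] (not flagged merged).
#' @export
read_bed <- function(path, genome) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  if (!any(keep)) {
    return(interval_set(tibble::tibble(chrom = character(), start = numeric(),
                                       end = numeric()), genome))
  }
  lineno <- which(keep)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  ncols <- vapply(parts, length, 1L)
  if (any(ncols < 3)) {
    stop(sprintf("BED parse error at line %d: fewer than 3 columns",
                 lineno[which(ncols < 3)[1]]), call. = FALSE)
  }
  chrom <- vapply(parts, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) |
                 start != floor(start) | end != floor(end))
  if (length(bad)) {
    stop(sprintf("BED parse error at line %d: non-integer coordinates",
                 lineno[bad[1]]), call. = FALSE)
  }
  bad <- which(start < 0 | start >= end)
  if (length(bad)) {
    stop(sprintf("BED parse error at line %d: start >= end", lineno[bad[1]]),
         call. = FALSE)
  }
  name <- ifelse(ncols >= 4,
                 vapply(parts, function(p) if (length(p) >= 4) p[[4]] else NA_character_, ""),
                 NA_character_)
  interval_set(tibble::tibble(chrom = chrom, start = start, end = end,
                              name = name), genome)
}

#' Write an interval table as BED
#'
#' Emits sorted tab-separated BED3 (or BED4 when any name is present),
#' deterministically.
#'
#' @param x An [interval_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  if (nrow(x) > 0 && any(!is.na(x$name))) {
    lines <- sprintf("%s\t%d\t%d\t%s", x$chrom, x$start, x$end,
                     ifelse(is.na(x$name), ".", x$name))
  } else {
    lines <- sprintf("%s\t%d\t%d", x$chrom, x$start, x$end)
  }
  writeLines(lines, path)
  invisible(path)
}

# ---- set operations ---------------------------------------------------------

#' Merge overlapping and book-ended intervals
#'
#' Union of intervals; intervals that overlap or abut (0-bp gap) on the
#' same chromosome are joined, matching the default behaviour of the
#' standard BED merge tool. Idempotent; names are dropped.
#'
#' @param x An [interval_set()].
#' @return A merged [interval_set()] with `merged` flag set.
#' @export
merge_intervals <- function(x) {
  if (nrow(x) == 0) {
    return(interval_set(x, iv_genome(x), merged = TRUE))
  }
  gr_to_iv(GenomicRanges::reduce(as_gr(x)), iv_genome(x), merged = TRUE)
}

#' Intersect two interval tables
#'
#' Returns the merged sub-intervals covered by both inputs. Symmetric in
#' covered base pairs. Inputs must share the genome build.
#'
#' @param a,b [interval_set()] objects on the same build.
#' @return A merged [interval_set()].
#' @export
intersect_intervals <- function(a, b) {
  check_same_build(a, b)
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(interval_set(tibble::tibble(chrom = character(), start = numeric(),
                                       end = numeric()), iv_genome(a),
                        merged = TRUE))
  }
  gr_to_iv(GenomicRanges::intersect(as_gr(a), as_gr(b)), iv_genome(a),
           merged = TRUE)
}

#' Subtract one interval table from another
#'
#' Sub-intervals of `a` not covered by `b`; together with
#' [intersect_intervals()] this partitions the merged footprint of `a`.
#'
#' @inheritParams intersect_intervals
#' @return A merged [interval_set()].
#' @export
subtract_intervals <- function(a, b) {
  check_same_build(a, b)
  if (nrow(a) == 0) {
    return(interval_set(a, iv_genome(a), merged = TRUE))
  }
  if (nrow(b) == 0) return(merge_intervals(a))
  gr_to_iv(GenomicRanges::setdiff(as_gr(a), as_gr(b)), iv_genome(a),
           merged = TRUE)
}

#' Proportion of one annotation's base pairs covered by another
#'
#' `total_bp(intersect(a, b)) / total_bp(a)`. Asymmetric by design: the
#' denominator is `a`. Both inputs must already be merged so that base
#' pairs are counted once.
#'
#' @inheritParams intersect_intervals
#' @return A fraction in `[0, 1]`.
#' @export
overlap_proportion <- function(a, b) {
  check_same_build(a, b)
  if (!is_merged(a) || !is_merged(b)) {
    stop("overlap_proportion requires merged inputs; call merge_intervals() first",
         call. = FALSE)
  }
  denom <- total_bp(a)
  if (denom == 0) {
    stop("overlap_proportion undefined: total_bp(a) is 0", call. = FALSE)
  }
  total_bp(intersect_intervals(a, b)) / denom
}

#' Count elements overlapping an annotation
#'
#' Number of intervals in `elements` with at least one overlapping base
#' in `annot`; each element is counted at most once (`mode = "element"`,
#' the default, mirroring `-u`-style overlap counting). `mode = "pair"`
#' instead counts every (element, annotation interval) overlapping pair,
#' for sensitivity checks.
#'
#' @param elements An [interval_set()] of elements (e.g. gene spans).
#' @param annot A merged [interval_set()] annotation.
#' @param mode `"element"` or `"pair"`.
#' @return Non-negative integer count.
#' @export
count_overlapping <- function(elements, annot, mode = c("element", "pair")) {
  mode <- match.arg(mode)
  check_same_build(elements, annot)
  if (nrow(elements) == 0 || nrow(annot) == 0) return(0L)
  n <- GenomicRanges::countOverlaps(as_gr(elements), as_gr(annot),
                                    minoverlap = 1L)
  if (mode == "element") sum(n > 0L) else as.integer(sum(n))
}
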