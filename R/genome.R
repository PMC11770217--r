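#' Define a genome as an ordered chromosome table
#'
#' A genome definition is the coordinate frame every interval table is
#' validated against: an ordered set of chromosome names with lengths in
#' base pairs. Chromosomes are stored in natural order (`chr1 < chr2 <
#' ... < chr10`) so that all sorted output is deterministic.
#'
#' @param chromosomes Either a named numeric vector of chromosome lengths
#'   (names are chromosome names) or a data frame with columns `chrom`
#'   and `length`.
#' @param build_label Free-text label for the genome build; interval
#'   tables carry it and operations refuse to mix builds.
#' @return A tibble with columns `chrom` and `length`, class
#'   `genome_def`, with attribute `build_label`.
#' @examples
#' genome_define(c(chr1 = 1e6, chr2 = 5e5), build_label = "toy")
#' @export
genome_define <- function(chromosomes, build_label = "custom") {
  if (is.data.frame(chromosomes)) {
    stopifnot(all(c("chrom", "length") %in% names(chromosomes)))
    tbl <- tibble::tibble(
      chrom = as.character(chromosomes$chrom),
      length = as.numeric(chromosomes$length)
    )
  } else {
    if (is.null(names(chromosomes)) || any(names(chromosomes) == "")) {
      stop("chromosome lengths must be named", call. = FALSE)
    }
    tbl <- tibble::tibble(
      chrom = names(chromosomes),
      length = as.numeric(chromosomes)
    )
  }
  if (anyDuplicated(tbl$chrom)) {
    stop("duplicate chromosome names in genome definition", call. = FALSE)
  }
  if (any(!is.finite(tbl$length)) || any(tbl$length < 1)) {
    stop("all chromosome lengths must be >= 1", call. = FALSE)
  }
  tbl$length <- round(tbl$length)
  tbl <- tbl[natural_chrom_order(tbl$chrom), , drop = FALSE]
  structure(tbl, build_label = build_label,
            class = c("genome_def", class(tibble::as_tibble(tbl))))
}

#' Read a UCSC-style chrom.sizes file
#'
#' Two tab-separated columns, chromosome name and length, no header.
#'
#' @param path Path to the chrom.sizes file.
#' @inheritParams genome_define
#' @return A [genome_define()] object.
#' @export
read_chrom_sizes <- function(path, build_label = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty chrom.sizes file: ", path, call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 2)
  if (length(bad)) {
    stop(sprintf("chrom.sizes parse error at line %d: expected 2 columns", bad[1]),
         call. = FALSE)
  }
  nm <- vapply(parts, `[[`, "", 1L)
  len <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (anyNA(len)) {
    stop(sprintf("chrom.sizes parse error at line %d: non-numeric length",
                 which(is.na(len))[1]), call. = FALSE)
  }
  genome_define(stats::setNames(len, nm), build_label = build_label)
}

#' @export
print.genome_def <- function(x, ...) {
  cat(sprintf("<genome_def> build '%s': %d chromosome(s), %s bp total\n",
              genome_build(x), nrow(x), format(sum(x$length), big.mark = ",")))
  NextMethod()
}

#' Total genome length in base pairs
#' @param genome A [genome_define()] object.
#' @return Numeric scalar, sum of chromosome lengths.
#' @export
genome_size <- function(genome) sum(genome$length)

#' @rdname genome_size
#' @export
genome_build <- function(genome) attr(genome, "build_label") %||% "custom"

# natural sort order for chromosome names: numeric suffix first, rest after
natural_chrom_order <- function(x) {
  stripped <- sub("^chr", "", x, ignore.case = TRUE)
  num <- suppressWarnings(as.numeric(stripped))
  order(is.na(num), num, x, method = "radix")
}
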