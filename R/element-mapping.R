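#' Default protein-coding biotype whitelist
#'
#' Biotype labels (Ensembl/VEP vocabulary) treated as protein-coding
#' features when mapping significant variants to genes. The default is
#' the conventional protein-coding-like list spanning immunoglobulin and
#' T-cell-receptor segment genes and decay/pseudogene edge cases; it is
#' fully user-overridable.
#'
#' @return Character vector of biotype labels.
#' @export
default_biotypes <- function() {
  c("protein_coding", "IG_C_gene", "IG_D_gene", "IG_J_gene", "IG_LV_gene",
    "IG_M_gene", "IG_V_gene", "IG_Z_gene", "nonsense_mediated_decay",
    "nontranslating_CDS", "non_stop_decay", "polymorphic_pseudogene",
    "TR_C_gene", "TR_D_gene", "TR_J_gene")
}

#' Read a GWAS hits table
#'
#' Tab-separated with header and columns `chrom`, `pos` (1-based),
#' `id`, `pvalue`. Rows are the trait's independent genome-wide
#' significant loci (LD clumping is assumed done upstream).
#'
#' @param path Path to the TSV.
#' @param genome Optional [genome_define()]; if given, positions are
#'   validated against chromosome bounds.
#' @return A tibble with columns `chrom`, `pos`, `id`, `pvalue`.
#' @export
read_gwas_hits <- function(path, genome = NULL) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("chrom", "pos", "id", "pvalue")
  if (!all(req %in% names(x))) {
    stop("hits table needs columns chrom, pos, id, pvalue: ", path,
         call. = FALSE)
  }
  x <- tibble::as_tibble(x)[, req]
  x$chrom <- as.character(x$chrom)
  x$pos <- as.numeric(x$pos)
  x$id <- as.character(x$id)
  if (any(!is.finite(x$pos)) || any(x$pos < 1)) {
    stop("hit positions must be positive 1-based integers", call. = FALSE)
  }
  if (any(x$pvalue <= 0 | x$pvalue > 1)) {
    stop("hit p-values must lie in (0, 1]", call. = FALSE)
  }
  if (!is.null(genome)) {
    unknown <- setdiff(unique(x$chrom), genome$chrom)
    if (length(unknown)) {
      stop("unknown chromosome(s) in hits: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    lens <- genome$length[match(x$chrom, genome$chrom)]
    if (any(x$pos > lens)) stop("hit position beyond chromosome end",
                                call. = FALSE)
  }
  x
}

#' Read a gene feature table
#'
#' Two source formats are supported. A TSV with header and columns
#' `feature_id`, `chrom`, `start`, `end`, `strand`, `biotype`, with
#' 1-based inclusive coordinates (converted to the package's 0-based
#' half-open convention on read). Or a GFF3 file, from which gene-level
#' records are taken, with the biotype read from the `biotype`,
#' `gene_biotype` or `gene_type` attribute (requires the rtracklayer
#' package).
#'
#' @param path Path to the gene table.
#' @param format `"tsv"` or `"gff3"`; guessed from the file extension by
#'   default.
#' @return A tibble with columns `feature_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`, `biotype`.
#' @export
read_gene_table <- function(path, format = c("auto", "tsv", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE))
      "gff3" else "tsv"
  }
  if (format == "gff3") {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      stop("reading GFF3 requires the rtracklayer package", call. = FALSE)
    }
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
    md <- S4Vectors::mcols(gr)
    biotype <- md$biotype %||% md$gene_biotype %||% md$gene_type
    if (is.null(biotype)) {
      stop("GFF3 gene records carry no biotype/gene_biotype attribute",
           call. = FALSE)
    }
    fid <- md$gene_id %||% md$ID %||% md$Name
    g <- tibble::tibble(
      feature_id = as.character(fid),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1,
      end = as.numeric(GenomicRanges::end(gr)),
      strand = as.character(GenomicRanges::strand(gr)),
      biotype = as.character(biotype)
    )
    g$strand[g$strand == "*"] <- "."
    return(g)
  }
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("feature_id", "chrom", "start", "end", "strand", "biotype")
  if (!all(req %in% names(x))) {
    stop("gene table needs columns feature_id, chrom, start, end, strand, biotype",
         call. = FALSE)
  }
  tibble::tibble(
    feature_id = as.character(x$feature_id),
    chrom = as.character(x$chrom),
    start = as.numeric(x$start) - 1,  # 1-based inclusive -> 0-based half-open
    end = as.numeric(x$end),
    strand = as.character(x$strand),
    biotype = as.character(x$biotype)
  )
}

#' Map significant variants to their closest allowed gene
#'
#' For each hit, among whitelisted-biotype features on the same
#' chromosome, the distance is 0 if the variant base lies inside the
#' feature span and otherwise the number of bases between the variant
#' and the nearest feature edge. The closest feature with distance
#' `<= dist_bp` (window inclusive) is returned; ties are broken by
#' smaller start coordinate, then lexicographic `feature_id`. A hit with
#' no candidate maps to `NA`, which is a valid outcome.
#'
#' @param hits A hits tibble (see [read_gwas_hits()]).
#' @param genes A gene tibble (see [read_gene_table()]).
#' @param whitelist Character vector of allowed biotypes.
#' @param dist_bp Maximum mapping distance in bp (default 5000).
#' @return `hits` with added columns `feature_id` and `distance`
#'   (`NA` where unmapped).
#' @export
map_hits <- function(hits, genes, whitelist = default_biotypes(),
                     dist_bp = 5000) {
  stopifnot(dist_bp >= 0, length(whitelist) >= 1)
  wl <- genes[genes$biotype %in% whitelist, , drop = FALSE]
  hits <- tibble::as_tibble(hits)
  hits$.hit_row <- seq_len(nrow(hits))
  if (nrow(wl) == 0 || nrow(hits) == 0) {
    hits$feature_id <- NA_character_
    hits$distance <- NA_real_
    hits$.hit_row <- NULL
    return(hits)
  }
  cand <- dplyr::inner_join(
    dplyr::select(hits, ".hit_row", "chrom", "pos"),
    dplyr::select(wl, "chrom", g_start = "start", g_end = "end", "feature_id"),
    by = "chrom", relationship = "many-to-many"
  )
  h0 <- cand$pos - 1  # variant base, 0-based
  cand$distance <- pmax(0, cand$g_start - h0, h0 - (cand$g_end - 1))
  cand <- cand[cand$distance <= dist_bp, , drop = FALSE]
  best <- cand |>
    dplyr::arrange(.data$distance, .data$g_start, .data$feature_id) |>
    dplyr::distinct(.data$.hit_row, .keep_all = TRUE) |>
    dplyr::select(".hit_row", "feature_id", "distance")
  out <- dplyr::left_join(hits, best, by = ".hit_row")
  out$.hit_row <- NULL
  out
}

#' Build a trait's element set
#'
#' Maps every significant locus to its closest whitelisted gene within
#' `dist_bp`, drops unmapped hits, and deduplicates by `feature_id`. The
#' element intervals are the full gene-body spans, which is what overlap
#' counting uses downstream.
#'
#' @inheritParams map_hits
#' @param genome A [genome_define()] object.
#' @param trait_id Label recorded on the element set.
#' @return An [interval_set()] subclassed as `element_set`, with
#'   attributes `trait_id`, `n_input_hits` and `dist_bp`; interval names
#'   are the feature ids.
#' @export
build_element_set <- function(hits, genes, genome,
                              whitelist = default_biotypes(),
                              dist_bp = 5000, trait_id = "trait") {
  mapped <- map_hits(hits, genes, whitelist = whitelist, dist_bp = dist_bp)
  mapped <- mapped[!is.na(mapped$feature_id), , drop = FALSE]
  feats <- genes[match(unique(mapped$feature_id), genes$feature_id), ,
                 drop = FALSE]
  es <- interval_set(
    tibble::tibble(chrom = feats$chrom, start = feats$start, end = feats$end,
                   name = feats$feature_id),
    genome
  )
  structure(es, trait_id = trait_id, n_input_hits = nrow(hits),
            dist_bp = dist_bp,
            class = c("element_set", class(es)))
}

#' @rdname build_element_set
#' @param es An `element_set`.
#' @export
trait_id <- function(es) attr(es, "trait_id") %||% NA_character_

#' Apply the minimum element-set size filter
#'
#' Traits whose element set has fewer than `min_set_size` members lack
#' power for the overlap statistic and are rejected. The boundary is
#' inclusive: a set of exactly `min_set_size` passes. Rejection is a
#' typed return value (`element_set_rejection`), not an error.
#'
#' @param es An element set from [build_element_set()].
#' @param min_set_size Minimum number of unique features (default 50; 40
#'   is a commonly used laxer preset).
#' @return `es` unchanged if it passes, otherwise an
#'   `element_set_rejection` object carrying the trait id and size.
#' @export
filter_min_size <- function(es, min_set_size = 50) {
  if (nrow(es) >= min_set_size) return(es)
  structure(
    list(trait_id = trait_id(es), size = nrow(es),
         min_set_size = min_set_size),
    class = "element_set_rejection"
  )
}

#' @rdname filter_min_size
#' @param x Object to test.
#' @export
is_rejected <- function(x) inherits(x, "element_set_rejection")

#' @export
print.element_set_rejection <- function(x, ...) {
  cat(sprintf("<element_set_rejection> trait '%s': %d element(s), need >= %d\n",
              x$trait_id, x$size, x$min_set_size))
  invisible(x)
}

#' Write an element set as BED
#'
#' BED4 with the feature id in the name column.
#' @param es An element set.
#' @param path Output path.
#' @export
write_element_set <- function(es, path) write_bed(es, path)
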