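# Independent brute-force oracles for the interval engine, plus small
# fixture builders. Deliberately naive O(n*m) implementations on plain
# data frames, sharing no code with the package's set operations.

toy_genome <- function(lens = c(chr1 = 10000, chr2 = 8000)) {
  genome_define(lens, build_label = "toy")
}

iv <- function(genome, chrom, start, end, name = NA_character_) {
  interval_set(tibble::tibble(chrom = chrom, start = start, end = end,
                              name = name), genome)
}

random_intervals <- function(genome, n, max_len = 400) {
  k <- sample.int(nrow(genome), n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  len <- pmin(len, genome$length[k])
  start <- floor(runif(n) * (genome$length[k] - len + 1))
  iv(genome, genome$chrom[k], start, start + len)
}

empty_plain <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric())
}

# union by sort + running-maximum scan per chromosome
bf_merge <- function(df) {
  if (nrow(df) == 0) return(empty_plain())
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  run_end <- stats::ave(df$end, df$chrom, FUN = cummax)
  n <- nrow(df)
  new_block <- c(TRUE, df$chrom[-1] != df$chrom[-n] |
                   df$start[-1] > run_end[-n])
  grp <- cumsum(new_block)
  data.frame(chrom = df$chrom[new_block],
             start = df$start[new_block],
             end = as.numeric(tapply(df$end, grp, max)))
}

# all pairs, clipped, then merged
bf_intersect <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(empty_plain())
  ii <- rep(seq_len(nrow(a)), times = nrow(b))
  jj <- rep(seq_len(nrow(b)), each = nrow(a))
  s <- pmax(a$start[ii], b$start[jj])
  e <- pmin(a$end[ii], b$end[jj])
  keep <- a$chrom[ii] == b$chrom[jj] & s < e
  if (!any(keep)) return(empty_plain())
  bf_merge(data.frame(chrom = a$chrom[ii][keep], start = s[keep],
                      end = e[keep]))
}

# per a-interval: clip the blockers, merge them, emit the gaps
bf_subtract <- function(a, b) {
  pieces <- vector("list", nrow(a))
  for (i in seq_len(nrow(a))) {
    s <- a$start[i]
    e <- a$end[i]
    sel <- b$chrom == a$chrom[i] & b$start < e & b$end > s
    if (!any(sel)) {
      pieces[[i]] <- data.frame(chrom = a$chrom[i], start = s, end = e)
      next
    }
    blocked <- bf_merge(data.frame(chrom = a$chrom[i],
                                   start = pmax(b$start[sel], s),
                                   end = pmin(b$end[sel], e)))
    gs <- c(s, blocked$end)
    ge <- c(blocked$start, e)
    ok <- gs < ge
    if (any(ok)) {
      pieces[[i]] <- data.frame(chrom = a$chrom[i], start = gs[ok],
                                end = ge[ok])
    }
  }
  pieces <- pieces[!vapply(pieces, is.null, TRUE)]
  if (length(pieces) == 0) return(empty_plain())
  bf_merge(do.call(rbind, pieces))
}

# elements with any overlapping annotation interval (all-pairs matrix)
bf_count <- function(elements, annot) {
  if (nrow(elements) == 0 || nrow(annot) == 0) return(0L)
  same <- outer(elements$chrom, annot$chrom, "==")
  ov <- outer(elements$start, annot$end, "<") &
    t(outer(annot$start, elements$end, "<"))
  sum(rowSums(same & ov) > 0)
}

as_plain <- function(x) {
  data.frame(chrom = as.character(x$chrom), start = as.numeric(x$start),
             end = as.numeric(x$end))
}

# small, fast simulation configuration shared across tests
small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_chroms = 2, chrom_length = 2e6, n_genes = 900,
         annot_coverage = 0.05, n_hits = 60),
    list(...)
  )
  do.call(sim_config, args)
}
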