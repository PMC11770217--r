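#' Configuration for the synthetic study generator
#'
#' Desk-scale defaults: a 2 x 10 Mb genome, 2,000 genes with log-normal
#' lengths (median 2 kb, sigma 0.5 on the log scale), 80% of genes
#' protein-coding, a clustered annotation covering 5% of the genome in
#' ~1 kb regions, and 60 significant loci per trait. `rho` is the
#' planted enrichment: the probability that a hit's gene is drawn from
#' the genes overlapping the annotation rather than uniformly; `rho = 0`
#' is a null trait. Planting acts at the gene level because the
#' pipeline's statistic counts overlapping elements.
#'
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Chromosome length in bp.
#' @param n_genes Number of genes.
#' @param gene_length_median,gene_length_sigma Log-normal gene-length
#'   parameters (median bp, log-scale sigma).
#' @param prop_coding Fraction of genes given a whitelisted
#'   (protein_coding) biotype.
#' @param annot_coverage Target merged genome fraction of the
#'   annotation, in (0, 1).
#' @param annot_length_median,annot_length_sigma Log-normal annotation
#'   region-length parameters.
#' @param n_hits Significant loci per trait.
#' @param rho Planted enrichment probability in `[0, 1]`.
#' @param dist_bp Variant-to-gene mapping window (hits are placed within
#'   `dist_bp / 2` of their source gene).
#' @param n_reps Default background replicates for runs on this
#'   configuration.
#' @param seed Base seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_chroms = 2, chrom_length = 1e7, n_genes = 2000,
                       gene_length_median = 2000, gene_length_sigma = 0.5,
                       prop_coding = 0.8, annot_coverage = 0.05,
                       annot_length_median = 1000, annot_length_sigma = 0.5,
                       n_hits = 60, rho = 0, dist_bp = 5000, n_reps = 1000,
                       seed = 1) {
  cfg <- list(n_chroms = n_chroms, chrom_length = chrom_length,
              n_genes = n_genes, gene_length_median = gene_length_median,
              gene_length_sigma = gene_length_sigma,
              prop_coding = prop_coding, annot_coverage = annot_coverage,
              annot_length_median = annot_length_median,
              annot_length_sigma = annot_length_sigma, n_hits = n_hits,
              rho = rho, dist_bp = dist_bp, n_reps = n_reps, seed = seed)
  stopifnot(cfg$n_chroms >= 1, cfg$chrom_length >= 1, cfg$n_genes >= 1,
            cfg$n_hits >= 1, cfg$rho >= 0, cfg$rho <= 1,
            cfg$annot_coverage > 0, cfg$annot_coverage < 1,
            cfg$prop_coding > 0, cfg$prop_coding <= 1)
  if (cfg$gene_length_median >= cfg$chrom_length) {
    stop("gene lengths must fit within a chromosome", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

non_coding_biotypes <- c("lincRNA", "antisense", "processed_pseudogene",
                         "miRNA", "snoRNA")

#' Simulate a genome and gene table
#'
#' Chromosomes `chr1..chrN` of equal length; gene lengths log-normal
#' (clamped to the chromosome), placements uniform (genes may overlap,
#' as real gene models do); biotypes protein_coding with probability
#' `prop_coding`, otherwise drawn from common non-coding labels.
#'
#' @param cfg A [sim_config()].
#' @param seed Seed (defaults to `cfg$seed`).
#' @return A list with elements `genome` (a [genome_define()]) and
#'   `genes` (tibble as from [read_gene_table()]).
#' @export
simulate_genome_and_genes <- function(cfg, seed = cfg$seed) {
  set.seed(seed)
  genome <- genome_define(
    stats::setNames(rep(cfg$chrom_length, cfg$n_chroms),
                    paste0("chr", seq_len(cfg$n_chroms))),
    build_label = "synthetic"
  )
  n <- cfg$n_genes
  len <- round(stats::rlnorm(n, meanlog = log(cfg$gene_length_median),
                             sdlog = cfg$gene_length_sigma))
  len <- pmin(pmax(len, 50), cfg$chrom_length)
  chrom_idx <- sample.int(cfg$n_chroms, n, replace = TRUE)
  start <- floor(stats::runif(n) * (cfg$chrom_length - len + 1))
  biotype <- ifelse(stats::runif(n) < cfg$prop_coding, "protein_coding",
                    sample(non_coding_biotypes, n, replace = TRUE))
  genes <- tibble::tibble(
    feature_id = sprintf("G%05d", seq_len(n)),
    chrom = paste0("chr", chrom_idx),
    start = start,
    end = start + len,
    strand = sample(c("+", "-"), n, replace = TRUE),
    biotype = biotype
  )
  list(genome = genome, genes = genes)
}

#' Simulate a clustered annotation with target coverage
#'
#' Adds random log-normal-length regions until the merged footprint
#' reaches `annot_coverage` of the genome; the realised coverage lands
#' within ~2% of the target (the last region can overshoot by at most
#' its own length, which is tiny relative to the target).
#'
#' @inheritParams simulate_genome_and_genes
#' @param genome The genome to annotate.
#' @return A merged [interval_set()].
#' @export
simulate_annotation <- function(cfg, genome, seed = cfg$seed + 1000L) {
  set.seed(seed)
  target <- cfg$annot_coverage * genome_size(genome)
  mean_len <- exp(log(cfg$annot_length_median) +
                    cfg$annot_length_sigma^2 / 2)
  acc <- NULL
  covered <- 0
  while (covered < target) {
    n_new <- max(10L, ceiling((target - covered) / mean_len * 0.9))
    len <- round(stats::rlnorm(n_new, log(cfg$annot_length_median),
                               cfg$annot_length_sigma))
    len <- pmin(pmax(len, 10), min(genome$length))
    new <- place_random_intervals(len, genome)
    acc <- if (is.null(acc)) new else dplyr::bind_rows(acc, new)
    merged <- merge_intervals(interval_set(acc, genome))
    covered <- total_bp(merged)
    acc <- tibble::as_tibble(merged)[, c("chrom", "start", "end")]
  }
  merged
}

#' Simulate one trait's genome-wide significant hits
#'
#' For each of `n_hits` loci: with probability `rho` the source gene is
#' drawn uniformly from whitelisted genes overlapping the annotation,
#' otherwise uniformly from all whitelisted genes; the hit is then
#' placed uniformly within `dist_bp / 2` of the gene span (clamped to
#' the chromosome). P-values are uniform below genome-wide significance.
#'
#' @inheritParams simulate_genome_and_genes
#' @param genome,genes Output of [simulate_genome_and_genes()].
#' @param annot The annotation from [simulate_annotation()].
#' @param trait Label used in variant ids.
#' @return A hits tibble (`chrom`, `pos`, `id`, `pvalue`).
#' @export
simulate_trait_hits <- function(cfg, genome, genes, annot, trait = "T1",
                                seed = cfg$seed + 2000L) {
  set.seed(seed)
  wl <- genes[genes$biotype %in% default_biotypes(), , drop = FALSE]
  if (nrow(wl) == 0) stop("no whitelisted genes to sample hits from",
                          call. = FALSE)
  wl_iv <- interval_set(
    tibble::tibble(chrom = wl$chrom, start = wl$start, end = wl$end,
                   name = wl$feature_id), genome)
  ov <- GenomicRanges::countOverlaps(as_gr(wl_iv), as_gr(annot)) > 0
  # countOverlaps follows wl_iv's sorted order; map back to gene rows
  ov_ids <- wl_iv$name[ov]
  overlapping <- which(wl$feature_id %in% ov_ids)
  if (cfg$rho > 0 && length(overlapping) == 0) {
    stop("planted enrichment requested but no whitelisted gene overlaps the annotation",
         call. = FALSE)
  }
  n <- cfg$n_hits
  planted <- stats::runif(n) < cfg$rho
  gidx <- integer(n)
  gidx[planted] <- overlapping[sample.int(length(overlapping),
                                          sum(planted), replace = TRUE)]
  gidx[!planted] <- sample.int(nrow(wl), sum(!planted), replace = TRUE)
  half <- floor(cfg$dist_bp / 2)
  lo <- pmax(wl$start[gidx] - half, 0)
  hi <- pmin(wl$end[gidx] + half,
             genome$length[match(wl$chrom[gidx], genome$chrom)])
  pos0 <- lo + floor(stats::runif(n) * (hi - lo))
  tibble::tibble(
    chrom = wl$chrom[gidx],
    pos = pos0 + 1,
    id = sprintf("%s_rs%04d", trait, seq_len(n)),
    pvalue = stats::runif(n, 1e-12, 5e-8),
    source_gene = wl$feature_id[gidx]  # planted truth, not written to TSV
  )
}

#' Simulate a complete synthetic study
#'
#' One genome, gene table and annotation shared by `n_traits` traits;
#' trait i gets hits simulated with planted enrichment `rho[i]`
#' (recycled) and its own derived seed. Convenience wrapper used by the
#' validation suite.
#'
#' @inheritParams simulate_trait_hits
#' @param n_traits Number of traits.
#' @param rho Planted enrichment per trait (recycled).
#' @return A list: `genome`, `genes`, `annot`, `hits` (named list of
#'   hits tibbles), `rho` (named vector), `element_sets` (named list
#'   built with the config's `dist_bp`).
#' @export
simulate_study <- function(cfg, n_traits = 1, rho = cfg$rho,
                           seed = cfg$seed) {
  base <- simulate_genome_and_genes(cfg, seed = seed)
  annot <- simulate_annotation(cfg, base$genome, seed = seed + 1000L)
  rho <- rep_len(rho, n_traits)
  ids <- sprintf("T%03d", seq_len(n_traits))
  hits <- vector("list", n_traits)
  esets <- vector("list", n_traits)
  for (i in seq_len(n_traits)) {
    cfg_i <- cfg
    cfg_i$rho <- rho[i]
    hits[[i]] <- simulate_trait_hits(cfg_i, base$genome, base$genes, annot,
                                     trait = ids[i], seed = seed + 2000L + i)
    esets[[i]] <- build_element_set(hits[[i]], base$genes, base$genome,
                                    dist_bp = cfg$dist_bp, trait_id = ids[i])
  }
  names(hits) <- names(esets) <- ids
  list(genome = base$genome, genes = base$genes, annot = annot, hits = hits,
       rho = stats::setNames(rho, ids), element_sets = esets)
}

#' Simulate a pair of method-results tables with tunable agreement
#'
#' Both tables share a latent per-trait effect; each adds independent
#' noise sized so the expected correlation between the two enrichment
#' columns is `agreement`. `agreement = 1` gives identical rankings;
#' negative values anti-correlate the tables. Fixture generator for
#' [rank_concordance()] and [meta_batch()].
#'
#' @param n_traits Number of traits (rows per table).
#' @param agreement Target correlation in `[-1, 1]`.
#' @param effect_sd Latent effect standard deviation.
#' @param annot_id Annotation label stamped on rows.
#' @param seed Integer seed.
#' @return A list of two tibbles `a` and `b` with columns `trait_id`,
#'   `annot_id`, `enrichment`, `se`, `p`.
#' @export
simulate_results_tables <- function(n_traits = 50, agreement = 0.8,
                                    effect_sd = 1, annot_id = "A1",
                                    seed = 1) {
  stopifnot(agreement >= -1, agreement <= 1)
  set.seed(seed)
  z <- stats::rnorm(n_traits, 0, effect_sd)
  aa <- abs(agreement)
  noise_sd <- if (aa == 1) 0 else effect_sd * sqrt((1 - aa) / aa)
  if (aa == 0) {
    a_val <- stats::rnorm(n_traits, 0, effect_sd)
    b_val <- stats::rnorm(n_traits, 0, effect_sd)
  } else {
    a_val <- z + stats::rnorm(n_traits, 0, noise_sd)
    b_val <- sign(agreement) * z + stats::rnorm(n_traits, 0, noise_sd)
  }
  mk <- function(v) {
    se <- stats::runif(n_traits, 0.1, 0.3)
    tibble::tibble(
      trait_id = sprintf("T%03d", seq_len(n_traits)),
      annot_id = annot_id,
      enrichment = v,
      se = se,
      p = pmin(pmax(2 * stats::pnorm(-abs(v / se)), 1e-300), 1)
    )
  }
  list(a = mk(a_val), b = mk(b_val))
}

#' Write a synthetic fixture directory
#'
#' Emits exactly the file formats the pipeline reads: `genome.chrom.sizes`,
#' `genes.tsv` (1-based inclusive coordinates), `annotation.bed`, one
#' `hits_<trait>.tsv` per trait, and `sim_config.txt` (flat key=value).
#'
#' @inheritParams simulate_study
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_fixture_dir <- function(cfg, dir, n_traits = 1, rho = cfg$rho,
                              seed = cfg$seed) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  study <- simulate_study(cfg, n_traits = n_traits, rho = rho, seed = seed)
  writeLines(sprintf("%s\t%d", study$genome$chrom, study$genome$length),
             file.path(dir, "genome.chrom.sizes"))
  g <- study$genes
  readr::write_tsv(
    tibble::tibble(feature_id = g$feature_id, chrom = g$chrom,
                   start = g$start + 1, end = g$end, strand = g$strand,
                   biotype = g$biotype),
    file.path(dir, "genes.tsv"), progress = FALSE
  )
  write_bed(study$annot, file.path(dir, "annotation.bed"))
  for (id in names(study$hits)) {
    readr::write_tsv(
      study$hits[[id]][, c("chrom", "pos", "id", "pvalue")],
      file.path(dir, sprintf("hits_%s.tsv", id)), progress = FALSE
    )
  }
  cfg_lines <- vapply(names(unclass(cfg)), function(k)
    sprintf("%s=%s", k, format(cfg[[k]], scientific = FALSE)), "")
  writeLines(c(cfg_lines, sprintf("n_traits=%d", n_traits)),
             file.path(dir, "sim_config.txt"))
  invisible(dir)
}
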