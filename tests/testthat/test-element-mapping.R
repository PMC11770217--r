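mk_genes <- function(...) {
  rows <- list(...)
  tibble::tibble(
    feature_id = vapply(rows, `[[`, "", 1),
    chrom = vapply(rows, `[[`, "", 2),
    start = as.numeric(vapply(rows, `[[`, "", 3)),
    end = as.numeric(vapply(rows, `[[`, "", 4)),
    strand = "+",
    biotype = vapply(rows, `[[`, "", 5)
  )
}

mk_hits <- function(chrom, pos) {
  tibble::tibble(chrom = chrom, pos = pos,
                 id = sprintf("rs%d", seq_along(pos)), pvalue = 1e-9)
}

test_that("hits map to the closest whitelisted feature within the window", {
  genes <- mk_genes(
    list("far_gene", "chr1", "3000", "4000", "protein_coding"),
    list("near_gene", "chr1", "14500", "15000", "protein_coding"),
    list("closer_lnc", "chr1", "10500", "12000", "lincRNA")
  )
  m <- map_hits(mk_hits("chr1", 10000), genes, dist_bp = 5000)
  # the nearer lincRNA is not whitelisted; far_gene is beyond the window
  expect_equal(m$feature_id, "near_gene")
  expect_equal(m$distance, 14500 - 9999)

  inside <- map_hits(mk_hits("chr1", 3500), genes, dist_bp = 5000)
  expect_equal(inside$feature_id, "far_gene")
  expect_equal(inside$distance, 0)

  none <- map_hits(mk_hits("chr2", 10000), genes, dist_bp = 5000)
  expect_true(is.na(none$feature_id))
})

test_that("the mapping window boundary is inclusive", {
  pos <- 10000  # variant base is 9999 in 0-based coordinates
  genes <- mk_genes(
    list("at_5000", "chr1", as.character(9999 + 5000), "20000",
         "protein_coding")
  )
  expect_equal(map_hits(mk_hits("chr1", pos), genes, dist_bp = 5000)$feature_id,
               "at_5000")
  genes$start <- genes$start + 1
  expect_true(is.na(map_hits(mk_hits("chr1", pos), genes,
                             dist_bp = 5000)$feature_id))
})

test_that("equidistant candidates break ties by start then feature id", {
  genes <- mk_genes(
    list("B_gene", "chr1", "10100", "10200", "protein_coding"),
    list("A_gene", "chr1", "9800", "9900", "protein_coding")
  )
  # variant base 9999: left gene ends at 9899 (distance 100),
  # right gene starts at 10100 (distance 101) -> left wins on distance
  m <- map_hits(mk_hits("chr1", 10000), genes, dist_bp = 5000)
  expect_equal(m$feature_id, "A_gene")
  # force an exact tie: both at distance 100
  genes$start[1] <- 10099
  m2 <- map_hits(mk_hits("chr1", 10000), genes, dist_bp = 5000)
  expect_equal(m2$feature_id, "A_gene")  # smaller start wins
  # same span, tie broken lexicographically
  genes2 <- mk_genes(
    list("Zed", "chr1", "10099", "10200", "protein_coding"),
    list("Abc", "chr1", "10099", "10200", "protein_coding")
  )
  expect_equal(map_hits(mk_hits("chr1", 10000), genes2,
                        dist_bp = 5000)$feature_id, "Abc")
})

test_that("element sets deduplicate and respect the distance threshold", {
  g <- genome_define(c(chr1 = 1e7), build_label = "toy")
  genes <- mk_genes(list("g1", "chr1", "1000", "3000", "protein_coding"),
                    list("g2", "chr1", "50000", "52000", "protein_coding"))
  hits <- mk_hits("chr1", c(1500, 2500, 50500))
  es <- build_element_set(hits, genes, g, trait_id = "tr")
  expect_equal(nrow(es), 2)  # two hits in g1 deduplicate
  expect_setequal(es$name, c("g1", "g2"))
  expect_equal(trait_id(es), "tr")
  expect_equal(attr(es, "n_input_hits"), 3L)

  # widening the window grows the set by exactly the loci parked 5-10 kb out
  set.seed(11)
  # genes 20 kb apart so a 7 kb offset is unambiguous at both windows
  base_pos <- seq(20000, by = 20000, length.out = 100)
  genes100 <- tibble::tibble(
    feature_id = sprintf("G%03d", 1:100), chrom = "chr1",
    start = base_pos, end = base_pos + 1000, strand = "+",
    biotype = "protein_coding"
  )
  offset <- rep(100, 100)          # 95 hits right next to their gene
  far <- sample(100, 5)
  offset[far] <- 7000              # 5 hits sit 5-10 kb away
  hits100 <- mk_hits("chr1", base_pos + 1000 + offset)
  es5k <- build_element_set(hits100, genes100, g, dist_bp = 5000)
  es10k <- build_element_set(hits100, genes100, g, dist_bp = 10000)
  expect_equal(nrow(es5k), 95)
  expect_equal(nrow(es10k), 100)
  # monotonicity: a wider window never shrinks the set
  for (d in c(0, 200, 5000, 8000)) {
    expect_lte(nrow(build_element_set(hits100, genes100, g, dist_bp = d)),
               nrow(build_element_set(hits100, genes100, g, dist_bp = d + 500)))
  }
})

test_that("the minimum-size filter is an inclusive boundary with typed rejection", {
  g <- genome_define(c(chr1 = 1e7), build_label = "toy")
  mk_es <- function(n) {
    start <- seq(0, by = 2000, length.out = n)
    es <- interval_set(tibble::tibble(chrom = "chr1", start = start,
                                      end = start + 1000,
                                      name = sprintf("g%d", seq_len(n))), g)
    structure(es, trait_id = "tr", n_input_hits = n,
              class = c("element_set", class(es)))
  }
  expect_true(is_rejected(filter_min_size(mk_es(49))))
  expect_false(is_rejected(filter_min_size(mk_es(50))))
  rej <- filter_min_size(mk_es(0))
  expect_true(is_rejected(rej))
  expect_equal(rej$size, 0)
  expect_equal(filter_min_size(mk_es(40), min_set_size = 40)$name[1], "g1")
})

test_that("gene tables read from TSV and GFF3 with coordinate conversion", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    feature_id = "g1", chrom = "chr1", start = 101, end = 200,
    strand = "+", biotype = "protein_coding"
  ), path)
  g <- read_gene_table(path)
  expect_equal(g$start, 100)  # 1-based inclusive -> 0-based half-open
  expect_equal(g$end, 200)

  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    paste("chr1", "src", "gene", "101", "200", ".", "+", ".",
          "ID=g1;biotype=protein_coding", sep = "\t"),
    paste("chr1", "src", "exon", "101", "150", ".", "+", ".",
          "Parent=g1", sep = "\t")
  ), gff)
  g2 <- read_gene_table(gff)
  expect_equal(nrow(g2), 1)  # exon record ignored
  expect_equal(g2$start, 100)
  expect_equal(g2$biotype, "protein_coding")
})

test_that("hits tables validate coordinates and p-values", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(chrom = "chr1", pos = 100, id = "rs1",
                                  pvalue = 2), path)
  expect_error(read_gwas_hits(path), "p-values")
  readr::write_tsv(tibble::tibble(chrom = "chr9", pos = 100, id = "rs1",
                                  pvalue = 1e-9), path)
  expect_error(read_gwas_hits(path, toy_genome()), "chr9")
})
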