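mk_es_lengths <- function(lengths, genome) {
  start <- cumsum(c(0, head(lengths, -1) + 500))
  es <- interval_set(tibble::tibble(
    chrom = genome$chrom[1], start = start, end = start + lengths,
    name = sprintf("g%d", seq_along(lengths))), genome)
  structure(es, trait_id = "tr", n_input_hits = length(lengths),
            class = c("element_set", class(es)))
}

test_that("decile bins split by sorted index with mean lengths", {
  g <- genome_define(c(chr1 = 1e6), build_label = "toy")

  b1 <- make_length_bins(mk_es_lengths(seq(1000, 10000, by = 1000), g))
  expect_equal(b1$n, rep(1L, 10))
  expect_equal(b1$mean_length, seq(1000, 10000, by = 1000))

  b2 <- make_length_bins(mk_es_lengths(rep(2000, 20), g))
  expect_equal(sum(b2$n), 20)
  expect_true(all(b2$mean_length == 2000))

  b3 <- make_length_bins(mk_es_lengths(sample(500:5000, 25), g))
  expect_equal(sum(b3$n), 25)
  expect_true(all(abs(b3$n - mean(b3$n)) <= 1))
  expect_true(all(diff(b3$mean_length) >= 0))
})

test_that("background sets match bin counts and place uniformly", {
  g <- genome_define(c(chr1 = 1e5), build_label = "toy")
  bins <- tibble::tibble(bin = 1:2, n = c(40L, 20L),
                         mean_length = c(1000, 3000))
  s <- sample_background_set(bins, g, seed = 5)
  expect_equal(nrow(s), 60)
  expect_equal(sort(table(s$end - s$start)),
               sort(table(rep(c(1000, 3000), c(40, 20)))))
  expect_identical(as_plain(sample_background_set(bins, g, seed = 5)),
                   as_plain(s))

  # one chromosome of length L, one element of length l:
  # start should be uniform on [0, L - l]
  l <- 2e4
  bins1 <- tibble::tibble(bin = 1, n = 1L, mean_length = l)
  set.seed(99)
  starts <- replicate(10000, sample_background_set(bins1, g)$start)
  L <- 1e5
  se <- (L - l) / sqrt(12) / sqrt(10000)
  expect_lt(abs(mean(starts) - (L - l) / 2), 3 * se)
  expect_true(all(starts >= 0 & starts <= L - l))

  big <- tibble::tibble(bin = 1, n = 1L, mean_length = 2e5)
  expect_error(sample_background_set(big, g), "exceeds")
})

test_that("intersections per bp is the element count over total length", {
  g <- genome_define(c(chr1 = 1e5), build_label = "toy")
  elements <- mk_es_lengths(rep(250, 4), g)  # total 1000 bp
  annot <- merge_intervals(iv(g, "chr1", 0, 5000))  # covers all 4
  expect_equal(intersections_per_bp(elements, annot), 4 / 1000)
  empty <- merge_intervals(iv(g, character(), numeric(), numeric()))
  expect_equal(intersections_per_bp(elements, empty), 0)
  one <- iv(g, "chr1", 0, 100)
  expect_equal(intersections_per_bp(one, merge_intervals(one)), 1 / 100)
})

test_that("degenerate backgrounds fall back to empirical p-values", {
  g <- genome_define(c(chr1 = 1e5), build_label = "toy")
  es <- mk_es_lengths(rep(1000, 20), g)

  whole <- merge_intervals(iv(g, "chr1", 0, 1e5))
  bg <- build_background(es, whole, g, n_reps = 50, seed = 1)
  expect_true(all(bg$values == bg$values[1]))  # every replicate saturates
  expect_match(bg$fit_note, "degenerate|fallback")
  expect_false(is.finite(bg$shape))

  none <- merge_intervals(iv(g, character(), numeric(), numeric()))
  bg0 <- build_background(es, none, g, n_reps = 50, seed = 1)
  expect_equal(bg0$n_zero, 50)
  expect_match(bg0$fit_note, "fallback")
  # empirical rank p-value: all zeros, observed 0 ties everything
  expect_equal(weibull_pvalue(bg0, 0), 1)
  expect_equal(weibull_pvalue(bg0, 1e-3), 1 / 51)
})

test_that("background generation is deterministic under a fixed seed", {
  g <- genome_define(c(chr1 = 1e6, chr2 = 5e5), build_label = "toy")
  es <- mk_es_lengths(sample(500:3000, 30), g)
  annot <- merge_intervals(iv(g, c("chr1", "chr2"), c(0, 1000),
                              c(50000, 60000)))
  b1 <- build_background(es, annot, g, n_reps = 100, seed = 7)
  b2 <- build_background(es, annot, g, n_reps = 100, seed = 7)
  expect_identical(b1$values, b2$values)
  expect_identical(b1$shape, b2$shape)
})

test_that("Weibull MLE recovers known parameters and matches a grid-search oracle", {
  set.seed(2024)
  x <- rweibull(10000, shape = 2, scale = 1)
  fit <- fit_weibull_mle(x)
  expect_gt(fit[["shape"]], 1.9)
  expect_lt(fit[["shape"]], 2.1)
  expect_lt(abs(fit[["scale"]] - 1), 0.05)

  # independent oracle: log-likelihood grid search on the same sample
  grid_ll <- function(k, lam) {
    sum(dweibull(x, shape = k, scale = lam, log = TRUE))
  }
  ks <- seq(1.6, 2.4, by = 0.005)
  lams <- seq(0.85, 1.15, by = 0.005)
  ll <- outer(ks, lams, Vectorize(grid_ll))
  best <- which(ll == max(ll), arr.ind = TRUE)
  expect_lt(abs(fit[["shape"]] - ks[best[1, 1]]), 0.02)
  expect_lt(abs(fit[["scale"]] - lams[best[1, 2]]), 0.02)

  # scale-equivariance of the rescaled fitting path
  fit_small <- fit_weibull_mle(x * 1e-5)
  expect_equal(fit_small[["shape"]], fit[["shape"]], tolerance = 1e-6)
  expect_equal(fit_small[["scale"]], fit[["scale"]] * 1e-5,
               tolerance = 1e-6)
})

test_that("the Weibull tail p-value has exact closed forms and is monotone", {
  bg1 <- structure(list(values = numeric(0), counts = NULL, shape = 1,
                        scale = 1, n_zero = 0, n_reps = 100,
                        bg_total_bp = 1, fit_note = "weibull", seed = NULL),
                   class = "background_dist")
  expect_equal(weibull_pvalue(bg1, 0), 1.0, tolerance = 1e-12)
  expect_equal(weibull_pvalue(bg1, log(2)), 0.5, tolerance = 1e-12)

  bg2 <- bg1
  bg2$shape <- 2
  expect_equal(weibull_pvalue(bg2, 1), exp(-1), tolerance = 1e-12)

  obs <- seq(0, 3, by = 0.1)
  p <- vapply(obs, weibull_pvalue, numeric(1), bg = bg2)
  expect_true(all(diff(p) < 0))
  expect_error(weibull_pvalue(bg2, -0.1), ">= 0")
})

test_that("fitted backgrounds recover shape/scale on realistic trait runs", {
  cfg <- small_cfg()
  st <- simulate_study(cfg, n_traits = 1, rho = 0, seed = 3)
  es <- st$element_sets[[1]]
  bg <- build_background(es, st$annot, st$genome, n_reps = 400, seed = 2)
  expect_match(bg$fit_note, "weibull")
  expect_true(is.finite(bg$shape) && bg$shape > 0)
  # fitted tail stays close to the empirical tail even though the
  # underlying counts are discrete
  qs <- quantile(bg$values, c(0.25, 0.5, 0.75, 0.9))
  for (q in qs) {
    p_w <- weibull_pvalue(bg, q)
    p_e <- (1 + sum(bg$values >= q)) / (bg$n_reps + 1)
    expect_lt(abs(p_w - p_e), 0.12)
  }
})

test_that("Weibull and empirical p-value paths agree on continuous backgrounds", {
  set.seed(61)
  x <- rweibull(1000, shape = 1.7, scale = 3e-5)
  fit <- fit_weibull_mle(x)
  bg_fit <- structure(list(values = x, counts = NULL,
                           shape = fit[["shape"]], scale = fit[["scale"]],
                           n_zero = 0, n_reps = length(x), bg_total_bp = 1,
                           fit_note = "weibull", seed = NULL),
                      class = "background_dist")
  bg_emp <- bg_fit
  bg_emp$shape <- bg_emp$scale <- NA_real_
  bg_emp$fit_note <- "empirical fallback"
  # Kolmogorov distance between the two p-value functions
  tt <- seq(0, max(x), length.out = 500)
  d <- abs(vapply(tt, weibull_pvalue, numeric(1), bg = bg_fit) -
             vapply(tt, weibull_pvalue, numeric(1), bg = bg_emp))
  expect_lt(max(d), 0.05)
})

test_that("background mean scales with annotation coverage", {
  cfg <- small_cfg()
  st <- simulate_study(cfg, n_traits = 1, rho = 0, seed = 5)
  es <- st$element_sets[[1]]
  cfg2 <- small_cfg(annot_coverage = 0.10)
  annot2 <- simulate_annotation(cfg2, st$genome, seed = 77)
  bg1 <- build_background(es, st$annot, st$genome, n_reps = 400, seed = 9)
  bg2 <- build_background(es, annot2, st$genome, n_reps = 400, seed = 9)
  ratio <- mean(bg2$values) / mean(bg1$values)
  expect_gt(ratio, 1.5)
  expect_lt(ratio, 2.6)
})

test_that("backgrounds persist to TSV + JSON and reload exactly", {
  g <- genome_define(c(chr1 = 1e6), build_label = "toy")
  es <- mk_es_lengths(rep(1000, 30), g)
  annot <- merge_intervals(iv(g, "chr1", seq(0, 9e5, by = 1e5),
                              seq(0, 9e5, by = 1e5) + 2e4))
  bg <- build_background(es, annot, g, n_reps = 100, seed = 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_background(bg, path)
  back <- read_background(path)
  expect_equal(back$values, bg$values)
  expect_equal(back$shape, bg$shape)
  expect_equal(back$n_reps, bg$n_reps)
  expect_equal(weibull_pvalue(back, mean(bg$values)),
               weibull_pvalue(bg, mean(bg$values)))
})
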