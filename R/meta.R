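#' Random-effects meta-analysis with correlated sampling errors
#'
#' Summarises a category of traits' enrichment estimates under the model
#' `y = mu * 1 + u + e`, where the sampling errors `e` have covariance
#' `diag(s) %*% R %*% diag(s)` (R a trait-by-trait genetic correlation
#' matrix) and the random effects `u` are independent with variance
#' `tau2`. `tau2` is estimated by restricted maximum likelihood over
#' `[0, 10 * var(y)]`; `mu` by generalised least squares at the REML
#' `tau2`; `se(mu) = (1' V^-1 1)^{-1/2}` with `V` the total covariance;
#' the two-sided p-value (and implied confidence interval) uses a
#' Student-t reference with `n - 1` degrees of freedom by default:
#' categories hold only a handful of traits, and a plain normal
#' reference is anticonservative when `tau2` is estimated from so few
#' estimates. Set `ref = "z"` for the normal reference (used
#' automatically when `n = 1`).
#'
#' The correlation can alternatively be placed on the random effect
#' (`struct = "tau2R"`, giving `Cov(u) = tau2 * R` and independent
#' sampling errors); the default keeps it in the sampling covariance.
#' Non-positive-semidefinite `R` inputs are repaired by clipping
#' eigenvalues at 1e-8 and rescaling to unit diagonal.
#'
#' @param y Numeric vector of effect estimates (one per trait).
#' @param s Numeric vector of standard errors (all > 0).
#' @param R Trait correlation matrix (defaults to identity).
#' @param struct `"sampling"` (R in the error covariance) or `"tau2R"`.
#' @param ref Reference distribution for the p-value: `"t"` (df `n - 1`,
#'   default) or `"z"`.
#' @param category Optional label carried into the result.
#' @return A `meta_re` object; see [tidy.meta_re()] for the tibble form.
#' @examples
#' fit <- meta_random_effects(c(1.2, 0.8, 1.5), c(0.3, 0.4, 0.3))
#' tidy(fit)
#' @export
meta_random_effects <- function(y, s, R = NULL,
                                struct = c("sampling", "tau2R"),
                                ref = c("t", "z"),
                                category = NA_character_) {
  struct <- match.arg(struct)
  ref <- match.arg(ref)
  n <- length(y)
  stopifnot(n >= 1, length(s) == n, all(is.finite(y)), all(is.finite(s)))
  if (any(s <= 0)) stop("all standard errors must be > 0", call. = FALSE)
  if (is.null(R)) R <- diag(n)
  R <- as.matrix(R)
  stopifnot(nrow(R) == n, ncol(R) == n)
  R <- repair_psd(R)

  if (n == 1) {
    z <- y / s
    return(new_meta_re(category, mu_hat = y, se_mu = s, z = z,
                       p = 2 * stats::pnorm(-abs(z)), tau2 = 0, n = 1,
                       struct = struct, ref = "z"))
  }

  Sigma <- diag(s) %*% R %*% diag(s)
  one <- rep(1, n)
  V_of <- function(tau2) {
    if (struct == "sampling") Sigma + tau2 * diag(n) else
      diag(s^2) + tau2 * R
  }
  reml_nll <- function(tau2) {
    V <- V_of(tau2)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    logdetV <- 2 * sum(log(diag(ch)))
    Vi1 <- backsolve(ch, forwardsolve(t(ch), one))
    w <- sum(Vi1)
    mu <- sum(Vi1 * y) / w
    r <- y - mu
    Vir <- backsolve(ch, forwardsolve(t(ch), r))
    0.5 * (logdetV + log(w) + sum(r * Vir))
  }
  upper <- max(10 * stats::var(y), 1e-8)
  opt <- stats::optimize(reml_nll, interval = c(0, upper))
  tau2 <- opt$minimum
  # boundary polish: accept 0 when it is at least as good
  if (reml_nll(0) <= opt$objective + 1e-10) tau2 <- 0

  V <- V_of(tau2)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) {
    stop(sprintf("singular covariance in meta-analysis for category '%s'",
                 category), call. = FALSE)
  }
  Vi1 <- backsolve(ch, forwardsolve(t(ch), one))
  w <- sum(Vi1)
  mu_hat <- sum(Vi1 * y) / w
  se_mu <- 1 / sqrt(w)
  z <- mu_hat / se_mu
  p <- if (ref == "t") 2 * stats::pt(-abs(z), df = n - 1) else
    2 * stats::pnorm(-abs(z))
  new_meta_re(category, mu_hat = mu_hat, se_mu = se_mu, z = z, p = p,
              tau2 = tau2, n = n, struct = struct, ref = ref)
}

#' Confidence interval for a meta-analysis summary estimate
#'
#' Uses the fit's reference distribution (t with `n - 1` df, or normal).
#'
#' @param object A `meta_re` fit.
#' @param parm Ignored (one parameter).
#' @param level Confidence level (default 0.95).
#' @param ... Unused.
#' @return A 1 x 2 matrix of lower and upper bounds.
#' @export
confint.meta_re <- function(object, parm, level = 0.95, ...) {
  a <- (1 - level) / 2
  crit <- if (object$ref == "t" && object$n > 1)
    stats::qt(1 - a, df = object$n - 1) else stats::qnorm(1 - a)
  out <- matrix(object$mu_hat + c(-1, 1) * crit * object$se_mu, nrow = 1,
                dimnames = list("mu", sprintf("%.1f %%", 100 * c(a, 1 - a))))
  out
}

new_meta_re <- function(category, mu_hat, se_mu, z, p, tau2, n, struct,
                        ref) {
  structure(
    list(category = category, mu_hat = mu_hat, se_mu = se_mu, z = z, p = p,
         tau2 = tau2, n = n, struct = struct, ref = ref),
    class = "meta_re"
  )
}

#' @export
print.meta_re <- function(x, ...) {
  cat(sprintf(
    "<meta_re> %s: mu = %.4f (se %.4f), z = %.3f, p = %.3g, tau2 = %.4g, n = %d\n",
    ifelse(is.na(x$category), "(uncategorised)", x$category),
    x$mu_hat, x$se_mu, x$z, x$p, x$tau2, x$n))
  invisible(x)
}

#' Tidy a correlated random-effects meta-analysis fit
#'
#' @param x A `meta_re` object.
#' @param ... Unused.
#' @return One-row tibble: `category`, `mu_hat`, `se_mu`, `z`, `p`,
#'   `tau2`, `n`.
#' @export
tidy.meta_re <- function(x, ...) {
  tibble::tibble(category = x$category, mu_hat = x$mu_hat, se_mu = x$se_mu,
                 z = x$z, p = x$p, tau2 = x$tau2, n = x$n)
}

#' @rdname tidy.meta_re
#' @export
glance.meta_re <- function(x, ...) {
  tibble::tibble(n = x$n, tau2 = x$tau2, struct = x$struct)
}

#' Meta-analyse a results batch by trait category
#'
#' Joins a results table (needing `trait_id`, `annot_id`, `enrichment`,
#' `se`) to a trait-to-category map, fits [meta_random_effects()] for
#' every (category, annotation) block using the matching submatrix of
#' the full trait correlation matrix, and BH-adjusts the block p-values
#' over the batch. Traits with missing standard errors, or absent from
#' the category map, are excluded with a warning; empty categories are
#' skipped.
#'
#' @param results Results tibble with `se` column.
#' @param categories Tibble with columns `trait_id`, `category`.
#' @param R_full Optional full correlation matrix with trait ids as
#'   dimnames; identity is assumed for missing pairs.
#' @param struct Variance structure, see [meta_random_effects()].
#' @return Tibble with one row per (category, annot_id) plus `q`.
#' @export
meta_batch <- function(results, categories, R_full = NULL,
                       struct = "sampling") {
  stopifnot(all(c("trait_id", "annot_id", "enrichment", "se") %in%
                  names(results)),
            all(c("trait_id", "category") %in% names(categories)))
  results <- tibble::as_tibble(results)
  bad_se <- !is.finite(results$se) | results$se <= 0
  if (any(bad_se)) {
    warning(sprintf("%d row(s) without usable SE excluded from meta-analysis",
                    sum(bad_se)))
    results <- results[!bad_se, , drop = FALSE]
  }
  unknown <- setdiff(unique(results$trait_id), categories$trait_id)
  if (length(unknown)) {
    warning("trait(s) missing from category map excluded: ",
            paste(unknown, collapse = ", "))
  }
  joined <- dplyr::inner_join(results, categories, by = "trait_id")
  if (nrow(joined) == 0) stop("no categorised rows to meta-analyse",
                              call. = FALSE)
  out <- joined |>
    dplyr::group_by(.data$category, .data$annot_id) |>
    dplyr::group_modify(function(d, key) {
      Rsub <- subset_correlation(R_full, d$trait_id)
      tidy(meta_random_effects(d$enrichment, d$se, R = Rsub, struct = struct,
                               category = key$category))[-1]
    }) |>
    dplyr::ungroup()
  out$q <- adjust_bh(out$p)
  out
}

# pull the submatrix for the given traits; identity for ids not present
subset_correlation <- function(R_full, ids) {
  n <- length(ids)
  if (is.null(R_full)) return(diag(n))
  R <- diag(n)
  dimnames(R) <- list(ids, ids)
  have <- intersect(ids, rownames(R_full))
  R[have, have] <- R_full[have, have]
  R
}

#' Read a square correlation matrix from TSV
#'
#' First column and header row hold trait ids.
#'
#' @param path Path to the TSV.
#' @return A symmetric matrix with trait-id dimnames.
#' @export
read_correlation_matrix <- function(path) {
  x <- utils::read.delim(path, check.names = FALSE, row.names = 1)
  m <- as.matrix(x)
  if (nrow(m) != ncol(m) || !all(rownames(m) == colnames(m))) {
    stop("correlation matrix must be square with matching row/col ids",
         call. = FALSE)
  }
  m
}

# clip negative eigenvalues at 1e-8 and rescale to unit diagonal
repair_psd <- function(R) {
  R <- (R + t(R)) / 2
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= 1e-8) return(R)
  vals <- pmax(e$values, 1e-8)
  R2 <- e$vectors %*% diag(vals, nrow = length(vals)) %*% t(e$vectors)
  stats::cov2cor(R2)
}
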