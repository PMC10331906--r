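#' Profile log-likelihood of a trait under lambda-scaled Brownian motion
#'
#' Evaluates, at a given lambda, the multivariate-normal log-likelihood of
#' tip values `x` under Brownian motion on the lambda-transformed
#' phylogenetic covariance, profiled analytically over the root state z0 and
#' the rate sigma^2:
#' z0 = (1' W^-1 1)^-1 1' W^-1 x, sigma2 = (x - z0)' W^-1 (x - z0) / n, and
#' logL = -0.5 (n log 2 pi + log |sigma2 W| + n), with W the transformed
#' covariance. All solves go through the Cholesky factor of W; no explicit
#' inverse is formed.
#'
#' @param x numeric trait vector; if named, names must match `rownames(V)`.
#' @param V untransformed matrix from [phylo_vcv()].
#' @param lambda scalar in `[0, lambda_max]`.
#' @param lambda_max admissible upper bound for lambda.
#' @return list with `loglik`, `root_state`, `sigma2`.
#' @export
bm_profile_loglik <- function(x, V, lambda, lambda_max = 1) {
  n <- length(x)
  if (n != nrow(V)) stop("length(x) must equal dim(V)", call. = FALSE)
  if (n < 2L) stop("need at least 2 species", call. = FALSE)
  if (!is.null(names(x))) {
    if (!setequal(names(x), rownames(V)))
      stop("names of x do not match rownames of V", call. = FALSE)
    x <- x[rownames(V)]
  }
  W <- lambda_transform(V, lambda, lambda_max)
  R <- tryCatch(chol(W), error = function(e)
    stop("transformed covariance is not positive definite at lambda = ",
         lambda, ": ", conditionMessage(e), call. = FALSE))
  # half-whitened vectors: (R^-T v) so v' W^-1 u = <R^-T v, R^-T u>
  w1 <- backsolve(R, rep(1, n), transpose = TRUE)
  wx <- backsolve(R, x, transpose = TRUE)
  z0 <- sum(w1 * wx) / sum(w1 * w1)
  wr <- wx - z0 * w1
  sigma2 <- sum(wr * wr) / n
  if (sigma2 <= 0 || !is.finite(sigma2))
    stop("degenerate data: zero residual variance (constant trait?)",
         call. = FALSE)
  logdetW <- 2 * sum(log(diag(R)))
  loglik <- -0.5 * (n * log(2 * pi) + n * log(sigma2) + logdetW + n)
  list(loglik = loglik, root_state = z0, sigma2 = sigma2)
}

#' Maximum-likelihood estimate of Pagel's lambda with likelihood-ratio test
#'
#' Maximizes the Brownian-motion profile likelihood over lambda in
#' `[0, lambda_max]` by Brent's bounded scalar search started on each half of
#' the interval plus the endpoints, at tolerance 1e-8 (the profile can be
#' multimodal near the boundaries). Significance of phylogenetic signal is
#' assessed by a likelihood-ratio test of the fit against lambda = 0
#' (phylogenetic independence), with the statistic referred to a chi-square
#' distribution with 1 df. The chi-square reference is conservative at the
#' lambda = 0 boundary; it is the convention of the standard comparative
#' implementations and is kept for comparability.
#'
#' @param x named numeric vector of one value per species.
#' @param tree a `phylo`; pruned to `names(x)` if larger. Species in `x`
#'   absent from the tree are dropped with a warning.
#' @param lambda_max upper search bound, default 1.
#' @return object of class `lambda_fit`: list with `lambda_hat`, `sigma2_hat`,
#'   `root_state`, `loglik`, `loglik_lambda0`, `lrt_stat`, `p_value`,
#'   `n_species`.
#' @export
fit_lambda <- function(x, tree, lambda_max = 1) {
  if (is.null(names(x))) stop("x must be named by species", call. = FALSE)
  names(x) <- normalize_labels(names(x))
  x <- x[!is.na(x)]
  drop <- setdiff(names(x), tree$tip.label)
  if (length(drop) > 0L) {
    warning("dropping ", length(drop), " species absent from tree: ",
            paste(utils::head(drop, 5), collapse = ", "),
            if (length(drop) > 5) ", ...", call. = FALSE)
    x <- x[setdiff(names(x), drop)]
  }
  if (length(x) < 3L)
    stop("need at least 3 species for lambda inference, got ", length(x),
         call. = FALSE)
  tree <- prune_to_taxa(tree, names(x))
  V <- phylo_vcv(tree, order = names(x))
  off <- V; diag(off) <- 0
  if (all(abs(off) < 1e-12))
    stop("star phylogeny: lambda has no effect on the likelihood ",
         "(no shared branch lengths)", call. = FALSE)
  obj <- function(lam) bm_profile_loglik(x, V, lam, lambda_max)$loglik
  mid <- lambda_max / 2
  cand <- list(
    stats::optimize(obj, c(0, mid), maximum = TRUE, tol = 1e-8),
    stats::optimize(obj, c(mid, lambda_max), maximum = TRUE, tol = 1e-8)
  )
  lams <- c(vapply(cand, `[[`, numeric(1), "maximum"), 0, lambda_max)
  lls <- c(vapply(cand, `[[`, numeric(1), "objective"), obj(0), obj(lambda_max))
  best <- which.max(lls)
  lambda_hat <- lams[best]
  fit <- bm_profile_loglik(x, V, lambda_hat, lambda_max)
  ll0 <- bm_profile_loglik(x, V, 0, lambda_max)$loglik
  lrt <- max(0, 2 * (fit$loglik - ll0))
  structure(list(
    lambda_hat = lambda_hat,
    sigma2_hat = fit$sigma2,
    root_state = fit$root_state,
    loglik = fit$loglik,
    loglik_lambda0 = ll0,
    lrt_stat = lrt,
    p_value = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
    n_species = length(x)
  ), class = "lambda_fit")
}

#' @export
print.lambda_fit <- function(x, ...) {
  cat(sprintf(
    "Pagel's lambda fit (n = %d)\n  lambda = %.4f  sigma2 = %.4g  logL = %.4f\n  LRT vs lambda = 0: stat = %.4f, p = %.4g\n",
    x$n_species, x$lambda_hat, x$sigma2_hat, x$loglik, x$lrt_stat, x$p_value))
  invisible(x)
}

#' Highest-density interval of an empirical sample
#'
#' The shortest contiguous window of the sorted sample containing
#' `ceiling(mass * N)` values; among equal-width windows the one with the
#' smallest lower endpoint is returned. This is the summary used to report
#' every statistic across the posterior set of phylogenies.
#'
#' @param sample numeric vector, length >= 2.
#' @param mass coverage fraction in (0, 1), default 0.95.
#' @return object of class `hdp_interval`: list with `lower`, `upper`, `mass`.
#' @export
hdp_interval <- function(sample, mass = 0.95) {
  sample <- sample[!is.na(sample)]
  n <- length(sample)
  if (n < 2L) stop("need at least 2 values", call. = FALSE)
  if (!(mass > 0 && mass < 1)) stop("mass must be in (0, 1)", call. = FALSE)
  s <- sort(sample)
  m <- min(n, ceiling(mass * n))
  widths <- s[m:n] - s[seq_len(n - m + 1L)]
  i <- which.min(widths)  # first minimum = smallest lower endpoint
  structure(list(lower = s[i], upper = s[i + m - 1L], mass = mass),
            class = "hdp_interval")
}

#' @export
print.hdp_interval <- function(x, ...) {
  cat(sprintf("%.0f%% HDP [%.4g, %.4g]\n", 100 * x$mass, x$lower, x$upper))
  invisible(x)
}

#' Pagel's lambda across a set of phylogenies
#'
#' Fits [fit_lambda()] on every member of a tree set (each pruned to the
#' species of `x`) and summarizes the per-tree estimates with a 95% HDP
#' interval, the standard way of propagating phylogenetic uncertainty from a
#' tree posterior. Per-tree numerical failures are dropped with a message;
#' more than 10% failures aborts.
#'
#' @param x named trait vector.
#' @param trees a `multiPhylo`.
#' @param mass HDP coverage, default 0.95.
#' @param lambda_max upper search bound.
#' @return object of class `lambda_distribution`: list with `per_tree_fits`,
#'   `lambda_hats`, `hdp`, `n_failed`.
#' @export
lambda_across_trees <- function(x, trees, mass = 0.95, lambda_max = 1) {
  trees <- as_tree_set(trees)
  fits <- vector("list", length(trees))
  failed <- integer(0)
  for (i in seq_along(trees)) {
    fits[[i]] <- tryCatch(
      suppressWarnings(fit_lambda(x, trees[[i]], lambda_max)),
      error = function(e) NULL)
    if (is.null(fits[[i]])) failed <- c(failed, i)
  }
  if (length(failed) > 0.10 * length(trees))
    stop(length(failed), " of ", length(trees),
         " per-tree fits failed (> 10%)", call. = FALSE)
  if (length(failed) > 0L)
    message("dropped ", length(failed), " failed per-tree fits")
  ok <- fits[!vapply(fits, is.null, logical(1))]
  lh <- vapply(ok, `[[`, numeric(1), "lambda_hat")
  structure(list(per_tree_fits = ok, lambda_hats = lh,
                 hdp = hdp_interval(lh, mass), n_failed = length(failed)),
            class = "lambda_distribution")
}
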