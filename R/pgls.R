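#' Generalized least squares under a known covariance
#'
#' Estimates `beta = (X' V^-1 X)^-1 X' V^-1 y` with standard errors
#' `sqrt(diag(sigma2 (X' V^-1 X)^-1))`, `sigma2 = e' V^-1 e / (n - p)`,
#' t statistics and two-tailed p-values on `n - p` degrees of freedom, and
#' the ML log-likelihood. All quadratic forms are computed through the
#' Cholesky factor of `V`; no explicit matrix inverse is formed.
#'
#' @param y response vector (n).
#' @param X design matrix (n x p) including the intercept column.
#' @param V positive-definite covariance matrix (n x n); a plain matrix or
#'   the output of [phylo_vcv()]/[lambda_transform()].
#' @return object of class `gls_fit`: list with `coefficients`,
#'   `standard_errors`, `t_stats`, `p_values`, `sigma2`, `loglik`, `n`,
#'   `df_resid`, `residuals`, `degenerate` (TRUE when the fit is exact).
#' @export
gls_fit <- function(y, X, V) {
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  if (nrow(X) != n || nrow(V) != n || ncol(V) != n)
    stop("y, X, V dimensions do not agree", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (n - p < 1L) stop("no residual degrees of freedom", call. = FALSE)
  R <- tryCatch(chol(V), error = function(e)
    stop("covariance matrix is not positive definite: ",
         conditionMessage(e), call. = FALSE))
  yt <- backsolve(R, y, transpose = TRUE)
  Xt <- backsolve(R, X, transpose = TRUE)
  XtX <- crossprod(Xt)
  Rx <- chol(XtX)
  beta <- backsolve(Rx, backsolve(Rx, crossprod(Xt, yt), transpose = TRUE))
  beta <- drop(beta)
  names(beta) <- colnames(X)
  et <- yt - Xt %*% beta
  rss <- sum(et^2)
  df <- n - p
  sigma2 <- rss / df
  degenerate <- sigma2 < 1e-12 * mean(diag(V)) * max(1, stats::var(y))
  if (degenerate)
    warning("degenerate fit: residual variance is (numerically) zero",
            call. = FALSE)
  XtXinv_diag <- diag(chol2inv(Rx))
  se <- sqrt(sigma2 * XtXinv_diag)
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df = df)
  sig2_ml <- rss / n
  logdetV <- 2 * sum(log(diag(R)))
  loglik <- -0.5 * (n * log(2 * pi) + n * log(sig2_ml) + logdetV + n)
  structure(list(
    coefficients = beta, standard_errors = se, t_stats = tval,
    p_values = pval, sigma2 = sigma2, loglik = loglik,
    n = n, df_resid = df, residuals = drop(y - X %*% beta),
    degenerate = degenerate
  ), class = "gls_fit")
}

#' @export
print.gls_fit <- function(x, ...) {
  tab <- data.frame(estimate = x$coefficients, se = x$standard_errors,
                    t = x$t_stats, p = x$p_values)
  cat(sprintf("GLS fit: n = %d, df = %d, sigma2 = %.4g, logL = %.4f\n",
              x$n, x$df_resid, x$sigma2, x$loglik))
  print(tab, digits = 4)
  invisible(x)
}

#' Specify one PGLS model
#'
#' @param response name of the response column (a trait's cv).
#' @param predictors character vector of predictor column names (numeric;
#'   binary predictors coded 0/1).
#' @param lambda either a number in `[0, 1]` fixing Pagel's lambda on the
#'   residual covariance (default 1, full Brownian motion — the default of
#'   the standard PGLS implementations), or `"ml"` to profile it by maximum
#'   likelihood.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(response, predictors, lambda = 1) {
  stopifnot(is.character(response), length(response) == 1L)
  if (!identical(lambda, "ml") &&
      !(is.numeric(lambda) && length(lambda) == 1L && lambda >= 0 && lambda <= 1))
    stop("lambda must be a number in [0, 1] or \"ml\"", call. = FALSE)
  structure(list(response = response, predictors = as.character(predictors),
                 lambda = lambda), class = "model_spec")
}

#' Phylogenetic generalized least squares on a species table
#'
#' Builds the design matrix with an intercept from the named columns of
#' `data`, drops species with any missing model variable (list-wise, with a
#' message), prunes the tree to the retained species (species absent from
#' the tree are likewise dropped, with a warning), forms the phylogenetic
#' covariance, applies the lambda transform (fixed value or ML-profiled over
#' `[0, 1]`), and fits [gls_fit()].
#'
#' @param data data.frame with a `species` column and all model columns.
#' @param spec a [model_spec()].
#' @param tree a `phylo`.
#' @return a `gls_fit` with extra fields `lambda` (value used), `lambda_mode`,
#'   `species` (those analyzed) and `spec`.
#' @export
pgls_fit <- function(data, spec, tree) {
  stopifnot(inherits(spec, "model_spec"))
  cols <- c(spec$response, spec$predictors)
  missing_cols <- setdiff(c("species", cols), names(data))
  if (length(missing_cols) > 0L)
    stop("data is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  data$species <- normalize_labels(data$species)
  keep <- stats::complete.cases(data[, cols, drop = FALSE])
  if (sum(!keep) > 0L)
    message("dropping ", sum(!keep), " species with missing model variables")
  d <- data[keep, , drop = FALSE]
  in_tree <- d$species %in% tree$tip.label
  if (any(!in_tree)) {
    warning("dropping ", sum(!in_tree), " species absent from tree",
            call. = FALSE)
    d <- d[in_tree, , drop = FALSE]
  }
  p <- length(spec$predictors) + 1L
  if (nrow(d) < p + 2L)
    stop("too few species (", nrow(d), ") for ", p,
         " coefficients; model cannot converge", call. = FALSE)
  tr <- prune_to_taxa(tree, d$species)
  V <- phylo_vcv(tr, order = d$species)
  y <- d[[spec$response]]
  X <- cbind("(Intercept)" = 1,
             as.matrix(d[, spec$predictors, drop = FALSE]))
  if (identical(spec$lambda, "ml")) {
    obj <- function(lam) gls_fit(y, X, lambda_transform(V, lam))$loglik
    opt <- stats::optimize(obj, c(0, 0.5), maximum = TRUE, tol = 1e-8)
    opt2 <- stats::optimize(obj, c(0.5, 1), maximum = TRUE, tol = 1e-8)
    lams <- c(opt$maximum, opt2$maximum, 0, 1)
    lls <- c(opt$objective, opt2$objective, obj(0), obj(1))
    lam_hat <- lams[which.max(lls)]
  } else {
    lam_hat <- spec$lambda
  }
  fit <- gls_fit(y, X, lambda_transform(V, lam_hat))
  fit$lambda <- lam_hat
  fit$lambda_mode <- if (identical(spec$lambda, "ml")) "ml" else "fixed"
  fit$species <- d$species
  fit$spec <- spec
  fit
}

#' PGLS across a tree set with HDP summaries
#'
#' Fits the model on the MCC tree and on every member of the tree set, then
#' summarizes each coefficient's estimate, t statistic and p-value across
#' trees with a 95% HDP interval — the reporting convention for analyses run
#' over a posterior sample of phylogenies.
#'
#' @param data species data.frame (see [pgls_fit()]).
#' @param spec a [model_spec()].
#' @param trees a `multiPhylo`.
#' @param mcc the MCC `phylo` (e.g. from [maximum_clade_credibility()]).
#' @param mass HDP coverage, default 0.95.
#' @return object of class `pgls_distribution`: list with `mcc_fit`,
#'   `per_tree_fits`, `hdp` (list per coefficient of intervals for `beta`,
#'   `t`, `p`), `n_failed`.
#' @export
pgls_across_trees <- function(data, spec, trees, mcc, mass = 0.95) {
  trees <- as_tree_set(trees)
  mcc_fit <- pgls_fit(data, spec, mcc)
  fits <- vector("list", length(trees))
  failed <- integer(0)
  for (i in seq_along(trees)) {
    fits[[i]] <- tryCatch(
      suppressMessages(suppressWarnings(pgls_fit(data, spec, trees[[i]]))),
      error = function(e) NULL)
    if (is.null(fits[[i]])) failed <- c(failed, i)
  }
  if (length(failed) > 0.10 * length(trees))
    stop(length(failed), " of ", length(trees),
         " per-tree fits failed (> 10%)", call. = FALSE)
  ok <- fits[!vapply(fits, is.null, logical(1))]
  coefs <- names(mcc_fit$coefficients)
  hdp <- lapply(coefs, function(cf) {
    b <- vapply(ok, function(f) f$coefficients[[cf]], numeric(1))
    t <- vapply(ok, function(f) f$t_stats[[cf]], numeric(1))
    p <- vapply(ok, function(f) f$p_values[[cf]], numeric(1))
    list(beta = hdp_interval(b, mass), t = hdp_interval(t, mass),
         p = hdp_interval(p, mass))
  })
  names(hdp) <- coefs
  structure(list(mcc_fit = mcc_fit, per_tree_fits = ok, hdp = hdp,
                 n_failed = length(failed)),
            class = "pgls_distribution")
}

#' Merge trait summaries with species covariates into one model frame
#'
#' Derives the numeric predictors used by the model families: `nest_type_dome`
#' (1 = dome, reference = open cup), `builder_single` (1 = single parent,
#' reference = both parents), `innovation` (0/1 as supplied, reference =
#' non-innovative) and `clutch_size_range = clutch_max - clutch_min`.
#'
#' @param summary output of [summarize_species()].
#' @param covariates data.frame with columns `species, body_mass_g,
#'   nest_type, innovation, clutch_min, clutch_max, builder`.
#' @param log_body_mass transform body mass to the log scale (default FALSE;
#'   mass enters untransformed, with this switch documenting the ambiguity).
#' @return merged data.frame keyed by species.
#' @export
prepare_model_frame <- function(summary, covariates, log_body_mass = FALSE) {
  req <- c("species", "body_mass_g", "nest_type", "innovation",
           "clutch_min", "clutch_max", "builder")
  missing_cols <- setdiff(req, names(covariates))
  if (length(missing_cols) > 0L)
    stop("covariates missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  covariates$species <- normalize_labels(covariates$species)
  summary$species <- normalize_labels(summary$species)
  bad <- setdiff(stats::na.omit(covariates$nest_type), c("cup", "dome"))
  if (length(bad) > 0L)
    stop("nest_type must be 'cup' or 'dome'", call. = FALSE)
  bad <- setdiff(stats::na.omit(covariates$builder), c("both", "single"))
  if (length(bad) > 0L)
    stop("builder must be 'both' or 'single'", call. = FALSE)
  d <- merge(summary, covariates, by = "species", all.x = TRUE, sort = TRUE)
  d$nest_type_dome <- as.numeric(d$nest_type == "dome")
  d$builder_single <- as.numeric(d$builder == "single")
  d$clutch_size_range <- d$clutch_max - d$clutch_min
  if (any(d$clutch_size_range < 0, na.rm = TRUE))
    stop("clutch_max < clutch_min for some species", call. = FALSE)
  if (log_body_mass) d$body_mass_g <- log(d$body_mass_g)
  d
}

#' The three PGLS model families per nest trait
#'
#' For each trait's coefficient of variation: (A) sampling-span controls,
#' `cv ~ year_range + latitude_range`; (B) behavioural-flexibility
#' predictors, `cv ~ innovation + body_mass_g + nest_type_dome`; (C)
#' clutch-and-builder predictors, `cv ~ clutch_size_range + builder_single`.
#' Reference levels: non-innovative, open-cup nest, both-parent builders.
#'
#' @param traits trait names, default all four.
#' @param lambda lambda mode passed to each [model_spec()], default fixed 1.
#' @return named list of 3 x length(traits) `model_spec`s, names like
#'   `"A_cup_depth"`.
#' @export
build_nest_models <- function(traits = nest_traits(), lambda = 1) {
  fams <- list(
    A = c("year_range", "latitude_range"),
    B = c("innovation", "body_mass_g", "nest_type_dome"),
    C = c("clutch_size_range", "builder_single")
  )
  out <- list()
  for (tr in traits) {
    for (f in names(fams)) {
      out[[paste(f, tr, sep = "_")]] <-
        model_spec(paste0("cv_", tr), fams[[f]], lambda = lambda)
    }
  }
  out
}
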