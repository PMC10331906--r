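test_that("gls_fit matches hand OLS arithmetic with identity covariance", {
  y <- c(1, 2, 3)
  X <- cbind("(Intercept)" = rep(1, 3))
  f <- gls_fit(y, X, diag(3))
  expect_equal(unname(f$coefficients), 2)
  expect_equal(f$sigma2, 1)
  expect_equal(unname(f$standard_errors), sqrt(1 / 3))
  expect_equal(f$df_resid, 2L)

  # perfect fit flagged as degenerate
  x <- 1:4
  Xp <- cbind(1, x)
  expect_warning(fp <- gls_fit(1 + x, Xp, diag(4)), "degenerate")
  expect_true(fp$degenerate)
})

test_that("gls_fit equals the Cholesky-whitening OLS oracle on random instances", {
  set.seed(37)
  for (i in 1:40) {
    n <- sample(6:30, 1)
    p <- sample(1:3, 1)
    X <- cbind(1, matrix(rnorm(n * p), n))
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(p)))
    A <- matrix(rnorm(n * n), n)
    V <- crossprod(A) + diag(n)
    y <- X %*% rnorm(p + 1) + rnorm(n)
    f <- gls_fit(drop(y), X, V)
    o <- oracle_gls(drop(y), X, V)
    expect_equal(unname(f$coefficients), o$beta, tolerance = 1e-8)
    expect_equal(unname(f$standard_errors), o$se, tolerance = 1e-8)
    expect_equal(unname(f$t_stats), o$t, tolerance = 1e-8)
    expect_equal(unname(f$p_values), o$p, tolerance = 1e-8)
    expect_equal(f$sigma2, o$sigma2, tolerance = 1e-8)
  }
})

test_that("gls_fit rejects rank-deficient designs and misaligned input", {
  X <- cbind("(Intercept)" = rep(1, 6), a = 1:6, b = 2 * (1:6))
  expect_error(gls_fit(rnorm(6), X, diag(6)), "collinear")
  expect_error(gls_fit(rnorm(5), X, diag(6)), "dimensions")
})

test_that("star-tree PGLS with lambda 1 reproduces textbook OLS on 5 points", {
  # hand-verified 5-point dataset
  d <- data.frame(species = sprintf("s%d", 1:5),
                  cv_cup_depth = c(0.04, 0.07, 0.05, 0.10, 0.08),
                  year_range = c(10, 40, 20, 80, 60),
                  latitude_range = c(1, 4, 2, 9, 6))
  star <- parse_newick("(s1:1,s2:1,s3:1,s4:1,s5:1);")
  spec <- model_spec("cv_cup_depth", "year_range", lambda = 1)
  f <- pgls_fit(d, spec, star)
  ref <- summary(lm(cv_cup_depth ~ year_range, d))$coefficients
  expect_equal(unname(f$coefficients), unname(ref[, 1]), tolerance = 1e-8)
  expect_equal(unname(f$t_stats), unname(ref[, 3]), tolerance = 1e-8)
  expect_equal(unname(f$p_values), unname(ref[, 4]), tolerance = 1e-8)
})

test_that("pgls_fit recovers a simulated slope under Brownian errors", {
  set.seed(43)
  betas <- replicate(30, {
    tr <- simulate_yule_tree(100, 1)
    e <- simulate_bm_traits(tr, 0, 0.04, 1)
    x <- rnorm(100)
    d <- data.frame(species = tr$tip.label, y = 1 + 0.5 * x + unname(e), x = x)
    f <- pgls_fit(d, model_spec("y", "x"), tr)
    f$coefficients[["x"]]
  })
  expect_lt(abs(mean(betas) - 0.5), 0.05)
})

test_that("pgls_fit enforces sample-size, missingness and coding contracts", {
  tr <- simulate_yule_tree(10, 1, seed = 3)
  d <- data.frame(species = tr$tip.label, y = rnorm(10),
                  a = rnorm(10), b = rnorm(10), c = rnorm(10))
  expect_error(pgls_fit(d[1:5, ], model_spec("y", c("a", "b", "c")), tr),
               "too few species")
  d2 <- d; d2$a[1:3] <- NA
  expect_message(f <- pgls_fit(d2, model_spec("y", "a"), tr), "dropping 3")
  expect_equal(f$n, 7L)
  d3 <- d; d3$a <- 0  # constant binary column collinear with intercept
  expect_error(pgls_fit(d3, model_spec("y", "a"), tr), "collinear")
})

test_that("p-values are invariant to rescaling a continuous predictor", {
  set.seed(47)
  tr <- simulate_yule_tree(40, 1)
  e <- simulate_bm_traits(tr, 0, 1, 1)
  d <- data.frame(species = tr$tip.label, y = unname(e) + 0.2 * rnorm(40),
                  x = rnorm(40))
  f1 <- pgls_fit(d, model_spec("y", "x"), tr)
  d$x <- d$x * 1000
  f2 <- pgls_fit(d, model_spec("y", "x"), tr)
  expect_equal(f1$t_stats[["x"]], f2$t_stats[["x"]], tolerance = 1e-8)
  expect_equal(f1$p_values[["x"]], f2$p_values[["x"]], tolerance = 1e-8)
})

test_that("ML-profiled lambda beats misfit lambda on average", {
  set.seed(53)
  wins <- replicate(20, {
    tr <- simulate_yule_tree(80, 1)
    e <- simulate_bm_traits(tr, 0, 1, 0.5)
    d <- data.frame(species = tr$tip.label, y = unname(e), x = rnorm(80))
    fm <- pgls_fit(d, model_spec("y", "x", lambda = "ml"), tr)
    f0 <- pgls_fit(d, model_spec("y", "x", lambda = 0), tr)
    f1 <- pgls_fit(d, model_spec("y", "x", lambda = 1), tr)
    fm$loglik >= max(f0$loglik, f1$loglik) - 1e-8
  })
  expect_gte(mean(wins), 0.95)
})

test_that("pgls_across_trees is exact bookkeeping with identical trees", {
  tr <- simulate_yule_tree(25, 1, seed = 61)
  e <- simulate_bm_traits(tr, 0, 1, 1, seed = 62)
  d <- data.frame(species = tr$tip.label, y = unname(e), x = rnorm(25))
  trees <- c(tr, tr, tr, tr)
  dist <- pgls_across_trees(d, model_spec("y", "x"), trees, tr)
  expect_length(dist$per_tree_fits, 4L)
  expect_equal(dist$per_tree_fits[[3]]$coefficients, dist$mcc_fit$coefficients)
  for (h in dist$hdp) {
    expect_equal(h$beta$lower, h$beta$upper)
    expect_equal(h$p$lower, h$p$upper)
  }
})

test_that("build_nest_models enumerates the three families with correct arity", {
  specs <- build_nest_models()
  expect_length(specs, 12L)
  expect_length(specs[["B_cup_depth"]]$predictors, 3L)  # + intercept = 4 cols
  expect_length(specs[["C_nest_height"]]$predictors, 2L)
  expect_equal(specs[["A_internal_diameter"]]$predictors,
               c("year_range", "latitude_range"))
  expect_equal(specs[["B_cup_depth"]]$response, "cv_cup_depth")
})

test_that("prepare_model_frame derives codings with the documented reference levels", {
  summary <- data.frame(species = c("A_a", "B_b"), cv_cup_depth = c(0.05, 0.07),
                        year_range = c(10, 20), latitude_range = c(1, 2))
  cov <- data.frame(species = c("A a", "B b"), body_mass_g = c(10, 20),
                    nest_type = c("cup", "dome"), innovation = c(0, 1),
                    clutch_min = c(2, 3), clutch_max = c(4, 3),
                    builder = c("both", "single"))
  mf <- prepare_model_frame(summary, cov)
  expect_equal(mf$nest_type_dome, c(0, 1))     # reference: open cup
  expect_equal(mf$builder_single, c(0, 1))     # reference: both parents
  expect_equal(mf$clutch_size_range, c(2, 0))
  cov$nest_type[1] <- "burrow"
  expect_error(prepare_model_frame(summary, cov), "nest_type")
  cov$nest_type[1] <- "cup"; cov$builder <- NULL
  expect_error(prepare_model_frame(summary, cov), "builder")
})
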