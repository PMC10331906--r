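#' Configuration for a synthetic museum nest study
#'
#' Defaults reproduce the sampling structure of the motivating museum
#' dataset: 55 passerine species, 8-25 nests per species, 3 caliper repeats
#' per nest, four log-scale nest dimensions, and a posterior-like set of
#' 1000 phylogenies. Trait log-means and Brownian rates are set so species
#' means span the observed ranges (cup depth roughly 2.5-9.2 cm, nest height
#' 3.7-20.8 cm, internal diameter 2-10.4 cm, external diameter 5.2-16.9 cm on
#' a unit-height tree), and the coefficient-of-variation process is centred
#' at 5% with spread chosen so realized species CVs span roughly 1-27%.
#'
#' @param n_species number of species (tree tips).
#' @param nests_min,nests_max per-species nest counts are uniform on this range.
#' @param n_repeats repeated measurements per nest.
#' @param n_trees number of phylogenies in the emulated posterior set.
#' @param birth_rate Yule speciation rate for the generator tree.
#' @param trait_means_z0 named numeric: root state of each trait's log-mean
#'   process (log cm).
#' @param trait_sigma2 named numeric: Brownian rate of each trait's log-mean
#'   process (per unit tree height).
#' @param trait_cor correlation between traits' species-mean processes.
#' @param lambda_means Pagel's lambda of the species-mean processes.
#' @param lambda_cv Pagel's lambda of the latent process generating
#'   within-species CVs.
#' @param cv_base baseline coefficient of variation (fraction).
#' @param cv_spread half-range of the CV process: one latent standard
#'   deviation moves the CV from `cv_base` to `cv_base + cv_spread`
#'   (multiplicatively; must be positive and `< cv_base`).
#' @param measurement_error_sd sd (cm) of caliper noise added to each repeat.
#' @param clutch_effect,builder_effect,nesttype_effect,innovation_effect
#'   additive shifts of the species CV per unit predictor (clutch-size range;
#'   single-parent builder; dome nest; innovative species). Defaults are the
#'   magnitudes of the effects reported for museum nests: a dome-nest shift
#'   of about +2 CV percentage points, small positive clutch-range and
#'   single-builder shifts, and no innovation effect.
#' @param tree_jitter_sdlog sdlog of the multiplicative lognormal jitter
#'   applied to branch lengths to emulate posterior spread (topology fixed).
#' @param year_window calendar window for collection years.
#' @param seed integer seed; the whole study is a deterministic function of
#'   the configuration including this seed.
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(
    n_species = 55L, nests_min = 8L, nests_max = 25L, n_repeats = 3L,
    n_trees = 1000L, birth_rate = 1,
    trait_means_z0 = c(cup_depth = 1.6, nest_height = 2.2,
                       internal_diameter = 1.6, external_diameter = 2.3),
    trait_sigma2 = c(cup_depth = 0.12, nest_height = 0.16,
                     internal_diameter = 0.16, external_diameter = 0.10),
    trait_cor = 0.5,
    lambda_means = 1, lambda_cv = 1,
    cv_base = 0.05, cv_spread = 0.03,
    measurement_error_sd = 0.05,
    clutch_effect = 0.005, builder_effect = 0.01,
    nesttype_effect = 0.02, innovation_effect = 0,
    tree_jitter_sdlog = 0.1,
    year_window = c(1850L, 1990L),
    seed = 1L) {
  cfg <- list(n_species = as.integer(n_species), nests_min = as.integer(nests_min),
              nests_max = as.integer(nests_max), n_repeats = as.integer(n_repeats),
              n_trees = as.integer(n_trees), birth_rate = birth_rate,
              trait_means_z0 = trait_means_z0, trait_sigma2 = trait_sigma2,
              trait_cor = trait_cor, lambda_means = lambda_means,
              lambda_cv = lambda_cv, cv_base = cv_base, cv_spread = cv_spread,
              measurement_error_sd = measurement_error_sd,
              clutch_effect = clutch_effect, builder_effect = builder_effect,
              nesttype_effect = nesttype_effect,
              innovation_effect = innovation_effect,
              tree_jitter_sdlog = tree_jitter_sdlog,
              year_window = year_window, seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_species >= 4L, nests_min >= 2L, nests_max >= nests_min,
              n_repeats >= 1L, n_trees >= 1L, birth_rate > 0,
              all(trait_sigma2 > 0), trait_cor >= 0, trait_cor < 1,
              lambda_means >= 0, lambda_means <= 1,
              lambda_cv >= 0, lambda_cv <= 1,
              cv_base > 0, measurement_error_sd >= 0,
              tree_jitter_sdlog >= 0, year_window[2] >= year_window[1])
    if (!setequal(names(trait_means_z0), nest_traits()) ||
        !setequal(names(trait_sigma2), nest_traits()))
      stop("trait_means_z0 and trait_sigma2 must be named by the four nest traits",
           call. = FALSE)
    if (any(trait_means_z0 <= 0))
      stop("trait log-means must be positive (measurements well above 1 cm)",
           call. = FALSE)
  })
  if (!(cfg$cv_spread > 0 && cfg$cv_spread < cfg$cv_base))
    stop("invalid config: cv_spread must be in (0, cv_base)", call. = FALSE)
  class(cfg) <- "simulation_config"
  cfg
}

#' Simulate an ultrametric pure-birth (Yule) phylogeny
#'
#' Wraps [ape::rphylo()] with extinction set to zero and rescales total tree
#' height to 1, so Brownian rates and lambda are on a common scale across
#' simulated studies. Tip labels are `Species_001`, `Species_002`, ...
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate speciation rate.
#' @param seed optional integer; when given, the tree is a deterministic
#'   function of it.
#' @return an ultrametric `phylo` of height 1.
#' @export
simulate_yule_tree <- function(n_tips, birth_rate = 1, seed = NULL) {
  stopifnot(n_tips >= 2L)
  if (!is.null(seed)) set.seed(as.integer(seed))
  tree <- ape::rphylo(n_tips, birth = birth_rate, death = 0)
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- sprintf("Species_%03d", seq_len(n_tips))
  tree
}

#' Simulate species trait values under lambda-scaled Brownian motion
#'
#' One multivariate-normal draw with mean `z0` and covariance
#' `sigma2 * lambda_transform(phylo_vcv(tree), lambda)`, via the Cholesky
#' factor of the transformed covariance.
#'
#' @param tree a `phylo`.
#' @param z0 root state (ancestral mean).
#' @param sigma2 Brownian rate (> 0).
#' @param lambda Pagel's lambda in `[0, 1]`.
#' @param seed optional integer seed.
#' @return named numeric vector of one value per tip.
#' @export
simulate_bm_traits <- function(tree, z0, sigma2, lambda = 1, seed = NULL) {
  stopifnot(sigma2 > 0)
  if (!is.null(seed)) set.seed(as.integer(seed))
  V <- phylo_vcv(tree)
  W <- lambda_transform(V, lambda)
  R <- tryCatch(chol(sigma2 * unclass(W)), error = function(e)
    stop("transformed covariance not positive definite", call. = FALSE))
  x <- drop(z0 + crossprod(R, stats::rnorm(nrow(W))))
  names(x) <- rownames(W)
  x
}

# correlated per-trait BM draws: tip x trait matrix with between-trait
# correlation rho and per-trait rates sigma2 (matrix-normal construction)
.simulate_bm_matrix <- function(tree, z0, sigma2, rho, lambda) {
  V <- lambda_transform(phylo_vcv(tree), lambda)
  n <- nrow(V); k <- length(z0)
  Sig <- diag(sqrt(sigma2)) %*% (matrix(rho, k, k) + diag(1 - rho, k)) %*%
    diag(sqrt(sigma2))
  Z <- matrix(stats::rnorm(n * k), n, k)
  X <- crossprod(chol(unclass(V)), Z) %*% chol(Sig)
  X <- sweep(X, 2, z0, "+")
  dimnames(X) <- list(rownames(V), names(z0))
  X
}

#' Simulate a complete synthetic nest study with known truth
#'
#' Generates everything the analysis pipeline consumes, mirroring the
#' structure of a museum nest collection study:
#' \enumerate{
#'   \item a Yule generator tree plus `n_trees` branch-length-jittered copies
#'     emulating a posterior tree set (topology fixed);
#'   \item per-trait species mean log-sizes from correlated Brownian motion
#'     with signal `lambda_means`;
#'   \item per-species, per-trait coefficients of variation from a latent
#'     Brownian process with signal `lambda_cv`, passed through a positive
#'     log-link around `cv_base` and truncated to `[0.005, 0.35]`, then
#'     shifted by the configured covariate effects;
#'   \item species covariates: dome nest, innovation and single-builder
#'     status as threshold-dichotomized Brownian liabilities (hence
#'     phylogenetically clumped), plus small-integer clutch sizes;
#'   \item specimen records: per nest a true log-size drawn around the
#'     species mean with sd `cv * mean_log`, and `n_repeats` caliper
#'     measurements with additive raw-scale noise; collection years and
#'     latitudes uniform within species-specific windows.
#' }
#' The `truth` element records every generating quantity needed to score
#' recovery. The designated MCC tree is the generator tree itself: all
#' members of the jittered set share its topology.
#'
#' @param config a [simulation_config()].
#' @return list of class `synthetic_study`: `trees` (multiPhylo), `mcc`
#'   (phylo), `specimens` (data.frame), `covariates` (data.frame), `truth`
#'   (list), `config`.
#' @export
simulate_study <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  traits <- nest_traits()
  gen_tree <- simulate_yule_tree(config$n_species, config$birth_rate,
                                 seed = sample.int(2^30, 1))
  sp <- gen_tree$tip.label

  trees <- vector("list", config$n_trees)
  for (i in seq_len(config$n_trees)) {
    tr <- gen_tree
    if (config$tree_jitter_sdlog > 0)
      tr$edge.length <- tr$edge.length *
        stats::rlnorm(length(tr$edge.length), 0, config$tree_jitter_sdlog)
    trees[[i]] <- tr
  }
  class(trees) <- "multiPhylo"

  z0 <- config$trait_means_z0[traits]
  s2 <- config$trait_sigma2[traits]
  mean_logs <- .simulate_bm_matrix(gen_tree, z0, s2, config$trait_cor,
                                   config$lambda_means)

  # covariates first (their effects feed the CV process)
  liab <- function() simulate_bm_traits(gen_tree, 0, 1, 1)
  l_dome <- liab(); l_innov <- liab(); l_build <- liab()
  dome <- as.numeric(l_dome > stats::median(l_dome))
  innovation <- as.numeric(l_innov > stats::median(l_innov))
  single <- as.numeric(l_build > stats::quantile(l_build, 0.7))
  clutch_min <- sample(2:5, config$n_species, replace = TRUE)
  clutch_range <- pmin(stats::rpois(config$n_species, 1.5), 6L)
  body_mass <- exp(simulate_bm_traits(gen_tree, log(30), 0.35, 0.5))

  s_link <- log((config$cv_base + config$cv_spread) / config$cv_base)
  shift <- config$clutch_effect * clutch_range +
    config$builder_effect * single +
    config$nesttype_effect * dome +
    config$innovation_effect * innovation
  cv_true <- matrix(NA_real_, config$n_species, length(traits),
                    dimnames = list(sp, traits))
  for (tr in traits) {
    u <- simulate_bm_traits(gen_tree, 0, 1, config$lambda_cv)
    u <- (u - mean(u)) / stats::sd(u)
    cv_true[, tr] <- pmin(pmax(config$cv_base * exp(s_link * u) + shift,
                               0.005), 0.35)
  }

  n_nests <- config$nests_min +
    sample.int(config$nests_max - config$nests_min + 1L, config$n_species,
               replace = TRUE) - 1L
  yr_w <- config$year_window
  yr_width <- stats::runif(config$n_species, 2, min(80, yr_w[2] - yr_w[1]))
  yr_start <- stats::runif(config$n_species, yr_w[1], yr_w[2] - yr_width)
  lat_centre <- stats::runif(config$n_species, -35, 55)
  lat_width <- stats::runif(config$n_species, 0.5, 20)

  rows <- vector("list", config$n_species)
  for (i in seq_len(config$n_species)) {
    ni <- n_nests[i]
    log_true <- sapply(traits, function(tr)
      stats::rnorm(ni, mean_logs[i, tr], cv_true[i, tr] * mean_logs[i, tr]))
    log_true <- matrix(log_true, nrow = ni)
    raw_true <- exp(log_true)
    yrs <- round(stats::runif(ni, yr_start[i], yr_start[i] + yr_width[i]))
    lats <- stats::runif(ni, lat_centre[i] - lat_width[i] / 2,
                         lat_centre[i] + lat_width[i] / 2)
    reps <- lapply(seq_len(config$n_repeats), function(r) {
      meas <- raw_true +
        matrix(stats::rnorm(ni * length(traits), 0,
                            config$measurement_error_sd), ni)
      meas <- pmax(meas, 0.05)
      df <- data.frame(species = sp[i],
                       specimen_id = sprintf("N%03d", seq_len(ni)),
                       repeat_id = r, stringsAsFactors = FALSE)
      colnames(meas) <- .trait_cols(traits)
      cbind(df, as.data.frame(meas), year = yrs, latitude = lats)
    })
    rows[[i]] <- do.call(rbind, reps)
  }
  specimens <- do.call(rbind, rows)
  rownames(specimens) <- NULL

  covariates <- data.frame(
    species = sp,
    body_mass_g = round(as.numeric(body_mass), 1),
    nest_type = ifelse(dome == 1, "dome", "cup"),
    innovation = innovation,
    clutch_min = clutch_min,
    clutch_max = clutch_min + clutch_range,
    builder = ifelse(single == 1, "single", "both"),
    stringsAsFactors = FALSE)

  truth <- list(
    species = sp,
    mean_logs = mean_logs,
    cv = cv_true,
    lambda_means = config$lambda_means,
    lambda_cv = config$lambda_cv,
    effects = c(clutch = config$clutch_effect, builder = config$builder_effect,
                nesttype = config$nesttype_effect,
                innovation = config$innovation_effect),
    n_nests = stats::setNames(n_nests, sp),
    seed = config$seed)

  structure(list(trees = trees, mcc = gen_tree, specimens = specimens,
                 covariates = covariates, truth = truth, config = config),
            class = "synthetic_study")
}

#' Write a synthetic study to plain-text files
#'
#' Writes `specimens.csv`, `covariates.csv`, `trees.nwk` (one Newick per
#' line), `mcc.nwk`, `truth.json` and `config.json` into a directory, the
#' same formats the pipeline reads.
#'
#' @param study a `synthetic_study`.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(study$specimens, file.path(dir, "specimens.csv"),
                   row.names = FALSE)
  utils::write.csv(study$covariates, file.path(dir, "covariates.csv"),
                   row.names = FALSE)
  writeLines(vapply(study$trees, serialize_newick, character(1)),
             file.path(dir, "trees.nwk"))
  writeLines(serialize_newick(study$mcc), file.path(dir, "mcc.nwk"))
  truth <- study$truth
  # keep names through JSON: matrices as species-keyed frames, named
  # vectors as objects
  truth$mean_logs <- cbind(data.frame(species = rownames(truth$mean_logs)),
                           as.data.frame(truth$mean_logs, row.names = NULL))
  truth$cv <- cbind(data.frame(species = rownames(truth$cv)),
                    as.data.frame(truth$cv, row.names = NULL))
  truth$effects <- as.list(truth$effects)
  truth$n_nests <- as.list(truth$n_nests)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(unclass(study$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
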