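#' Run the full comparative analysis of nest-morphology variation
#'
#' End-to-end orchestration of the analysis plan: per-species trait
#' summaries (CVs of log-transformed dimensions), Pagel's lambda
#' phylogenetic signal for each trait's CV, each trait's species mean and
#' body mass (on the MCC tree, with likelihood-ratio tests, and across the
#' tree set as a 95% HDP interval), and the three PGLS model families per
#' trait (sampling spans; innovation + body mass + nest type; clutch range +
#' building effort), also aggregated across trees.
#'
#' @param specimens specimen table (data.frame or CSV path).
#' @param covariates species covariate table (data.frame or CSV path), or
#'   `NULL` for a signal-only run (the PGLS families needing covariates and
#'   the body-mass signal are then skipped with a warning).
#' @param mcc the MCC `phylo` (or Newick path).
#' @param trees optional `multiPhylo` (or Newick path, one tree per line);
#'   when `NULL` only MCC-tree fits are reported, without HDP intervals.
#' @param traits traits to analyze.
#' @param lambda_pgls lambda mode for the PGLS residual covariance: a fixed
#'   number in `[0, 1]` (default 1) or `"ml"`.
#' @param hdp_mass HDP coverage, default 0.95.
#' @param log_body_mass see [prepare_model_frame()].
#' @return list of class `report_bundle`: `species_summary`, `signal`
#'   (data.frame: one row per analyzed quantity with `lambda_mcc`, `p_mcc`,
#'   `hdp_low`, `hdp_high`), `signal_draws` (per-tree lambda estimates),
#'   `pgls` (list of `pgls_distribution` or `gls_fit` per model),
#'   `pgls_tables` (tidy coefficient tables), `manifest`.
#' @export
run_analysis <- function(specimens, covariates = NULL, mcc, trees = NULL,
                         traits = nest_traits(), lambda_pgls = 1,
                         hdp_mass = 0.95, log_body_mass = FALSE) {
  if (is.character(specimens)) specimens <- read_specimens(specimens)
  if (is.character(covariates)) covariates <- utils::read.csv(covariates,
                                                              stringsAsFactors = FALSE)
  if (is.character(mcc)) mcc <- parse_newick(readLines(mcc, warn = FALSE)[1])
  if (is.character(trees)) trees <- read_tree_set(trees)
  summary <- summarize_species(specimens)

  quantities <- list()
  for (tr in traits) {
    quantities[[paste0("cv_", tr)]] <- stats::setNames(summary[[paste0("cv_", tr)]],
                                                       summary$species)
    quantities[[paste0("mean_log_", tr)]] <-
      stats::setNames(summary[[paste0("mean_log_", tr)]], summary$species)
  }
  if (!is.null(covariates)) {
    quantities[["body_mass"]] <- stats::setNames(covariates$body_mass_g,
                                                 normalize_labels(covariates$species))
  } else {
    warning("no covariates supplied: skipping body-mass signal and PGLS families B/C",
            call. = FALSE)
  }

  signal_rows <- list()
  signal_draws <- list()
  for (qn in names(quantities)) {
    x <- quantities[[qn]]
    fit <- suppressWarnings(fit_lambda(x, mcc))
    row <- data.frame(quantity = qn, n = fit$n_species,
                      lambda_mcc = fit$lambda_hat, p_mcc = fit$p_value,
                      hdp_low = NA_real_, hdp_high = NA_real_,
                      stringsAsFactors = FALSE)
    if (!is.null(trees)) {
      dist <- suppressMessages(lambda_across_trees(x, trees, mass = hdp_mass))
      row$hdp_low <- dist$hdp$lower
      row$hdp_high <- dist$hdp$upper
      signal_draws[[qn]] <- dist$lambda_hats
    }
    signal_rows[[qn]] <- row
  }
  signal <- do.call(rbind, signal_rows)
  rownames(signal) <- NULL

  model_frame <- if (!is.null(covariates)) {
    prepare_model_frame(summary, covariates, log_body_mass)
  } else {
    summary
  }
  fams <- if (!is.null(covariates)) c("A", "B", "C") else "A"
  specs <- build_nest_models(traits, lambda = lambda_pgls)
  specs <- specs[grepl(paste0("^(", paste(fams, collapse = "|"), ")_"),
                       names(specs))]
  pgls <- list()
  for (mn in names(specs)) {
    pgls[[mn]] <- tryCatch({
      if (!is.null(trees)) {
        suppressMessages(suppressWarnings(
          pgls_across_trees(model_frame, specs[[mn]], trees, mcc, hdp_mass)))
      } else {
        suppressMessages(suppressWarnings(
          pgls_fit(model_frame, specs[[mn]], mcc)))
      }
    }, error = function(e) {
      warning("model ", mn, " failed: ", conditionMessage(e), call. = FALSE)
      NULL
    })
  }

  bundle <- structure(list(
    species_summary = summary,
    signal = signal,
    signal_draws = signal_draws,
    pgls = pgls,
    pgls_tables = lapply(pgls, pgls_table),
    manifest = list(
      package_version = as.character(utils::packageVersion("nestvar")),
      n_species = nrow(summary),
      n_trees = if (is.null(trees)) 0L else length(trees),
      traits = traits,
      lambda_pgls = lambda_pgls,
      hdp_mass = hdp_mass,
      models_fit = names(Filter(Negate(is.null), pgls)),
      n_per_model = vapply(pgls, function(m) {
        if (is.null(m)) NA_integer_
        else if (inherits(m, "pgls_distribution")) m$mcc_fit$n else m$n
      }, integer(1))
    )
  ), class = "report_bundle")
  bundle
}

#' Tidy coefficient table for one fitted PGLS model
#'
#' @param m a `gls_fit` or `pgls_distribution` (or `NULL`).
#' @return data.frame with one row per coefficient: estimate, se, t, p, and
#'   (for across-tree fits) the HDP bounds of beta, t and p.
#' @export
pgls_table <- function(m) {
  if (is.null(m)) return(NULL)
  fit <- if (inherits(m, "pgls_distribution")) m$mcc_fit else m
  tab <- data.frame(term = names(fit$coefficients),
                    estimate = unname(fit$coefficients),
                    se = unname(fit$standard_errors),
                    t = unname(fit$t_stats),
                    p = unname(fit$p_values),
                    stringsAsFactors = FALSE)
  if (inherits(m, "pgls_distribution")) {
    tab$beta_hdp_low <- vapply(m$hdp, function(h) h$beta$lower, numeric(1))
    tab$beta_hdp_high <- vapply(m$hdp, function(h) h$beta$upper, numeric(1))
    tab$t_hdp_low <- vapply(m$hdp, function(h) h$t$lower, numeric(1))
    tab$t_hdp_high <- vapply(m$hdp, function(h) h$t$upper, numeric(1))
    tab$p_hdp_low <- vapply(m$hdp, function(h) h$p$lower, numeric(1))
    tab$p_hdp_high <- vapply(m$hdp, function(h) h$p$upper, numeric(1))
  }
  tab
}

#' Write a report bundle to disk
#'
#' Writes `species_summary.csv` (with CV both as fraction and percent),
#' `signal.csv`, per-tree `signal_draws.csv`, one `pgls_<model>.csv` per
#' fitted model, and `manifest.json`. Nothing time-stamped is written, so
#' repeated runs with the same inputs are byte-identical.
#'
#' @param bundle a `report_bundle`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ss <- bundle$species_summary
  for (tr in bundle$manifest$traits)
    ss[[paste0("cv_pct_", tr)]] <- 100 * ss[[paste0("cv_", tr)]]
  utils::write.csv(ss, file.path(dir, "species_summary.csv"), row.names = FALSE)
  utils::write.csv(bundle$signal, file.path(dir, "signal.csv"), row.names = FALSE)
  if (length(bundle$signal_draws) > 0L)
    utils::write.csv(as.data.frame(bundle$signal_draws),
                     file.path(dir, "signal_draws.csv"), row.names = FALSE)
  for (mn in names(bundle$pgls_tables)) {
    tab <- bundle$pgls_tables[[mn]]
    if (!is.null(tab))
      utils::write.csv(tab, file.path(dir, paste0("pgls_", mn, ".csv")),
                       row.names = FALSE)
  }
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Score a report bundle against the truth of a synthetic study
#'
#' Compares the estimated phylogenetic signal of each trait's CV against the
#' generating `lambda_cv`, of each trait's mean against `lambda_means`, and
#' each fitted PGLS covariate coefficient against the generating effect
#' size, with absolute errors and HDP coverage flags.
#'
#' @param bundle a `report_bundle` produced from the study's own data.
#' @param truth the `truth` element of the [simulate_study()] output.
#' @return data.frame: `quantity`, `true`, `estimate`, `abs_error`,
#'   `hdp_low`, `hdp_high`, `covered`.
#' @export
compare_to_truth <- function(bundle, truth) {
  stopifnot(inherits(bundle, "report_bundle"))
  truth$effects <- unlist(truth$effects)  # robust to JSON round-trips
  truth$species <- as.character(unlist(truth$species))
  if (!setequal(bundle$species_summary$species, truth$species))
    stop("species of bundle and truth do not match; bundle was not produced ",
         "from this study", call. = FALSE)
  rows <- list()
  for (i in seq_len(nrow(bundle$signal))) {
    qn <- bundle$signal$quantity[i]
    true <- if (grepl("^cv_", qn)) truth$lambda_cv
            else if (grepl("^mean_log_", qn)) truth$lambda_means
            else NA_real_
    if (is.na(true)) next
    lo <- bundle$signal$hdp_low[i]; hi <- bundle$signal$hdp_high[i]
    rows[[paste0("lambda_", qn)]] <- data.frame(
      quantity = paste0("lambda_", qn), true = true,
      estimate = bundle$signal$lambda_mcc[i],
      abs_error = abs(bundle$signal$lambda_mcc[i] - true),
      hdp_low = lo, hdp_high = hi,
      covered = if (is.na(lo)) NA else (true >= lo & true <= hi),
      stringsAsFactors = FALSE)
  }
  eff_map <- c(clutch_size_range = "clutch", builder_single = "builder",
               nest_type_dome = "nesttype", innovation = "innovation")
  for (mn in names(bundle$pgls_tables)) {
    tab <- bundle$pgls_tables[[mn]]
    if (is.null(tab)) next
    for (j in seq_len(nrow(tab))) {
      term <- tab$term[j]
      if (!term %in% names(eff_map)) next
      true <- unname(truth$effects[eff_map[[term]]])
      lo <- if ("beta_hdp_low" %in% names(tab)) tab$beta_hdp_low[j] else NA_real_
      hi <- if ("beta_hdp_high" %in% names(tab)) tab$beta_hdp_high[j] else NA_real_
      rows[[paste(mn, term, sep = ".")]] <- data.frame(
        quantity = paste0("beta_", mn, "_", term), true = true,
        estimate = tab$estimate[j], abs_error = abs(tab$estimate[j] - true),
        hdp_low = lo, hdp_high = hi,
        covered = if (is.na(lo)) NA else (true >= lo & true <= hi),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
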