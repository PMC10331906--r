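#' Nest trait names
#'
#' The four nest dimensions measured on each specimen, in centimetres.
#'
#' @return character vector of trait names.
#' @export
nest_traits <- function() {
  c("cup_depth", "nest_height", "internal_diameter", "external_diameter")
}

.trait_cols <- function(traits = nest_traits()) paste0(traits, "_cm")

.specimen_cols <- function() {
  c("species", "specimen_id", "repeat_id", .trait_cols(), "year", "latitude")
}

#' Read a specimen-level nest measurement table
#'
#' Expects the columns `species, specimen_id, repeat_id, cup_depth_cm,
#' nest_height_cm, internal_diameter_cm, external_diameter_cm, year,
#' latitude`. Each row is one repeated measurement of one nest specimen;
#' trait cells may be empty (missing). All measurements must be in
#' centimetres: the coefficient of variation of log-values is not
#' unit-invariant, so mixed units invalidate every downstream statistic.
#'
#' @param path path to a CSV file.
#' @return a validated specimen `data.frame`.
#' @export
read_specimens <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_specimen_table(df)
}

#' Validate a specimen table
#'
#' Checks required columns, positivity of present trait values (with the
#' offending row reported), repeat ids in 1..3, and uniqueness of the
#' (species, specimen_id, repeat_id) key.
#'
#' @param df a data.frame of specimen records.
#' @return the validated data.frame.
#' @export
as_specimen_table <- function(df) {
  missing_cols <- setdiff(.specimen_cols(), names(df))
  if (length(missing_cols) > 0L)
    stop("specimen table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0L) stop("specimen table is empty", call. = FALSE)
  df$species <- normalize_labels(df$species)
  for (col in .trait_cols()) {
    bad <- which(!is.na(df[[col]]) & df[[col]] <= 0)
    if (length(bad) > 0L)
      stop("non-positive value in ", col, " at row ", bad[1], call. = FALSE)
  }
  if (!all(df$repeat_id %in% 1:3))
    stop("repeat_id must be in 1..3", call. = FALSE)
  key <- paste(df$species, df$specimen_id, df$repeat_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (species, specimen_id, repeat_id) at row ",
         which(duplicated(key))[1], call. = FALSE)
  df
}

#' Measurement repeatability (one-way ANOVA intraclass correlation)
#'
#' Quantifies agreement of the repeated caliper measurements of each nest:
#' ICC = (MS_among - MS_within) / (MS_among + (k - 1) MS_within), with mean
#' squares from a one-way ANOVA of measurement on specimen and k the common
#' repeat count. For unbalanced designs the harmonic mean of the per-specimen
#' repeat counts is used for k, with a message.
#'
#' @param table a specimen table.
#' @param trait one of [nest_traits()].
#' @return list with `trait`, `icc`, `ms_among`, `ms_within`, `n_specimens`,
#'   `k_repeats`.
#' @export
repeatability <- function(table, trait) {
  trait <- match.arg(trait, nest_traits())
  col <- paste0(trait, "_cm")
  d <- table[!is.na(table[[col]]), c("species", "specimen_id", col)]
  d$nest <- factor(paste(d$species, d$specimen_id, sep = "\r"))
  counts <- table(d$nest)
  counts <- counts[counts >= 2]
  if (length(counts) < 2L)
    stop("need >= 2 specimens with >= 2 repeats for ", trait, call. = FALSE)
  d <- d[d$nest %in% names(counts), , drop = FALSE]
  d$nest <- droplevels(d$nest)
  fit <- stats::aov(d[[col]] ~ d$nest)
  # only the mean squares are used; the F-test (unreliable for exact fits)
  # is not, so its warning is irrelevant here
  tab <- suppressWarnings(stats::anova(fit))
  ms_among <- tab[["Mean Sq"]][1]
  ms_within <- tab[["Mean Sq"]][2]
  tol <- 1e-12 * mean(d[[col]])^2
  if (ms_among <= tol && ms_within <= tol)
    stop("no variance in ", trait, ": all measurements identical", call. = FALSE)
  k <- as.numeric(counts)
  if (length(unique(k)) == 1L) {
    k_eff <- k[1]
  } else {
    k_eff <- length(k) / sum(1 / k)
    message("unbalanced repeats for ", trait, "; using harmonic-mean k = ",
            signif(k_eff, 4))
  }
  icc <- (ms_among - ms_within) / (ms_among + (k_eff - 1) * ms_within)
  list(trait = trait, icc = icc, ms_among = ms_among, ms_within = ms_within,
       n_specimens = length(counts), k_repeats = k_eff)
}

#' Per-species trait summaries: log-means, coefficients of variation, ranges
#'
#' For each nest the repeated measurements are averaged on the raw (cm) scale
#' and the per-nest mean is natural-log transformed. Per species and trait,
#' the mean and sample (n-1) standard deviation of the per-nest log values
#' give the coefficient of variation cv = sd_log / mean_log, the
#' dimensionless measure of intraspecific nest-building variation. Sampling
#' spans (max - min collection year, max - min latitude) are returned per
#' species for use as nuisance predictors.
#'
#' Species with a single nest for a trait get `NA` for that cv (with a
#' warning); a non-positive mean log value aborts, since it indicates trait
#' values at or below 1 cm dominating — almost always a unit inconsistency.
#'
#' @param table a specimen table (see [as_specimen_table()]).
#' @param traits traits to summarize, default all four.
#' @return a data.frame with one row per species: `species`,
#'   `n_nests_<trait>`, `mean_log_<trait>`, `sd_log_<trait>`, `cv_<trait>`,
#'   `year_range`, `latitude_range`.
#' @export
summarize_species <- function(table, traits = nest_traits()) {
  table <- as_specimen_table(table)
  species <- sort(unique(table$species))
  out <- data.frame(species = species, stringsAsFactors = FALSE)
  single_nest <- character(0)
  for (tr in traits) {
    col <- paste0(tr, "_cm")
    n_v <- mean_v <- sd_v <- cv_v <- rep(NA_real_, length(species))
    for (i in seq_along(species)) {
      d <- table[table$species == species[i] & !is.na(table[[col]]), ]
      if (nrow(d) == 0L) next
      nest_mean <- tapply(d[[col]], d$specimen_id, mean)
      log_means <- log(as.numeric(nest_mean))
      n_v[i] <- length(log_means)
      mean_v[i] <- mean(log_means)
      if (mean_v[i] <= 0)
        stop("mean log ", tr, " <= 0 for species ", species[i],
             "; check that measurements are in consistent cm units",
             call. = FALSE)
      if (length(log_means) >= 2L) {
        sd_v[i] <- stats::sd(log_means)
        cv_v[i] <- sd_v[i] / mean_v[i]
      } else {
        single_nest <- c(single_nest, paste0(species[i], ":", tr))
      }
    }
    out[[paste0("n_nests_", tr)]] <- n_v
    out[[paste0("mean_log_", tr)]] <- mean_v
    out[[paste0("sd_log_", tr)]] <- sd_v
    out[[paste0("cv_", tr)]] <- cv_v
  }
  if (length(single_nest) > 0L)
    warning("cv omitted for species with a single nest: ",
            paste(single_nest, collapse = ", "), call. = FALSE)
  out$year_range <- as.numeric(tapply(table$year, table$species,
                                      function(y) diff(range(y)))[species])
  out$latitude_range <- as.numeric(tapply(table$latitude, table$species,
                                          function(l) diff(range(l)))[species])
  rownames(out) <- NULL
  out
}
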