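# Synthetic suspected-VAP cohort generator. Hierarchical sampling per
# episode: confirmed-VAP label first, then group-conditional clinical
# features, then (if an ultrasound exam exists) consolidation type, and
# size / laterality / bronchogram conditional on a consolidation being
# present. All printed-table-derivable frequencies come from the pilot
# cohort constants in calibration.R; shapes the pilot tables cannot
# identify (continuous mixtures, microbiology and radiography mixes) are
# fixed defaults exposed in the config.

#' Lognormal parameters from a median and quartiles
#'
#' Inverts a median/IQR summary into lognormal parameters:
#' `mu = log(median)` and `sigma` as the least-squares solution of the two
#' quartile equations `log(q1) = mu - z75 sigma`,
#' `log(q3) = mu + z75 sigma` (`z75 = qnorm(0.75) ~ 0.6745`), i.e.
#' `sigma = (log(q3) - log(q1)) / (2 z75)`.
#'
#' @param median,q1,q3 positive, with `q1 <= median <= q3`.
#' @return list of class `"lognormal_params"` with `mu`, `sigma`.
#' @examples
#' lognormal_from_quartiles(0.47, 0.17, 1.32)  # mu ~ -0.755, sigma ~ 1.52
#' @export
lognormal_from_quartiles <- function(median, q1, q3) {
  if (!all(is.finite(c(median, q1, q3))) || any(c(median, q1, q3) <= 0))
    stop("quartiles must be positive", call. = FALSE)
  if (q1 > median || median > q3)
    stop("quartiles must satisfy q1 <= median <= q3", call. = FALSE)
  z75 <- stats::qnorm(0.75)
  structure(list(mu = unname(log(median)),
                 sigma = unname((log(q3) - log(q1)) / (2 * z75))),
            class = "lognormal_params")
}

#' Default generator configuration
#'
#' The study conditions: confirmed-VAP prevalence 51/108, ultrasound
#' coverage 84/108, per-group LUS-finding conditionals taken verbatim from
#' the pilot counts ([pilot_lus_counts()]), per-group lognormal PCT fitted
#' to the printed median/IQRs, secretion and fever frequencies from the
#' pilot descriptive table, and configurable mixtures for temperature,
#' leukocytes, P/F ratio, microbiology and radiography (not identifiable
#' from the printed tables; defaults chosen to populate every score band).
#'
#' @param n default cohort size (108, the pilot size).
#' @return list of class `"generator_config"`.
#' @export
default_generator_config <- function(n = 108) {
  cs <- pilot_cohort_summary()
  counts <- pilot_lus_counts()
  grab <- function(feature, levels, col) {
    sub <- counts[counts$feature == feature, ]
    stats::setNames(sub[[col]][match(levels, sub$level)], levels)
  }
  # type conditionals use the LUS-subset group sizes (49 / 35)
  type_vap    <- grab("consolidation_type", .consolidation_levels, "vap") / cs$n_lus_vap
  type_no_vap <- grab("consolidation_type", .consolidation_levels, "no_vap") / cs$n_lus_no_vap
  # size / laterality / bronchogram conditionals are restricted to the
  # consolidated patients of each group (48 VAP, 28 no-VAP)
  n_cons_vap    <- cs$n_lus_vap - counts$vap[counts$feature == "consolidation_type" & counts$level == "none"]
  n_cons_no_vap <- cs$n_lus_no_vap - counts$no_vap[counts$feature == "consolidation_type" & counts$level == "none"]
  size_vap    <- grab("size_band", c("lt15", "s15to20", "gt20"), "vap") / n_cons_vap
  size_no_vap <- grab("size_band", c("lt15", "s15to20", "gt20"), "no_vap") / n_cons_no_vap
  lat_vap     <- grab("laterality", c("bilateral", "unilateral"), "vap") / n_cons_vap
  lat_no_vap  <- grab("laterality", c("bilateral", "unilateral"), "no_vap") / n_cons_no_vap
  # bronchogram "none" among consolidated = printed none minus the
  # unconsolidated patients (who necessarily have no bronchogram)
  bg_vap <- grab("bronchogram", .bronchogram_levels, "vap")
  bg_vap["none"] <- bg_vap["none"] -
    counts$vap[counts$feature == "consolidation_type" & counts$level == "none"]
  bg_no_vap <- grab("bronchogram", .bronchogram_levels, "no_vap")
  bg_no_vap["none"] <- bg_no_vap["none"] -
    counts$no_vap[counts$feature == "consolidation_type" & counts$level == "none"]
  wq <- cs$wbc_quartiles
  config <- list(
    n = n,
    prevalence = cs$n_vap / cs$n_total,
    p_lus_performed = cs$n_lus / cs$n_total,
    consolidation_type = list(vap = type_vap, no_vap = type_no_vap),
    size_given_consolidated = list(vap = size_vap, no_vap = size_no_vap),
    laterality_given_consolidated = list(vap = lat_vap, no_vap = lat_no_vap),
    bronchogram_given_consolidated = list(vap = bg_vap / n_cons_vap,
                                          no_vap = bg_no_vap / n_cons_no_vap),
    pct = list(
      vap = do.call(lognormal_from_quartiles, as.list(unname(cs$pct_quartiles$vap))),
      no_vap = do.call(lognormal_from_quartiles, as.list(unname(cs$pct_quartiles$no_vap)))),
    p_pct_missing = 0,
    secretions = list(
      vap = cs$secretions$vap / sum(cs$secretions$vap),
      no_vap = cs$secretions$no_vap / sum(cs$secretions$no_vap)),
    p_fever = c(vap = cs$fever$vap[1] / cs$fever$vap[2],
                no_vap = cs$fever$no_vap[1] / cs$fever$no_vap[2]),
    temperature = list(febrile = c(mean = 39.2, sd = 0.7),
                       afebrile = c(mean = 37.1, sd = 0.5)),
    wbc = list(
      vap = lognormal_from_quartiles(wq["median"], wq["q1"], wq["q3"]),
      no_vap = lognormal_from_quartiles(wq["median"], wq["q1"], wq["q3"])),
    p_bands500 = c(vap = 0.15, no_vap = 0.05),
    p_pf_low = c(vap = 0.65, no_vap = 0.60),
    pf = list(low = c(mean = 180, sd = 35), high = c(mean = 300, sd = 45)),
    p_ards = c(vap = 0.10, no_vap = 0.10),
    microbiology = list(
      vap = c(negative = 0.15, positive = 0.40, positive_with_gram_match = 0.45),
      no_vap = c(negative = 0.35, positive = 0.45, positive_with_gram_match = 0.20)),
    radiography = list(
      vap = c(no_infiltrate = 0.25, patchy_diffuse = 0.35, localized = 0.40),
      no_vap = c(no_infiltrate = 0.30, patchy_diffuse = 0.40, localized = 0.30)),
    seed = NULL)
  structure(config, class = "generator_config")
}

.check_prob_vector <- function(p, what) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop(sprintf("generator config: '%s' is not a probability vector", what),
         call. = FALSE)
}

#' Validate a generator configuration
#'
#' @param config a `"generator_config"` list.
#' @return `config`, invisibly; errors on an invalid configuration.
#' @export
validate_generator_config <- function(config) {
  if (config$prevalence <= 0 || config$prevalence >= 1)
    stop("generator config: prevalence must lie in (0, 1)", call. = FALSE)
  if (config$p_lus_performed < 0 || config$p_lus_performed > 1)
    stop("generator config: p_lus_performed must lie in [0, 1]", call. = FALSE)
  for (f in c("consolidation_type", "size_given_consolidated",
              "laterality_given_consolidated", "bronchogram_given_consolidated",
              "secretions", "microbiology", "radiography"))
    for (g in c("vap", "no_vap"))
      .check_prob_vector(config[[f]][[g]], paste(f, g, sep = "/"))
  for (g in c("vap", "no_vap")) {
    if (config$pct[[g]]$sigma < 0 || config$wbc[[g]]$sigma < 0)
      stop("generator config: lognormal sigma must be non-negative", call. = FALSE)
  }
  invisible(config)
}

.sample_levels <- function(n, levels, prob) {
  if (n == 0) return(character(0))
  levels[sample.int(length(levels), n, replace = TRUE, prob = prob)]
}

# group-conditional categorical draw: prob vectors indexed by vap status
.draw_by_group <- function(vap, levels, probs) {
  out <- character(length(vap))
  out[vap]  <- .sample_levels(sum(vap), levels, probs$vap)
  out[!vap] <- .sample_levels(sum(!vap), levels, probs$no_vap)
  out
}

#' Generate a synthetic suspected-VAP cohort
#'
#' Draws `n` episodes under a [default_generator_config()] (or an override)
#' with a single seed governing all randomness. Sampling is hierarchical:
#' the confirmed-VAP label, then group-conditional clinical features, then
#' ultrasound existence, consolidation type, and size / laterality /
#' bronchogram conditional on a consolidation (structural zeros: an
#' unconsolidated exam carries no size, laterality or bronchogram).
#' Identical `(config, n, seed)` reproduce the identical cohort.
#'
#' @param config a `"generator_config"`.
#' @param n cohort size; defaults to `config$n`.
#' @param seed integer seed; defaults to `config$seed`.
#' @return cohort data frame in the cohort CSV schema (see
#'   [read_cohort()]).
#' @export
generate_cohort <- function(config = default_generator_config(), n = config$n,
                            seed = config$seed) {
  validate_generator_config(config)
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  vap <- stats::runif(n) < config$prevalence
  grp <- ifelse(vap, "vap", "no_vap")

  febrile <- stats::runif(n) < config$p_fever[grp]
  tmp_par <- config$temperature
  temperature <- ifelse(febrile,
    stats::rnorm(n, tmp_par$febrile["mean"], tmp_par$febrile["sd"]),
    stats::rnorm(n, tmp_par$afebrile["mean"], tmp_par$afebrile["sd"]))
  temperature <- round(pmin(pmax(temperature, 25), 45), 1)

  wbc <- numeric(n)
  pct <- numeric(n)
  for (g in c("vap", "no_vap")) {
    idx <- grp == g
    wbc[idx] <- stats::rlnorm(sum(idx), config$wbc[[g]]$mu, config$wbc[[g]]$sigma)
    pct[idx] <- stats::rlnorm(sum(idx), config$pct[[g]]$mu, config$pct[[g]]$sigma)
  }
  wbc <- round(wbc)
  pct <- round(pct, 2)
  pct[stats::runif(n) < config$p_pct_missing] <- NA_real_

  has_bands <- stats::runif(n) < config$p_bands500[grp]
  band_forms <- ifelse(has_bands, round(stats::runif(n, 500, 1500)),
                       round(stats::runif(n, 0, 400)))

  pf_low <- stats::runif(n) < config$p_pf_low[grp]
  pf_ratio <- ifelse(pf_low,
    stats::rnorm(n, config$pf$low["mean"], config$pf$low["sd"]),
    stats::rnorm(n, config$pf$high["mean"], config$pf$high["sd"]))
  pf_ratio <- round(pmax(pf_ratio, 40), 1)
  ards <- as.integer(stats::runif(n) < config$p_ards[grp])

  secretions   <- .draw_by_group(vap, .secretions_levels, config$secretions)
  microbiology <- .draw_by_group(vap, .microbiology_levels, config$microbiology)
  radiography  <- .draw_by_group(vap, .radiography_levels, config$radiography)

  lus_performed <- as.integer(stats::runif(n) < config$p_lus_performed)
  consolidation_type <- rep(NA_character_, n)
  size_band <- rep(NA_character_, n)
  laterality <- rep(NA_character_, n)
  bronchogram <- rep(NA_character_, n)
  on <- lus_performed == 1
  consolidation_type[on] <- .draw_by_group(vap[on], .consolidation_levels,
                                           config$consolidation_type)
  cons <- on & !is.na(consolidation_type) & consolidation_type != "none"
  size_band[on] <- "none"; laterality[on] <- "none"; bronchogram[on] <- "none"
  size_band[cons] <- .draw_by_group(vap[cons], c("lt15", "s15to20", "gt20"),
                                    config$size_given_consolidated)
  laterality[cons] <- .draw_by_group(vap[cons], c("bilateral", "unilateral"),
                                     config$laterality_given_consolidated)
  bronchogram[cons] <- .draw_by_group(vap[cons], .bronchogram_levels,
                                      config$bronchogram_given_consolidated)

  data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    vap_confirmed = as.integer(vap),
    temperature_c = temperature,
    wbc_per_mm3 = wbc,
    band_forms_per_mm3 = band_forms,
    pf_ratio = pf_ratio,
    ards = ards,
    secretions = secretions,
    radiography = radiography,
    microbiology = microbiology,
    pct_ng_ml = pct,
    lus_performed = lus_performed,
    consolidation_type = consolidation_type,
    size_band = size_band,
    laterality = laterality,
    bronchogram = bronchogram,
    stringsAsFactors = FALSE)
}
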