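#' Configuration for the synthetic response generator
#'
#' Defines the data-generating model used to emulate a screening campaign:
#' for each non-centerpoint run,
#' `Y = (baseline + sum(beta_i * x_i) + sum(beta_ij * x_i * x_j) + day + month) * (1 + eps)`
#' with `x` the coded levels, `day`/`month` additive normal random effects
#' (drawn once per day / month label), and `eps ~ N(0, cv)` multiplicative
#' noise. Yield is never generated directly; it is always derived as
#' titer / dry cell mass. Values are truncated at a small positive floor.
#'
#' The defaults emulate the observed behaviour of the lycopene strain:
#' baselines of 8 g/L dry cell mass and 8.5 mg/L titer with coefficient
#' sets spanning roughly 4-12 g/L and 1-16 mg/L over the screening
#' design, the largest coefficients on the container factors and glycerol,
#' a well-volume x shake-speed interaction as the largest single
#' interaction, within-day noise CVs of 3.5% (dry cell mass) and 7.2%
#' (titer), and day/month effect SDs sized so centerpoint replicates show
#' pooled two-month CVs near 4.9% / 11.4% with a few percent of variance
#' attributable to month.
#'
#' @param baseline Named baseline means: `dry_cell_mass` (g/L), `titer`
#'   (mg/L).
#' @param main_effects Named list (per response) of named coded
#'   half-difference coefficients; factors absent from the vector have
#'   coefficient 0.
#' @param interactions Named list (per response) of named interaction
#'   coefficients, names like `"well_volume:shake_speed"`.
#' @param noise_cv Named within-day multiplicative noise CVs (fractions).
#' @param day_sd Named SDs of the additive day random effect (response
#'   units).
#' @param month_sd Named SDs of the additive month random effect.
#' @param floor Positive lower truncation bound for generated responses.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(
    baseline = c(dry_cell_mass = 8, titer = 8.5),
    main_effects = default_main_effects(),
    interactions = default_interactions(),
    noise_cv = c(dry_cell_mass = 0.035, titer = 0.072),
    day_sd = c(dry_cell_mass = 0.27, titer = 0.72),
    month_sd = c(dry_cell_mass = 0.06, titer = 0.21),
    floor = 0.1) {
  stopifnot(all(noise_cv >= 0), all(day_sd >= 0), all(month_sd >= 0),
            floor > 0, all(baseline > 0))
  structure(list(baseline = baseline, main_effects = main_effects,
                 interactions = interactions, noise_cv = noise_cv,
                 day_sd = day_sd, month_sd = month_sd, floor = floor),
            class = "simulation_config")
}

#' @rdname simulation_config
#' @export
default_main_effects <- function() {
  list(
    dry_cell_mass = c(
      yeast_extract = 0.5, glycerol = 0.8, tryptone = 0.3,
      magnesium_sulfate = 0.2, yeast_extract_source = 0.25,
      ph = 0.2, buffer_capacity = 0.15, osmolality = -0.3,
      well_volume = 0.6, well_fill_volume = -0.7, well_cover = 0.4,
      well_bottom = 0.2, shake_speed = 0.9,
      flask_volume = 0.3, flask_fill_volume = -0.4, flask_cover = 0.3,
      flask_baffles = 0.3,
      growth_time = 0.3, temperature = 0.2, inoculum_amount = 0.2,
      inoculum_age = 0.15, antibiotic_concentration = 0.1),
    titer = c(
      yeast_extract = 0.5, glycerol = 1.0, tryptone = 0.3,
      magnesium_sulfate = 0.3, yeast_extract_source = 0.3,
      ph = 0.3, buffer_capacity = 0.2, osmolality = -0.4,
      well_volume = 1.0, well_fill_volume = -1.2, well_cover = 0.5,
      well_bottom = 0.3, shake_speed = 1.6,
      flask_volume = 0.5, flask_fill_volume = -0.5, flask_cover = 0.4,
      flask_baffles = 0.4,
      growth_time = 0.4, temperature = 0.3, inoculum_amount = 0.2,
      inoculum_age = 0.2, antibiotic_concentration = 0.15))
}

#' @rdname simulation_config
#' @export
default_interactions <- function() {
  list(
    dry_cell_mass = c("well_volume:shake_speed" = 0.3,
                      "magnesium_sulfate:yeast_extract_source" = -0.2),
    titer = c("well_volume:shake_speed" = 0.8,
              "magnesium_sulfate:yeast_extract_source" = -0.3,
              "well_fill_volume:shake_speed" = -0.4))
}

#' Simulate responses for a design
#'
#' Applies the generating model in [simulation_config()] to every run of a
#' design: coded main effects and interactions, day/month random effects
#' for runs carrying day/month labels, multiplicative noise, floor
#' truncation, yield derived as titer / dry cell mass. Deterministic for
#' a given seed.
#'
#' @param design A `design_table`; `NA` coded cells (inapplicable factors)
#'   contribute 0.
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @return A `response_table` with one row per design run.
#' @export
simulate_responses <- function(design, config = simulation_config(),
                               seed = 1L) {
  stopifnot(inherits(design, "design_table"),
            inherits(config, "simulation_config"))
  facs <- design_factors(design)
  X <- as.matrix(as.data.frame(design)[facs])
  X[is.na(X)] <- 0
  priced <- unique(unlist(lapply(config$main_effects, names)))
  unpriced <- setdiff(facs, priced)
  if (length(unpriced)) {
    warning("design factor(s) not priced in the config (coefficient 0): ",
            paste(unpriced, collapse = ", "), call. = FALSE)
  }
  n <- nrow(design)
  out <- data.frame(run_id = design$run_id, stringsAsFactors = FALSE)
  with_seed(seed, {
    days <- unique(stats::na.omit(design$day))
    months <- unique(stats::na.omit(design$month))
    for (rsp in names(config$baseline)) {
      beta <- config$main_effects[[rsp]]
      beta <- beta[names(beta) %in% facs]
      mu <- rep(config$baseline[[rsp]], n)
      if (length(beta)) {
        mu <- mu + drop(X[, names(beta), drop = FALSE] %*% beta)
      }
      for (term in names(config$interactions[[rsp]] %||% numeric(0))) {
        pr <- strsplit(term, ":", fixed = TRUE)[[1]]
        if (!all(pr %in% facs)) next
        mu <- mu + config$interactions[[rsp]][[term]] * X[, pr[1]] * X[, pr[2]]
      }
      if (length(days)) {
        day_eff <- stats::setNames(
          stats::rnorm(length(days), 0, config$day_sd[[rsp]]), days)
        has_day <- !is.na(design$day)
        mu[has_day] <- mu[has_day] + day_eff[as.character(design$day[has_day])]
      }
      if (length(months)) {
        month_eff <- stats::setNames(
          stats::rnorm(length(months), 0, config$month_sd[[rsp]]), months)
        has_m <- !is.na(design$month)
        mu[has_m] <- mu[has_m] + month_eff[design$month[has_m]]
      }
      y <- mu * (1 + stats::rnorm(n, 0, config$noise_cv[[rsp]]))
      out[[rsp]] <- pmax(y, config$floor)
    }
  })
  out$yield <- out$titer / out$dry_cell_mass
  response_table(out)
}

#' Simulate the centerpoint replicate group
#'
#' Generates centerpoint-level responses with day and month random effects
#' for the time-reproducibility analysis: `n_reps` replicates on each of
#' `n_days` days split between two months (default 7 + 5 days, 48 runs).
#'
#' @param config A [simulation_config()].
#' @param n_days,n_reps,month_split Replicate structure; see
#'   [build_group3()].
#' @param seed Integer seed.
#' @param catalogue Factor catalogue used to build the underlying design.
#' @return Data frame with `run_id`, `day`, `month`, `replicate` and the
#'   three response columns; convert with [as_replicate_set()] for the
#'   repeatability/reproducibility statistics.
#' @export
simulate_group3 <- function(config = simulation_config(), n_days = 12L,
                            n_reps = 4L, month_split = c(7L, 5L), seed = 1L,
                            catalogue = lycopene_factor_catalogue()) {
  design <- build_group3(catalogue, n_reps = n_reps, n_days = n_days,
                         month_split = month_split)
  resp <- simulate_responses(design, config, seed = seed)
  cbind(as.data.frame(design)[c("run_id", "day", "month", "replicate")],
        as.data.frame(resp)[c("dry_cell_mass", "titer", "yield")])
}

#' Simulate raw plate measurements from responses
#'
#' Inverts the assay chain: sets A700 and the two lycopene absorbances so
#' that applying the calibration curves and dilution factor recovers the
#' responses exactly in the noise-free case; optional additive Gaussian
#' signal noise emulates reader error.
#'
#' @param responses A `response_table`.
#' @param curve475,curve507,od_curve Calibration curves (as used by
#'   [assemble_responses()]).
#' @param dilution_factor Dilution factor applied to all runs.
#' @param signal_sd Additive SD of reader noise on each absorbance signal.
#' @param seed Integer seed (used only when `signal_sd > 0`).
#' @return A [plate_measurements()] table.
#' @export
simulate_raw_plate <- function(responses, curve475, curve507, od_curve,
                               dilution_factor = 25, signal_sd = 0,
                               seed = 1L) {
  stopifnot(inherits(responses, "response_table"))
  a475 <- responses$titer / (curve475$slope * dilution_factor)
  a507 <- responses$titer / (curve507$slope * dilution_factor)
  a700 <- responses$dry_cell_mass / (od_curve$slope * dilution_factor)
  if (signal_sd > 0) {
    n <- length(a475)
    with_seed(seed, {
      a475 <- a475 + stats::rnorm(n, 0, signal_sd)
      a507 <- a507 + stats::rnorm(n, 0, signal_sd)
      a700 <- a700 + stats::rnorm(n, 0, signal_sd)
    })
  }
  plate_measurements(responses$run_id, a475 = a475, a507 = a507,
                     a600 = 0, a700 = a700,
                     dilution_factor = dilution_factor)
}
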