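#' Default three-group screening campaign plan
#'
#' The 256-run campaign layout: Group 1 screens factor effects and
#' within-category interactions in 112 runs split over four experiments by
#' factor category (media `2^(8-3)`, microwell containers `2^5`, shake
#' flasks `2^4`, other factors `2^5`); Group 2 re-screens the factors in
#' 96 runs split by observed effect size (nine large-effect factors
#' `2^(9-3)`, eight small-effect factors `2^(8-3)`); Group 3 replicates the
#' centerpoint condition 4 times on each of 12 days, 7 days in the first
#' month and 5 in the fourth (48 runs).
#'
#' The large/small split assigns the container factors, glycerol and the
#' remaining media-component factors with category-level interactions
#' (magnesium sulfate, yeast extract source) plus osmolality to the
#' large-effect experiment; level sets are stated explicitly per experiment
#' rather than inherited implicitly.
#'
#' @param randomize_runs Randomize run order within each experiment when the
#'   campaign is built with a seed?
#' @return A list describing groups and experiments, consumed by
#'   [build_campaign()].
#' @export
default_campaign_plan <- function(randomize_runs = TRUE) {
  list(
    randomize_runs = randomize_runs,
    group1 = list(
      media = list(
        factors = c("yeast_extract", "glycerol", "tryptone",
                    "magnesium_sulfate", "yeast_extract_source",
                    "ph", "buffer_capacity", "osmolality"),
        p = 3L),
      microwell = list(
        factors = c("well_volume", "well_fill_volume", "well_cover",
                    "well_bottom", "shake_speed"),
        p = 0L,
        na_factors = c("flask_volume", "flask_fill_volume",
                       "flask_cover", "flask_baffles")),
      flask = list(
        factors = c("flask_volume", "flask_fill_volume", "flask_cover",
                    "flask_baffles"),
        p = 0L,
        na_factors = c("well_volume", "well_fill_volume", "well_cover",
                       "well_bottom")),
      other = list(
        factors = c("growth_time", "temperature", "inoculum_amount",
                    "inoculum_age", "antibiotic_concentration"),
        p = 0L,
        na_factors = c("flask_volume", "flask_fill_volume",
                       "flask_cover", "flask_baffles"))
    ),
    group2 = list(
      large = list(
        factors = c("glycerol", "magnesium_sulfate", "yeast_extract_source",
                    "osmolality", "well_volume", "well_fill_volume",
                    "well_cover", "well_bottom", "shake_speed"),
        p = 3L,
        na_factors = c("flask_volume", "flask_fill_volume",
                       "flask_cover", "flask_baffles")),
      small = list(
        factors = c("yeast_extract", "tryptone", "ph", "buffer_capacity",
                    "growth_time", "temperature", "inoculum_amount",
                    "antibiotic_concentration"),
        p = 3L,
        na_factors = c("flask_volume", "flask_fill_volume",
                       "flask_cover", "flask_baffles"))
    ),
    group3 = list(n_reps = 4L, n_days = 12L, month_split = c(7L, 5L))
  )
}

#' Read / write a campaign plan as YAML
#'
#' @param path File path.
#' @return `read_campaign_plan()` returns a plan list; `write_campaign_plan()`
#'   returns `path` invisibly.
#' @export
read_campaign_plan <- function(path) {
  plan <- yaml::read_yaml(path)
  for (g in c("group1", "group2")) {
    plan[[g]] <- lapply(plan[[g]], function(e) {
      e$p <- as.integer(e$p %||% 0L)
      e
    })
  }
  plan$group3$n_reps <- as.integer(plan$group3$n_reps)
  plan$group3$n_days <- as.integer(plan$group3$n_days)
  plan$group3$month_split <- as.integer(plan$group3$month_split)
  plan
}

#' @rdname read_campaign_plan
#' @param plan A campaign plan list.
#' @export
write_campaign_plan <- function(plan, path) {
  yaml::write_yaml(plan, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Centerpoint replicate design (time-reproducibility group)
#'
#' Builds the all-centerpoint design: `n_reps` replicate runs on each of
#' `n_days` days, the days split between a first and a fourth month. All
#' factors sit at coded level 0; natural levels come from the factor center
#' levels and the centerpoint policy. Factors named in `na_factors`
#' (defaults to the shake-flask factors, inapplicable to plate-based
#' centerpoint runs) decode to `NA`.
#'
#' @param catalogue Named list of [factor_spec()] objects.
#' @param n_reps Replicates per day.
#' @param n_days Number of days.
#' @param month_split Integer vector: days in the first and fourth month.
#' @param policy Centerpoint policy, see [centerpoint_policy()].
#' @param na_factors Factors left unset (decode to `NA`).
#' @return A `design_table` of `n_reps * n_days` centerpoint runs with
#'   `day`, `month` and `replicate` filled in.
#' @export
build_group3 <- function(catalogue = lycopene_factor_catalogue(),
                         n_reps = 4L, n_days = 12L, month_split = c(7L, 5L),
                         policy = centerpoint_policy(),
                         na_factors = c("flask_volume", "flask_fill_volume",
                                        "flask_cover", "flask_baffles")) {
  stopifnot(n_days >= 2L, n_reps >= 1L, sum(month_split) == n_days)
  catalogue <- as_factor_list(catalogue)
  n <- n_reps * n_days
  day <- rep(seq_len(n_days), each = n_reps)
  month <- ifelse(day <= month_split[1], "month1", "month4")
  df <- data.frame(
    run_id = sprintf("G3-d%02d-r%d", day, rep(seq_len(n_reps), n_days)),
    group = "group3",
    experiment = "centerpoint",
    run_order = seq_len(n),
    replicate = rep(seq_len(n_reps), n_days),
    day = day,
    month = month,
    centerpoint = TRUE,
    stringsAsFactors = FALSE)
  codes <- as.data.frame(matrix(0L, n, length(catalogue)))
  names(codes) <- names(catalogue)
  df <- cbind(df, codes)
  policy <- policy[setdiff(names(policy), na_factors)]
  new_design_table(df, catalogue, center_policy = policy)
}

#' Build the full screening campaign
#'
#' Assembles the three-group design table from a factor catalogue and a
#' campaign plan: each Group 1/2 experiment is a full or fractional
#' factorial over its own factors (other factors held at the centerpoint
#' reference, coded 0), and Group 3 is the centerpoint replicate block.
#' With the default plan and catalogue this reconstructs the 256-run
#' campaign (112 + 96 + 48).
#'
#' @param catalogue Named list of [factor_spec()] objects.
#' @param plan Campaign plan, see [default_campaign_plan()].
#' @param seed Optional integer seed; when given and the plan enables
#'   randomization, run order is randomized independently within each
#'   experiment.
#' @param groups Which groups to build (subset of `"group1"`, `"group2"`,
#'   `"group3"`).
#' @return A `design_table` with group and experiment labels; the alias
#'   structures and generator words of the fractional experiments are kept
#'   in the `experiments` attribute.
#' @examples
#' camp <- build_campaign(seed = 1)
#' table(camp$group)
#' @export
build_campaign <- function(catalogue = lycopene_factor_catalogue(),
                           plan = default_campaign_plan(), seed = NULL,
                           groups = c("group1", "group2", "group3")) {
  catalogue <- as_factor_list(catalogue)
  groups <- match.arg(groups, several.ok = TRUE)
  pieces <- list()
  exp_meta <- list()
  seed_i <- 0L

  for (grp in intersect(c("group1", "group2"), groups)) {
    for (exp_name in names(plan[[grp]])) {
      exp <- plan[[grp]][[exp_name]]
      missing <- setdiff(exp$factors, names(catalogue))
      if (length(missing)) {
        stop("plan experiment '", exp_name, "' names factors absent from ",
             "the catalogue: ", paste(missing, collapse = ", "),
             call. = FALSE)
      }
      facs <- catalogue[exp$factors]
      if ((exp$p %||% 0L) > 0L) {
        ff <- fractional_factorial(facs, p = exp$p,
                                   generators = exp$generators,
                                   experiment = exp_name)
        d <- ff$design
        exp_meta[[exp_name]] <- list(alias = ff$alias,
                                     generators = ff$alias$generators)
      } else {
        d <- full_factorial(facs, experiment = exp_name)
        exp_meta[[exp_name]] <- list(alias = NULL, generators = character(0))
      }
      if (!is.null(seed) && isTRUE(plan$randomize_runs)) {
        seed_i <- seed_i + 1L
        d <- randomize(d, seed = seed + seed_i)
      }
      d$group <- grp
      d$run_id <- sprintf("%s-%s-%02d", toupper(sub("group", "G", grp)),
                          exp_name, seq_len(nrow(d)))
      # held factors: coded 0 (centerpoint reference); inapplicable: NA
      held <- setdiff(names(catalogue), exp$factors)
      dd <- as.data.frame(d)
      for (fn in held) dd[[fn]] <- 0L
      for (fn in intersect(exp$na_factors %||% character(0), held)) {
        dd[[fn]] <- NA_integer_
      }
      pieces[[exp_name]] <- dd[c(design_meta_cols, names(catalogue))]
    }
  }

  if ("group3" %in% groups) {
    g3 <- plan$group3
    d3 <- build_group3(catalogue, n_reps = g3$n_reps, n_days = g3$n_days,
                       month_split = g3$month_split)
    pieces[["centerpoint"]] <- as.data.frame(d3)[c(design_meta_cols,
                                                   names(catalogue))]
  }

  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  design <- new_design_table(out, catalogue,
                             center_policy = centerpoint_policy())
  attr(design, "experiments") <- exp_meta
  design
}

#' Extract one experiment from a campaign design
#'
#' Returns the rows of a single experiment with only its varied factors as
#' factor columns, so the single-experiment effect machinery (balance,
#' orthogonality, REM) applies directly. The experiment's alias structure,
#' if fractional, is re-attached.
#'
#' @param campaign A campaign `design_table` from [build_campaign()].
#' @param experiment Experiment label.
#' @return A `design_table`.
#' @export
campaign_experiment <- function(campaign, experiment) {
  stopifnot(experiment %in% campaign$experiment)
  rows <- campaign$experiment == experiment
  df <- as.data.frame(campaign)[rows, , drop = FALSE]
  factors <- attr(campaign, "factors")
  varied <- vapply(design_factors(campaign), function(fn) {
    all(c(-1L, 1L) %in% df[[fn]])
  }, logical(1))
  keep <- design_factors(campaign)[varied]
  df <- df[c(design_meta_cols, keep)]
  rownames(df) <- NULL
  meta <- attr(campaign, "experiments")[[experiment]]
  new_design_table(df, factors[keep], alias = meta$alias,
                   center_policy = attr(campaign, "center_policy"))
}
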