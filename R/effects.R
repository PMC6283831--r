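join_design_responses <- function(design, responses, response,
                                  exclude_center = TRUE) {
  stopifnot(inherits(design, "design_table"),
            response %in% names(responses))
  df <- merge(as.data.frame(design), as.data.frame(responses), by = "run_id")
  if (exclude_center) df <- df[!df$centerpoint, , drop = FALSE]
  df <- df[!is.na(df[[response]]), , drop = FALSE]
  df
}

#' Relative effect magnitude of a main effect
#'
#' The relative effect magnitude (REM) of a factor is the absolute value
#' of the difference between the mean response at its high and low levels,
#' divided by the overall mean response of the experiment:
#' `REM = |mean(Y[+]) - mean(Y[-])| / mean(Y)`. Centerpoint runs are
#' excluded throughout (the statistic is a two-level contrast). REM is
#' dimensionless and invariant to positive rescaling of the response.
#'
#' @param design A single-experiment `design_table`.
#' @param responses A `response_table` (or any data frame with `run_id` and
#'   the response column).
#' @param factor_name Name of the factor column.
#' @param response Response column name.
#' @return One-row data frame (class `effect_table`): `response`,
#'   `factor1`, `factor2` (`NA` for a main effect), `signed_effect` (the
#'   mean difference in response units), `rem`, `denominator` (the overall
#'   mean), `n_runs`.
#' @export
rem_main <- function(design, responses, factor_name, response) {
  df <- join_design_responses(design, responses, response)
  x <- df[[factor_name]]
  y <- df[[response]]
  if (!all(c(-1, 1) %in% x)) {
    stop("factor '", factor_name, "' does not have both levels present",
         call. = FALSE)
  }
  ybar <- mean(y)
  if (abs(ybar) < .Machine$double.eps) {
    stop("overall mean response is zero; REM undefined", call. = FALSE)
  }
  signed <- mean(y[x == 1]) - mean(y[x == -1])
  effect_row(response, factor_name, NA_character_, signed,
             abs(signed / ybar), ybar, length(y))
}

#' Relative effect magnitude of a two-factor interaction
#'
#' The interaction REM is the absolute cell-means contrast
#' `|mean(Y[++]) + mean(Y[--]) - mean(Y[+-]) - mean(Y[-+])|` divided by
#' the overall mean response. The contrast is used exactly in this form
#' (no division by 2), so it is twice the classical half-difference
#' interaction effect; it is symmetric in the two factors and zero for
#' purely additive responses.
#'
#' @inheritParams rem_main
#' @param factor_i,factor_j The two factor column names.
#' @return One-row `effect_table` data frame.
#' @export
rem_interaction <- function(design, responses, factor_i, factor_j, response) {
  df <- join_design_responses(design, responses, response)
  xi <- df[[factor_i]]
  xj <- df[[factor_j]]
  y <- df[[response]]
  cells <- list(pp = y[xi == 1 & xj == 1],   mm = y[xi == -1 & xj == -1],
                pm = y[xi == 1 & xj == -1],  mp = y[xi == -1 & xj == 1])
  if (any(lengths(cells) == 0L)) {
    stop("empty cell for interaction ", factor_i, ":", factor_j,
         call. = FALSE)
  }
  ybar <- mean(y)
  if (abs(ybar) < .Machine$double.eps) {
    stop("overall mean response is zero; REM undefined", call. = FALSE)
  }
  signed <- mean(cells$pp) + mean(cells$mm) - mean(cells$pm) - mean(cells$mp)
  effect_row(response, factor_i, factor_j, signed,
             abs(signed / ybar), ybar, length(y))
}

effect_row <- function(response, f1, f2, signed, rem, denom, n) {
  structure(
    data.frame(response = response, factor1 = f1, factor2 = f2,
               signed_effect = signed, rem = rem, denominator = denom,
               n_runs = n, aliased_with = NA_character_,
               stringsAsFactors = FALSE),
    class = c("effect_table", "data.frame"))
}

#' All main-effect and interaction REMs of one experiment
#'
#' Computes the REM of every varied factor and (for `max_order = 2`) every
#' within-experiment factor pair on the requested responses. For
#' fractional designs, each interaction is annotated with the effects it
#' is aliased to (from the design's alias structure), since confounded
#' contrasts are numerically identical.
#'
#' @param design A single-experiment `design_table`.
#' @param responses A `response_table`.
#' @param response Response column names (default: all present).
#' @param max_order 1 for main effects only, 2 to include pairs.
#' @return An `effect_table` data frame, one row per (response, effect).
#' @export
all_effects <- function(design, responses,
                        response = response_names(responses),
                        max_order = 2L) {
  stopifnot(max_order %in% 1:2)
  facs <- design_factors(design)
  alias <- attr(design, "alias")
  rows <- list()
  for (rsp in response) {
    for (fn in facs) {
      rows[[length(rows) + 1L]] <- rem_main(design, responses, fn, rsp)
    }
    if (max_order == 2L && length(facs) >= 2L) {
      pairs <- utils::combn(facs, 2L, simplify = FALSE)
      for (pr in pairs) {
        r <- rem_interaction(design, responses, pr[1], pr[2], rsp)
        r$aliased_with <- alias_label(alias, facs, pr)
        rows[[length(rows) + 1L]] <- r
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("effect_table", "data.frame"))
}

# translate the alias partners of a factor pair into factor-name labels
alias_label <- function(alias, factor_names, pair) {
  if (is.null(alias)) return(NA_character_)
  letter_of <- stats::setNames(alias$letters, factor_names)
  name_of <- stats::setNames(factor_names, alias$letters)
  key <- word_string(sort(letter_of[pair]))
  partners <- setdiff(alias$alias_groups[[key]], key)
  if (length(partners) == 0L) return(NA_character_)
  labels <- vapply(partners, function(w) {
    paste(name_of[parse_word(w)], collapse = ":")
  }, character(1))
  paste(labels, collapse = "; ")
}

#' Normal and half-normal probability plot coordinates for effects
#'
#' Effect screening: ordered effects are paired with standard-normal
#' quantiles at the Blom plotting positions `(i - 0.375) / (n + 0.25)`.
#' Null effects fall on a line through the origin; real effects stand off
#' it as extreme points. The half-normal variant orders absolute effects
#' against upper-half-normal quantiles.
#'
#' @param effects An `effect_table` (its `signed_effect` column is used)
#'   or a numeric vector of effects; at least 3.
#' @param half Use the half-normal variant on absolute effects?
#' @return Data frame with `quantile`, `effect` and `label`, sorted
#'   ascending; ties in the sort are broken by label for determinism.
#' @export
normal_plot_coords <- function(effects, half = FALSE) {
  if (inherits(effects, "effect_table")) {
    labels <- ifelse(is.na(effects$factor2), effects$factor1,
                     paste(effects$factor1, effects$factor2, sep = ":"))
    eff <- effects$signed_effect
  } else {
    eff <- as.numeric(effects)
    labels <- if (!is.null(names(effects))) names(effects) else
      paste0("effect", seq_along(eff))
  }
  n <- length(eff)
  if (n < 3L) stop("need at least 3 effects", call. = FALSE)
  if (half) eff <- abs(eff)
  ord <- order(eff, labels)
  p <- (seq_len(n) - 0.375) / (n + 0.25)
  q <- if (half) stats::qnorm((1 + p) / 2) else stats::qnorm(p)
  data.frame(quantile = q, effect = eff[ord], label = labels[ord],
             stringsAsFactors = FALSE)
}

#' Min-max normalize responses to the unit interval
#'
#' Each response column is mapped to `(y - min) / (max - min)` over all
#' runs, so the smallest observed value is exactly 0 and the largest
#' exactly 1. The transform is monotone; order is preserved.
#'
#' @param responses A `response_table`.
#' @param response Columns to normalize (default all responses present).
#' @return The table with normalized response columns.
#' @export
normalize_responses <- function(responses,
                                response = response_names(responses)) {
  out <- responses
  for (rsp in response) {
    y <- out[[rsp]]
    rng <- range(y, na.rm = TRUE)
    if (diff(rng) == 0) {
      stop("response '", rsp, "' is constant; cannot normalize",
           call. = FALSE)
    }
    out[[rsp]] <- (y - rng[1]) / diff(rng)
  }
  out
}

#' Fit a linear screening model on coded factor levels
#'
#' Least-squares fit of a response on the coded (-1/+1) main-effect
#' columns, optionally with selected two-factor interaction terms. On an
#' orthogonal design the fitted coefficient of a factor is exactly half
#' its mean-difference effect, so `REM = |2 * beta| / mean(Y)` — the
#' cross-check used throughout the test suite. Used to train on one group
#' of experiments and predict another (reproducibility under changed
#' conditions of use).
#'
#' @param design A `design_table` (training runs).
#' @param responses A `response_table` for the training runs.
#' @param response Response column name.
#' @param factors Factor columns to include (default: all varied factors).
#' @param interactions Optional character vector of `"f1:f2"` interaction
#'   terms.
#' @param include_center Include centerpoint rows in the fit (coded 0)?
#' @return A `response_model`: list with the `lm` fit, term names and
#'   `train_r2`.
#' @export
fit_response_model <- function(design, responses, response,
                               factors = NULL, interactions = NULL,
                               include_center = FALSE) {
  df <- join_design_responses(design, responses, response,
                              exclude_center = !include_center)
  if (is.null(factors)) {
    factors <- Filter(function(fn) length(unique(df[[fn]])) > 1L,
                      design_factors(design))
  }
  X <- model_frame(df, factors, interactions)
  X$.y <- df[[response]]
  fit <- stats::lm(.y ~ ., data = X)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("rank-deficient model; aliased terms: ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  }
  train_r2 <- model_r2(df[[response]], stats::fitted(fit))
  structure(list(fit = fit, response = response, factors = factors,
                 interactions = interactions, train_r2 = train_r2),
            class = "response_model")
}

model_frame <- function(df, factors, interactions) {
  X <- df[factors]
  X[is.na(X)] <- 0   # inapplicable factors sit at the held reference
  for (term in interactions %||% character(0)) {
    pr <- strsplit(term, ":", fixed = TRUE)[[1]]
    stopifnot(length(pr) == 2L, all(pr %in% names(df)))
    X[[paste(pr, collapse = ".x.")]] <- X[[pr[1]]] * X[[pr[2]]]
  }
  X
}

#' @export
print.response_model <- function(x, ...) {
  cat(sprintf("<response_model> %s ~ %d main effect(s)%s, train r2 = %.3f\n",
              x$response, length(x$factors),
              if (length(x$interactions %||% character(0))) {
                paste0(" + ", length(x$interactions), " interaction(s)")
              } else "",
              x$train_r2))
  invisible(x)
}

#' Predict responses for a design from a fitted screening model
#'
#' @param object A `response_model`.
#' @param design A `design_table` with the model's factor columns.
#' @param ... Unused.
#' @return Numeric vector of predictions, named by `run_id`.
#' @export
predict.response_model <- function(object, design, ...) {
  df <- as.data.frame(design)
  X <- model_frame(df, object$factors, object$interactions)
  stats::setNames(stats::predict(object$fit, newdata = X), df$run_id)
}

#' Coefficient of determination
#'
#' Default is the variance-explained form `1 - SS_res / SS_tot` with
#' `SS_tot` taken about the mean of the observed values — on a test set
#' this penalizes both spread and bias of the predictions and can be
#' negative. `method = "cor"` gives the squared Pearson correlation
#' alternative.
#'
#' @param observed,predicted Numeric vectors.
#' @param method `"vexplained"` (default) or `"cor"`.
#' @return The r-squared value.
#' @export
model_r2 <- function(observed, predicted,
                     method = c("vexplained", "cor")) {
  method <- match.arg(method)
  keep <- !is.na(observed) & !is.na(predicted)
  observed <- observed[keep]; predicted <- predicted[keep]
  if (method == "cor") return(stats::cor(observed, predicted)^2)
  1 - sum((observed - predicted)^2) / sum((observed - mean(observed))^2)
}

#' Score a fitted model on held-out runs
#'
#' @param object A `response_model`.
#' @param design Test `design_table`.
#' @param responses Test `response_table`.
#' @param method Passed to [model_r2()].
#' @return Test-set r-squared.
#' @export
score_response_model <- function(object, design, responses,
                                 method = c("vexplained", "cor")) {
  df <- join_design_responses(design, responses, object$response,
                              exclude_center = TRUE)
  pred <- predict(object, new_design_table(df, attr(design, "factors")))
  model_r2(df[[object$response]], pred, method = method)
}
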