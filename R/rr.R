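#' Centerpoint replicate observations
#'
#' Container for repeatability/reproducibility analysis: one response
#' measured on replicate runs nested in days, days nested in months.
#'
#' @param value Numeric response values.
#' @param day Day index or label for each observation.
#' @param month Month label for each observation (optional for
#'   repeatability-only use).
#' @param replicate Replicate index within day (optional, informational).
#' @param response Response name carried as an attribute.
#' @return A `replicate_set` data frame.
#' @export
replicate_set <- function(value, day, month = NULL, replicate = NULL,
                          response = "response") {
  n <- length(value)
  stopifnot(is.numeric(value), length(day) == n)
  df <- data.frame(value = value, day = as.character(day),
                   month = if (is.null(month)) NA_character_ else
                     as.character(rep_len(month, n)),
                   replicate = if (is.null(replicate)) NA_integer_ else
                     as.integer(rep_len(replicate, n)),
                   stringsAsFactors = FALSE)
  structure(df, response = response,
            class = c("replicate_set", "data.frame"))
}

#' Convert simulated (or measured) centerpoint data to a replicate set
#'
#' @param x Data frame with `day`, `month`, `replicate` and response
#'   columns (e.g. from [simulate_group3()]).
#' @param response Which response column to extract.
#' @return A [replicate_set()].
#' @export
as_replicate_set <- function(x, response) {
  stopifnot(response %in% names(x))
  replicate_set(x[[response]], day = x$day, month = x$month,
                replicate = x$replicate, response = response)
}

day_split <- function(set, min_reps = 2L, warn = TRUE) {
  groups <- split(set$value, set$day)
  small <- lengths(groups) < min_reps
  if (any(small) && warn) {
    warning("excluding day(s) with fewer than ", min_reps, " replicates: ",
            paste(names(groups)[small], collapse = ", "), call. = FALSE)
  }
  groups[!small]
}

#' Repeatability coefficient of variation
#'
#' Within-day dispersion under unchanged conditions: the sample standard
#' deviation of each day's replicates divided by that day's mean, averaged
#' over days and expressed in percent. Days with fewer than 2 replicates
#' are excluded with a warning.
#'
#' @param set A [replicate_set()].
#' @return Mean within-day relative SD, percent.
#' @export
repeatability_cv <- function(set) {
  groups <- day_split(set)
  if (length(groups) == 0L) {
    stop("no day has 2 or more replicates", call. = FALSE)
  }
  day_cv <- vapply(groups, function(v) stats::sd(v) / mean(v), numeric(1))
  mean(day_cv) * 100
}

#' Reproducibility coefficient of variation
#'
#' Dispersion under changed conditions (here: time, in months). The
#' default pools all observations across the months and reports their SD
#' over the grand mean (`method = "pooled"`); the gauge-style alternative
#' (`method = "components"`) reports only the between-month variance
#' component `max(0, (MS_between - MS_within) / n0)` from one-way ANOVA,
#' again relative to the grand mean. Both are percentages.
#'
#' @param set A [replicate_set()] with at least 2 month labels.
#' @param method `"pooled"` (default) or `"components"`.
#' @return Reproducibility CV, percent.
#' @export
reproducibility_cv <- function(set, method = c("pooled", "components")) {
  method <- match.arg(method)
  if (length(unique(set$month[!is.na(set$month)])) < 2L) {
    stop("reproducibility requires at least 2 month labels", call. = FALSE)
  }
  y <- set$value
  if (method == "pooled") return(stats::sd(y) / mean(y) * 100)
  g <- factor(set$month)
  fit <- stats::aov(y ~ g)
  ms <- summary(fit)[[1]][["Mean Sq"]]
  n_j <- tabulate(g)
  n0 <- (sum(n_j) - sum(n_j^2) / sum(n_j)) / (nlevels(g) - 1)
  sigma2_b <- max(0, (ms[1] - ms[2]) / n0)
  sqrt(sigma2_b) / mean(y) * 100
}

# Brown-Forsythe statistic: one-way ANOVA F on absolute deviations from
# group medians. Returns a closure bound to a fixed grouping for speed in
# permutation loops.
bf_statistic_factory <- function(g) {
  g <- as.factor(g)
  k <- nlevels(g)
  idx <- split(seq_along(g), g)
  n_j <- lengths(idx)
  N <- length(g)
  if (k < 2L || any(n_j < 2L)) {
    stop("variance homogeneity needs >= 2 groups with >= 2 values each",
         call. = FALSE)
  }
  function(y) {
    dbj <- numeric(k); ssw <- 0; total <- 0
    for (j in seq_len(k)) {
      yj <- y[idx[[j]]]
      dj <- abs(yj - stats::median.default(yj))
      m <- mean.default(dj)
      dbj[j] <- m
      ssw <- ssw + sum((dj - m)^2)
      total <- total + sum(dj)
    }
    ssb <- sum(n_j * (dbj - total / N)^2)
    if (ssw == 0) {
      return(if (ssb == 0) 0 else Inf)
    }
    (ssb / (k - 1)) / (ssw / (N - k))
  }
}

#' Variance homogeneity across days (Brown-Forsythe)
#'
#' Tests whether within-day spread is the same on every day using the
#' Brown-Forsythe statistic: the one-way ANOVA F computed on absolute
#' deviations from each day's median, which is robust to non-normality.
#' The default p-value is a permutation null — observations are centred at
#' their day medians (removing day location effects) and reassigned to
#' days at random, recomputing the statistic each time — which keeps the
#' test calibrated at the small replicate counts typical of centerpoint
#' designs, where the classical F reference (`p_method = "F"`) is
#' anticonservative.
#'
#' @param set A [replicate_set()] with >= 2 days of >= 2 replicates.
#' @param p_method `"permutation"` (default) or `"F"`.
#' @param B Number of permutations.
#' @param seed Optional seed for the permutation null.
#' @return List with `statistic`, `p_value`, `df` (for the F reference)
#'   and `p_method`.
#' @export
variance_homogeneity <- function(set, p_method = c("permutation", "F"),
                                 B = 999L, seed = NULL) {
  p_method <- match.arg(p_method)
  groups <- day_split(set, warn = FALSE)
  if (length(groups) < 2L) {
    stop("need at least 2 days with 2 or more replicates", call. = FALSE)
  }
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)))
  bf <- bf_statistic_factory(g)
  stat <- bf(y)
  k <- nlevels(g)
  N <- length(y)
  if (p_method == "F") {
    p <- stats::pf(stat, k - 1, N - k, lower.tail = FALSE)
  } else {
    centred <- y - stats::ave(y, g, FUN = stats::median)
    t0 <- bf(centred)
    run <- function() {
      exceed <- 0L
      for (b in seq_len(B)) {
        if (bf(sample(centred)) >= t0) exceed <- exceed + 1L
      }
      (1 + exceed) / (B + 1)
    }
    p <- if (is.null(seed)) run() else with_seed(seed, run())
  }
  list(statistic = stat, p_value = p, df = c(k - 1, N - k),
       p_method = p_method)
}

#' Fraction of variance attributable to month
#'
#' One-way ANOVA of the response on month: the between-month sum of
#' squares over the total sum of squares (eta squared), in percent.
#' Scale-free; 0 for identical month distributions, 100 when months are
#' fully separated with no within-month variance.
#'
#' @param set A [replicate_set()] with >= 2 months.
#' @return Percent of total sum of squares, in `[0, 100]`.
#' @export
month_variance_fraction <- function(set) {
  g <- factor(set$month)
  if (nlevels(g) < 2L) stop("need at least 2 months", call. = FALSE)
  y <- set$value
  ss_total <- sum((y - mean(y))^2)
  if (ss_total == 0) stop("zero total sum of squares", call. = FALSE)
  fit <- stats::aov(y ~ g)
  ss <- summary(fit)[[1]][["Sum Sq"]]
  ss[1] / ss_total * 100
}

#' Full repeatability and reproducibility report
#'
#' Bundles the per-day summaries and the four centerpoint statistics:
#' repeatability CV, reproducibility CV (the pooled default is logged in
#' the report alongside the variance-component alternative), the
#' Brown-Forsythe homogeneity test, and the month variance fraction.
#'
#' @param set A [replicate_set()].
#' @param seed Seed for the permutation homogeneity test.
#' @return An `rr_report` list.
#' @export
rr_report <- function(set, seed = NULL) {
  groups <- day_split(set, warn = FALSE)
  per_day <- data.frame(
    day = names(groups),
    n = lengths(groups),
    mean = vapply(groups, mean, numeric(1)),
    sd = vapply(groups, stats::sd, numeric(1)),
    stringsAsFactors = FALSE)
  rownames(per_day) <- NULL
  has_months <- length(unique(set$month[!is.na(set$month)])) >= 2L
  structure(list(
    response = attr(set, "response"),
    per_day = per_day,
    repeatability_cv = repeatability_cv(set),
    reproducibility_cv = if (has_months) reproducibility_cv(set) else NA_real_,
    reproducibility_cv_components =
      if (has_months) reproducibility_cv(set, "components") else NA_real_,
    reproducibility_method = "pooled",
    homogeneity = variance_homogeneity(set, seed = seed),
    month_variance_fraction =
      if (has_months) month_variance_fraction(set) else NA_real_),
    class = "rr_report")
}

#' @export
print.rr_report <- function(x, ...) {
  cat("<rr_report>", x$response, "\n")
  cat(sprintf("  repeatability CV (mean within-day relative SD): %.2f%%\n",
              x$repeatability_cv))
  if (!is.na(x$reproducibility_cv)) {
    cat(sprintf("  reproducibility CV (pooled SD / grand mean): %.2f%%\n",
                x$reproducibility_cv))
    cat(sprintf("  reproducibility CV (between-month component): %.2f%%\n",
                x$reproducibility_cv_components))
    cat(sprintf("  month variance fraction (eta^2): %.2f%%\n",
                x$month_variance_fraction))
  }
  cat(sprintf("  variance homogeneity: BF = %.3f, p = %.3f (%s)\n",
              x$homogeneity$statistic, x$homogeneity$p_value,
              x$homogeneity$p_method))
  cat(sprintf("  %d day(s), %d observation(s)\n",
              nrow(x$per_day), sum(x$per_day$n)))
  invisible(x)
}
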