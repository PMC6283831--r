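two_month_set <- function(values_by_day, reps_per_day, month_split = NULL) {
  n_days <- length(values_by_day)
  if (is.null(month_split)) month_split <- c(ceiling(n_days / 2),
                                             floor(n_days / 2))
  day <- rep(seq_len(n_days), times = reps_per_day)
  month <- ifelse(day <= month_split[1], "m1", "m4")
  replicate_set(unlist(values_by_day), day = day, month = month,
                response = "dry_cell_mass")
}

test_that("repeatability CV averages per-day relative SDs", {
  # one day (90, 100, 110): SD 10 over mean 100 -> 10%; two such days -> 10%
  set1 <- two_month_set(list(c(90, 100, 110), c(90, 100, 110)), c(3, 3))
  expect_equal(repeatability_cv(set1), 10)
  # identical replicates -> 0%
  set0 <- two_month_set(list(c(5, 5, 5), c(7, 7, 7)), c(3, 3))
  expect_equal(repeatability_cv(set0), 0)
  # days with a single replicate are excluded with a warning
  set2 <- replicate_set(c(90, 100, 110, 42), day = c(1, 1, 1, 2))
  expect_warning(cv <- repeatability_cv(set2), "fewer than 2")
  expect_equal(cv, 10)
  singletons <- replicate_set(c(1, 2), day = c(1, 2))
  suppressWarnings(expect_error(repeatability_cv(singletons), "no day"))
})

test_that("reproducibility CV pools observations over the grand mean", {
  # month means 100 and 110, zero within-month noise, balanced
  set <- two_month_set(list(rep(100, 4), rep(110, 4)), c(4, 4), c(1, 1))
  y <- c(rep(100, 4), rep(110, 4))
  expect_equal(reproducibility_cv(set), sd(y) / mean(y) * 100)
  # identical months, zero noise -> 0
  set0 <- two_month_set(list(rep(8, 4), rep(8, 4)), c(4, 4), c(1, 1))
  expect_equal(reproducibility_cv(set0), 0)
  expect_error(reproducibility_cv(
    replicate_set(1:4, day = c(1, 1, 2, 2), month = "m1")), "2 month")
  # the between-month component alternative is reported relative to the mean
  expect_equal(reproducibility_cv(set, method = "components"),
               sqrt(max(0, (var(c(100, 110)) * 4 - 0) / 4)) / 105 * 100,
               tolerance = 0.05)
})

test_that("reproducibility dominates the repeatability contribution", {
  cfg <- simulation_config(noise_cv = c(dry_cell_mass = 0.035, titer = 0.072),
                           day_sd = c(dry_cell_mass = 0.3, titer = 0.7),
                           month_sd = c(dry_cell_mass = 0.1, titer = 0.2))
  worse <- 0L
  for (seed in 1:30) {
    g3 <- simulate_group3(cfg, seed = seed)
    set <- as_replicate_set(g3, "dry_cell_mass")
    worse <- worse + (reproducibility_cv(set) >= 0.8 * repeatability_cv(set))
  }
  # pooled dispersion includes the day/month components on top of noise
  expect_gte(worse, 29)
})

test_that("month variance fraction is eta squared from one-way ANOVA", {
  # hand ANOVA: months (1,2,3) and (2,3,4): SSB 1.5, SST 5.5
  set <- replicate_set(c(1, 2, 3, 2, 3, 4), day = c(1, 1, 1, 2, 2, 2),
                       month = c("m1", "m1", "m1", "m4", "m4", "m4"))
  expect_equal(month_variance_fraction(set), 1.5 / 5.5 * 100,
               tolerance = 1e-9)
  # identical month distributions -> 0%
  set0 <- replicate_set(c(1, 2, 1, 2), day = c(1, 1, 2, 2),
                        month = c("m1", "m1", "m4", "m4"))
  expect_equal(month_variance_fraction(set0), 0)
  # fully separated months with zero within-month variance -> 100%
  set1 <- replicate_set(c(5, 5, 9, 9), day = c(1, 1, 2, 2),
                        month = c("m1", "m1", "m4", "m4"))
  expect_equal(month_variance_fraction(set1), 100)
  # identity: eta2 = 1 - SSW/SST
  y <- c(1.2, 3.4, 2.2, 5.1, 4.0, 3.3)
  m <- c("m1", "m1", "m1", "m4", "m4", "m4")
  set2 <- replicate_set(y, day = c(1, 1, 2, 2, 3, 3), month = m)
  ssw <- sum(tapply(y, m, function(v) sum((v - mean(v))^2)))
  sst <- sum((y - mean(y))^2)
  expect_equal(month_variance_fraction(set2), (1 - ssw / sst) * 100)
})

test_that("rr statistics are invariant under positive rescaling", {
  g3 <- simulate_group3(seed = 5)
  set <- as_replicate_set(g3, "titer")
  scaled <- replicate_set(set$value * 37, set$day, set$month,
                          set$replicate, "titer")
  expect_equal(repeatability_cv(scaled), repeatability_cv(set))
  expect_equal(reproducibility_cv(scaled), reproducibility_cv(set))
  expect_equal(month_variance_fraction(scaled), month_variance_fraction(set))
  expect_equal(variance_homogeneity(scaled, p_method = "F")$statistic,
               variance_homogeneity(set, p_method = "F")$statistic)
})

test_that("the Brown-Forsythe statistic matches the classical oracle", {
  skip_if_not_installed("car")
  set.seed(31)
  for (i in 1:5) {
    y <- rnorm(48, 10, 1)
    day <- rep(1:12, each = 4)
    set <- replicate_set(y, day = day)
    got <- variance_homogeneity(set, p_method = "F")
    oracle <- car::leveneTest(y ~ factor(day), center = median)
    expect_equal(got$statistic, oracle[1, "F value"], tolerance = 1e-10)
    expect_equal(got$p_value, oracle[1, "Pr(>F)"], tolerance = 1e-10)
  }
})

test_that("degenerate homogeneity inputs behave as documented", {
  # two identical-valued days: statistic 0
  set <- replicate_set(c(3, 3, 3, 3), day = c(1, 1, 2, 2))
  expect_equal(variance_homogeneity(set, p_method = "F")$statistic, 0)
  expect_error(variance_homogeneity(replicate_set(1:3, day = c(1, 1, 2))),
               "2 days")
})

test_that("the homogeneity test flags a grossly inflated day", {
  # power oracle at 8 replicates/day, where a 10x spread inflation is
  # detectable at p < 0.01
  nrep <- 8
  day <- rep(1:12, each = nrep)
  hits_perm <- hits_f <- logical(60)
  set.seed(77)
  for (i in seq_along(hits_perm)) {
    y <- rnorm(12 * nrep, 10, 0.5)
    y[day == 1] <- 10 + (y[day == 1] - 10) * 10
    set <- replicate_set(y, day = day)
    hits_f[i] <- variance_homogeneity(set, p_method = "F")$p_value < 0.01
    hits_perm[i] <- variance_homogeneity(set, B = 499L,
                                         seed = i)$p_value < 0.01
  }
  expect_gte(mean(hits_f), 0.95)
  expect_gte(mean(hits_perm), 0.95)
})

test_that("rr_report bundles all centerpoint statistics coherently", {
  g3 <- simulate_group3(seed = 11)
  set <- as_replicate_set(g3, "dry_cell_mass")
  rep <- rr_report(set, seed = 4)
  expect_equal(nrow(rep$per_day), 12)
  expect_equal(sum(rep$per_day$n), 48)
  expect_equal(rep$repeatability_cv, repeatability_cv(set))
  expect_equal(rep$reproducibility_cv, reproducibility_cv(set))
  expect_gte(rep$month_variance_fraction, 0)
  expect_lte(rep$month_variance_fraction, 100)
  expect_true(rep$homogeneity$p_value > 0 && rep$homogeneity$p_value <= 1)
  expect_output(print(rep), "repeatability CV")
})
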