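test_that("full factorials have the right size, balance and orthogonality", {
  for (k in c(1, 2, 4, 5)) {
    d <- full_factorial(toy_factors(k))
    expect_equal(nrow(d), 2^k)
    X <- design_matrix(d)
    # exact integer check: X'X = n I on factor columns
    expect_true(all(crossprod(X) == diag(2^k, k)))
    expect_true(all(colSums(X == 1) == 2^(k - 1)))
  }
  d1 <- full_factorial(toy_factors(1))
  expect_equal(d1$f1, c(-1L, 1L))
  expect_error(full_factorial(toy_factors(2)[0]), "between 1 and 12")
})

test_that("microwell and shake-flask experiment sizes match the campaign text", {
  cat22 <- lycopene_factor_catalogue()
  micro <- full_factorial(cat22[c("well_volume", "well_fill_volume",
                                  "well_cover", "well_bottom",
                                  "shake_speed")])
  expect_equal(nrow(micro), 32)
  flask <- full_factorial(cat22[c("flask_volume", "flask_fill_volume",
                                  "flask_cover", "flask_baffles")])
  expect_equal(nrow(flask), 16)
})

test_that("fractional factorials give 2^(k-p) runs with orthogonal columns", {
  cases <- list(c(8, 3), c(9, 3), c(5, 2), c(6, 2))
  for (cs in cases) {
    k <- cs[1]; p <- cs[2]
    ff <- fractional_factorial(toy_factors(k), p = p)
    n <- 2^(k - p)
    expect_equal(nrow(ff$design), n)
    X <- design_matrix(ff$design)
    expect_true(all(crossprod(X) == diag(n, k)))
  }
})

test_that("defining relation and resolution match hand algebra for 2^(5-2)", {
  # D=AB, E=AC: words ABD, ACE and their product BCDE; shortest word 3
  al <- alias_structure(5, 2, c("D=AB", "E=AC"))
  expect_setequal(al$defining_relation, c("ABD", "ACE", "BCDE"))
  expect_equal(al$resolution, 3)
  # main effect A is aliased with BD and CE (products of A with the words)
  expect_setequal(al$alias_groups[["A"]], c("BD", "CE"))
})

test_that("word-algebra aliases equal brute-force column-product aliases", {
  for (cs in list(c(4, 1), c(5, 2), c(6, 3))) {
    k <- cs[1]; p <- cs[2]
    ff <- fractional_factorial(toy_factors(k), p = p)
    expected <- brute_force_aliases(ff$design)
    got <- alias_groups_as_names(ff$alias, names(toy_factors(k)))
    for (key in names(expected)) {
      expect_identical(got[[key]], expected[[key]], label = key)
    }
  }
})

test_that("shipped 2^(8-3) and 2^(9-3) designs are resolution IV", {
  expect_gte(alias_structure(8, 3)$resolution, 4)
  expect_gte(alias_structure(9, 3)$resolution, 4)
  # so no main effect is aliased with a two-factor interaction
  for (al in list(alias_structure(8, 3), alias_structure(9, 3))) {
    mains <- al$alias_groups[nchar(names(al$alias_groups)) == 1L]
    expect_true(all(lengths(mains) == 0L))
  }
})

test_that("malformed or dependent generators are rejected", {
  expect_error(alias_structure(5, 2, c("D=AB", "EAC")), "malformed")
  expect_error(fractional_factorial(toy_factors(6), p = 2,
                                    generators = c("E=AB", "E=AC")),
               "not independent")
  expect_error(alias_structure(5, 2, c("D=AF", "E=AC")), "base letters")
})

test_that("projection: dropping any factor leaves columns balanced", {
  ff <- fractional_factorial(toy_factors(8), p = 3)
  X <- design_matrix(ff$design)
  for (drop_col in colnames(X)) {
    Xp <- X[, setdiff(colnames(X), drop_col), drop = FALSE]
    expect_true(all(colSums(Xp) == 0), label = drop_col)
  }
})

test_that("centerpoints append coded-zero rows with policy-backed naturals", {
  d <- full_factorial(toy_factors(3))
  expect_identical(add_centerpoints(d, 0), d)
  d2 <- add_centerpoints(d, 5)
  expect_equal(nrow(d2), 8 + 5)
  expect_equal(sum(d2$centerpoint), 5)
  expect_true(all(design_matrix(d2, include_center = TRUE)[d2$centerpoint, ] == 0))
  nat <- natural_levels(d2)
  expect_true(all(nat$f1[d2$centerpoint] == 1))  # toy center level
  # a factor without center or policy must be refused
  spec_nc <- factor_spec("nc", "Time", "quantitative", 1, 2)
  d3 <- full_factorial(list(spec_nc))
  expect_error(add_centerpoints(d3, 2, policy = list()), "no center level")
  d4 <- add_centerpoints(d3, 2, policy = list(nc = 1.7))
  expect_equal(natural_levels(d4)$nc[d4$centerpoint], c(1.7, 1.7))
})

test_that("centerpoint natural levels of the media factors hit the recipe", {
  cat22 <- lycopene_factor_catalogue()
  d <- add_centerpoints(full_factorial(cat22[c("yeast_extract", "glycerol",
                                               "tryptone")]), 1)
  nat <- natural_levels(d)
  cp <- nat[nrow(nat), ]
  expect_equal(cp$yeast_extract, 24)
  expect_equal(cp$glycerol, 5)
  expect_equal(cp$tryptone, 12)
})

test_that("randomization is a seeded permutation that leaves content alone", {
  d <- full_factorial(toy_factors(4))
  r1 <- randomize(d, seed = 11)
  r2 <- randomize(d, seed = 11)
  expect_identical(r1$run_order, r2$run_order)
  expect_setequal(r1$run_order, seq_len(nrow(d)))
  expect_identical(design_matrix(r1), design_matrix(d))
  # different seeds disagree with overwhelming probability
  set.seed(42)
  pairs <- matrix(sample.int(1e6, 200), ncol = 2)
  same <- apply(pairs, 1, function(s) {
    identical(randomize(d, s[1])$run_order, randomize(d, s[2])$run_order)
  })
  expect_lt(mean(same), 0.05)
})

test_that("the default campaign reconstructs the 256-run layout", {
  camp <- build_campaign(seed = 1)
  expect_equal(nrow(camp), 256)
  expect_equal(as.vector(table(camp$group)), c(112, 96, 48))
  sizes <- table(camp$experiment[camp$group == "group1"])
  expect_equal(sizes[["media"]], 32)      # 2^(8-3)
  expect_equal(sizes[["microwell"]], 32)  # 2^5
  expect_equal(sizes[["flask"]], 16)      # 2^4
  expect_equal(sizes[["other"]], 32)      # 2^5
  sizes2 <- table(camp$experiment[camp$group == "group2"])
  expect_equal(sizes2[["large"]], 64)     # 2^(9-3)
  expect_equal(sizes2[["small"]], 32)     # 2^(8-3)
  # group-wise builds
  expect_equal(nrow(build_campaign(groups = "group1")), 112)
  expect_equal(nrow(build_campaign(groups = "group2")), 96)
  expect_equal(nrow(build_campaign(groups = "group3")), 48)
})

test_that("campaign experiments stay balanced and carry their aliases", {
  camp <- build_campaign(seed = 2)
  for (en in c("media", "microwell", "flask", "other", "large", "small")) {
    d <- campaign_experiment(camp, en)
    X <- design_matrix(d)
    expect_true(all(crossprod(X) == diag(nrow(X), ncol(X))), label = en)
  }
  d_media <- campaign_experiment(camp, "media")
  expect_s3_class(attr(d_media, "alias"), "alias_structure")
  expect_gte(attr(d_media, "alias")$resolution, 4)
})

test_that("a plan naming unknown factors is rejected", {
  plan <- default_campaign_plan()
  plan$group1$media$factors <- c(plan$group1$media$factors, "unobtainium")
  expect_error(build_campaign(plan = plan), "unobtainium")
})

test_that("campaign plans round-trip through YAML", {
  plan <- default_campaign_plan()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_campaign_plan(plan, path)
  plan2 <- read_campaign_plan(path)
  camp2 <- build_campaign(plan = plan2)
  expect_equal(nrow(camp2), 256)
  expect_equal(plan2$group1$media$p, 3L)
})

test_that("designs write to delimited text with coded and natural columns", {
  d <- add_centerpoints(full_factorial(toy_factors(2)), 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_design(d, path)
  df <- utils::read.csv(path)
  expect_equal(nrow(df), 5)
  expect_true(all(c("f1_code", "f1", "run_id", "centerpoint") %in% names(df)))
  expect_equal(df$f1, c(0, 2, 0, 2, 1))
})
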