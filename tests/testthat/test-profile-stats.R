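test_that("mutation_fraction handles zeros, ratios and bad counts", {
  expect_equal(mutation_fraction(0L, 100L), 0)
  expect_equal(mutation_fraction(5L, 200L), 0.025)
  expect_true(is.na(mutation_fraction(0L, 0L)))
  expect_error(mutation_fraction(7L, 0L), "exceeds coverage")
})

test_that("aligned-reads distribution tallies every reference", {
  rec <- sample_record(aligned_reads = c(r1 = 10L, r2 = 10L))
  h <- reads_per_reference_distribution(rec, n_bins = 1)
  expect_equal(h$counts, 2L)
  empty <- reads_per_reference_distribution(sample_record())
  expect_length(empty$counts, 0L)
  sim <- small_sim()
  h81 <- reads_per_reference_distribution(sim$study$samples$rep1)
  expect_equal(sum(h81$counts), length(sim$study$references))
})

test_that("mutations-per-read histogram equals a direct tally", {
  h <- mutations_per_read_histogram(c(0L, 0L, 1L, 2L))
  expect_equal(h$counts[1:3], c(2L, 1L, 1L))
  expect_equal(h$total_reads, 4L)
  h0 <- mutations_per_read_histogram(integer(0))
  expect_true(all(h0$counts == 0L))
  withr::with_seed(9, {
    reads <- rpois(10000, 2)
    h2 <- mutations_per_read_histogram(reads, cap = 10L)
    for (b in 0:9) expect_equal(h2$counts[b + 1L], sum(reads == b))
    expect_equal(h2$counts[11L], sum(reads >= 10))
  })
})

test_that("compare_profiles: identity, anti-correlation, masking, errors", {
  v <- make_view(c(0.01, 0.03, 0.02, 0.05))
  cmp <- compare_profiles(v, v)
  expect_equal(cmp$pearson_r, 1)
  expect_equal(cmp$r_squared, 1)
  expect_equal(cmp$rmse, 0)
  expect_equal(cmp$slope, 1)
  expect_equal(cmp$intercept, 0)

  a <- make_view(c(0.01, 0.02, 0.03, 0.04))
  b <- make_view(c(0.04, 0.03, 0.02, 0.01))
  expect_equal(compare_profiles(a, b)$pearson_r, -1)

  m <- make_view(c(0.01, NA, 0.03, 0.04))
  expect_equal(compare_profiles(m, v)$n, 3L)
  expect_error(compare_profiles(make_view(c(NA, NA, 0.1, NA)), v),
               "insufficient data")
  expect_error(compare_profiles(v, make_view(rep(0.1, 3))),
               "not position-parallel")
  expect_error(
    compare_profiles(v, make_view(rep(0.1, 4), section = "other")),
    "different reference/section")
})

test_that("comparison statistics match the direct-summation oracle", {
  withr::with_seed(17, {
    for (rep in 1:5) {
      y <- runif(6, 0, 0.1)   # sample 1
      x <- runif(6, 0, 0.1)   # sample 2
      cmp <- compare_profiles(make_view(y), make_view(x))
      o <- oracle_compare(x, y)
      expect_equal(cmp$pearson_r, o$r, tolerance = 1e-12)
      expect_equal(cmp$rmse, o$rmse, tolerance = 1e-12)
      expect_equal(cmp$slope, o$slope, tolerance = 1e-12)
      expect_equal(cmp$intercept, o$intercept, tolerance = 1e-12)
    }
  })
})

test_that("squared correlation equals regression R-squared for the OLS fit", {
  withr::with_seed(23, {
    y <- runif(20, 0, 0.1); x <- runif(20, 0, 0.1)
    cmp <- compare_profiles(make_view(y), make_view(x))
    fit <- stats::lm(y ~ x)
    expect_equal(cmp$r_squared, summary(fit)$r.squared, tolerance = 1e-12)
    expect_equal(cmp$slope, unname(stats::coef(fit)[2]), tolerance = 1e-12)
  })
})

test_that("r is affine-invariant and rmse translation-equivariant; swap symmetry", {
  withr::with_seed(31, {
    y <- runif(12, 0, 0.2); x <- runif(12, 0, 0.2)
    base <- compare_profiles(make_view(y), make_view(x))
    scaled <- compare_profiles(make_view(0.3 * y + 0.01), make_view(x))
    expect_equal(scaled$pearson_r, base$pearson_r, tolerance = 1e-12)
    shifted <- compare_profiles(make_view(y + 0.05), make_view(x + 0.05))
    expect_equal(shifted$rmse, base$rmse, tolerance = 1e-12)
    swapped <- compare_profiles(make_view(x), make_view(y))
    expect_equal(swapped$pearson_r, base$pearson_r, tolerance = 1e-12)
    expect_equal(swapped$rmse, base$rmse, tolerance = 1e-12)
    # OLS exchange: slope_yx * slope_xy = r^2
    expect_equal(swapped$slope * base$slope, base$pearson_r^2,
                 tolerance = 1e-12)
  })
})

test_that("degenerate constant input yields a masked statistic with a reason", {
  flat <- make_view(rep(0.02, 5))
  wob <- make_view(c(0.01, 0.02, 0.03, 0.02, 0.01))
  cmp <- compare_profiles(flat, wob)
  expect_true(is.na(cmp$pearson_r))
  expect_match(cmp$degenerate_reason, "constant")
  expect_false(is.na(cmp$rmse))
})

test_that("delta profiles subtract, propagate masks, and anti-commute", {
  a <- make_view(c(0.05, 0.01, NA))
  b <- make_view(c(0.02, 0.03, 0.04))
  d <- delta_profile(a, b)
  expect_equal(d$delta, c(0.03, -0.02, NA))
  expect_equal(delta_profile(a, a)$delta, c(0, 0, NA))
  d2 <- delta_profile(b, a)
  expect_equal(d$delta, -d2$delta)
})

test_that("ls_origin normalization inverts exact scalings and matches its formula", {
  p1 <- make_view(c(0.01, 0.02, 0.04, 0.06))
  p2 <- make_view(2 * c(0.01, 0.02, 0.04, 0.06))
  nr <- normalize_profiles(p1, p2)
  expect_equal(nr$factor, 0.5)
  expect_equal(nr$normalized$fraction, p1$fraction)
  expect_equal(normalize_profiles(p1, p1)$factor, 1)
  withr::with_seed(41, {
    x <- runif(10, 0, 0.1); y <- runif(10, 0, 0.1)
    nr2 <- normalize_profiles(make_view(x), make_view(y))
    sxy <- 0; syy <- 0
    for (i in 1:10) { sxy <- sxy + x[i] * y[i]; syy <- syy + y[i]^2 }
    expect_equal(nr2$factor, sxy / syy, tolerance = 1e-12)
  })
  expect_error(normalize_profiles(p1, make_view(rep(0, 4))), "all zero")
})

test_that("ls_origin minimizes the scaling residual (local optimality)", {
  withr::with_seed(43, {
    for (i in 1:20) {
      x <- runif(15, 0, 0.1); y <- runif(15, 0.001, 0.1)
      k <- normalize_profiles(make_view(x), make_view(y))$factor
      resid <- function(kk) sum((x - kk * y)^2)
      expect_lte(resid(k), resid(k * 1.01))
      expect_lte(resid(k), resid(k * 0.99))
    }
  })
})

test_that("clipped normalized fractions are counted and warned about", {
  p1 <- make_view(c(1, 1, 0.9))
  p2 <- make_view(c(0.5, 0.99, 0.8))
  expect_warning(nr <- normalize_profiles(p1, p2), "clipped")
  expect_gt(nr$n_clipped, 0)
  expect_true(all(nr$normalized$fraction <= 1))
})

test_that("fraction_identity stacks substitution targets over coverage", {
  p <- position_profile("r", "full", 1:2, c("G", "A"),
                        coverage = c(100L, 100L), mutated = c(10L, 0L),
                        sub_counts = list(A = c(2L, 0L), C = c(0L, 0L),
                                          G = c(5L, 0L), T = c(3L, 0L)))
  fi <- fraction_identity(p)
  expect_equal(unlist(fi[1, c("to_A", "to_C", "to_G", "to_T")],
                      use.names = FALSE),
               c(0.02, 0, 0.05, 0.03))
  expect_equal(sum(fi[2, c("to_A", "to_C", "to_G", "to_T")]), 0)
  # stack sum never exceeds the mutation fraction on simulated data
  sim <- small_sim()
  prof <- get_profile(sim$study, "rep1", names(sim$study$references)[1],
                      "full")
  stack <- fraction_identity(prof)
  tot <- rowSums(stack[, c("to_A", "to_C", "to_G", "to_T")])
  expect_true(all(tot <= prof$fraction + 1e-12, na.rm = TRUE))
})

test_that("variable series is sorted by value whatever the sample order", {
  s <- tiny_study()
  # add a third sample out of order
  p3 <- get_profile(s, "s1", "ref1", "full")
  s$samples$s3 <- sample_record(
    variables = list(MgCl2 = list(value = 1, unit = "mM")),
    profiles = list(p3))
  ser <- variable_series(s, "ref1", 2L, "MgCl2")
  expect_equal(ser$value, c(0, 1, 10))
  expect_equal(ser$fraction[1], 10 / 200)
  one <- variable_series(s, "ref1", 2L, "MgCl2", section = "full")
  expect_equal(nrow(one), 3L)
})

test_that("variable series excludes samples lacking the variable, with warning", {
  s <- tiny_study()
  s$samples$s2$variables <- list()
  expect_warning(ser <- variable_series(s, "ref1", 2L, "MgCl2"),
                 "excluded sample.*s2")
  expect_equal(nrow(ser), 1L)
  expect_error(suppressWarnings(variable_series(s, "ref1", 5L, "MgCl2")),
               "masked in every sample")
})
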