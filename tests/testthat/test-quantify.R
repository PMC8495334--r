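test_that("standard curves recover exact lines and reject bad designs", {
  d <- mixture_design("pork", "beef")
  cv <- fit_standard_curve(d, 1000 * d$fractions, "VNVDEVGGEALGR")
  expect_equal(cv$slope, 1000, tolerance = 1e-9)
  expect_equal(cv$intercept, 0, tolerance = 1e-9)
  expect_equal(cv$r_squared, 1, tolerance = 1e-12)
  # constant intensities: zero slope, zero r-squared
  flat <- fit_standard_curve(d, rep(5, 6), "X")
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_equal(flat$r_squared, 0)
  # design validation
  expect_error(mixture_design("a", "b", c(0, 0.5)), ">= 3")
  expect_error(mixture_design("a", "b", c(0, 0.5, 0.4)), "increasing")
  expect_error(mixture_design("a", "b", c(0, 0.5, 1.2)), "\\[0, 1\\]")
  expect_error(fit_standard_curve(d, 1:5, "X"), "multiple")
})

test_that("replicates are averaged per level (or kept when asked)", {
  d <- mixture_design("pork", "beef", c(0, 0.5, 1))
  # 3 levels x 2 replicates, level-major
  ints <- c(10, 14, 510, 514, 1010, 1014)
  cv <- fit_standard_curve(d, ints, "X")
  expect_equal(cv$n_points, 3)
  expect_equal(cv$slope, 1000, tolerance = 1e-9)
  cv_all <- fit_standard_curve(d, ints, "X", average_replicates = FALSE)
  expect_equal(cv_all$n_points, 6)
  expect_equal(cv_all$slope, 1000, tolerance = 1e-9)
  # matrix input: one row per level
  m <- matrix(ints, nrow = 3, byrow = TRUE)
  expect_equal(fit_standard_curve(d, m, "X")$slope, 1000, tolerance = 1e-9)
})

test_that("noisy simulated curves recover the true slope", {
  spec <- intensity_spec(slope = 500, intercept = 50, noise_sd = 10,
                         replicates = 3, seed = 21)
  tab <- simulate_mixture_intensities(spec)
  d <- mixture_design("a", "b")
  m <- matrix(tab$intensity, nrow = 6, byrow = TRUE)
  cv <- fit_standard_curve(d, m, "PEPTIDE1")
  expect_lt(abs(cv$slope - 500), 3 * cv$slope_se)
  expect_gt(cv$r_squared, 0.99)
})

test_that("inverse prediction inverts the curve and flags clipping", {
  d <- mixture_design("pork", "beef")
  cv <- fit_standard_curve(d, 1000 * d$fractions, "X")
  est <- estimate_fraction(cv, 200)
  expect_equal(est$fraction, 0.2, tolerance = 1e-12)
  expect_false(est$clipped)
  # below-intercept observation clips to zero with the flag set
  cv2 <- fit_standard_curve(d, 1000 * d$fractions + 100, "X")
  est2 <- estimate_fraction(cv2, 50)
  expect_equal(est2$fraction, 0)
  expect_true(est2$clipped)
  # near-zero slope is unquantifiable
  flat <- fit_standard_curve(d, rep(5, 6), "X")
  expect_error(estimate_fraction(flat, 5), "unquantifiable")
})

test_that("noiseless round trips recover every design fraction", {
  d <- mixture_design("duck", "beef")
  slope <- 732.5; intercept <- 41.2
  cv <- fit_standard_curve(d, slope * d$fractions + intercept, "X")
  for (f in d$fractions) {
    est <- estimate_fraction(cv, slope * f + intercept)
    expect_equal(est$fraction, f, tolerance = 1e-9)
  }
})

test_that("complementary mixtures give mirrored curves on noiseless data", {
  # same physical samples read through the target marker and through the
  # background marker: fractions sum to 1, so slopes are equal and
  # opposite and the intercepts swap roles
  fr <- c(0, 0.2, 0.4, 0.6, 0.8, 1)
  slope <- 900; intercept <- 30
  fwd <- fit_standard_curve(mixture_design("pork", "beef", fr),
                            slope * fr + intercept, "X")
  rev <- fit_standard_curve(mixture_design("beef", "pork", fr),
                            slope * (1 - fr) + intercept, "Y")
  expect_equal(fwd$slope, -rev$slope, tolerance = 1e-9)
  expect_equal(rev$intercept, fwd$intercept + fwd$slope, tolerance = 1e-9)
})

test_that("the consensus median resists a corrupted panel member", {
  expect_equal(consensus_estimate(c(0.18, 0.20, 0.22))$fraction, 0.20)
  single <- consensus_estimate(0.31)
  expect_equal(single$fraction, 0.31)
  expect_equal(single$spread, 0)
  expect_error(consensus_estimate(numeric(0)), "no estimates")
  # 3-peptide panels, one biased x2: median beats mean on average
  set.seed(9)
  err_med <- err_mean <- numeric(100)
  for (i in 1:100) {
    truth <- runif(1, 0.1, 0.5)
    ests <- truth + rnorm(3, 0, 0.01)
    ests[3] <- ests[3] * 2
    err_med[i] <- abs(consensus_estimate(ests)$fraction - truth)
    err_mean[i] <- abs(mean(ests) - truth)
  }
  expect_lt(mean(err_med), mean(err_mean))
})

test_that("the calibration LOD follows the 3.3 sigma over slope rule", {
  d <- mixture_design("chicken", "lamb")
  cv <- fit_standard_curve(d, 1000 * d$fractions, "X")
  cv$slope <- 1000   # exact, avoids fp noise in the assertion
  expect_equal(lod_estimate(cv, c(97, 100, 103)), 3.3 * 3 / 1000)
  expect_equal(lod_estimate(cv, c(5, 5, 5)), 0)
  expect_error(lod_estimate(cv, c(1, 2)), ">= 3")
  flat <- cv; flat$slope <- 0
  expect_error(lod_estimate(flat, c(1, 2, 3)), "unquantifiable")
})

test_that("contaminant detection flags planted species only", {
  panel <- data.frame(
    species = c("pork", "pork", "beef"),
    sequence = c("VNVDEVGGEALGR", "DQGSYEDFVEGLR", "TLEDQVNELK"),
    stringsAsFactors = FALSE)
  d <- mixture_design("pork", "beef")
  curves <- list(
    `pork:VNVDEVGGEALGR` =
      fit_standard_curve(d, 1000 * d$fractions, "VNVDEVGGEALGR"))
  sample <- c(`pork:VNVDEVGGEALGR` = 200, `pork:DQGSYEDFVEGLR` = 0,
              `beef:TLEDQVNELK` = 0)
  rep <- detect_contaminant(sample, panel, curves)
  pork <- rep[rep$species == "pork", ]
  expect_true(pork$detected)
  expect_equal(pork$fraction, 0.2, tolerance = 1e-9)
  expect_equal(pork$supporting, "VNVDEVGGEALGR")
  expect_false(rep$detected[rep$species == "beef"])
  # all-zero sample detects nothing
  none <- detect_contaminant(sample * 0, panel, curves)
  expect_false(any(none$detected))
})

test_that("r-squared approaches one as noise vanishes", {
  d <- mixture_design("a", "b")
  sds <- c(100, 10, 1, 0)
  r2 <- vapply(sds, function(s) {
    tab <- simulate_mixture_intensities(
      intensity_spec(slope = 500, intercept = 50, noise_sd = s,
                     replicates = 3, seed = 4))
    m <- matrix(tab$intensity, nrow = 6, byrow = TRUE)
    fit_standard_curve(d, m, "P")$r_squared
  }, numeric(1))
  expect_true(all(diff(r2) >= 0))
  expect_equal(r2[4], 1, tolerance = 1e-12)
})
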