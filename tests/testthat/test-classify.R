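test_that("1-D calibration returns the midpoint for symmetric classes", {
  s <- training_samples(c(2, 2, 2, 1, 1, 1), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  # zero pooled variance: boundary is the plain midpoint
  expect_error(fit_cutoff_1d(s), NA)
  fit <- fit_cutoff_1d(training_samples(c(2, 2.0001, 2, 1, 1.0001, 1),
                                        c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)))
  expect_equal(fit$cutoff_r, 1.5, tolerance = 1e-3)
})

test_that("1-D calibration recovers the analytic Gaussian boundary", {
  set.seed(701)
  r <- c(rnorm(500, 2.4, 0.2), rnorm(500, 1.5, 0.2))
  lab <- rep(c(TRUE, FALSE), each = 500)
  fit <- fit_cutoff_1d(training_samples(r, lab))
  expect_lt(abs(fit$cutoff_r - 1.95), 0.05)
})

test_that("1-D calibration at the published class means matches the printed cut-off", {
  set.seed(702)
  # group-2 regime: positives around 2.42, negatives around 1.53, equal spread
  r <- c(rnorm(400, 2.42, 0.2), rnorm(400, 1.53, 0.2))
  lab <- rep(c(TRUE, FALSE), each = 400)
  fit <- fit_cutoff_1d(training_samples(r, lab))
  expect_lt(abs(fit$cutoff_r - 1.98), 0.05)
})

test_that("unequal class sizes shift the boundary toward the smaller class side", {
  set.seed(703)
  r <- c(rnorm(100, 2.4, 0.2), rnorm(900, 1.5, 0.2))
  lab <- rep(c(TRUE, FALSE), c(100, 900))
  fit <- fit_cutoff_1d(training_samples(r, lab))
  # prior term log(n_neg/n_pos)/(mu_p - mu_n) * s2 > 0 pushes the cut up
  expect_gt(fit$cutoff_r, 1.95)
})

test_that("calibration errors on degenerate inputs", {
  expect_error(fit_cutoff_1d(training_samples(c(1, 2), c(TRUE, TRUE))),
               "per class")
  expect_error(fit_cutoff_1d(training_samples(c(1, 1, 1, 1),
                                              c(TRUE, TRUE, FALSE, FALSE))),
               "identical")
  # infinite sentinels are excluded from the moments
  s <- training_samples(c(Inf, 2, 2.1, 1, 1.1), c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_silent(fit_cutoff_1d(s))
})

test_that("1-D boundary agrees with an independent LDA implementation", {
  skip_if_not_installed("MASS")
  set.seed(704)
  r <- c(rnorm(300, 2.1, 0.25), rnorm(300, 1.4, 0.25))
  lab <- rep(c(TRUE, FALSE), each = 300)
  fit <- fit_cutoff_1d(training_samples(r, lab))
  m <- MASS::lda(x ~ r, data = data.frame(r = r, x = lab))
  grid <- data.frame(r = seq(1.0, 2.6, by = 0.001))
  pred <- predict(m, grid)$class == "TRUE"
  boundary <- grid$r[which(pred)[1]]
  expect_lt(abs(fit$cutoff_r - boundary), 0.01)
})

test_that("2-D LDA weights reflect feature informativeness", {
  set.seed(705)
  n <- 400
  # pk flag identical across classes: reduces to the R cut-off
  s <- training_samples(c(rnorm(n, 2.4, 0.2), rnorm(n, 1.5, 0.2)),
                        rep(c(TRUE, FALSE), each = n),
                        pk_flag = rep(1L, 2 * n))
  fit <- suppressWarnings(fit_lda_2d(s, "flag"))
  boundary <- -fit$bias / fit$weight_r
  expect_lt(abs(boundary - 1.95), 0.06)
  expect_lt(abs(fit$weight_pk) * 1e-6, abs(fit$weight_r))

  # classes separated only by pk_flag
  s <- training_samples(rnorm(2 * n, 1.9, 0.2), rep(c(TRUE, FALSE), each = n),
                        pk_flag = c(rbinom(n, 1, 0.95), rbinom(n, 1, 0.05)))
  fit <- fit_lda_2d(s, "flag")
  expect_gt(abs(fit$weight_pk), 10 * abs(fit$weight_r))
})

test_that("2-D LDA matches the closed-form boundary on known Gaussians", {
  set.seed(706)
  n <- 800
  mu_p <- c(2.3, 0.8); mu_n <- c(1.5, 0.2); sd2 <- c(0.25, 0.35)
  s <- training_samples(c(rnorm(n, mu_p[1], sd2[1]), rnorm(n, mu_n[1], sd2[1])),
                        rep(c(TRUE, FALSE), each = n),
                        pk_energy = c(rnorm(n, mu_p[2], sd2[2]),
                                      rnorm(n, mu_n[2], sd2[2])))
  fit <- fit_lda_2d(s, "energy")
  w_true <- (mu_p - mu_n) / sd2^2
  # direction of the discriminant (scale-free comparison)
  expect_equal(fit$weight_pk / fit$weight_r, w_true[2] / w_true[1],
               tolerance = 0.15)
  # midpoint of the class means lies on the fitted line (equal priors)
  mid <- (mu_p + mu_n) / 2
  score <- fit$weight_r * mid[1] + fit$weight_pk * mid[2] + fit$bias
  expect_lt(abs(score), 0.35)
})

test_that("2-D LDA agrees with an independent implementation on predictions", {
  skip_if_not_installed("MASS")
  set.seed(707)
  n <- 300
  s <- training_samples(c(rnorm(n, 2.2, 0.3), rnorm(n, 1.5, 0.3)),
                        rep(c(TRUE, FALSE), each = n),
                        pk_flag = c(rbinom(n, 1, 0.7), rbinom(n, 1, 0.2)))
  fit <- fit_lda_2d(s, "flag")
  m <- MASS::lda(lab ~ r + pk, data = data.frame(r = s$r, pk = s$pk_flag,
                                                 lab = s$label))
  grid <- expand.grid(r = seq(1, 2.8, by = 0.05), pk = c(0, 1))
  mine <- predict(fit, grid)
  theirs <- predict(m, grid)$class == "TRUE"
  expect_gt(mean(mine == theirs), 0.98)
})

test_that("decisions follow the cut-off, sentinel and rescue rules", {
  tmpl <- random_nested(30)
  g1 <- group_model(1, "CrPV", tmpl)
  g4 <- group_model(4, "PV", tmpl)
  expect_equal(g1$cutoff_r, 1.61)
  expect_equal(g4$cutoff_r, 1.58)

  no_pk <- structure(list(has_pk = FALSE, pk_energy = 0,
                          structure = arc_annotated("A")), class = "pk_result")
  yes_pk <- structure(list(has_pk = TRUE, pk_energy = -8,
                           structure = arc_annotated("A")), class = "pk_result")

  # positive-group mean R for group 1 exceeds its cut-off
  expect_true(decide_candidate(1.90, NULL, g1, mode = "r_only"))
  # negative-group mean R for group 4 falls below its cut-off
  expect_false(decide_candidate(1.49, NULL, g4, mode = "r_only"))
  # perfect template match passes everywhere
  expect_true(decide_candidate(Inf, NULL, g1, mode = "r_only"))
  expect_true(decide_candidate(Inf, no_pk, g4, mode = "r_plus_pk"))

  # pseudoknot rescue within the relax band only
  expect_false(decide_candidate(1.55, no_pk, g1, mode = "r_plus_pk"))
  expect_true(decide_candidate(1.55, yes_pk, g1, mode = "r_plus_pk"))
  expect_false(decide_candidate(1.45, yes_pk, g1, mode = "r_plus_pk"))
  expect_error(decide_candidate(1.55, yes_pk, g1, mode = "r_plus_pk",
                                relax = NULL), "relax")

  # monotone in r: raising r never flips positive -> negative
  rs <- seq(1.2, 2.2, by = 0.05)
  dec <- vapply(rs, decide_candidate, logical(1), pk = yes_pk, model = g1,
                mode = "r_plus_pk")
  expect_true(all(diff(dec) >= 0))
})

test_that("confusion metrics reproduce their defining ratios", {
  expect_equal(sensitivity(confusion_summary(133, 0, 0, 80)), 62.44,
               tolerance = 5e-3)
  expect_equal(sensitivity(confusion_summary(0, 0, 1, 5)), 0)
  expect_equal(specificity(confusion_summary(0, 1, 33, 0)), 97.06,
               tolerance = 5e-3)
  expect_error(sensitivity(confusion_summary(0, 1, 1, 0)), "undefined")
  expect_error(specificity(confusion_summary(1, 0, 0, 1)), "undefined")
  expect_error(confusion_summary(-1, 0, 0, 0), "non-negative")
})

test_that("metric values are invariant under scaling the confusion counts", {
  cs1 <- confusion_summary(7, 3, 21, 5)
  cs4 <- confusion_summary(28, 12, 84, 20)
  expect_equal(sensitivity(cs1), sensitivity(cs4))
  expect_equal(specificity(cs1), specificity(cs4))
  expect_equal(prediction_rate(7, 36), prediction_rate(28, 144))
})

test_that("accuracy_rate and false_rates are the stated arithmetic identities", {
  expect_equal(accuracy_rate(87.50, 97.06), 92.28)
  expect_equal(accuracy_rate(100, 97.06), 98.53)
  expect_equal(accuracy_rate(0, 100), 50)
  expect_equal(unname(false_rates(56.34, 98.85)), c(43.66, 1.15))
  expect_equal(unname(false_rates(100, 50)), c(0, 50))
  expect_error(accuracy_rate(120, 50))
})

test_that("prediction_rate follows the printed two-decimal convention", {
  expect_equal(prediction_rate(2526, 3096), 81.59)
  expect_equal(prediction_rate(16, 16), 100)
  expect_equal(prediction_rate(0, 10), 0)
  expect_error(prediction_rate(5, 0))
  expect_error(prediction_rate(11, 10))
})
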