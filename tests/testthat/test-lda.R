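test_that("co-occurrence grid normalizes by the possible pair count", {
  pairs <- data.frame(
    abs_type = rep(1, 40), delta_dist = rep(1, 40),
    status = rep(c("present", "absent", "unknown"), c(20, 10, 10))
  )
  g <- build_grid(pairs)
  expect_equal(g$n_possible, 40)
  expect_equal(g$pct_present, 50)
  expect_equal(g$pct_absent, 25)

  # unexamined cell: both percentages zero
  pairs2 <- rbind(pairs, data.frame(abs_type = 2, delta_dist = 3,
                                    status = rep("unknown", 5)))
  g2 <- build_grid(pairs2)
  cell <- g2[g2$abs_type == 2, ]
  expect_equal(cell$pct_present + cell$pct_absent, 0)
  expect_equal(cell$n_possible, 5)
})

test_that("case construction rounds percentages (halves up) and recounts", {
  g <- data.frame(abs_type = c(0, 1, 2), delta_dist = c(1, 2, 3),
                  pct_absent = c(25.0, 0.5, 0), pct_present = c(50.0, 49.4, 0))
  cases <- construct_cases(g)
  expect_equal(sum(cases$label == "absent" & cases$cell == 1), 25)
  expect_equal(sum(cases$label == "present" & cases$cell == 1), 50)
  expect_equal(sum(cases$cell == 2), 1 + 49)  # 0.5 rounds up, 49.4 down
  expect_equal(sum(cases$cell == 3), 0)
  # independent recount: total equals sum of rounded percentages
  expect_equal(nrow(cases),
               sum(floor(g$pct_absent + 0.5)) + sum(floor(g$pct_present + 0.5)))
  expect_true(all(cases$abs_type[cases$cell == 2] == 1))
})

test_that("1-D discriminant posterior equals the closed-form Gaussian posterior", {
  set.seed(41)
  x0 <- rnorm(300, -1); x1 <- rnorm(300, 1)
  cases <- data.frame(v = c(x0, x1),
                      label = factor(rep(c("absent", "present"), each = 300)))
  m <- fit_lda(cases, predictors = "v")
  # boundary at the midpoint of symmetric classes
  mid <- mean(c(mean(x0), mean(x1)))
  expect_equal(predict(m, data.frame(v = mid)), 0.5, tolerance = 1e-10)

  s2 <- ((299) * var(x0) + (299) * var(x1)) / 598
  grid <- data.frame(v = seq(-3, 3, 0.25))
  expect_equal(predict(m, grid),
               oracle_gaussian_posterior(grid$v, mean(x0), mean(x1), s2),
               tolerance = 1e-10)
})

test_that("discriminant model matches MASS::lda posteriors on constructed cases", {
  x <- synthetic_connectome(generator_config(n_areas = 36, seed = 43))
  pv <- join_status(pair_variables(x$parcellation, x$hierarchy), x$table)
  cases <- construct_cases(build_grid(pv))
  m <- fit_lda(cases)
  ref <- MASS::lda(label ~ abs_type + delta_dist, data = cases,
                   prior = c(0.5, 0.5))
  post <- predict(ref, cases)$posterior[, "present"]
  expect_equal(unname(predict(m, cases)), unname(post), tolerance = 1e-6)
  # standardized coefficient definition: |w_j| * pooled within-class SD
  expect_equal(unname(m$standardized_coefficients),
               unname(abs(m$weights) * sqrt(diag(m$pooled_covariance))))
})

test_that("posterior is monotone decreasing in each predictor for negative weights", {
  x <- synthetic_connectome(generator_config(n_areas = 36, seed = 44))
  pv <- join_status(pair_variables(x$parcellation, x$hierarchy), x$table)
  m <- fit_lda(construct_cases(build_grid(pv)))
  expect_true(all(m$weights < 0))
  grid <- expand.grid(abs_type = 0:4, delta_dist = 1:6)
  post <- matrix(predict(m, grid), nrow = 5)
  expect_true(all(apply(post, 2, diff) < 0))  # along abs_type
  expect_true(all(apply(post, 1, diff) < 0))  # along delta_dist
})

test_that("degenerate case sets are rejected", {
  one_class <- data.frame(abs_type = 1:4, delta_dist = 1:4,
                          label = factor(rep("present", 4),
                                         levels = c("absent", "present")))
  expect_error(fit_lda(one_class), "empty")
  flat <- data.frame(abs_type = rep(1, 6), delta_dist = rep(2, 6),
                     label = factor(rep(c("absent", "present"), 3)))
  expect_error(fit_lda(flat), "singular")
})

test_that("threshold decisions partition pairs and tighten monotonically", {
  set.seed(46)
  ths <- seq(0.60, 0.90, 0.05)
  for (rep in 1:20) {
    post <- runif(60)
    decided <- sapply(ths, function(th) {
      dec <- classify_posterior(post, th)
      expect_true(all(dec %in% c("present", "absent", "unclassified")))
      expect_true(all((dec == "present") == (post >= th)))
      expect_true(all((dec == "absent") == (post <= 1 - th)))
      sum(dec != "unclassified")
    })
    expect_true(all(diff(decided) <= 0))
  }
})

test_that("cross-validation is perfect on separable cases and tightens with theta", {
  set.seed(47)
  cases <- data.frame(
    abs_type = c(rnorm(120, 0, 0.2), rnorm(120, 4, 0.2)),
    delta_dist = c(rnorm(120, 1, 0.2), rnorm(120, 6, 0.2)),
    label = factor(rep(c("present", "absent"), each = 120))
  )
  cv <- cross_validate(cases, n_cycles = 30, seed = 9)
  expect_true(all(cv$summary$acc_overall_mean == 1))
  expect_true(all(diff(cv$summary$n_classified_mean) <= 0))
  # determinism under a fixed seed
  cv2 <- cross_validate(cases, n_cycles = 30, seed = 9)
  expect_identical(cv$summary, cv2$summary)
})

test_that("unknown-pair prediction applies the threshold rule and skips undefined pairs", {
  x <- synthetic_connectome(generator_config(n_areas = 36, seed = 48))
  # drop one area's type so some unknown pairs lack predictors
  x$parcellation$areas$structural_type[1] <- NA
  pv <- join_status(pair_variables(x$parcellation, x$hierarchy), x$table)
  m <- fit_lda(construct_cases(build_grid(pv)))
  pred <- predict_unknown(m, pv)
  n_unknown_defined <- sum(pv$status == "unknown" & !is.na(pv$abs_type))
  expect_equal(nrow(pred), n_unknown_defined)
  expect_false(x$parcellation$areas$name[1] %in% c(pred$source, pred$target))
  expect_identical(pred$decision_0.75,
                   classify_posterior(pred$posterior, 0.75))
  counts <- sapply(attr(pred, "thresholds"), n_decided, predictions = pred)
  expect_true(all(diff(counts) <= 0))

  sm <- prediction_status_matrix(pred, pv)
  known <- pv[pv$status != "unknown", ]
  expect_true(all(sm[cbind(known$source, known$target)] ==
                    paste0("known-", known$status)))
  dec <- pred[pred$decision_0.90 != "unclassified", ][1, ]
  expect_match(sm[dec$source, dec$target], "pred-.*@0.90")
})
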