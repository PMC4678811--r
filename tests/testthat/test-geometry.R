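test_that("the Forster relation reproduces its fixed points", {
  expect_equal(fret_to_distance(0.5, forster_params(60)), 60, tolerance = 1e-12)
  expect_equal(fret_to_distance(0.2, forster_params(60)), 75.6, tolerance = 0.05)
  expect_equal(distance_to_fret(60, forster_params(60)), 0.5, tolerance = 1e-12)
  expect_equal(round(distance_to_fret(76, forster_params(60)), 1), 0.2)
  expect_lt(distance_to_fret(1e4, forster_params(60)), 1e-10)
  expect_error(fret_to_distance(0), "strictly inside")
  expect_error(fret_to_distance(1), "strictly inside")
  expect_error(distance_to_fret(-5), "positive")
})

test_that("forward and inverse Forster transforms are mutual inverses and monotone", {
  p <- forster_params(60)
  E <- seq(0.01, 0.99, by = 0.01)
  expect_equal(distance_to_fret(fret_to_distance(E, p), p), E, tolerance = 1e-9)
  R <- seq(20, 150, by = 1)
  expect_equal(fret_to_distance(distance_to_fret(R, p), p), R, tolerance = 1e-9)
  expect_true(all(diff(fret_to_distance(E, p)) < 0))
  expect_true(all(diff(distance_to_fret(R, p)) < 0))
})

test_that("A-form contour lengths follow length_bp * rise", {
  expect_equal(helix_contour_length(helix_arm("stem I", 10)), 28)
  expect_equal(helix_contour_length(helix_arm("stem II", 17)), 47.6, tolerance = 1e-9)
  expect_equal(helix_contour_length(helix_arm("x", 0)), 0)
  expect_error(helix_arm("x", 5, rise_per_bp = 4), "rise_per_bp")
})

default_arms <- function() {
  list(helix_arm("stem I", 10), helix_arm("stem II", 17),
       helix_arm("5' stem-loop", 8))
}

test_that("a 76 A measurement ranks stems I/II coaxial stacking first", {
  meas <- data.frame(arm_a = "stem I", arm_b = "stem II", distance = 75.6)
  rk <- rank_stacking_models(default_arms(), meas)
  expect_identical(rk$stacked_pair[1], "stem I + stem II")
  expect_equal(rk$residual[1], 0, tolerance = 1e-9)
  expect_identical(rk$family[1], "A")
  # collinear prediction is exactly the sum of the contour lengths
  expect_equal(rk$predicted_label_distance[1], 28 + 47.6, tolerance = 1e-12)
  expect_error(rank_stacking_models(default_arms(),
                                    data.frame(arm_a = "stem IX", arm_b = "stem II",
                                               distance = 50)),
               "unknown arm")
})

test_that("a half-length measurement demotes the collinear model below a bent one", {
  meas <- data.frame(arm_a = "stem I", arm_b = "stem II",
                     distance = 0.5 * (28 + 47.6))
  rk <- rank_stacking_models(default_arms(), meas, include_bent = TRUE)
  sub <- rk[rk$stacked_pair == "stem I + stem II", ]
  expect_lt(which(sub$geometry == "bent"), which(sub$geometry == "coaxial"))
  expect_lt(sub$residual[sub$geometry == "bent"],
            sub$residual[sub$geometry == "coaxial"])
})

test_that("ranking is invariant to measurement order and recovers planar geometries", {
  arms <- default_arms()
  L <- vapply(arms, helix_contour_length, numeric(1))
  # generate a planar junction: stems I+II collinear, stem-loop at 60 deg to stem I
  d12 <- predict_label_distance(L[1], L[2], 180)
  d13 <- predict_label_distance(L[1], L[3], 60)
  d23 <- predict_label_distance(L[2], L[3], 120)
  meas <- data.frame(arm_a = c("stem I", "stem I", "stem II"),
                     arm_b = c("stem II", "5' stem-loop", "5' stem-loop"),
                     distance = c(d12, d13, d23))
  rk <- rank_stacking_models(arms, meas)
  expect_identical(rk$stacked_pair[1], "stem I + stem II")
  # order invariance
  rk2 <- rank_stacking_models(arms, meas[c(3, 1, 2), ])
  expect_identical(rk$stacked_pair, rk2$stacked_pair)
  expect_equal(rk$residual, rk2$residual)
  # 1-degree grid oracle over inter-arm angles agrees on the best pair
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  oracle_resid <- vapply(seq_along(pairs), function(i) {
    pr <- pairs[[i]]
    abs(predict_label_distance(L[pr[1]], L[pr[2]], 180) - meas$distance[c(1, 2, 3)][i])
  }, numeric(1))
  expect_identical(which.min(oracle_resid), 1L)
})

test_that("bent-model angle recovery matches a grid-search oracle", {
  L1 <- 28; L2 <- 47.6
  for (true_angle in c(45, 90, 135)) {
    d <- predict_label_distance(L1, L2, true_angle)
    grid <- 0:180
    oracle_angle <- grid[which.min(abs(predict_label_distance(L1, L2, grid) - d))]
    meas <- data.frame(arm_a = "stem I", arm_b = "stem II", distance = d)
    rk <- rank_stacking_models(list(helix_arm("stem I", 10),
                                    helix_arm("stem II", 17),
                                    helix_arm("5' stem-loop", 8)),
                               meas, include_bent = TRUE)
    bent <- rk[rk$stacked_pair == "stem I + stem II" & rk$geometry == "bent", ]
    expect_equal(bent$angle_deg, oracle_angle, tolerance = 1)
    expect_equal(bent$residual, 0, tolerance = 1e-4)
  }
})

test_that("distance uncertainties propagate consistently with Monte Carlo", {
  model <- structure(list(components = data.frame(mean = 0.2, sigma = 0.05,
                                                  weight = 1, se_mean = 0.01)),
                     class = "mixture_model")
  est <- estimate_distances(model, forster_params(60))
  expect_equal(est$distance_A, 75.6, tolerance = 0.05)
  set.seed(19)
  mc <- fret_to_distance(rnorm(10000, 0.2, 0.01), forster_params(60))
  expect_equal(est$se_distance_A, sd(mc), tolerance = 0.05 * sd(mc))
  # finite-difference check of the analytic derivative
  eps <- 1e-6
  fd <- (fret_to_distance(0.2 + eps) - fret_to_distance(0.2 - eps)) / (2 * eps)
  expect_equal(est$se_distance_A, abs(fd) * 0.01, tolerance = 1e-6)
  # zero standard error propagates to zero distance error
  model$components$se_mean <- 0
  model$components$mean <- 0.5
  est0 <- estimate_distances(model, forster_params(60))
  expect_equal(est0$distance_A, 60, tolerance = 1e-9)
  expect_equal(est0$se_distance_A, 0)
  # out-of-range component means are flagged, distance omitted
  model$components <- data.frame(mean = c(0.3, 1.4), sigma = 0.05, weight = 0.5,
                                 se_mean = 0.01)
  est2 <- estimate_distances(model, forster_params(60))
  expect_identical(est2$flagged, c(FALSE, TRUE))
  expect_true(is.na(est2$distance_A[2]))
})
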