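test_that("apparent FRET is the acceptor fraction of total intensity", {
  tr <- manual_trace(rep(0.5, 20))
  ft <- compute_fret(tr)
  expect_equal(ft$fret, rep(0.5, 20))
  tr2 <- manual_trace(rep(0.2, 20))
  expect_equal(compute_fret(tr2)$fret, rep(0.2, 20))
})

test_that("noiseless simulated traces round-trip their state mean exactly", {
  cfg <- small_config(states = data.frame(fret_mean = 0.3, weight = 1),
                      noise_sigma = 0, donor_bleach_lifetime = 1e7,
                      acceptor_bleach_lifetime = 1e7)
  set.seed(5)
  tr <- simulate_trace(cfg, 1L)$trace
  ft <- compute_fret(tr)
  expect_true(all(ft$fret[ft$valid] == 0.3))
})

test_that("FRET stays in [0,1] for non-negative channels and NA below threshold", {
  set.seed(11)
  tr <- manual_trace(runif(50), total = 80)
  ft <- compute_fret(tr)
  expect_true(all(ft$fret[ft$valid] >= 0 & ft$fret[ft$valid] <= 1))
  # post-bleach background frames are flagged undefined, not dropped
  tr2 <- manual_trace(rep(0.4, 60), bleach_at = 31)
  tr2$I_D <- tr2$I_D + rnorm(60, 0, 2)
  tr2$I_A <- tr2$I_A + rnorm(60, 0, 2)
  ft2 <- compute_fret(tr2)
  expect_length(ft2$fret, 60)
  expect_true(all(is.na(ft2$fret[40:60])))
})

test_that("step detection finds clean steps exactly and none in constants", {
  expect_length(detect_steps(rep(100, 50))$change_points, 0)
  x <- c(rep(100, 500), rep(0, 500))
  sf <- detect_steps(x)
  expect_identical(sf$change_points, 501L)
  expect_equal(sf$segment_means, c(100, 0))
})

test_that("noisy staircase change points land within 2 frames of truth", {
  set.seed(31)
  x <- c(rep(100, 70), rep(60, 60), rep(0, 70)) + rnorm(200, 0, 5)
  sf <- detect_steps(x)
  oracle <- exhaustive_steps(x, sf$penalty)
  expect_length(sf$change_points, 2)
  expect_true(all(abs(sf$change_points - c(71, 131)) <= 2))
  expect_identical(sf$change_points, as.integer(oracle$change_points))
})

test_that("the segmenter matches the exhaustive least-squares oracle on small instances", {
  set.seed(77)
  for (rep_i in 1:12) {
    n <- sample(60:200, 1)
    n_cp <- sample(0:2, 1)
    cps <- sort(sample(seq(10, n - 10), n_cp))
    levels <- cumsum(c(100, sample(c(-60, 60, -40), n_cp, replace = TRUE)))
    x <- rep(levels, diff(c(0, cps, n))) + rnorm(n, 0, 4)
    sf <- detect_steps(x)
    oracle <- exhaustive_steps(x, sf$penalty, max_cp = 2L)
    if (length(sf$change_points) <= 2L) {
      expect_identical(sf$change_points, as.integer(oracle$change_points))
      expect_equal(sf$objective, oracle$objective, tolerance = 1e-9)
    } else {
      # the DP explored a richer segmentation: it can only improve
      expect_lte(sf$objective, oracle$objective + 1e-9)
    }
  }
})

test_that("QC passes clean single-bleach molecules and truncates at the first bleach", {
  cfg <- small_config(states = data.frame(fret_mean = 0.3, weight = 1),
                      n_molecules = 40L, n_frames = 400L,
                      donor_bleach_lifetime = 120, acceptor_bleach_lifetime = 200,
                      seed = 8L)
  ens <- simulate_ensemble(cfg)
  fts <- qc_select(ens$traces)
  qt <- qc_table(fts)
  m <- merge(qt, ens$ground_truth, by = "molecule_id")
  bleached <- !is.na(m$donor_bleach_frame)
  expect_gt(mean(m$qc_pass[bleached]), 0.8)
  # detected bleach frame agrees with ground truth for passers; acceptor
  # bleaches in the first frames leave no pre-step segment to detect, so a
  # molecule bleaching that early is effectively donor-only from the start
  ok <- m$qc_pass & bleached &
    (is.na(m$acceptor_bleach_frame) | m$acceptor_bleach_frame > 5)
  truth_first <- pmin(m$donor_bleach_frame[ok],
                      ifelse(is.na(m$acceptor_bleach_frame[ok]), Inf,
                             m$acceptor_bleach_frame[ok]))
  expect_true(all(abs(m$bleach_frame[ok] - truth_first) <= 2))
})

test_that("molecules that never bleach fail QC", {
  tr <- manual_trace(rep(0.3, 100))
  tr$I_D <- tr$I_D + rnorm(100, 0, 5)
  tr$I_A <- tr$I_A + rnorm(100, 0, 5)
  fts <- qc_select(tr)
  expect_false(fts[[1]]$qc_pass)
  expect_identical(fts[[1]]$qc_reason, "no_bleach_in_window")
  expect_true("no_bleach_in_window" %in% names(attr(fts, "reason_tally")))
})

test_that("two-molecule aggregates are rejected at high sensitivity", {
  cfg <- small_config(states = data.frame(fret_mean = c(0.2, 0.4),
                                          weight = c(0.5, 0.5)),
                      n_frames = 600L, donor_bleach_lifetime = 150,
                      acceptor_bleach_lifetime = 250)
  set.seed(21)
  aggs <- lapply(1:30, function(i)
    simulate_aggregate(cfg, c(1L, 2L), sprintf("agg_%02d", i))$trace)
  fts <- qc_select(do.call(rbind, aggs))
  rejected <- mean(!vapply(fts, `[[`, logical(1), "qc_pass"))
  expect_gte(rejected, 0.9)
})

test_that("mean FRET ignores everything after the bleach frame", {
  # identical pre-bleach signal, wildly different post-bleach garbage
  pre <- rep(0.25, 200)
  tr1 <- manual_trace(pre, bleach_at = 151)
  tr2 <- manual_trace(pre, bleach_at = 151)
  tr2$I_A[160:200] <- 500  # corrupt only post-bleach frames
  tr2$I_D[160:200] <- 500
  f1 <- qc_select(tr1)[[1]]
  f2 <- qc_select(tr2)[[1]]
  expect_true(isTRUE(f1$qc_pass))
  expect_equal(f1$mean_fret, 0.25, tolerance = 1e-12)
  if (isTRUE(f2$qc_pass)) expect_equal(f2$mean_fret, f1$mean_fret)
})

test_that("static and dynamic traces are told apart", {
  # constant-state trace: static
  tr <- manual_trace(rep(0.3, 300), bleach_at = 281)
  tr$I_D <- tr$I_D + c(rnorm(280, 0, 5), rnorm(20, 0, 5))
  tr$I_A <- tr$I_A + rnorm(300, 0, 5)
  ft <- classify_static(qc_select(tr)[[1]])
  expect_true(ft$is_static)
  # two-state trace alternating 0.2/0.6 every 100 frames: dynamic
  E <- rep(rep(c(0.2, 0.6), each = 100), length.out = 500)
  tr2 <- manual_trace(E, bleach_at = 481)
  tr2$I_D <- tr2$I_D + rnorm(500, 0, 4)
  tr2$I_A <- tr2$I_A + rnorm(500, 0, 4)
  ft2 <- classify_static(qc_select(tr2)[[1]])
  expect_false(ft2$is_static)
  # too-short pre-bleach region: indeterminate, flagged
  tr3 <- manual_trace(rep(0.3, 100), bleach_at = 16)
  tr3$I_D <- tr3$I_D + rnorm(100, 0, 3)
  tr3$I_A <- tr3$I_A + rnorm(100, 0, 3)
  f3 <- qc_select(tr3, qc_policy(min_prebleach_frames = 5L))[[1]]
  if (isTRUE(f3$qc_pass)) {
    f3 <- classify_static(f3, min_dwell = 10L)
    expect_true(is.na(f3$is_static))
  }
})

test_that("nearly all molecules of a single-state ensemble classify static", {
  cfg <- fixture_config("stemI-stemII", "naked", seed = 13L)
  ens <- simulate_ensemble(cfg, assignment = "proportional")
  fts <- classify_static_ensemble(qc_select(ens$traces))
  passed <- Filter(function(ft) isTRUE(ft$qc_pass), fts)
  flags <- vapply(passed, `[[`, logical(1), "is_static")
  # molecules bleaching too fast for dynamics to be assessable are flagged
  # NA and excluded from the determinate static fraction
  expect_gte(mean(flags, na.rm = TRUE), 0.95)
  expect_lt(mean(is.na(flags)), 0.15)
})
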