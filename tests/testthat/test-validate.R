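test_that("cell equivalence applies 5% length and 1.5 degree tolerances", {
  a <- unit_cell(57.8, 57.8, 150.1)
  expect_true(cells_equivalent(a, a))
  scaled04 <- unit_cell(57.8 * 1.04, 57.8, 150.1)
  scaled06 <- unit_cell(57.8 * 1.06, 57.8, 150.1)
  expect_true(cells_equivalent(a, scaled04))
  expect_false(cells_equivalent(a, scaled06))
  gamma2 <- unit_cell(57.8, 57.8, 150.1, 90, 90, 92)
  expect_false(cells_equivalent(a, gamma2))
  gamma1 <- unit_cell(57.8, 57.8, 150.1, 90, 90, 91)
  expect_true(cells_equivalent(a, gamma1))
  # symmetry
  set.seed(31)
  for (i in 1:10) {
    b <- unit_cell(57.8 * runif(1, 0.9, 1.1), 57.8, 150.1,
                   90, 90, runif(1, 88, 92))
    expect_equal(cells_equivalent(a, b), cells_equivalent(b, a))
  }
})

test_that("spot integration is a background-subtracted disc sum", {
  radii <- integration_radii()  # 3, 4, 5
  expect_equal(integrate_spot(matrix(9, 40, 40), c(20, 20), radii), 0)
  # disc of value 10 on zero background: 10 * n_int
  fr <- matrix(0, 40, 40)
  dist <- sqrt(outer(((1:40) - 1 - 20)^2, ((1:40) - 1 - 20)^2, "+"))
  fr[dist <= 3] <- 10
  n_int <- sum(dist <= 3)
  expect_equal(integrate_spot(fr, c(20, 20), radii), 10 * n_int)
  # linearity without masking
  set.seed(14)
  f1 <- matrix(rpois(1600, 20), 40, 40)
  f2 <- matrix(rpois(1600, 5), 40, 40)
  expect_equal(integrate_spot(f1 + f2, c(17.2, 21.4), radii),
               integrate_spot(f1, c(17.2, 21.4), radii) +
                 integrate_spot(f2, c(17.2, 21.4), radii))
  expect_error(integrate_spot(f1, c(2, 2), radii), "edge")
  expect_true(is.na(integrate_spot(f1, c(20, 20), radii,
                                   mask = matrix(TRUE, 40, 40))))
})

test_that("background-only integrations stay within the noise band", {
  set.seed(6)
  radii <- integration_radii()
  n_int <- sum(sqrt(outer((-5:5)^2, (-5:5)^2, "+")) <= 3)
  bg_sigma <- sqrt(20) * 5  # Poisson(20) photons at gain 5
  vals <- replicate(100, {
    fr <- matrix(rpois(3600, 20) * 5, 60, 60)
    integrate_spot(fr, c(runif(1, 10, 49), runif(1, 10, 49)), radii)
  })
  expect_gte(mean(abs(vals) < 5 * bg_sigma * sqrt(n_int)), 0.95)
})

test_that("match_fraction is greedy, one-to-one and order-invariant", {
  obs <- data.frame(fast = c(10, 30, 50), slow = c(10, 30, 50),
                    n_pixels = 2L, intensity = c(5, 9, 1), snr = 10,
                    d = c(3, 2.5, 2))
  pred <- data.frame(fast = c(10, 30, 50), slow = c(10, 30, 50),
                     d = c(3, 2.5, 2))
  expect_equal(match_fraction(pred, obs, 3), 1)
  expect_equal(match_fraction(pred, obs[0, ], 3), 0)
  expect_equal(match_fraction(pred[0, ], obs, 3), 0)
  # two predictions near one observed peak: only one can claim it
  pred2 <- data.frame(fast = c(10, 11), slow = c(10, 10), d = c(3, 2.9))
  expect_equal(match_fraction(pred2, obs, 3), 0.5)
  # permuting both lists never changes the fraction
  set.seed(17)
  predr <- data.frame(fast = runif(20, 0, 100), slow = runif(20, 0, 100),
                      d = runif(20, 2, 6))
  obsr <- data.frame(fast = runif(15, 0, 100), slow = runif(15, 0, 100),
                     n_pixels = 2L, intensity = runif(15), snr = 10,
                     d = runif(15, 2, 6))
  base <- match_fraction(predr, obsr, 5)
  for (i in 1:5) {
    expect_equal(match_fraction(predr[sample(20), ], obsr[sample(15), ], 5),
                 base)
  }
})

test_that("true solutions are supported and foreign cells are not", {
  set.seed(23)
  run <- quick_run(seed = 101, duration_s = 4,
                   sample = default_sample("thaumatin"))
  geom <- run$config$geometry
  mp <- match_params()
  single <- run$events$event_id[run$events$n_crystals == 1 &
                                  run$events$n_true_peaks >= 15]
  expect_gte(length(single), 3)
  foreign <- default_sample("proteinase_k")$cell
  n_trials <- 0; n_foreign_low <- 0
  for (ev in single[1:min(8, length(single))]) {
    obs <- truth_peak_list(run, ev)
    cry <- run$crystals[run$crystals$event_id == ev, ]
    R <- matrix(as.numeric(cry[1, paste0("r", rep(1:3, each = 3),
                                         rep(1:3, 3))]),
                3, byrow = TRUE)
    pred <- predict_reflections(run$config$sample$cell, R, geom,
                                run$config$excitation_tol, run$config$d_min)
    expect_gte(match_fraction(pred, obs, mp$position_tolerance), 0.8)
    for (k in 1:3) {
      predf <- predict_reflections(foreign, random_rotation(), geom,
                                   run$config$excitation_tol,
                                   run$config$d_min)
      n_trials <- n_trials + 1
      if (match_fraction(predf, obs, mp$position_tolerance) <
            mp$support_fraction) {
        n_foreign_low <- n_foreign_low + 1
      }
    }
  }
  expect_gte(n_foreign_low / n_trials, 0.95)
})

test_that("the contamination audit clears a single-sample run", {
  set.seed(29)
  run <- quick_run(seed = 55, duration_s = 3)
  cells <- list(thaumatin = default_sample("thaumatin")$cell,
                proteinase_k = default_sample("proteinase_k")$cell)
  ids <- run$events$event_id[run$events$n_true_peaks >= 15]
  peaks <- setNames(lapply(ids, function(ev) truth_peak_list(run, ev)),
                    as.character(ids))
  sol <- audit_solutions(run, cells, event_ids = ids)
  truth <- setNames(rep("thaumatin", length(ids)), as.character(ids))
  audit <- contamination_audit(peaks, sol, cells, run$config$geometry,
                               true_labels = truth)
  expect_equal(audit$n_foreign_only, 0L)
  own <- audit$table[audit$table$cell_label == "thaumatin", ]
  expect_true(all(own$supported))
  # empty audit
  empty <- contamination_audit(list(), sol[0, ], cells,
                               run$config$geometry)
  expect_equal(nrow(empty$table), 0)
})

test_that("a mixed run is supported by each event's own cell", {
  set.seed(37)
  runA <- quick_run(seed = 61, duration_s = 2,
                    sample = default_sample("thaumatin"))
  runB <- quick_run(seed = 62, duration_s = 2,
                    sample = default_sample("xylanase"))
  cells <- list(thaumatin = default_sample("thaumatin")$cell,
                xylanase = default_sample("xylanase")$cell)
  audit_one <- function(run, own_label, offset) {
    ids <- run$events$event_id[run$events$n_true_peaks >= 15][1:3]
    peaks <- setNames(lapply(ids, function(ev) truth_peak_list(run, ev)),
                      as.character(ids))
    sol <- audit_solutions(run, cells, event_ids = ids)
    truth <- setNames(rep(own_label, length(ids)), as.character(ids))
    contamination_audit(peaks, sol, cells, run$config$geometry,
                        true_labels = truth)
  }
  a <- audit_one(runA, "thaumatin")
  b <- audit_one(runB, "xylanase")
  expect_equal(a$n_foreign_only, 0L)
  expect_equal(b$n_foreign_only, 0L)
  own_a <- a$table[a$table$cell_label == "thaumatin", "supported"]
  own_b <- b$table[b$table$cell_label == "xylanase", "supported"]
  expect_true(all(own_a))
  expect_true(all(own_b))
})
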