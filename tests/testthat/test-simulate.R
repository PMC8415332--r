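test_that("crystal occupancy is Poisson in the probed volume", {
  set.seed(3)
  expect_true(all(draw_crystal_count(0, 0.25, n = 100) == 0))
  # CLT bound on the sample mean at lambda = 0.5
  x <- draw_crystal_count(2, 0.25, n = 1e5)
  expect_lt(abs(mean(x) - 0.5), 3 * sqrt(0.5 / 1e5))
  # a full 0.25 nl probed at 400 crystals/nl averages 100 crystals
  y <- draw_crystal_count(400, 0.25, n = 2e4)
  expect_lt(abs(mean(y) - 100), 3 * sqrt(100 / 2e4))
  # chi-squared goodness of fit at alpha = 0.01, lambda = 2
  z <- draw_crystal_count(4, 0.5, n = 1e4)
  ks <- 0:8
  obs <- tabulate(pmin(z, 8) + 1, nbins = 9)
  p <- dpois(ks, 2); p[9] <- 1 - ppois(7, 2)
  chi2 <- sum((obs - 1e4 * p)^2 / (1e4 * p))
  expect_lt(chi2, qchisq(0.99, df = 8))
})

test_that("predicted reflections match brute-force lattice enumeration", {
  # independent oracle: plain loops over all |h|,|k|,|l| <= ceil(a/d_min)
  # with textbook formulas, no shared code path
  geom <- small_geom()
  cell <- unit_cell(100, 100, 100, label = "toy-cubic")
  d_min <- 2; tol <- 5e-4
  set.seed(21)
  R <- random_rotation()
  got <- predict_reflections(cell, R, geom, tol, d_min)

  lam <- geom$wavelength
  hmax <- ceiling(100 / d_min)
  hs <- expand.grid(h = -hmax:hmax, k = -hmax:hmax, l = -hmax:hmax)
  hs <- hs[rowSums(abs(hs)) > 0, ]
  q0 <- rbind(hs$h / 100, hs$k / 100, hs$l / 100)  # cubic: B = I/a
  q <- R %*% q0
  qlen <- sqrt(colSums(q^2))
  kmag <- 1 / lam
  exc <- abs(sqrt(q[1, ]^2 + q[2, ]^2 + (q[3, ] + kmag)^2) - kmag)
  keep <- qlen <= 1 / d_min & exc <= tol
  kz <- q[3, keep] + kmag
  fast <- geom$beam_center[1] + geom$detector_distance_mm *
    q[1, keep] / kz / (geom$pixel_pitch_um * 1e-3)
  slow <- geom$beam_center[2] + geom$detector_distance_mm *
    q[2, keep] / kz / (geom$pixel_pitch_um * 1e-3)
  inside <- kz > 0 & fast >= 0 & fast <= geom$frame_shape[2] - 1 &
    slow >= 0 & slow <= geom$frame_shape[1] - 1
  want <- data.frame(h = hs$h[keep][inside], k = hs$k[keep][inside],
                     l = hs$l[keep][inside],
                     fast = fast[inside], slow = slow[inside])

  expect_gt(nrow(got), 0)
  expect_equal(nrow(got), nrow(want))
  key <- function(df) paste(df$h, df$k, df$l)
  expect_setequal(key(got), key(want))
  m <- match(key(want), key(got))
  expect_equal(got$fast[m], want$fast, tolerance = 1e-9)
  expect_equal(got$slow[m], want$slow, tolerance = 1e-9)
})

test_that("predicted reflections respect d_min, frame bounds and tolerance", {
  geom <- beamline_geometry()
  cell <- default_sample("thaumatin")$cell
  set.seed(5)
  for (i in 1:3) {
    p <- predict_reflections(cell, random_rotation(), geom,
                             excitation_tol = 2e-4, d_min = 2)
    expect_true(all(p$d >= 2))
    expect_true(all(p$fast >= 0 & p$fast <= geom$frame_shape[2] - 1))
    expect_true(all(p$slow >= 0 & p$slow <= geom$frame_shape[1] - 1))
  }
  # measure-zero Ewald intersection at vanishing tolerance
  p0 <- predict_reflections(cell, random_rotation(), geom,
                            excitation_tol = 1e-12, d_min = 2)
  expect_lte(nrow(p0), 1)
})

test_that("render_frame composes peaks, rings and noise as specified", {
  geom <- small_geom()
  dark <- sim_config(geometry = geom, duration_s = 1,
                     ring_bands = list(), background_level = 0,
                     noise_model = FALSE)
  expect_true(all(render_frame(NULL, dark) == 0L))

  # noise off: integrated ADU of a single peak equals the Debye-Waller
  # scaled mass within 1%
  s <- default_sample("thaumatin")
  cfg <- sim_config(geometry = geom, sample = s, ring_bands = list(),
                    background_level = 0, noise_model = FALSE)
  pred <- data.frame(fast = 120.3, slow = 118.7, d = 2.5)
  fr <- render_frame(pred, cfg)
  expected <- cfg$gain * s$peak_scale_i0 * exp(-s$b_factor / (2 * 2.5^2))
  expect_lt(abs(sum(fr) - expected) / expected, 0.01)

  # ring: azimuthal mean maximal at the predicted radius +- 1 px
  rcfg <- sim_config(geometry = geom, ring_bands = list(c(2.09, 2, 30)),
                     background_level = 0, noise_model = FALSE)
  fr2 <- render_frame(NULL, rcfg)
  r <- round(radius_map(geom))
  prof <- tapply(as.numeric(fr2), as.numeric(r), mean)
  rmax <- as.numeric(names(prof))[which.max(prof)]
  expect_lt(abs(rmax - d_to_ring_radius(geom, 2.09)), 1.5)
})

test_that("simulate_run honours clock, blanks, depletion and determinism", {
  cfg <- sim_config(duration_s = 10, seed = 9, render = FALSE)
  run <- simulate_run(cfg)
  expect_equal(nrow(run$events), 100)  # 10 s at 10 Hz
  expect_equal(run$events$time_s, (0:99) / 10)

  all_miss <- simulate_run(sim_config(
    drop = drop_model(miss_probability = 1), duration_s = 3, seed = 1,
    render = FALSE))
  expect_true(all(all_miss$events$is_blank))
  expect_equal(sum(all_miss$events$n_crystals), 0)
  expect_equal(nrow(all_miss$truth_peaks), 0)

  dep <- simulate_run(sim_config(duration_s = 4, seed = 2,
                                 depletion_time_s = 2, render = FALSE))
  late <- dep$events$time_s >= 2
  expect_true(all(dep$events$is_buffer[late]))
  expect_true(all(dep$events$n_crystals[late] == 0))

  again <- simulate_run(cfg)
  expect_identical(run$events, again$events)
  expect_identical(run$truth_peaks, again$truth_peaks)

  # blank events carry no ground-truth peaks; all truth d >= d_min
  blanks <- run$events$event_id[run$events$is_blank]
  expect_false(any(run$truth_peaks$event_id %in% blanks))
  expect_true(all(run$truth_peaks$d >= cfg$d_min))
})

test_that("rendered frames are reproducible for a fixed seed", {
  cfg <- sim_config(geometry = small_geom(), duration_s = 0.3, seed = 77)
  a <- simulate_run(cfg); b <- simulate_run(cfg)
  expect_identical(a$frames, b$frames)
})

test_that("a run round-trips through its on-disk form", {
  run <- simulate_run(sim_config(geometry = small_geom(),
                                 duration_s = 0.5, seed = 4))
  d <- tempfile("run_")
  write_run(run, d)
  ev <- read.csv(file.path(d, "events.csv"))
  expect_equal(ev$event_id, run$events$event_id)
  expect_equal(ev$n_crystals, run$events$n_crystals)
  st <- read_frames(file.path(d, "frames.rds"))
  expect_identical(st$frames, run$frames)
  expect_identical(st$event_id, run$events$event_id)
  cfg <- jsonlite::read_json(file.path(d, "config.json"))
  expect_equal(cfg$seed, 4)
  expect_error(read_frames(file.path(d, "nope.rds")), "not found")
})
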