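run_stats <- function() {
  read.delim(system.file("extdata", "dod_run_stats.tsv",
                         package = "dropsfx"))
}

correct_col <- c(thaumatin = "indexed_th", proteinase_k = "indexed_pk",
                 xylanase = "indexed_xy",
                 alcohol_dehydrogenase = "indexed_ad")

test_that("hit rate is a plain percentage with guarded denominator", {
  expect_equal(hit_rate(0, 100), 0)
  expect_equal(hit_rate(100, 100), 100)
  expect_equal(hit_rate(1109, 4384), 100 * 1109 / 4384)
  expect_equal(round(hit_rate(1109, 4384), 1), 25.3)
  expect_error(hit_rate(0, 0), "undefined")
})

test_that("crystal indexing rate handles multi-crystal counts and empty runs", {
  expect_equal(round(crystal_indexing_rate(271, 1083)$rate, 1), 25.0)
  expect_equal(round(crystal_indexing_rate(266, 363)$rate, 1), 73.3)
  r0 <- crystal_indexing_rate(0, 0)
  expect_equal(r0$rate, 0)
  expect_true(r0$undefined)
  # crystal-level counting can exceed 100%
  expect_gt(crystal_indexing_rate(150, 100)$rate, 100)
})

test_that("event indexing rate counts multi-crystal hits once", {
  is_hit <- rep(TRUE, 10)
  idx <- c(3L, 1L, 1L, 1L, rep(0L, 6))  # 4 indexed events, one with 3 lattices
  expect_equal(event_indexing_rate(is_hit, idx)$rate, 40)
  expect_true(event_indexing_rate(logical(5), integer(5))$undefined)
  expect_equal(event_indexing_rate(rep(TRUE, 4), rep(1L, 4))$rate, 100)
})

test_that("published per-run statistics are reproduced exactly", {
  tab <- run_stats()
  for (i in seq_len(nrow(tab))) {
    n_idx <- tab[[correct_col[[tab$sample[i]]]]][i]
    got <- crystal_indexing_rate(n_idx, tab$n_hits[i])
    shown <- if (got$undefined) 0 else
      dropsfx:::round_half_away(got$rate, 1)
    expect_equal(shown, tab$indexing_rate_pct[i],
                 info = paste("run", tab$run[i]))
  }
  # event-level rate never exceeds the crystal-level rate when every
  # indexed event carries at least one crystal
  set.seed(19)
  for (k in 1:20) {
    n <- 50
    lat <- rpois(n, 0.7)
    is_hit <- rep(TRUE, n)
    ev <- event_indexing_rate(is_hit, lat)$rate
    cr <- crystal_indexing_rate(sum(lat), n)$rate
    expect_lte(ev, cr)
  }
})

test_that("run_summary reports counts, rates and guarded averages", {
  mk_events <- function(n_hits, n_miss, idx_per_hit = 1L,
                        label = "thaumatin") {
    rows <- lapply(seq_len(n_hits + n_miss), function(i) {
      hit <- i <= n_hits
      event_record(
        event_id = i - 1L, time_s = (i - 1) / 10,
        n_peaks = if (hit) 20L else 0L, is_hit = hit,
        mean_peak_intensity = if (hit) 900 else NA_real_,
        indexed_crystals = if (hit && idx_per_hit > 0)
          setNames(as.integer(idx_per_hit), label) else integer(0),
        resolution_limit = if (hit) 3.0 else NA_real_)
    })
    do.call(rbind, rows)
  }
  run <- run_table("r1", "thaumatin", mk_events(10, 30), 4)
  s <- run_summary(run)
  expect_equal(s$n_events, 40)
  expect_equal(s$n_hits, 10)
  expect_equal(s$hit_rate_pct, 25.0)
  expect_equal(s$indexing_rate_pct, 100)
  expect_equal(s$avg_n_peaks, 20)
  expect_equal(s$avg_peak_intensity_adu, 900)
  expect_equal(s$avg_resolution_limit, 3.0)

  # the printed 92.0 arises from 709 indexed / 771 hits
  expect_equal(dropsfx:::round_half_away(
    crystal_indexing_rate(709, 771)$rate, 1), 92.0)

  blanks <- run_table("r2", "thaumatin", mk_events(0, 20), 2)
  sb <- run_summary(blanks)
  expect_equal(sb$n_hits, 0)
  expect_true(sb$indexing_rate_undefined)
  expect_equal(sb$indexing_rate_pct, 0)
  expect_true(is.na(sb$avg_n_peaks))
  expect_true(is.na(sb$avg_peak_intensity_adu))

  single <- run_table("r3", "thaumatin", mk_events(1, 0), 1)
  ss <- run_summary(single)
  expect_equal(ss$avg_n_peaks, 20)
  expect_equal(ss$avg_peak_intensity_adu, 900)
})

test_that("display rounding is one decimal, half away from zero", {
  expect_equal(dropsfx:::round_half_away(25.05), 25.1)
  expect_equal(dropsfx:::round_half_away(-25.05), -25.1)
  expect_equal(dropsfx:::round_half_away(100 * 271 / 1083), 25.0)
})

test_that("binned series preserves totals and exposes inter-run gaps", {
  mk_run <- function(run_id, start, n, hit_every = 2) {
    rows <- lapply(seq_len(n), function(i) {
      hit <- i %% hit_every == 0
      event_record(event_id = i - 1L, time_s = (i - 1) / 10,
                   n_peaks = if (hit) 20L else 0L, is_hit = hit,
                   indexed_crystals = if (hit) c(thaumatin = 1L)
                   else integer(0))
    })
    run_table(run_id, "thaumatin", do.call(rbind, rows),
              duration_s = n / 10, start_s = start)
  }
  r1 <- mk_run("31", 0, 300)      # 30 s
  r2 <- mk_run("32", 30 + 139, 300)  # after a 139 s wash interval
  bs <- binned_series(list(r1, r2), bin_width_s = 10)
  expect_gte(sum(!bs$valid), 13)
  expect_equal(sum(bs$n_hits, na.rm = TRUE),
               sum(r1$events$is_hit) + sum(r2$events$is_hit))
  expect_equal(sum(bs$n_events), 600)
  # constant hit pattern -> flat occupied series
  flat <- binned_series(list(r1), bin_width_s = 10)
  expect_true(all(abs(flat$hit_rate_pct[flat$valid] - 50) < 1e-9))
  # overlapping runs are rejected
  expect_error(binned_series(list(r1, mk_run("x", 10, 100)), 10),
               "overlap")
  # hit-free bins are flagged, not zero-filled
  r3 <- mk_run("33", 0, 100, hit_every = 1e9)
  b3 <- binned_series(list(r3), 5)
  expect_true(all(is.na(b3$event_indexing_rate_pct[b3$valid])))
})
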