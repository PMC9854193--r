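test_that("normalized intensity is background-ratio arithmetic", {
  expect_equal(normalized_intensity(100, 100), 0)
  expect_equal(normalized_intensity(300, 100), 2)
  expect_equal(normalized_intensity(300, 100, identified = FALSE), 0)
  expect_error(normalized_intensity(300, 0), "roi2_mean")
  expect_error(normalized_intensity(300, -5), "roi2_mean")
})

test_that("normalization is invariant to any joint multiplicative gain", {
  set.seed(1)
  roi1 <- runif(50, 100, 400)
  roi2 <- runif(50, 50, 150)
  for (gain in c(0.2, 1, 3.7, 100)) {
    expect_equal(normalized_intensity(gain * roi1, gain * roi2),
                 normalized_intensity(roi1, roi2), tolerance = 1e-12)
  }
})

test_that("SNR is background-noise-scaled peak height", {
  expect_equal(snr(150, 50, 10), 10)
  expect_equal(snr(50, 50, 10), 0)
  expect_error(snr(150, 50, 0), "bg_sd")
})

test_that("ROI measurement behaves on flat and single-pixel images", {
  flat <- list(matrix(7, 31, 31))
  m <- measure_movie(flat, data.frame(x = 16, y = 16),
                     roi1_diameter_um = 0.6, pixel_size_um = 0.1)
  expect_equal(m$roi1_max, 7)
  expect_equal(m$roi2_mean, 7)
  expect_equal(normalized_intensity(m$roi1_max, m$roi2_mean), 0)

  img <- matrix(10, 31, 31)
  img[16, 16] <- 10 + 55  # amplitude A over background B at the center
  m2 <- measure_movie(list(img), data.frame(x = 16, y = 16),
                      roi1_diameter_um = 0.6, pixel_size_um = 0.1)
  expect_equal(m2$roi1_max, 65)
  expect_equal(m2$roi2_mean, 10)
})

test_that("multiplicative decay leaves the normalized movie trace flat", {
  mv <- gen_spot_movie(data.frame(x = 16, y = 16, amplitude = 50,
                                  width = 1.5),
                       dim_px = c(32, 32), background_mean = 100,
                       noise_sd = 0, n_frames = 20,
                       bleach_tau_frames = 8, seed = 2)
  m <- measure_movie(mv, data.frame(x = 16, y = 16),
                     roi1_diameter_um = 0.8, pixel_size_um = 0.1)
  norm <- normalized_intensity(m$roi1_max, m$roi2_mean)
  expect_lt(max(abs(norm - norm[1])) / norm[1], 0.01)
  # while the raw signal decays by orders of magnitude
  expect_lt(m$roi1_max[20] / m$roi1_max[1], 0.1)
})

test_that("initiation detection debounces and respects the threshold", {
  times <- 0:9 * 5
  expect_true(is.na(detect_initiation(rep(0, 10), times, threshold = 0.3)))
  spike <- c(0, 0, 5, 0, 0, 0, 0, 0, 0, 0)
  expect_true(is.na(detect_initiation(spike, times, threshold = 0.3,
                                      min_consecutive = 2)))
  ramp <- c(0, 0, 0, 1, 2, 3, 3, 3, 3, 3)
  expect_equal(detect_initiation(ramp, times, threshold = 0.5), 15)
  expect_error(detect_initiation(numeric(0), numeric(0)), "empty")
})

test_that("initiation time is monotone in the threshold", {
  set.seed(7)
  for (rep_i in 1:20) {
    vals <- cumsum(abs(rnorm(40, 0.1, 0.2)))
    times <- seq_along(vals)
    t_lo <- detect_initiation(vals, times, threshold = 0.5)
    t_hi <- detect_initiation(vals, times, threshold = 2)
    if (!is.na(t_lo) && !is.na(t_hi)) expect_gte(t_hi, t_lo)
    if (is.na(t_lo)) expect_true(is.na(t_hi))
  }
})

test_that("paired traces built at 20 and 42 min differ by 22 min", {
  sim <- gen_trace_pairs(n_cells = 1, n_timepoints = 80, dt_min = 2,
                         offset_mean_min = 22, offset_sd_min = 0,
                         t_first_on_min = 20, intrinsic_sd = 0,
                         extrinsic_sd = 0, fluct_sd = 0, meas_cv = 0,
                         seed = 5)
  rec <- activation_records(sim$traces, threshold = 0.05)
  expect_equal(rec$pattern, "sequential")
  expect_equal(rec$time_difference, 22)
})

test_that("activation classification partitions every pair", {
  expect_equal(classify_activation(NA, NA)$pattern, "none")
  expect_equal(classify_activation(10, NA)$pattern, "one_allele")
  expect_equal(classify_activation(NA, 12)$pattern, "one_allele")
  expect_equal(classify_activation(10, 10)$pattern, "same_time")
  expect_equal(classify_activation(10, 14, same_time_window = 5)$pattern,
               "same_time")
  expect_equal(classify_activation(10, 40, same_time_window = 5)$pattern,
               "sequential")
  grid <- expand.grid(t1 = c(NA, 0, 10, 30), t2 = c(NA, 0, 10, 30))
  pats <- mapply(function(a, b) classify_activation(a, b)$pattern,
                 grid$t1, grid$t2)
  expect_true(all(pats %in% c("none", "one_allele", "same_time",
                              "sequential")))
})

test_that("single-allele activation appears at the generator rate", {
  sim <- gen_trace_pairs(n_cells = 150, n_timepoints = 100, dt_min = 2,
                         offset_mean_min = 20, offset_sd_min = 10,
                         p_silent_second_allele = 0.38, seed = 8)
  rec <- activation_records(sim$traces)
  frac <- mean(rec$pattern == "one_allele")
  expect_lt(abs(frac - 0.38), 3 * sqrt(0.38 * 0.62 / 150))
})

test_that("plateau time works on steps, ramps and generator cohorts", {
  times <- 0:40 * 1
  step <- c(rep(0, 10), rep(5, 31))
  expect_equal(plateau_time(step, times, smooth_window = 1), 10)
  ramp <- seq(0, 1, length.out = 41)  # max at t = 40
  expect_equal(plateau_time(ramp, times, smooth_window = 1), 36)
  expect_true(is.na(plateau_time(rep(0, 41), times)))

  mean_plateau <- function(pt, seed) {
    sim <- gen_trace_pairs(n_cells = 20, n_timepoints = 150, dt_min = 2,
                           offset_mean_min = 0, offset_sd_min = 0,
                           t_first_on_min = 10, plateau_time_min = pt,
                           fluct_sd = 0, meas_cv = 0, seed = seed)
    tr <- sim$traces
    tr$normalized <- normalized_intensity(tr$roi1_max, tr$roi2_mean)
    mean(vapply(unique(tr$cell_id), function(cid) {
      al <- tr[tr$cell_id == cid & tr$allele == 1, ]
      plateau_time(al$normalized, al$t_min)
    }, 0))
  }
  # analytic expectation: initiation at 10 min + 90% of the ramp
  expect_equal(mean_plateau(180, 21), 10 + 0.9 * 180, tolerance = 0.1)
  expect_equal(mean_plateau(25, 22), 10 + 0.9 * 25, tolerance = 0.2)
})

test_that("memory statistics summarize and test the cohorts", {
  rec <- data.frame(cycle = c("a", "a", "a", "b", "b", "b"),
                    time_difference = c(5, 5, 5, 5, 5, 5))
  ms <- memory_statistics(rec)
  expect_equal(ms$per_group$sd, c(0, 0))
  expect_equal(ms$test$p.value, 1)  # identical groups

  sim <- gen_trace_pairs(n_cells = 55, n_timepoints = 150, dt_min = 2,
                         offset_mean_min = 44.2, offset_sd_min = 33.5,
                         seed = 30)
  rec2 <- activation_records(sim$traces)
  m <- mean(rec2$time_difference, na.rm = TRUE)
  expect_lt(abs(m - 44.2), 2 * 33.5 / sqrt(55))
})
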