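test_that("track filtering enforces the consecutive-frame minimum", {
  mk <- function(id, frames) data.frame(track_id = id, frame = frames,
                                        t_s = frames * 0.01,
                                        x_um = 0, y_um = 0)
  tab <- rbind(mk("a", 0:18), mk("b", 0:19), mk("c", 0:50))
  out <- filter_tracks(tab, min_frames = 20)
  expect_setequal(unique(out$track_id), c("b", "c"))
  # a long track with a gap only counts its longest consecutive run
  gap <- mk("d", c(0:9, 20:29))
  expect_equal(nrow(filter_tracks(gap, min_frames = 20)), 0)
  expect_warning(out2 <- filter_tracks(tab[0, ]), "empty")
  expect_equal(nrow(out2), 0)
  bad <- mk("e", 0:25); bad$x_um[3] <- NaN
  expect_warning(filter_tracks(bad), "malformed")
})

test_that("MSD matches closed forms and the brute-force double loop", {
  # identical positions
  still <- trajectory(data.frame(x_um = rep(1, 30), y_um = rep(2, 30)),
                      dt = 0.01)
  expect_true(all(compute_msd(still, 10)$msd == 0))
  # straight line x = v t: MSD(t) = (v t)^2 exactly
  v <- 1.7; n <- 50
  line <- trajectory(data.frame(x_um = v * (0:(n - 1)) * 0.01,
                                y_um = 0), dt = 0.01)
  m <- compute_msd(line, 10)
  expect_equal(m$msd, (v * m$t_s)^2, tolerance = 1e-12)
  # brute-force equality on random walks
  for (seed in 1:5) {
    tr <- gen_trajectory("diffusive", n_frames = 100, dt = 0.01,
                         D_micro = 0.3, sigma_loc = 0.02, seed = seed)
    m2 <- compute_msd(tr, 30)
    expect_equal(m2$msd, oracle_msd(tr, 30), tolerance = 1e-12)
  }
  expect_warning(compute_msd(still, 100), "truncated")
  expect_error(compute_msd(still[1, ], 1), "2 frames")
})

test_that("gyration ratio reads track anisotropy", {
  coll <- trajectory(data.frame(x_um = 1:10, y_um = 2 * (1:10) + 3),
                     dt = 0.01)
  expect_equal(as.numeric(gyration_ratio(coll)), 0, tolerance = 1e-10)
  square <- trajectory(data.frame(x_um = c(0, 1, 1, 0),
                                  y_um = c(0, 0, 1, 1)), dt = 0.01)
  expect_equal(as.numeric(gyration_ratio(square)), 1)
  # hand eigen-decomposition: points (0,0), (1,0), (1,1) give population
  # covariance [[2/9, 1/9], [1/9, 2/9]], eigenvalues 1/3 and 1/9,
  # radii ratio sqrt(1/3)
  tri <- trajectory(data.frame(x_um = c(0, 1, 1), y_um = c(0, 0, 1)),
                    dt = 0.01)
  expect_equal(as.numeric(gyration_ratio(tri)), sqrt(1 / 3),
               tolerance = 1e-12)
  expect_equal(as.numeric(gyration_ratio(tri, of = "eigenvalues")), 1 / 3,
               tolerance = 1e-12)
  degen <- trajectory(data.frame(x_um = rep(1, 5), y_um = rep(1, 5)),
                      dt = 0.01)
  expect_equal(as.numeric(gyration_ratio(degen)), 1)
  expect_true(attr(gyration_ratio(degen), "degenerate"))
})

test_that("max displacement is the largest pairwise distance", {
  tr <- trajectory(data.frame(x_um = c(0, 3, 1, 0), y_um = c(0, 4, 1, 1)),
                   dt = 0.01)
  expect_equal(max_displacement(tr), 5)
  long <- gen_trajectory("diffusive", n_frames = 300, dt = 0.01,
                         D_micro = 0.3, seed = 2)
  expect_equal(max_displacement(long),
               max(dist(cbind(long$x_um, long$y_um))))
})

test_that("model fits are self-consistent on noiseless curves", {
  dt <- 0.01
  t <- (1:10) * dt
  # exact confinement curve, L = 0.5, tau = 0.074
  L <- 0.5; tau <- 0.074
  curve_conf <- structure(
    data.frame(lag = 1:10, t_s = t, msd = (L^2 / 3) * (1 - exp(-t / tau)),
               n_pairs = 100), dt = dt,
    class = c("msd_curve", "data.frame"))
  f1 <- fit_msd_models(curve_conf)
  expect_equal(f1$confined$L, L, tolerance = 0.01)
  expect_equal(f1$confined$tau, tau, tolerance = 0.01)
  expect_equal(f1$confined$D, L^2 / (12 * tau), tolerance = 0.02)
  # exact linear curve 4 D t
  D <- 0.2839
  curve_lin <- curve_conf; curve_lin$msd <- 4 * D * t
  f2 <- fit_msd_models(curve_lin)
  expect_equal(f2$powerlaw$alpha, 1, tolerance = 0.01)
  expect_equal(f2$powerlaw$D, D, tolerance = 0.01)
  # exact ballistic curve pushed through the power law: alpha -> 2
  v <- 3.1715
  curve_bal <- curve_conf; curve_bal$msd <- (v * t)^2
  f3 <- fit_msd_models(curve_bal)
  expect_equal(f3$powerlaw$alpha, 2, tolerance = 0.01)
  expect_equal(f3$directed$v, v, tolerance = 1e-6)
  expect_error(fit_msd_models(curve_conf, fit_lags = 1:3), "at least 4")
})

test_that("cohort parameter recovery hits the generator ground truth", {
  dt <- 0.01; n_frames <- 100; n_tracks <- 200
  # diffusive: Table-1-scale nuclear D
  D <- 0.2839
  trs <- gen_trajectory_cohort(n_tracks, "diffusive", n_frames, dt,
                               D_micro = D, seed = 1000)$trajectories
  rec <- recover_motion_parameters(trs, "diffusive")
  expect_equal(rec$D, D, tolerance = 0.05)
  expect_equal(rec$alpha, 1, tolerance = 0.1)
  # directed: nuclear directed speed
  v <- 3.1715
  trs2 <- gen_trajectory_cohort(n_tracks, "directed", n_frames, dt,
                                v = v, seed = 2000)$trajectories
  rec2 <- recover_motion_parameters(trs2, "directed")
  expect_equal(rec2$v, v, tolerance = 0.05)
  # corralled: derived D = L^2/(12 tau) within 10%
  Dc <- 0.2818
  trs3 <- gen_trajectory_cohort(n_tracks, "corralled", n_frames, dt,
                                D_micro = Dc, L_box = 0.5,
                                seed = 3000)$trajectories
  rec3 <- recover_motion_parameters(trs3, "corralled")
  expect_equal(rec3$D, Dc, tolerance = 0.10)
  # stationary: plateau is 4 sigma_loc^2
  trs4 <- gen_trajectory_cohort(n_tracks, "stationary", n_frames, dt,
                                sigma_loc = 0.02, seed = 4000)$trajectories
  rec4 <- recover_motion_parameters(trs4, "stationary")
  expect_equal(rec4$msd_plateau, 4 * 0.02^2, tolerance = 0.05)
})

test_that("ensemble MSD is the track-average of per-track MSDs", {
  trs <- gen_trajectory_cohort(5, "diffusive", 50, 0.01, D_micro = 0.2,
                               seed = 5)$trajectories
  em <- ensemble_msd(trs, 8)
  manual <- rowMeans(vapply(trs, function(tr)
    compute_msd(tr, 8)$msd, numeric(8)))
  expect_equal(em$msd, manual, tolerance = 1e-12)
})
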