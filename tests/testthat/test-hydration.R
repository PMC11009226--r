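test_that("ideal-gas trajectory gives g(r) = 1 within counting error", {
  tr <- simulate_trajectory(traj_gen_params(n_frames = 1000, n_waters = 500,
                                            box_length = 28, seed = 2))
  r <- rdf(tr, center_role = "OC", partner_role = "HW",
           bin_width = 0.2, r_max = 10)
  sel <- r$r >= 3 & r$r <= 10
  expected <- r$counts[sel] / r$g[sel]      # ideal-gas bin expectations
  z <- (r$counts[sel] - expected) / sqrt(expected)
  expect_lt(max(abs(z)), 3)                 # Poisson counting oracle
  expect_lt(abs(mean(r$g[sel]) - 1), 0.01)
  # coordination number matches the analytic sphere volume within 2%
  n_ideal <- r$rho * (4 / 3) * pi * 6^3
  expect_lt(abs(coordination_number(r, 6) / n_ideal - 1), 0.02)
})

test_that("RDF noise shrinks as 1/sqrt(sample size)", {
  spread <- function(frames, seed) {
    tr <- simulate_trajectory(traj_gen_params(n_frames = frames,
                                              n_waters = 200,
                                              box_length = 28, seed = seed))
    r <- rdf(tr, bin_width = 0.25, r_max = 10)
    sd(r$g[r$r >= 3 & r$r <= 10])
  }
  s_small <- spread(60, 21)
  s_large <- spread(540, 22)   # 9x the frames: expect ~3x less noise
  expect_gt(s_small / s_large, 1.8)
  expect_lt(s_small / s_large, 5)
})

test_that("designed shell puts the RDF peak and coordination where built", {
  tr <- simulate_trajectory(traj_gen_params(n_frames = 80, n_waters = 12,
                                            shell_model = "designed_shell",
                                            n_shell = 2, seed = 3))
  r <- rdf(tr, bin_width = 0.05, r_max = 6)
  expect_lt(abs(r$r[which.max(r$g)] - 1.65), 0.05)
  expect_lt(abs(coordination_number(r, 2.55) - 2), 0.02)
  # g(r) integration agrees with direct per-frame counting
  direct <- mean(vapply(tr$frames, function(f) {
    d <- chex2dir:::min_image_dist(f$coords[1, ],
                                   f$coords[tr$labels == "HW", ],
                                   tr$box_length)
    sum(d < 2.55)
  }, numeric(1)))
  expect_lt(abs(coordination_number(r, 2.55) - direct), 0.02)
  expect_error(coordination_number(r, 7), "range")
})

test_that("a single pinned partner occupies exactly one RDF bin", {
  co <- matrix(c(5, 5, 5,   5 + 1.83, 5, 5), 2, 3, byrow = TRUE)
  tr <- make_frame_traj(c("OC", "HW"), list(co), box = 20)
  r <- rdf(tr, bin_width = 0.05, r_max = 8)
  expect_equal(sum(r$counts > 0), 1L)
  expect_equal(r$counts[floor(1.83 / 0.05) + 1], 1)
  expect_error(rdf(tr, partner_role = "OW"), "no atoms")
  expect_error(rdf(tr, bin_width = 0.05, r_max = 15), "half the box")
})

test_that("hydrogen-bond geometry rules match their definition", {
  # ideal linear O-H...O bond at 2.8 A donor-acceptor distance
  lin <- matrix(c(5, 5, 5,        # OC (acceptor)
                  7.8, 5, 5,      # OW (donor)
                  6.84, 5, 5),    # HW on the D->A line
                3, 3, byrow = TRUE)
  tr <- make_frame_traj(c("OC", "OW", "HW"), list(lin), box = 20)
  expect_equal(hbond_count(tr)$mean, 1)
  # beyond the 3.5 A distance cutoff: never counted
  far <- lin; far[2:3, 1] <- far[2:3, 1] + 0.8
  expect_equal(hbond_count(make_frame_traj(c("OC", "OW", "HW"),
                                           list(far), 20))$mean, 0)
  # deviation angle beyond 40 degrees: not counted under the default rule
  bent <- lin
  bent[3, ] <- c(7.8 - 0.96 * cos(50 * pi / 180),
                 5 + 0.96 * sin(50 * pi / 180), 5)
  expect_equal(hbond_count(make_frame_traj(c("OC", "OW", "HW"),
                                           list(bent), 20))$mean, 0)
  # the literal at-proton convention excludes even the linear bond
  expect_equal(hbond_count(tr, angle = "at_proton")$mean, 0)
  expect_error(hbond_count(tr, acceptor_role = "XX"), "missing role")
})

test_that("hydrogen-bond counts equal the brute-force oracle", {
  tr <- simulate_trajectory(traj_gen_params(n_frames = 3, n_waters = 50,
                                            box_length = 28, seed = 8))
  got <- hbond_count(tr)$per_frame
  want <- vapply(tr$frames, function(f)
    oracle_hbond_count(f$coords, tr$labels, tr$box_length), integer(1))
  expect_identical(got, want)
})

test_that("hydrogen-bond counts are invariant under rigid translation", {
  tr <- simulate_trajectory(traj_gen_params(n_frames = 4, n_waters = 30,
                                            box_length = 28, seed = 9))
  base <- hbond_count(tr)$per_frame
  shifted <- tr
  shifted$frames <- lapply(tr$frames, function(f) {
    f$coords <- (sweep(f$coords, 2, c(13.7, -4.2, 99.1), "+")) %% 28
    f
  })
  expect_identical(hbond_count(shifted)$per_frame, base)
  # frame reordering only permutes the per-frame counts
  rev_tr <- tr
  rev_tr$frames <- rev(tr$frames)
  expect_identical(hbond_count(rev_tr)$per_frame, rev(base))
})

test_that("nearest-distance extraction matches a full sort", {
  tr <- simulate_trajectory(traj_gen_params(n_frames = 10, n_waters = 40,
                                            box_length = 28, seed = 10))
  nd <- nearest_hw_distances(tr)
  expect_true(all(nd$r1 <= nd$r2))
  want <- vapply(tr$frames, function(f) {
    d <- sort(chex2dir:::min_image_dist(f$coords[1, ],
                                        f$coords[tr$labels == "HW", ],
                                        tr$box_length))
    d[1:2]
  }, numeric(2))
  expect_equal(nd$r1, want[1, ])
  expect_equal(nd$r2, want[2, ])
  expect_equal(sum(nd$r1_hist$probability), 1)
})

test_that("pinned two-water geometry gives delta-like r1/r2 histograms", {
  co <- matrix(c(10, 10, 10,
                 10 + 1.65, 10, 10,
                 10, 10 + 1.85, 10), 3, 3, byrow = TRUE)
  tr <- make_frame_traj(c("OC", "HW", "HW"), list(co, co), box = 24)
  nd <- nearest_hw_distances(tr)
  expect_equal(nd$r1, c(1.65, 1.65))
  expect_equal(nd$r2, c(1.85, 1.85))
  expect_equal(sum(nd$r1_hist$probability > 0), 1L)
})

test_that("hydration classification separates the two distance modes", {
  cl <- classify_hydration(c(1.85, 3.0))
  expect_equal(as.character(cl$labels), c("SHB", "WHB"))
  expect_equal(classify_hydration(c(1.2, 2.0, 2.5))$shb_fraction, 1)
  expect_error(classify_hydration(numeric(0)), "empty")
})

test_that("telegraph trajectories reach the stationary bound fraction", {
  tr <- simulate_trajectory(traj_gen_params(n_frames = 3000, n_waters = 6,
                                            shell_model = "telegraph_hbond",
                                            telegraph_rates = c(on = 2, off = 1),
                                            frame_dt = 0.25, seed = 4))
  nd <- nearest_hw_distances(tr)
  cl <- classify_hydration(nd$r2)
  expect_lt(abs(cl$shb_fraction - 2 / 3), 3 * cl$shb_fraction_se)
})

test_that("XYZ files round-trip through write and read", {
  tr <- simulate_trajectory(traj_gen_params(n_frames = 3, n_waters = 4,
                                            seed = 6))
  tr$telegraph_state <- NULL
  path <- tempfile(fileext = ".xyz")
  write_xyz(tr, path)
  back <- read_xyz(path)
  expect_equal(back$labels, tr$labels)
  expect_equal(back$box_length, tr$box_length)
  for (i in seq_along(tr$frames)) {
    expect_equal(back$frames[[i]]$coords, tr$frames[[i]]$coords,
                 tolerance = 1e-9)
    expect_equal(back$frames[[i]]$time, tr$frames[[i]]$time)
  }
})
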