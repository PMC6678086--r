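make_frame_from_axes <- function(axes, origin = c(0, 0, 0)) {
  domainmotion:::new_local_frame(origin, axes, c(3, 2, 1))
}

test_that("pair_angles: closed forms and symmetry", {
  id <- make_frame_from_axes(diag(3))
  expect_equal(unname(pair_angles(id, id)), c(0, 0, 0))
  rotated <- make_frame_from_axes(rot_z(90) %*% diag(3))
  expect_equal(unname(pair_angles(id, rotated)), c(90, 90, 0),
               tolerance = 1e-12)
  expect_equal(pair_angles(id, rotated), pair_angles(rotated, id))
})

test_that("pair_angles equals direct dot/arccos on random triad pairs", {
  set.seed(41)
  for (i in 1:25) {
    A <- make_frame_from_axes(random_rotation())
    B <- make_frame_from_axes(random_rotation())
    got <- unname(pair_angles(A, B))
    oracle <- vapply(1:3, function(j)
      acos(max(-1, min(1, sum(A$axes[, j] * B$axes[, j])))) * 180 / pi,
      numeric(1))
    expect_equal(got, oracle, tolerance = 1e-9)
    expect_true(all(got >= 0 & got <= 180))
  }
})

test_that("orientation_series recovers a constant rotation about v2 exactly", {
  sp <- motion_spec(n_atoms = c(40L, 40L), duration = 2,
                    output_interval = 0.04, jitter_sd = 0,
                    rotation = list(list(axis = "y",
                                         model = list(type = "constant",
                                                      d0 = 25))),
                    seed = 42L)
  run <- generate_trajectory(sp)
  specs <- synthetic_domain_specs(sp)
  fa <- frame_series(run$trajectory, specs$domA, run$reference)
  fb <- frame_series(run$trajectory, specs$domB, run$reference)
  os <- orientation_series(fa, fb)
  expect_lt(max(abs(os$alpha_deg - 25)), 1e-6)
  expect_lt(max(abs(os$beta_deg)), 1e-6)
  expect_lt(max(abs(os$gamma_deg - 25)), 1e-6)
})

test_that("orientation_series with jitter recovers the mean angle within 1 degree", {
  sp <- motion_spec(n_atoms = c(104L, 117L), duration = 8,
                    output_interval = 0.04, jitter_sd = 0.01,
                    rotation = list(list(axis = "y",
                                         model = list(type = "constant",
                                                      d0 = 25))),
                    seed = 43L)
  run <- generate_trajectory(sp)
  specs <- synthetic_domain_specs(sp)
  fa <- frame_series(run$trajectory, specs$domA, run$reference)
  fb <- frame_series(run$trajectory, specs$domB, run$reference)
  os <- orientation_series(fa, fb)
  expect_lt(abs(mean(os$alpha_deg) - 25), 1)
  expect_lt(abs(mean(os$gamma_deg) - 25), 1)
})

test_that("orientation_series validates lengths and times", {
  set.seed(44)
  traj <- make_test_trajectory(rep(list(anisotropic_cloud(20)), 3))
  fs <- frame_series(traj, domain_spec("d", "A", list(c(1, 20))),
                     frame_coords(traj, 1))
  short <- fs
  short$frames <- short$frames[1:2]
  short$times <- short$times[1:2]
  expect_error(orientation_series(fs, short), "lengths differ")
})

test_that("ks_two_sample: exact values and agreement with stats::ks.test", {
  expect_equal(ks_two_sample(1:5, 1:5)$D, 0)
  expect_equal(ks_two_sample(c(1, 2), c(10, 11))$D, 1)
  expect_equal(ks_two_sample(c(1, 2, 3), c(2, 3, 4))$D, 1 / 3)
  set.seed(45)
  for (i in 1:50) {
    x <- rnorm(sample(3:40, 1))
    y <- rnorm(sample(3:40, 1), mean = runif(1, -1, 1))
    got <- ks_two_sample(x, y)$D
    oracle <- unname(suppressWarnings(stats::ks.test(x, y)$statistic))
    expect_equal(got, oracle, tolerance = 1e-12)
  }
  expect_error(ks_two_sample(numeric(0), 1), "non-empty")
})

test_that("KS D is invariant under common strictly monotone transforms", {
  set.seed(46)
  x <- rnorm(50); y <- rnorm(60, 0.5)
  d0 <- ks_two_sample(x, y)$D
  expect_equal(ks_two_sample(exp(x), exp(y))$D, d0)
  expect_equal(ks_two_sample(x^3, y^3)$D, d0)
  expect_equal(ks_two_sample(5 * x - 2, 5 * y - 2)$D, d0)
})

test_that("compare_states reports means, n-1 SDs and KS D", {
  cmp <- compare_states(rep(2, 5), rep(2, 7))
  expect_equal(cmp$mean_free, 2)
  expect_equal(cmp$sd_free, 0)
  expect_equal(cmp$ks$D, 0)

  set.seed(47)
  free <- rnorm(1e4, 57, 2)
  bound <- rnorm(1e4, 63, 4)
  cmp2 <- compare_states(free, bound)
  expect_lt(abs(cmp2$mean_free - 57), 0.1)
  expect_lt(abs(cmp2$mean_bound - 63), 0.2)
  expect_lt(abs(cmp2$sd_free - 2), 0.1)
  expect_lt(abs(cmp2$sd_bound - 4), 0.1)
  expect_equal(cmp2$sd_free, sd(free))      # n-1 convention

  expect_warning(cmp3 <- compare_states(1, c(2, 3)), "single-element")
  expect_equal(cmp3$sd_free, 0)
})

test_that("angle_histogram counts half-open bins with a closed last bin", {
  h <- angle_histogram(rep(10, 7), 5)
  expect_equal(sum(h$counts), 7L)
  expect_equal(h$counts[h$bin_edges[-length(h$bin_edges)] == 10], 7L)

  h0 <- angle_histogram(numeric(0), 5)
  expect_true(all(h0$counts == 0L))

  grid <- seq(0, 179.5, by = 0.5)
  h2 <- angle_histogram(grid, 1)
  expect_true(all(h2$counts == 2L))
  expect_equal(length(h2$counts), 180L)

  h180 <- angle_histogram(180, 5)           # boundary lands in last bin
  expect_equal(h180$counts[length(h180$counts)], 1L)
  expect_error(angle_histogram(10, 0), "positive")
})
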