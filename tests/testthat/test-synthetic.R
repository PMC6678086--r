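test_that("make_base_clouds: reproducible, correctly shaped, identifiable", {
  sp <- motion_spec(n_atoms = c(200L, 200L), seed = 61L)
  c1 <- make_base_clouds(sp)
  c2 <- make_base_clouds(sp)
  expect_identical(c1, c2)                 # same seed -> bit-identical

  # sample principal SDs within 15% of the spec at n = 200
  for (d in c("a", "b")) {
    lf <- pca_frame(c1[[d]])
    got <- sqrt(lf$eigenvalues)
    want <- sp$shape_sd[[d]]
    expect_lt(max(abs(got - want) / want), 0.15)
    # canonical orientation: principal axes are the lab axes
    expect_equal(abs(lf$axes), diag(3), tolerance = 1e-8)
  }

  expect_error(motion_spec(shape_sd = list(a = c(1, 1, 1),
                                           b = c(1.05, 0.7, 0.35))),
               "isotropic")
})

test_that("generate_trajectory honours the frame-count convention", {
  sp <- motion_spec(n_atoms = c(10L, 10L), duration = 1,
                    output_interval = 0.04, jitter_sd = 0)
  run <- generate_trajectory(sp)
  expect_equal(n_frames(run$trajectory), 25L)
  expect_equal(run$trajectory$times[1], 0.04)  # frames start at k = 1
  expect_equal(nrow(run$ground_truth), 25L)
})

test_that("zero jitter, constant distance closes the loop exactly", {
  sp <- motion_spec(n_atoms = c(30L, 30L), duration = 2,
                    output_interval = 0.04, jitter_sd = 0,
                    distance_model = list(type = "constant", d0 = 2.5),
                    rotation = list(list(axis = "x",
                                         model = list(type = "constant",
                                                      d0 = 0))))
  run <- generate_trajectory(sp)
  specs <- synthetic_domain_specs(sp)
  ds <- interdomain_distance_series(run$trajectory, specs$domA, specs$domB)
  expect_lt(max(abs(ds$distance_nm - 2.5)), 1e-9)
})

test_that("OU rotation runs are reproducible from the seed", {
  sp <- motion_spec(n_atoms = c(20L, 20L), duration = 2,
                    output_interval = 0.1, seed = 62L)
  g1 <- generate_trajectory(sp)$ground_truth
  g2 <- generate_trajectory(sp)$ground_truth
  expect_identical(g1, g2)
})

test_that("angle error is zero-mean and shrinks with the jitter level", {
  sds <- c(0.02, 0.005, 0.00125)
  err_sd <- vapply(sds, function(js) {
    sp <- motion_spec(n_atoms = c(104L, 117L), duration = 6,
                      output_interval = 0.04, jitter_sd = js,
                      rotation = list(list(axis = "y",
                                           model = list(type = "constant",
                                                        d0 = 25))),
                      seed = 63L)
    run <- generate_trajectory(sp)
    specs <- synthetic_domain_specs(sp)
    fa <- frame_series(run$trajectory, specs$domA, run$reference)
    fb <- frame_series(run$trajectory, specs$domB, run$reference)
    os <- orientation_series(fa, fb)
    err <- os$alpha_deg - run$ground_truth$alpha_true_deg
    expect_lt(abs(mean(err)), 3 * sd(err) / sqrt(length(err)) + 0.02)
    sd(err)
  }, numeric(1))
  expect_true(all(diff(err_sd) < 0))
})

test_that("state ensembles contrast rotational variance by construction", {
  base <- motion_spec(n_atoms = c(40L, 40L), duration = 4,
                      output_interval = 0.04)
  bound <- make_state_ensemble("bound", 3, base, master_seed = 9L)
  free <- make_state_ensemble("free", 3, base, master_seed = 9L)
  expect_length(bound, 3L)
  seeds <- vapply(bound, function(r) r$spec$seed, integer(1))
  expect_equal(anyDuplicated(seeds), 0L)
  # reproducible from the master seed
  bound2 <- make_state_ensemble("bound", 3, base, master_seed = 9L)
  expect_identical(bound[[2]]$ground_truth, bound2[[2]]$ground_truth)
  # pooled ground-truth rotation SD strictly larger for free
  sd_b <- sd(unlist(lapply(bound, function(r) r$ground_truth$beta_true_deg)))
  sd_f <- sd(unlist(lapply(free, function(r) r$ground_truth$beta_true_deg)))
  expect_gt(sd_f, sd_b)
  expect_error(make_state_ensemble("complexed", 3, base), "unknown state")
})

test_that("OU stationary SD of the angle channel is recovered from the series", {
  base <- motion_spec(n_atoms = c(104L, 117L), duration = 40,
                      output_interval = 0.2, jitter_sd = 0.02)
  runs <- make_state_ensemble("free", 10, base, master_seed = 17L)
  pooled <- unlist(lapply(runs, function(run) {
    specs <- synthetic_domain_specs(run$spec)
    fa <- frame_series(run$trajectory, specs$domA, run$reference)
    fb <- frame_series(run$trajectory, specs$domB, run$reference)
    orientation_series(fa, fb)$beta_deg
  }))
  # per-run SD about the run mean, averaged: estimates the stationary SD 6
  per_run_sd <- vapply(split(pooled, rep(1:10, each = 200)), sd, numeric(1))
  expect_lt(abs(mean(per_run_sd) - 6) / 6, 0.2)
})

test_that("motion_spec validates fields individually", {
  expect_error(motion_spec(n_atoms = c(2L, 10L)), "n_atoms")
  expect_error(motion_spec(jitter_sd = -1), "jitter_sd")
  expect_error(motion_spec(duration = 0), "duration")
  expect_error(motion_spec(output_interval = 0), "output_interval")
  expect_error(motion_spec(distance_model = list(type = "warp")),
               "unknown type")
  expect_error(motion_spec(rotation = list(list(model = list(type = "ou",
                                                             mean = 0,
                                                             tau = 1,
                                                             sd = 1)))),
               "axis")
  expect_error(motion_spec(breathing = list(domain = "a", axis = 1,
                                            amplitude = 0.1, period = 0)),
               "period")
})
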