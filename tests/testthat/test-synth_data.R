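test_that("population sampling is deterministic and respects degenerate variance", {
  cfg <- population_config(n_subjects = 3, seed = 7)
  p1 <- sample_population(cfg)
  p2 <- sample_population(cfg)
  expect_identical(p1, p2)

  cfg0 <- population_config(n_subjects = 4, seed = 3,
                            between_subject_sd = list(amp = 0, time = 0))
  pop0 <- sample_population(cfg0)
  shapes <- lapply(pop0, `[[`, "grf_shape")
  for (i in 2:4) expect_identical(shapes[[i]], shapes[[1]])

  expect_error(population_config(n_subjects = 0), "positive")
  expect_error(population_config(n_subjects = 2, dropout_prob = 1), "dropout")
})

test_that("heel-height effect matches its configured distribution", {
  pop <- sample_population(population_config(n_subjects = 4000, seed = 5))
  hd <- vapply(pop, `[[`, numeric(1), "heel_delta_cm")
  se <- 0.7504 / sqrt(length(hd))
  expect_lt(abs(mean(hd) - 4.988), 3 * se)
  expect_lt(abs(sd(hd) - 0.7504) / 0.7504, 0.05)
  expect_true(all(hd > 0))
})

test_that("GRF strides reproduce the expected stance morphology", {
  pop <- small_pop(5, 11)
  for (subj in pop[1:3]) {
    st <- quick_stride(subj, "sport", stride_seed = 2)
    n <- nrow(st$series)
    bw <- st$body_weight_N
    fy <- st$series$fy_L / bw
    # contact boundaries carry no force
    expect_equal(fy[1], 0, tolerance = 1e-12)
    expect_equal(fy[n], 0, tolerance = 1e-12)
    # double bump: two maxima ~1.2 BW around a sub-BW unloading minimum
    expect_gt(max(fy[1:(n / 2)]), 1.05)
    expect_gt(max(fy[(n / 2):n]), 1.05)
    expect_lt(fy[round(n / 2)], 1)
    # anterior-posterior: braking then propulsion with a zero crossing
    fx <- st$series$fx_L / bw
    expect_lt(min(fx[1:(n / 2)]), -0.1)
    expect_gt(max(fx[(n / 2):n]), 0.1)
    # lateral plateau signs: positive left, mirrored negative right
    mid <- (round(n / 3)):(round(2 * n / 3))
    expect_true(all(st$series$fz_L[mid] > 0))
    expect_true(all(st$series$fz_R[mid] < 0))
  }
})

test_that("stride generation is seed-deterministic and heels scale the extremes", {
  subj <- small_pop(5, 11)[[2]]
  s1 <- quick_stride(subj, "sport", stride_seed = 9)
  s2 <- quick_stride(subj, "sport", stride_seed = 9)
  expect_identical(s1$series, s2$series)

  heels <- quick_stride(subj, "heels", stride_seed = 9)
  sport <- s1
  expect_lt(heels$stance_s, sport$stance_s)           # shorter stance
  ratio <- max(heels$series$fy_L) / max(sport$series$fy_L)
  expect_gt(ratio, 1.02)                              # amplified extremes
  expect_error(synth_grf_stride(subj, "barefoot"), "arg")
})

test_that("skeleton stream is an exact additive height model when noise-free", {
  cfg <- population_config(n_subjects = 2, seed = 4, sensor_noise_sd = 0,
                           dropout_prob = 0, osc_amp_mean_cm = 0,
                           osc_amp_sd_cm = 0)
  pop <- sample_population(cfg)
  subj <- pop[[1]]
  log_s <- synth_skeleton_stream(subj, "sport", n_cycles = 2, seed = 3)
  h_s <- gaitid:::chain_heights(log_s)
  expect_equal(h_s, rep(subj$true_height_sport_cm, length(h_s)),
               tolerance = 1e-9)
  log_h <- synth_skeleton_stream(subj, "heels", n_cycles = 2, seed = 3)
  h_h <- gaitid:::chain_heights(log_h)
  expect_equal(h_h - h_s, rep(subj$heel_delta_cm, length(h_s)),
               tolerance = 1e-9)
})

test_that("within-cycle head oscillation stays below the physiological cap", {
  pop <- sample_population(population_config(n_subjects = 30, seed = 6))
  amp <- vapply(pop, `[[`, numeric(1), "osc_amp_cm")
  expect_true(all(amp <= 9.5))
  tr <- attr(synth_skeleton_stream(pop[[1]], "sport", n_cycles = 5, seed = 1),
             "truth")
  expect_lte(max(tr$osc_cm) - min(tr$osc_cm), 9.5)
})

test_that("dataset building honours the footwear plan and stride counts", {
  pop <- small_pop(4, 21)
  ds_a <- build_dataset(pop, 4, scenario_plan("a"), seed = 1,
                        sampling_rate_hz = 120)
  fw_gal <- unique(vapply(ds_a$gallery$strides, `[[`, character(1), "footwear"))
  fw_pro <- unique(vapply(ds_a$probes, `[[`, character(1), "footwear"))
  expect_identical(fw_gal, "sport")
  expect_identical(fw_pro, "sport")

  ds_b <- build_dataset(pop, 4, scenario_plan("b"), seed = 1,
                        sampling_rate_hz = 120)
  expect_identical(unique(vapply(ds_b$gallery$strides, `[[`, character(1),
                                 "footwear")), "sport")
  expect_setequal(unique(vapply(ds_b$probes, `[[`, character(1), "footwear")),
                  c("sport", "heels"))

  # per-subject bookkeeping: ns strides per planned footwear, disjoint split
  ns <- 6
  ds <- build_dataset(pop, ns, scenario_plan("b"), seed = 2,
                      sampling_rate_hz = 120)
  gal_per <- table(ds$gallery$subject_id)
  expect_true(all(gal_per == ceiling(ns / 2)))
  probes_per <- table(vapply(ds$probes, `[[`, character(1), "subject_id"),
                      vapply(ds$probes, `[[`, character(1), "footwear"))
  expect_true(all(probes_per[, "sport"] == floor(ns / 2)))
  expect_true(all(probes_per[, "heels"] == ns))

  expect_error(build_dataset(pop, 4, list(gallery = "sport", probe = "flipflops")),
               "unknown footwear")
})

test_that("tightening within-subject noise never hurts closed-set recovery", {
  base <- population_config(n_subjects = 8, seed = 13)
  ccr_of <- function(within_amp) {
    cfg <- population_config(n_subjects = 8, seed = 13,
                             within_subject_sd = list(amp = within_amp,
                                                      time = 0.004))
    rep <- run_scenario("a", n_subjects = 8, repetitions = 2, seed = 5,
                        gen_config = cfg, per_subject_strides = 4,
                        sampling_rate_hz = 100)
    mean(rep$CCR)
  }
  expect_gte(ccr_of(0.012), ccr_of(0.12))
})
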