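# Synthetic cohort generator: study design, determinism, and closure with
# the fitting stage.

test_that("the default cohort reproduces the study design", {
  cohort <- simulate_cohort(cohort_config(seed = 5))
  obs <- cohort$observations
  sites <- unique(obs[, c("animal_id", "lesion_id")])
  expect_equal(nrow(sites), 36)
  expect_equal(take_rate(obs), 28 / 36)

  # group scan schedules: weekly from baseline to sacrifice
  days_by_animal <- tapply(obs$day, obs$animal_id, function(d) sort(unique(d)))
  expect_equal(days_by_animal[["pig01"]], c(0, 7, 14))
  expect_equal(days_by_animal[["pig04"]], c(0, 7, 14, 21))
  expect_equal(days_by_animal[["pig09"]], c(0, 7, 14, 21, 28))

  # baseline scans never show a lesion
  expect_true(all(obs$volume_mm3[obs$day == 0] == 0))
  expect_true(all(!obs$detected[obs$day == 0]))
})

test_that("take allocation is exact for any seed and take rate", {
  for (seed in c(1, 2, 99)) {
    cohort <- simulate_cohort(cohort_config(seed = seed))
    expect_equal(take_rate(cohort$observations), 28 / 36)
  }
  half <- simulate_cohort(cohort_config(take_rate = 0.5, seed = 3))
  expect_equal(take_rate(half$observations), 18 / 36)
})

test_that("identical seeds give identical cohorts", {
  a <- simulate_cohort(cohort_config(seed = 17))
  b <- simulate_cohort(cohort_config(seed = 17))
  expect_identical(a$observations, b$observations)
  expect_identical(a$truth, b$truth)
  c2 <- simulate_cohort(cohort_config(seed = 18))
  expect_false(identical(a$observations, c2$observations))
})

test_that("the noiseless limit reproduces the generating curve exactly", {
  cfg <- cohort_config(noise_cv = 0, animal_kappa_cv = 0, seed = 9)
  cohort <- simulate_cohort(cfg)
  obs <- cohort$observations
  takes21 <- obs[obs$day == 21 & obs$detected, ]
  expect_equal(mean(takes21$volume_mm3),
               volume_at(cfg$growth_truth, 21), tolerance = 1e-12)
})

test_that("regression trajectories are continuous at the breakpoint", {
  cfg <- cohort_config(noise_cv = 0, animal_kappa_cv = 0, seed = 2)
  truth <- simulate_cohort(cfg)$truth
  takes <- truth[truth$take & truth$day %in% c(21, 28), ]
  v21 <- unique(takes$volume_true[takes$day == 21])
  expect_equal(v21, volume_at(cfg$growth_truth, 21), tolerance = 1e-12)
  # beyond the breakpoint volumes fall along the matched regression curve
  v28 <- unique(takes$volume_true[takes$day == 28])
  expect_lt(v28, v21)
})

test_that("impossible schedules are rejected at configuration", {
  expect_error(cohort_config(groups = c("5" = 9)), "sacrifice day 5")
  expect_error(cohort_config(take_rate = 1.2), "take_rate")
  expect_error(cohort_config(groups = c("14" = 2, "21" = 3, "28" = 3)),
               "sum to n_animals")
})

test_that("noise-free pipeline closure recovers the generating parameters", {
  cfg <- cohort_config(noise_cv = 0, animal_kappa_cv = 0, seed = 21)
  cohort <- simulate_cohort(cfg)
  fit <- fit_phase(cohort$observations, fit_config("growth"))
  expect_equal(fit$par[["c"]], cfg$growth_truth$c, tolerance = 1e-3)
  expect_equal(fit$par[["kappa"]], cfg$growth_truth$kappa, tolerance = 1e-3)
  expect_equal(fit$par[["theta"]], cfg$growth_truth$theta, tolerance = 1e-3)
})

test_that("kappa recovery under default cohort noise is nearly unbiased", {
  # 100 replicate cohorts at the default noise and between-animal
  # variability; the population growth fit (per-day means across takes)
  # recovers kappa with small bias. A single 3-point lesion, by contrast,
  # interpolates its noise exactly and has a heavy-tailed kappa estimate,
  # so the population design is what makes recovery stable.
  ks <- vapply(seq_len(100), function(i) {
    cohort <- simulate_cohort(cohort_config(seed = 1000 + i))
    fit <- suppressWarnings(fit_phase(cohort$observations,
                                      fit_config("growth")))
    fit$par[["kappa"]]
  }, numeric(1))
  expect_lt(abs(mean(ks) - 0.146), 0.1 * 0.146)
})

test_that("forced full regression zeroes the final scan of takes", {
  cfg <- cohort_config(full_regression_prob = 1, noise_cv = 0,
                       animal_kappa_cv = 0, seed = 4)
  obs <- simulate_cohort(cfg)$observations
  final <- obs[obs$animal_id == "pig09" & obs$day == 28, ]
  expect_true(all(final$volume_mm3 == 0))
  expect_true(all(!final$detected))
})

test_that("rasterised lesions reproduce their true volumes within 2%", {
  cfg <- cohort_config(noise_cv = 0, animal_kappa_cv = 0, seed = 7)
  cohort <- simulate_cohort(cfg)
  truth <- cohort$truth
  vol <- rasterize_lesions(truth, "pig04", 14, grid_shape = c(96, 96, 48))
  m <- measure_all(vol)
  takes <- truth[truth$animal_id == "pig04" & truth$day == 14 & truth$take, ]
  expect_equal(nrow(m), nrow(takes))
  for (i in seq_len(nrow(m))) {
    site_idx <- m$label[i]
    v_true <- truth$volume_true[truth$animal_id == "pig04" &
                                  truth$day == 14][site_idx]
    expect_lt(abs(m$volume[i] - v_true) / v_true, 0.02)
  }
  # a lesion below the detection limit is absent from the map
  vol7 <- rasterize_lesions(truth, "pig04", 14, grid_shape = c(96, 96, 48),
                            detection_limit = 1e9)
  expect_error(measure_all(vol7), "no lesions")
  # oversized lesions are rejected with advice
  expect_error(rasterize_lesions(truth, "pig04", 14,
                                 grid_shape = c(16, 16, 16)),
               "larger grid")
})

test_that("rasterise -> measure -> table round-trips the generating volumes", {
  cfg <- cohort_config(noise_cv = 0, animal_kappa_cv = 0, seed = 13)
  cohort <- simulate_cohort(cfg)
  truth <- cohort$truth
  animal <- "pig05"
  days <- c(7, 14, 21)
  meas <- do.call(rbind, lapply(days, function(d) {
    lv <- rasterize_lesions(truth, animal, d, grid_shape = c(96, 96, 48))
    m <- measure_all(lv)
    data.frame(animal_id = animal, lesion_id = sprintf("site%d", m$label),
               day = d, volume_mm3 = m$volume, surface_mm2 = m$surface_area)
  }))
  tab <- longitudinal_table(meas, scan_days = days)
  merged <- merge(tab[tab$detected, ],
                  truth[truth$animal_id == animal, ],
                  by = c("animal_id", "lesion_id", "day"))
  expect_gt(nrow(merged), 0)
  expect_true(all(abs(merged$volume_mm3 - merged$volume_true) /
                    merged$volume_true < 0.02))
})
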