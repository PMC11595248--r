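#' Configuration of a synthetic inoculation cohort
#'
#' Describes the generative model for a weekly-scanned multi-animal liver
#' inoculation study. The defaults emulate the reference study design:
#' 9 animals with 4 inoculation sites each, sacrifice groups of 3 animals
#' at days 14, 21 and 28 (each group scanned weekly from day 0 to its
#' sacrifice day), a site take rate of 28/36 (~78%), logistic growth to
#' the day-21 breakpoint followed by logistic regression, per-animal
#' variation of the growth-rate constant, multiplicative lognormal
#' measurement noise, and a volumetric detection limit.
#'
#' Takes are allocated exactly — `round(take_rate * n_sites)` sites are
#' chosen by seeded shuffling — rather than by independent coin flips, so
#' the realised take fraction is reproducible for any seed.
#'
#' @param n_animals Number of animals; default 9.
#' @param sites_per_animal Inoculation sites per animal; default 4.
#' @param groups Named integer vector mapping sacrifice day to group size;
#'   default `c("14" = 3, "21" = 3, "28" = 3)`. Scan days per group are
#'   weekly from 0 to the sacrifice day.
#' @param take_rate Fraction of sites producing a lesion; default 28/36.
#' @param growth_truth [logistic_params()] of the growth phase; default the
#'   reference growth curve (c = 5.823, kappa = 0.146, theta = 8.740e8).
#' @param regression_truth [logistic_params()] of the regression phase;
#'   default the reference regression curve (c = 5.909e-4, kappa = -0.360,
#'   theta = 1.470e9).
#' @param breakpoint_day Growth/regression breakpoint; default 21.
#' @param animal_kappa_cv Lognormal coefficient of variation of a mean-1
#'   per-animal multiplier applied to both phase rate constants; default
#'   0.25 (growth rates vary widely between animals but are consistent
#'   within one).
#' @param noise_cv Multiplicative lognormal measurement noise CV on
#'   observed volumes; default 0.10.
#' @param detection_limit Volume in mm^3 below which a lesion is not
#'   detectable on CT; default 50.
#' @param full_regression_prob Probability that a take in the longest
#'   follow-up group is forced to complete regression (volume 0) at the
#'   final scan, on top of regressions that emerge from the dynamics;
#'   default 0.
#' @param seed Integer seed making the whole cohort deterministic.
#' @param conv A [cell_volume_conversion()].
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_animals = 9,
                          sites_per_animal = 4,
                          groups = c("14" = 3, "21" = 3, "28" = 3),
                          take_rate = 28 / 36,
                          growth_truth = logistic_params(5.823, 0.146, 8.740e8),
                          regression_truth = logistic_params(5.909e-4, -0.360, 1.470e9),
                          breakpoint_day = 21,
                          animal_kappa_cv = 0.25,
                          noise_cv = 0.10,
                          detection_limit = 50,
                          full_regression_prob = 0,
                          seed = 1,
                          conv = cell_volume_conversion()) {
  stopifnot(n_animals >= 1, sites_per_animal >= 1,
            inherits(growth_truth, "logistic_params"),
            inherits(regression_truth, "logistic_params"),
            breakpoint_day > 0, animal_kappa_cv >= 0, noise_cv >= 0,
            detection_limit >= 0,
            full_regression_prob >= 0, full_regression_prob <= 1)
  if (take_rate < 0 || take_rate > 1) {
    stop("'take_rate' must lie in [0, 1]", call. = FALSE)
  }
  sac_days <- as.numeric(names(groups))
  if (length(groups) == 0 || any(is.na(sac_days))) {
    stop("'groups' must be a named vector mapping sacrifice day to group size",
         call. = FALSE)
  }
  if (any(sac_days < 7)) {
    stop("invalid schedule: sacrifice day ", min(sac_days),
         " precedes the first post-baseline scan (day 7)", call. = FALSE)
  }
  if (sum(groups) != n_animals) {
    stop("group sizes (", sum(groups), ") must sum to n_animals (",
         n_animals, ")", call. = FALSE)
  }
  structure(list(n_animals = n_animals, sites_per_animal = sites_per_animal,
                 groups = groups, take_rate = take_rate,
                 growth_truth = growth_truth,
                 regression_truth = regression_truth,
                 breakpoint_day = breakpoint_day,
                 animal_kappa_cv = animal_kappa_cv, noise_cv = noise_cv,
                 detection_limit = detection_limit,
                 full_regression_prob = full_regression_prob,
                 seed = seed, conv = conv),
            class = "cohort_config")
}

# Mean-1 lognormal deviates with a given coefficient of variation.
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# True lesion volume trajectory: growth curve up to the breakpoint, then a
# regression curve made continuous with it at the breakpoint by rescaling
# the regression shape coefficient per lesion.
true_volume <- function(day, growth, regression, breakpoint_day, conv) {
  v_bp <- volume_at(growth, breakpoint_day, conv)
  ratio <- regression$theta / (conv$alpha * v_bp) - 1
  c_reg <- ratio * exp(regression$kappa * breakpoint_day)
  reg_cont <- logistic_params(c_reg, regression$kappa, regression$theta)
  ifelse(day <= breakpoint_day,
         volume_at(growth, pmax(day, 0), conv),
         volume_at(reg_cont, day, conv))
}

#' Simulate a synthetic longitudinal inoculation cohort
#'
#' Draws a full cohort from a [cohort_config()]: assigns animals to
#' sacrifice groups, allocates takes exactly, applies per-animal rate
#' multipliers, evaluates each take's two-phase true volume trajectory on
#' its scan schedule, applies multiplicative measurement noise, and
#' censors observations below the detection limit (emitted as
#' `detected = FALSE`, volume 0). Baseline (day 0) rows carry volume 0.
#' Byte-identical output for identical config (including seed).
#'
#' @param config A [cohort_config()].
#' @return A list of class `lesion_cohort` with `observations` (a
#'   [lesion_table] data.frame) and `truth` (per site x day: generating
#'   parameters after animal effects, take indicator, true and observed
#'   volumes).
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_config(seed = 42))
#' take_rate(cohort$observations)  # 28/36 sites ever detected
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  conv <- config$conv

  sac_days <- as.numeric(names(config$groups))
  animal_sac <- rep(sac_days, times = config$groups)
  n_sites <- config$n_animals * config$sites_per_animal

  # exact take allocation by shuffling
  n_takes <- round(config$take_rate * n_sites)
  take_flags <- sample(rep(c(TRUE, FALSE), c(n_takes, n_sites - n_takes)))

  kappa_mult <- rlnorm_cv(config$n_animals, config$animal_kappa_cv)

  obs_rows <- list()
  truth_rows <- list()
  site <- 0L
  for (a in seq_len(config$n_animals)) {
    animal_id <- sprintf("pig%02d", a)
    scan_days <- seq(0, animal_sac[a], by = 7)
    growth_a <- logistic_params(config$growth_truth$c,
                                config$growth_truth$kappa * kappa_mult[a],
                                config$growth_truth$theta)
    regr_a <- logistic_params(config$regression_truth$c,
                              config$regression_truth$kappa * kappa_mult[a],
                              config$regression_truth$theta)
    for (s in seq_len(config$sites_per_animal)) {
      site <- site + 1L
      lesion_id <- sprintf("site%d", s)
      take <- take_flags[site]
      forced_zero <- take && animal_sac[a] > config$breakpoint_day &&
        stats::runif(1) < config$full_regression_prob
      v_true <- if (take) {
        true_volume(scan_days, growth_a, regr_a, config$breakpoint_day, conv)
      } else {
        rep(0, length(scan_days))
      }
      v_true[scan_days == 0] <- 0
      if (forced_zero) v_true[scan_days == max(scan_days)] <- 0
      noise <- rlnorm_cv(length(scan_days), config$noise_cv)
      v_obs <- v_true * noise
      detected <- v_obs >= config$detection_limit & v_true > 0
      v_obs[!detected] <- 0
      obs_rows[[site]] <- data.frame(
        animal_id = animal_id, lesion_id = lesion_id, day = scan_days,
        volume_mm3 = v_obs, surface_mm2 = NA_real_, detected = detected)
      truth_rows[[site]] <- data.frame(
        animal_id = animal_id, lesion_id = lesion_id, day = scan_days,
        take = take, kappa_multiplier = kappa_mult[a],
        growth_c = growth_a$c, growth_kappa = growth_a$kappa,
        growth_theta = growth_a$theta,
        regression_kappa = regr_a$kappa,
        regression_theta = regr_a$theta,
        volume_true = v_true, volume_observed = v_obs)
    }
  }
  observations <- do.call(rbind, obs_rows)
  rownames(observations) <- NULL
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  validate_lesion_table(observations)
  structure(list(observations = observations, truth = truth,
                 config = config),
            class = "lesion_cohort")
}

#' @export
print.lesion_cohort <- function(x, ...) {
  n_sites <- nrow(unique(x$truth[, c("animal_id", "lesion_id")]))
  cat(sprintf("Synthetic lesion cohort: %d animals, %d sites, take rate %.1f%% (seed %d)\n",
              x$config$n_animals, n_sites,
              100 * take_rate(x$observations), x$config$seed))
  invisible(x)
}

#' Rasterise synthetic lesions into a 3-D label map
#'
#' Renders each detectable lesion of one scan day as a digital sphere (an
#' ellipsoid in voxel units under anisotropic spacing) whose voxelised
#' volume approximates the lesion's true volume at that day. Lesions are
#' placed on a non-overlapping grid of slots; labels number the sites in
#' table order. Lesions below the detection limit (or non-takes) are
#' absent from the map.
#'
#' @param truth The `truth` table of a [simulate_cohort()] result,
#'   restricted internally to one `animal_id`.
#' @param animal_id Animal to rasterise.
#' @param day Scan day to rasterise.
#' @param grid_shape Integer length-3 array dimensions; default
#'   `c(128, 128, 128)`.
#' @param spacing Voxel spacing in mm; default `c(1, 1, 1)`.
#' @param detection_limit Volumes below this (mm^3) are omitted; default 50.
#' @return A [label_volume()]; labels map to site index within the animal.
#' @export
rasterize_lesions <- function(truth, animal_id, day,
                              grid_shape = c(128, 128, 128),
                              spacing = c(1, 1, 1),
                              detection_limit = 50) {
  rows <- truth[truth$animal_id == animal_id & truth$day == day, ,
                drop = FALSE]
  if (nrow(rows) == 0) {
    stop("no truth rows for animal ", animal_id, " at day ", day,
         call. = FALSE)
  }
  labels <- array(0L, grid_shape)
  vox <- prod(spacing)
  n_slots <- nrow(rows)
  # slot centres on a regular grid along x
  slot_x <- (seq_len(n_slots) - 0.5) / n_slots * grid_shape[1] * spacing[1]
  centre_yz <- c(grid_shape[2] * spacing[2], grid_shape[3] * spacing[3]) / 2
  cx <- (seq_len(grid_shape[1]) - 0.5) * spacing[1]
  cy <- (seq_len(grid_shape[2]) - 0.5) * spacing[2]
  cz <- (seq_len(grid_shape[3]) - 0.5) * spacing[3]
  for (i in seq_len(n_slots)) {
    v <- rows$volume_true[i]
    if (v < detection_limit) next
    r <- (3 * v / (4 * pi))^(1 / 3)
    slot_width <- grid_shape[1] * spacing[1] / n_slots
    if (2 * r > min(slot_width, centre_yz * 2)) {
      stop("lesion of radius ", signif(r, 4), " mm does not fit the grid; ",
           "use a larger grid_shape", call. = FALSE)
    }
    # digital ball of exactly round(v / voxel volume) voxels: the k voxel
    # centres nearest the slot centre, so voxelised volume is within half a
    # voxel of the true volume
    k <- max(1L, as.integer(round(v / vox)))
    dx2 <- (cx - slot_x[i])^2
    dy2 <- (cy - centre_yz[1])^2
    dz2 <- (cz - centre_yz[2])^2
    dist2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
    labels[order(as.vector(dist2))[seq_len(k)]] <- i
  }
  label_volume(labels, spacing)
}
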