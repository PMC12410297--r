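#' Simulate a reference-region time-activity curve
#'
#' Drives a one-tissue compartment (irreversible-free of specific binding)
#' reference region with a plasma input: the noise-free curve is
#' `K1_ref * (C_p (*) exp(-k2prime t))`, integrated over each frame and
#' divided by the frame duration. Frame noise is additive Gaussian with
#' variance `noise_scale * C / dt` (a count-statistics proxy: short early
#' frames are noisier). All activities are assumed decay-corrected.
#'
#' @param schedule a [frame_schedule()].
#' @param input plasma input: a [feng_input_params()], a function of time
#'   (minutes), or a numeric vector already sampled on the fine grid.
#' @param K1_ref delivery rate of the reference tissue (mL/cm^3/min), `> 0`.
#' @param k2prime efflux rate of the reference tissue (1/min), `> 0`.
#' @param noise_scale variance scale of the frame noise; `0` is deterministic.
#' @param seed optional RNG seed (the caller's RNG stream is restored).
#' @param dt fine integration grid step (minutes).
#' @return A [tac()] whose `"fine"` attribute carries the exact noise-free
#'   fine-grid curve used downstream by the target simulator.
#' @export
simulate_reference_tac <- function(schedule = default_frame_schedule(),
                                   input = feng_input_params(),
                                   K1_ref = 0.1, k2prime = 0.1,
                                   noise_scale = 0, seed = NULL, dt = 0.01) {
  stopifnot(K1_ref > 0, k2prime > 0, noise_scale >= 0)
  if (nrow(schedule) == 0L) stop("frame schedule is empty")
  tt <- fine_times(schedule, dt)
  cp <- if (inherits(input, "feng_input_params")) {
    feng_input(input, tt)
  } else if (is.function(input)) {
    input(tt)
  } else if (is.numeric(input)) {
    if (length(input) != length(tt)) stop("numeric input curve must match the fine grid")
    input
  } else stop("unsupported input curve type")
  fine <- K1_ref * convolve_exp(cp, k2prime, dt = dt)
  framed <- frame_average(fine, dt, schedule)
  noisy <- with_seed(seed, add_frame_noise(framed, schedule$frame_duration, noise_scale))
  out <- tac(schedule, noisy, region = "reference")
  attr(out, "fine") <- list(dt = dt, values = fine)
  out
}

add_frame_noise <- function(values, durations, noise_scale) {
  if (noise_scale == 0) return(values)
  sd <- sqrt(noise_scale * pmax(values, 0) / durations)
  values + stats::rnorm(length(values), 0, sd)
}

#' Simulate a target-region TAC satisfying the SRTM2 operational equation
#'
#' Generates `C_T(t) = R1 [C_R(t) + (k2prime - k2a) (C_R (*) exp(-k2a t))]`
#' from a reference TAC, so the generated curve's distribution volume ratio
#' is exactly `R1 k2prime / k2a` by construction and basis-function fits have
#' an analytic truth.
#'
#' @param reference a [tac()]; its exact fine-grid curve is used when the
#'   `"fine"` attribute (attached by [simulate_reference_tac()]) is present,
#'   otherwise the framed curve is interpolated.
#' @param R1 relative delivery rate (target K1 / reference K1), `> 0`.
#' @param k2a apparent efflux rate of the target (1/min), `> 0`.
#' @param k2prime reference-region efflux rate (1/min), `> 0`.
#' @inheritParams simulate_reference_tac
#' @param region region name for the returned TAC.
#' @return A [tac()] with true `DVR = R1 * k2prime / k2a`.
#' @export
simulate_target_tac_srtm <- function(reference, R1, k2a, k2prime,
                                     noise_scale = 0, seed = NULL,
                                     region = NA_character_, dt = 0.01) {
  stopifnot(inherits(reference, "tac") || is.data.frame(reference))
  stopifnot(R1 > 0, k2a > 0, k2prime > 0, noise_scale >= 0)
  sched <- tac_schedule(reference)
  ref_fine <- tac_fine(reference, dt = dt)
  fine <- R1 * (ref_fine + (k2prime - k2a) * convolve_exp(ref_fine, k2a, dt = dt))
  framed <- frame_average(fine, dt, sched)
  noisy <- with_seed(seed, add_frame_noise(framed, sched$frame_duration, noise_scale))
  out <- tac(sched, noisy, region = region)
  attr(out, "fine") <- list(dt = dt, values = fine)
  out
}

#' Cohort specification for the spinal cord simulator
#'
#' Describes, per experimental group, the regional truth (mean/SD of the true
#' DVR and the mean R1) from which per-animal kinetics are drawn.
#'
#' @param groups named list (one element per group) of data frames with
#'   columns `region`, `mean_dvr`, `sd_dvr`, `mean_r1`. All groups must list
#'   the same regions.
#' @param n_per_group named integer vector, animals per group (`>= 1`).
#' @param noise_scale TAC noise variance scale (see
#'   [simulate_reference_tac()]).
#' @param seed integer RNG seed for the whole cohort.
#' @param schedule a [frame_schedule()].
#' @param k2prime shared reference-tissue efflux rate (1/min).
#' @param reference_region name of the reference region (must be listed).
#' @param K1_ref_mean,K1_ref_sd between-animal variability of the reference
#'   delivery rate (mL/cm^3/min).
#' @param timepoint free-text label copied into the output tables.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(groups, n_per_group, noise_scale = 0.05, seed = 1L,
                        schedule = default_frame_schedule(), k2prime = 0.1,
                        reference_region = "SC1",
                        K1_ref_mean = 0.1, K1_ref_sd = 0.01,
                        timepoint = NA_character_) {
  stopifnot(is.list(groups), length(groups) >= 1L, !is.null(names(groups)))
  stopifnot(all(names(groups) %in% names(n_per_group)))
  if (any(n_per_group < 1)) stop("n_per_group must be >= 1")
  regions <- NULL
  for (g in names(groups)) {
    df <- groups[[g]]
    need <- c("region", "mean_dvr", "sd_dvr", "mean_r1")
    if (!all(need %in% names(df))) stop("group tables need columns region, mean_dvr, sd_dvr, mean_r1")
    if (any(df$sd_dvr < 0)) stop("sd_dvr must be nonnegative")
    if (any(df$mean_dvr <= 0) || any(df$mean_r1 <= 0)) stop("mean_dvr and mean_r1 must be positive")
    if (is.null(regions)) regions <- sort(df$region)
    if (!identical(sort(df$region), regions)) {
      stop("all groups must list the same regions")
    }
  }
  if (!(reference_region %in% regions)) stop("reference_region missing from the group tables")
  structure(list(groups = groups, n_per_group = n_per_group,
                 noise_scale = noise_scale, seed = seed, schedule = schedule,
                 k2prime = k2prime, reference_region = reference_region,
                 K1_ref_mean = K1_ref_mean, K1_ref_sd = K1_ref_sd,
                 timepoint = timepoint),
            class = "cohort_spec")
}

#' Default sham vs SCI cohort specification
#'
#' Ships the study conditions of a T7 contusion experiment quantified against
#' the cervical cord (SC1): regional true-DVR means/SDs for the lesion
#' epicenter (SC3) and lower thoracic cord (SC4) follow the reported group
#' values, SC1 is the reference (DVR 1 by definition), SC2/SC5 show no group
#' difference, and a brain-stem (BS) region with roughly 2.2-fold SC1 uptake
#' is included so reference switching is exercised. On day 1 the lesion R1 is
#' reduced to 0.7 (acute delivery deficit); by days 9-11 delivery has
#' recovered.
#'
#' @param timepoint `"day1"` or `"day9_11"`.
#' @param n_per_group animals per group (default 7 sham, 9 SCI).
#' @param noise_scale,seed passed to [cohort_spec()].
#' @return A [cohort_spec()].
#' @export
default_cohort_spec <- function(timepoint = c("day1", "day9_11"),
                                n_per_group = c(sham = 7L, SCI = 9L),
                                noise_scale = 0.05, seed = 1L) {
  timepoint <- match.arg(timepoint)
  base <- data.frame(
    region = c("SC1", "SC2", "SC3", "SC4", "SC5", "BS"),
    mean_dvr = c(1.00, 0.80, 0.72, 0.77, 0.85, 2.20),
    sd_dvr   = c(0.00, 0.05, 0.066, 0.043, 0.05, 0.15),
    mean_r1  = c(1.00, 1.00, 1.00, 1.00, 1.00, 1.00))
  sham <- base
  sci <- base
  if (timepoint == "day1") {
    sci$mean_dvr[sci$region == "SC3"] <- 0.28
    sci$sd_dvr[sci$region == "SC3"] <- 0.098
    sci$mean_r1[sci$region == "SC3"] <- 0.70
  } else {
    sham$mean_dvr[sham$region == "SC3"] <- 0.66
    sham$sd_dvr[sham$region == "SC3"] <- 0.032
    sci$mean_dvr[sci$region == "SC3"] <- 0.31
    sci$sd_dvr[sci$region == "SC3"] <- 0.052
    sci$mean_dvr[sci$region == "SC4"] <- 0.70
    sci$sd_dvr[sci$region == "SC4"] <- 0.022
  }
  cohort_spec(groups = list(sham = sham, SCI = sci), n_per_group = n_per_group,
              noise_scale = noise_scale, seed = seed, timepoint = timepoint)
}

#' Simulate a sham/SCI cohort of regional TACs with known truth
#'
#' Per animal, draws a reference delivery rate and a shared noise-free
#' reference curve; per region, draws the true DVR from the group's
#' `Normal(mean, SD)` truncated above 0.05, derives
#' `k2a = R1 k2prime / DVR`, and generates the region TAC (including the
#' reference region itself, whose truth is DVR 1) with frame noise. The truth
#' table is returned alongside the TACs.
#'
#' @param spec a [cohort_spec()].
#' @return A list of class `sc_cohort`: `tacs` (long data frame with columns
#'   `animal_id`, `group`, `region`, `frame_start_min`, `frame_duration_min`,
#'   `activity_kBq_per_mL`), `truth` (per animal/region `true_DVR`,
#'   `true_R1`, `true_k2a`), and the echoed `spec`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  sched <- spec$schedule
  with_seed(spec$seed, {
    tac_rows <- list()
    truth_rows <- list()
    for (g in names(spec$groups)) {
      gt <- spec$groups[[g]]
      for (i in seq_len(spec$n_per_group[[g]])) {
        id <- sprintf("%s_%02d", g, i)
        k1 <- rnorm_trunc(1L, spec$K1_ref_mean, spec$K1_ref_sd, lower = 0.02)
        ref <- simulate_reference_tac(sched, K1_ref = k1, k2prime = spec$k2prime,
                                      noise_scale = 0)
        for (r in seq_len(nrow(gt))) {
          dvr <- rnorm_trunc(1L, gt$mean_dvr[r], gt$sd_dvr[r], lower = 0.05)
          r1 <- gt$mean_r1[r]
          k2a <- r1 * spec$k2prime / dvr
          reg <- simulate_target_tac_srtm(ref, R1 = r1, k2a = k2a,
                                          k2prime = spec$k2prime,
                                          noise_scale = spec$noise_scale,
                                          region = gt$region[r])
          tac_rows[[length(tac_rows) + 1L]] <- data.frame(
            animal_id = id, group = g, region = gt$region[r],
            frame_start_min = reg$frame_start,
            frame_duration_min = reg$frame_duration,
            activity_kBq_per_mL = reg$activity)
          truth_rows[[length(truth_rows) + 1L]] <- data.frame(
            animal_id = id, group = g, region = gt$region[r],
            true_DVR = dvr, true_R1 = r1, true_k2a = k2a, K1_ref = k1)
        }
      }
    }
    structure(list(tacs = do.call(rbind, tac_rows),
                   truth = do.call(rbind, truth_rows),
                   spec = spec),
              class = "sc_cohort")
  })
}

#' Split a long cohort TAC table into per-animal TAC lists
#'
#' @param tacs long TAC data frame (schema of [simulate_cohort()]).
#' @return Named list (animal id) of named lists (region) of [tac()] objects,
#'   each carrying the animal's group in the `"group"` attribute.
#' @export
split_cohort_tacs <- function(tacs) {
  need <- c("animal_id", "group", "region", "frame_start_min",
            "frame_duration_min", "activity_kBq_per_mL")
  if (!all(need %in% names(tacs))) stop("TAC table lacks the cohort schema columns")
  out <- list()
  for (id in unique(tacs$animal_id)) {
    sub <- tacs[tacs$animal_id == id, ]
    regions <- list()
    for (r in unique(sub$region)) {
      rr <- sub[sub$region == r, ]
      sched <- frame_schedule(rr$frame_start_min, rr$frame_duration_min)
      regions[[r]] <- tac(sched, rr$activity_kBq_per_mL, region = r)
    }
    attr(regions, "group") <- sub$group[1]
    out[[id]] <- regions
  }
  out
}
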