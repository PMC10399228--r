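#' Filter steps needed to reach a gravity level
#'
#' Counts the filter steps after a transition until the MAP estimate first
#' comes within `tol` of the target level: the working definition of
#' (re)adaptation time used throughout the package.
#'
#' @param sim A `grav_sim`.
#' @param after Model time of the transition (steps strictly after this
#'   time are counted).
#' @param target Target gravity level (g units).
#' @param tol Tolerance (g units).
#' @return Integer step count (1 = first step after the transition), or
#'   `Inf` if the level is never reached.
#' @export
steps_to_reach <- function(sim, after, target, tol = 0.05) {
  st <- sim$steps
  sel <- which(st$t > after)
  if (!length(sel)) {
    return(Inf)
  }
  hit <- which(abs(st$map_estimate[sel] - target) <= tol)
  if (!length(hit)) Inf else hit[1]
}

#' Exploration-cascade events around a gravity transition
#'
#' After a gravity step the maximum-likelihood history (HML) collapses,
#' which widens the jitter, which in turn raises the LTM priority weight.
#' This helper locates, for one transition, the first filter step at which
#' each of the three signals crosses a relative threshold, so the ordering
#' of the cascade can be asserted.
#'
#' @param sim A `grav_sim`.
#' @param at Model time of the transition.
#' @param horizon Steps after the transition to search.
#' @param drop_frac HML counts as dropped when below `drop_frac` times its
#'   pre-transition value.
#' @param rise_factor Sigma / W count as risen when above `rise_factor`
#'   times their pre-transition values.
#' @return A one-row tibble with step indices (relative to the transition)
#'   `hml_drop`, `sigma_rise`, `w_rise` (`NA` if not observed within the
#'   horizon).
#' @export
transition_events <- function(sim, at, horizon = 50, drop_frac = 0.5,
                              rise_factor = 2) {
  st <- sim$steps
  pre <- max(which(st$t <= at))
  post <- which(st$t > at)
  post <- post[seq_len(min(horizon, length(post)))]
  first_at <- function(cond) {
    i <- which(cond)
    if (length(i)) i[1] else NA_integer_
  }
  tibble::tibble(
    hml_drop = first_at(st$hml[post] < drop_frac * st$hml[pre]),
    sigma_rise = first_at(st$sigma[post] > rise_factor * st$sigma[pre]),
    w_rise = first_at(st$W[post] > rise_factor * st$W[pre])
  )
}

#' Peak perceived-to-actual roll ratio over a window
#'
#' Ratio of the peak absolute perceived roll to the peak absolute actual
#' roll over a time window, both sampled at the filter steps. A ratio above
#' 1 is tilt overestimation (the G-excess pattern in unadapted
#' hyper-gravity); an adapted observer sits near 1.
#'
#' @param sim A `grav_sim`.
#' @param from,to Window bounds (model seconds).
#' @return A single ratio (or `NA` if the window contains no steps).
#' @export
peak_roll_ratio <- function(sim, from, to) {
  st <- sim$steps
  sel <- st$t >= from & st$t <= to
  if (!any(sel)) {
    return(NA_real_)
  }
  max(abs(st$roll_perceived[sel])) / max(abs(st$roll_true[sel]))
}

#' Paired comparison of readaptation speed with and without LTM
#'
#' Runs the same scenario twice per seed -- long-term memory enabled and
#' disabled -- with a shared sensor-noise realization, and counts the filter
#' steps needed to re-enter each listed target level after its transition.
#'
#' @param motion A `grav_motion` with a gravity schedule.
#' @param config A [engine_config()] (its `ltm_enabled` flag is overridden).
#' @param seeds Integer vector of master seeds (one pair of runs per seed).
#' @param transitions A data frame with columns `at` (transition time) and
#'   `target` (level entered), e.g. rows of the schedule; defaults to every
#'   transition in the schedule after the first segment.
#' @param tol Tolerance on the MAP estimate (g units).
#' @return A tibble with one row per seed x transition: `seed`, `at`,
#'   `target`, `steps_ltm`, `steps_no_ltm`.
#' @export
compare_ltm_adaptation <- function(motion, config = engine_config(),
                                   seeds = 1:10, transitions = NULL,
                                   tol = 0.05) {
  schedule <- attr(motion, "schedule")
  if (is.null(transitions)) {
    if (is.null(schedule) || nrow(schedule) < 2) {
      abort("no transitions in the scenario; supply `transitions`.")
    }
    transitions <- data.frame(
      at = schedule$start[-1], target = schedule$level[-1]
    )
  }
  cfg_on <- config
  cfg_on$ltm_enabled <- TRUE
  cfg_off <- config
  cfg_off$ltm_enabled <- FALSE
  purrr::map_dfr(seeds, function(s) {
    sim_on <- simulate_adaptation(motion, cfg_on, seed = s, keep_particles = FALSE)
    sim_off <- simulate_adaptation(motion, cfg_off, seed = s, keep_particles = FALSE)
    purrr::map_dfr(seq_len(nrow(transitions)), function(i) {
      tibble::tibble(
        seed = s,
        at = transitions$at[i],
        target = transitions$target[i],
        steps_ltm = steps_to_reach(sim_on, transitions$at[i],
          transitions$target[i],
          tol = tol
        ),
        steps_no_ltm = steps_to_reach(sim_off, transitions$at[i],
          transitions$target[i],
          tol = tol
        )
      )
    })
  })
}
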