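#' Tidy a simulation into per-step records
#'
#' @param x A `grav_sim` from [simulate_adaptation()].
#' @param ... Unused.
#' @return A tibble with one row per filter step: time, MAP estimate, true
#'   gravity, maximum likelihood, HML, jitter width, LTM weight, central
#'   NIS, true and perceived roll, LTM mass (total and near each scheduled
#'   level) and effective sample size.
#' @method tidy grav_sim
#' @export
tidy.grav_sim <- function(x, ...) {
  x$steps
}

#' One-row summary of a simulation
#'
#' @param x A `grav_sim`.
#' @param final_window Number of trailing filter steps used for the final
#'   MAP summary.
#' @param ... Unused.
#' @return A tibble with one row: step counts, final-window median MAP,
#'   final true gravity, their absolute difference, the fraction of steps
#'   spent harmonious (central NIS below the threshold) and the peak jitter
#'   width.
#' @method glance grav_sim
#' @export
glance.grav_sim <- function(x, final_window = 20, ...) {
  st <- x$steps
  fw <- tail(st$map_estimate, final_window)
  tibble::tibble(
    n_steps = x$n_steps,
    n_particles = x$config$n_particles,
    ltm_enabled = x$config$ltm_enabled,
    final_map = stats::median(fw),
    final_g_true = tail(st$g_true, 1),
    final_abs_error = abs(stats::median(fw) - tail(st$g_true, 1)),
    harmonious_frac = mean(st$central_nis < x$config$nu),
    peak_sigma = max(st$sigma)
  )
}

#' Plot the adaptation trajectory
#'
#' Facetted time-series view of a simulation: MAP gravity estimate against
#' the true schedule, maximum likelihood and its history (HML), jitter
#' width, LTM priority weight, and central NIS against the harmony
#' threshold.
#'
#' @param object A `grav_sim`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot grav_sim
#' @export
autoplot.grav_sim <- function(object, ...) {
  st <- object$steps
  long <- dplyr::bind_rows(
    tibble::tibble(
      t = st$t, panel = "gravity (g)", series = "MAP estimate",
      value = st$map_estimate
    ),
    tibble::tibble(
      t = st$t, panel = "gravity (g)", series = "true",
      value = st$g_true
    ),
    tibble::tibble(
      t = st$t, panel = "likelihood", series = "max likelihood",
      value = st$max_lik
    ),
    tibble::tibble(t = st$t, panel = "likelihood", series = "HML", value = st$hml),
    tibble::tibble(
      t = st$t, panel = "jitter sigma (g)", series = "sigma",
      value = st$sigma
    ),
    tibble::tibble(t = st$t, panel = "LTM weight W", series = "W", value = st$W),
    tibble::tibble(
      t = st$t, panel = "central NIS", series = "NIS",
      value = st$central_nis
    )
  )
  long$panel <- factor(long$panel, levels = unique(long$panel))
  ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$value, colour = .data$series)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::geom_hline(
      data = data.frame(panel = factor("central NIS",
        levels = levels(long$panel)
      ), nu = object$config$nu),
      ggplot2::aes(yintercept = .data$nu), linetype = 2, colour = "grey40"
    ) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "model time", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Particle-cloud plot
#'
#' One point per particle per filter step, sized by its posterior weight:
#' the standard view of hypothesis evolution, in which learned states show
#' up as intermittent low-weight particles far from the main cluster.
#'
#' @param sim A `grav_sim` run with `keep_particles = TRUE`.
#' @param thin Plot every `thin`-th filter step.
#' @return A ggplot object.
#' @export
plot_particles <- function(sim, thin = 1) {
  if (is.null(sim$particles)) {
    abort("run `simulate_adaptation()` with `keep_particles = TRUE`.")
  }
  ks <- seq(1, ncol(sim$particles), by = thin)
  df <- tibble::tibble(
    t = rep(sim$steps$t[ks], each = nrow(sim$particles)),
    x = as.vector(sim$particles[, ks]),
    w = as.vector(sim$weights[, ks])
  )
  truth <- tibble::tibble(t = sim$steps$t, g = sim$steps$g_true)
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$x)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$w), alpha = 0.25, colour = "steelblue") +
    ggplot2::geom_step(
      data = truth, ggplot2::aes(.data$t, .data$g),
      colour = "black", linewidth = 0.3
    ) +
    ggplot2::scale_size_area(max_size = 2, guide = "none") +
    ggplot2::labs(
      x = "model time", y = "gravity hypothesis (g)",
      title = "Particle cloud (point size = posterior weight)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot perceived vs actual roll tilt
#'
#' @param sim A `grav_sim`.
#' @param from,to Optional window bounds (model seconds).
#' @return A ggplot object.
#' @export
plot_tilt <- function(sim, from = -Inf, to = Inf) {
  st <- dplyr::filter(sim$steps, .data$t >= from, .data$t <= to)
  long <- tidyr::pivot_longer(
    st[, c("t", "roll_true", "roll_perceived")],
    cols = -"t", names_to = "series", values_to = "roll"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$roll, colour = .data$series)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = "model time", y = "roll (deg)", colour = NULL) +
    ggplot2::theme_minimal()
}
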