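#' Stimulus event
#'
#' A rectangular current pulse delivered to one population of one area.
#' Defaults follow the standard sensory cue: 0.3 nA for 0.5 s.
#'
#' @param area target area name.
#' @param population \code{"A"}, \code{"B"} or \code{"inhibitory"}.
#' @param onset pulse onset (s).
#' @param duration pulse duration (s), > 0.
#' @param amplitude pulse amplitude (nA).
#' @return Object of class \code{"stimulus_event"}.
#' @export
stimulus_event <- function(area, population = c("A", "B", "inhibitory"),
                           onset = 1, duration = 0.5, amplitude = 0.3) {
  population <- match.arg(population)
  if (duration <= 0) stop("duration must be > 0")
  structure(list(area = area, population = population, onset = onset,
                 duration = duration, amplitude = amplitude),
            class = "stimulus_event")
}

#' Silencing specification
#'
#' Areas clamped to zero rate and zero conductance over a time window, so
#' they neither fire nor transmit (a "sink of current"). \code{end = Inf}
#' silences for the rest of the trial (permanent lesion).
#'
#' @param areas character vector of area names.
#' @param start,end window (s).
#' @return Object of class \code{"silencing_spec"}.
#' @export
silencing_spec <- function(areas, start = 0, end = Inf) {
  if (end <= start) stop("end must exceed start")
  structure(list(areas = areas, start = start, end = end),
            class = "silencing_spec")
}

as_event_list <- function(events) {
  if (is.null(events)) return(list())
  if (inherits(events, "stimulus_event")) return(list(events))
  stopifnot(all(vapply(events, inherits, TRUE, "stimulus_event")))
  events
}

events_matrix <- function(events, net, dt, n_steps) {
  events <- as_event_list(events)
  if (length(events) == 0) return(matrix(0, 0, 5))
  do.call(rbind, lapply(events, function(e) {
    i <- area_index(net, e$area)
    pop <- match(e$population, c("A", "B", "inhibitory")) - 1L
    on <- round(e$onset / dt)
    off <- min(round((e$onset + e$duration) / dt), n_steps)
    c(i - 1L, pop, on, off, e$amplitude)
  }))
}

silence_matrix <- function(silencing, net, dt, n_steps) {
  if (is.null(silencing)) return(matrix(0, 0, 3))
  if (inherits(silencing, "silencing_spec")) silencing <- list(silencing)
  do.call(rbind, lapply(silencing, function(s) {
    idx <- area_index(net, s$areas)
    on <- round(s$start / dt)
    off <- if (is.finite(s$end)) round(s$end / dt) else n_steps
    cbind(idx - 1L, on, off)
  }))
}

#' Simulate the cortical network
#'
#' Integrates the coupled stochastic system with fixed-step Euler-Maruyama.
#' The initial condition defaults to the coupled spontaneous state; stimulus
#' events add pulse currents to the targeted population, and silenced areas
#' are clamped to zero (no firing, no transmission) during their window.
#'
#' @param object a \code{\link{build_network}} model.
#' @param nsim number of trials; if > 1 a list of simulations is returned,
#'   with seeds \code{seed + 0:(nsim-1)}.
#' @param seed integer RNG seed (mandatory for stochastic runs).
#' @param duration trial length (s).
#' @param dt integration step (s).
#' @param events a \code{\link{stimulus_event}} or list thereof.
#' @param silencing a \code{\link{silencing_spec}} or list thereof.
#' @param deterministic disable the Ornstein-Uhlenbeck noise.
#' @param init initial state matrix (areas x 9) or \code{NULL} for the
#'   spontaneous state.
#' @param record_every store the rates every this many steps.
#' @param ... unused.
#' @return Object of class \code{"wm_sim"}: list with \code{time} (s),
#'   \code{rA}, \code{rB}, \code{rC} (time x area rate matrices, Hz),
#'   \code{final} state, \code{events}, \code{silencing}, \code{seed},
#'   diagnostics, and the network's spontaneous reference rates.
#' @examples
#' net <- build_network(generate_synthetic_connectome(seed = 1))
#' sim <- simulate(net, seed = 1, duration = 4,
#'                 events = stimulus_event("V1"))
#' @export
simulate.cortical_network <- function(object, nsim = 1, seed = NULL,
                                      duration = 10, dt = 5e-4,
                                      events = NULL, silencing = NULL,
                                      deterministic = FALSE, init = NULL,
                                      record_every = 20L, ...) {
  if (dt <= 0) stop("dt must be positive")
  if (!deterministic && is.null(seed))
    stop("a seed is mandatory for stochastic simulations")
  if (nsim > 1) {
    return(lapply(seq_len(nsim) - 1L, function(k) {
      simulate.cortical_network(object, nsim = 1, seed = seed + k,
                                duration = duration, dt = dt, events = events,
                                silencing = silencing,
                                deterministic = deterministic, init = init,
                                record_every = record_every)
    }))
  }
  n_steps <- as.integer(round(duration / dt))
  ev <- events_matrix(events, object, dt, n_steps)
  sil <- silence_matrix(silencing, object, dt, n_steps)
  st <- if (is.null(init)) object$spont else init
  if (!is.null(seed)) set.seed(seed)
  res <- sim_network_cpp(st, cpp_params(object), object$W_EE, object$W_EI,
                         object$G, object$Z, ev, sil,
                         dt, n_steps, as.integer(record_every),
                         deterministic, 0, 1000L)
  if (res$unstable)
    stop(sprintf(
      "integration unstable at t = %.3f s (|dS| > 0.2 in one step); reduce dt",
      res$steps_run * dt))
  if (res$n_clip > 0)
    warning(sprintf("gating variables clipped to [0, 1] %d times", res$n_clip))
  dimnames(res$rA) <- dimnames(res$rB) <- dimnames(res$rC) <-
    list(NULL, object$areas)
  rownames(res$final) <- object$areas
  colnames(res$final) <- colnames(object$spont)
  structure(list(time = res$time, rA = res$rA, rB = res$rB, rC = res$rC,
                 final = res$final, areas = object$areas, dt = dt,
                 seed = seed, events = as_event_list(events),
                 silencing = silencing, n_clip = res$n_clip,
                 h = object$h,
                 spont_rate = stats::setNames(rep(object$spont_rate_iso,
                   length(object$areas)), object$areas)),
            class = "wm_sim")
}

#' Relax the network deterministically to a nearby attractor
#'
#' Noise-free integration with an early exit once the maximum rate change
#' per check interval falls below \code{tol}; used by the attractor census
#' and the fixed-point consistency checks.
#'
#' @param net a \code{\link{build_network}} model.
#' @param init initial state matrix (areas x 9).
#' @param max_time maximum integration time (s).
#' @param dt step (s).
#' @param tol convergence tolerance (Hz per check interval).
#' @param check_interval interval between convergence checks (s).
#' @param silencing optional \code{\link{silencing_spec}} (applied for the
#'   whole relaxation).
#' @return List with \code{state} (final areas x 9 matrix), \code{converged},
#'   \code{time_run} (s).
#' @export
relax_network <- function(net, init = NULL, max_time = 20, dt = 1e-3,
                          tol = 0.01, check_interval = 0.5,
                          silencing = NULL) {
  st <- if (is.null(init)) net$spont else init
  n_steps <- as.integer(round(max_time / dt))
  sil <- silence_matrix(silencing, net, dt, n_steps)
  res <- sim_network_cpp(st, cpp_params(net), net$W_EE, net$W_EI,
                         net$G, net$Z, matrix(0, 0, 5), sil,
                         dt, n_steps, 0L, TRUE,
                         tol, as.integer(check_interval / dt))
  if (res$unstable) stop("instability during relaxation; reduce dt")
  st <- res$final
  rownames(st) <- net$areas
  colnames(st) <- colnames(net$spont)
  list(state = st, converged = res$converged,
       time_run = res$steps_run * dt)
}

#' @export
print.wm_sim <- function(x, ...) {
  cat(sprintf("Network simulation: %d areas, %.1f s (%d samples kept)\n",
              ncol(x$rA), max(x$time), length(x$time)))
  if (length(x$events) > 0)
    for (e in x$events)
      cat(sprintf("  event: %s pool %s, %.2f nA at %.2f-%.2f s\n",
                  e$area, e$population, e$amplitude, e$onset,
                  e$onset + e$duration))
  invisible(x)
}

#' Plot population-A rate traces
#'
#' @param x a \code{"wm_sim"} object.
#' @param areas areas to draw (default: six spread across the hierarchy).
#' @param pool \code{"A"}, \code{"B"} or \code{"C"}.
#' @param ... passed to \code{matplot}.
#' @export
plot.wm_sim <- function(x, areas = NULL, pool = "A", ...) {
  if (is.null(areas)) {
    ord <- order(x$h)
    areas <- x$areas[ord[unique(round(seq(1, length(ord), length.out = 6)))]]
  }
  idx <- match(areas, x$areas)
  m <- switch(pool, A = x$rA, B = x$rB, C = x$rC)
  graphics::matplot(x$time, m[, idx, drop = FALSE], type = "l", lty = 1,
                    xlab = "time (s)", ylab = sprintf("rate pool %s (Hz)", pool),
                    ...)
  graphics::legend("topleft", legend = areas, lty = 1,
                   col = seq_along(areas), bty = "n", cex = 0.8)
  invisible(x)
}

#' Summarize delay-period activity
#'
#' Mean cued-pool rate per area over a delay window, the set of areas with
#' sustained activity (rate above the spontaneous rate plus a margin), the
#' selectivity index (cued minus anti-cued pool rate) and the ranked-rate
#' gap separating active from inactive areas.
#'
#' @param sim a \code{"wm_sim"} object.
#' @param window length-2 window (s); default: the last 2 s of the trial.
#' @param threshold activity threshold (Hz); default: spontaneous + 5 Hz.
#' @param cued cued pool, \code{"A"} or \code{"B"}.
#' @param sel_margin selectivity margin (Hz): the \code{selective_active}
#'   set additionally requires the cued pool to exceed the anti-cued pool by
#'   this much, which excludes areas whose baseline is tonically (and
#'   symmetrically) elevated.
#' @return Object of class \code{"delay_summary"}: list with \code{table}
#'   (data.frame: area, h, rate of cued and anti-cued pools, active and
#'   selective flags), \code{active} and \code{selective_active} (area
#'   names), \code{threshold}, \code{window},
#'   \code{gap} (rate separation between the slowest active and the fastest
#'   inactive area; NA when one group is empty) and
#'   \code{rate_orders} (rate-ranked and hierarchy orderings).
#' @export
summarize_delay_activity <- function(sim, window = NULL, threshold = NULL,
                                     cued = c("A", "B"), sel_margin = 5) {
  cued <- match.arg(cued)
  t_end <- max(sim$time)
  if (is.null(window)) window <- c(max(t_end - 2, 0), t_end)
  if (window[2] > t_end + 1e-9 || window[1] >= window[2])
    stop("window must be increasing and inside the simulated time")
  cue_ev <- Filter(function(e) e$population %in% c("A", "B"), sim$events)
  offsets <- vapply(cue_ev, function(e) e$onset + e$duration, 0)
  if (length(offsets) > 0 && window[1] < max(offsets))
    warning("delay window starts before the last stimulus offset")
  keep <- sim$time >= window[1] & sim$time <= window[2]
  mc <- colMeans((if (cued == "A") sim$rA else sim$rB)[keep, , drop = FALSE])
  ma <- colMeans((if (cued == "A") sim$rB else sim$rA)[keep, , drop = FALSE])
  if (is.null(threshold)) threshold <- mean(sim$spont_rate) + 5
  active <- mc > threshold
  selective <- active & (mc - ma > sel_margin)
  tab <- data.frame(area = sim$areas, h = as.numeric(sim$h),
                    rate_cued = as.numeric(mc), rate_anti = as.numeric(ma),
                    selectivity = as.numeric(mc - ma),
                    active = active, selective = selective, row.names = NULL)
  # separation between the slowest active and fastest inactive area: the
  # "gap" in the ranked delay rates that marks the transition in space
  gap <- if (any(active) && any(!active)) {
    min(mc[active]) - max(mc[!active])
  } else {
    NA_real_
  }
  structure(list(table = tab, active = sim$areas[active],
                 selective_active = sim$areas[selective],
                 threshold = threshold, window = window,
                 gap = gap,
                 rate_orders = list(
                   rate = sim$areas[order(mc, decreasing = TRUE)],
                   hierarchy = sim$areas[order(sim$h, decreasing = TRUE)])),
            class = "delay_summary")
}

#' @export
print.delay_summary <- function(x, ...) {
  cat(sprintf(
    "Delay summary (%.1f-%.1f s, threshold %.1f Hz): %d/%d areas active\n",
    x$window[1], x$window[2], x$threshold, length(x$active),
    nrow(x$table)))
  if (is.finite(x$gap))
    cat(sprintf("  ranked-rate gap %.1f Hz between active and inactive groups\n",
                x$gap))
  invisible(x)
}
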