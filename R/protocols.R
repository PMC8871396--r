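#' Run a cue/delay working-memory trial
#'
#' Delivers a selective cue pulse to one area's pool A (by default the
#' bottom-of-hierarchy area, i.e. the primary sensory entry point) and
#' summarizes delay-period activity.
#'
#' @param net a \code{\link{build_network}} model.
#' @param cue_area area receiving the cue; default: lowest hierarchy value.
#' @param amplitude,cue_onset,cue_duration cue pulse parameters (nA, s, s).
#' @param duration trial length (s).
#' @param population cued pool.
#' @param seed RNG seed.
#' @param deterministic disable noise.
#' @param dt integration step (s).
#' @param ... passed to \code{\link{summarize_delay_activity}}.
#' @return List with \code{sim} (\code{wm_sim}) and \code{summary}
#'   (\code{delay_summary}).
#' @export
run_wm_trial <- function(net, cue_area = NULL, amplitude = 0.3,
                         cue_onset = 1, cue_duration = 0.5, duration = 10,
                         population = "A", seed = 1, deterministic = FALSE,
                         dt = 5e-4, ...) {
  if (is.null(cue_area)) cue_area <- net$areas[which.min(net$h)]
  ev <- stimulus_event(cue_area, population, onset = cue_onset,
                       duration = cue_duration, amplitude = amplitude)
  sim <- simulate(net, seed = seed, duration = duration, dt = dt,
                  events = ev, deterministic = deterministic)
  list(sim = sim, summary = summarize_delay_activity(sim, cued = population,
                                                     ...))
}

# majority vote over the top-k hierarchy areas: which pool holds the memory
decide_outcome <- function(sim, window, threshold, k = 5, sel_margin = 5) {
  ord <- order(sim$h, decreasing = TRUE)
  top <- ord[seq_len(min(k, length(ord)))]
  keep <- sim$time >= window[1] & sim$time <= window[2]
  ra <- colMeans(sim$rA[keep, top, drop = FALSE])
  rb <- colMeans(sim$rB[keep, top, drop = FALSE])
  na <- sum(ra > threshold & ra - rb > sel_margin)
  nb <- sum(rb > threshold & rb - ra > sel_margin)
  if (na == 0 && nb == 0) return("lost")
  if (nb > na) "switched-to-distractor" else "retained-cue"
}

#' Run a distractor trial
#'
#' Cue to pool A followed, after \code{gap} seconds, by a distractor of the
#' same duration delivered to pool B; the outcome is decided by majority over
#' the five top-hierarchy areas in the late delay window.
#'
#' @param net a \code{\link{build_network}} model.
#' @param cue_area,distractor_area stimulated areas (default: bottom of the
#'   hierarchy for both, as in a same-modality distractor).
#' @param cue_amplitude,distractor_amplitude pulse strengths (nA).
#' @param gap delay between cue offset and distractor onset (s).
#' @param cue_onset,pulse_duration timing (s).
#' @param tail_time delay simulated after distractor offset (s).
#' @param threshold activity threshold (Hz); default spontaneous + 5.
#' @param seed RNG seed.
#' @param deterministic disable noise.
#' @param dt integration step (s).
#' @return List with \code{outcome} (\code{"retained-cue"},
#'   \code{"switched-to-distractor"} or \code{"lost"}) and \code{sim}.
#' @export
run_distractor_trial <- function(net, cue_area = NULL,
                                 distractor_area = NULL,
                                 cue_amplitude = 0.3,
                                 distractor_amplitude = 0.3,
                                 gap = 4, cue_onset = 1, pulse_duration = 0.5,
                                 tail_time = 4, threshold = NULL,
                                 seed = 1, deterministic = FALSE, dt = 5e-4) {
  if (is.null(cue_area)) cue_area <- net$areas[which.min(net$h)]
  if (is.null(distractor_area)) distractor_area <- cue_area
  d_onset <- cue_onset + pulse_duration + gap
  duration <- d_onset + pulse_duration + tail_time
  events <- list(
    stimulus_event(cue_area, "A", onset = cue_onset,
                   duration = pulse_duration, amplitude = cue_amplitude))
  if (distractor_amplitude > 0)
    events <- c(events, list(
      stimulus_event(distractor_area, "B", onset = d_onset,
                     duration = pulse_duration,
                     amplitude = distractor_amplitude)))
  sim <- simulate(net, seed = seed, duration = duration, dt = dt,
                  events = events, deterministic = deterministic)
  if (is.null(threshold)) threshold <- mean(sim$spont_rate) + 5
  window <- c(duration - 2, duration)
  list(outcome = decide_outcome(sim, window, threshold), sim = sim)
}

#' Minimal effective stimulus strength
#'
#' Bisection on pulse amplitude for either role: the minimal cue strength
#' that elicits a sustained distributed pattern, or the minimal distractor
#' strength that overwrites a stored cue. The outcome must be monotone in
#' amplitude over the bracket (verified at the endpoints).
#'
#' @param net a \code{\link{build_network}} model.
#' @param role \code{"cue"} or \code{"distractor"}.
#' @param bracket length-2 amplitude bracket (nA).
#' @param tol bisection tolerance (nA).
#' @param cue_amplitude cue strength used when probing distractors (nA).
#' @param deterministic,seed,dt,... passed to the underlying trials.
#' @return Threshold amplitude (nA).
#' @export
minimal_strength_search <- function(net, role = c("cue", "distractor"),
                                    bracket = c(0.01, 0.9), tol = 0.01,
                                    cue_amplitude = 0.3,
                                    deterministic = TRUE, seed = 1,
                                    dt = 5e-4, ...) {
  role <- match.arg(role)
  succeeds <- function(amp) {
    if (role == "cue") {
      tr <- run_wm_trial(net, amplitude = amp, duration = 8, seed = seed,
                         deterministic = deterministic, dt = dt, ...)
      length(tr$summary$selective_active) > 0
    } else {
      tr <- run_distractor_trial(net, cue_amplitude = cue_amplitude,
                                 distractor_amplitude = amp, gap = 4,
                                 tail_time = 3, seed = seed,
                                 deterministic = deterministic, dt = dt)
      tr$outcome != "retained-cue"
    }
  }
  lo <- bracket[1]
  hi <- bracket[2]
  s_lo <- succeeds(lo)
  s_hi <- succeeds(hi)
  if (s_lo || !s_hi)
    stop(sprintf(
      "bracket does not straddle the threshold (outcome %s at %.3f, %s at %.3f)",
      s_lo, lo, s_hi, hi))
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (succeeds(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Targeted shutdown of a distributed attractor
#'
#' Establishes a cue-evoked attractor, then delivers an excitatory pulse to
#' the inhibitory populations of a small set of top-hierarchy (frontal)
#' areas, and reports whether the whole network returns to the spontaneous
#' state.
#'
#' @param net a \code{\link{build_network}} model.
#' @param targets areas receiving the shutdown input; default: the four
#'   top-hierarchy areas (9/46v, 9/46d, F7, 8B on the canonical gradient).
#' @param amplitude shutdown pulse strength (nA).
#' @param shutdown_duration pulse length (s).
#' @param cue_area,cue_amplitude cue parameters.
#' @param settle time between cue offset and shutdown onset (s).
#' @param tail_time time simulated after the shutdown pulse (s).
#' @param threshold activity threshold (Hz).
#' @param seed,deterministic,dt integration controls.
#' @return List with \code{sim}, \code{pre} and \code{post}
#'   (\code{delay_summary} before/after shutdown) and \code{shut_down}
#'   (logical: no area active at trial end).
#' @export
run_shutdown_protocol <- function(net, targets = NULL, amplitude = 0.3,
                                  shutdown_duration = 1.0,
                                  cue_area = NULL, cue_amplitude = 0.3,
                                  settle = 3, tail_time = 4, threshold = NULL,
                                  seed = 1, deterministic = FALSE,
                                  dt = 5e-4) {
  if (is.null(targets)) {
    ord <- order(net$h, decreasing = TRUE)
    targets <- net$areas[ord[1:4]]
  } else {
    area_index(net, targets)  # validate names
  }
  if (is.null(cue_area)) cue_area <- net$areas[which.min(net$h)]
  cue_off <- 1 + 0.5
  shut_on <- cue_off + settle
  duration <- shut_on + shutdown_duration + tail_time
  events <- c(
    list(stimulus_event(cue_area, "A", onset = 1, duration = 0.5,
                        amplitude = cue_amplitude)),
    lapply(targets, function(a)
      stimulus_event(a, "inhibitory", onset = shut_on,
                     duration = shutdown_duration, amplitude = amplitude)))
  sim <- simulate(net, seed = seed, duration = duration, dt = dt,
                  events = events, deterministic = deterministic)
  pre <- summarize_delay_activity(sim, window = c(shut_on - 1, shut_on),
                                  threshold = threshold)
  post <- summarize_delay_activity(sim, window = c(duration - 1, duration),
                                   threshold = threshold)
  list(sim = sim, pre = pre, post = post,
       shut_down = length(post$active) == 0)
}
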