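#' Parameters of the local three-population circuit
#'
#' Constructs the parameter set of one cortical area modelled as a reduced
#' three-variable circuit: two stimulus-selective excitatory populations (A, B)
#' whose synaptic drive is carried by slow NMDA-like gating variables, and one
#' inhibitory population with fast GABA-like dynamics. Defaults reproduce the
#' baseline sensory-area operating point; along the cortical hierarchy only
#' \code{J_s} (local self-excitation) and \code{J_IE} (excitatory drive onto
#' the inhibitory pool) vary.
#'
#' Inhibitory couplings \code{J_EI} and \code{J_II} carry their negative sign
#' explicitly.
#'
#' @param tau_N NMDA gating time constant (s).
#' @param tau_G GABA conductance time constant (s).
#' @param gamma NMDA coupling factor (dimensionless).
#' @param gamma_I GABA coupling factor (dimensionless).
#' @param J_s local excitatory self-coupling (nA).
#' @param J_c cross-coupling between the two excitatory pools (nA).
#' @param J_EI inhibitory-to-excitatory coupling (nA, must be <= 0).
#' @param J_IE excitatory-to-inhibitory coupling (nA, must be >= 0).
#' @param J_II inhibitory self-coupling (nA, must be <= 0).
#' @param I0_A,I0_B,I0_C background currents (nA).
#' @param a,b,d excitatory transfer-function gain (Hz/nA), threshold (Hz) and
#'   curvature (s).
#' @param g_I,c1,c0,r0 inhibitory transfer-function divisor, gain (Hz/nA),
#'   threshold (Hz) and baseline rate (Hz).
#' @param tau_r relaxation time constant of the firing rates (s).
#' @param tau_noise Ornstein-Uhlenbeck noise time constant (s).
#' @param sigma_A,sigma_B,sigma_C noise amplitudes (nA).
#' @return An object of class \code{"local_circuit_params"} (named list).
#' @examples
#' p <- local_circuit_params()
#' phi_excitatory(0.4, p)  # 1/d at threshold
#' @export
local_circuit_params <- function(tau_N = 0.060, tau_G = 0.005,
                                 gamma = 1.282, gamma_I = 2,
                                 J_s = 0.3213, J_c = 0.0107,
                                 J_EI = -0.31, J_IE = 0.15, J_II = -0.12,
                                 I0_A = 0.3294, I0_B = 0.3294, I0_C = 0.26,
                                 a = 135, b = 54, d = 0.308,
                                 g_I = 4, c1 = 615, c0 = 177, r0 = 5.5,
                                 tau_r = 0.002, tau_noise = 0.002,
                                 sigma_A = 0.005, sigma_B = 0.005,
                                 sigma_C = 0) {
  p <- list(tau_N = tau_N, tau_G = tau_G, gamma = gamma, gamma_I = gamma_I,
            J_s = J_s, J_c = J_c, J_EI = J_EI, J_IE = J_IE, J_II = J_II,
            I0_A = I0_A, I0_B = I0_B, I0_C = I0_C,
            a = a, b = b, d = d, g_I = g_I, c1 = c1, c0 = c0, r0 = r0,
            tau_r = tau_r, tau_noise = tau_noise,
            sigma_A = sigma_A, sigma_B = sigma_B, sigma_C = sigma_C)
  validate_local_params(p)
  class(p) <- "local_circuit_params"
  p
}

validate_local_params <- function(p) {
  taus <- c(p$tau_N, p$tau_G, p$tau_r, p$tau_noise)
  if (any(!is.finite(unlist(p))))
    stop("local circuit parameters must be finite")
  if (any(taus <= 0)) stop("time constants must be strictly positive")
  if (p$J_EI > 0 || p$J_II > 0)
    stop("inhibitory couplings J_EI, J_II must be <= 0")
  if (any(c(p$J_s, p$J_c, p$J_IE) < 0))
    stop("excitatory couplings J_s, J_c, J_IE must be >= 0")
  if (any(c(p$a, p$c1, p$g_I) <= 0)) stop("gains a, c1, g_I must be > 0")
  invisible(p)
}

#' @export
print.local_circuit_params <- function(x, ...) {
  cat("Local circuit parameters (three-population reduced model)\n")
  cat(sprintf("  J_s = %.4f nA, J_IE = %.4f nA (gradient-bearing couplings)\n",
              x$J_s, x$J_IE))
  cat(sprintf("  tau_N = %g ms, tau_G = %g ms, noise sigma = %g nA\n",
              1000 * x$tau_N, 1000 * x$tau_G, x$sigma_A))
  invisible(x)
}

#' Transfer function of the excitatory populations
#'
#' \code{phi_excitatory(I) = (aI - b) / (1 - exp(-d(aI - b)))}, the standard
#' smoothed threshold-linear f-I curve of reduced mean-field excitatory
#' populations. The removable 0/0 singularity at \code{aI = b} is handled
#' analytically (limit \code{1/d}); \code{expm1} keeps the evaluation accurate
#' arbitrarily close to threshold.
#'
#' @param I input current (nA); vectorised.
#' @param params a \code{\link{local_circuit_params}} object.
#' @return Firing rate (Hz).
#' @export
phi_excitatory <- function(I, params = local_circuit_params()) {
  if (any(!is.finite(I))) stop("input current must be finite")
  x <- params$a * I - params$b
  out <- ifelse(x == 0, 1 / params$d, x / (-expm1(-params$d * x)))
  as.numeric(out)
}

#' Transfer function of the inhibitory population
#'
#' Threshold-linear curve \code{phi_inhibitory(I) = (c1 I - c0)/g_I + r0},
#' rectified at zero rate, i.e. \code{max(c1 I - c0 + g_I r0, 0)/g_I}. At
#' threshold input \code{I = c0/c1} it returns the baseline rate \code{r0}.
#'
#' @inheritParams phi_excitatory
#' @return Firing rate (Hz).
#' @export
phi_inhibitory <- function(I, params = local_circuit_params()) {
  if (any(!is.finite(I))) stop("input current must be finite")
  pmax(params$c1 * I - params$c0 + params$g_I * params$r0, 0) / params$g_I
}

#' Initial (resting) state of one area
#'
#' @param params a \code{\link{local_circuit_params}} object.
#' @return Named numeric vector with components \code{S_A, S_B, S_C, r_A, r_B,
#'   r_C, x_A, x_B, x_C} (all zero).
#' @export
area_state <- function(params = local_circuit_params()) {
  s <- numeric(9)
  names(s) <- c("S_A", "S_B", "S_C", "r_A", "r_B", "r_C", "x_A", "x_B", "x_C")
  s
}

#' Population input currents
#'
#' Total current entering each of the three populations:
#' \deqn{I_A = J_s S_A + J_c S_B + J_{EI} S_C + I_{0A} + I_{net,A} + stim_A + x_A}
#' (B analogous with \code{J_s} and \code{J_c} exchanged) and
#' \deqn{I_C = J_{IE}(S_A + S_B) + J_{II} S_C + I_{0C} + I_{net,C} + stim_C + x_C.}
#'
#' @param state named state vector as returned by \code{\link{area_state}}.
#' @param params a \code{\link{local_circuit_params}} object.
#' @param net_input length-3 long-range input currents (nA), order (A, B, C).
#' @param stim length-3 stimulus currents (nA).
#' @return Named numeric vector \code{c(I_A, I_B, I_C)} (nA).
#' @export
population_currents <- function(state, params = local_circuit_params(),
                                net_input = c(0, 0, 0), stim = c(0, 0, 0)) {
  if (any(!is.finite(c(state, net_input, stim))))
    stop("state and inputs must be finite")
  p <- params
  IA <- p$J_s * state["S_A"] + p$J_c * state["S_B"] + p$J_EI * state["S_C"] +
    p$I0_A + net_input[1] + stim[1] + state["x_A"]
  IB <- p$J_c * state["S_A"] + p$J_s * state["S_B"] + p$J_EI * state["S_C"] +
    p$I0_B + net_input[2] + stim[2] + state["x_B"]
  IC <- p$J_IE * (state["S_A"] + state["S_B"]) + p$J_II * state["S_C"] +
    p$I0_C + net_input[3] + stim[3] + state["x_C"]
  c(I_A = unname(IA), I_B = unname(IB), I_C = unname(IC))
}

#' Advance one area by a single Euler-Maruyama step
#'
#' Reference single-area integrator (the coupled network uses the compiled
#' equivalent). Gating variables follow
#' \code{dS/dt = -S/tau_N + gamma (1 - S) r} (excitatory) and
#' \code{dS_C/dt = -S_C/tau_G + gamma_I r_C}; rates relax towards the transfer
#' functions with time constant \code{tau_r}; the noise currents are
#' Ornstein-Uhlenbeck processes with stationary s.d.
#' \code{sigma * sqrt(tau_noise / 2)}.
#'
#' @param state named state vector (see \code{\link{area_state}}).
#' @param params a \code{\link{local_circuit_params}} object.
#' @param dt time step (s); must satisfy \code{dt <= tau_r}.
#' @param net_input,stim length-3 current vectors (nA).
#' @param deterministic if \code{TRUE} the noise increments are skipped.
#' @return Updated named state vector.
#' @export
step_area <- function(state, params = local_circuit_params(), dt = 5e-4,
                      net_input = c(0, 0, 0), stim = c(0, 0, 0),
                      deterministic = FALSE) {
  if (!is.numeric(dt) || dt <= 0) stop("dt must be positive")
  if (dt > params$tau_r) stop("dt must not exceed tau_r for stability")
  p <- params
  I <- population_currents(state, p, net_input, stim)
  fA <- phi_excitatory(I[["I_A"]], p)
  fB <- phi_excitatory(I[["I_B"]], p)
  fC <- phi_inhibitory(I[["I_C"]], p)
  s <- state
  s["S_A"] <- clip01(state["S_A"] +
    dt * (-state["S_A"] / p$tau_N + p$gamma * (1 - state["S_A"]) * state["r_A"]))
  s["S_B"] <- clip01(state["S_B"] +
    dt * (-state["S_B"] / p$tau_N + p$gamma * (1 - state["S_B"]) * state["r_B"]))
  s["S_C"] <- max(state["S_C"] +
    dt * (-state["S_C"] / p$tau_G + p$gamma_I * state["r_C"]), 0)
  s["r_A"] <- max(state["r_A"] + dt / p$tau_r * (fA - state["r_A"]), 0)
  s["r_B"] <- max(state["r_B"] + dt / p$tau_r * (fB - state["r_B"]), 0)
  s["r_C"] <- max(state["r_C"] + dt / p$tau_r * (fC - state["r_C"]), 0)
  if (deterministic) {
    eta <- c(0, 0, 0)
  } else {
    eta <- stats::rnorm(3)
  }
  sig <- c(p$sigma_A, p$sigma_B, p$sigma_C)
  for (k in 1:3) {
    xk <- c("x_A", "x_B", "x_C")[k]
    s[xk] <- state[xk] + dt * (-state[xk] / p$tau_noise) +
      sig[k] * sqrt(dt) * eta[k]
  }
  s
}

clip01 <- function(x) min(max(x, 0), 1)

## ---- fixed points of the isolated area ----------------------------------

# Steady inhibitory rate given total excitatory gating S_A + S_B, solving the
# linear self-consistency r_C = phi_C(J_IE St + J_II tau_G gamma_I r_C + I0_C).
rc_steady <- function(St, p) {
  den <- 1 - p$c1 * p$J_II * p$tau_G * p$gamma_I / p$g_I
  num <- (p$c1 * (p$J_IE * St + p$I0_C) - p$c0 + p$g_I * p$r0) / p$g_I
  max(num / den, 0)
}

fp_residual <- function(r, p) {
  SA <- p$gamma * p$tau_N * r[1] / (1 + p$gamma * p$tau_N * r[1])
  SB <- p$gamma * p$tau_N * r[2] / (1 + p$gamma * p$tau_N * r[2])
  rC <- rc_steady(SA + SB, p)
  SC <- p$tau_G * p$gamma_I * rC
  IA <- p$J_s * SA + p$J_c * SB + p$J_EI * SC + p$I0_A
  IB <- p$J_c * SA + p$J_s * SB + p$J_EI * SC + p$I0_B
  c(phi_excitatory(IA, p) - r[1], phi_excitatory(IB, p) - r[2])
}

newton2 <- function(r, p, tol = 1e-12, maxit = 200) {
  for (i in seq_len(maxit)) {
    f <- fp_residual(r, p)
    if (max(abs(f)) < tol) return(list(r = r, ok = TRUE))
    h <- 1e-7
    J <- matrix(0, 2, 2)
    for (j in 1:2) {
      rp <- r
      rp[j] <- rp[j] + h
      J[, j] <- (fp_residual(rp, p) - f) / h
    }
    dr <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(dr)) return(list(r = r, ok = FALSE))
    lam <- 1
    repeat {
      rn <- pmax(r + lam * dr, 0)
      if (max(abs(fp_residual(rn, p))) < max(abs(f)) || lam < 1e-4) break
      lam <- lam / 2
    }
    r <- pmax(r + lam * dr, 0)
  }
  list(r = r, ok = max(abs(fp_residual(r, p))) < 1e-8)
}

# Deterministic right-hand side of the six dynamical variables of one area
# (noise currents are decoupled and always stable, so they are omitted from
# the stability analysis).
area_rhs6 <- function(y, p) {
  SA <- y[1]; SB <- y[2]; SC <- y[3]; rA <- y[4]; rB <- y[5]; rC <- y[6]
  IA <- p$J_s * SA + p$J_c * SB + p$J_EI * SC + p$I0_A
  IB <- p$J_c * SA + p$J_s * SB + p$J_EI * SC + p$I0_B
  IC <- p$J_IE * (SA + SB) + p$J_II * SC + p$I0_C
  c(-SA / p$tau_N + p$gamma * (1 - SA) * rA,
    -SB / p$tau_N + p$gamma * (1 - SB) * rB,
    -SC / p$tau_G + p$gamma_I * rC,
    (phi_excitatory(IA, p) - rA) / p$tau_r,
    (phi_excitatory(IB, p) - rB) / p$tau_r,
    (phi_inhibitory(IC, p) - rC) / p$tau_r)
}

fp_is_stable <- function(y, p, eig_tol = -1e-8) {
  J <- matrix(0, 6, 6)
  f0 <- area_rhs6(y, p)
  h <- 1e-7
  for (j in 1:6) {
    yp <- y
    yp[j] <- yp[j] + h
    J[, j] <- (area_rhs6(yp, p) - f0) / h
  }
  all(Re(eigen(J, only.values = TRUE)$values) < eig_tol)
}

#' Fixed points of an isolated area
#'
#' Solves the noise-free self-consistency \code{r_i = phi_i(I_i)} with gating
#' variables at steady state, by damped Newton iteration from a grid of rate
#' initial guesses, then labels stability from the eigenvalues of the
#' six-variable Jacobian. In the monostable regime there is a single
#' (symmetric, \code{S_A = S_B}) fixed point; past the saddle-node bifurcation
#' a pair of selective memory states (plus saddles) appears.
#'
#' @param params a \code{\link{local_circuit_params}} object.
#' @param rate_grid initial guesses for the excitatory rates (Hz).
#' @param dedup_tol deduplication tolerance in S-space.
#' @return \code{data.frame} with columns \code{S_A, S_B, S_C, r_A, r_B, r_C,
#'   stable}, one row per distinct fixed point.
#' @export
find_fixed_points <- function(params = local_circuit_params(),
                              rate_grid = c(0.1, 0.5, 1, 2, 5, 10, 20, 40, 80),
                              dedup_tol = 1e-6) {
  p <- params
  sols <- list()
  for (ra in rate_grid) {
    for (rb in rate_grid) {
      s <- newton2(c(ra, rb), p)
      if (!s$ok) next
      dup <- any(vapply(sols, function(z) max(abs(z - s$r)) < 1e-4, TRUE))
      if (!dup) sols[[length(sols) + 1]] <- s$r
    }
  }
  if (length(sols) == 0) stop("no fixed points found from any initial guess")
  rows <- lapply(sols, function(r) {
    SA <- p$gamma * p$tau_N * r[1] / (1 + p$gamma * p$tau_N * r[1])
    SB <- p$gamma * p$tau_N * r[2] / (1 + p$gamma * p$tau_N * r[2])
    rC <- rc_steady(SA + SB, p)
    SC <- p$tau_G * p$gamma_I * rC
    y <- c(SA, SB, SC, r[1], r[2], rC)
    data.frame(S_A = SA, S_B = SB, S_C = SC,
               r_A = r[1], r_B = r[2], r_C = rC,
               stable = fp_is_stable(y, p))
  })
  out <- do.call(rbind, rows)
  # dedup in S-space at the requested tolerance
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(out))) {
      if (j <= i || !keep[j]) next
      if (max(abs(out[i, 1:3] - out[j, 1:3])) < dedup_tol) keep[j] <- FALSE
    }
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$r_A + out$r_B), , drop = FALSE]
}

#' Spontaneous (symmetric low-activity) fixed point
#'
#' @param params a \code{\link{local_circuit_params}} object.
#' @return Named state vector (9 components, noise currents zero).
#' @export
spontaneous_state <- function(params = local_circuit_params()) {
  fps <- find_fixed_points(params)
  st <- fps[fps$stable, , drop = FALSE]
  if (nrow(st) == 0) stop("no stable fixed point found")
  low <- st[which.min(st$r_A + st$r_B), ]
  s <- area_state(params)
  s[1:6] <- as.numeric(low[1, 1:6])
  s
}

#' Critical local coupling for isolated-area bistability
#'
#' Scans \code{J_s} for the smallest value at which an isolated area has more
#' than one stable fixed point (the saddle-node where selective memory states
#' appear), refined by bisection. With \code{co_vary_JIE = TRUE} the
#' excitatory-to-inhibitory coupling follows the spontaneous-state balance
#' relation \code{J_IE = (J_0 - J_s - J_c) / (2 J_EI zeta)} at every probed
#' \code{J_s}; with the default parameters the transition lies at
#' approximately 0.4655 nA.
#'
#' @param params baseline \code{\link{local_circuit_params}}.
#' @param Js_range length-2 numeric bracket for the scan (nA).
#' @param co_vary_JIE logical; re-balance \code{J_IE} at each probed
#'   \code{J_s}.
#' @param tol bisection tolerance (nA).
#' @return Critical \code{J_s} (nA).
#' @export
critical_coupling_scan <- function(params = local_circuit_params(),
                                   Js_range = c(0.42, 0.50),
                                   co_vary_JIE = TRUE, tol = 1e-4) {
  const <- compute_balance_constants(params)
  n_stable <- function(Js) {
    p <- params
    p$J_s <- Js
    if (co_vary_JIE) p$J_IE <- balance_jie(Js, const, params)
    sum(find_fixed_points(p)$stable)
  }
  lo <- Js_range[1]
  hi <- Js_range[2]
  if (n_stable(lo) > 1 || n_stable(hi) <= 1)
    stop("Js_range does not bracket the monostable-to-bistable transition")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (n_stable(mid) > 1) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
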