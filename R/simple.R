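#' Specification of the simplified excitatory-node network
#'
#' A fully connected network of \code{N} excitatory firing-rate nodes with a
#' gradient of self-coupling, used to isolate the minimal ingredients of
#' distributed working memory. Each node obeys
#' \deqn{dr_i/dt = -r_i + \phi(J_i r_i + (G/(N-1)) \sum_{j \ne i} a_{ij} r_j + I)}
#' with \eqn{\phi} a logistic sigmoid and \eqn{a_{ij}} feedforward/feedback
#' asymmetry multipliers (\code{ff_factor} on projections from lower to
#' higher nodes, \code{fb_factor} on the reverse). The gradient is either
#' linear in the node index or saturating (hyperbolic, mimicking the shape
#' of the spine-count data); self-excitation is kept below every node's
#' isolated bifurcation value.
#'
#' @param N number of nodes.
#' @param gradient \code{"linear"} or \code{"saturating"}.
#' @param J_range self-coupling endpoints (sigmoid input units).
#' @param G inter-node coupling strength.
#' @param I background input.
#' @param ff_factor,fb_factor asymmetry multipliers (feedforward >= 1,
#'   feedback <= 1 for an inhibitory-feedback-like asymmetry).
#' @param sat_k curvature of the saturating gradient (larger = earlier
#'   saturation).
#' @param phi_max,phi_theta,phi_beta sigmoid maximum rate, threshold and
#'   width.
#' @return Object of class \code{"simple_net_spec"} including the per-node
#'   couplings \code{J} and their mean \code{J_eta0}.
#' @export
simple_net_spec <- function(N = 30, gradient = c("saturating", "linear"),
                            J_range = c(0.2, 0.64), G = 0.2, I = 0.06,
                            ff_factor = 1, fb_factor = 1, sat_k = 15,
                            phi_max = 1, phi_theta = 0.5, phi_beta = 0.08) {
  gradient <- match.arg(gradient)
  x <- seq(0, 1, length.out = N)
  # both gradient forms describe the same saturating spine-count-like
  # profile; the linear form is its least-squares line, which overshoots the
  # saturating ceiling at the top end and undershoots at the bottom
  p <- (1 + sat_k) * x / (1 + sat_k * x)
  sat_vals <- J_range[1] + diff(J_range) * p
  J <- if (gradient == "saturating") {
    sat_vals
  } else {
    unname(stats::fitted(stats::lm(sat_vals ~ x)))
  }
  A <- matrix(1, N, N)
  A[upper.tri(A)] <- fb_factor  # column j > row i: higher -> lower source
  A[lower.tri(A)] <- ff_factor  # column j < row i: lower -> higher source
  diag(A) <- 0
  structure(list(N = N, gradient = gradient, J = J, J_eta0 = mean(J),
                 G = G, I = I, A = A, ff_factor = ff_factor,
                 fb_factor = fb_factor,
                 phi = list(max = phi_max, theta = phi_theta,
                            beta = phi_beta)),
            class = "simple_net_spec")
}

phi_sigmoid <- function(x, phi) phi$max / (1 + exp(-(x - phi$theta) / phi$beta))

#' @export
print.simple_net_spec <- function(x, ...) {
  cat(sprintf(
    "Simplified network: N = %d, %s gradient J in [%.3f, %.3f], G = %.3f\n",
    x$N, x$gradient, min(x$J), max(x$J), x$G))
  if (x$ff_factor != 1 || x$fb_factor != 1)
    cat(sprintf("  FF/FB asymmetry: ff = %.2f, fb = %.2f\n",
                x$ff_factor, x$fb_factor))
  invisible(x)
}

#' Simulate the simplified network
#'
#' Deterministic Euler integration of the node rates (time in units of the
#' intrinsic relaxation constant).
#'
#' @param spec a \code{\link{simple_net_spec}}.
#' @param init initial rates (length N); default all zero.
#' @param duration,dt integration length and step (intrinsic time units).
#' @param record_every keep every this many steps.
#' @return List with \code{time} and \code{rates} (time x node matrix).
#' @export
simulate_simple_network <- function(spec, init = NULL, duration = 60,
                                    dt = 0.02, record_every = 10L) {
  N <- spec$N
  r <- if (is.null(init)) numeric(N) else as.numeric(init)
  stopifnot(length(r) == N)
  n_steps <- round(duration / dt)
  n_rec <- floor(n_steps / record_every)
  out <- matrix(0, n_rec, N)
  tt <- numeric(n_rec)
  k <- 0L
  couple <- spec$G / (N - 1)
  for (s in seq_len(n_steps)) {
    inp <- spec$J * r + couple * as.numeric(spec$A %*% r) + spec$I
    dr <- dt * (-r + phi_sigmoid(inp, spec$phi))
    if (max(abs(dr)) > 0.5 * spec$phi$max)
      stop("instability in simple-network integration; reduce dt")
    r <- pmax(r + dr, 0)
    if (s %% record_every == 0) {
      k <- k + 1L
      out[k, ] <- r
      tt[k] <- s * dt
    }
  }
  list(time = tt, rates = out, final = r)
}

#' First-order mean-field solutions
#'
#' Self-consistent network-average rates solving
#' \code{R = phi((J_eta0 + G) R + I)}, found by bracketed root finding on a
#' fine grid of R; stability from the slope condition
#' \code{(J_eta0 + G) phi'(x) < 1}.
#'
#' @param spec a \code{\link{simple_net_spec}}.
#' @param n_grid grid resolution over [0, phi_max].
#' @return \code{data.frame} with columns \code{R} and \code{stable}
#'   (1 root in the monostable regime; 3 roots, two stable, when bistable).
#' @export
meanfield_solutions <- function(spec, n_grid = 2000) {
  Jg <- spec$J_eta0 + spec$G
  g <- function(R) phi_sigmoid(Jg * R + spec$I, spec$phi) - R
  grid <- seq(0, spec$phi$max, length.out = n_grid)
  v <- g(grid)
  roots <- numeric(0)
  for (i in seq_len(n_grid - 1)) {
    if (v[i] == 0) roots <- c(roots, grid[i])
    if (v[i] * v[i + 1] < 0)
      roots <- c(roots, stats::uniroot(g, c(grid[i], grid[i + 1]),
                                       tol = 1e-10)$root)
  }
  roots <- unique(round(roots, 8))
  dphi <- function(x) {
    p <- phi_sigmoid(x, spec$phi)
    p * (1 - p / spec$phi$max) / spec$phi$beta
  }
  data.frame(R = roots, stable = Jg * dphi(Jg * roots + spec$I) < 1)
}

#' Count bistable nodes across a coupling range
#'
#' A node is counted bistable if, embedded in the network, a stable state
#' exists in which it fires at a high rate while the all-low state is also
#' stable. Stable patterns are found by relaxing from the all-low state and
#' from "top-m" seeds (the m highest-gradient nodes initialised high, for
#' m = 1..N), which reveals partial attractors that an all-high
#' initialisation would jump over.
#'
#' @param spec a \code{\link{simple_net_spec}} (its \code{G} is ignored).
#' @param G_range numeric vector of couplings to scan.
#' @param gap rate classifying a node as high; default half the sigmoid
#'   maximum.
#' @param duration relaxation length per initialisation.
#' @return \code{data.frame} with columns \code{G}, \code{n_bistable}
#'   (largest stable high-set size), \code{n_partial_patterns} (number of
#'   distinct stable patterns with 0 < size < N) and \code{partial_sizes}
#'   (comma-separated sizes).
#' @export
count_bistable_areas <- function(spec, G_range, gap = NULL, duration = 120) {
  if (is.null(gap)) gap <- 0.5 * spec$phi$max
  ord <- order(spec$J, decreasing = TRUE)
  rows <- lapply(G_range, function(G) {
    sp <- spec
    sp$G <- G
    lo <- simulate_simple_network(sp, init = rep(0, sp$N),
                                  duration = duration)$final
    base_quiet <- all(lo < gap)
    sizes <- integer(0)
    for (m in seq_len(sp$N)) {
      init <- rep(0, sp$N)
      init[ord[seq_len(m)]] <- sp$phi$max
      fin <- simulate_simple_network(sp, init = init,
                                     duration = duration)$final
      sizes <- c(sizes, sum(fin > gap))
    }
    sizes <- unique(sizes)
    partial <- sizes[sizes > 0 & sizes < sp$N]
    data.frame(G = G,
               n_bistable = if (base_quiet) max(c(sizes, 0)) else 0L,
               n_partial_patterns = length(partial),
               partial_sizes = paste(sort(partial), collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
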