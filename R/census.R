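#' Numerical attractor census
#'
#' Samples random activity seeds (a uniformly sized random subset of areas
#' initialised at an elevated pool-A gating value), relaxes the noise-free
#' network, binarizes the resulting spatial activity pattern and
#' deduplicates. Distinct attractors are defined by the binary active/
#' inactive vector over areas only (pool identity is recorded but ignored
#' for identity). The all-spontaneous pattern is excluded from the count,
#' and samples that fail to converge within \code{relax_time} are discarded
#' and reported in the diagnostics.
#'
#' @param net a \code{\link{build_network}} model.
#' @param n_samples number of random seeds.
#' @param relax_time maximum relaxation time per sample (s).
#' @param dt integration step (s); relaxations are deterministic, so a
#'   coarser step than the stochastic default is adequate.
#' @param threshold activity threshold (Hz); default spontaneous + 5.
#' @param seed RNG seed for the sampling stream.
#' @param seed_value elevated initial pool-A gating value.
#' @param tol,check_interval convergence controls (see
#'   \code{\link{relax_network}}).
#' @param confirm_time after apparent convergence, integrate this much
#'   longer and discard the sample unless the binarized pattern is
#'   unchanged (guards against slow transients).
#' @return Object of class \code{"attractor_census"}: list with
#'   \code{patterns} (unique patterns x areas logical matrix),
#'   \code{rates} (matching matrix of pool-A delay rates), \code{states}
#'   (list of full state matrices, one per pattern), \code{sizes},
#'   \code{hits} (samples landing on each pattern), \code{n_samples},
#'   \code{n_nonconverged}, \code{threshold}, and the sampling metadata.
#' @export
enumerate_attractors <- function(net, n_samples = 5000, relax_time = 20,
                                 dt = 1e-3, threshold = NULL, seed = 1,
                                 seed_value = 0.3, tol = 0.01,
                                 check_interval = 0.5, confirm_time = 2) {
  n <- length(net$areas)
  if (is.null(threshold)) threshold <- net$spont_rate_iso + 5
  set.seed(seed)
  pat_key <- character(0)
  patterns <- list()
  rates <- list()
  states <- list()
  hits <- integer(0)
  n_nc <- 0L
  for (k in seq_len(n_samples)) {
    sz <- sample.int(n, 1)
    subset <- sample.int(n, sz)
    st <- net$spont
    st[subset, "S_A"] <- seed_value
    rx <- relax_network(net, init = st, max_time = relax_time, dt = dt,
                        tol = tol, check_interval = check_interval)
    if (!rx$converged) {
      n_nc <- n_nc + 1L
      next
    }
    act <- rx$state[, "r_A"] > threshold | rx$state[, "r_B"] > threshold
    if (confirm_time > 0) {
      # guard against slow transients that pass the rate-change tolerance:
      # integrate on and require the binarized pattern to be unchanged
      rx2 <- relax_network(net, init = rx$state, max_time = confirm_time,
                           dt = dt, tol = tol,
                           check_interval = check_interval)
      act2 <- rx2$state[, "r_A"] > threshold | rx2$state[, "r_B"] > threshold
      if (!identical(act, act2)) {
        n_nc <- n_nc + 1L
        next
      }
      rx <- rx2
    }
    if (!any(act)) next  # spontaneous pattern: not a WM attractor
    key <- paste(as.integer(act), collapse = "")
    i <- match(key, pat_key)
    if (is.na(i)) {
      pat_key <- c(pat_key, key)
      patterns[[length(patterns) + 1]] <- act
      rates[[length(rates) + 1]] <- pmax(rx$state[, "r_A"], rx$state[, "r_B"])
      states[[length(states) + 1]] <- rx$state
      hits <- c(hits, 1L)
    } else {
      hits[i] <- hits[i] + 1L
    }
  }
  P <- if (length(patterns) > 0) {
    do.call(rbind, patterns)
  } else {
    matrix(FALSE, 0, n)
  }
  colnames(P) <- net$areas
  R <- if (length(rates) > 0) do.call(rbind, rates) else matrix(0, 0, n)
  colnames(R) <- net$areas
  structure(list(patterns = P, rates = R, states = states,
                 sizes = rowSums(P), hits = hits,
                 n_samples = n_samples, n_nonconverged = n_nc,
                 threshold = threshold, relax_time = relax_time,
                 confirm_time = confirm_time, dt = dt,
                 seed = seed, seed_value = seed_value,
                 G = net$G, J_max = net$J_max, areas = net$areas),
            class = "attractor_census")
}

#' @export
print.attractor_census <- function(x, ...) {
  cat(sprintf(
    "Attractor census: %d distinct WM patterns from %d seeds (G = %.2f, J_max = %.3f)\n",
    nrow(x$patterns), x$n_samples, x$G, x$J_max))
  if (x$n_nonconverged > 0)
    cat(sprintf("  %d non-converged samples discarded\n", x$n_nonconverged))
  if (nrow(x$patterns) > 0)
    cat(sprintf("  sizes: %d-%d areas (median %g)\n", min(x$sizes),
                max(x$sizes), stats::median(x$sizes)))
  invisible(x)
}

#' Participation index
#'
#' Fraction of the distinct attractors in which each area is active.
#'
#' @param census an \code{\link{enumerate_attractors}} result.
#' @return Named numeric vector in [0, 1].
#' @export
participation_index <- function(census) {
  if (nrow(census$patterns) == 0) {
    warning("empty census: no attractors")
    return(stats::setNames(numeric(length(census$areas)), census$areas))
  }
  colMeans(census$patterns)
}

#' Correlation between attractor size and firing rate
#'
#' Pearson correlation between the number of active areas of each attractor
#' and the mean pool rate of its active areas.
#'
#' @param census an \code{\link{enumerate_attractors}} result with at least
#'   three distinct patterns.
#' @return Correlation coefficient.
#' @export
size_rate_correlation <- function(census) {
  if (nrow(census$patterns) < 3)
    stop("size-rate correlation requires at least 3 distinct patterns")
  mean_rate <- vapply(seq_len(nrow(census$patterns)), function(i) {
    mean(census$rates[i, census$patterns[i, ]])
  }, 0)
  if (stats::sd(census$sizes) < 1e-12 || stats::sd(mean_rate) < 1e-12) {
    warning("degenerate variance: size-rate correlation undefined")
    return(NA_real_)
  }
  stats::cor(census$sizes, mean_rate)
}

#' Attractor survival under silencing
#'
#' For each set of silenced areas, every attractor of the intact network is
#' re-relaxed with those areas clamped off; it survives if the remaining
#' active set is non-empty and the relaxation converges.
#'
#' @param net the intact \code{\link{build_network}} model used for the
#'   census.
#' @param census an \code{\link{enumerate_attractors}} result.
#' @param silenced_sets list of character vectors of area names (an empty
#'   vector means no silencing).
#' @param relax_time,dt,tol relaxation controls.
#' @return Numeric vector: percentage of attractors surviving each set.
#' @export
silencing_survival <- function(net, census, silenced_sets,
                               relax_time = 20, dt = 1e-3, tol = 0.01) {
  if (!is.list(silenced_sets)) silenced_sets <- list(silenced_sets)
  vapply(silenced_sets, function(set) {
    if (nrow(census$patterns) == 0) return(NA_real_)
    if (length(set) == 0) return(100)
    idx <- area_index(net, set)
    sil <- silencing_spec(set, 0, Inf)
    surv <- vapply(seq_along(census$states), function(i) {
      st <- census$states[[i]]
      st[idx, ] <- 0
      rx <- relax_network(net, init = st, max_time = relax_time, dt = dt,
                          tol = tol, silencing = sil)
      act <- rx$state[, "r_A"] > census$threshold |
        rx$state[, "r_B"] > census$threshold
      act[idx] <- FALSE
      rx$converged && any(act)
    }, TRUE)
    100 * mean(surv)
  }, 0)
}
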