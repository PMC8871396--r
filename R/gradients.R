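#' Balance constants of the spontaneous state
#'
#' Quasi-steady elimination of the fast inhibitory variables gives the
#' conductance-per-current factor \code{zeta}, the offset \code{beta}, the
#' invariant excitatory drive coefficient
#' \code{J_0 = J_s + J_c + 2 J_EI J_IE zeta} (0.2112 nA at defaults) and the
#' long-range E/I balancing factor
#' \code{Z = 2 c1 tau_G gamma_I J_EI / (c1 tau_G gamma_I J_II - g_I)}.
#' Holding \code{J_0} fixed while varying \code{J_s} keeps the spontaneous
#' fixed point identical across areas; \code{Z} makes equal activity in the
#' two selective pools of a source area exert zero net long-range effect.
#'
#' @param params a \code{\link{local_circuit_params}} object.
#' @return Object of class \code{"balance_constants"}: list with \code{zeta}
#'   (1/nA), \code{beta}, \code{J0} (nA), \code{Z}.
#' @export
compute_balance_constants <- function(params = local_circuit_params()) {
  p <- params
  den <- p$g_I - p$J_II * p$tau_G * p$gamma_I * p$c1
  if (abs(den) < 1e-12) stop("degenerate parameters: zero balance denominator")
  zeta <- p$tau_G * p$gamma_I * p$c1 / den
  beta <- p$tau_G * p$gamma_I * (p$c1 * p$I0_C + p$g_I * p$r0 - p$c0) / den
  J0 <- p$J_s + p$J_c + 2 * p$J_EI * p$J_IE * zeta
  Z <- 2 * p$c1 * p$tau_G * p$gamma_I * p$J_EI /
    (p$c1 * p$tau_G * p$gamma_I * p$J_II - p$g_I)
  out <- list(zeta = zeta, beta = beta, J0 = J0, Z = Z)
  if (any(!is.finite(unlist(out)))) stop("non-finite balance constants")
  class(out) <- "balance_constants"
  out
}

#' @export
print.balance_constants <- function(x, ...) {
  cat(sprintf(
    "Balance constants: zeta = %.4f 1/nA, beta = %.5f, J0 = %.4f nA, Z = %.4f\n",
    x$zeta, x$beta, x$J0, x$Z))
  invisible(x)
}

#' Balanced excitatory-to-inhibitory coupling
#'
#' \code{J_IE = (J_0 - J_s - J_c) / (2 J_EI zeta)}: the value that keeps the
#' spontaneous fixed point invariant as the local self-coupling \code{J_s}
#' varies along the gradient. Valid (non-negative) for
#' \code{J_s >= J_0 - J_c}.
#'
#' @param J_s local self-coupling (nA); vectorised.
#' @param constants a \code{\link{compute_balance_constants}} result.
#' @param params a \code{\link{local_circuit_params}} object.
#' @return \code{J_IE} (nA).
#' @export
balance_jie <- function(J_s, constants = compute_balance_constants(params),
                        params = local_circuit_params()) {
  jie <- (constants$J0 - J_s - params$J_c) / (2 * params$J_EI * constants$zeta)
  bad <- jie < -1e-12
  if (any(bad))
    stop(sprintf(
      "J_s = %.4f below validity bound %.4f nA: balanced J_IE would be %.4f",
      J_s[bad][1], constants$J0 - params$J_c, jie[bad][1]))
  pmax(jie, 0)
}

#' Age-correct spine counts
#'
#' Multiplies measured basal-dendrite spine counts by the per-area age
#' correction factor (compensating the spine loss of older animals); missing
#' measurements stay missing.
#'
#' @param records \code{data.frame} with columns \code{area},
#'   \code{spine_count} and \code{age_factor}.
#' @return The input with a \code{corrected_count} column appended.
#' @export
correct_spine_counts <- function(records) {
  stopifnot(all(c("area", "spine_count", "age_factor") %in% names(records)))
  if (any(records$spine_count < 0, na.rm = TRUE))
    stop("negative spine counts are invalid")
  if (any(records$age_factor < 1, na.rm = TRUE))
    stop("age correction factors must be >= 1")
  records$corrected_count <- records$spine_count * records$age_factor
  records
}

#' Packaged spine-count table
#'
#' Layer 2/3 pyramidal basal-dendrite spine counts for the 30 modelled areas
#' with age-correction factors, already age-corrected via
#' \code{\link{correct_spine_counts}}. Areas without a published measurement
#' carry \code{NA} and are filled from their hierarchical position when a
#' gradient is built.
#'
#' @return \code{data.frame} with columns \code{rank} (position in the
#'   SLN-derived hierarchy), \code{area}, \code{spine_count},
#'   \code{age_factor}, \code{corrected_count}.
#' @export
macaque_spine_table <- function() {
  path <- system.file("extdata", "spine_counts.csv", package = "wmnet")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  correct_spine_counts(tab)
}

#' Canonical 30-area name list
#'
#' The modelled macaque cortical areas in anatomical-hierarchy order.
#' @return Character vector of length 30.
#' @export
macaque_areas <- function() {
  c("V1", "V2", "V4", "DP", "MT", "8m", "5", "8l", "2", "TEO",
    "F1", "STPc", "7A", "46d", "10", "9/46v", "9/46d", "F5", "TEpd", "PBr",
    "7m", "LIP", "F2", "7B", "ProM", "STPi", "F7", "8B", "STPr", "24c")
}

#' Fit the anatomical hierarchy from SLN data
#'
#' Assigns each area a hierarchical value \code{H_i} such that differences
#' predict the supragranular labelled-neuron fraction of a projection through
#' a logistic link: \code{SLN(j -> i) ~ plogis(H_i - H_j)} (rows of the SLN
#' matrix are targets). Fitted by a quasibinomial GLM on all existing edges
#' (optionally weighted by FLN), gauge-fixed by anchoring the minimum
#' \code{H} to zero, and normalised to \code{h = H / max(H)}.
#'
#' @param SLN square matrix in [0, 1], rows = target, columns = source.
#' @param FLN optional square weight matrix; edges with \code{FLN > 0} enter
#'   the fit. If \code{NULL}, all finite off-diagonal SLN entries are used.
#' @param weight_by_fln logical; use FLN values as GLM prior weights.
#' @param areas optional area names.
#' @return Object of class \code{"hierarchy_fit"}: list with \code{h}
#'   (normalised values in [0, 1]), \code{H} (raw, min anchored at 0),
#'   \code{areas}, \code{glm} (the fitted model or NULL if degenerate).
#' @export
fit_hierarchy_from_sln <- function(SLN, FLN = NULL, weight_by_fln = FALSE,
                                   areas = NULL) {
  n <- nrow(SLN)
  stopifnot(ncol(SLN) == n)
  if (is.null(areas)) areas <- rownames(SLN)
  if (is.null(areas)) areas <- paste0("A", seq_len(n))
  has_edge <- if (is.null(FLN)) {
    !diag(TRUE, n) & is.finite(SLN)
  } else {
    FLN > 0
  }
  idx <- which(has_edge, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("no edges to fit the hierarchy on")
  y <- SLN[idx]
  if (any(y < 0 | y > 1)) stop("SLN values must lie in [0, 1]")
  if (max(y) - min(y) < 1e-12) {
    warning("degenerate SLN (all equal): returning a flat hierarchy")
    out <- list(h = stats::setNames(rep(0, n), areas),
                H = stats::setNames(rep(0, n), areas),
                areas = areas, glm = NULL)
    class(out) <- "hierarchy_fit"
    return(out)
  }
  # design: +1 on the target area, -1 on the source; drop area 1 (H_1 = 0)
  X <- matrix(0, nrow(idx), n)
  X[cbind(seq_len(nrow(idx)), idx[, 1])] <- X[cbind(seq_len(nrow(idx)), idx[, 1])] + 1
  X[cbind(seq_len(nrow(idx)), idx[, 2])] <- X[cbind(seq_len(nrow(idx)), idx[, 2])] - 1
  X <- X[, -1, drop = FALSE]
  colnames(X) <- paste0("H", seq_len(n)[-1])
  w <- if (weight_by_fln && !is.null(FLN)) FLN[idx] else rep(1, nrow(idx))
  dat <- data.frame(y = y, X, check.names = FALSE)
  fit <- stats::glm(y ~ . - 1, family = stats::quasibinomial("logit"),
                    data = dat, weights = w)
  H <- c(0, stats::coef(fit))
  H[!is.finite(H)] <- 0
  H <- H - min(H)
  h <- if (max(H) > 0) H / max(H) else H
  out <- list(h = stats::setNames(h, areas), H = stats::setNames(H, areas),
              areas = areas, glm = fit)
  class(out) <- "hierarchy_fit"
  out
}

#' @export
print.hierarchy_fit <- function(x, ...) {
  cat(sprintf("SLN hierarchy fit over %d areas\n", length(x$h)))
  ord <- order(x$h)
  cat("  bottom:", paste(utils::head(x$areas[ord], 3), collapse = ", "),
      "| top:", paste(utils::tail(x$areas[ord], 3), collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.hierarchy_fit <- function(object, normalized = TRUE, ...) {
  if (normalized) object$h else object$H
}

#' Hierarchy values from spine counts with proxy fill
#'
#' Builds the normalised gradient position \code{h_i} used for the synaptic
#' gradient: min-max normalised age-corrected spine counts where measured;
#' areas without spine data are filled from a linear regression of corrected
#' counts on the SLN-derived hierarchy position, then the full vector is
#' renormalised to [0, 1].
#'
#' @param spine_table \code{data.frame} as from \code{\link{macaque_spine_table}}.
#' @param hierarchy numeric vector of hierarchy positions per area (same
#'   order); defaults to the table's \code{rank} column.
#' @return List with \code{h} (named, in [0, 1]) and \code{source}
#'   (\code{"spine"} or \code{"hierarchy-proxy"} per area).
#' @export
spine_hierarchy <- function(spine_table = macaque_spine_table(),
                            hierarchy = NULL) {
  tab <- spine_table
  if (!"corrected_count" %in% names(tab)) tab <- correct_spine_counts(tab)
  if (is.null(hierarchy)) hierarchy <- tab$rank
  miss <- is.na(tab$corrected_count)
  cc <- tab$corrected_count
  if (any(miss)) {
    fit <- stats::lm(cc ~ hierarchy, data = data.frame(cc = cc, hierarchy))
    cc[miss] <- stats::predict(fit,
      newdata = data.frame(hierarchy = hierarchy[miss]))
  }
  h <- (cc - min(cc)) / (max(cc) - min(cc))
  list(h = stats::setNames(h, tab$area),
       source = stats::setNames(ifelse(miss, "hierarchy-proxy", "spine"),
                                tab$area))
}

#' Gradient of local self-coupling
#'
#' \code{J_s^i = J_min + (J_max - J_min) h_i} for normalised hierarchy values
#' \code{h} in [0, 1].
#'
#' @param h numeric vector in [0, 1].
#' @param J_min,J_max gradient endpoints (nA).
#' @return Numeric vector of per-area \code{J_s} (nA), named like \code{h}.
#' @export
build_js_gradient <- function(h, J_min = 0.21, J_max = 0.42) {
  if (J_max < J_min) stop("J_max must be >= J_min")
  if (any(h < -1e-12 | h > 1 + 1e-12)) stop("h must lie in [0, 1]")
  J_min + (J_max - J_min) * pmin(pmax(h, 0), 1)
}
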