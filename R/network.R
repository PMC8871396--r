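#' Build the multi-area cortical network model
#'
#' Assembles a simulatable network from a connectome bundle: per-area local
#' circuits on the macroscopic gradient (\code{J_s} linear in the hierarchy
#' value, \code{J_IE} co-varied so every isolated area shares the same
#' spontaneous fixed point), FLN-derived long-range weights split into
#' excitatory (SLN-weighted) and inhibitory (counterstream-inhibitory-bias)
#' pathways, and the global coupling \code{G} with the E/I balancing factor
#' \code{Z}.
#'
#' Named configurations (\code{mode}):
#' \describe{
#'   \item{distributed}{\code{J_max = 0.42}, \code{G = 0.48}; all areas
#'     monostable in isolation, memory held by inter-areal loops.}
#'   \item{strongly-distributed}{\code{J_max = 0.26}, \code{G = 0.48}.}
#'   \item{localized}{\code{J_max = 0.468}, \code{G = 0.21}; feedback
#'     (SLN < 0.5) projections removed entirely, so there are no long-range
#'     loops and memory relies on intrinsically bistable top areas.}
#'   \item{custom}{no preset; \code{J_max} and \code{G} as given.}
#' }
#' Explicitly supplied \code{J_max} / \code{G} always override the preset.
#'
#' @param bundle a \code{\link{connectome_bundle}}.
#' @param h per-area normalised hierarchy values in [0, 1]; defaults to the
#'   spine-count gradient (\code{\link{spine_hierarchy}}) for the canonical
#'   30 macaque areas, else to the bundle's latent hierarchy.
#' @param mode one of \code{"distributed"}, \code{"strongly-distributed"},
#'   \code{"localized"}, \code{"custom"}.
#' @param J_min,J_max gradient endpoints (nA).
#' @param G global coupling strength.
#' @param cib_scale counterstream-inhibitory-bias scale (0 disables CIB).
#' @param fef_cap cap on the inhibitory-targeting fraction for FEF targets.
#' @param params baseline \code{\link{local_circuit_params}}.
#' @param k1,k2,normalize_fln FLN rescaling controls (see
#'   \code{\link{rescale_fln}}).
#' @param fef_targets,fef_sources cap scope (see
#'   \code{\link{assemble_projection_weights}}).
#' @return Object of class \code{"cortical_network"}.
#' @examples
#' bun <- generate_synthetic_connectome(seed = 1)
#' net <- build_network(bun)
#' net
#' @export
build_network <- function(bundle, h = NULL,
                          mode = c("distributed", "strongly-distributed",
                                   "localized", "custom"),
                          J_min = 0.21, J_max = NULL, G = NULL,
                          cib_scale = 1, fef_cap = 0.4,
                          params = local_circuit_params(),
                          k1 = 1.2, k2 = 0.3, normalize_fln = TRUE,
                          fef_targets = c("8l", "8m"), fef_sources = NULL) {
  mode <- match.arg(mode)
  preset <- switch(mode,
    "distributed" = list(J_max = 0.42, G = 0.48),
    "strongly-distributed" = list(J_max = 0.26, G = 0.48),
    "localized" = list(J_max = 0.468, G = 0.21),
    "custom" = list(J_max = NULL, G = NULL))
  if (is.null(J_max)) J_max <- preset$J_max
  if (is.null(G)) G <- preset$G
  if (is.null(J_max) || is.null(G))
    stop("J_max and G must be given for mode = \"custom\"")
  if (is.null(h)) {
    canonical <- length(bundle$areas) == 30 &&
      all(canon_name(bundle$areas) %in% canon_name(macaque_areas()))
    h <- if (canonical) {
      # the gradient the model is calibrated on: age-corrected spine counts,
      # proxy-filled from the anatomical hierarchy where unmeasured
      spine_hierarchy()$h[match(canon_name(bundle$areas),
                                canon_name(macaque_areas()))]
    } else {
      bundle$hierarchy
    }
    if (is.null(h))
      stop("no hierarchy available: supply h or a bundle with $hierarchy")
  }
  n <- length(bundle$areas)
  stopifnot(length(h) == n)
  const <- compute_balance_constants(params)
  Js <- build_js_gradient(h, J_min, J_max)
  JIE <- balance_jie(Js, const, params)
  W <- rescale_fln(bundle$FLN, k1 = k1, k2 = k2, normalize = normalize_fln)
  pw <- assemble_projection_weights(bundle, W, Js, J_max = J_max,
                                    cib_scale = cib_scale, fef_cap = fef_cap,
                                    fef_targets = fef_targets,
                                    fef_sources = fef_sources)
  W_EE <- pw$W_EE
  W_EI <- pw$W_EI
  if (mode == "localized") {
    # remove feedback projections entirely (no long-range loops); feedforward
    # projections keep their Z-balanced inhibitory fraction so the tonic
    # drive stays balanced
    fb <- bundle$SLN < 0.5
    W_EE[fb] <- 0
    W_EI[fb] <- 0
  }
  net <- structure(list(
    areas = bundle$areas, h = stats::setNames(as.numeric(h), bundle$areas),
    params = params, Js = Js, JIE = JIE, constants = const,
    W_EE = W_EE, W_EI = W_EI, G = G, Z = const$Z,
    cib_scale = cib_scale, fef_cap = fef_cap,
    J_min = J_min, J_max = J_max, mode = mode,
    SLN = bundle$SLN), class = "cortical_network")
  iso <- spontaneous_state(params)
  net$spont_rate_iso <- unname(iso["r_A"])
  net$spont <- network_spontaneous_state(net, iso = iso)
  net
}

# parameter list handed to the compiled integrator
cpp_params <- function(net) {
  p <- net$params
  c(p[setdiff(names(p), c("J_s", "J_IE"))],
    list(Js_vec = as.numeric(net$Js), JIE_vec = as.numeric(net$JIE)))
}

# Coupled spontaneous state: start every area at the isolated spontaneous
# fixed point and relax the coupled deterministic system.
network_spontaneous_state <- function(net, relax_time = 4, dt = 5e-4,
                                      iso = spontaneous_state(net$params)) {
  n <- length(net$areas)
  st <- matrix(rep(iso, each = n), nrow = n)
  res <- sim_network_cpp(st, cpp_params(net), net$W_EE, net$W_EI,
                         net$G, net$Z,
                         matrix(0, 0, 5), matrix(0, 0, 3),
                         dt, as.integer(relax_time / dt), 0L, TRUE,
                         1e-5, as.integer(0.25 / dt))
  if (res$unstable) stop("instability while relaxing the spontaneous state")
  out <- res$final
  rownames(out) <- net$areas
  colnames(out) <- names(iso)
  out
}

#' @export
print.cortical_network <- function(x, ...) {
  cat(sprintf("Cortical network model: %d areas, mode \"%s\"\n",
              length(x$areas), x$mode))
  cat(sprintf("  gradient J_s in [%.3f, %.3f] nA, G = %.2f, cib_scale = %g\n",
              min(x$Js), max(x$Js), x$G, x$cib_scale))
  cat(sprintf("  spontaneous rate %.2f Hz (pool A, coupled state)\n",
              mean(x$spont[, "r_A"])))
  invisible(x)
}

#' @export
summary.cortical_network <- function(object, ...) {
  df <- data.frame(area = object$areas, h = object$h, J_s = object$Js,
                   J_IE = object$JIE,
                   r_spont = object$spont[, "r_A"], row.names = NULL)
  cat(sprintf("Cortical network (%s): %d areas, G = %.2f, Z = %.4f\n",
              object$mode, length(object$areas), object$G, object$Z))
  print(df, digits = 4)
  invisible(df)
}

#' Open input gates on selected areas
#'
#' Gating multiplies the strength of incoming synaptic projections onto the
#' "open" areas by \code{(1 + g_s)}; closed areas are untouched. By default
#' only long-range projections are scaled; \code{include_local = TRUE} also
#' scales the local couplings \code{J_s}, \code{J_c}.
#'
#' @param net a \code{\link{build_network}} model.
#' @param open_areas character vector of area names.
#' @param g_s gating increment (>= 0).
#' @param include_local also scale local recurrent couplings.
#' @return A modified \code{cortical_network}.
#' @export
apply_gating <- function(net, open_areas, g_s, include_local = FALSE) {
  if (g_s < 0) stop("g_s must be >= 0")
  idx <- match(canon_name(open_areas), canon_name(net$areas))
  if (any(is.na(idx)))
    stop("unknown area name(s): ",
         paste(open_areas[is.na(idx)], collapse = ", "))
  net$W_EE[idx, ] <- (1 + g_s) * net$W_EE[idx, ]
  net$W_EI[idx, ] <- (1 + g_s) * net$W_EI[idx, ]
  if (include_local) {
    net$Js[idx] <- (1 + g_s) * net$Js[idx]
  }
  net$spont <- network_spontaneous_state(net)
  net
}

area_index <- function(net, areas) {
  idx <- match(canon_name(areas), canon_name(net$areas))
  if (any(is.na(idx)))
    stop("unknown area name(s): ", paste(areas[is.na(idx)], collapse = ", "))
  idx
}
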