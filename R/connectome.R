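#' @title Anatomical connectome bundle
#' @description Construct and validate a connectome bundle: ordered area
#'   names, a directed FLN matrix (fraction of labelled neurons; rows =
#'   target, columns = source, so entry \code{[x, y]} is the projection
#'   y -> x) and an SLN matrix (supragranular labelled-neuron fraction, in
#'   [0, 1]; near 1 = feedforward, near 0 = feedback). Distances are optional
#'   and unused by the dynamics.
#' @param areas character vector of area names.
#' @param FLN,SLN square numeric matrices (rows = target, columns = source).
#' @param distances optional square matrix (mm).
#' @param hierarchy optional latent/normalised hierarchy values per area.
#' @return Object of class \code{"connectome"}.
#' @export
connectome_bundle <- function(areas, FLN, SLN, distances = NULL,
                              hierarchy = NULL) {
  n <- length(areas)
  if (!is.matrix(FLN) || any(dim(FLN) != n))
    stop(sprintf("FLN must be a %d x %d matrix", n, n))
  if (!is.matrix(SLN) || any(dim(SLN) != n))
    stop(sprintf("SLN must be a %d x %d matrix", n, n))
  bad <- which(FLN < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("negative FLN at [%d, %d]", bad[1, 1], bad[1, 2]))
  dg <- which(diag(FLN) != 0)
  if (length(dg) > 0)
    stop(sprintf("FLN diagonal must be zero (violated at [%d, %d])",
                 dg[1], dg[1]))
  bad <- which(SLN < 0 | SLN > 1, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("SLN outside [0, 1] at [%d, %d]", bad[1, 1], bad[1, 2]))
  miss <- which(FLN > 0 & !is.finite(SLN), arr.ind = TRUE)
  if (nrow(miss) > 0)
    stop(sprintf("SLN missing where FLN > 0 at [%d, %d]",
                 miss[1, 1], miss[1, 2]))
  dimnames(FLN) <- dimnames(SLN) <- list(areas, areas)
  if (!is.null(distances)) dimnames(distances) <- list(areas, areas)
  out <- list(areas = areas, FLN = FLN, SLN = SLN, distances = distances,
              hierarchy = hierarchy)
  class(out) <- "connectome"
  out
}

#' @export
print.connectome <- function(x, ...) {
  dens <- mean(x$FLN[row(x$FLN) != col(x$FLN)] > 0)
  rng <- range(x$FLN[x$FLN > 0])
  cat(sprintf("Connectome: %d areas, density %.2f, FLN range [%.2e, %.2e]\n",
              length(x$areas), dens, rng[1], rng[2]))
  invisible(x)
}

# case/punctuation-insensitive canonical form of an area name
canon_name <- function(x) toupper(gsub("[^A-Za-z0-9]", "", x))

#' Load a connectome from CSV files
#'
#' Matrices are CSV with a header row and first column of area names (rows =
#' target, columns = source). Area order is matched against \code{areas}
#' case- and punctuation-insensitively and the matrices are re-ordered into
#' that canonical order.
#'
#' @param fln_path,sln_path CSV file paths.
#' @param dist_path optional CSV path of distances.
#' @param areas canonical area order; defaults to the row names of the FLN
#'   file.
#' @return A validated \code{\link{connectome_bundle}}.
#' @export
load_connectome <- function(fln_path, sln_path, dist_path = NULL,
                            areas = NULL) {
  read_mat <- function(path) {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    storage.mode(m) <- "double"
    m
  }
  FLN <- read_mat(fln_path)
  SLN <- read_mat(sln_path)
  if (nrow(FLN) != ncol(FLN)) stop("FLN matrix is not square")
  if (is.null(areas)) areas <- rownames(FLN)
  reorder <- function(m, what) {
    key <- canon_name(areas)
    ri <- match(key, canon_name(rownames(m)))
    ci <- match(key, canon_name(colnames(m)))
    if (any(is.na(ri)) || any(is.na(ci)))
      stop(sprintf("%s: area names do not match the canonical list (%s)",
                   what, paste(areas[is.na(ri) | is.na(ci)], collapse = ", ")))
    m[ri, ci, drop = FALSE]
  }
  FLN <- reorder(FLN, "FLN")
  SLN <- reorder(SLN, "SLN")
  D <- if (!is.null(dist_path)) reorder(read_mat(dist_path), "distances")
  connectome_bundle(areas, FLN, SLN, D)
}

#' Write a connectome to CSV files
#'
#' @param bundle a \code{\link{connectome_bundle}}.
#' @param fln_path,sln_path output CSV paths.
#' @export
write_connectome <- function(bundle, fln_path, sln_path) {
  wr <- function(m, path) {
    df <- data.frame(area = rownames(m), m, check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE)
  }
  wr(bundle$FLN, fln_path)
  wr(bundle$SLN, sln_path)
  invisible(bundle)
}

#' Generate a synthetic connectome
#'
#' Emulates the statistical structure of the macaque tract-tracing data:
#' areas carry a latent hierarchy equally spaced on [0, 1]; directed edges
#' exist with probability \code{density}; FLN weights are log-uniform over
#' \code{fln_range} (heavy-tailed, spanning several orders of magnitude);
#' SLN follows a logistic function of hierarchy differences,
#' \code{SLN(y -> x) = plogis(sln_slope (h_x - h_y))}, so projections from
#' lower to higher areas are feedforward (SLN > 0.5).
#'
#' @param n_areas number of areas (>= 2).
#' @param density edge probability in (0, 1].
#' @param seed integer RNG seed (reproducible bundles).
#' @param sln_slope slope of the logistic hierarchy link.
#' @param fln_range length-2 positive range of FLN weights.
#' @param locality weight in [0, 1] of the hierarchy-distance component of
#'   the (log) FLN magnitude: 0 gives fully independent log-uniform weights;
#'   larger values make near-tier projections systematically stronger, as in
#'   the exponential distance rule of real cortical graphs.
#' @param edge_locality length scale (in rank-distance units) of the edge
#'   probability, \code{p(y -> x) ~ density exp(-rank distance /
#'   edge_locality)} rescaled to the requested mean density, emulating the
#'   exponential distance rule of real cortical graphs; \code{Inf} gives
#'   distance-independent edges.
#' @param hier_warp curvature of the latent hierarchy spacing,
#'   \code{h = log(1 + hier_warp x)/log(1 + hier_warp)} over the uniform
#'   rank coordinate \code{x}; 0 gives equal spacing.
#' @param sln_precision beta precision of the SLN draw around its logistic
#'   mean; \code{Inf} (default) uses the mean itself, finite values add the
#'   beta-binomial-style scatter seen in real laminar counts.
#' @param areas optional names; defaults to \code{\link{macaque_areas}} when
#'   \code{n_areas == 30}, else \code{A1..An} in hierarchy order.
#' @return A \code{\link{connectome_bundle}} with the latent hierarchy stored
#'   in \code{$hierarchy}.
#' @export
generate_synthetic_connectome <- function(n_areas = 30, density = 0.66,
                                          seed = 1, sln_slope = 6.5,
                                          fln_range = c(1e-6, 1e-1),
                                          locality = 0,
                                          edge_locality = 0.35,
                                          hier_warp = 9,
                                          sln_precision = Inf,
                                          areas = NULL) {
  if (n_areas < 2) stop("n_areas must be >= 2")
  if (density <= 0 || density > 1) stop("density must be in (0, 1]")
  if (any(fln_range <= 0)) stop("fln_range must be positive")
  if (is.null(areas)) {
    areas <- if (n_areas == 30) macaque_areas() else
      paste0("A", seq_len(n_areas))
  }
  x <- seq(0, 1, length.out = n_areas)  # uniform rank coordinate
  # latent hierarchy: logarithmically warped, so hierarchical separations are
  # largest between early sensory areas and compressed near the top, matching
  # the laminar (SLN) structure of real data where e.g. V1-V2 projections are
  # decisively feedforward/feedback while frontal-frontal pairs are mixed
  h <- if (hier_warp > 0) log(1 + hier_warp * x) / log(1 + hier_warp) else x
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  n <- n_areas
  off <- row(diag(n)) != col(diag(n))
  if (locality < 0 || locality > 1) stop("locality must be in [0, 1]")
  dx <- abs(outer(x, x, "-"))  # rank distance, a proxy for spatial distance
  p_edge <- matrix(density, n, n)
  if (is.finite(edge_locality)) {
    w <- exp(-dx / edge_locality)
    p_edge <- pmin(density * w / mean(w[row(w) != col(w)]), 1)
  }
  edge <- matrix(FALSE, n, n)
  edge[off] <- stats::runif(sum(off)) < p_edge[off]
  FLN <- matrix(0, n, n)
  lr <- log10(fln_range)
  u <- matrix(stats::runif(n * n), n, n)
  # log-magnitude interpolates between a distance rule and pure log-uniform
  lmag <- lr[2] - (lr[2] - lr[1]) * (locality * dx + (1 - locality) * u)
  FLN[edge] <- 10^lmag[edge]
  # SLN: beta-distributed around a logistic function of hierarchy distance.
  # The low precision makes SLN bimodal, as in real laminar data: even
  # near-tier reciprocal pairs get one clearly feedforward and one clearly
  # feedback direction, rather than both sitting at 0.5.
  mu <- stats::plogis(sln_slope * outer(h, h, "-"))  # [x, y] = h_x - h_y
  SLN <- if (is.finite(sln_precision)) {
    matrix(stats::rbeta(n * n, mu * sln_precision,
                        (1 - mu) * sln_precision), n, n)
  } else {
    mu
  }
  diag(SLN) <- 0.5
  connectome_bundle(areas, FLN, SLN, hierarchy = stats::setNames(h, areas))
}

#' Rescale FLN weights
#'
#' Compresses the heavy-tailed FLN weights with the power law
#' \code{FLN^k2} and normalises so the weights are commensurate with the
#' firing-rate model's couplings (zeros stay zero). Normalisation variants:
#' \describe{
#'   \item{post (default)}{\code{W = k1 FLN^k2 / rowSums(FLN^k2)}: each
#'     target's incoming weight sums to \code{k1}. This keeps the total
#'     long-range drive per area independent of in-degree, which keeps
#'     memory-state rates in the tens of Hz and the spontaneous baseline
#'     quiet.}
#'   \item{pre}{row-normalise FLN to sum 1, then \code{W = k1 FLN^k2}. The
#'     power transform inflates row sums roughly like \code{n^(1-k2)} for
#'     \code{n} sources.}
#'   \item{none}{\code{W = k1 FLN^k2} on the raw values.}
#' }
#'
#' @param FLN non-negative matrix, rows = target.
#' @param k1,k2 rescaling coefficients; \code{k2} must be > 0.
#' @param normalize \code{"post"}, \code{"pre"} or \code{"none"} (logical
#'   \code{TRUE}/\code{FALSE} are accepted as \code{"pre"}/\code{"none"}).
#' @return Rescaled weight matrix \code{W}.
#' @export
rescale_fln <- function(FLN, k1 = 1.2, k2 = 0.3, normalize = "post") {
  if (k2 <= 0) stop("k2 must be positive")
  if (any(FLN < 0)) stop("FLN must be non-negative")
  if (is.logical(normalize)) normalize <- if (normalize) "pre" else "none"
  normalize <- match.arg(normalize, c("post", "pre", "none"))
  M <- FLN
  if (normalize == "pre") {
    rs <- rowSums(M)
    nz <- rs > 0
    M[nz, ] <- M[nz, , drop = FALSE] / rs[nz]
  }
  W <- matrix(0, nrow(M), ncol(M), dimnames = dimnames(M))
  pos <- M > 0
  W[pos] <- M[pos]^k2
  if (normalize == "post") {
    rs <- rowSums(W)
    nz <- rs > 0
    W[nz, ] <- W[nz, , drop = FALSE] / rs[nz]
  }
  k1 * W
}

#' Shuffle projection strengths
#'
#' Permutes the multiset of positive off-diagonal entries uniformly at random
#' among the positive positions; absent projections (zeros) stay zero. Used
#' to probe whether results depend on the detailed arrangement of weights.
#'
#' @param W square weight matrix.
#' @param seed integer RNG seed.
#' @return Matrix with identical entry multiset, shuffled in place.
#' @export
shuffle_projection_weights <- function(W, seed = 1) {
  if (nrow(W) != ncol(W)) stop("W must be square")
  pos <- which(W > 0 & row(W) != col(W))
  if (length(pos) < 2) return(W)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  W[pos] <- W[sample(pos)]
  W
}

#' Assemble long-range projection weights
#'
#' Applies the target-side gradient scaling
#' \code{W[x, y] -> (J_s^x / J_max) W[x, y]}, then splits each projection
#' between the excitatory pathway, scaled by SLN (feedforward bias), and the
#' inhibitory pathway, scaled by the counterstream inhibitory bias
#' \code{min(cib_scale (1 - SLN), cap)}. The cap is \code{fef_cap} for
#' projections onto the frontal-eye-field areas (targets \code{8l}, \code{8m}
#' by default) and 1 elsewhere; it keeps inhibitory feedback onto FEF weak so
#' those areas can sustain delay activity. The balancing factor \code{Z} and
#' global coupling \code{G} multiply the inhibitory and all pathways at
#' simulation time.
#'
#' @param bundle a \code{\link{connectome_bundle}}.
#' @param W rescaled weight matrix from \code{\link{rescale_fln}}.
#' @param Js per-area local coupling vector (nA), target-side gradient.
#' @param J_max gradient upper endpoint (nA).
#' @param cib_scale scalar multiplier on the (1 - SLN) inhibitory-targeting
#'   fraction (the CIB strength sweep parameter); the per-projection fraction
#'   saturates at the cap.
#' @param fef_cap cap on the inhibitory-targeting fraction for FEF targets.
#' @param fef_targets character vector of capped target areas (matched
#'   case/punctuation-insensitively; silently skipped if absent, e.g. on
#'   synthetic bundles with generic names).
#' @param fef_sources optional source filter for the cap: only projections
#'   from these areas are capped (default all sources).
#' @return Object of class \code{"projection_weights"}: list with \code{W_EE},
#'   \code{W_EI}, \code{cib_scale}, \code{fef_cap}.
#' @export
assemble_projection_weights <- function(bundle, W, Js, J_max = 0.42,
                                        cib_scale = 1, fef_cap = 0.4,
                                        fef_targets = c("8l", "8m"),
                                        fef_sources = NULL) {
  n <- length(bundle$areas)
  stopifnot(all(dim(W) == n), length(Js) == n)
  Wg <- (Js / J_max) * W  # row (target-side) scaling
  cap <- matrix(1, n, n)
  ti <- match(canon_name(fef_targets), canon_name(bundle$areas))
  ti <- ti[!is.na(ti)]
  si <- if (is.null(fef_sources)) {
    seq_len(n)
  } else {
    m <- match(canon_name(fef_sources), canon_name(bundle$areas))
    if (any(is.na(m)))
      stop("unknown area name in fef_sources: ",
           paste(fef_sources[is.na(m)], collapse = ", "))
    m
  }
  if (length(ti) > 0) cap[ti, si] <- fef_cap
  frac_I <- pmin(cib_scale * (1 - bundle$SLN), cap)
  out <- list(W_EE = Wg * bundle$SLN, W_EI = Wg * frac_I,
              cib_scale = cib_scale, fef_cap = fef_cap)
  class(out) <- "projection_weights"
  out
}
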