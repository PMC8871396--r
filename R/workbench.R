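#' Load an experiment configuration
#'
#' Reads a YAML or JSON experiment description, validates the keys and fills
#' defaults. Recognised top-level keys: \code{connectome} (either
#' \code{synthetic: {n_areas, density, seed, sln_slope}} or
#' \code{{fln, sln}} CSV paths), \code{gradient} (\code{J_min},
#' \code{J_max}), \code{G}, \code{cib_scale}, \code{fef_cap}, \code{mode},
#' \code{protocol} (\code{type} plus type-specific fields), and
#' \code{numerics} (\code{dt}, \code{duration}, \code{seed}).
#'
#' @param path file path (extension decides the parser).
#' @return Object of class \code{"experiment_config"} with all defaults
#'   resolved.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  known <- c("connectome", "gradient", "G", "cib_scale", "fef_cap", "mode",
             "protocol", "numerics", "name")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  defaults <- list(
    connectome = list(synthetic = list(n_areas = 30, density = 0.66,
                                       seed = 1, sln_slope = 4)),
    gradient = list(J_min = 0.21, J_max = NULL),
    G = NULL, cib_scale = 1, fef_cap = 0.4, mode = "distributed",
    protocol = list(type = "simulate"),
    numerics = list(dt = 5e-4, duration = 10, seed = 1))
  merge2 <- function(def, usr) {
    if (is.null(usr)) return(def)
    if (!is.list(def) || !is.list(usr)) return(usr)
    for (k in names(usr)) def[[k]] <- merge2(def[[k]], usr[[k]])
    def
  }
  cfg <- merge2(defaults, cfg)
  if (!is.null(cfg$connectome$fln) && !file.exists(cfg$connectome$fln))
    stop("connectome file not found: ", cfg$connectome$fln)
  if (!is.null(cfg$connectome$sln) && !file.exists(cfg$connectome$sln))
    stop("connectome file not found: ", cfg$connectome$sln)
  if (is.null(cfg$numerics$seed))
    stop("a seed is mandatory in numerics$seed")
  class(cfg) <- c("experiment_config", "list")
  cfg
}

config_bundle <- function(cfg) {
  cn <- cfg$connectome
  if (!is.null(cn$fln)) {
    load_connectome(cn$fln, cn$sln)
  } else {
    s <- cn$synthetic
    generate_synthetic_connectome(n_areas = s$n_areas, density = s$density,
                                  seed = s$seed, sln_slope = s$sln_slope)
  }
}

config_network <- function(cfg) {
  bundle <- config_bundle(cfg)
  build_network(bundle, mode = cfg$mode, J_min = cfg$gradient$J_min,
                J_max = cfg$gradient$J_max, G = cfg$G,
                cib_scale = cfg$cib_scale, fef_cap = cfg$fef_cap)
}

config_events <- function(net, cfg) {
  evs <- cfg$protocol$events
  if (is.null(evs)) return(NULL)
  lapply(evs, function(e) {
    area_index(net, e$area)  # name resolution check
    stimulus_event(e$area,
                   population = if (is.null(e$population)) "A" else e$population,
                   onset = if (is.null(e$onset)) 1 else e$onset,
                   duration = if (is.null(e$duration)) 0.5 else e$duration,
                   amplitude = if (is.null(e$amplitude)) 0.3 else e$amplitude)
  })
}

#' Run a configured experiment
#'
#' Dispatches on \code{protocol$type}: \code{"simulate"} (cue/delay trial
#' with optional silencing and gating), \code{"census"},
#' \code{"silence"} (survival of a census under silenced sets),
#' \code{"distractor"}, or \code{"simple"} (simplified-model bistability
#' scan). Writes tidy CSV traces / summary JSON plus a manifest carrying the
#' full resolved configuration, seed and package version, and returns the
#' result invisibly.
#'
#' @param cfg an \code{\link{load_config}} result (or a path to one).
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the computed result object.
#' @export
run_experiment <- function(cfg, out_dir) {
  if (is.character(cfg)) cfg <- load_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  type <- cfg$protocol$type
  num <- cfg$numerics
  result <- switch(type,
    simulate = {
      net <- config_network(cfg)
      if (!is.null(cfg$protocol$gating))
        net <- apply_gating(net, cfg$protocol$gating$open_areas,
                            cfg$protocol$gating$g_s)
      events <- config_events(net, cfg)
      sil <- if (!is.null(cfg$protocol$silencing)) {
        s <- cfg$protocol$silencing
        area_index(net, s$areas)
        silencing_spec(s$areas,
                       start = if (is.null(s$start)) 0 else s$start,
                       end = if (is.null(s$end)) Inf else s$end)
      }
      sim <- simulate(net, seed = num$seed, duration = num$duration,
                      dt = num$dt, events = events, silencing = sil)
      summ <- summarize_delay_activity(sim)
      write_traces_csv(sim, file.path(out_dir, "traces.csv"))
      jsonlite::write_json(
        list(active = summ$active, threshold = summ$threshold,
             window = summ$window, table = summ$table),
        file.path(out_dir, "delay_summary.json"),
        auto_unbox = TRUE, digits = NA)
      list(sim = sim, summary = summ)
    },
    census = {
      net <- config_network(cfg)
      ns <- cfg$protocol$n_samples
      cen <- enumerate_attractors(net,
        n_samples = if (is.null(ns)) 5000 else ns,
        relax_time = if (is.null(cfg$protocol$relax_time)) 20 else
          cfg$protocol$relax_time,
        seed = num$seed)
      write_census_json(cen, file.path(out_dir, "census.json"))
      utils::write.csv(
        data.frame(pattern = apply(cen$patterns, 1, function(z)
          paste(as.integer(z), collapse = "")),
          size = cen$sizes, hits = cen$hits),
        file.path(out_dir, "census_summary.csv"), row.names = FALSE)
      cen
    },
    silence = {
      net <- config_network(cfg)
      cen <- read_census_json(cfg$protocol$census_file, net)
      sets <- cfg$protocol$silenced_sets
      surv <- silencing_survival(net, cen, sets)
      utils::write.csv(
        data.frame(set = vapply(sets, paste, "", collapse = "+"),
                   pct_surviving = surv),
        file.path(out_dir, "survival.csv"), row.names = FALSE)
      surv
    },
    distractor = {
      net <- config_network(cfg)
      pr <- cfg$protocol
      tr <- run_distractor_trial(net,
        distractor_amplitude = if (is.null(pr$distractor_amplitude)) 0.3 else
          pr$distractor_amplitude,
        gap = if (is.null(pr$gap)) 4 else pr$gap,
        seed = num$seed, dt = num$dt)
      write_traces_csv(tr$sim, file.path(out_dir, "traces.csv"))
      jsonlite::write_json(list(outcome = tr$outcome),
                           file.path(out_dir, "outcome.json"),
                           auto_unbox = TRUE)
      tr
    },
    simple = {
      pr <- cfg$protocol
      spec <- simple_net_spec(
        gradient = if (is.null(pr$gradient)) "saturating" else pr$gradient,
        ff_factor = if (is.null(pr$ff_factor)) 1 else pr$ff_factor,
        fb_factor = if (is.null(pr$fb_factor)) 1 else pr$fb_factor)
      Gr <- if (is.null(pr$G_range)) seq(0.05, 0.6, by = 0.05) else
        unlist(pr$G_range)
      counts <- count_bistable_areas(spec, Gr)
      utils::write.csv(counts, file.path(out_dir, "bistable_counts.csv"),
                       row.names = FALSE)
      counts
    },
    stop("unknown protocol type: ", type))
  manifest <- list(config = unclass(cfg), seed = num$seed,
                   package_version = as.character(utils::packageVersion("wmnet")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(result)
}

write_traces_csv <- function(sim, path) {
  n <- length(sim$areas)
  tidy <- data.frame(
    time = rep(sim$time, times = 3 * n),
    area = rep(rep(sim$areas, each = length(sim$time)), times = 3),
    population = rep(c("A", "B", "C"), each = n * length(sim$time)),
    rate = c(as.numeric(sim$rA), as.numeric(sim$rB), as.numeric(sim$rC)))
  utils::write.csv(tidy, path, row.names = FALSE)
}

write_census_json <- function(cen, path) {
  jsonlite::write_json(list(
    areas = cen$areas,
    patterns = apply(cen$patterns, 1, function(z)
      paste(as.integer(z), collapse = "")),
    sizes = cen$sizes, hits = cen$hits,
    meta = list(n_samples = cen$n_samples, relax_time = cen$relax_time,
                threshold = cen$threshold, G = cen$G, J_max = cen$J_max,
                seed = cen$seed, seed_value = cen$seed_value,
                n_nonconverged = cen$n_nonconverged)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_census_json <- function(path, net) {
  j <- jsonlite::fromJSON(path)
  P <- do.call(rbind, lapply(j$patterns, function(s)
    as.integer(strsplit(s, "")[[1]]) == 1L))
  colnames(P) <- j$areas
  # rebuild representative states by re-seeding each pattern at the elevated
  # gating value and relaxing (states are not serialized)
  states <- lapply(seq_len(nrow(P)), function(i) {
    st <- net$spont
    st[P[i, ], "S_A"] <- j$meta$seed_value
    relax_network(net, init = st, max_time = j$meta$relax_time)$state
  })
  structure(list(patterns = P, rates = matrix(NA_real_, nrow(P), ncol(P)),
                 states = states, sizes = rowSums(P),
                 hits = j$hits, n_samples = j$meta$n_samples,
                 n_nonconverged = j$meta$n_nonconverged,
                 threshold = j$meta$threshold,
                 relax_time = j$meta$relax_time, dt = NA,
                 seed = j$meta$seed, seed_value = j$meta$seed_value,
                 G = j$meta$G, J_max = j$meta$J_max, areas = j$areas),
            class = "attractor_census")
}
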