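#' Census for a scaled model cylinder
#'
#' Keeps the default density (200,000 cells per cubic mm) and the default
#' per-type proportions (core: 37/33/15/8/7 percent of the core population;
#' shell: 85/15 excitatory/inhibitory) while scaling counts to the cylinder's
#' volume, for matched-density reduced models.
#'
#' @param geometry List with `core_radius`, `shell_radius`, `height` (um).
#' @param density Cells per cubic mm.
#' @return Named integer census vector.
#' @export
scaled_census <- function(geometry, density = 200000) {
  vol_core <- pi * geometry$core_radius^2 * geometry$height / 1e9      # mm^3
  vol_shell <- pi * (geometry$shell_radius^2 - geometry$core_radius^2) *
    geometry$height / 1e9
  n_core <- round(density * vol_core)
  n_shell <- round(density * vol_shell)
  core_prop <- c(Scnn1a = 0.37, Rorb = 0.33, Nr5a1 = 0.15, PV1 = 0.08, PV2 = 0.07)
  shell_prop <- c(LIF_exc = 0.85, LIF_inh = 0.15)
  out <- c(round(core_prop * n_core), round(shell_prop * n_shell))
  storage.mode(out) <- "integer"
  out
}

#' Build a complete layer 4 network
#'
#' Instantiates the cell table, recurrent connectivity under the chosen rule,
#' the LGN filter bank with its retinotopic feedforward wiring, and the
#' background generators with their wiring, and applies a base weight matrix.
#' With the default geometry this reproduces the full 45,000-cell model; a
#' smaller `geometry` builds a matched-density reduced model (the filter bank
#' and generator pool are scaled to the same densities over the smaller
#' footprint).
#'
#' @param rule Connectivity/weight rule ("LL", "LR", "RL", "RR").
#' @param seed Integer master seed (component seeds are derived from it).
#' @param geometry Cylinder geometry in um.
#' @param census Per-type counts; defaults to [default_census()] for the
#'   default geometry, else [scaled_census()].
#' @param synapse_model "instantaneous" or "kinetic".
#' @param filter_params LGN filter sampling ranges.
#' @param class_matrix Base weight matrix; defaults to
#'   [default_class_matrix()] for the synapse model.
#' @param lgn_margin Margin in degrees added around the mapped cortical extent
#'   when sizing the filter field (capped at the full 130 x 90 field).
#' @param with_lgn,with_background Set FALSE to skip building a component.
#' @return An `l4_network` list: `cells`, `recurrent`, `lgn_bank`,
#'   `lgn_edges`, `generators`, `bg_edges`, `class_matrix`, `rule`,
#'   `synapse_model`, `geometry`, `seed`.
#' @export
build_network <- function(rule = c("LL", "LR", "RL", "RR"), seed = 1L,
                          geometry = default_geometry(), census = NULL,
                          synapse_model = c("instantaneous", "kinetic"),
                          filter_params = default_filter_params(),
                          class_matrix = NULL, lgn_margin = 25,
                          with_lgn = TRUE, with_background = TRUE) {
  rule <- match.arg(rule)
  synapse_model <- match.arg(synapse_model)
  if (is.null(census)) {
    census <- if (identical(geometry, default_geometry())) default_census()
              else scaled_census(geometry)
  }
  if (is.null(class_matrix)) class_matrix <- default_class_matrix(synapse_model)

  cells <- assign_tuning(place_cells(census, geometry, seed))
  recurrent <- build_recurrent(cells, rule, seed = seed + 1L)
  recurrent <- assign_weights(recurrent, class_matrix, cells, rule)

  lgn_bank <- NULL; lgn_edges <- NULL
  if (with_lgn) {
    az <- 120 * geometry$shell_radius / 1000
    el <- 50 * geometry$shell_radius / 1000
    field <- c(min(2 * (az + lgn_margin), 130), min(2 * (el + lgn_margin), 90))
    n_per_type <- round(9000 / (130 * 90) * prod(field) / 3)
    lgn_bank <- place_filters(n_per_type, field, seed = seed + 2L, params = filter_params)
    lgn_edges <- wire_lgn_to_l4(lgn_bank, cells, seed = seed + 3L)
    lgn_edges$weight <- class_matrix["LGN", cells$cell_type[lgn_edges$tgt + 1L]]
  }

  generators <- NULL; bg_edges <- NULL
  if (with_background) {
    gen_radius <- geometry$shell_radius + 150
    n_gen <- round(3000 / (pi * 995^2) * pi * gen_radius^2)
    generators <- place_generators(n_gen, gen_radius, seed = seed + 4L)
    bg_edges <- wire_background(cells, generators, seed = seed + 5L)
    bg_edges$weight <- class_matrix["BKG", cells$cell_type[bg_edges$tgt + 1L]]
  }

  structure(list(cells = cells, recurrent = recurrent, lgn_bank = lgn_bank,
                 lgn_edges = lgn_edges, generators = generators,
                 bg_edges = bg_edges, class_matrix = class_matrix, rule = rule,
                 synapse_model = synapse_model, geometry = geometry, seed = seed),
            class = "l4_network")
}

#' @export
print.l4_network <- function(x, ...) {
  cat(sprintf("l4_network [%s, %s synapses]: %d cells, %d recurrent edges\n",
              x$rule, x$synapse_model, nrow(x$cells), nrow(x$recurrent)))
  if (!is.null(x$lgn_bank))
    cat(sprintf("  LGN: %d filters, %d feedforward edges\n",
                nrow(x$lgn_bank), nrow(x$lgn_edges)))
  if (!is.null(x$generators))
    cat(sprintf("  background: %d generators, %d edges\n",
                nrow(x$generators), nrow(x$bg_edges)))
  invisible(x)
}

#' Re-apply a weight matrix to all connection sets of a network
#'
#' Used by the calibration stages: only per-(source class, target type)
#' scalars change; edge topology, synapse counts, and the per-edge
#' like-to-like factors are rebuilt from the same rule, untouched.
#'
#' @param net An `l4_network`.
#' @param class_matrix New base weight matrix.
#' @return The network with updated weights.
#' @export
apply_class_matrix <- function(net, class_matrix) {
  net$class_matrix <- class_matrix
  net$recurrent <- assign_weights(net$recurrent, class_matrix, net$cells, net$rule)
  if (!is.null(net$lgn_edges))
    net$lgn_edges$weight <- class_matrix["LGN", net$cells$cell_type[net$lgn_edges$tgt + 1L]]
  if (!is.null(net$bg_edges))
    net$bg_edges$weight <- class_matrix["BKG", net$cells$cell_type[net$bg_edges$tgt + 1L]]
  net
}

#' Simulate trials of a stimulus on a network
#'
#' Computes the deterministic LGN filter-bank rates for the movie once, then
#' per trial samples fresh LGN Poisson spike trains and an independent
#' background wave schedule (each trial sees a unique combination of
#' background-on/off epochs), applies any perturbation, and runs the network.
#'
#' @param net An `l4_network`.
#' @param movie A `stimulus_movie`, or NULL for a background-only run.
#' @param n_trials Number of trials.
#' @param seed Integer seed; trial t uses seed + t.
#' @param t_stop Simulation length in ms (defaults to the movie length).
#' @param regime "full", "feedforward" (no recurrent, no background),
#'   "background_only" (no LGN, no recurrent), or "lgn_only" (no recurrent).
#' @param pert Optional [perturbation()].
#' @param params Point-neuron parameters; defaults to the network's synapse
#'   model.
#' @param rates Optional precomputed LGN rate matrix (from
#'   [filter_bank_response()]), to avoid recomputation across calls.
#' @param analysis_start Start of the accumulator window in ms.
#' @return List with `spikes` (cell_id, time, trial), `accum` (summed over
#'   trials), `n_trials`, `audit` (summed counters), `rates` (as used).
#' @export
run_stimulus <- function(net, movie, n_trials = 1, seed = 1L, t_stop = NULL,
                         regime = c("full", "feedforward", "background_only", "lgn_only"),
                         pert = NULL, params = NULL, rates = NULL,
                         analysis_start = 500) {
  regime <- match.arg(regime)
  if (is.null(params))
    params <- point_neuron_params(net$synapse_model)
  use_lgn <- regime != "background_only" && !is.null(net$lgn_edges) &&
    (!is.null(movie) || !is.null(rates))
  use_bg <- regime %in% c("full", "background_only") && !is.null(net$bg_edges)
  use_rec <- regime == "full"
  if (is.null(t_stop)) {
    if (is.null(movie)) stop("t_stop required without a movie")
    t_stop <- dim(movie$frames)[3] * movie$dt
  }
  if (use_lgn && is.null(rates)) rates <- filter_bank_response(net$lgn_bank, movie)

  all_spikes <- vector("list", n_trials)
  accum <- NULL
  audit <- NULL
  for (tr in seq_len(n_trials)) {
    set.seed(seed + tr)
    inputs <- list()
    if (use_lgn) {
      nt <- nrow(rates)
      hit <- which(matrix(stats::runif(length(rates)), nt) < rates / 1000, arr.ind = TRUE)
      lgn_sp <- data.frame(src = net$lgn_bank$filter_id[hit[, 2]], time = hit[, 1] - 0.5)
      inputs <- c(inputs, list(external_input(lgn_sp, net$lgn_edges, "LGN")))
    }
    if (use_bg) {
      sched <- generate_waves(t_stop, seed = NULL,
                              footprint_radius = net$geometry$shell_radius + 150)
      bg_sp <- background_spikes(sched, net$generators, t_stop, seed = NULL)
      inputs <- c(inputs, list(external_input(bg_sp, net$bg_edges, "BKG")))
    }
    if (!is.null(pert))
      inputs <- apply_perturbation(inputs, pert, net$cells, t_stop, seed = seed + tr)
    out <- simulate_network(net$cells, if (use_rec) net$recurrent else NULL,
                            inputs, params, t_stop, analysis_start = analysis_start)
    sp <- out$spikes
    sp$trial <- rep(tr, nrow(sp))
    all_spikes[[tr]] <- sp
    if (is.null(accum)) accum <- out$accum else {
      accum$lgn_exc <- accum$lgn_exc + out$accum$lgn_exc
      accum$total_exc <- accum$total_exc + out$accum$total_exc
    }
    if (is.null(audit)) audit <- out$audit else
      audit <- Map(`+`, audit, out$audit)
  }
  list(spikes = do.call(rbind, all_spikes), accum = accum, n_trials = n_trials,
       audit = audit, rates = rates)
}

#' Constant LGN rate matrix for a gray screen
#'
#' On a uniform gray screen every filter's rate is its baseline R0 (the
#' temporal kernel integrates to zero, and the first 500 ms is overridden to
#' R0 regardless); this builds that rate matrix directly, avoiding a
#' full-frame convolution whose result is known exactly.
#'
#' @param bank An `lgn_bank`.
#' @param t_stop Duration in ms.
#' @return Rate matrix (ms x filters) of baselines.
#' @export
gray_rates <- function(bank, t_stop) {
  matrix(bank$R0, nrow = as.integer(t_stop), ncol = nrow(bank), byrow = TRUE)
}

#' Mean firing rate per cell type or class
#'
#' @param spikes data.frame with `cell_id`, `time` (and optionally `trial`).
#' @param cells The `cell_table`.
#' @param window Analysis window in ms.
#' @param n_trials Number of trials the spikes were pooled from.
#' @param by "cell_type" or "ei_class".
#' @param subset Optional logical vector over cells (e.g. core only).
#' @return Named numeric vector of mean rates in Hz.
#' @export
rates_by_group <- function(spikes, cells, window, n_trials = 1,
                           by = c("ei_class", "cell_type"), subset = NULL) {
  by <- match.arg(by)
  if (is.null(subset)) subset <- rep(TRUE, nrow(cells))
  sel <- spikes$time >= window[1] & spikes$time < window[2]
  counts <- tabulate(match(spikes$cell_id[sel], cells$cell_id), nbins = nrow(cells))
  rate <- counts / (diff(window) / 1000) / n_trials
  vapply(split(rate[subset], cells[[by]][subset]), mean, 0.0)
}
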