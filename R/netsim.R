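#' Point-neuron model parameters
#'
#' Membrane and synapse constants for the two point-neuron variants. The
#' kinetic model uses a single-exponential excitatory synapse and a
#' peak-normalized difference-of-exponentials inhibitory synapse, with
#' constants per target class: tau_e = 1, tau_i1 = 4, tau_i2 = 17 ms onto
#' excitatory cells and tau_e = 7, tau_i1 = 1, tau_i2 = 8 ms onto inhibitory
#' cells. Membrane time constants default to 15 ms (E) and 10 ms (I); these
#' are calibration inputs standing in for the averages of the detailed cell
#' models, not measured constants. Threshold is normalized to 1, reset to 0.
#'
#' @param synapse_model "instantaneous" (charge-dump) or "kinetic".
#' @param tau_m Named vector of membrane time constants (ms) for E and I cells.
#' @param refractory Refractory period in ms; inputs arriving during it are
#'   discarded.
#' @param kinetic List of per-target-class synaptic time constants.
#' @return A `point_neuron_params` list.
#' @export
point_neuron_params <- function(synapse_model = c("instantaneous", "kinetic"),
                                tau_m = c(E = 15, I = 10), refractory = 3,
                                kinetic = list(E = c(tau_e = 1, tau_i1 = 4, tau_i2 = 17),
                                               I = c(tau_e = 7, tau_i1 = 1, tau_i2 = 8))) {
  synapse_model <- match.arg(synapse_model)
  stopifnot(all(tau_m > 0), refractory >= 0,
            all(unlist(kinetic) > 0),
            kinetic$E["tau_i2"] > kinetic$E["tau_i1"],
            kinetic$I["tau_i2"] > kinetic$I["tau_i1"])
  structure(list(synapse_model = synapse_model, tau_m = tau_m,
                 refractory = refractory, kinetic = kinetic),
            class = "point_neuron_params")
}

#' Bundle an external spike source with its feedforward edges
#'
#' @param spikes data.frame with `src` (source ids matching `edges$src`) and
#'   `time` (ms).
#' @param edges A feedforward `connection_set` with populated weights.
#' @param label Source label; "LGN" marks events counted in the LGN input
#'   accumulator.
#' @return An `external_input` list.
#' @export
external_input <- function(spikes, edges, label = "input") {
  if (any(is.na(edges$weight))) stop("external input edges must have weights assigned")
  structure(list(spikes = spikes, edges = edges, label = label),
            class = "external_input")
}

# Expand source spikes through feedforward edges into per-target events.
# Returns data.frame(step, tgt_row0, w, lgn).
expand_events <- function(input, cells, dt, nsteps) {
  edges <- input$edges
  spikes <- input$spikes
  if (nrow(edges) == 0 || is.null(spikes) || nrow(spikes) == 0)
    return(data.frame(step = integer(0), tgt = integer(0), w = numeric(0), lgn = integer(0)))
  o <- order(edges$src)
  es <- edges$src[o]
  runs <- rle(es)
  start <- cumsum(c(1L, runs$lengths[-length(runs$lengths)]))
  mi <- match(spikes$src, runs$values)
  keep <- which(!is.na(mi))
  if (length(keep) == 0)
    return(data.frame(step = integer(0), tgt = integer(0), w = numeric(0), lgn = integer(0)))
  nrep <- runs$lengths[mi[keep]]
  rows <- o[sequence(nrep) + rep(start[mi[keep]], nrep) - 1L]
  times <- rep(spikes$time[keep], nrep) + edges$delay[rows]
  step <- as.integer(round(times / dt))
  tgt <- match(edges$tgt[rows], cells$cell_id) - 1L
  if (anyNA(tgt)) stop("input edges reference unknown cell ids")
  w <- edges$weight[rows] * edges$n_syn[rows]
  ok <- step >= 0L & step < nsteps
  data.frame(step = step[ok], tgt = tgt[ok], w = w[ok],
             lgn = as.integer(identical(input$label, "LGN")))
}

#' Simulate the point-neuron network
#'
#' Runs a fixed-step (default 0.1 ms) simulation of the leaky
#' integrate-and-fire network under the instantaneous or kinetic synapse
#' model. Per arriving excitatory event the target's input accumulators are
#' incremented by the event's summed weight (LGN-only and all-excitatory
#' sums), which is what the LGN input fraction is computed from.
#'
#' @param cells A `cell_table`.
#' @param recurrent Recurrent `connection_set` with weights, or NULL for a
#'   feedforward-only run.
#' @param inputs List of `external_input` objects (LGN, background,
#'   perturbation sources).
#' @param params A `point_neuron_params`.
#' @param t_stop Simulation length in ms.
#' @param dt Time step in ms (at most 1 ms; delays and the refractory period
#'   resolve exactly on the default 0.1 ms grid).
#' @param analysis_start Accumulators only integrate events from this time on
#'   (the first 500 ms is an equilibration epoch disregarded by analysis).
#' @return A `spike_data` list: `spikes` (data.frame cell_id, time), `accum`
#'   (per-cell LGN and total excitatory input sums), `audit` (event
#'   conservation counters), `t_stop`, `params`.
#' @export
simulate_network <- function(cells, recurrent = NULL, inputs = list(),
                             params = point_neuron_params(), t_stop, dt = 0.1,
                             analysis_start = 500) {
  if (dt > 1) stop("dt must be at most 1 ms")
  nsteps <- as.integer(ceiling(t_stop / dt))
  n <- nrow(cells)
  ei <- as.integer(cells$ei_class == "I")
  tau_m <- unname(params$tau_m[ifelse(ei == 1, "I", "E")])

  if (!is.null(recurrent) && nrow(recurrent) > 0) {
    if (any(is.na(recurrent$weight))) stop("recurrent weights must be assigned")
    src_row <- match(recurrent$src, cells$cell_id) - 1L
    tgt_row <- match(recurrent$tgt, cells$cell_id) - 1L
    if (anyNA(src_row) || anyNA(tgt_row)) stop("recurrent edges reference unknown cell ids")
    o <- order(src_row)
    rec_ptr <- c(0L, cumsum(tabulate(src_row + 1L, nbins = n)))
    rec_tgt <- tgt_row[o]
    rec_w <- (recurrent$weight * recurrent$n_syn)[o]
    delay <- recurrent$delay[1]
  } else {
    rec_ptr <- integer(n + 1); rec_tgt <- integer(0); rec_w <- numeric(0)
    delay <- 1.0
  }

  if (inherits(inputs, "external_input")) inputs <- list(inputs)
  evs <- lapply(inputs, expand_events, cells = cells, dt = dt, nsteps = nsteps)
  ev <- if (length(evs)) do.call(rbind, evs) else
    data.frame(step = integer(0), tgt = integer(0), w = numeric(0), lgn = integer(0))
  ev <- ev[order(ev$step), , drop = FALSE]

  model <- if (params$synapse_model == "kinetic") 1L else 0L
  kin <- c(params$kinetic$E, params$kinetic$I)
  res <- simulate_cpp(ei, tau_m, t_stop, dt, params$refractory, delay, model,
                      as.integer(rec_ptr), rec_tgt, rec_w,
                      ev$step, ev$tgt, ev$w, ev$lgn,
                      as.numeric(kin), analysis_start)
  structure(list(
    spikes = data.frame(cell_id = cells$cell_id[res$cell + 1L], time = res$time),
    accum = data.frame(cell_id = cells$cell_id, lgn_exc = res$lgn_exc,
                       total_exc = res$tot_exc),
    audit = list(n_external = nrow(ev), n_applied = res$n_applied,
                 n_discarded = res$n_discarded, n_delivered = res$n_delivered,
                 n_scheduled_recurrent = res$n_scheduled_recurrent,
                 n_external_processed = res$n_external_processed),
    state = data.frame(cell_id = cells$cell_id, v = res$state_v, e = res$state_e,
                       a = res$state_a, b = res$state_b),
    state_time = res$state_time,
    t_stop = t_stop, dt = dt, params = params), class = "spike_data")
}

#' @export
print.spike_data <- function(x, ...) {
  cat(sprintf("spike_data: %d spikes over %g ms (%s synapses)\n",
              nrow(x$spikes), x$t_stop, x$params$synapse_model))
  invisible(x)
}

#' Describe an optogenetic-style perturbation
#'
#' `silence_population` attaches one inhibitory synapse driven by a 100 Hz
#' Poisson train to a random fraction of the cells of the target type(s); the
#' synaptic weight scales linearly with the labeled current strength, with
#' `weight_per_100pA` the weight corresponding to the -100 pA label.
#' `silence_lgn` deletes all LGN spikes from `onset` on.
#'
#' @param kind "silence_population" or "silence_lgn".
#' @param target_type Cell type(s) to silence (silence_population).
#' @param fraction Fraction of the target type's cells perturbed.
#' @param strength_pA Labeled current in pA (negative; -30/-50/-100/-150).
#' @param onset Perturbation onset in ms.
#' @param weight_per_100pA Silencing synapse weight magnitude equivalent to
#'   the -100 pA label (see [calibrate_silencing_weight()]).
#' @return A `perturbation` list.
#' @export
perturbation <- function(kind = c("silence_population", "silence_lgn"),
                         target_type = "Scnn1a", fraction = 1,
                         strength_pA = -100, onset = 0, weight_per_100pA = 0.5) {
  kind <- match.arg(kind)
  if (fraction < 0 || fraction > 1) stop("fraction must lie in [0, 1]")
  structure(list(kind = kind, target_type = target_type, fraction = fraction,
                 strength_pA = strength_pA, onset = onset,
                 weight_per_100pA = weight_per_100pA), class = "perturbation")
}

#' Apply a perturbation to simulation inputs
#'
#' @param inputs List of `external_input` objects (the LGN input must carry
#'   label "LGN" for `silence_lgn`).
#' @param pert A [perturbation()].
#' @param cells The `cell_table` (needed for `silence_population`).
#' @param t_stop Simulation length in ms (Poisson silencing trains span
#'   `onset`..`t_stop`).
#' @param seed Integer seed for cell selection and Poisson trains.
#' @return The modified list of inputs.
#' @export
apply_perturbation <- function(inputs, pert, cells = NULL, t_stop = NULL, seed = 1L) {
  if (inherits(inputs, "external_input")) inputs <- list(inputs)
  if (pert$kind == "silence_lgn") {
    for (i in seq_along(inputs)) {
      if (identical(inputs[[i]]$label, "LGN")) {
        sp <- inputs[[i]]$spikes
        inputs[[i]]$spikes <- sp[sp$time < pert$onset, , drop = FALSE]
      }
    }
    return(inputs)
  }
  if (is.null(cells) || is.null(t_stop))
    stop("silence_population needs cells and t_stop")
  if (!all(pert$target_type %in% cells$cell_type)) stop("unknown target type")
  if (pert$fraction == 0) return(inputs)
  set.seed(seed)
  pool <- cells$cell_id[cells$cell_type %in% pert$target_type]
  sel <- sort(sample(pool, round(pert$fraction * length(pool))))
  if (length(sel) == 0) return(inputs)
  w <- -pert$weight_per_100pA * abs(pert$strength_pA) / 100
  counts <- stats::rpois(length(sel), 100 * (t_stop - pert$onset) / 1000)
  spikes <- data.frame(
    src = rep(seq_along(sel) - 1L, counts),
    time = pert$onset + stats::runif(sum(counts)) * (t_stop - pert$onset))
  edges <- data.frame(src = seq_along(sel) - 1L, tgt = sel, n_syn = 1L,
                      weight = w, delay = 1.0)
  c(inputs, list(external_input(spikes, edges, label = "silencing")))
}

#' Calibrate the silencing-synapse weight
#'
#' Finds the inhibitory synapse weight at which a 100 Hz Poisson silencing
#' source reduces a benchmark cell's firing rate to a target fraction of its
#' unperturbed rate, mirroring the benchmark used to map the -100 pA current
#' label onto a synaptic weight. The benchmark cell is an excitatory point
#' neuron driven by a Poisson excitatory source.
#'
#' @param drive_rate Benchmark excitatory drive rate in Hz.
#' @param drive_weight Benchmark excitatory event weight.
#' @param target_fraction Residual rate fraction defining full (-100 pA)
#'   silencing.
#' @param params Point-neuron parameters.
#' @param t_stop Benchmark duration in ms.
#' @param seed Integer seed.
#' @return The calibrated weight magnitude (use as `weight_per_100pA`).
#' @export
calibrate_silencing_weight <- function(drive_rate = 2000, drive_weight = 0.05,
                                       target_fraction = 0.1,
                                       params = point_neuron_params(),
                                       t_stop = 20000, seed = 1L) {
  cells <- data.frame(cell_id = 0L, cell_type = "LIF_exc", ei_class = "E",
                      x = 0, y = 0, z = 0, is_core = FALSE, theta_assigned = 0)
  class(cells) <- c("cell_table", "data.frame")
  rate_at <- function(w_inh) {
    set.seed(seed)
    drive <- data.frame(src = 0L,
                        time = sort(stats::runif(stats::rpois(1, drive_rate * t_stop / 1000),
                                                 0, t_stop)))
    sil <- data.frame(src = 0L,
                      time = sort(stats::runif(stats::rpois(1, 100 * t_stop / 1000), 0, t_stop)))
    inputs <- list(
      external_input(drive, data.frame(src = 0L, tgt = 0L, n_syn = 1L,
                                       weight = drive_weight, delay = 1), "drive"),
      external_input(sil, data.frame(src = 0L, tgt = 0L, n_syn = 1L,
                                     weight = -w_inh, delay = 1), "silencing"))
    if (w_inh == 0) inputs <- inputs[1]
    out <- simulate_network(cells, NULL, inputs, params, t_stop, analysis_start = 0)
    nrow(out$spikes) / (t_stop / 1000)
  }
  r0 <- rate_at(0)
  if (r0 <= 0) stop("benchmark cell does not fire without silencing; raise drive_rate")
  f <- function(w) rate_at(w) - target_fraction * r0
  stats::uniroot(f, lower = 0, upper = 1, extendInt = "downX", tol = 1e-3)$root
}
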