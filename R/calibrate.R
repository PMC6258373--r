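#' Target firing rates for weight calibration
#'
#' Spontaneous-rate targets are the midpoints of the reported bands (0.5-1.0
#' Hz excitatory, 1.5-2.0 Hz inhibitory). The maximal grating response
#' targets and the feedforward-regime targets are configuration defaults
#' standing in for the reference rates the original optimization used (which
#' came from separate simulations and experimental reports).
#'
#' The Rmax defaults sit close to the feedforward-regime preferred-population
#' rates: in the reference simulations the maximal grating responses of the
#' full network were approximately the same as in the LGN-only case (recurrent
#' connections suppress non-preferred responses rather than raise the peak).
#'
#' @return List with `spont`, `rmax`, `feedforward` (each named E/I, in Hz).
#' @export
default_rate_targets <- function() {
  list(spont = c(E = 0.75, I = 1.75),
       rmax = c(E = 6, I = 12),
       feedforward = c(E = 4, I = 8))
}

damped_scale <- function(achieved, target, damp = 0.35, clamp = c(0.5, 2)) {
  if (achieved <= 0) return(if (target <= 0) 1 else clamp[2])
  min(max((target / achieved)^damp, clamp[1]), clamp[2])
}

#' Calibrate LGN-to-L4 weights in the feedforward regime
#'
#' Iteratively scales the LGN weight per target type so that feedforward-only
#' firing rates (no recurrent or background input) during a drifting grating
#' match the per-class targets.
#'
#' @param net An `l4_network`.
#' @param movie Training grating movie.
#' @param targets Target rates in Hz, named either per class (E/I) or per cell
#'   type.
#' @param tol Convergence tolerance in Hz.
#' @param max_iter Iteration cap.
#' @param seed Integer seed.
#' @param rates Optional precomputed LGN rate matrix for `movie`.
#' @return List with the updated `class_matrix`, `log` (per-iteration rates),
#'   and `converged`.
#' @export
calibrate_lgn_weights <- function(net, movie, targets = default_rate_targets()$feedforward,
                                  tol = 0.5, max_iter = 20, seed = 1L, rates = NULL) {
  cm <- net$class_matrix
  types <- colnames(cm)
  ei_of <- cell_type_table()$ei_class[match(types, cell_type_table()$cell_type)]
  goal <- if (all(types %in% names(targets))) targets[types] else targets[ei_of]
  t_stop <- dim(movie$frames)[3] * movie$dt
  if (is.null(rates)) rates <- filter_bank_response(net$lgn_bank, movie)
  log <- list()
  converged <- FALSE
  # one fixed training trial, reused every iteration (deterministic loop)
  for (it in seq_len(max_iter)) {
    net <- apply_class_matrix(net, cm)
    out <- run_stimulus(net, movie, n_trials = 1, seed = seed,
                        regime = "feedforward", rates = rates)
    r <- rates_by_group(out$spikes, net$cells, c(500, t_stop), by = "cell_type")
    r <- r[types]
    log[[it]] <- r
    err <- abs(r - goal)
    if (all(err <= tol)) { converged <- TRUE; break }
    for (j in seq_along(types))
      cm["LGN", types[j]] <- cm["LGN", types[j]] * damped_scale(r[j], goal[j])
  }
  if (!converged)
    warning("LGN weight calibration did not converge; returning best effort")
  list(class_matrix = cm, log = do.call(rbind, log), converged = converged)
}

#' Calibrate background weights in the background-only regime
#'
#' Scales the background weight per target type so background-only firing
#' rates come out close to, and slightly below, the spontaneous-rate targets.
#'
#' @param net An `l4_network`.
#' @param targets Per-class spontaneous targets in Hz.
#' @param undershoot Fraction of the target aimed for (background alone should
#'   sit slightly below the spontaneous rate).
#' @param t_stop Length of each background-only evaluation in ms.
#' @param n_trials Trials averaged per iteration.
#' @param tol Convergence tolerance in Hz.
#' @param max_iter Iteration cap.
#' @param seed Integer seed.
#' @return List with `class_matrix`, `log`, `converged`.
#' @export
calibrate_background_weights <- function(net, targets = default_rate_targets()$spont,
                                         undershoot = 0.8, t_stop = 5000,
                                         n_trials = 2, tol = 0.25, max_iter = 20,
                                         seed = 1L) {
  cm <- net$class_matrix
  types <- colnames(cm)
  ei_of <- cell_type_table()$ei_class[match(types, cell_type_table()$cell_type)]
  scaled <- targets * undershoot
  goal <- if (all(types %in% names(scaled))) scaled[types] else scaled[ei_of]
  log <- list()
  converged <- FALSE
  # fixed training trials, reused every iteration (deterministic loop)
  for (it in seq_len(max_iter)) {
    net <- apply_class_matrix(net, cm)
    out <- run_stimulus(net, NULL, n_trials = n_trials, seed = seed,
                        t_stop = t_stop, regime = "background_only")
    r <- rates_by_group(out$spikes, net$cells, c(500, t_stop),
                        n_trials = n_trials, by = "cell_type")
    r <- r[types]
    log[[it]] <- r
    err <- abs(r - goal)
    if (all(err <= tol)) { converged <- TRUE; break }
    for (j in seq_along(types))
      cm["BKG", types[j]] <- cm["BKG", types[j]] * damped_scale(r[j], goal[j])
  }
  if (!converged)
    warning("background weight calibration did not converge; returning best effort")
  list(class_matrix = cm, log = do.call(rbind, log), converged = converged)
}

#' Calibrate recurrent weights in the full network
#'
#' With the feedforward weights already fixed, iteratively scales the
#' recurrent excitatory and inhibitory weights per target type (a damped
#' multiplicative fixed-point loop, alternating the excitatory and inhibitory
#' source classes) until the spontaneous rate matches its target within
#' `tol_spont` and the preferred-grating response matches the Rmax target
#' within `tol_rmax`, per population. The training data are one gray-screen
#' trial and one drifting-grating trial. A synchrony guard rejects iterates
#' whose 5 ms-binned population rate exceeds 10x its median (epileptic-like
#' time-locked activity) by scaling excitation down and inhibition up.
#'
#' Only the per-class scalars move; edge topology and the per-edge
#' like-to-like weight structure are preserved (so the same protocol applies
#' identically to the LL, LR, RL, and RR variants).
#'
#' @param net An `l4_network` (weights from the two feedforward stages).
#' @param movie Training grating movie (direction should be on the assigned-
#'   preference grid so a preferred population exists).
#' @param targets List with `spont` and `rmax` per class, see
#'   [default_rate_targets()].
#' @param tol_spont,tol_rmax Tolerances in Hz. The spontaneous tolerance
#'   defaults tighter than the nominal 0.5 Hz so that converged rates stay
#'   inside the reported 0.5-1.0 / 1.5-2.0 Hz bands.
#' @param grating_window Grating analysis window in ms.
#' @param spont_t_stop Gray-trial length in ms.
#' @param max_iter Iteration cap.
#' @param seed Integer seed.
#' @param rates Optional precomputed LGN rate matrix for `movie`.
#' @return List with `class_matrix`, `log` (iteration, per-class spont and
#'   rmax), `converged`.
#' @export
calibrate_recurrent_weights <- function(net, movie, targets = default_rate_targets(),
                                        tol_spont = 0.25, tol_rmax = 1.0,
                                        grating_window = NULL, spont_t_stop = 2000,
                                        max_iter = 40, seed = 1L, rates = NULL) {
  cm <- net$class_matrix
  types <- colnames(cm)
  tt <- cell_type_table()
  ei_of <- tt$ei_class[match(types, tt$cell_type)]
  t_movie <- dim(movie$frames)[3] * movie$dt
  if (is.null(grating_window)) grating_window <- c(500, t_movie)
  if (is.null(rates)) rates <- filter_bank_response(net$lgn_bank, movie)
  gdir <- attr(movie, "direction")
  if (is.null(gdir)) gdir <- 0
  pref <- fold_delta_ori(net$cells$theta_assigned - gdir) <= 22.5
  log <- list()
  converged <- FALSE
  rmax_limited <- FALSE
  # lowest excitatory weight per type known to destabilize the network; the
  # excitatory update bisects toward this bound instead of crossing it
  e_unstable <- rep(Inf, length(types)); names(e_unstable) <- types
  # the training set is one fixed grating trial and one fixed gray trial:
  # reusing the same trial seed every iteration makes the fixed-point loop
  # deterministic in the weights
  for (it in seq_len(max_iter)) {
    net <- apply_class_matrix(net, cm)
    gr <- run_stimulus(net, movie, n_trials = 1, seed = seed,
                       regime = "full", rates = rates)
    sp <- run_stimulus(net, NULL, n_trials = 1, seed = seed + 50L,
                       t_stop = spont_t_stop, regime = "full",
                       rates = gray_rates(net$lgn_bank, spont_t_stop))
    spont <- rates_by_group(sp$spikes, net$cells, c(500, spont_t_stop), by = "ei_class")
    rmax <- rates_by_group(gr$spikes, net$cells, grating_window,
                           by = "ei_class", subset = pref)
    spont <- spont[c("E", "I")]; rmax <- rmax[c("E", "I")]
    spont[is.na(spont)] <- 0; rmax[is.na(rmax)] <- 0
    # synchrony guard on the grating run: time-locked bursts (binned population
    # rate far above its median) or runaway sustained activity
    pop <- bin_rate(gr$spikes$time, grating_window, 5) / nrow(net$cells)
    sync <- (stats::median(pop) > 0 && max(pop) > 10 * stats::median(pop)) ||
      mean(rmax) > 4 * mean(targets$rmax)
    log[[it]] <- c(iter = it, spont_E = spont["E"], spont_I = spont["I"],
                   rmax_E = rmax["E"], rmax_I = rmax["I"], sync = as.numeric(sync))
    if (sync) {
      e_unstable <- pmin(e_unstable, cm["E", types])
      cm["E", ] <- cm["E", ] * 0.75
      next
    }
    # the excitatory weight can only rise toward (the geometric midpoint of)
    # the lowest weight known to destabilize; when that bracket is tight the
    # maximal stable response is below the Rmax target and is accepted as the
    # best-effort outcome (spontaneous targets still have to be met)
    rmax_ceiling <- all(is.finite(e_unstable) &
                          e_unstable / cm["E", types] < 1.3) &&
      all(rmax < targets$rmax - tol_rmax)
    ok_spont <- all(abs(spont - targets$spont) <= tol_spont)
    ok_rmax <- all(abs(rmax - targets$rmax) <= tol_rmax)
    if (ok_spont && (ok_rmax || rmax_ceiling)) {
      # accept only if an independent trial (fresh background and LGN draws)
      # also stays clear of synchronous runaway; the stability boundary
      # fluctuates between trials, so training-trial stability alone is not
      # enough to keep the frozen weights safely below it
      gv <- run_stimulus(net, movie, n_trials = 1, seed = seed + 1L,
                         regime = "full", rates = rates)
      rv <- rates_by_group(gv$spikes, net$cells, grating_window,
                           by = "ei_class", subset = pref)
      rv[is.na(rv)] <- 0
      popv <- bin_rate(gv$spikes$time, grating_window, 5) / nrow(net$cells)
      sync_v <- (stats::median(popv) > 0 && max(popv) > 10 * stats::median(popv)) ||
        mean(rv) > 4 * mean(targets$rmax)
      if (sync_v) {
        e_unstable <- pmin(e_unstable, cm["E", types])
        cm["E", ] <- cm["E", ] * 0.75
        next
      }
      converged <- TRUE
      rmax_limited <- !ok_rmax
      break
    }
    # simultaneous damped updates: excitatory classes track Rmax, inhibitory
    # classes track the spontaneous rate (more inhibition lowers it)
    for (j in seq_along(types)) {
      prop <- cm["E", types[j]] *
        damped_scale(rmax[ei_of[j]], targets$rmax[ei_of[j]], damp = 0.25,
                     clamp = c(0.7, 1.15))
      if (prop > cm["E", types[j]])
        prop <- min(prop, sqrt(cm["E", types[j]] * e_unstable[types[j]]))
      cm["E", types[j]] <- prop
      cm["I", types[j]] <- cm["I", types[j]] *
        damped_scale(targets$spont[ei_of[j]], spont[ei_of[j]], damp = 0.25,
                     clamp = c(0.75, 1.35))
    }
  }
  if (!converged)
    warning("recurrent weight calibration did not converge; returning best effort")
  if (rmax_limited)
    warning("Rmax target unreachable below the stability boundary; ",
            "spontaneous targets met, maximal stable response accepted")
  list(class_matrix = cm, log = do.call(rbind, log), converged = converged,
       rmax_limited = rmax_limited)
}
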