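# Shared fixtures. The heavy ones (full-scale build, calibrated reduced
# networks) are built once per test run and memoized; the full-scale fixture
# keeps summaries and small subsets rather than the 20-million-edge list.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# minimal hand-built cell table
mk_cells <- function(n = 1, ei = rep("E", n), x = rep(0, n), y = rep(0, n),
                     theta = rep(0, n), type = NULL) {
  if (is.null(type)) type <- ifelse(ei == "E", "LIF_exc", "LIF_inh")
  d <- data.frame(cell_id = seq_len(n) - 1L, cell_type = type, ei_class = ei,
                  x = x, y = y, z = 0, is_core = FALSE, theta_assigned = theta,
                  stringsAsFactors = FALSE)
  class(d) <- c("cell_table", "data.frame")
  d
}

mk_bank <- function(ftype = "ON", x0 = 0, y0 = 0, sigma_c = 2.5, A_c = 1.8e-4,
                    k = 0.04, R0 = 3, dx = 0, dy = 0) {
  n <- max(lengths(list(ftype, x0, y0, sigma_c, A_c, k, R0)))
  b <- data.frame(filter_id = seq_len(n) - 1L, ftype = ftype, x0 = x0, y0 = y0,
                  dx = dx, dy = dy, sigma_c = sigma_c, A_c = A_c, k = k, R0 = R0,
                  stringsAsFactors = FALSE)
  class(b) <- c("lgn_bank", "data.frame")
  b
}

# one-neuron drive helper
single_event_input <- function(times, weight, n_syn = 1L, delay = 1, label = "drive") {
  external_input(data.frame(src = 0L, time = times),
                 data.frame(src = 0L, tgt = 0L, n_syn = n_syn, weight = weight,
                            delay = delay), label)
}

# Full-scale default model: cells, filter bank, LGN wiring, plus degree and
# synapse summaries of the LL recurrent build and the recurrent edges among
# core excitatory cells (for pair-based connectivity properties). The full
# edge list is summarized and discarded to keep memory bounded.
full_build <- function() memo("full_build", function() {
  cells <- assign_tuning(place_cells(seed = 1))
  conns <- build_recurrent(cells, "LL", seed = 2)
  ds <- degree_summary(conns, cells, core_only = TRUE)
  core_e_ids <- cells$cell_id[cells$is_core & cells$ei_class == "E"]
  keep <- conns$src %in% core_e_ids & conns$tgt %in% core_e_ids
  conns_core_e <- as.data.frame(conns[keep, c("src", "tgt")])
  rm(conns, keep)
  bank <- place_filters(seed = 3)
  ff <- wire_lgn_to_l4(bank, cells, seed = 4)
  lgn_syn <- numeric(nrow(cells))
  agg <- rowsum(as.numeric(ff$n_syn), ff$tgt)
  lgn_syn[match(as.integer(rownames(agg)), cells$cell_id)] <- agg[, 1]
  per_filter <- tabulate(ff$src + 1L, nbins = nrow(bank))
  list(cells = cells, bank = bank, ff = ff,
       ds_core = ds$by_class, per_cell = ds$per_cell,
       conns_core_e = conns_core_e, core_e_ids = core_e_ids,
       lgn_syn = lgn_syn, per_filter = per_filter)
})

# Matched-density reduced network (150/250 um), instantaneous synapses,
# calibrated through the three stages on the standard training stimuli.
calibrated_smallnet <- function() memo("smallnet", function() {
  geom <- list(core_radius = 150, shell_radius = 250, height = 100)
  net <- build_network("LL", seed = 7, geometry = geom, lgn_margin = 18)
  mv <- make_grating(0, 0.05, 4, 80, 1000)
  rates <- filter_bank_response(net$lgn_bank, mv)
  s1 <- suppressWarnings(calibrate_lgn_weights(net, mv, rates = rates, seed = 11))
  net <- apply_class_matrix(net, s1$class_matrix)
  s2 <- suppressWarnings(calibrate_background_weights(net, seed = 12))
  net <- apply_class_matrix(net, s2$class_matrix)
  s3 <- suppressWarnings(
    calibrate_recurrent_weights(net, mv, rates = rates, seed = 13))
  net <- apply_class_matrix(net, s3$class_matrix)
  list(net = net, stage1 = s1, stage2 = s2, stage3 = s3)
})

# Eight-direction TF = 2 Hz grating battery on the calibrated reduced
# network: spikes and accumulators per direction plus per-cell tuning.
tf2_battery <- function() memo("tf2_battery", function() {
  net <- calibrated_smallnet()$net
  dirs <- seq(0, 315, by = 45)
  res <- lapply(dirs, function(d) {
    mv <- make_grating(d, 0.05, 2, 80, 2500)
    out <- run_stimulus(net, mv, n_trials = 2, seed = 100 + d)
    out$rates <- NULL
    out
  })
  rate_mat <- sapply(res, function(r) {
    sel <- r$spikes$time >= 500
    tabulate(match(r$spikes$cell_id[sel], net$cells$cell_id),
             nbins = nrow(net$cells)) / 2 / 2.5
  })
  list(net = net, dirs = dirs, res = res, rate_mat = rate_mat,
       pref_idx = apply(rate_mat, 1, which.max))
})

variant_geometry <- function() list(core_radius = 125, shell_radius = 200, height = 100)

# The four rule variants at a smaller matched-density scale (125/200 um),
# each carried through the same calibration protocol; returns their mean
# excitatory OSI from an 8-direction battery, the calibrated LL network, and
# the direction-0 LGN rate matrix (reused by the synapse-model comparison).
variant_osi <- function() memo("variant_osi", function() {
  geom <- variant_geometry()
  mv <- make_grating(0, 0.05, 4, 80, 1000)
  mean_osi <- c(LL = NA_real_, RL = NA_real_, LR = NA_real_, RR = NA_real_)
  net_ll <- NULL; ff_cm <- NULL; rates_train <- NULL
  dirs <- seq(0, 315, by = 45)
  rates_dir <- NULL
  for (rule in names(mean_osi)) {
    net <- build_network(rule, seed = 7, geometry = geom, lgn_margin = 18)
    if (is.null(ff_cm)) {
      rates_train <- filter_bank_response(net$lgn_bank, mv)
      s1 <- suppressWarnings(calibrate_lgn_weights(net, mv, rates = rates_train, seed = 11))
      net <- apply_class_matrix(net, s1$class_matrix)
      s2 <- suppressWarnings(calibrate_background_weights(net, seed = 12))
      ff_cm <- s2$class_matrix
      rates_dir <- lapply(dirs, function(d)
        filter_bank_response(net$lgn_bank, make_grating(d, 0.05, 4, 80, 1500)))
    }
    net <- apply_class_matrix(net, ff_cm)
    s3 <- suppressWarnings(
      calibrate_recurrent_weights(net, mv, rates = rates_train, seed = 13))
    net <- apply_class_matrix(net, s3$class_matrix)
    E <- net$cells$ei_class == "E"
    rm_ <- sapply(seq_along(dirs), function(i) {
      out <- run_stimulus(net, NULL, n_trials = 1, seed = 200 + i,
                          t_stop = 2000, rates = rates_dir[[i]])
      sel <- out$spikes$time >= 500
      tabulate(match(out$spikes$cell_id[sel], net$cells$cell_id),
               nbins = nrow(net$cells)) / 1.5
    })
    resp <- apply(rm_, 1, max) >= 1
    mean_osi[rule] <- mean(apply(rm_[E & resp, , drop = FALSE], 1,
                                 function(f) osi(f, dirs)), na.rm = TRUE)
    if (rule == "LL") net_ll <- net
  }
  list(mean_osi = mean_osi, net_ll = net_ll)
})

# Kinetic-synapse variant of the LL network at the 125/200 um scale, taken
# through the same calibration protocol.
calibrated_kinetic <- function() memo("kinetic", function() {
  geom <- variant_geometry()
  net <- build_network("LL", seed = 7, geometry = geom, lgn_margin = 18,
                       synapse_model = "kinetic")
  mv <- make_grating(0, 0.05, 4, 80, 1000)
  rates <- filter_bank_response(net$lgn_bank, mv)
  s1 <- suppressWarnings(calibrate_lgn_weights(net, mv, rates = rates, seed = 11))
  net <- apply_class_matrix(net, s1$class_matrix)
  s2 <- suppressWarnings(calibrate_background_weights(net, seed = 12))
  net <- apply_class_matrix(net, s2$class_matrix)
  s3 <- suppressWarnings(
    calibrate_recurrent_weights(net, mv, rates = rates, seed = 13))
  apply_class_matrix(net, s3$class_matrix)
})
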