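test_that("threshold, reset and refractory contracts hold for single neurons", {
  cells <- mk_cells(1)
  # suprathreshold event: exactly one spike at arrival (+delay)
  out <- simulate_network(cells, NULL,
                          list(single_event_input(10, weight = 0.6, n_syn = 2L)),
                          t_stop = 50, analysis_start = 0)
  expect_equal(out$spikes$time, 11)
  # no input, no output
  out0 <- simulate_network(cells, NULL, list(), t_stop = 50)
  expect_equal(nrow(out0$spikes), 0L)
  # two suprathreshold inputs 2 ms apart: one spike (3 ms refractory)
  out2 <- simulate_network(cells, NULL,
                           list(single_event_input(c(10, 12), weight = 1.2)),
                           t_stop = 50, analysis_start = 0)
  expect_equal(nrow(out2$spikes), 1L)
  expect_equal(out2$audit$n_discarded, 1)
  # 3 ms apart: two spikes
  out3 <- simulate_network(cells, NULL,
                           list(single_event_input(c(10, 13), weight = 1.2)),
                           t_stop = 50, analysis_start = 0)
  expect_equal(nrow(out3$spikes), 2L)
})

test_that("subthreshold activation decays with the membrane constant", {
  cells <- mk_cells(1)
  # two 0.55 events: together suprathreshold only if close in time
  for (gap in c(1, 50)) {
    out <- simulate_network(cells, NULL,
                            list(single_event_input(c(10, 10 + gap), weight = 0.55)),
                            t_stop = 100, analysis_start = 0)
    expect_equal(nrow(out$spikes), if (gap == 1) 1L else 0L)
  }
})

test_that("kinetic state propagation matches the matrix-exponential oracle", {
  skip_if_not_installed("Matrix")
  params <- point_neuron_params("kinetic")
  inputs <- list(single_event_input(10, weight = 0.3, label = "e"),
                 single_event_input(20, weight = -0.2, label = "i"))
  for (ei in c("E", "I")) {
    cells <- mk_cells(1, ei = ei)
    out <- simulate_network(cells, NULL, inputs, params = params, t_stop = 60,
                            analysis_start = 0)
    kin <- params$kinetic[[ei]]
    tau_m <- unname(params$tau_m[ei])
    M <- rbind(c(-1 / tau_m, 1, -1, 1),
               c(0, -1 / kin["tau_e"], 0, 0),
               c(0, 0, -1 / kin["tau_i1"], 0),
               c(0, 0, 0, -1 / kin["tau_i2"]))
    t1 <- kin[["tau_i1"]]; t2 <- kin[["tau_i2"]]
    tp <- log(t2 / t1) * t1 * t2 / (t2 - t1)
    fi <- 1 / (exp(-tp / t2) - exp(-tp / t1))
    x <- c(0, 0, 0, 0)
    x <- as.vector(Matrix::expm(M * 11) %*% x); x[2] <- x[2] + 0.3
    x <- as.vector(Matrix::expm(M * 10) %*% x)
    x[3] <- x[3] + fi * (-0.2); x[4] <- x[4] + fi * (-0.2)
    x <- as.vector(Matrix::expm(M * (out$state_time - 21)) %*% x)
    got <- unlist(out$state[1, c("v", "e", "a", "b")])
    expect_lt(max(abs(got - x) / pmax(abs(x), 1e-9)), 1e-6)
  }
})

test_that("every cell's inter-spike intervals respect the refractory period", {
  pipe <- tf2_battery()
  sp <- pipe$res[[1]]$spikes
  isis <- unlist(lapply(split(sp$time, list(sp$cell_id, sp$trial), drop = TRUE),
                        function(t) diff(sort(t))))
  expect_gte(min(isis), 3 - 1e-9)
})

test_that("event accounting balances inputs, applications and discards", {
  # quiet tail ensures no recurrent events remain in flight at the end
  cells <- mk_cells(3, ei = c("E", "E", "I"))
  rec <- data.frame(src = c(0L, 0L, 1L), tgt = c(1L, 2L, 2L), n_syn = 3L,
                    weight = c(0.5, 0.5, -0.2), delay = 1)
  class(rec) <- c("connection_set", "data.frame")
  set.seed(30)
  drive <- external_input(
    data.frame(src = 0L, time = sort(runif(200, 5, 400))),
    data.frame(src = 0L, tgt = 0L, n_syn = 1L, weight = 1.1, delay = 1), "drive")
  out <- simulate_network(cells, rec, list(drive), t_stop = 600, analysis_start = 0)
  a <- out$audit
  expect_equal(a$n_applied + a$n_discarded, a$n_delivered)
  expect_equal(a$n_delivered, a$n_external_processed + a$n_scheduled_recurrent)
  expect_equal(a$n_external_processed, 200)
})

test_that("input accumulators sum applied excitatory weights by source", {
  cells <- mk_cells(1)
  lgn <- single_event_input(c(600, 700), weight = 0.2, n_syn = 3L, label = "LGN")
  bkg <- single_event_input(c(650, 720), weight = 0.1, n_syn = 2L, label = "BKG")
  out <- simulate_network(cells, NULL, list(lgn, bkg), t_stop = 1000)
  expect_equal(out$accum$lgn_exc, 2 * 0.2 * 3)
  expect_equal(out$accum$total_exc, 2 * 0.2 * 3 + 2 * 0.1 * 2)
  # events before analysis_start are not accumulated
  out2 <- simulate_network(cells, NULL,
                           list(single_event_input(100, 0.2, label = "LGN")),
                           t_stop = 1000)
  expect_equal(out2$accum$lgn_exc, 0)
  fr <- lgn_fraction(out$accum)
  expect_equal(fr$lgn_fraction, 1.2 / 1.6)
})

test_that("perturbations modify inputs as declared", {
  cells <- mk_cells(4, type = rep("Scnn1a", 4))
  cells$is_core <- TRUE
  lgn <- single_event_input(c(500, 900, 1200, 1500), weight = 0.1, label = "LGN")
  # LGN silencing removes spikes from onset on
  cut <- apply_perturbation(list(lgn), perturbation("silence_lgn", onset = 1000))
  expect_equal(cut[[1]]$spikes$time, c(500, 900))
  # zero fraction leaves inputs unchanged
  p0 <- perturbation("silence_population", "Scnn1a", fraction = 0)
  expect_identical(apply_perturbation(list(lgn), p0, cells, 2000, seed = 1),
                   list(lgn))
  # full fraction attaches one negative-weight 100 Hz source per cell
  p1 <- perturbation("silence_population", "Scnn1a", fraction = 1,
                     strength_pA = -100, weight_per_100pA = 0.4)
  mod <- apply_perturbation(list(lgn), p1, cells, 2000, seed = 1)
  expect_length(mod, 2)
  sil <- mod[[2]]
  expect_equal(sort(sil$edges$tgt), 0:3)
  expect_true(all(sil$edges$weight == -0.4))
  n100 <- nrow(sil$spikes) / 4 / 2           # per cell per second
  expect_lt(abs(n100 - 100), 40)
  # strength scales linearly: -50 pA weight is half the -100 pA weight
  p50 <- perturbation("silence_population", "Scnn1a", strength_pA = -50,
                      weight_per_100pA = 0.4)
  mod50 <- apply_perturbation(list(lgn), p50, cells, 2000, seed = 1)
  expect_equal(mod50[[2]]$edges$weight, rep(-0.2, 4))
  expect_error(apply_perturbation(list(lgn),
                                  perturbation("silence_population", "Nope"),
                                  cells, 2000), "target type")
})

test_that("a calibrated silencing weight suppresses the benchmark cell", {
  w <- calibrate_silencing_weight(drive_rate = 1500, drive_weight = 0.05,
                                  target_fraction = 0.2, t_stop = 8000, seed = 2)
  expect_gt(w, 0)
  expect_lt(w, 1)
})
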