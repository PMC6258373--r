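test_that("connection probability follows the distance and orientation rules", {
  expect_equal(connection_probability("E", "E", 0, 0, "LL"), 0.34)
  expect_equal(connection_probability("E", "E", 300, 0, "LL"), 0)
  expect_equal(connection_probability("E", "E", 0, 90, "LL"), 0.17)
  expect_equal(connection_probability("E", "E", 150, 0, "LL"), 0.17)
  expect_equal(connection_probability("E", "I", 0, 0, "LL"), 0.26)
  expect_equal(connection_probability("E", "E", 0, 90, "RL"), 0.255)
  expect_equal(connection_probability("E", "I", 0, 0, "RR"), 0.255)
  expect_equal(connection_probability("I", "E", 0, 0, "LL"), 1)
  expect_equal(connection_probability("I", "I", 160, 0, "LL"), 0)
  expect_equal(connection_probability("I", "E", 80, 45, "LL"), 0.5)
  expect_error(connection_probability("E", "E", -1, 0, "LL"), "distance")
  expect_error(connection_probability("E", "E", 0, 91, "LL"), "delta_ori")
})

test_that("forced p = 1 toy layout yields the complete digraph", {
  # 100 co-located inhibitory cells: p = 1 for every ordered pair
  cells <- mk_cells(100, ei = rep("I", 100))
  conns <- build_recurrent(cells, "LL", seed = 1)
  expect_equal(nrow(conns), 9900L)
  expect_false(any(conns$src == conns$tgt))
  expect_false(any(duplicated(paste(conns$src, conns$tgt))))
  expect_true(all(conns$n_syn >= 3 & conns$n_syn <= 7))
  expect_true(all(sort(unique(conns$n_syn)) == 3:7))
})

test_that("cells beyond the cutoff are never connected", {
  cells <- mk_cells(2, x = c(0, 1000))
  conns <- build_recurrent(cells, "LL", seed = 1)
  expect_equal(nrow(conns), 0L)
})

test_that("builds are reproducible by seed", {
  cells <- assign_tuning(place_cells(c(Scnn1a = 300, PV1 = 60), seed = 9))
  a <- build_recurrent(cells, "LL", seed = 3)
  b <- build_recurrent(cells, "LL", seed = 3)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("analytic expected degree matches Monte-Carlo rebuilds on a toy net", {
  set.seed(11)
  n <- 25
  cells <- mk_cells(n, ei = sample(c("E", "I"), n, TRUE),
                    x = runif(n, 0, 250), y = runif(n, 0, 250),
                    theta = runif(n, 0, 360))
  # analytic expected out-degree per cell
  exp_out <- sapply(seq_len(n), function(i) {
    j <- setdiff(seq_len(n), i)
    d <- sqrt((cells$x[i] - cells$x[j])^2 + (cells$y[i] - cells$y[j])^2)
    dori <- fold_delta_ori(cells$theta_assigned[i] - cells$theta_assigned[j])
    sum(connection_probability(cells$ei_class[i], cells$ei_class[j], d, dori, "LL"))
  })
  reps <- 1200
  out_sum <- numeric(n)
  for (r in seq_len(reps)) {
    conns <- build_recurrent(cells, "LL", seed = 10000 + r)
    out_sum <- out_sum + tabulate(conns$src + 1L, nbins = n)
  }
  mc_mean <- out_sum / reps
  se <- sqrt(pmax(exp_out, 0.05)) / sqrt(reps)   # binomial-sum variance bound
  expect_true(all(abs(mc_mean - exp_out) <= 3 * se + 0.02))
})

test_that("weights carry class sign and the like-to-like factor", {
  cells <- mk_cells(4, ei = c("E", "E", "E", "I"), x = c(0, 1, 2, 3),
                    theta = c(0, 50, 90, 10))
  conns <- data.frame(src = c(0L, 0L, 0L, 3L), tgt = c(1L, 2L, 3L, 0L),
                      n_syn = 5L, weight = NA_real_, delay = 1)
  class(conns) <- c("connection_set", "data.frame")
  cm <- default_class_matrix()
  w <- assign_weights(conns, cm, cells, rule = "LL")
  base <- cm["E", "LIF_exc"]
  expect_equal(w$weight[1], base * exp(-50^2 / 50^2))      # F_w = 1/e
  expect_equal(w$weight[1] / base, exp(-1), tolerance = 1e-12)
  expect_equal(w$weight[2], base * exp(-90^2 / 50^2))
  expect_equal(w$weight[3], cm["E", "LIF_inh"])            # E->I: no F_w
  expect_lt(w$weight[4], 0)                                # I source negative
  # RR rule leaves E->E weights at base
  wr <- assign_weights(conns, cm, cells, rule = "RR")
  expect_equal(wr$weight[1], base)
  expect_equal(wr$weight[2], base)
  # F_w at zero orientation difference is 1
  cells0 <- cells; cells0$theta_assigned <- 0
  w0 <- assign_weights(conns, cm, cells0, rule = "LL")
  expect_equal(w0$weight[1], base)
  expect_error(assign_weights(conns, cm[, 1:2], cells, rule = "LL"), "target types")
})

test_that("degree summary reports forced and empty cases", {
  cells <- mk_cells(10, ei = rep("I", 10))
  conns <- build_recurrent(cells, "LL", seed = 1)   # co-located: complete digraph
  ds <- degree_summary(conns, cells)
  expect_true(all(ds$per_cell$in_deg == 9))
  expect_true(all(ds$per_cell$out_deg == 9))
  empty <- conns[0, ]
  ds0 <- degree_summary(empty, cells)
  expect_true(all(ds0$per_cell$in_deg == 0))
  expect_equal(ds0$by_class$syn_in_mean, 0)
})

test_that("seed change alters edges but not degree statistics materially", {
  cells <- assign_tuning(place_cells(scaled_census(
    list(core_radius = 150, shell_radius = 250, height = 100)),
    list(core_radius = 150, shell_radius = 250, height = 100), seed = 21))
  a <- build_recurrent(cells, "LL", seed = 1)
  b <- build_recurrent(cells, "LL", seed = 2)
  expect_false(identical(a$src, b$src))
  da <- degree_summary(a, cells, core_only = TRUE)$by_class
  db <- degree_summary(b, cells, core_only = TRUE)$by_class
  # means should agree within ~3 standard errors of the per-cell spread
  n <- da$n
  tol <- 3 * (da$in_deg_sd / sqrt(n) + db$in_deg_sd / sqrt(n))
  expect_true(all(abs(da$in_deg_mean - db$in_deg_mean) <= tol))
})
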