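test_that("spontaneous rates use the second half of gray trials", {
  # 1 spike in 20 windows: the minimum resolvable nonzero rate, 0.1 Hz
  sp <- data.frame(cell_id = 0L, time = 700, trial = 3L)
  expect_equal(unname(spont_rate(sp, 0L, n_trials = 20)), 0.1)
  # no spikes -> 0
  none <- data.frame(cell_id = integer(0), time = numeric(0), trial = integer(0))
  expect_equal(unname(spont_rate(none, 0L, n_trials = 20)), 0)
  # exactly 1 spike per 500 ms window -> 2 Hz
  sp2 <- data.frame(cell_id = 0L, time = rep(750, 20), trial = 1:20)
  expect_equal(unname(spont_rate(sp2, 0L, n_trials = 20)), 2)
  # spikes in the first 500 ms are ignored
  sp3 <- data.frame(cell_id = 0L, time = c(100, 499, 600), trial = 1L)
  expect_equal(unname(spont_rate(sp3, 0L, n_trials = 20)), 0.1)
  expect_error(spont_rate(data.frame(cell_id = 0L, time = 1), 0L), "trial")
})

test_that("OSI follows the orientation-doubled resultant", {
  expect_equal(osi(rep(3, 8)), 0)                       # full cancellation
  expect_equal(osi(c(5, 0, 0, 0, 0, 0, 0, 0)), 1)       # single direction
  # complex-sum oracle cases: the alternating curve cancels exactly under
  # orientation doubling; breaking the symmetry leaves resultant 2 of mass 14
  expect_equal(osi(c(2, 1, 2, 1, 2, 1, 2, 1)), 0, tolerance = 1e-12)
  expect_equal(osi(c(3, 1, 2, 1, 3, 1, 2, 1)), 2 / 14, tolerance = 1e-12)
  expect_true(is.na(osi(rep(0, 8))))
  # invariant to uniform rate scaling and common rotation
  set.seed(1); f2 <- runif(8)
  expect_equal(osi(f2), osi(7.3 * f2))
  expect_equal(osi(f2), osi(f2, seq(0, 315, by = 45) + 30))
})

test_that("DSI compares preferred and opposite directions", {
  expect_equal(dsi(c(3, 1, 0, 0, 1, 0, 0, 0)), 0.5)     # (3-1)/(3+1)
  expect_equal(dsi(c(2, 0, 0, 0, 2, 0, 0, 0)), 0)       # f_pref = f_null
  expect_equal(dsi(c(4, 1, 1, 1, 0, 1, 1, 1)), 1)       # f_null = 0
  expect_true(is.na(dsi(rep(0, 8))))
  # rate-scaling invariance
  f <- c(5, 2, 1, 0.5, 2, 1, 0.2, 3)
  expect_equal(dsi(f), dsi(3.1 * f))
})

test_that("F0/F1 conventions recover sinusoid parameters", {
  tt <- seq(0, 999, by = 1) / 1000
  sig <- 5 + 2 * sin(2 * pi * 4 * tt)
  expect_equal(f0_f1(sig, 4, "fourier_abs"), c(F0 = 5, F1 = 2), tolerance = 1e-6)
  expect_equal(f0_f1(sig, 4, "fit_2b"), c(F0 = 5, F1 = 4), tolerance = 1e-6)
  expect_equal(f0_f1(rep(3, 500), 4)[["F1"]], 0)
  # phase does not matter
  sig2 <- 5 + 2 * sin(2 * pi * 4 * tt + 1.1)
  expect_equal(f0_f1(sig2, 4)[["F1"]], 2, tolerance = 1e-6)
  expect_error(f0_f1(sig[1:100], 4), "cycle")
})

test_that("lifetime sparsity matches its closed form and orderings", {
  expect_equal(sparsity(c(1, 3)), 0.4)                  # worked example
  expect_equal(sparsity(rep(2, 10)), 0)                 # uniform response
  expect_equal(sparsity(c(0, 0, 0, 7)), 1)              # single active bin
  expect_true(is.na(sparsity(rep(0, 5))))
  # scale invariance; concentration increases sparsity
  f <- c(1, 2, 3, 4)
  expect_equal(sparsity(f), sparsity(10 * f))
  expect_lt(sparsity(c(2, 2, 1, 1)), sparsity(c(3, 2, 1, 0)))
  expect_error(sparsity(3), "bins")
})

test_that("CV of ISIs is reported squared (with an unsquared option)", {
  reg <- data.frame(time = seq(0, 1000, by = 50), trial = 1)
  expect_equal(cv_isi(reg), 0)
  expect_true(is.na(cv_isi(data.frame(time = c(1, 2), trial = 1))))
  irr <- data.frame(time = c(0, 10, 40, 45, 100), trial = 1)
  isis <- diff(irr$time)
  expect_equal(cv_isi(irr), (sd(isis) / mean(isis))^2)
  expect_equal(cv_isi(irr, squared = FALSE), sd(isis) / mean(isis))
})

test_that("Fano factor is near 1 for homogeneous Poisson trains", {
  set.seed(42)
  trains <- lapply(1:40, function(tr) {
    n <- rpois(1, 20 * 10)                   # 20 Hz for 10 s
    data.frame(time = sort(runif(n, 0, 10000)), trial = tr)
  })
  sp <- do.call(rbind, trains)
  f <- fano_factor(sp, trials = 1:40, t_range = c(0, 10000))
  expect_lt(abs(f - 1), 0.2)
})

test_that("signal and noise correlations behave on constructed counts", {
  a <- matrix(rep(c(5, 1, 3, 2, 8, 1, 0, 4), 3), nrow = 8)
  expect_equal(unname(pair_correlations(a, a)["signal"]), 1)
  set.seed(2)
  b <- a + matrix(rnorm(24, sd = 0.1), nrow = 8)
  expect_gt(pair_correlations(a + matrix(rnorm(24, sd = .1), 8), b)["signal"], 0.9)
  # independent noise: noise correlation near zero
  x <- matrix(rnorm(800), 8); y <- matrix(rnorm(800), 8)
  expect_lt(abs(pair_correlations(x, y)["noise"]), 0.15)
})

test_that("OMI reflects silencing and no-change cases", {
  expect_equal(omi(0, 4), -1)
  expect_equal(omi(3, 3), 0)
  expect_equal(omi(3, 1), 0.5)
  expect_true(is.na(omi(0, 0)))
  expect_equal(omi(c(0, 2), c(4, 2)), c(-1, 0))
})

test_that("skewness is the third standardized moment", {
  expect_equal(skewness(c(-2, -1, 0, 1, 2)), 0)
  expect_equal(skewness(c(0, 0, 0, 9)), 2 / sqrt(3), tolerance = 1e-12)
  expect_true(is.na(skewness(rep(4, 5))))
  expect_true(is.na(skewness(c(1, 2))))
  set.seed(3)
  expect_lt(abs(skewness(rnorm(20000))), 0.06)
})

test_that("MUA spectra find imposed rhythms and obey weight scaling", {
  cells <- mk_cells(20, x = runif(20, -200, 200), y = runif(20, -200, 200))
  # common 20 Hz periodic firing
  sp <- do.call(rbind, lapply(0:19, function(i)
    data.frame(cell_id = i, time = seq(25, 2000, by = 50), trial = 1)))
  spec <- mua_spectrum(sp, cells, t_range = c(0, 2000))
  expect_equal(spec$freq[which.max(spec$power)], 20)
  # no spikes: flat zero spectrum
  spec0 <- mua_spectrum(sp[0, ], cells, t_range = c(0, 2000))
  expect_true(all(spec0$power == 0))
  # moving all cells to half the distance doubles weights, quadrupling power
  cells2 <- cells; cells2$x <- cells$x / 2; cells2$y <- cells$y / 2
  spec2 <- mua_spectrum(sp, cells2, t_range = c(0, 2000))
  expect_equal(spec2$power[-1], 4 * spec$power[-1], tolerance = 1e-6)
})

test_that("LGN convergence groups pairs by recurrent coupling", {
  lgn <- data.frame(src = c(1L, 2L, 3L, 1L, 2L, 3L, 7L, 8L),
                    tgt = c(0L, 0L, 0L, 1L, 1L, 1L, 2L, 2L))
  rec <- data.frame(src = c(0L, 1L, 0L), tgt = c(1L, 0L, 2L))
  pairs <- rbind(c(0, 1), c(0, 2), c(1, 2))
  cv <- lgn_convergence(pairs, lgn, rec)
  expect_equal(cv$convergence[1], 3 / 6)        # identical source sets: max 0.5
  expect_equal(cv$convergence[2], 0)            # disjoint source sets
  expect_equal(cv$coupling, c("reciprocal", "one_way", "none"))
})

test_that("amplification fits recover exact and noisy linear relations", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(unname(amplification_fit(x, 2 * x)), c(2, 0, 1))
  expect_equal(unname(amplification_fit(x, x)), c(1, 0, 1))
  set.seed(4)
  xx <- runif(200, 0, 10)
  fit <- amplification_fit(xx, 2 * xx + rnorm(200, sd = 0.5))
  expect_lt(abs(fit["A"] - 2), 0.1)
  expect_true(all(is.na(amplification_fit(rep(1, 5), x))))
})

test_that("flash PSTH recovers injected peak latencies", {
  set.seed(5)
  onset <- 600
  mk <- function(mu, n) rnorm(n, mu, 8)
  sp <- data.frame(time = c(mk(onset + 60, 4000), mk(onset + 160, 2000)), trial = 1)
  out <- flash_psth(sp, n_cells = 100, n_trials = 1, t_range = c(0, 1200),
                    flash_onset = onset)
  expect_equal(nrow(out$peaks), 2L)
  expect_lt(abs(out$peaks$latency[1] - 60), 6)
  expect_lt(abs(out$peaks$latency[2] - 160), 6)
  expect_gt(out$peaks$magnitude[1], out$peaks$magnitude[2])
  # flat record: no peaks
  flat <- flash_psth(sp[0, ], 100, 1, c(0, 1200), onset)
  expect_equal(nrow(flat$peaks), 0L)
})

test_that("bounded metrics stay in range on random spike structures", {
  set.seed(6)
  for (rep in 1:20) {
    f <- rexp(8) * sample(c(0.1, 1, 10), 1)
    expect_true(osi(f) >= 0 && osi(f) <= 1 + 1e-12)
    expect_true(dsi(f) >= -1e-12 && dsi(f) <= 1 + 1e-12)
    s <- sparsity(rexp(30))
    expect_true(s >= 0 && s <= 1 + 1e-12)
    o <- omi(rexp(1), rexp(1))
    expect_true(o >= -1 && o <= 1)
  }
})

test_that("tuning curves and Rmax follow the trial-averaged convention", {
  # two conditions x 2 trials for one cell: direction 90 strongest
  grid <- expand.grid(direction = c(0, 90), sf = 0.05, tf = c(2, 4))
  mk <- function(d, tf, n) if (n == 0) NULL else
    data.frame(cell_id = 0L, time = seq(600, 2900, length.out = n), trial = 1L,
               direction = d, sf = 0.05, tf = tf)
  sp <- rbind(mk(0, 2, 5), mk(0, 4, 10), mk(90, 2, 40), mk(90, 4, 20),
              # spikes in the gray prefix must be discarded
              data.frame(cell_id = 0L, time = 100, trial = 1L,
                         direction = 0, sf = 0.05, tf = 2))
  tc <- tuning_and_rmax(sp, 0L, n_trials = 2, window = c(500, 3000))
  expect_true(tc$defined)
  expect_equal(tc$pref_direction, 90)
  expect_equal(tc$pref_tf, 2)                       # strongest at 90 deg, TF 2
  expect_equal(tc$rmax, 40 / 2 / 2.5)               # max condition rate
  expect_equal(unname(tc$by_direction["0"]), (5 + 10) / 2 / 2 / 2.5)
  # single condition: Rmax is that condition's rate
  one <- mk(0, 2, 8)
  tc1 <- tuning_and_rmax(one, 0L, n_trials = 2, window = c(500, 3000))
  expect_equal(tc1$rmax, 8 / 2 / 2.5)
  # silent cell: undefined flag
  tc0 <- tuning_and_rmax(sp[0, ], 0L, n_trials = 2)
  expect_false(tc0$defined)
  expect_equal(tc0$rmax, 0)
})
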