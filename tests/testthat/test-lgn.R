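test_that("temporal kernel has its analytic zeros and zero integral", {
  k <- 0.04
  expect_equal(temporal_kernel(k, 0), 0)
  expect_equal(temporal_kernel(k, sqrt(6) / k), 0)
  expect_lt(abs(integrate(function(t) temporal_kernel(k, t), 0, Inf)$value), 1e-8)
  # bin-integrated weights used in convolution preserve the zero integral
  for (kk in c(0.032, 0.045, 0.056))
    expect_lt(abs(sum(layer4sim:::temporal_kernel_bins(kk))), 1e-4)
  expect_error(temporal_kernel(-1, 1), "k")
  expect_error(temporal_kernel(0.04, -1), "t")
})

test_that("spatial kernel matches center-surround closed forms", {
  sub <- list(x0 = 1, y0 = -2, sigma_c = 2.5, A_c = 3)
  expect_equal(spatial_kernel(sub, 1, -2), 3 * 5 / 6)      # (5/6) A_c at center
  expect_lt(abs(spatial_kernel(sub, 1 + 30, -2)), 1e-6)    # far field ~ 0
  int2d <- integrate(Vectorize(function(r)
    2 * pi * r * spatial_kernel(list(x0 = 0, y0 = 0, sigma_c = 2.5, A_c = 3),
                                r, 0)), 0, 80)$value
  expect_equal(int2d, 2 * pi / 3 * 3 * 2.5^2, tolerance = 1e-6)
})

test_that("a static gray movie returns the baseline rate", {
  f <- mk_bank(R0 = 3.2)
  mv <- make_gray(1500, width = 48, height = 48)
  r <- filter_response(f, mv)
  expect_equal(r, rep(3.2, 1500), tolerance = 1e-3)
  rb <- filter_bank_response(f, mv)
  expect_equal(rb[, 1], r, tolerance = 1e-10)
  short <- make_gray(500, width = 48, height = 48)
  expect_error(filter_response(f, short, gray_override = 600), "500")
})

test_that("single-filter and bank responses agree on gratings", {
  f <- mk_bank(ftype = "ON_OFF", dx = 2, dy = 1.5, R0 = 4)
  mv <- make_grating(30, 0.05, 4, 80, 700, width = 48, height = 48)
  r1 <- filter_response(f, mv)
  r2 <- filter_bank_response(f, mv)[, 1]
  # the two paths use direct vs FFT convolution; agreement to FFT roundoff
  expect_equal(r1, r2, tolerance = 1e-6)
  expect_true(all(r1 >= 0))
})

test_that("ON and OFF filters are luminance mirrors in their linear range", {
  on <- mk_bank("ON", A_c = 2e-5, R0 = 100)
  off <- mk_bank("OFF", A_c = 2e-5, R0 = 100)
  mv <- make_grating(45, 0.05, 4, 80, 800, width = 48, height = 48)
  ron <- filter_response(on, mv)
  roff <- filter_response(off, mv)
  # S and 255 - S cancel in the linear response when neither filter rectifies
  expect_equal(ron + roff, rep(200, length(ron)), tolerance = 1e-4)
})

test_that("Poisson spike generation matches its rate contract", {
  expect_length(generate_spikes(rep(0, 1000), seed = 1), 0)
  n <- length(generate_spikes(rep(10, 100000), seed = 2))   # 10 Hz x 100 s
  expect_lt(abs(n - 1000), 4 * sqrt(1000))
  a <- generate_spikes(rep(50, 5000), seed = 3)
  b <- generate_spikes(rep(50, 5000), seed = 4)
  expect_false(identical(a, b))
  expect_error(generate_spikes(c(-1, 2)), "nonnegative")
})

test_that("retinotopy maps cortex to visual field linearly", {
  expect_equal(unname(retinotopy_map(0, 0)), cbind(0, 0), ignore_attr = TRUE)
  expect_equal(retinotopy_map(0.5, 0)[1, ], c(azimuth = 60, elevation = 0))
  expect_equal(retinotopy_map(0, -0.2)[1, ], c(azimuth = 0, elevation = -10))
})

test_that("the default bank has 9,000 filters inside the field", {
  bank <- full_build()$bank
  expect_equal(nrow(bank), 9000L)
  expect_equal(as.integer(table(bank$ftype)), rep(3000L, 3))
  expect_true(all(abs(bank$x0) <= 65 & abs(bank$y0) <= 45))
  onoff <- bank[bank$ftype == "ON_OFF", ]
  expect_true(all(sqrt(onoff$dx^2 + onoff$dy^2) > 0))      # displaced subfields
  expect_true(all(bank$sigma_c > 0 & bank$A_c > 0 & bank$k > 0 & bank$R0 > 0))
})

test_that("lasso wiring respects caps, reach, and synapse counts", {
  fb <- full_build()
  ff <- fb$ff
  expect_true(all(ff$n_syn == 30L))
  nf <- tabulate(ff$tgt + 1L, nbins = nrow(fb$cells))
  E <- fb$cells$ei_class == "E"
  expect_lte(max(nf[E]), 24L)
  expect_lte(max(nf[!E]), 45L)
  # a filter far from a cell's mapped position is never selected
  pos <- retinotopy_map(fb$cells$x / 1000, fb$cells$y / 1000)
  idx <- match(ff$tgt, fb$cells$cell_id)
  fidx <- match(ff$src, fb$bank$filter_id)
  dist <- sqrt((fb$bank$x0[fidx] - pos[idx, 1])^2 +
                 (fb$bank$y0[fidx] - pos[idx, 2])^2)
  expect_lt(max(dist), 30)   # all selected filters lie within lasso reach
})

test_that("calibrated parameter ranges reproduce the SF/TF targets per filter", {
  pars <- suppressWarnings(calibrate_filter_params())
  expect_true(pars$sigma_c[1] < pars$sigma_c[2])
  expect_true(pars$k[1] < pars$k[2])
  # endpoint filters prefer the targets on the battery grids
  sfg <- c(0.025, 0.05, 0.1, 0.2, 0.4, 0.8)
  tfg <- c(1, 2, 4, 8, 15)
  for (sig in pars$sigma_c) {
    f <- mk_bank(sigma_c = sig, k = mean(pars$k), A_c = mean(pars$A_c))
    f0 <- vapply(sfg, function(sf) {
      mv <- suppressWarnings(make_grating(0, sf, 4, 80, 1500, width = 64, height = 64))
      f0_f1(filter_response(f, mv)[-(1:500)], 4)[["F0"]]
    }, 0.0)
    expect_equal(sfg[which.max(f0)], 0.05)
  }
  for (kk in pars$k) {
    f <- mk_bank(sigma_c = mean(pars$sigma_c), k = kk, A_c = mean(pars$A_c))
    f0 <- vapply(tfg, function(tf) {
      mv <- make_grating(0, 0.05, tf, 80, 2000, width = 64, height = 64)
      f0_f1(filter_response(f, mv)[-(1:500)], tf)[["F0"]]
    }, 0.0)
    expect_equal(tfg[which.max(f0)], 4)
  }
  # doubling A_c doubles the pre-rectification linear response
  f1 <- mk_bank(A_c = 1e-5, R0 = 100)
  f2 <- mk_bank(A_c = 2e-5, R0 = 100)
  mv <- make_grating(0, 0.05, 4, 80, 700, width = 48, height = 48)
  l1 <- filter_response(f1, mv) - 100
  l2 <- filter_response(f2, mv) - 100
  expect_equal(l2, 2 * l1, tolerance = 1e-8)
})

test_that("single-subfield filters carry no F1 orientation bias; ON_OFF do", {
  dirs <- seq(0, 315, by = 45)
  on <- mk_bank("ON")
  onoff <- mk_bank("ON_OFF", dx = 2.5, dy = 0, R0 = 3)
  f1_of <- function(f) vapply(dirs, function(d) {
    mv <- make_grating(d, 0.05, 4, 80, 1000, width = 56, height = 56)
    f0_f1(filter_response(f, mv)[-(1:500)], 4)[["F1"]]
  }, 0.0)
  f1_on <- f1_of(on)
  f1_oo <- f1_of(onoff)
  # axially symmetric kernel: F1 equal across directions
  expect_lt(diff(range(f1_on)) / max(f1_on), 0.05)
  # displaced subfields: F1 strongly direction dependent
  expect_gt(diff(range(f1_oo)) / max(f1_oo), 0.3)
})
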