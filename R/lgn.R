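#' Temporal kernel of an LGN filter
#'
#' The biphasic transient kernel D_t(t) = k t exp(-k t) (1 - k^2 t^2 / 6),
#' which integrates to zero over \[0, Inf): a transient filter gives no
#' sustained response to a static scene.
#'
#' @param k Rate constant in 1/ms (positive).
#' @param t Time in ms (nonnegative), vectorized.
#' @return Kernel values.
#' @export
temporal_kernel <- function(k, t) {
  if (k <= 0) stop("k must be positive")
  if (any(t < 0)) stop("t must be nonnegative")
  k * t * exp(-k * t) * (1 - k^2 * t^2 / 6)
}

# Exact integrals of the temporal kernel over 1-ms bins (antiderivative in
# closed form), truncated once the pointwise kernel falls below tol of its
# peak and the remaining tail mass is negligible. Using bin integrals rather
# than point samples preserves the zero-integral property of the kernel on
# the discrete grid.
temporal_kernel_bins <- function(k, h = 1, tol = 1e-6) {
  antideriv <- function(t) {
    e <- exp(-k * t)
    f1 <- -e * (k * t + 1) / k
    f2 <- -(k^3 / 6) * e * (t^3 / k + 3 * t^2 / k^2 + 6 * t / k^3 + 6 / k^4)
    f1 - f2
  }
  tmax <- max(ceiling(30 / k / h) * h, 5 * h)
  edges <- seq(0, tmax, by = h)
  w <- diff(antideriv(edges))
  peak <- max(abs(w))
  keep <- max(which(abs(w) > tol * peak))
  w[seq_len(keep)]
}

#' Spatial kernel of a receptive subfield
#'
#' Center-surround difference of Gaussians with surround amplitude A_c/6 and
#' surround width 2 sigma_c:
#' D_S(x, y) = A_c exp(-r^2 / (2 sigma_c^2)) - (A_c/6) exp(-r^2 / (8 sigma_c^2)).
#'
#' @param subfield List with `x0`, `y0` (center, degrees), `sigma_c` (degrees),
#'   `A_c` (amplitude).
#' @param x,y Evaluation coordinates in degrees (vectorized together).
#' @return Kernel values.
#' @export
spatial_kernel <- function(subfield, x, y) {
  r2 <- (x - subfield$x0)^2 + (y - subfield$y0)^2
  sc2 <- subfield$sigma_c^2
  subfield$A_c * exp(-r2 / (2 * sc2)) - (subfield$A_c / 6) * exp(-r2 / (8 * sc2))
}

#' Default LGN filter parameter ranges
#'
#' Sampling ranges for the filter-bank kinetics. The sigma_c and k ranges are
#' those produced by [calibrate_filter_params()] for the default targets
#' (preferred SF 0.05 cpd, preferred TF 4 Hz); A_c is the calibrated amplitude
#' with the 10 percent sampling variation; R0 spans typical LGN spontaneous
#' rates.
#'
#' @return List of two-element ranges: `sigma_c` (deg), `k` (1/ms), `A_c`
#'   (amplitude units), `R0` (Hz), plus `onoff_sep_sigma`, the ON/OFF
#'   subfield separation in units of sigma_c.
#' @export
default_filter_params <- function() {
  list(sigma_c = c(1.8, 3.4), k = c(0.032, 0.056),
       A_c = c(0.9, 1.1) * 1.79e-4, R0 = c(1, 6), onoff_sep_sigma = 2)
}

#' Place the LGN filter bank in visual space
#'
#' Creates `n_per_type` filters of each of the three transient types (ON, OFF,
#' ON_OFF) with centers uniform over the visual field and kernel parameters
#' drawn uniformly from the calibrated ranges. ON_OFF filters get two
#' subfields displaced symmetrically about the center in a random direction.
#'
#' @param n_per_type Filters per type (default 3000, i.e. 9000 filters).
#' @param field Field extent c(width, height) in degrees, centered on 0.
#' @param seed Integer seed.
#' @param params Parameter ranges, see [default_filter_params()].
#' @return An `lgn_bank` data.frame: `filter_id` (0-based), `ftype`, `x0`,
#'   `y0`, `dx`, `dy` (half-offset of the ON subfield for ON_OFF filters;
#'   0 otherwise), `sigma_c`, `A_c`, `k`, `R0`.
#' @export
place_filters <- function(n_per_type = 3000, field = c(130, 90), seed = 1L,
                          params = default_filter_params()) {
  set.seed(seed)
  n <- 3L * n_per_type
  ftype <- rep(c("ON", "OFF", "ON_OFF"), each = n_per_type)
  sigma_c <- stats::runif(n, params$sigma_c[1], params$sigma_c[2])
  sep <- params$onoff_sep_sigma * sigma_c / 2        # half-separation
  ang <- stats::runif(n, 0, 2 * pi)
  onoff <- ftype == "ON_OFF"
  bank <- data.frame(
    filter_id = seq_len(n) - 1L,
    ftype = ftype,
    x0 = stats::runif(n, -field[1] / 2, field[1] / 2),
    y0 = stats::runif(n, -field[2] / 2, field[2] / 2),
    dx = ifelse(onoff, sep * cos(ang), 0),
    dy = ifelse(onoff, sep * sin(ang), 0),
    sigma_c = sigma_c,
    A_c = stats::runif(n, params$A_c[1], params$A_c[2]),
    k = stats::runif(n, params$k[1], params$k[2]),
    R0 = stats::runif(n, params$R0[1], params$R0[2]),
    stringsAsFactors = FALSE
  )
  attr(bank, "field") <- field
  attr(bank, "seed") <- seed
  class(bank) <- c("lgn_bank", "data.frame")
  bank
}

# One row per receptive subfield: filter row index, polarity (+1 ON / -1 OFF),
# center, kernel parameters.
bank_subfields <- function(bank) {
  one <- bank$ftype != "ON_OFF"
  a <- data.frame(row = which(one),
                  pol = ifelse(bank$ftype[one] == "ON", 1, -1),
                  cx = bank$x0[one], cy = bank$y0[one])
  two <- which(!one)
  b <- data.frame(row = rep(two, 2),
                  pol = rep(c(1, -1), each = length(two)),
                  cx = c(bank$x0[two] + bank$dx[two], bank$x0[two] - bank$dx[two]),
                  cy = c(bank$y0[two] + bank$dy[two], bank$y0[two] - bank$dy[two]))
  sub <- rbind(a, b)
  sub$sigma_c <- bank$sigma_c[sub$row]
  sub$A_c <- bank$A_c[sub$row]
  sub
}

# Spatial projection L_s(t) for a set of subfields against a movie, on the
# pixel grid with the kernel truncated at a 3*sigma_s box. Returns an
# nt x nsub matrix of ON-polarity projections (the OFF input 255 - S is an
# affine flip handled by the caller). Values include the pixel-area factor.
bank_spatial_project <- function(subfields, movie) {
  d <- dim(movie$frames)
  xs <- pixel_axis(d[1], movie$pixel_deg)
  ys <- pixel_axis(d[2], movie$pixel_deg)
  nsub <- nrow(subfields)
  x0 <- integer(nsub); y0 <- integer(nsub); wx <- integer(nsub); wy <- integer(nsub)
  kerns <- vector("list", nsub)
  for (s in seq_len(nsub)) {
    half <- 3 * 2 * subfields$sigma_c[s]             # 3 * sigma_s
    ix <- which(xs >= subfields$cx[s] - half & xs <= subfields$cx[s] + half)
    iy <- which(ys >= subfields$cy[s] - half & ys <= subfields$cy[s] + half)
    if (length(ix) == 0 || length(iy) == 0)
      stop("subfield kernel support does not overlap the movie frame")
    x0[s] <- ix[1] - 1L; y0[s] <- iy[1] - 1L
    wx[s] <- length(ix); wy[s] <- length(iy)
    sub <- list(x0 = subfields$cx[s], y0 = subfields$cy[s],
                sigma_c = subfields$sigma_c[s], A_c = subfields$A_c[s])
    kerns[[s]] <- spatial_kernel(sub, outer(xs[ix], rep(1, length(iy))),
                                 outer(rep(1, length(ix)), ys[iy])) * movie$pixel_deg^2
  }
  koff <- c(0L, cumsum(vapply(kerns, length, 1L)))[seq_len(nsub)]
  lgn_spatial_project_cpp(movie$frames, dim(movie$frames),
                          x0, y0, wx, wy, unlist(kerns), as.integer(koff))
}

# Causal temporal convolution of each column of ls (nt x m) with the
# bin-integrated temporal kernel for the given k values (one per column).
# The pre-movie past is padded with each column's first value.
bank_temporal_convolve <- function(ls, kvals) {
  nt <- nrow(ls); m <- ncol(ls)
  uk <- unique(kvals)
  bins <- lapply(uk, temporal_kernel_bins)
  maxlen <- max(vapply(bins, length, 1L))
  n2 <- stats::nextn(nt + 2 * maxlen, 2)
  out <- matrix(0, nt, m)
  for (ui in seq_along(uk)) {
    cols <- which(kvals == uk[ui])
    w <- bins[[ui]]; lk <- length(w)
    kf <- stats::fft(c(w, numeric(n2 - lk)))
    pad <- matrix(0, n2, length(cols))
    pad[seq_len(lk), ] <- rep(ls[1, cols, drop = FALSE], each = lk)  # past = first frame
    pad[lk + seq_len(nt), ] <- ls[, cols, drop = FALSE]
    conv <- Re(stats::mvfft(stats::mvfft(pad) * kf, inverse = TRUE)) / n2
    out[, cols] <- conv[lk + seq_len(nt), , drop = FALSE]
  }
  out
}

# Assemble firing rates from per-subfield linear responses.
# ls: nt x nsub ON-polarity projections; subfields as from bank_subfields().
bank_rates <- function(bank, subfields, ls_on, gray_override = 500) {
  nt <- nrow(ls_on)
  lt <- bank_temporal_convolve(ls_on, bank$k[subfields$row])
  lt <- sweep(lt, 2, subfields$pol, "*")             # OFF input 255 - S flips sign of L
  rates <- matrix(0, nt, nrow(bank))
  for (fi in seq_len(nrow(bank))) {
    scols <- which(subfields$row == fi)
    r0 <- bank$R0[fi]
    if (bank$ftype[fi] == "ON_OFF") {
      # summed subfield rates minus the shared baseline, clamped: a negative
      # rate (both subfields rectified to zero) cannot drive a Poisson process
      r <- pmax(pmax(r0 + lt[, scols[1]], 0) + pmax(r0 + lt[, scols[2]], 0) - r0, 0)
    } else {
      r <- pmax(r0 + lt[, scols[1]], 0)
    }
    if (gray_override > 0) r[seq_len(min(gray_override, nt))] <- r0
    rates[, fi] <- r
  }
  rates
}

#' Firing-rate response of the LGN filter bank to a movie
#'
#' Applies every filter's spatiotemporal kernel to the movie (space-then-time
#' separable convolution on the pixel grid), adds the baseline R0, rectifies,
#' combines ON/OFF subfields for two-subfield filters (sum of rectified
#' subfield rates minus the baseline), and overwrites the first 500 ms with R0
#' to suppress the stimulus-onset transient.
#'
#' @param bank An `lgn_bank` (or subset of its rows).
#' @param movie A `stimulus_movie`.
#' @param gray_override Length of the initial epoch forced to R0, in ms.
#' @return Matrix of rates in Hz, `nt` rows (1 ms steps) by `nrow(bank)` columns.
#' @export
filter_bank_response <- function(bank, movie, gray_override = 500) {
  if (dim(movie$frames)[3] < gray_override)
    stop("movie must be at least as long as the 500 ms gray-override epoch")
  sub <- bank_subfields(bank)
  ls <- bank_spatial_project(sub, movie)
  bank_rates(bank, sub, ls, gray_override)
}

#' Firing-rate response of a single LGN filter
#'
#' Reference single-filter path; equivalent to one column of
#' [filter_bank_response()] but computed with plain R convolutions.
#'
#' @param filter One row of an `lgn_bank`.
#' @param movie A `stimulus_movie`.
#' @param gray_override Length of the initial epoch forced to R0, in ms.
#' @return Numeric vector of rates in Hz at 1 ms resolution.
#' @export
filter_response <- function(filter, movie, gray_override = 500) {
  if (dim(movie$frames)[3] < gray_override)
    stop("movie must be at least as long as the 500 ms gray-override epoch")
  stopifnot(nrow(filter) == 1)
  sub <- bank_subfields(filter)
  d <- dim(movie$frames)
  xs <- pixel_axis(d[1], movie$pixel_deg)
  ys <- pixel_axis(d[2], movie$pixel_deg)
  w <- temporal_kernel_bins(filter$k)
  lt <- matrix(0, d[3], nrow(sub))
  for (s in seq_len(nrow(sub))) {
    half <- 3 * 2 * sub$sigma_c[s]
    ix <- which(xs >= sub$cx[s] - half & xs <= sub$cx[s] + half)
    iy <- which(ys >= sub$cy[s] - half & ys <= sub$cy[s] + half)
    kern <- spatial_kernel(list(x0 = sub$cx[s], y0 = sub$cy[s],
                                sigma_c = sub$sigma_c[s], A_c = sub$A_c[s]),
                           outer(xs[ix], rep(1, length(iy))),
                           outer(rep(1, length(ix)), ys[iy])) * movie$pixel_deg^2
    sig <- movie$frames[ix, iy, , drop = FALSE]
    if (sub$pol[s] < 0) sig <- 255 - sig
    dim(sig) <- c(length(ix) * length(iy), d[3])
    lsp <- as.vector(crossprod(matrix(kern, ncol = 1), sig))
    lk <- length(w)
    padded <- c(rep(lsp[1], lk), lsp)
    lt[, s] <- stats::filter(padded, w, method = "convolution", sides = 1)[lk + seq_len(d[3])]
  }
  r0 <- filter$R0
  r <- if (filter$ftype == "ON_OFF") {
    pmax(pmax(r0 + lt[, 1], 0) + pmax(r0 + lt[, 2], 0) - r0, 0)
  } else {
    pmax(r0 + lt[, 1], 0)
  }
  if (gray_override > 0) r[seq_len(min(gray_override, length(r)))] <- r0
  r
}

#' Sample a Poisson spike train from a rate series
#'
#' Inhomogeneous Poisson sampling at 1 ms resolution (one Bernoulli draw per
#' bin with p = rate * dt, the thinning equivalent at these rates).
#'
#' @param rate Nonnegative rate series in Hz at 1 ms steps.
#' @param seed Integer seed, or NULL to use the current RNG state.
#' @return Numeric vector of spike times in ms (bin centers).
#' @export
generate_spikes <- function(rate, seed = NULL) {
  if (any(rate < 0)) stop("rate must be nonnegative")
  if (!is.null(seed)) set.seed(seed)
  p <- pmin(rate / 1000, 1)
  which(stats::runif(length(p)) < p) - 0.5
}

#' Map cortical position to visual-field coordinates
#'
#' Linear retinotopy: 120 degrees of azimuth per mm of cortex in x and 50
#' degrees of elevation per mm in y, with the model center mapped to the
#' center of the visual field.
#'
#' @param x,y Cortical position in mm (the cell table is in um; divide by 1000).
#' @return Matrix with columns `azimuth`, `elevation` in degrees.
#' @export
retinotopy_map <- function(x, y) {
  cbind(azimuth = 120 * x, elevation = 50 * y)
}

#' Wire LGN filters to layer 4 cells through lasso subfields
#'
#' For each target cell, capture regions ("lassos") are placed around the
#' cell's retinotopic position, one per filter type. Inhibitory targets get
#' three concentric circles with diameters drawn from \[15, 20\] degrees.
#' Excitatory targets get a circular ON_OFF lasso plus ON and OFF ellipses
#' (minor radius \[3, 4\] deg, aspect ratio \[2.8, 3.0\]) whose centers are
#' separated by \[10, 11\] deg along the cell's assigned preferred
#' orientation, with minor axes along the center-connecting line; the ON_OFF
#' circle radius equals the ellipse minor radius. Candidate filters are those
#' whose receptive-subfield centers fall inside the matching lasso (for
#' two-subfield filters, either kernel center); ON_OFF candidates must also
#' have their own ON-OFF axis within 15 degrees (orientation difference) of
#' the cell's assigned orientation. A random subset up to the per-type cap
#' (8 for excitatory, 15 for inhibitory targets) is selected, each
#' contributing 30 synapses.
#'
#' @param filters An `lgn_bank`.
#' @param cells A tuned `cell_table`.
#' @param seed Integer seed.
#' @param cap_exc,cap_inh Per-type caps on selected filters.
#' @param n_syn_per_filter Synapses per selected filter.
#' @return A `connection_set` data.frame (`src` = filter_id, `tgt` = cell_id,
#'   `n_syn`, `weight` = NA, `delay`).
#' @export
wire_lgn_to_l4 <- function(filters, cells, seed = 1L, cap_exc = 8L, cap_inh = 15L,
                           n_syn_per_filter = 30L) {
  set.seed(seed)
  pos <- retinotopy_map(cells$x / 1000, cells$y / 1000)

  # spatial index of filters per type (bins of 5 deg)
  binsz <- 5
  types <- c("ON", "OFF", "ON_OFF")
  index <- lapply(types, function(ty) {
    idx <- which(filters$ftype == ty)
    bx <- floor(filters$x0[idx] / binsz); by <- floor(filters$y0[idx] / binsz)
    key <- paste(bx, by)
    list(idx = split(idx, key))
  })
  names(index) <- types
  lookup <- function(ty, xmin, xmax, ymin, ymax) {
    keys <- as.vector(outer(floor(xmin / binsz):floor(xmax / binsz),
                            floor(ymin / binsz):floor(ymax / binsz), paste))
    unlist(index[[ty]]$idx[keys], use.names = FALSE)
  }
  onoff_axis_ori <- atan2(filters$dy, filters$dx) * 180 / pi  # ON-OFF axis, direction
  onoff_reach <- max(sqrt(filters$dx^2 + filters$dy^2))       # subfield offset bound
  inside_onoff <- function(cand, cx, cy, rad) {
    ((filters$x0[cand] + filters$dx[cand] - cx)^2 +
       (filters$y0[cand] + filters$dy[cand] - cy)^2 <= rad^2) |
      ((filters$x0[cand] - filters$dx[cand] - cx)^2 +
         (filters$y0[cand] - filters$dy[cand] - cy)^2 <= rad^2)
  }

  n <- nrow(cells)
  src_l <- vector("list", n); tgt_l <- vector("list", n)
  for (ci in seq_len(n)) {
    az <- pos[ci, 1]; el <- pos[ci, 2]
    inh <- cells$ei_class[ci] == "I"
    chosen <- integer(0)
    if (inh) {
      for (ty in types) {
        rad <- stats::runif(1, 15, 20) / 2
        marg <- if (ty == "ON_OFF") rad + onoff_reach else rad
        cand <- lookup(ty, az - marg, az + marg, el - marg, el + marg)
        if (length(cand) == 0) next
        if (ty == "ON_OFF") {
          cand <- cand[inside_onoff(cand, az, el, rad)]
          if (length(cand) > 0) {
            d <- fold_delta_ori(onoff_axis_ori[cand] - cells$theta_assigned[ci])
            cand <- cand[d <= 15]
          }
        } else {
          cand <- cand[(filters$x0[cand] - az)^2 + (filters$y0[cand] - el)^2 <= rad^2]
        }
        if (length(cand) > cap_inh) cand <- sample(cand, cap_inh)
        chosen <- c(chosen, cand)
      }
    } else {
      rm_ <- stats::runif(1, 3, 4)
      aspect <- stats::runif(1, 2.8, 3.0)
      rmaj <- rm_ * aspect
      sep <- stats::runif(1, 10, 11)
      phi <- cells$theta_assigned[ci] * pi / 180
      ux <- cos(phi); uy <- sin(phi)
      centers <- rbind(ON  = c(az + sep / 2 * ux, el + sep / 2 * uy),
                       OFF = c(az - sep / 2 * ux, el - sep / 2 * uy))
      # ON and OFF ellipses: minor axis along (ux, uy), major perpendicular
      for (ty in c("ON", "OFF")) {
        cc <- centers[ty, ]
        cand <- lookup(ty, cc[1] - rmaj, cc[1] + rmaj, cc[2] - rmaj, cc[2] + rmaj)
        if (length(cand) == 0) next
        dx <- filters$x0[cand] - cc[1]; dy <- filters$y0[cand] - cc[2]
        along <- dx * ux + dy * uy
        perp <- -dx * uy + dy * ux
        cand <- cand[(along / rm_)^2 + (perp / rmaj)^2 <= 1]
        if (length(cand) > cap_exc) cand <- sample(cand, cap_exc)
        chosen <- c(chosen, cand)
      }
      # circular ON_OFF lasso of radius = minor radius, with the axis condition
      marg <- rm_ + onoff_reach
      cand <- lookup("ON_OFF", az - marg, az + marg, el - marg, el + marg)
      if (length(cand) > 0) {
        cand <- cand[inside_onoff(cand, az, el, rm_)]
        if (length(cand) > 0) {
          d <- fold_delta_ori(onoff_axis_ori[cand] - cells$theta_assigned[ci])
          cand <- cand[d <= 15]
        }
        if (length(cand) > cap_exc) cand <- sample(cand, cap_exc)
        chosen <- c(chosen, cand)
      }
    }
    if (length(chosen) > 0) {
      src_l[[ci]] <- filters$filter_id[chosen]
      tgt_l[[ci]] <- rep(cells$cell_id[ci], length(chosen))
    }
  }
  edges <- data.frame(src = unlist(src_l), tgt = unlist(tgt_l))
  edges$n_syn <- as.integer(n_syn_per_filter)
  edges$weight <- NA_real_
  edges$delay <- 1.0
  edges <- edges[order(edges$tgt, edges$src), , drop = FALSE]
  rownames(edges) <- NULL
  attr(edges, "seed") <- seed
  attr(edges, "source") <- "LGN"
  class(edges) <- c("connection_set", "data.frame")
  edges
}

#' Calibrate LGN filter parameter ranges
#'
#' Replaces the unavailable published sampling table by a grid search against
#' the stated targets: sigma_c candidates are screened so a single-subfield
#' filter's F0 tuning over the SF grid peaks at `target_sf`; k candidates so
#' F0 tuning over the TF grid peaks at `target_tf`; the amplitude A_c is then
#' scaled (by root finding on the pre-rectification linear response, which is
#' proportional to A_c) so that the bank's maximal F0 -- attained by a
#' two-subfield filter at the preferred grating -- sits just inside the
#' 11-12 Hz target window even at the +10 percent edge of the A_c sampling
#' variation.
#'
#' @param target_sf Target preferred spatial frequency (cpd).
#' @param target_tf Target preferred temporal frequency (Hz).
#' @param target_peak_f0 Two-element window for the bank's maximal F0 (Hz).
#' @param sf_grid,tf_grid Grating battery grids.
#' @param sigma_candidates,k_candidates Candidate values screened.
#' @param R0_range Baseline-rate sampling range (Hz).
#' @param contrast Grating contrast in percent.
#' @param frame c(width, height) in pixels of the screening movies (gratings
#'   are full-field, so a small frame around the filter suffices).
#' @param duration Grating duration (ms) of the screening movies.
#' @return Parameter ranges in the shape of [default_filter_params()].
#' @export
calibrate_filter_params <- function(target_sf = 0.05, target_tf = 4,
                                    target_peak_f0 = c(11, 12),
                                    sf_grid = GRATING_SFS, tf_grid = GRATING_TFS,
                                    sigma_candidates = seq(1.6, 4.2, by = 0.2),
                                    k_candidates = seq(0.020, 0.080, by = 0.004),
                                    R0_range = c(1, 6), contrast = 80,
                                    frame = c(64, 64), duration = 2000) {
  r0_mid <- mean(R0_range)
  mk_bank <- function(sigma, k, ftype = "ON", sep_sigma = 2) {
    n <- max(length(sigma), length(k))
    sigma <- rep_len(sigma, n); k <- rep_len(k, n)
    onoff <- ftype == "ON_OFF"
    b <- data.frame(filter_id = seq_len(n) - 1L, ftype = ftype, x0 = 0, y0 = 0,
                    dx = if (onoff) sep_sigma * sigma / 2 else 0, dy = 0,
                    sigma_c = sigma, A_c = 1, k = k, R0 = r0_mid,
                    stringsAsFactors = FALSE)
    class(b) <- c("lgn_bank", "data.frame")
    b
  }
  f0_of <- function(rates, tf) {
    apply(rates[-seq_len(500), , drop = FALSE], 2, function(r) f0_f1(r, tf)[["F0"]])
  }
  contiguous_run <- function(ok, values, what) {
    if (!any(ok)) stop("no ", what, " candidate hits the target; best candidates: ",
                       paste(signif(values[seq_len(min(3, length(values)))], 3), collapse = ", "))
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    runs <- which(r$values)
    best <- runs[which.max(r$lengths[runs])]
    range(values[starts[best]:ends[best]])
  }

  # stage 1: sigma_c from SF tuning (separable kernels: independent of k)
  bank_s <- mk_bank(sigma_candidates, stats::median(k_candidates))
  f0_sf <- vapply(sf_grid, function(sf) {
    mv <- make_grating(0, sf, target_tf, contrast, duration,
                       width = frame[1], height = frame[2])
    f0_of(filter_bank_response(bank_s, mv), target_tf)
  }, numeric(length(sigma_candidates)))
  ok_s <- apply(f0_sf, 1, function(v) sf_grid[which.max(v)] == target_sf)
  sigma_range <- contiguous_run(ok_s, sigma_candidates, "sigma_c")

  # stage 2: k from TF tuning at the target SF
  bank_k <- mk_bank(mean(sigma_range), k_candidates)
  f0_tf <- vapply(tf_grid, function(tf) {
    mv <- make_grating(0, target_sf, tf, contrast, duration,
                       width = frame[1], height = frame[2])
    f0_of(filter_bank_response(bank_k, mv), tf)
  }, numeric(length(k_candidates)))
  ok_k <- apply(f0_tf, 1, function(v) tf_grid[which.max(v)] == target_tf)
  k_range <- contiguous_run(ok_k, k_candidates, "k")

  # stage 3: A_c so the bank's maximal F0 stays inside the target window.
  # The max is attained by a two-subfield (ON_OFF) filter at the corner of
  # the sigma/k ranges with the largest gain at the preferred grating, with
  # the top baseline rate; pre-rectification L scales linearly with A_c.
  corners <- expand.grid(sigma = c(sigma_range, mean(sigma_range)),
                         k = c(k_range, mean(k_range)))
  bank_m <- mk_bank(corners$sigma, corners$k, ftype = "ON_OFF")
  bank_m$R0 <- R0_range[2]
  mv <- make_grating(0, target_sf, target_tf, contrast, duration,
                     width = frame[1], height = frame[2])
  sub <- bank_subfields(bank_m)
  lt <- bank_temporal_convolve(bank_spatial_project(sub, mv), bank_m$k[sub$row])
  lt <- sweep(lt, 2, sub$pol, "*")
  win <- -seq_len(500)
  f0_at <- function(A) {
    max(vapply(seq_len(nrow(bank_m)), function(fi) {
      scols <- which(sub$row == fi)
      r <- pmax(bank_m$R0[fi] + A * lt[, scols[1]], 0) +
        pmax(bank_m$R0[fi] + A * lt[, scols[2]], 0) - bank_m$R0[fi]
      f0_f1(r[win], target_tf)[["F0"]]
    }, 0.0))
  }
  f0_cap <- target_peak_f0[2] - 0.1 * diff(target_peak_f0)
  a_high <- stats::uniroot(function(A) f0_at(A) - f0_cap,
                           lower = 1e-6, upper = 1, extendInt = "upX", tol = 1e-8)$root
  list(sigma_c = sigma_range, k = k_range,
       A_c = c(0.9, 1.1) * a_high / 1.1, R0 = R0_range, onoff_sep_sigma = 2)
}
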