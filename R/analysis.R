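#' Spontaneous firing rate from gray-screen trials
#'
#' Uses the spikes from the second 500 ms of each 1000 ms gray trial, then
#' averages the per-trial rates; with 20 trials the smallest resolvable
#' nonzero rate is 0.1 Hz.
#'
#' @param spikes data.frame with `cell_id`, `time` (ms), `trial`.
#' @param cell_ids Cells to report (rates are 0 for silent cells).
#' @param n_trials Number of trials present.
#' @param window Analysis window in ms within each trial.
#' @return Named numeric vector of rates in Hz, one per cell id.
#' @export
spont_rate <- function(spikes, cell_ids, n_trials = 20, window = c(500, 1000)) {
  if (is.null(spikes$trial)) stop("spikes must carry a trial column")
  if (length(unique(spikes$trial)) > n_trials) stop("more trials present than declared")
  sel <- spikes$time >= window[1] & spikes$time < window[2]
  counts <- table(factor(spikes$cell_id[sel], levels = cell_ids))
  as.numeric(counts) / (n_trials * diff(window) / 1000)
}

#' Trial-averaged tuning curve and maximal grating response
#'
#' Firing rates use the spikes from the grating presentation (the first
#' 500 ms gray prefix is discarded) averaged over trials, separately per
#' condition. Rmax is the maximum over all conditions. The preferred
#' direction is the argmax of the response averaged across all SF/TF at each
#' direction; preferred SF/TF maximize the response at that direction.
#'
#' @param spikes data.frame with `cell_id`, `time`, `trial`, and condition
#'   columns `direction`, `sf`, `tf`.
#' @param cell_id The cell to analyze.
#' @param n_trials Trials per condition.
#' @param window Analysis window in ms (grating presentation).
#' @return A `tuning_curve` list: `conditions` (per-condition rates),
#'   `by_direction` (rates averaged over SF/TF), `rmax`, `pref_direction`,
#'   `pref_sf`, `pref_tf`, `defined`.
#' @export
tuning_and_rmax <- function(spikes, cell_id, n_trials, window = c(500, 3000)) {
  sp <- spikes[spikes$cell_id == cell_id &
                 spikes$time >= window[1] & spikes$time < window[2], , drop = FALSE]
  grid <- unique(spikes[, c("direction", "sf", "tf")])
  grid <- grid[order(grid$direction, grid$sf, grid$tf), , drop = FALSE]
  dur_s <- diff(window) / 1000
  key <- function(d) paste(d$direction, d$sf, d$tf)
  cnt <- table(factor(key(sp), levels = key(grid)))
  grid$rate <- as.numeric(cnt) / (n_trials * dur_s)
  by_dir <- vapply(split(grid$rate, grid$direction), mean, 0.0)
  dirs <- as.numeric(names(by_dir))
  if (all(grid$rate == 0)) {
    return(structure(list(conditions = grid, by_direction = by_dir, rmax = 0,
                          pref_direction = NA_real_, pref_sf = NA_real_,
                          pref_tf = NA_real_, defined = FALSE),
                     class = "tuning_curve"))
  }
  pref_dir <- dirs[which.max(by_dir)]
  at_pref <- grid[grid$direction == pref_dir, , drop = FALSE]
  best <- at_pref[which.max(at_pref$rate), , drop = FALSE]
  structure(list(conditions = grid, by_direction = by_dir, rmax = max(grid$rate),
                 pref_direction = pref_dir, pref_sf = best$sf, pref_tf = best$tf,
                 defined = TRUE), class = "tuning_curve")
}

#' Orientation selectivity index (one minus circular variance)
#'
#' OSI = |sum_k f_k exp(2 i theta_k) / sum_k f_k| with theta_k the stimulus
#' directions in radians and f_k the rate responses.
#'
#' @param rates Response per direction (Hz).
#' @param directions Directions in degrees (default the 8-direction grid).
#' @return OSI in \[0, 1\], or NA if all rates are zero.
#' @export
osi <- function(rates, directions = seq(0, 315, by = 45)) {
  if (any(rates < 0)) stop("rates must be nonnegative")
  if (sum(rates) <= 0) return(NA_real_)
  th <- directions * pi / 180
  Mod(sum(rates * exp(2i * th)) / sum(rates))
}

#' Direction selectivity index
#'
#' DSI = (f_pref - f_null) / (f_pref + f_null), with f_null the response at
#' the direction opposite the preferred one.
#'
#' @inheritParams osi
#' @return DSI in \[0, 1\], or NA if f_pref + f_null is zero.
#' @export
dsi <- function(rates, directions = seq(0, 315, by = 45)) {
  if (sum(rates) <= 0) return(NA_real_)
  ip <- which.max(rates)
  null_dir <- (directions[ip] + 180) %% 360
  inul <- which(directions %% 360 == null_dir)
  if (length(inul) == 0) stop("no condition opposite the preferred direction")
  fp <- rates[ip]; fn <- rates[inul]
  if (fp + fn == 0) return(NA_real_)
  (fp - fn) / (fp + fn)
}

#' F0 and F1 components of a cyclic response
#'
#' Cycle-averages the (trial-averaged) signal at the stimulus frequency.
#' F0 is the cycle mean. F1 follows the selected convention: `fourier_abs`
#' takes the modulus of the Fourier component at the stimulus frequency (for
#' a + b sin(wt), F1 = |b|); `fit_2b` fits b sin(wt + phi) to the
#' mean-subtracted cycle average and reports F1 = 2 |b|.
#'
#' @param signal Numeric series sampled at `dt` ms steps.
#' @param stimulus_freq Stimulus frequency in Hz.
#' @param convention "fourier_abs" or "fit_2b".
#' @param dt Sampling step in ms.
#' @return c(F0, F1).
#' @export
f0_f1 <- function(signal, stimulus_freq, convention = c("fourier_abs", "fit_2b"),
                  dt = 1) {
  convention <- match.arg(convention)
  period <- 1000 / stimulus_freq / dt          # samples per cycle (may be fractional)
  ncyc <- floor(length(signal) / period)
  if (ncyc < 1) stop("signal shorter than one stimulus cycle")
  nuse <- floor(ncyc * period)
  x <- signal[seq_len(nuse)]
  ts <- (seq_len(nuse) - 1) * dt / 1000        # seconds
  f0 <- mean(x)
  w <- 2 * pi * stimulus_freq
  bs <- 2 * mean((x - f0) * sin(w * ts))
  bc <- 2 * mean((x - f0) * cos(w * ts))
  amp <- sqrt(bs^2 + bc^2)
  f1 <- if (convention == "fourier_abs") amp else 2 * amp
  c(F0 = f0, F1 = f1)
}

#' Lifetime sparsity (Vinje-Gallant)
#'
#' S = (1 - (sum f_i / n)^2 / (sum f_i^2 / n)) / (1 - 1/n) over time bins of
#' the trial-averaged response (33.3 ms bins by convention, matching a 30 Hz
#' frame rate).
#'
#' @param rates Trial-averaged response per time bin.
#' @return Sparsity in \[0, 1\], or NA if all bins are zero.
#' @export
sparsity <- function(rates) {
  n <- length(rates)
  if (n < 2) stop("need at least 2 bins")
  if (any(rates < 0)) stop("rates must be nonnegative")
  if (all(rates == 0)) return(NA_real_)
  (1 - (sum(rates) / n)^2 / (sum(rates^2) / n)) / (1 - 1 / n)
}

#' Bin spikes into a rate series
#'
#' @param times Spike times in ms.
#' @param t_range c(start, end) in ms.
#' @param bin Bin width in ms.
#' @param n_trials Number of trials averaged over.
#' @return Rates in Hz per bin.
#' @export
bin_rate <- function(times, t_range, bin, n_trials = 1) {
  edges <- seq(t_range[1], t_range[2], by = bin)
  if (edges[length(edges)] < t_range[2]) edges <- c(edges, t_range[2])
  counts <- graphics::hist(times[times >= t_range[1] & times < t_range[2]],
                           breaks = edges, plot = FALSE)$counts
  counts / (diff(edges) / 1000) / n_trials
}

#' Coefficient of variation of inter-spike intervals
#'
#' Reported, following the source convention, as the squared ratio of the
#' standard deviation to the mean of the ISIs (set `squared = FALSE` for the
#' conventional unsquared ratio). ISIs are pooled over trials.
#'
#' @param spikes data.frame with `time` and `trial` for one cell.
#' @param squared Report the squared ratio (the printed definition).
#' @return CV (possibly squared), or NA with fewer than 2 ISIs.
#' @export
cv_isi <- function(spikes, squared = TRUE) {
  isis <- unlist(lapply(split(spikes$time, spikes$trial),
                        function(t) diff(sort(t))), use.names = FALSE)
  if (length(isis) < 2) return(NA_real_)
  r <- stats::sd(isis) / mean(isis)
  if (squared) r^2 else r
}

#' Fano factor from sliding-window spike counts
#'
#' Counts spikes in 50 ms windows sliding in 10 ms steps across all trials;
#' the Fano factor is the slope of the regression of count variances on count
#' means across window positions.
#'
#' @param spikes data.frame with `time` and `trial` for one cell.
#' @param trials Trial ids present (including silent trials).
#' @param t_range Analysis window in ms.
#' @param window,step Sliding window length and step in ms.
#' @return Fano factor, or NA when degenerate.
#' @export
fano_factor <- function(spikes, trials, t_range, window = 50, step = 10) {
  starts <- seq(t_range[1], t_range[2] - window, by = step)
  counts <- vapply(trials, function(tr) {
    tt <- spikes$time[spikes$trial == tr]
    vapply(starts, function(s) sum(tt >= s & tt < s + window), 0L)
  }, integer(length(starts)))
  mu <- rowMeans(counts)
  va <- apply(counts, 1, stats::var)
  if (stats::var(mu) == 0) return(NA_real_)
  unname(stats::coef(stats::lm(va ~ mu))[2])
}

#' Signal and noise correlations between two cells
#'
#' Signal correlation: Pearson correlation of the trial-averaged spike counts
#' across stimuli (the 8 grating directions, or 333 ms windows for movies and
#' spontaneous activity). Noise correlation: Pearson correlation of
#' single-trial counts within each stimulus, averaged over stimuli.
#'
#' @param counts_a,counts_b Matrices of spike counts, stimuli x trials.
#' @return c(signal, noise); entries NA when degenerate.
#' @export
pair_correlations <- function(counts_a, counts_b) {
  stopifnot(all(dim(counts_a) == dim(counts_b)))
  ma <- rowMeans(counts_a); mb <- rowMeans(counts_b)
  sig <- if (stats::sd(ma) == 0 || stats::sd(mb) == 0) NA_real_ else stats::cor(ma, mb)
  per_stim <- vapply(seq_len(nrow(counts_a)), function(i) {
    a <- counts_a[i, ]; b <- counts_b[i, ]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_ else stats::cor(a, b)
  }, 0.0)
  c(signal = sig, noise = mean(per_stim, na.rm = TRUE))
}

#' Optogenetic modulation index
#'
#' OMI = (f_p - f_control) / (f_p + f_control); -1 is total silencing.
#'
#' @param f_p Rate with perturbation (Hz).
#' @param f_control Rate without (Hz).
#' @return OMI in \[-1, 1\], NA where both rates are zero. Vectorized.
#' @export
omi <- function(f_p, f_control) {
  out <- (f_p - f_control) / (f_p + f_control)
  out[f_p + f_control == 0] <- NA_real_
  out
}

#' Skewness (third standardized moment)
#'
#' mean(((f - mean(f)) / sd_pop(f))^3) in linear rate space, with the
#' population (1/n) standard deviation.
#'
#' @param f Numeric sample (rates).
#' @return Skewness, or NA with fewer than 3 values or zero variance.
#' @export
skewness <- function(f) {
  n <- length(f)
  if (n < 3) return(NA_real_)
  s <- sqrt(mean((f - mean(f))^2))
  if (s == 0) return(NA_real_)
  mean(((f - mean(f)) / s)^3)
}

#' Multi-unit activity power spectrum
#'
#' The MUA signal is the 1 ms-binned firing rate accumulated over all neurons
#' with inverse-distance weights 1/r_i from the recording position (r capped
#' below at 1 um to avoid the singularity); its power spectrum is computed by
#' FFT, averaged over trials.
#'
#' @param spikes data.frame with `cell_id`, `time`, `trial`.
#' @param cells `cell_table` giving positions.
#' @param center Recording position c(x, y) in um (default the model center).
#' @param t_range Analysis window in ms.
#' @param bin Bin width in ms.
#' @return data.frame with `freq` (Hz) and `power`.
#' @export
mua_spectrum <- function(spikes, cells, center = c(0, 0), t_range, bin = 1) {
  r <- pmax(sqrt((cells$x - center[1])^2 + (cells$y - center[2])^2), 1)
  wt <- 1 / r
  names(wt) <- as.character(cells$cell_id)
  edges <- seq(t_range[1], t_range[2], by = bin)
  nb <- length(edges) - 1
  if (is.null(spikes$trial)) spikes$trial <- 1
  trials <- sort(unique(spikes$trial))
  if (length(trials) == 0) trials <- 1
  pw <- 0
  for (tr in trials) {
    sp <- spikes[spikes$trial == tr, , drop = FALSE]
    sp <- sp[sp$time >= t_range[1] & sp$time < t_range[2], , drop = FALSE]
    sig <- numeric(nb)
    if (nrow(sp) > 0) {
      bi <- pmin(nb, floor((sp$time - t_range[1]) / bin) + 1)
      agg <- rowsum(wt[as.character(sp$cell_id)], bi)
      sig[as.integer(rownames(agg))] <- agg[, 1]
    }
    sig <- sig / (bin / 1000)                     # weighted rate
    ft <- stats::fft(sig - mean(sig))
    pw <- pw + Mod(ft)^2 / nb
  }
  pw <- pw / length(trials)
  freq <- (seq_len(nb) - 1) / (nb * bin / 1000)
  keep <- seq_len(floor(nb / 2))
  data.frame(freq = freq[keep], power = pw[keep])
}

#' LGN fraction of excitatory synaptic input
#'
#' From the per-cell input accumulators of [simulate_network()] (summed
#' weights of applied excitatory events): fraction = LGN sum / total
#' excitatory sum, per cell.
#'
#' @param accum Per-cell accumulator data.frame (`cell_id`, `lgn_exc`,
#'   `total_exc`), or the sum of several trials' accumulators.
#' @return data.frame with `cell_id` and `lgn_fraction` (NA when the cell
#'   received no excitatory input).
#' @export
lgn_fraction <- function(accum) {
  frac <- ifelse(accum$total_exc > 0, accum$lgn_exc / accum$total_exc, NA_real_)
  data.frame(cell_id = accum$cell_id, lgn_fraction = frac)
}

#' LGN convergence of cell pairs by recurrent coupling
#'
#' For each pair, the convergence is the number of LGN filters connecting to
#' both cells divided by the sum of the numbers connecting to each;
#' pairs are classified as unconnected, one-way, or reciprocally connected by
#' the recurrent edges.
#'
#' @param pairs Two-column matrix/data.frame of cell ids.
#' @param lgn_edges Feedforward `connection_set` (src = filter id).
#' @param recurrent Recurrent `connection_set`.
#' @return data.frame with `a`, `b`, `convergence`, `coupling`.
#' @export
lgn_convergence <- function(pairs, lgn_edges, recurrent) {
  pairs <- as.data.frame(pairs)
  names(pairs)[1:2] <- c("a", "b")
  src_by_cell <- split(lgn_edges$src, lgn_edges$tgt)
  ekey <- paste(recurrent$src, recurrent$tgt)
  ab <- paste(pairs$a, pairs$b) %in% ekey
  ba <- paste(pairs$b, pairs$a) %in% ekey
  coup <- ifelse(ab & ba, "reciprocal", ifelse(ab | ba, "one_way", "none"))
  conv <- vapply(seq_len(nrow(pairs)), function(i) {
    sa <- src_by_cell[[as.character(pairs$a[i])]]
    sb <- src_by_cell[[as.character(pairs$b[i])]]
    na <- length(sa); nb <- length(sb)
    if (na + nb == 0) NA_real_ else length(intersect(sa, sb)) / (na + nb)
  }, 0.0)
  data.frame(a = pairs$a, b = pairs$b, convergence = conv, coupling = coup)
}

#' Linear amplification fit
#'
#' Ordinary least squares of the full-network measure on the input-only
#' measure (e.g. total vs LGN-only input or rates), y = A x + B.
#'
#' @param x,y Per-condition measures.
#' @return c(A, B, r2), or NA values when x is degenerate.
#' @export
amplification_fit <- function(x, y) {
  if (length(x) < 2 || stats::sd(x) == 0) return(c(A = NA_real_, B = NA_real_, r2 = NA_real_))
  fit <- stats::lm(y ~ x)
  r2 <- if (stats::sd(y) == 0) 1 else stats::cor(x, y)^2
  c(A = unname(stats::coef(fit)[2]), B = unname(stats::coef(fit)[1]), r2 = r2)
}

#' Flash PSTH with first and second peak extraction
#'
#' Bins population spikes in 2 ms bins averaged over cells and trials, then
#' finds the first two local maxima after flash onset on a 10 ms-smoothed
#' copy of the PSTH.
#'
#' @param spikes data.frame with `time`, `trial` (population already selected).
#' @param n_cells,n_trials Normalization counts.
#' @param t_range Analysis range in ms.
#' @param flash_onset Flash onset time in ms.
#' @param bin Bin width in ms.
#' @param smooth_ms Smoothing window for peak detection in ms.
#' @return List with `time`, `psth` (Hz per cell), and `peaks` (data.frame
#'   `magnitude`, `latency` for up to two peaks; zero rows if none).
#' @export
flash_psth <- function(spikes, n_cells, n_trials, t_range, flash_onset,
                       bin = 2, smooth_ms = 10) {
  edges <- seq(t_range[1], t_range[2], by = bin)
  nb <- length(edges) - 1
  counts <- graphics::hist(spikes$time[spikes$time >= t_range[1] & spikes$time < t_range[2]],
                           breaks = edges, plot = FALSE)$counts
  psth <- counts / n_cells / n_trials / (bin / 1000)
  tmid <- edges[-length(edges)] + bin / 2
  kw <- max(1, round(smooth_ms / bin))
  sm <- stats::filter(psth, rep(1 / kw, kw), sides = 2)
  sm[is.na(sm)] <- 0
  after <- which(tmid >= flash_onset)
  pk_idx <- after[which(diff(sign(diff(c(-Inf, sm[after], -Inf)))) == -2)]
  pk_idx <- pk_idx[sm[pk_idx] > 0]
  if (length(pk_idx) == 0) {
    peaks <- data.frame(magnitude = numeric(0), latency = numeric(0))
  } else {
    pk_idx <- pk_idx[seq_len(min(2, length(pk_idx)))]
    peaks <- data.frame(magnitude = psth[pk_idx], latency = tmid[pk_idx] - flash_onset)
  }
  list(time = tmid, psth = psth, peaks = peaks)
}
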