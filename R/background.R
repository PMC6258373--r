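#' Generate a traveling-wave background schedule
#'
#' Waves of elevated Poisson drive sweep the cortical plane sequentially:
#' each wave has a duration uniform on \[200, 1200\] ms, is separated from the
#' previous one by a gap uniform on \[250, 1750\] ms, moves in a uniformly
#' random direction with an amplitude uniform on \[5, 15\] Hz, and is a band
#' 2000 um wide (infinite perpendicular extent). The wave speed is set so the
#' band fully traverses the model footprint within the wave's duration.
#'
#' @param total_time Schedule length in ms.
#' @param seed Integer seed, or NULL to use the current RNG state.
#' @param footprint_radius Radius in um of the disc the waves must traverse.
#' @param width Band width in um.
#' @return A `wave_schedule`: data.frame with `onset`, `duration`, `direction`
#'   (degrees), `amplitude` (Hz), `width`, `speed` (um/ms), plus attributes.
#' @export
generate_waves <- function(total_time, seed = NULL, footprint_radius = 995,
                           width = 2000) {
  if (total_time <= 0) stop("total_time must be positive")
  if (!is.null(seed)) set.seed(seed)
  onset <- duration <- direction <- amplitude <- numeric(0)
  t <- 0
  repeat {
    t <- t + stats::runif(1, 250, 1750)          # gap precedes each wave
    if (t >= total_time) break
    d <- stats::runif(1, 200, 1200)
    onset <- c(onset, t); duration <- c(duration, d)
    direction <- c(direction, stats::runif(1, 0, 360))
    amplitude <- c(amplitude, stats::runif(1, 5, 15))
    t <- t + d
  }
  waves <- data.frame(onset = onset, duration = duration, direction = direction,
                      amplitude = amplitude,
                      width = rep_len(width, length(onset)),
                      speed = (2 * footprint_radius + rep_len(width, length(onset))) / duration)
  attr(waves, "footprint_radius") <- footprint_radius
  attr(waves, "total_time") <- total_time
  class(waves) <- c("wave_schedule", "data.frame")
  waves
}

#' Background drive rate at a point and time
#'
#' The rate is the active wave's amplitude when the point lies inside the
#' moving band (a rectangular profile: the rate rises sharply as the wave
#' front passes), else zero.
#'
#' @param schedule A `wave_schedule`.
#' @param x,y Position in um.
#' @param t Time in ms (scalar or vector).
#' @return Rate in Hz, vectorized over `t`.
#' @export
wave_rate <- function(schedule, x, y, t) {
  r <- numeric(length(t))
  rad <- attr(schedule, "footprint_radius")
  for (w in seq_len(nrow(schedule))) {
    th <- schedule$direction[w] * pi / 180
    u <- x * cos(th) + y * sin(th)
    front <- -rad + schedule$speed[w] * (t - schedule$onset[w])
    active <- t >= schedule$onset[w] & t < schedule$onset[w] + schedule$duration[w] &
      u <= front & u > front - schedule$width[w]
    r[active] <- schedule$amplitude[w]
  }
  r
}

#' Place background Poisson generators
#'
#' @param n Number of generators.
#' @param radius Placement disc radius in um (model footprint plus the 150 um
#'   connection reach, so edge cells have full candidate pools).
#' @param seed Integer seed.
#' @return data.frame with `gen_id` (0-based), `x`, `y`.
#' @export
place_generators <- function(n = 3000, radius = 995, seed = 1L) {
  set.seed(seed)
  r <- radius * sqrt(stats::runif(n))
  phi <- stats::runif(n, 0, 2 * pi)
  data.frame(gen_id = seq_len(n) - 1L, x = r * cos(phi), y = r * sin(phi))
}

#' Wire background generators to layer 4 cells
#'
#' Each cell receives between 18 and 24 connections from generators within
#' 150 um. All of a cell's background connections share one synapse-count
#' multiplier m, drawn per cell from a long-tailed distribution on 1..16
#' (truncated geometric, heavily weighted toward 1), which produces the
#' skewed distribution of background input strengths across cells.
#'
#' @param cells A `cell_table`.
#' @param generators Generator table from [place_generators()].
#' @param seed Integer seed.
#' @param reach Connection radius in um.
#' @param n_conn_range Two-element range of connections per cell.
#' @param m_max Maximum synapse multiplier.
#' @param m_p Success parameter of the truncated geometric multiplier.
#' @return A `connection_set` (`src` = gen_id, `tgt` = cell_id, `n_syn` = m).
#' @export
wire_background <- function(cells, generators, seed = 1L, reach = 150,
                            n_conn_range = c(18L, 24L), m_max = 16L, m_p = 0.5) {
  set.seed(seed)
  n <- nrow(cells)
  # per-cell multiplier: truncated geometric on 1..m_max
  probs <- m_p * (1 - m_p)^(0:(m_max - 1))
  m <- sample.int(m_max, n, replace = TRUE, prob = probs / sum(probs))
  src_l <- vector("list", n)
  nconn <- sample(seq(n_conn_range[1], n_conn_range[2]), n, replace = TRUE)
  for (ci in seq_len(n)) {
    d2 <- (generators$x - cells$x[ci])^2 + (generators$y - cells$y[ci])^2
    cand <- which(d2 <= reach^2)
    if (length(cand) < nconn[ci])
      stop(sprintf("cell %d has only %d generators within %g um (needs %d); generator density too low",
                   cells$cell_id[ci], length(cand), reach, nconn[ci]))
    src_l[[ci]] <- generators$gen_id[sample(cand, nconn[ci])]
  }
  edges <- data.frame(src = unlist(src_l),
                      tgt = rep(cells$cell_id, nconn),
                      n_syn = rep(m, nconn),
                      weight = NA_real_,
                      delay = 1.0)
  edges <- edges[order(edges$tgt, edges$src), , drop = FALSE]
  rownames(edges) <- NULL
  attr(edges, "seed") <- seed
  attr(edges, "source") <- "BKG"
  class(edges) <- c("connection_set", "data.frame")
  edges
}

#' Sample background generator spike trains from a wave schedule
#'
#' Each generator fires as an inhomogeneous Poisson process at the wave rate
#' of its own position: amplitude while inside the sweeping band, zero
#' otherwise.
#'
#' @param schedule A `wave_schedule`.
#' @param generators Generator table.
#' @param total_time Simulation length in ms.
#' @param seed Integer seed, or NULL to use the current RNG state.
#' @return data.frame with `src` (gen_id) and `time` (ms), sorted by time.
#' @export
background_spikes <- function(schedule, generators, total_time, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rad <- attr(schedule, "footprint_radius")
  out_src <- vector("list", nrow(schedule))
  out_t <- vector("list", nrow(schedule))
  for (w in seq_len(nrow(schedule))) {
    th <- schedule$direction[w] * pi / 180
    u <- generators$x * cos(th) + generators$y * sin(th)
    # band covers u for front in [u, u + width]
    t_on <- schedule$onset[w] + (u + rad) / schedule$speed[w]
    t_off <- pmin(t_on + schedule$width[w] / schedule$speed[w],
                  schedule$onset[w] + schedule$duration[w], total_time)
    t_on <- pmax(t_on, schedule$onset[w])
    span <- pmax(t_off - t_on, 0)
    counts <- stats::rpois(nrow(generators), schedule$amplitude[w] * span / 1000)
    gi <- rep(seq_len(nrow(generators)), counts)
    out_src[[w]] <- generators$gen_id[gi]
    out_t[[w]] <- rep(t_on, counts) + stats::runif(sum(counts)) * rep(span, counts)
  }
  sp <- data.frame(src = as.integer(unlist(out_src)), time = as.numeric(unlist(out_t)))
  sp <- sp[sp$time < total_time, , drop = FALSE]
  sp[order(sp$time), , drop = FALSE]
}
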