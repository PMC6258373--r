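GRAY_LEVEL <- 127

new_movie <- function(frames, name, pixel_deg = 1.25, dt = 1) {
  stopifnot(length(dim(frames)) == 3)
  structure(list(frames = frames, dt = dt, pixel_deg = pixel_deg, name = name),
            class = "stimulus_movie")
}

#' @export
print.stimulus_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("stimulus_movie '%s': %dx%d px (%.3g deg/px), %d ms at %g ms/frame\n",
              x$name, d[1], d[2], x$pixel_deg, d[3] * x$dt, x$dt))
  invisible(x)
}

#' Pixel center coordinates in degrees
#'
#' Maps pixel indices to visual angles centered on the frame.
#' @param n Number of pixels along the axis.
#' @param pixel_deg Degrees per pixel.
#' @return Numeric vector of pixel-center angles in degrees.
#' @keywords internal
pixel_axis <- function(n, pixel_deg = 1.25) (seq_len(n) - (n + 1) / 2) * pixel_deg

movie_dims <- function(width, height) c(x = as.integer(width), y = as.integer(height))

#' Drifting square-wave grating movie
#'
#' A 500 ms mid-gray prefix followed by a square-wave grating (alternating
#' bright/dark stripes) drifting perpendicular to the stripes. Contrast c (in
#' percent) maps to luminance levels 127 +/- 1.27 c on the 0-255 scale.
#'
#' @param direction Drift direction in degrees (0 drifts toward +x).
#' @param sf Spatial frequency in cycles per degree.
#' @param tf Temporal frequency in Hz.
#' @param contrast Contrast in percent (80 is the battery default).
#' @param duration Grating presentation time in ms (after the gray prefix).
#' @param width,height Frame size in pixels.
#' @param pixel_deg Degrees per pixel.
#' @param gray_prefix Length of the leading gray epoch in ms.
#' @return A `stimulus_movie`.
#' @export
make_grating <- function(direction, sf, tf, contrast = 80, duration = 2500,
                         width = 192, height = 96, pixel_deg = 1.25,
                         gray_prefix = 500) {
  if (sf <= 0 || tf <= 0) stop("sf and tf must be positive")
  if (1 / sf < 2 * pixel_deg)
    warning(sprintf("spatial period %.3g deg is below 2 pixels; the grating is aliased", 1 / sf))
  xs <- pixel_axis(width, pixel_deg); ys <- pixel_axis(height, pixel_deg)
  th <- direction * pi / 180
  u <- outer(xs * cos(th), ys * sin(th), "+")        # projection on drift axis, deg
  nt <- as.integer(gray_prefix + duration)
  frames <- array(GRAY_LEVEL, dim = c(width, height, nt))
  amp <- 1.27 * contrast
  t_ms <- seq_len(duration) - 1
  spatial_phase <- 2 * pi * sf * u
  for (i in seq_along(t_ms)) {
    ph <- spatial_phase - 2 * pi * tf * t_ms[i] / 1000
    s <- sin(ph)
    frames[, , gray_prefix + i] <- GRAY_LEVEL + amp * ifelse(s >= 0, 1, -1)
  }
  mv <- new_movie(frames, grating_name(direction, sf, tf), pixel_deg)
  attr(mv, "direction") <- direction
  attr(mv, "sf") <- sf
  attr(mv, "tf") <- tf
  attr(mv, "contrast") <- contrast
  mv
}

GRATING_TFS <- c(1, 2, 4, 8, 15)
GRATING_SFS <- c(0.025, 0.05, 0.1, 0.2, 0.4, 0.8)
GRATING_DIRS <- seq(0, 315, by = 45)

#' Grating id of a battery condition, and back
#'
#' The battery of 240 gratings is numbered g1..g240 with temporal frequency
#' varying fastest, then spatial frequency, then direction, over the grids
#' TF = \{1,2,4,8,15\} Hz, SF = \{0.025,0.05,0.1,0.2,0.4,0.8\} cpd,
#' direction = \{0,45,...,315\} degrees.
#'
#' @param direction,sf,tf Grid values of the condition.
#' @return `grating_name` returns the id string ("g8"); `grating_params`
#'   returns a list with `direction`, `sf`, `tf` for an id.
#' @export
grating_name <- function(direction, sf, tf) {
  di <- match(direction, GRATING_DIRS); si <- match(sf, GRATING_SFS); ti <- match(tf, GRATING_TFS)
  if (any(is.na(c(di, si, ti))))
    return(sprintf("grating_dir%g_sf%g_tf%g", direction, sf, tf))
  sprintf("g%d", (di - 1) * 30 + (si - 1) * 5 + ti)
}

#' @rdname grating_name
#' @param id Grating id string such as "g8", or the bare number.
#' @export
grating_params <- function(id) {
  k <- as.integer(sub("^g", "", id))
  if (is.na(k) || k < 1 || k > 240) stop("grating id must be g1..g240")
  k <- k - 1L
  list(direction = GRATING_DIRS[k %/% 30 + 1],
       sf = GRATING_SFS[(k %% 30) %/% 5 + 1],
       tf = GRATING_TFS[k %% 5 + 1])
}

#' Full-field flash movie
#'
#' Type 1: gray 0-1000 ms, white 1000-2000 ms, gray 2000-3000 ms.
#' Type 2: gray 0-600 ms, white 600-650 ms, gray 650-1500 ms.
#'
#' @param kind "flash_1" or "flash_2".
#' @param width,height,pixel_deg Frame geometry.
#' @return A `stimulus_movie`.
#' @export
make_flash <- function(kind = c("flash_1", "flash_2"), width = 192, height = 96,
                       pixel_deg = 1.25) {
  kind <- match.arg(kind)
  epochs <- if (kind == "flash_1") c(1000, 2000, 3000) else c(600, 650, 1500)
  frames <- array(GRAY_LEVEL, dim = c(width, height, epochs[3]))
  frames[, , (epochs[1] + 1):epochs[2]] <- 255
  new_movie(frames, kind, pixel_deg)
}

#' Moving bar movie
#'
#' A single white or black bar, about 4 degrees wide, on a gray background,
#' sweeping the full field at 33.8 degrees per second after a 500 ms gray
#' prefix. `axis = "vert"` is a vertical bar moving left to right; `"hor"` is
#' a horizontal bar moving bottom to top.
#'
#' @param color "white" or "black".
#' @param axis "vert" or "hor" (bar orientation).
#' @param bar_width Bar width in degrees.
#' @param speed Sweep speed in degrees per second.
#' @param width,height,pixel_deg Frame geometry.
#' @param gray_prefix Leading gray epoch in ms.
#' @return A `stimulus_movie` named e.g. "Wbar_v50pixps_vert".
#' @export
make_bar <- function(color = c("white", "black"), axis = c("vert", "hor"),
                     bar_width = 4, speed = 33.8, width = 192, height = 96,
                     pixel_deg = 1.25, gray_prefix = 500) {
  color <- match.arg(color); axis <- match.arg(axis)
  level <- if (color == "white") 255 else 0
  coord <- if (axis == "vert") pixel_axis(width, pixel_deg) else pixel_axis(height, pixel_deg)
  span <- range(coord)
  travel <- diff(span) + bar_width              # fully enters and exits
  dur <- ceiling(travel / (speed / 1000))
  nt <- as.integer(gray_prefix + dur)
  frames <- array(GRAY_LEVEL, dim = c(width, height, nt))
  for (i in seq_len(dur)) {
    pos <- span[1] - bar_width / 2 + (i - 1) * speed / 1000
    inside <- abs(coord - pos) <= bar_width / 2
    if (any(inside)) {
      if (axis == "vert") frames[inside, , gray_prefix + i] <- level
      else frames[, inside, gray_prefix + i] <- level
    }
  }
  nm <- sprintf("%sbar_v50pixps_%s", if (color == "white") "W" else "B", axis)
  new_movie(frames, nm, pixel_deg)
}

#' Uniform gray movie
#'
#' @param duration Total duration in ms (at least 500).
#' @param width,height,pixel_deg Frame geometry.
#' @return A `stimulus_movie` named "spont".
#' @export
make_gray <- function(duration = 1000, width = 192, height = 96, pixel_deg = 1.25) {
  if (duration < 500) stop("duration must be at least 500 ms")
  new_movie(array(GRAY_LEVEL, dim = c(width, height, as.integer(duration))),
            "spont", pixel_deg)
}
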