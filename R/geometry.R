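#' Default cell census of the layer 4 model
#'
#' Per-type cell counts of the default 45,000-cell network: three excitatory
#' core types (Scnn1a, Rorb, Nr5a1), two parvalbumin-positive interneuron core
#' types (PV1, PV2), and the excitatory/inhibitory point-neuron shell types.
#'
#' @return Named integer vector of counts, one per cell type.
#' @export
default_census <- function() {
  c(Scnn1a = 3700L, Rorb = 3300L, Nr5a1 = 1500L, PV1 = 800L, PV2 = 700L,
    LIF_exc = 29750L, LIF_inh = 5250L)
}

#' Default cylinder geometry (micrometers)
#'
#' The core types occupy an inner cylinder of 400 um radius; the shell types
#' occupy the annulus out to 845 um. The slab is 100 um high.
#'
#' @return List with `core_radius`, `shell_radius`, `height` in um.
#' @export
default_geometry <- function() {
  list(core_radius = 400, shell_radius = 845, height = 100)
}

cell_type_table <- function() {
  data.frame(
    cell_type = c("Scnn1a", "Rorb", "Nr5a1", "PV1", "PV2", "LIF_exc", "LIF_inh"),
    ei_class  = c("E", "E", "E", "I", "I", "E", "I"),
    is_core   = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Place cells in the model cylinder
#'
#' Distributes cells of each type uniformly at random (per unit volume) in
#' their region: core types in the inner cylinder, shell types in the annulus.
#' Cell ids are contiguous 0-based blocks per type in census order, so the
#' first Scnn1a cell is id 0.
#'
#' @param census Named integer vector of per-type counts (see
#'   [default_census()]). Names must be a subset of the seven known types.
#' @param geometry List with `core_radius`, `shell_radius`, `height` in um.
#' @param seed Integer seed; the same seed reproduces positions exactly.
#' @return A `cell_table` data.frame with columns `cell_id`, `cell_type`,
#'   `ei_class`, `x`, `y`, `z`, `is_core`, and (after [assign_tuning()])
#'   `theta_assigned`.
#' @export
place_cells <- function(census = default_census(), geometry = default_geometry(),
                        seed = 1L) {
  tt <- cell_type_table()
  if (is.null(names(census)) || !all(names(census) %in% tt$cell_type))
    stop("census must be named with known cell types")
  if (any(census < 0)) stop("census counts must be nonnegative")
  if (geometry$core_radius <= 0 || geometry$shell_radius <= geometry$core_radius ||
      geometry$height <= 0)
    stop("geometry radii must satisfy 0 < core_radius < shell_radius, height > 0")

  census <- census[census > 0]
  ord <- match(tt$cell_type, names(census))
  census <- census[ord[!is.na(ord)]]  # canonical type order

  if (length(census) == 0) {
    cells <- data.frame(cell_id = integer(0), cell_type = character(0),
                        ei_class = character(0), x = numeric(0), y = numeric(0),
                        z = numeric(0), is_core = logical(0))
    attr(cells, "geometry") <- geometry
    attr(cells, "seed") <- seed
    class(cells) <- c("cell_table", "data.frame")
    return(cells)
  }

  set.seed(seed)
  pieces <- lapply(names(census), function(ty) {
    n <- census[[ty]]
    core <- tt$is_core[tt$cell_type == ty]
    if (core) {
      r <- geometry$core_radius * sqrt(stats::runif(n))
    } else {
      r <- sqrt(stats::runif(n, geometry$core_radius^2, geometry$shell_radius^2))
    }
    phi <- stats::runif(n, 0, 2 * pi)
    data.frame(
      cell_type = ty,
      ei_class  = tt$ei_class[tt$cell_type == ty],
      x = r * cos(phi), y = r * sin(phi),
      z = stats::runif(n, 0, geometry$height),
      is_core = core,
      stringsAsFactors = FALSE
    )
  })
  cells <- do.call(rbind, pieces)
  cells <- cbind(cell_id = seq_len(nrow(cells)) - 1L, cells)
  attr(cells, "geometry") <- geometry
  attr(cells, "seed") <- seed
  class(cells) <- c("cell_table", "data.frame")
  cells
}

#' Assign preferred directions by linear tiling
#'
#' Within each cell type, the assigned preferred direction tiles \[0, 360)
#' degrees linearly over the type's id order: the first id of a type gets 0
#' degrees, and a type of size n steps by 360/n. Orientation, where a rule
#' needs it, is the direction modulo 180.
#'
#' @param cells A `cell_table` from [place_cells()].
#' @return The same table with a `theta_assigned` column (degrees, \[0, 360)).
#' @export
assign_tuning <- function(cells) {
  theta <- numeric(nrow(cells))
  for (ty in unique(cells$cell_type)) {
    idx <- which(cells$cell_type == ty)
    n <- length(idx)
    theta[idx[order(cells$cell_id[idx])]] <- (seq_len(n) - 1) * 360 / n
  }
  cells$theta_assigned <- theta
  cells
}

#' Fold a direction difference into orientation space
#'
#' Maps a difference of preferred directions (degrees) to the orientation
#' difference in \[0, 90\]: directions 180 degrees apart share an orientation.
#'
#' @param dtheta Numeric vector of direction differences in degrees.
#' @return Orientation differences in \[0, 90\] degrees.
#' @export
fold_delta_ori <- function(dtheta) {
  d <- abs(dtheta) %% 180
  pmin(d, 180 - d)
}

#' @export
print.cell_table <- function(x, ...) {
  g <- attr(x, "geometry")
  cat(sprintf("cell_table: %d cells (%d core, %d shell)\n",
              nrow(x), sum(x$is_core), sum(!x$is_core)))
  if (!is.null(g))
    cat(sprintf("  cylinder: core r <= %g um, shell r <= %g um, height %g um\n",
                g$core_radius, g$shell_radius, g$height))
  print(table(x$cell_type))
  invisible(x)
}
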