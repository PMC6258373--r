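#' Write and read model tables as CSV
#'
#' Flat-table serialization: cell tables (`cell_id`, `cell_type`, `ei_class`,
#' `x`, `y`, `z`, `is_core`, `theta_assigned`), connection sets (`src`, `tgt`,
#' `n_syn`, `weight`, `delay`; the rule tag, seed and class matrix go to a
#' JSON sidecar), and spike tables (`cell_id`, `time`, `trial`).
#'
#' @param x Object to write.
#' @param path CSV file path.
#' @name io
NULL

#' @rdname io
#' @export
write_cells_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_cells_csv <- function(path) {
  cells <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(cells) <- c("cell_table", "data.frame")
  cells
}

#' @rdname io
#' @param sidecar Optional JSON sidecar path for edge metadata (rule tag,
#'   seed, class matrix).
#' @param class_matrix Optional class matrix stored in the sidecar.
#' @export
write_edges_csv <- function(x, path, sidecar = NULL, class_matrix = NULL) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  if (!is.null(sidecar)) {
    meta <- list(rule = attr(x, "rule"), seed = attr(x, "seed"),
                 source = attr(x, "source"))
    if (!is.null(class_matrix))
      meta$class_matrix <- list(values = class_matrix,
                                rows = rownames(class_matrix),
                                cols = colnames(class_matrix))
    jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname io
#' @export
read_edges_csv <- function(path, sidecar = NULL) {
  edges <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(edges) <- c("connection_set", "data.frame")
  if (!is.null(sidecar) && file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    attr(edges, "rule") <- meta$rule
    attr(edges, "seed") <- meta$seed
  }
  edges
}

#' @rdname io
#' @export
write_spikes_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_spikes_csv <- function(path) utils::read.csv(path)

#' Serialize a wave schedule to JSON
#'
#' @param schedule A `wave_schedule`.
#' @param path JSON file path.
#' @export
write_schedule_json <- function(schedule, path) {
  jsonlite::write_json(list(footprint_radius = attr(schedule, "footprint_radius"),
                            total_time = attr(schedule, "total_time"),
                            waves = as.data.frame(schedule)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_schedule_json
#' @export
read_schedule_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  waves <- as.data.frame(obj$waves)
  attr(waves, "footprint_radius") <- obj$footprint_radius
  attr(waves, "total_time") <- obj$total_time
  class(waves) <- c("wave_schedule", "data.frame")
  waves
}

#' Serialize a class weight matrix to JSON
#'
#' @param class_matrix Base weight matrix.
#' @param path JSON file path.
#' @export
write_class_matrix_json <- function(class_matrix, path) {
  jsonlite::write_json(list(rows = rownames(class_matrix),
                            cols = colnames(class_matrix),
                            values = apply(class_matrix, 1, identity, simplify = FALSE)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_class_matrix_json
#' @export
read_class_matrix_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- do.call(rbind, obj$values)
  rownames(m) <- obj$rows
  colnames(m) <- obj$cols
  m
}
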