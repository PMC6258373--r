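#' Pairwise connection probability under a functional rule
#'
#' The probability of a directed connection is the product of a linear
#' distance-dependent factor and (for E-to-E pairs under the "L"
#' connection-probability rules) a linear orientation-difference factor.
#' The distance factor peaks at zero separation (0.34 for E-to-E and 0.26 for
#' E-to-I under LL/LR; 0.255 for both under RL/RR; 1.0 for inhibitory sources)
#' and falls linearly to zero at the cutoff (300 um for excitatory sources,
#' 160 um for inhibitory sources). Under LL/LR, the E-to-E orientation factor
#' falls linearly from 1 at 0 degrees difference to 0.5 at 90 degrees.
#'
#' @param src_class,tgt_class "E" or "I" (vectors recycle).
#' @param distance Planar intersomatic distance in um (nonnegative).
#' @param delta_ori Orientation difference in degrees, in \[0, 90\].
#' @param rule One of "LL", "LR", "RL", "RR". First letter: connectivity rule;
#'   second letter: weight rule (ignored here).
#' @return Probability in \[0, 1\], vectorized.
#' @export
connection_probability <- function(src_class, tgt_class, distance, delta_ori = 0,
                                   rule = c("LL", "LR", "RL", "RR")) {
  rule <- match.arg(rule)
  if (any(distance < 0)) stop("distance must be nonnegative")
  if (any(delta_ori < 0 | delta_ori > 90)) stop("delta_ori must lie in [0, 90]")
  like_prob <- substr(rule, 1, 1) == "L"
  n <- max(length(src_class), length(tgt_class), length(distance), length(delta_ori))
  src_class <- rep_len(src_class, n); tgt_class <- rep_len(tgt_class, n)
  distance <- rep_len(distance, n); delta_ori <- rep_len(delta_ori, n)

  peak <- ifelse(src_class == "I", 1,
                 ifelse(tgt_class == "E",
                        if (like_prob) 0.34 else 0.255,
                        if (like_prob) 0.26 else 0.255))
  cutoff <- ifelse(src_class == "E", 300, 160)
  p <- peak * pmax(0, 1 - distance / cutoff)
  ee <- src_class == "E" & tgt_class == "E"
  if (like_prob) p[ee] <- p[ee] * (1 - 0.5 * delta_ori[ee] / 90)
  pmin(pmax(p, 0), 1)
}

#' Build the recurrent connection set
#'
#' Draws one independent Bernoulli trial per ordered cell pair with
#' [connection_probability()], assigns each established edge a synapse count
#' uniform on the integers 3..7, and a fixed conduction delay. Self-edges are
#' excluded. Distances are computed in the x-y plane.
#'
#' @param cells A tuned `cell_table` (see [assign_tuning()]).
#' @param rule Connectivity/weight rule tag ("LL", "LR", "RL", "RR").
#' @param seed Integer seed; the same seed reproduces the edge list exactly.
#' @param delay Synaptic delay in ms applied to every recurrent edge.
#' @return A `connection_set` data.frame with columns `src`, `tgt` (cell ids),
#'   `n_syn`, `weight` (NA until [assign_weights()]), `delay`; sorted by `tgt`.
#' @export
build_recurrent <- function(cells, rule = c("LL", "LR", "RL", "RR"), seed = 1L,
                            delay = 1.0) {
  rule <- match.arg(rule)
  if (is.null(cells$theta_assigned)) stop("cells must be tuned; run assign_tuning() first")
  like_prob <- substr(rule, 1, 1) == "L"
  set.seed(seed)
  res <- build_recurrent_cpp(cells$x, cells$y,
                             as.integer(cells$ei_class == "I"), cells$theta_assigned,
                             if (like_prob) 0.34 else 0.255,
                             if (like_prob) 0.26 else 0.255,
                             300, 160, like_prob)
  # cpp works in row indices (0-based); map to cell ids
  edges <- data.frame(src = cells$cell_id[res$src + 1L],
                      tgt = cells$cell_id[res$tgt + 1L],
                      n_syn = res$n_syn,
                      weight = rep(NA_real_, length(res$src)),
                      delay = rep(delay, length(res$src)))
  edges <- edges[order(edges$tgt, edges$src), , drop = FALSE]
  rownames(edges) <- NULL
  attr(edges, "rule") <- rule
  attr(edges, "seed") <- seed
  class(edges) <- c("connection_set", "data.frame")
  edges
}

#' Default base synaptic weights per (source class, target type)
#'
#' Magnitudes of the per-synapse weight in normalized activation units
#' (threshold = 1), for the four source classes (recurrent E, recurrent I,
#' LGN, background) and the seven target types. These are calibration starting
#' points, refined by the [calibrate_lgn_weights()] /
#' [calibrate_background_weights()] / [calibrate_recurrent_weights()] stages.
#'
#' @param model "instantaneous" or "kinetic"; kinetic synapses spread each
#'   event over the synaptic time constants, so their starting magnitudes are
#'   larger.
#' @return Numeric matrix, rows E/I/LGN/BKG, columns the seven cell types.
#' @export
default_class_matrix <- function(model = c("instantaneous", "kinetic")) {
  model <- match.arg(model)
  types <- cell_type_table()$cell_type
  m <- matrix(0, nrow = 4, ncol = length(types),
              dimnames = list(c("E", "I", "LGN", "BKG"), types))
  m["E", ]   <- 0.002
  m["I", ]   <- 0.01
  m["LGN", ] <- 0.01
  m["BKG", ] <- 0.05
  if (model == "kinetic") m <- m / 4
  m
}

#' Assign synaptic weights to a connection set
#'
#' Every edge gets the base weight of its (source class, target type) pair;
#' inhibitory-source edges are negative. Under the "L" weight rules (LL, RL),
#' E-to-E weights are additionally multiplied by the like-to-like factor
#' F_w = exp(-(delta_theta)^2 / sigma_theta^2), with delta_theta the
#' orientation difference folded into \[0, 90\] degrees.
#'
#' @param conns A `connection_set` from [build_recurrent()].
#' @param class_matrix Base weight magnitudes (see [default_class_matrix()]);
#'   rows "E" and "I" are used here.
#' @param cells The `cell_table` the edges refer to.
#' @param rule Rule tag; the second letter selects the weight rule.
#' @param sigma_theta Width of the like-to-like weight factor in degrees.
#' @return The connection set with the `weight` column populated.
#' @export
assign_weights <- function(conns, class_matrix, cells, rule = attr(conns, "rule"),
                           sigma_theta = 50) {
  if (is.null(rule)) stop("rule must be supplied or stored on the connection set")
  idx_src <- conns$src + 1L
  idx_tgt <- conns$tgt + 1L
  src_class <- cells$ei_class[idx_src]
  tgt_type <- cells$cell_type[idx_tgt]
  miss <- setdiff(unique(tgt_type), colnames(class_matrix))
  if (length(miss) > 0) stop("class_matrix lacks target types: ", paste(miss, collapse = ", "))
  w <- class_matrix[cbind(match(src_class, rownames(class_matrix)),
                          match(tgt_type, colnames(class_matrix)))]
  w <- abs(w) * ifelse(src_class == "E", 1, -1)
  if (substr(rule, 2, 2) == "L") {
    ee <- src_class == "E" & cells$ei_class[idx_tgt] == "E"
    dori <- fold_delta_ori(cells$theta_assigned[idx_src[ee]] -
                           cells$theta_assigned[idx_tgt[ee]])
    w[ee] <- w[ee] * exp(-dori^2 / sigma_theta^2)
  }
  conns$weight <- w
  attr(conns, "sigma_theta") <- sigma_theta
  conns
}

#' Degree and synapse-count summary of a connection set
#'
#' @param conns A `connection_set`.
#' @param cells The `cell_table` the edges refer to.
#' @param core_only If TRUE, summary statistics are computed over core cells
#'   only (cells in the inner cylinder have complete neighborhoods, which is
#'   the population the reported degree statistics describe); per-cell values
#'   are always returned for all cells.
#' @return List with `per_cell` (cell_id, in_deg, out_deg, syn_in), `by_class`
#'   and `by_type` data.frames of mean/sd in-degree, out-degree and incoming
#'   synapse totals.
#' @export
degree_summary <- function(conns, cells, core_only = FALSE) {
  n <- nrow(cells)
  in_deg <- tabulate(conns$tgt + 1L, nbins = n)
  out_deg <- tabulate(conns$src + 1L, nbins = n)
  syn_in <- numeric(n)
  if (nrow(conns) > 0) {
    agg <- rowsum(as.numeric(conns$n_syn), conns$tgt)
    syn_in[as.integer(rownames(agg)) + 1L] <- agg[, 1]
  }
  per_cell <- data.frame(cell_id = cells$cell_id, cell_type = cells$cell_type,
                         ei_class = cells$ei_class, is_core = cells$is_core,
                         in_deg = in_deg, out_deg = out_deg, syn_in = syn_in)
  sub <- if (core_only) per_cell[per_cell$is_core, ] else per_cell
  summarize <- function(key) {
    do.call(rbind, lapply(split(sub, sub[[key]]), function(d) {
      data.frame(group = d[[key]][1], n = nrow(d),
                 in_deg_mean = mean(d$in_deg), in_deg_sd = stats::sd(d$in_deg),
                 out_deg_mean = mean(d$out_deg), out_deg_sd = stats::sd(d$out_deg),
                 syn_in_mean = mean(d$syn_in), syn_in_sd = stats::sd(d$syn_in))
    }))
  }
  list(per_cell = per_cell, by_class = summarize("ei_class"), by_type = summarize("cell_type"))
}

#' @export
print.connection_set <- function(x, ...) {
  cat(sprintf("connection_set: %d edges", nrow(x)))
  if (!is.null(attr(x, "rule"))) cat(sprintf(" [rule %s]", attr(x, "rule")))
  cat("\n")
  if (nrow(x) > 0)
    cat(sprintf("  n_syn in [%d, %d]; weights %s\n", min(x$n_syn), max(x$n_syn),
                if (all(is.na(x$weight))) "unassigned" else "assigned"))
  invisible(x)
}
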