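# Deterministic trajectories and flip attribution ---------------------------

#' Default trajectory start state of the CLL model
#'
#' All nodes zero except the B-cell receptor, reflecting the model's
#' dependency on BCR stimulation.
#'
#' @param net a `boolean_network`.
#' @param on nodes set to 1 (default `"BCR"`).
#' @export
bcr_start_state <- function(net, on = "BCR") {
  idx <- match(on, net$nodes)
  if (anyNA(idx)) stop("unknown node(s): ", paste(on[is.na(idx)], collapse = ", "))
  s <- setNames(rep(0L, length(net$nodes)), net$nodes)
  s[idx] <- 1L
  s
}

#' Record the deterministic trajectory from a start state
#'
#' The full path of states from `start` up to and including one complete
#' traversal of the terminal attractor is recorded, together with per-step
#' node flips and the phenotype of the terminal attractor.
#'
#' @param net a `boolean_network`.
#' @param start 0/1 state vector.
#' @param indicators role -> node mapping for terminal-phenotype
#'   classification, or `NULL` to skip.
#' @param max_iter iteration cap.
#' @return a `trajectory`: list with `states` (matrix, one row per time
#'   step), `attractor_entry_index` (row index of the first cycle state),
#'   `attractor`, `phenotype` and `flips` (see [attribute_flips()]).
#' @export
trajectory <- function(net, start, indicators = NULL, max_iter = NULL) {
  start <- .check_state(net, start)
  if (is.null(max_iter))
    max_iter <- max(2L^min(length(net$nodes), 20L), 10000L)
  tr <- cpp_trajectory(.cpp_net(net), start, as.integer(max_iter))
  states <- tr$states
  colnames(states) <- net$nodes
  cyc_codes <- apply(states[seq(tr$transient + 1L,
                                tr$transient + tr$cycle_length), , drop = FALSE],
                     1L, state_to_index)
  rot <- which.min(cyc_codes)
  cyc_codes <- cyc_codes[c(seq(rot, length(cyc_codes)), seq_len(rot - 1L))]
  att <- .make_attractor(net, cyc_codes)
  out <- structure(list(states = states,
                        attractor_entry_index = tr$transient + 1L,
                        attractor = att,
                        phenotype = NULL,
                        flips = NULL),
                   class = "trajectory")
  if (!is.null(indicators) ||
      all(cll_indicators() %in% net$nodes)) {
    ind <- if (is.null(indicators)) cll_indicators() else indicators
    if (all(ind %in% net$nodes))
      out$phenotype <- classify_phenotype(att, ind)
  }
  out$flips <- attribute_flips(net, out)
  out
}

#' @export
print.trajectory <- function(x, ...) {
  cat("Trajectory:", nrow(x$states), "recorded states, attractor entered at",
      "step", x$attractor_entry_index - 1L,
      "(cycle length", x$attractor$length, ")\n")
  if (!is.null(x$phenotype))
    cat("Terminal phenotype:", x$phenotype$label, "\n")
  invisible(x)
}

#' Attribute node flips along a trajectory to their regulators
#'
#' For every step and every node whose value changed, the responsible
#' regulators are identified: among the regulators that themselves changed
#' in the preceding step, each is toggled back one at a time and the node's
#' function re-evaluated; regulators whose toggle reverts the output are
#' reported.  Flips of clamped nodes are attributed to `"intervention"`.
#'
#' @param net the `boolean_network` that produced the trajectory.
#' @param traj a `trajectory` (or a state matrix with one row per step).
#' @return data.frame with columns `step` (the time index of the new
#'   value), `node`, `from`, `to`, `regulators` (comma-separated active
#'   attribution), `regulator_values` (their values at the previous step).
#' @export
attribute_flips <- function(net, traj) {
  states <- if (inherits(traj, "trajectory")) traj$states else traj
  if (nrow(states) < 2L) {
    return(data.frame(step = integer(0), node = character(0),
                      from = integer(0), to = integer(0),
                      regulators = character(0),
                      regulator_values = character(0)))
  }
  rows <- list()
  for (t in 2:nrow(states)) {
    prev <- states[t - 1L, ]
    cur <- states[t, ]
    flipped <- which(prev != cur)
    for (i in flipped) {
      if (!is.na(net$fixed[i])) {
        rows[[length(rows) + 1L]] <- data.frame(
          step = t - 1L, node = net$nodes[i], from = prev[i], to = cur[i],
          regulators = "intervention", regulator_values = "")
        next
      }
      reg <- net$regulators[[i]]
      changed_reg <- if (t >= 3L)
        reg[states[t - 2L, reg] != prev[reg]] else reg
      responsible <- integer(0)
      for (r in changed_reg) {
        toggled <- prev
        toggled[r] <- 1L - toggled[r]
        if (evaluate_node(net, net$nodes[i], toggled) != cur[i])
          responsible <- c(responsible, r)
      }
      if (!length(responsible)) responsible <- changed_reg
      if (!length(responsible)) responsible <- reg
      rows[[length(rows) + 1L]] <- data.frame(
        step = t - 1L, node = net$nodes[i], from = prev[i], to = cur[i],
        regulators = paste(net$nodes[responsible], collapse = ","),
        regulator_values = paste(prev[responsible], collapse = ","))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(step = integer(0), node = character(0), from = integer(0),
               to = integer(0), regulators = character(0),
               regulator_values = character(0))
  rownames(out) <- NULL
  out
}
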