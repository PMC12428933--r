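# Attractor detection and landscape construction ---------------------------

.make_attractor <- function(net, codes) {
  n <- length(net$nodes)
  states <- matrix(unlist(lapply(codes, index_to_state, n = n)),
                   ncol = n, byrow = TRUE)
  colnames(states) <- net$nodes
  structure(list(codes = as.numeric(codes),
                 states = states,
                 length = length(codes),
                 canonical_key = paste(codes, collapse = ",")),
            class = "attractor")
}

#' @export
print.attractor <- function(x, ...) {
  kind <- if (x$length == 1L) "fixed point" else paste0(x$length, "-cycle")
  cat("Attractor (", kind, ")\n", sep = "")
  print(x$states)
  invisible(x)
}

.make_landscape <- function(net, cycles, basin, exact, n_samples = NA,
                            seed = NA) {
  attractors <- lapply(cycles, function(cc) .make_attractor(net, cc))
  # deterministic order: by canonical first code
  ord <- order(vapply(cycles, function(cc) cc[1L], numeric(1)))
  attractors <- attractors[ord]
  basin <- as.numeric(basin)[ord]
  structure(list(attractors = attractors,
                 basin_counts = basin,
                 basin_ratios = basin / sum(basin),
                 exact = exact,
                 n_samples = n_samples,
                 seed = seed,
                 nodes = net$nodes),
            class = "attractor_landscape")
}

#' @export
print.attractor_landscape <- function(x, ...) {
  cat("Attractor landscape:", length(x$attractors), "attractor(s),",
      if (x$exact) "exhaustive basins" else
        paste0("basins estimated from ", format(x$n_samples, big.mark = ","),
               " random starts"), "\n")
  for (i in seq_along(x$attractors)) {
    a <- x$attractors[[i]]
    cat(sprintf("  #%d length %d basin %.4f\n", i, a$length, x$basin_ratios[i]))
  }
  invisible(x)
}

#' Follow the deterministic dynamics from a start state to its attractor
#'
#' @param net a `boolean_network`.
#' @param start 0/1 state vector.
#' @param max_iter iteration cap; synchronous dynamics on a finite state
#'   space must cycle, so exceeding the cap signals a bug and raises an
#'   error.
#' @return a list with elements `attractor` (class `attractor`) and
#'   `transient` (number of steps before the first cycle state).
#' @export
find_attractor_from <- function(net, start, max_iter = NULL) {
  start <- .check_state(net, start)
  if (is.null(max_iter))
    max_iter <- max(2L^min(length(net$nodes), 20L), 10000L)
  tr <- cpp_trajectory(.cpp_net(net), start, as.integer(max_iter))
  cyc <- tr$states[seq(tr$transient + 1L, tr$transient + tr$cycle_length), ,
                   drop = FALSE]
  codes <- apply(cyc, 1L, state_to_index)
  rot <- which.min(codes)
  codes <- codes[c(seq(rot, length(codes)), seq_len(rot - 1L))]
  list(attractor = .make_attractor(net, codes), transient = tr$transient)
}

#' Exhaustive attractor landscape over all 2^n states
#'
#' Every state of the full state space is assigned to exactly one attractor,
#' so basin counts sum to `2^n`.  Intended as a small-network oracle.
#'
#' @param net a `boolean_network`.
#' @param max_nodes refuse larger networks (default 20); use
#'   [sampled_attractors()] beyond that.
#' @return an `attractor_landscape` with `exact = TRUE`.
#' @export
exhaustive_attractors <- function(net, max_nodes = 20L) {
  stopifnot(inherits(net, "boolean_network"))
  n <- length(net$nodes)
  if (n > max_nodes)
    stop("network has ", n, " nodes; exhaustive enumeration is limited to ",
         max_nodes, " - use sampled_attractors()")
  res <- cpp_exhaustive(.cpp_net(net))
  .make_landscape(net, res$cycles, res$basin, exact = TRUE)
}

#' Attractor landscape estimated from random start states
#'
#' Attractors are discovered by following the dynamics from uniformly random
#' start states; each attractor's basin ratio is the fraction of starts that
#' converged to it.  Attractors with very small basins can be missed; the
#' number of samples is recorded so coverage can be judged.
#'
#' @param net a `boolean_network`.
#' @param n_samples number of random start states.
#' @param seed optional integer seed (applied via [set.seed()]).
#' @param max_iter per-walk iteration cap.
#' @return an `attractor_landscape` with `exact = FALSE`.
#' @export
sampled_attractors <- function(net, n_samples, seed = NULL, max_iter = 100000L) {
  stopifnot(inherits(net, "boolean_network"), n_samples >= 1)
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_sample_attractors(.cpp_net(net), as.numeric(n_samples),
                               as.integer(max_iter))
  .make_landscape(net, res$cycles, res$basin, exact = FALSE,
                  n_samples = n_samples,
                  seed = if (is.null(seed)) NA else seed)
}

#' Basin-weighted per-node activity of a landscape
#'
#' Each node's activity is its mean value over every attractor's cycle
#' states, weighted by the attractor's basin ratio — the "fused" collapsed
#' representation of a landscape.
#'
#' @param landscape an `attractor_landscape`.
#' @return named numeric vector of activities in `[0, 1]`.
#' @export
fuse_landscape <- function(landscape) {
  stopifnot(inherits(landscape, "attractor_landscape"))
  acts <- vapply(landscape$attractors, function(a) colMeans(a$states),
                 numeric(length(landscape$nodes)))
  out <- as.numeric(acts %*% landscape$basin_ratios)
  setNames(out, landscape$nodes)
}
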