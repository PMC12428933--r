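# Bit-flip robustness against random N-K networks ---------------------------

#' Normalized Hamming distance between two states
#'
#' The number of differing bits divided by the vector length; a metric on
#' states scaled to `[0, 1]`.
#'
#' @param x,y 0/1 vectors of equal length.
#' @export
normalized_hamming <- function(x, y) {
  if (length(x) != length(y)) stop("state lengths differ")
  sum(as.integer(x) != as.integer(y)) / length(x)
}

#' One-step response to single bit-flip perturbations
#'
#' For each of `n_states` uniformly random states, one uniformly chosen bit
#' is flipped, both the original and the perturbed state are advanced one
#' synchronous step, and the normalized Hamming distance between the two
#' successors is recorded.
#'
#' @param net a `boolean_network`.
#' @param n_states number of random states.
#' @param seed optional integer seed.
#' @return numeric vector of `n_states` distances in `[0, 1]`.
#' @export
bitflip_response <- function(net, n_states = 1000L, seed = NULL) {
  stopifnot(inherits(net, "boolean_network"), n_states >= 1)
  if (!is.null(seed)) set.seed(seed)
  as.numeric(cpp_bitflip(.cpp_net(net), as.integer(n_states)))
}

#' Generate a random N-K Boolean network
#'
#' Node `i` receives `k[i]` distinct regulators drawn uniformly from all
#' nodes, and a truth table whose entries are independent fair coin flips.
#' Such networks serve as the topology-matched null model for robustness
#' testing.
#'
#' @param n number of nodes.
#' @param k per-node in-degree: a scalar or a length-`n` vector (entries may
#'   be 0, giving a constant node).
#' @param seed optional integer seed.
#' @return a `boolean_network` (functions are rendered as minterm
#'   expressions of their truth tables).
#' @export
random_nk_network <- function(n, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- as.integer(rep_len(k, n))
  if (any(k > n)) stop("in-degree k cannot exceed n")
  if (any(k < 0L)) stop("in-degree k must be nonnegative")
  nodes <- paste0("N", seq_len(n))
  regulators <- lapply(k, function(ki) sort(sample.int(n, ki)))
  truth <- lapply(k, function(ki) as.integer(rbinom(2L^ki, 1L, 0.5)))
  .network_from_tables(nodes, regulators, truth)
}

# Build a boolean_network directly from regulator lists + truth tables,
# synthesizing minterm expression text so the network serializes.  Drawn
# regulators are kept even when the random truth table happens to be
# constant (rendered as contradiction/tautology clauses over them): the
# structural in-degree of an N-K draw is part of the null model and must
# survive serialization.
.network_from_tables <- function(nodes, regulators, truth) {
  n <- length(nodes)
  functions <- character(n)
  exprs <- vector("list", n)
  mk_var <- function(nm) list(op = "var", name = nm)
  mk_not <- function(e) list(op = "not", args = list(e))
  mk_bin <- function(op, args)
    if (length(args) == 1L) args[[1L]] else list(op = op, args = args)
  for (i in seq_len(n)) {
    reg <- regulators[[i]]
    tt <- truth[[i]]
    if (length(reg) == 0L) {
      exprs[[i]] <- list(op = "const", value = tt[1L])
      functions[i] <- as.character(tt[1L])
      next
    }
    on <- which(tt == 1L) - 1L
    if (length(on) == 0L) {
      # contradiction over every drawn regulator
      exprs[[i]] <- mk_bin("or", lapply(nodes[reg], function(nm)
        mk_bin("and", list(mk_var(nm), mk_not(mk_var(nm))))))
    } else if (length(on) == 2L^length(reg)) {
      # tautology over every drawn regulator
      exprs[[i]] <- mk_bin("and", lapply(nodes[reg], function(nm)
        mk_bin("or", list(mk_var(nm), mk_not(mk_var(nm))))))
    } else {
      exprs[[i]] <- mk_bin("or", lapply(on, function(code) {
        bits <- bitwAnd(bitwShiftR(code, seq_along(reg) - 1L), 1L)
        mk_bin("and", lapply(seq_along(reg), function(j)
          if (bits[j] == 1L) mk_var(nodes[reg[j]])
          else mk_not(mk_var(nodes[reg[j]]))))
      }))
    }
    functions[i] <- NA_character_
  }
  # expression text is only needed for display/serialization; render lazily
  # here since deparsing is cheap relative to parsing
  todo <- is.na(functions)
  functions[todo] <- vapply(exprs[todo], .deparse_expr, "")
  net <- list(nodes = nodes,
              functions = setNames(functions, nodes),
              exprs = exprs,
              regulators = regulators,
              truth = truth,
              fixed = setNames(rep(NA_integer_, n), nodes))
  class(net) <- "boolean_network"
  net
}

#' In-, out- and total degree of every node
#'
#' The in-degree of a node is the number of distinct nodes referenced by its
#' function (self-loops count once); the out-degree is the number of
#' functions that reference it.
#'
#' @param net a `boolean_network`.
#' @return data.frame with columns `node`, `in_degree`, `out_degree`,
#'   `total_degree`.
#' @export
degree_distribution <- function(net) {
  stopifnot(inherits(net, "boolean_network"))
  n <- length(net$nodes)
  indeg <- vapply(net$regulators, length, integer(1))
  outdeg <- tabulate(unlist(net$regulators), nbins = n)
  data.frame(node = net$nodes, in_degree = indeg, out_degree = outdeg,
             total_degree = indeg + outdeg)
}

#' Robustness of a network relative to matched random N-K networks
#'
#' The reference network's mean one-step bit-flip distance (over `n_states`
#' random states) is compared with the same summary for `n_networks` random
#' N-K networks matching the reference's node count and per-node in-degree
#' multiset.  Smaller distances mean higher robustness; the empirical
#' p-value is the fraction of null networks at least as robust as the
#' reference.
#'
#' @param net a `boolean_network`.
#' @param n_networks number of random null networks.
#' @param n_states number of bit-flip trials per network.
#' @param seed optional integer seed.
#' @param k per-node in-degrees of the null networks; defaults to the
#'   reference network's own in-degrees.
#' @return a `robustness_result`: list with `observed` (mean distance),
#'   `observed_distances`, `null` (per-network mean distances), `p_value`
#'   (add-one corrected), `p_uncorrected`, `q05` (5% quantile of the null),
#'   and the parameters.
#' @export
robustness_test <- function(net, n_networks = 1000L, n_states = 1000L,
                            seed = NULL, k = NULL) {
  stopifnot(inherits(net, "boolean_network"))
  if (!is.null(seed)) set.seed(seed)
  n <- length(net$nodes)
  if (is.null(k)) k <- vapply(net$regulators, length, integer(1))
  k <- rep_len(as.integer(k), n)
  obs_d <- bitflip_response(net, n_states)
  null <- numeric(n_networks)
  for (j in seq_len(n_networks)) {
    rn <- random_nk_network(n, k)
    null[j] <- mean(bitflip_response(rn, n_states))
  }
  obs <- mean(obs_d)
  structure(list(observed = obs,
                 observed_distances = obs_d,
                 null = null,
                 p_value = (1 + sum(null <= obs)) / (n_networks + 1),
                 p_uncorrected = mean(null <= obs),
                 q05 = unname(quantile(null, 0.05)),
                 n_states = n_states, n_networks = n_networks,
                 seed = if (is.null(seed)) NA else seed),
            class = "robustness_result")
}

#' @export
print.robustness_result <- function(x, ...) {
  cat(sprintf(paste0("Bit-flip robustness: observed mean distance %.4f vs ",
                     "null 5%% quantile %.4f (%d networks)\n  p = %.4g ",
                     "(uncorrected %.4g)\n"),
              x$observed, x$q05, x$n_networks, x$p_value, x$p_uncorrected))
  invisible(x)
}
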