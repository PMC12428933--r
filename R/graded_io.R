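# Graded input-output analysis ----------------------------------------------
#
# Boolean inputs are softened into duty cycles: an input node at p% activity
# is overridden with a realized ON/OFF sequence containing exactly
# round(p*T/100) ON steps out of T, placed by a seeded uniform shuffle (one
# fresh realization per starting state, avoiding phase locking).  Output
# activity is the mean ON ratio over the last `window` steps, averaged over
# random starting states.

#' Realize a duty-cycle schedule
#'
#' @param percent integer activity percentage in 1..100.
#' @param t_steps number of simulated steps.
#' @return 0/1 vector of length `t_steps` with exactly
#'   `round(percent * t_steps / 100)` ones, in shuffled positions (uses the
#'   current RNG state).
#' @export
realize_schedule <- function(percent, t_steps) {
  if (percent < 1 || percent > 100) stop("percent must be in 1..100")
  n_on <- round(percent * t_steps / 100)
  seq_on <- c(rep(1L, n_on), rep(0L, t_steps - n_on))
  seq_on[sample.int(t_steps)]
}

#' Simulate with graded input schedules
#'
#' @param net a `boolean_network`.
#' @param schedules named integer vector of activity percentages (1..100),
#'   one or two entries, named by input node.
#' @param n_starts number of random starting states.
#' @param t_steps simulated steps per start.
#' @param window number of trailing steps over which activity is averaged.
#' @param seed optional integer seed.
#' @return named numeric vector: per-node mean activity in `[0, 1]`.
#' @export
graded_simulation <- function(net, schedules, n_starts = 250L, t_steps = 500L,
                              window = 100L, seed = NULL) {
  stopifnot(inherits(net, "boolean_network"))
  if (is.null(names(schedules)) || any(!nzchar(names(schedules))))
    stop("schedules must be named by input node")
  if (anyDuplicated(names(schedules))) stop("scheduled nodes must be distinct")
  nodes_idx <- match(names(schedules), net$nodes)
  if (anyNA(nodes_idx))
    stop("unknown scheduled node(s): ",
         paste(names(schedules)[is.na(nodes_idx)], collapse = ", "))
  if (any(!is.na(net$fixed[nodes_idx])))
    stop("scheduled node(s) also fixed by an intervention: ",
         paste(names(schedules)[!is.na(net$fixed[nodes_idx])], collapse = ", "))
  if (window > t_steps) stop("window must not exceed t_steps")
  if (!is.null(seed)) set.seed(seed)
  cn <- .cpp_net(net)
  n <- length(net$nodes)
  acc <- numeric(n)
  for (s in seq_len(n_starts)) {
    start <- sample(0:1, n, replace = TRUE)
    sched <- vapply(unname(schedules), realize_schedule, integer(t_steps),
                    t_steps = t_steps)
    acc <- acc + as.numeric(cpp_graded_one(cn, start, sched,
                                           as.integer(nodes_idx),
                                           as.integer(window)))
  }
  setNames(acc / n_starts, net$nodes)
}

#' Two-input graded activity grid
#'
#' Runs one [graded_simulation()] per combination of input percentages and
#' collects the output activities in long format, suitable for heatmap
#' plotting.  Each grid cell uses a sub-seed derived from the master seed
#' and the cell coordinates, so cells are independent of evaluation order.
#'
#' @param net a `boolean_network`.
#' @param input1,input2 names of the two (distinct) graded input nodes.
#' @param percents integer percentages for both axes (default
#'   `seq(5, 100, by = 5)`); a single resolution number `r` is expanded to
#'   `seq(r, 100, by = r)`.
#' @param outputs output node names (default: all non-input nodes).
#' @param n_starts,t_steps,window simulation parameters, see
#'   [graded_simulation()].
#' @param seed master integer seed.
#' @return data.frame with columns `input1_pct`, `input2_pct`, `node`,
#'   `activity`.
#' @export
io_grid <- function(net, input1, input2, percents = seq(5L, 100L, by = 5L),
                    outputs = NULL, n_starts = 250L, t_steps = 500L,
                    window = 100L, seed = NULL) {
  stopifnot(inherits(net, "boolean_network"))
  if (identical(input1, input2)) stop("the two graded inputs must differ")
  if (length(percents) == 1L && percents < 100L)
    percents <- seq(as.integer(percents), 100L, by = as.integer(percents))
  if (is.null(outputs)) outputs <- setdiff(net$nodes, c(input1, input2))
  missing_out <- setdiff(outputs, net$nodes)
  if (length(missing_out))
    stop("unknown output node(s): ", paste(missing_out, collapse = ", "))
  rows <- vector("list", length(percents)^2)
  pos <- 1L
  for (i in seq_along(percents)) {
    for (j in seq_along(percents)) {
      cell_seed <- if (is.null(seed)) NULL else
        (abs(seed) %% 65521L + i * 40503L + j * 10007L) %% 2147483647L
      act <- graded_simulation(net,
                               setNames(c(percents[i], percents[j]),
                                        c(input1, input2)),
                               n_starts = n_starts, t_steps = t_steps,
                               window = window, seed = cell_seed)
      rows[[pos]] <- data.frame(input1_pct = percents[i],
                                input2_pct = percents[j],
                                node = outputs,
                                activity = unname(act[outputs]))
      pos <- pos + 1L
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "inputs") <- c(input1, input2)
  attr(out, "params") <- list(n_starts = n_starts, t_steps = t_steps,
                              window = window,
                              seed = if (is.null(seed)) NA else seed)
  out
}
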