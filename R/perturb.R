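# KO/KI interventions and the exhaustive driver / drug-target screen --------

#' Construct an intervention (set of clamped nodes)
#'
#' @param ... named 0/1 values, e.g. `intervention(TP53 = 0, BMI1 = 1)`;
#'   0 is a knockout, 1 a knockin.
#' @param values alternatively, a named vector.
#' @export
intervention <- function(..., values = NULL) {
  v <- if (is.null(values)) c(...) else values
  if (length(v) < 1L) stop("an intervention needs at least one assignment")
  if (is.null(names(v)) || any(!nzchar(names(v))))
    stop("intervention values must be named by node")
  if (anyDuplicated(names(v))) {
    dup <- unique(names(v)[duplicated(names(v))])
    conflicting <- vapply(dup, function(d) length(unique(v[names(v) == d])) > 1L,
                          logical(1))
    if (any(conflicting))
      stop("conflicting assignments for node(s): ",
           paste(dup[conflicting], collapse = ", "))
    v <- v[!duplicated(names(v))]
  }
  if (any(!(v %in% c(0, 1)))) stop("intervention values must be 0 or 1")
  structure(setNames(as.integer(v), names(v)), class = "intervention")
}

#' Apply an intervention to a network
#'
#' @param net a `boolean_network`.
#' @param iv an [intervention()] or named 0/1 vector.
#' @return a new network with the nodes clamped; `net` is untouched.
#' @export
apply_interventions <- function(net, iv) {
  if (!inherits(iv, "intervention")) iv <- intervention(values = iv)
  fix_nodes(net, iv)
}

#' Enumerate all interventions of up to m hits over c candidate nodes
#'
#' Produces every assignment of 0/1 values to every subset of 1..m nodes,
#' `sum_{i=1..m} choose(c, i) * 2^i` interventions in total, in a
#' deterministic order (subsets in lexicographic node-index order, values in
#' binary counting order).
#'
#' @param nodes character vector of candidate node names, or a node count
#'   (names `N1..Nc` are generated).
#' @param m maximum number of simultaneous hits.
#' @return list of [intervention()] objects.
#' @export
enumerate_interventions <- function(nodes, m) {
  if (is.numeric(nodes) && length(nodes) == 1L)
    nodes <- paste0("N", seq_len(nodes))
  c_ <- length(nodes)
  if (c_ < 1L) stop("need at least one candidate node")
  if (m < 1L || m > c_) stop("m must satisfy 1 <= m <= ", c_)
  out <- vector("list", sum(choose(c_, seq_len(m)) * 2^seq_len(m)))
  pos <- 1L
  for (i in seq_len(m)) {
    subsets <- combn(c_, i)
    vals <- as.matrix(expand.grid(rep(list(0:1), i), KEEP.OUT.ATTRS = FALSE))
    # binary counting order: first column is the least-significant bit in
    # expand.grid; reorder so value patterns count up per subset
    for (s in seq_len(ncol(subsets))) {
      nm <- nodes[subsets[, s]]
      for (vrow in seq_len(nrow(vals))) {
        out[[pos]] <- intervention(values = setNames(vals[vrow, ], nm))
        pos <- pos + 1L
      }
    }
  }
  out
}

#' Closed-form size of the intervention enumeration
#' @param c_ number of candidate nodes.
#' @param m maximum hits.
#' @export
n_interventions <- function(c_, m) sum(choose(c_, seq_len(m)) * 2^seq_len(m))

#' Screening criteria on perturbed attractor landscapes
#'
#' @param forbidden_phenotypes labels whose basin fraction must be exactly 0
#'   (no attractor may contain a cycle state of that phenotype).
#' @param required_phenotype optional `list(label =, min_fraction =)`: the
#'   basin fraction of attractors whose precedence-dominant label matches
#'   must reach `min_fraction`.
#' @param node_constraints named 0/1 vector: each node must hold that value
#'   in every cycle state of every attractor (e.g. `c(SPhase = 1)` for a
#'   fully proliferative landscape).
#' @export
screen_criteria <- function(forbidden_phenotypes = character(0),
                            required_phenotype = NULL,
                            node_constraints = NULL) {
  bad <- setdiff(forbidden_phenotypes, .phenotype_levels)
  if (length(bad)) stop("unknown phenotype label(s): ", paste(bad, collapse = ", "))
  if (!is.null(required_phenotype)) {
    if (!all(c("label", "min_fraction") %in% names(required_phenotype)))
      stop("required_phenotype needs 'label' and 'min_fraction'")
    if (required_phenotype$label %in% forbidden_phenotypes)
      stop("phenotype ", sQuote(required_phenotype$label),
           " cannot be both required and forbidden")
  }
  structure(list(forbidden_phenotypes = forbidden_phenotypes,
                 required_phenotype = required_phenotype,
                 node_constraints = node_constraints),
            class = "screen_criteria")
}

.criteria_satisfied <- function(landscape, criteria, indicators) {
  needs_calls <- length(criteria$forbidden_phenotypes) ||
    !is.null(criteria$required_phenotype)
  calls <- if (needs_calls)
    lapply(landscape$attractors, classify_phenotype, indicators = indicators)
  if (length(criteria$forbidden_phenotypes)) {
    present <- unique(unlist(lapply(calls, `[[`, "state_labels")))
    if (any(criteria$forbidden_phenotypes %in% present)) return(FALSE)
  }
  if (!is.null(criteria$required_phenotype)) {
    dom <- vapply(calls, `[[`, "", "dominant")
    frac <- sum(landscape$basin_ratios[dom == criteria$required_phenotype$label])
    if (frac < criteria$required_phenotype$min_fraction) return(FALSE)
  }
  if (!is.null(criteria$node_constraints)) {
    for (nd in names(criteria$node_constraints)) {
      want <- criteria$node_constraints[[nd]]
      ok <- all(vapply(landscape$attractors,
                       function(a) all(a$states[, nd] == want), logical(1)))
      if (!ok) return(FALSE)
    }
  }
  TRUE
}

#' Exhaustive single/multi-hit intervention screen
#'
#' Enumerates every intervention of up to `m` hits over the candidate nodes,
#' recomputes the perturbed attractor landscape for each, and returns the
#' interventions whose landscape satisfies all criteria.  The driver screen
#' of the CLL model uses `forbidden_phenotypes = "anergy"` together with
#' `node_constraints = c(SPhase = 1)`; the drug-target screen forbids
#' `proliferation` or requires `apoptosis`.
#'
#' @param net a `boolean_network`.
#' @param criteria a [screen_criteria()].
#' @param m maximum simultaneous hits.
#' @param candidates candidate node names (default: all nodes without a
#'   fixed value, excluding `exclude`).
#' @param exclude optional nodes to leave out (e.g. indicator nodes or
#'   combinations judged biologically meaningless).
#' @param basin_method `"exhaustive"` (small networks) or `"sampled"`.
#' @param n_samples samples per landscape when `basin_method = "sampled"`.
#'   With sampled basins a phenotype counts as eliminated when its estimated
#'   basin fraction is exactly 0 among the samples.
#' @param seed master seed; per-intervention sub-seeds are derived from it
#'   so results do not depend on evaluation order.
#' @param indicators role -> node mapping.
#' @return data.frame with one row per passing intervention: a compact
#'   intervention string, hit count, number of attractors, and phenotype
#'   basin fractions.  The intervention objects are attached as the
#'   `interventions` attribute.
#' @export
screen_interventions <- function(net, criteria, m = 2L,
                                 candidates = NULL, exclude = character(0),
                                 basin_method = c("exhaustive", "sampled"),
                                 n_samples = 100000L, seed = NULL,
                                 indicators = cll_indicators()) {
  stopifnot(inherits(net, "boolean_network"), inherits(criteria, "screen_criteria"))
  basin_method <- match.arg(basin_method)
  if (is.null(candidates))
    candidates <- net$nodes[is.na(net$fixed)]
  candidates <- setdiff(candidates, exclude)
  ivs <- enumerate_interventions(candidates, m)
  keep <- logical(length(ivs))
  rows <- vector("list", length(ivs))
  for (i in seq_along(ivs)) {
    pert <- apply_interventions(net, ivs[[i]])
    ls <- if (basin_method == "exhaustive") {
      exhaustive_attractors(pert)
    } else {
      sub_seed <- if (is.null(seed)) NULL else (seed + i * 9973L) %% 2147483647L
      sampled_attractors(pert, n_samples, seed = sub_seed)
    }
    if (.criteria_satisfied(ls, criteria, indicators)) {
      keep[i] <- TRUE
      row <- data.frame(
        intervention = paste(names(ivs[[i]]),
                             ifelse(unclass(ivs[[i]]) == 1L, "KI", "KO"),
                             sep = ":", collapse = "+"),
        n_hits = length(ivs[[i]]),
        n_attractors = length(ls$attractors))
      if (all(indicators %in% net$nodes)) {
        fr <- phenotype_fractions(ls, indicators, use_dominant = TRUE)
        full <- setNames(numeric(length(.phenotype_levels)), .phenotype_levels)
        full[names(fr)] <- fr
        row <- cbind(row, as.data.frame(t(full), check.names = FALSE))
      }
      rows[[i]] <- row
    }
  }
  out <- do.call(rbind, rows[keep])
  if (is.null(out))
    out <- data.frame(intervention = character(0), n_hits = integer(0),
                      n_attractors = integer(0))
  rownames(out) <- NULL
  attr(out, "interventions") <- ivs[keep]
  out
}
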