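# Phenotype interpretation of attractors ------------------------------------
#
# Attractors are read out through indicator nodes.  The default roles match
# the reconstructed CLL/RS model: an anergy indicator (NFAT on; NF-kB, AKT
# and S phase off), an S-phase indicator (E2F and cyclin E jointly active),
# an apoptosis indicator (BIM active, AKT inactive), and the two cyclins
# used to call a cell-cycle alert (cyclin D and cyclin E active without
# S-phase entry).  Quiescence (G0) is the absence of all of these.

#' Default indicator-role mapping for the reconstructed CLL model
#'
#' @return named character vector mapping roles `anergy`, `s_phase`,
#'   `apoptosis`, `ccnd`, `ccne` to node names.
#' @export
cll_indicators <- function() {
  c(anergy = "Anergy", s_phase = "SPhase", apoptosis = "Apoptosis",
    ccnd = "CCND1", ccne = "CCNE1")
}

.phenotype_levels <- c("apoptosis", "proliferation", "cell_cycle_alert",
                       "anergy", "quiescent_G0", "mixed")

# state-wise label with the fixed precedence
.state_labels <- function(states, ind) {
  apo <- unname(states[, ind[["apoptosis"]]] == 1L)
  sph <- unname(states[, ind[["s_phase"]]] == 1L)
  alert <- unname(states[, ind[["ccnd"]]] == 1L &
                    states[, ind[["ccne"]]] == 1L) & !sph
  ane <- unname(states[, ind[["anergy"]]] == 1L)
  ifelse(apo, "apoptosis",
         ifelse(sph, "proliferation",
                ifelse(alert, "cell_cycle_alert",
                       ifelse(ane, "anergy", "quiescent_G0"))))
}

#' Classify an attractor into a phenotype
#'
#' Every cycle state receives a state-wise label with precedence
#' apoptosis > proliferation (S phase) > cell-cycle alert > anergy >
#' quiescent G0.  A cycle whose states all agree carries that label; a
#' heterogeneous cycle is labelled `mixed`.  The precedence winner over the
#' whole cycle is always reported as `dominant` (used by screening), along
#' with per-indicator activity fractions so stricter callers can be layered.
#'
#' @param attractor an `attractor`.
#' @param indicators named role -> node mapping, see [cll_indicators()].
#' @return a `phenotype_call`: list with `label`, `dominant`,
#'   `state_labels`, and `indicator_fractions`.
#' @export
classify_phenotype <- function(attractor, indicators = cll_indicators()) {
  stopifnot(inherits(attractor, "attractor"))
  need <- c("anergy", "s_phase", "apoptosis", "ccnd", "ccne")
  if (!all(need %in% names(indicators)))
    stop("indicator roles missing: ",
         paste(setdiff(need, names(indicators)), collapse = ", "))
  absent <- setdiff(indicators[need], colnames(attractor$states))
  if (length(absent))
    stop("indicator node(s) not in network: ", paste(absent, collapse = ", "))
  labels <- .state_labels(attractor$states, indicators)
  dominant <- .phenotype_levels[min(match(labels, .phenotype_levels))]
  label <- if (length(unique(labels)) == 1L) labels[1L] else "mixed"
  fr <- colMeans(attractor$states[, indicators[need], drop = FALSE])
  names(fr) <- need
  structure(list(label = label, dominant = dominant, state_labels = labels,
                 indicator_fractions = fr),
            class = "phenotype_call")
}

#' @export
print.phenotype_call <- function(x, ...) {
  cat("Phenotype:", x$label,
      if (x$label == "mixed") paste0("(dominant: ", x$dominant, ")") else "",
      "\n")
  print(round(x$indicator_fractions, 3))
  invisible(x)
}

#' Basin fraction of each phenotype in a landscape
#'
#' Attractors are classified with [classify_phenotype()] and their basin
#' ratios accumulated per label (the pie-chart representation of a
#' landscape).
#'
#' @param landscape an `attractor_landscape`.
#' @param indicators role -> node mapping.
#' @param use_dominant if `TRUE`, heterogeneous cycles count under their
#'   precedence-dominant label instead of `mixed`.
#' @return named numeric vector summing to 1.
#' @export
phenotype_fractions <- function(landscape, indicators = cll_indicators(),
                                use_dominant = FALSE) {
  stopifnot(inherits(landscape, "attractor_landscape"))
  calls <- lapply(landscape$attractors, classify_phenotype,
                  indicators = indicators)
  lab <- vapply(calls, function(p) if (use_dominant) p$dominant else p$label, "")
  out <- tapply(landscape$basin_ratios, lab, sum)
  setNames(as.numeric(out), names(out))
}

#' Per-node activity of a landscape restricted to selected attractors
#'
#' Like [fuse_landscape()] but keeping only attractors passing a predicate
#' (e.g. fully proliferative ones), with basin ratios renormalized over the
#' kept set.
#'
#' @param landscape an `attractor_landscape`.
#' @param keep logical vector (one per attractor) or a predicate function
#'   taking an `attractor` and returning `TRUE`/`FALSE`.
#' @export
fuse_landscape_subset <- function(landscape, keep) {
  if (is.function(keep))
    keep <- vapply(landscape$attractors, keep, logical(1))
  stopifnot(length(keep) == length(landscape$attractors))
  if (!any(keep)) stop("no attractor selected")
  sub <- landscape
  sub$attractors <- landscape$attractors[keep]
  sub$basin_counts <- landscape$basin_counts[keep]
  sub$basin_ratios <- landscape$basin_counts[keep] /
    sum(landscape$basin_counts[keep])
  fuse_landscape(sub)
}

#' Test whether an attractor is fully proliferative
#'
#' The S-phase indicator must be active in every cycle state.
#'
#' @param attractor an `attractor`.
#' @param s_phase_node name of the S-phase indicator node.
#' @export
is_fully_proliferative <- function(attractor, s_phase_node = "SPhase") {
  all(attractor$states[, s_phase_node] == 1L)
}
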