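# Step-function expression binarization (BASC-A style) ----------------------
#
# Values are sorted ascending and, for every number of discontinuities
# d = 1..N-2, the least-squares optimal d-step function is computed by
# dynamic programming.  Each optimal step function contributes its strongest
# discontinuity (the jump between adjacent step means weighted by the
# approximation error of thresholding the full series at that position,
# ties broken toward the lower index); the candidate break locations are
# aggregated by their median, and the binarization threshold is the
# midpoint of the two data values flanking the chosen break.  Significance
# is assessed by a resampling test of break strength against a featureless
# (no-jump, uniform) null: the statistic is the widest value interval
# spanned by 5% of consecutive sorted observations — the width of the
# empirical density valley a real discontinuity carves out — normalized by
# the data range; sorted uniform samples of the same size provide the null
# distribution.

# widest value interval spanned by 5% of consecutive sorted observations,
# normalized by the range (scale- and location-invariant)
.valley_width <- function(u) {
  n <- length(u)
  w <- max(1L, ceiling(0.05 * n))
  max(u[(1L + w):n] - u[1:(n - w)]) / (u[n] - u[1L])
}

#' Binarize a vector of expression values at a step-function discontinuity
#'
#' @param values numeric vector (>= 3 finite values, not all equal).
#' @param alpha significance level for the jump test.
#' @param n_resamples resamples for the no-jump null.
#' @param seed optional integer seed.
#' @param d_max cap on the number of step-function discontinuities scanned
#'   (`NULL` = the full ladder `1..N-2`; capping is a computational choice
#'   that leaves the aggregated break essentially unchanged on well
#'   separated data).
#' @return list with `threshold`, `binary` (1 where `value > threshold`),
#'   `p_value`, `break_index` (last sorted position below the break),
#'   `jump` (normalized break strength).
#' @export
basca_binarize <- function(values, alpha = 0.05, n_resamples = 100L,
                           seed = NULL, d_max = NULL) {
  v <- as.numeric(values)
  if (any(!is.finite(v))) stop("values must be finite")
  if (length(v) < 3L) stop("need at least 3 values")
  if (diff(range(v)) == 0) stop("degenerate input: all values equal")
  if (!is.null(seed)) set.seed(seed)
  ord <- order(v)
  u <- v[ord]
  n <- length(u)
  dm <- if (is.null(d_max)) n - 2L else min(as.integer(d_max), n - 2L)
  res <- cpp_basca_breaks(u, dm)
  # aggregate candidate breaks across d by their median location
  b <- floor(median(res$break_index))
  threshold <- (u[b] + u[b + 1L]) / 2
  # break strength: widest value interval covered by 5% of consecutive
  # observations, relative to the range (the valley a discontinuity leaves)
  strength <- .valley_width(u)
  null_strength <- numeric(n_resamples)
  for (r in seq_len(n_resamples))
    null_strength[r] <- .valley_width(sort(runif(n)))
  p <- (1 + sum(null_strength >= strength)) / (n_resamples + 1)
  list(threshold = threshold,
       binary = as.integer(v > threshold),
       p_value = p,
       significant = p <= alpha,
       break_index = b,
       jump = (u[b + 1L] - u[b]) / diff(range(u)),
       strength = strength)
}

#' Binarization result for a whole gene x cell matrix
#'
#' Applies [basca_binarize()] per gene.  Genes with no expression in any
#' cell are excluded with reason `all_zero`; genes whose discontinuity is
#' not significant at `alpha` (including constant nonzero genes) are
#' excluded with reason `not_significant`.
#'
#' @param mat numeric matrix or `Matrix` sparse matrix, genes in rows with
#'   rownames, cells in columns.
#' @param alpha significance level.
#' @param n_resamples resamples for the per-gene jump test.
#' @param seed optional integer master seed (per-gene sub-seeds derived).
#' @param d_max see [basca_binarize()]; default caps the discontinuity
#'   ladder at 30 for tractability on matrices with many cells.
#' @param transform `"log1p"` (default) applies `log(1 + x)` before the
#'   step-function fit, the conventional scale for positively skewed
#'   normalized expression values; `"identity"` fits the raw values.  The
#'   transform is monotone, so the binary calls are unaffected by scale and
#'   the reported threshold is mapped back to the input scale.
#' @return a `binarization_result`: list with `binary` (genes x cells 0/1
#'   matrix over non-excluded genes), `threshold`, `p_value`, `excluded`
#'   (logical), `reason` (NA, `"all_zero"` or `"not_significant"`), `genes`,
#'   `cells`.
#' @export
binarize_matrix <- function(mat, alpha = 0.05, n_resamples = 100L,
                            seed = NULL, d_max = 30L,
                            transform = c("log1p", "identity")) {
  transform <- match.arg(transform)
  genes <- rownames(mat)
  if (is.null(genes)) genes <- paste0("G", seq_len(nrow(mat)))
  cells <- colnames(mat)
  if (is.null(cells)) cells <- paste0("C", seq_len(ncol(mat)))
  ng <- nrow(mat)
  threshold <- rep(NA_real_, ng)
  p_value <- rep(NA_real_, ng)
  reason <- rep(NA_character_, ng)
  binary <- matrix(NA_integer_, ng, ncol(mat), dimnames = list(genes, cells))
  for (g in seq_len(ng)) {
    v <- as.numeric(mat[g, ])
    if (all(v == 0)) { reason[g] <- "all_zero"; next }
    if (diff(range(v)) == 0) { reason[g] <- "not_significant"; next }
    sub_seed <- if (is.null(seed)) NULL else (seed + g * 7919L) %% 2147483647L
    vf <- if (transform == "log1p") log1p(v) else v
    bb <- basca_binarize(vf, alpha = alpha, n_resamples = n_resamples,
                         seed = sub_seed, d_max = d_max)
    if (transform == "log1p") bb$threshold <- expm1(bb$threshold)
    threshold[g] <- bb$threshold
    p_value[g] <- bb$p_value
    if (!bb$significant) { reason[g] <- "not_significant"; next }
    binary[g, ] <- bb$binary
  }
  excluded <- !is.na(reason)
  structure(list(binary = binary[!excluded, , drop = FALSE],
                 threshold = setNames(threshold, genes),
                 p_value = setNames(p_value, genes),
                 excluded = setNames(excluded, genes),
                 reason = setNames(reason, genes),
                 genes = genes, cells = cells),
            class = "binarization_result")
}

#' @export
print.binarization_result <- function(x, ...) {
  cat("Binarization of", length(x$genes), "genes x", length(x$cells),
      "cells:", sum(!x$excluded), "binarized,",
      sum(x$reason == "all_zero", na.rm = TRUE), "all-zero,",
      sum(x$reason == "not_significant", na.rm = TRUE), "not significant\n")
  invisible(x)
}

#' Select proliferative (cyclin-positive) cells
#'
#' A cell is labelled proliferative / RS-like when at least one of the
#' cyclin D/E genes is 1 in the binarized data.
#'
#' @param binres a `binarization_result`.
#' @param cyclin_genes gene names of the cyclin signature.
#' @return character vector of selected cell identifiers.
#' @export
select_proliferative_cells <- function(binres,
                                       cyclin_genes = c("CCNE1", "CCNE2",
                                                        "CCND1", "CCND2",
                                                        "CCND3")) {
  stopifnot(inherits(binres, "binarization_result"))
  avail <- intersect(cyclin_genes, rownames(binres$binary))
  if (!length(avail))
    stop("no cyclin signature gene available after binarization (",
         paste(cyclin_genes, collapse = ", "), ")")
  hit <- colSums(binres$binary[avail, , drop = FALSE] == 1L) > 0L
  binres$cells[hit]
}

#' ROC-based binarization of scored markers
#'
#' Sweeps all candidate thresholds (midpoints between consecutive distinct
#' scores) and returns the one maximizing Youden's J = sensitivity +
#' specificity - 1 for separating the two label classes; scores above the
#' threshold are called positive.  Ties are broken toward the smallest
#' candidate threshold.
#'
#' @param scores numeric scores (e.g. H-scores).
#' @param labels two-level factor/vector of conditions.
#' @param positive the label treated as the positive class (default: the
#'   class with the larger mean score).
#' @return list with `threshold`, `sensitivity`, `specificity`, `youden`,
#'   `positive`.
#' @export
roc_binarize <- function(scores, labels, positive = NULL) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) != 2L)
    stop("labels must contain exactly two classes")
  labels <- droplevels(labels)
  if (is.null(positive)) {
    means <- tapply(scores, labels, mean)
    positive <- names(means)[which.max(means)]
  }
  is_pos <- labels == positive
  cand <- sort(unique(scores))
  thr <- (cand[-length(cand)] + cand[-1L]) / 2
  if (!length(thr)) thr <- cand[1L]
  best <- list(j = -Inf, thr = NA_real_, sens = NA_real_, spec = NA_real_)
  for (t in thr) {
    sens <- mean(scores[is_pos] > t)
    spec <- mean(scores[!is_pos] <= t)
    j <- sens + spec - 1
    if (j > best$j + 1e-12) best <- list(j = j, thr = t, sens = sens, spec = spec)
  }
  list(threshold = best$thr, sensitivity = best$sens, specificity = best$spec,
       youden = best$j, positive = positive)
}
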