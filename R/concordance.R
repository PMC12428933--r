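# Model / expression-data concordance ---------------------------------------

#' Default node -> gene (isoform group) mapping of the transcriptional core
#'
#' Nodes of the CLL model regulated mainly at the expression level, mapped
#' to their measurable genes including isoforms; per cell the group is
#' aggregated by OR.
#'
#' @return named list: node -> character vector of gene symbols.
#' @export
cll_node_gene_map <- function() {
  list(CD5 = "CD5",
       SET = "SET",
       BMI1 = "BMI1",
       CITED2 = "CITED2",
       NOTCH1 = c("NOTCH1", "NOTCH2", "NOTCH3", "NOTCH4"),
       S100A4 = "S100A4",
       PTEN = "PTEN",
       NFAT = c("NFATC1", "NFATC2"),
       TP53 = "TP53",
       MYC = "MYC",
       CDKN1A = "CDKN1A",
       CDKN2A = "CDKN2A",
       CDKN2B = "CDKN2B",
       CDKN1B = "CDKN1B")
}

#' Read a node -> gene mapping from a two-column TSV (node, gene)
#' @param path TSV file path, optional header line `node\tgene`.
#' @export
read_node_gene_map <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (identical(tolower(as.character(df[1, ])), c("node", "gene")))
    df <- df[-1, , drop = FALSE]
  if (anyDuplicated(df[[2]]))
    stop("a gene may map to at most one node; duplicated: ",
         paste(unique(df[[2]][duplicated(df[[2]])]), collapse = ", "))
  split(as.character(df[[2]]), as.character(df[[1]]))
}

#' Concordance between model activities and binarized expression
#'
#' For every mapped node the data-side activation is the fraction of
#' (selected) cells in which the OR over the node's non-excluded member
#' genes is 1; the node counts as active when that fraction reaches
#' `threshold` (default 30%, the Hans-score convention).  The model side is
#' active when the supplied fused activity reaches the same threshold.  A
#' node matches when both sides agree.
#'
#' @param model_activity named numeric vector of fused per-node activities
#'   in `[0, 1]` (typically from [fuse_landscape_subset()] restricted to
#'   fully proliferative attractors, mirroring the cyclin-based cell
#'   selection on the data side).
#' @param binres a `binarization_result`.
#' @param node_map node -> genes mapping, see [cll_node_gene_map()].
#' @param cells optional cell subset (e.g. from
#'   [select_proliferative_cells()]); default all cells.
#' @param threshold activation threshold on both sides.
#' @return data.frame with per-node data/model fractions, activity calls and
#'   `match`.
#' @export
concordance <- function(model_activity, binres, node_map = cll_node_gene_map(),
                        cells = NULL, threshold = 0.30) {
  stopifnot(inherits(binres, "binarization_result"))
  if (is.null(cells)) cells <- binres$cells
  cells <- intersect(cells, colnames(binres$binary))
  if (!length(cells)) stop("no cells to compare")
  nodes <- names(node_map)
  missing_model <- setdiff(nodes, names(model_activity))
  if (length(missing_model))
    stop("model activity missing for node(s): ",
         paste(missing_model, collapse = ", "))
  rows <- lapply(nodes, function(nd) {
    genes <- intersect(node_map[[nd]], rownames(binres$binary))
    if (!length(genes))
      stop("node ", nd, " has no non-excluded mapped gene")
    sig <- colSums(binres$binary[genes, cells, drop = FALSE] == 1L) > 0L
    data_frac <- mean(sig)
    model_frac <- unname(model_activity[[nd]])
    data.frame(node = nd,
               genes = paste(genes, collapse = ","),
               data_fraction = data_frac,
               model_fraction = model_frac,
               data_active = data_frac >= threshold,
               model_active = model_frac >= threshold,
               match = (data_frac >= threshold) == (model_frac >= threshold))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  attr(out, "n_cells") <- length(cells)
  out
}
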