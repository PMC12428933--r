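# File I/O: expression matrices, landscape JSON, fixture export -------------

#' Read a gene x cell expression matrix from TSV
#'
#' Expected layout: header row of cell identifiers, first column gene
#' names, tab-separated nonnegative values.
#'
#' @param path TSV file path.
#' @return base matrix with genes in rows.
#' @export
read_expression_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, row.names = 1L,
                   check.names = FALSE)
  m <- as.matrix(df)
  if (any(m < 0)) stop("expression values must be nonnegative")
  m
}

#' Write a gene x cell expression matrix as TSV
#' @param mat matrix with rownames (genes) and colnames (cells).
#' @param path output path.
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), as.matrix(mat), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sparse expression matrix in MatrixMarket format
#'
#' @param mtx path to the `.mtx` file (genes x cells).
#' @param genes path to a one-column gene-name file (one per row).
#' @param cells path to a one-column cell-barcode file (one per column).
#' @return a `Matrix::dgCMatrix` with dimnames.
#' @export
read_expression_mtx <- function(mtx, genes, cells) {
  m <- Matrix::readMM(mtx)
  gn <- readLines(genes, warn = FALSE)
  cn <- readLines(cells, warn = FALSE)
  if (nrow(m) != length(gn) || ncol(m) != length(cn))
    stop("matrix dimensions do not match gene/cell side files")
  dimnames(m) <- list(gn, cn)
  methods::as(m, "CsparseMatrix")
}

#' Serialize an attractor landscape to JSON
#'
#' Cycles are stored as integer state codes together with the node order,
#' so states can be reconstructed bit by bit (node 1 = least-significant
#' bit).
#'
#' @param landscape an `attractor_landscape`.
#' @param path output path (`NULL` returns the JSON string).
#' @export
write_landscape_json <- function(landscape, path = NULL) {
  obj <- list(nodes = landscape$nodes,
              exact = landscape$exact,
              n_samples = landscape$n_samples,
              seed = landscape$seed,
              attractors = lapply(seq_along(landscape$attractors), function(i) {
                a <- landscape$attractors[[i]]
                list(codes = a$codes,
                     length = a$length,
                     basin_count = landscape$basin_counts[i],
                     basin_ratio = landscape$basin_ratios[i])
              }))
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(json)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Export the bundled fixtures to a directory
#'
#' Writes every toy network, the reconstructed CLL/RS model (rule file plus
#' per-rule provenance TSV), and a default synthetic expression bundle
#' (dense TSV, sparse MatrixMarket triplet, and ground-truth TSV).
#'
#' @param dir output directory (created if missing).
#' @param seed seed for the synthetic expression bundle.
#' @export
export_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  toys <- toy_networks()
  for (nm in names(toys))
    write_network(toys[[nm]]$network, file.path(dir, paste0(nm, ".bn")))
  card <- reconstructed_cll_network()
  write_network(card$network, file.path(dir, "cll_rs_model.bn"))
  prov <- data.frame(node = names(card$provenance),
                     rule = unname(card$network$functions[names(card$provenance)]),
                     provenance = unname(card$provenance))
  write.table(prov, file.path(dir, "cll_rs_provenance.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  synth <- synth_expression(seed = seed)
  write_expression_tsv(synth$matrix, file.path(dir, "synthetic_expression.tsv"))
  sm <- methods::as(Matrix::Matrix(synth$matrix, sparse = TRUE), "generalMatrix")
  Matrix::writeMM(sm, file.path(dir, "synthetic_expression.mtx"))
  writeLines(rownames(synth$matrix), file.path(dir, "genes.tsv"))
  writeLines(colnames(synth$matrix), file.path(dir, "barcodes.tsv"))
  write.table(data.frame(gene = rownames(synth$truth), synth$truth,
                         check.names = FALSE),
              file.path(dir, "synthetic_truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
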