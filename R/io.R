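# Expression-matrix I/O. Cells-as-rows is the canonical orientation
# everywhere (the template covariance is cell-by-cell); use `transpose` when
# a file stores genes as rows. Dense CSV/TSV are read with base R, sparse
# MatrixMarket triplets through the Matrix package with genes/barcodes
# sidecar files.

#' Read an expression matrix
#'
#' @param path file path. For \code{format = "mtx"}, sidecar files
#'   \code{<stem>_genes.txt} and \code{<stem>_barcodes.txt} (one id per
#'   line) must sit next to the matrix unless given explicitly.
#' @param format \code{"csv"}, \code{"tsv"} or \code{"mtx"}; default guessed
#'   from the extension.
#' @param transpose logical; set when the file stores genes as rows.
#' @param genes,barcodes optional explicit sidecar paths for MTX input.
#' @return a numeric cells x genes matrix with cell ids as row names and
#'   gene ids as column names.
#' @export
read_expression <- function(path, format = NULL, transpose = FALSE,
                            genes = NULL, barcodes = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  format <- format %||% guess_format(path)
  x <- switch(format,
    csv = read_delim_matrix(path, ","),
    tsv = read_delim_matrix(path, "\t"),
    mtx = read_mtx_matrix(path, genes, barcodes),
    stop("unsupported format: ", format, call. = FALSE))
  if (transpose) x <- t(x)
  as_expression_matrix(x)
}

guess_format <- function(path) {
  switch(tolower(tools::file_ext(path)),
         csv = "csv", tsv = "tsv", txt = "tsv", mtx = "mtx",
         stop("cannot guess format from extension of ", path, call. = FALSE))
}

read_delim_matrix <- function(path, sep) {
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          check.names = FALSE, comment.char = "")
  bad <- !vapply(df, is.numeric, logical(1))
  if (any(bad))
    stop("non-numeric column(s) in ", path, ": ",
         paste(utils::head(names(df)[bad], 5), collapse = ", "),
         call. = FALSE)
  as.matrix(df)
}

read_mtx_matrix <- function(path, genes = NULL, barcodes = NULL) {
  stem <- sub("\\.mtx$", "", path)
  genes <- genes %||% paste0(stem, "_genes.txt")
  barcodes <- barcodes %||% paste0(stem, "_barcodes.txt")
  for (f in c(genes, barcodes))
    if (!file.exists(f))
      stop("missing MTX sidecar file: ", f, call. = FALSE)
  m <- as.matrix(Matrix::readMM(path))
  gid <- readLines(genes)
  bid <- readLines(barcodes)
  if (nrow(m) != length(bid) || ncol(m) != length(gid))
    stop(sprintf("MTX is %d x %d but sidecars list %d barcodes / %d genes",
                 nrow(m), ncol(m), length(bid), length(gid)), call. = FALSE)
  dimnames(m) <- list(bid, gid)
  m
}

#' Write an expression matrix
#'
#' @param x cells x genes matrix with ids.
#' @param path output path; sidecar id files are written next to it for MTX.
#' @param format \code{"csv"}, \code{"tsv"} or \code{"mtx"}; default guessed
#'   from the extension.
#' @return \code{path}, invisibly.
#' @export
write_expression <- function(x, path, format = NULL) {
  x <- as_expression_matrix(x)
  format <- format %||% guess_format(path)
  if (format %in% c("csv", "tsv")) {
    sep <- if (format == "csv") "," else "\t"
    df <- data.frame(cell_id = rownames(x) %||% seq_len(nrow(x)),
                     x, check.names = FALSE)
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  } else if (format == "mtx") {
    stem <- sub("\\.mtx$", "", path)
    Matrix::writeMM(Matrix::Matrix(x, sparse = TRUE), path)
    writeLines(colnames(x) %||% as.character(seq_len(ncol(x))),
               paste0(stem, "_genes.txt"))
    writeLines(rownames(x) %||% as.character(seq_len(nrow(x))),
               paste0(stem, "_barcodes.txt"))
  } else stop("unsupported format: ", format, call. = FALSE)
  invisible(path)
}
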