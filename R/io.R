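#' Read a feature x cell dataset from disk
#'
#' Supported formats: Matrix Market triplet (`.mtx`) with `features.tsv` /
#' `barcodes.tsv` sidecars (10x-style; sparse structure is preserved), and
#' dense delimited CSV/TSV with feature names in the first column and cell
#' identifiers in the header.
#'
#' @param path For `format = "mtx"`, either the `.mtx` file (sidecars are
#'   looked up next to it) or a directory containing `matrix.mtx`,
#'   `features.tsv` and `barcodes.tsv`. For delimited formats, the file
#'   path.
#' @param format One of `"mtx"`, `"csv"`, `"tsv"` (default: guessed from
#'   the extension).
#' @param transpose For delimited input whose rows are cells rather than
#'   features.
#' @return Feature x cell matrix (sparse `dgCMatrix` for mtx input).
#' @export
readDataset <- function(path, format = NULL, transpose = FALSE) {
  if (is.null(format)) {
    format <- if (dir.exists(path)) "mtx" else
      switch(tolower(tools::file_ext(path)),
             mtx = "mtx", csv = "csv", tsv = "tsv", txt = "tsv",
             stop("cannot guess format of '", path, "'"))
  }
  format <- match.arg(format, c("mtx", "csv", "tsv"))
  if (format == "mtx") {
    if (dir.exists(path)) {
      mtx <- file.path(path, "matrix.mtx")
      fFile <- file.path(path, "features.tsv")
      bFile <- file.path(path, "barcodes.tsv")
    } else {
      mtx <- path
      fFile <- file.path(dirname(path), "features.tsv")
      bFile <- file.path(dirname(path), "barcodes.tsv")
    }
    for (f in c(mtx, fFile, bFile)) {
      if (!file.exists(f)) stop("missing file: ", f)
    }
    m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
    feats <- utils::read.delim(fFile, header = FALSE,
                               stringsAsFactors = FALSE)[[1]]
    cells <- utils::read.delim(bFile, header = FALSE,
                               stringsAsFactors = FALSE)[[1]]
    if (length(feats) != nrow(m)) {
      stop("sidecar ", fFile, " names ", length(feats),
           " features but the matrix has ", nrow(m), " rows")
    }
    if (length(cells) != ncol(m)) {
      stop("sidecar ", bFile, " names ", length(cells),
           " cells but the matrix has ", ncol(m), " columns")
    }
    dimnames(m) <- list(feats, cells)
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- utils::read.table(path, sep = sep, header = TRUE,
                            row.names = 1, check.names = FALSE)
    m <- as.matrix(df)
    if (transpose) m <- t(m)
  }
  if (anyDuplicated(rownames(m))) {
    stop("duplicate feature names in ", path)
  }
  m
}

#' Write a dataset to disk
#'
#' @param data Feature x cell matrix.
#' @param path Output path: a directory for `format = "mtx"` (writes
#'   `matrix.mtx` + sidecars) or a file for delimited output.
#' @param format `"mtx"`, `"csv"` or `"tsv"`.
#' @return Invisibly, `path`.
#' @export
writeDataset <- function(data, path, format = c("mtx", "csv", "tsv")) {
  format <- match.arg(format)
  if (format == "mtx") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(methods::as(methods::as(data, "CsparseMatrix"),
                                "generalMatrix"),
                    file.path(path, "matrix.mtx"))
    writeLines(rownames(data), file.path(path, "features.tsv"))
    writeLines(colnames(data), file.path(path, "barcodes.tsv"))
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- data.frame(feature = rownames(data), .asDense(data),
                     check.names = FALSE)
    utils::write.table(df, path, sep = sep, quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Library-size log-normalization
#'
#' Scales each cell's counts to a common library size and applies
#' `log1p`. Cells with zero total count are left at zero with a warning.
#'
#' @param counts Nonnegative feature x cell matrix of counts.
#' @param target Target library size (default: median of the observed
#'   library sizes).
#' @return Normalized matrix, same shape and dimnames.
#' @export
logNormalize <- function(counts, target = NULL) {
  if (min(counts) < 0) stop("counts must be nonnegative")
  libs <- Matrix::colSums(counts)
  if (is.null(target)) target <- stats::median(libs[libs > 0])
  zero <- libs == 0
  if (any(zero)) {
    warning(sum(zero), " cells have zero total count and stay all-zero")
    libs[zero] <- 1
  }
  X <- .asDense(counts)
  log1p(sweep(X, 2, target / libs, "*"))
}

#' Select highly variable features by variance rank
#'
#' Ranks features by the variance of their (normalized) values and returns
#' the top `n`; ties are broken by feature name for determinism.
#'
#' @param data Feature x cell matrix.
#' @param n Number of features to select.
#' @return Character vector of feature names, highest variance first.
#' @export
selectHVG <- function(data, n) {
  if (n > nrow(data)) {
    stop("n (", n, ") exceeds the number of features (", nrow(data), ")")
  }
  X <- .asDense(data)
  mu <- rowMeans(X)
  v <- rowSums((X - mu)^2) / max(1L, ncol(X) - 1L)
  ord <- order(-v, rownames(X))
  rownames(X)[ord][seq_len(n)]
}

#' Read cell coordinates from TSV
#'
#' Expects columns `cell_id`, `x`, `y`.
#'
#' @param file TSV path.
#' @return Cells x 2 matrix with cell identifiers as row names.
#' @export
readCoordinates <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("cell_id", "x", "y")
  if (!all(need %in% names(df))) {
    stop("coordinate file must have columns: ", paste(need, collapse = ", "))
  }
  m <- as.matrix(df[, c("x", "y")])
  rownames(m) <- df$cell_id
  m
}

#' Write a joint embedding as TSV
#'
#' Writes `cell_id`, `dataset`, then one column per embedding dimension;
#' the column-to-reference block map goes to a sidecar
#' `<file>.blocks.tsv`.
#'
#' @param embedding A `mosaic_embedding`.
#' @param file Output TSV path.
#' @return Invisibly, the file path.
#' @export
writeEmbedding <- function(embedding, file) {
  ds <- embeddingDataset(embedding)
  df <- data.frame(cell_id = rownames(embedding),
                   dataset = if (is.null(ds)) NA else as.character(ds),
                   unclass(embedding), check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  blk <- embeddingBlock(embedding)
  if (!is.null(blk)) {
    utils::write.table(data.frame(dim = colnames(embedding),
                                  reference = as.character(blk)),
                       paste0(file, ".blocks.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(file)
}
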