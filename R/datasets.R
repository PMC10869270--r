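#' Validate a collection of mosaic datasets
#'
#' A dataset is a numeric matrix (dense or \pkg{Matrix} sparse) with features
#' as rows and cells as columns; row and column names are mandatory because
#' all feature matching is done by exact name equality. A collection is a
#' named list of such matrices. Cell identifiers must be unique across the
#' whole collection, since the joint embedding indexes cells by identifier.
#'
#' @param datasets Named list of feature x cell matrices with unique row
#'   (feature) and column (cell) names.
#' @return Invisibly, the validated list.
#' @export
#' @examples
#' d <- list(a = matrix(1:6, 3, 2, dimnames = list(paste0("g", 1:3),
#'                                                 paste0("c", 1:2))))
#' validateDatasets(d)
validateDatasets <- function(datasets) {
  if (!is.list(datasets) || length(datasets) < 1L) {
    stop("'datasets' must be a non-empty named list of matrices")
  }
  nms <- names(datasets)
  if (is.null(nms) || any(!nzchar(nms))) {
    stop("every dataset must be named")
  }
  dup <- unique(nms[duplicated(nms)])
  if (length(dup)) {
    stop("duplicate dataset names: ", paste(dup, collapse = ", "))
  }
  for (nm in nms) {
    x <- datasets[[nm]]
    if (!(is.matrix(x) || methods::is(x, "Matrix"))) {
      stop("dataset '", nm, "' is not a matrix")
    }
    if (nrow(x) < 1L || ncol(x) < 1L) {
      stop("dataset '", nm, "' is empty")
    }
    if (is.null(rownames(x)) || is.null(colnames(x))) {
      stop("dataset '", nm, "' must have feature (row) and cell (column) names")
    }
    if (anyDuplicated(rownames(x))) {
      stop("dataset '", nm, "' has duplicated feature names")
    }
    if (anyDuplicated(colnames(x))) {
      stop("dataset '", nm, "' has duplicated cell identifiers")
    }
  }
  allCells <- unlist(lapply(datasets, colnames), use.names = FALSE)
  if (anyDuplicated(allCells)) {
    dupc <- unique(allCells[duplicated(allCells)])
    stop("cell identifiers are shared between datasets: ",
         paste(utils::head(dupc, 5L), collapse = ", "),
         if (length(dupc) > 5L) ", ..." else "")
  }
  invisible(datasets)
}

# dense numeric matrix view of a (possibly sparse) dataset submatrix
.asDense <- function(x) {
  if (methods::is(x, "Matrix")) as.matrix(x) else x
}
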