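#' Cell type classification accuracy
#'
#' Fraction of cells whose predicted label equals the true label. Vectors
#' are joined by name when both are named, otherwise compared positionally.
#'
#' @param predicted,truth Label vectors over the same cell set.
#' @return Accuracy in \[0, 1\].
#' @export
classificationAccuracy <- function(predicted, truth) {
  if (!length(predicted) || !length(truth)) stop("empty label vectors")
  if (!is.null(names(predicted)) && !is.null(names(truth))) {
    if (!setequal(names(predicted), names(truth))) {
      stop("predicted and truth label different cell sets")
    }
    truth <- truth[names(predicted)]
  } else if (length(predicted) != length(truth)) {
    stop("label vectors differ in length and are not joinable by name")
  }
  mean(as.character(predicted) == as.character(truth))
}

.pairedCheck <- function(layer1, layer2) {
  layer1 <- as.matrix(layer1); layer2 <- as.matrix(layer2)
  if (nrow(layer1) != nrow(layer2)) {
    stop("paired layers must contain the same matched cells (one row each)")
  }
  if (!is.null(rownames(layer1)) && !is.null(rownames(layer2)) &&
      !identical(rownames(layer1), rownames(layer2))) {
    if (!setequal(rownames(layer1), rownames(layer2))) {
      stop("paired layers carry different matched cell identifiers")
    }
    layer2 <- layer2[rownames(layer1), , drop = FALSE]
  }
  list(layer1 = layer1, layer2 = layer2)
}

#' Jaccard similarity of within-layer neighbourhoods
#'
#' For matched cells measured on two omic layers embedded in a common
#' space, each cell's `k` nearest cells (default 100) are found within each
#' layer separately (excluding the cell itself); neighbour identity is
#' compared through the layer-matching bijection and the per-cell Jaccard
#' index of the two neighbour sets is returned. Values near 1 mean the two
#' layers place each cell in the same local context.
#'
#' @param layer1,layer2 Matched cells x dims matrices (row i of each is the
#'   same cell measured on the two layers).
#' @param k Neighbourhood size (default 100); must be below the layer size.
#' @return Numeric vector of per-cell Jaccard indices.
#' @export
jaccardNeighborhood <- function(layer1, layer2, k = 100) {
  p <- .pairedCheck(layer1, layer2)
  n <- nrow(p$layer1)
  if (k >= n) stop("k (", k, ") must be smaller than the layer size (", n, ")")
  nn1 <- .knnSelf(p$layer1, k)
  nn2 <- .knnSelf(p$layer2, k)
  vapply(seq_len(n), function(i) {
    a <- nn1[i, ]; b <- nn2[i, ]
    length(intersect(a, b)) / length(union(a, b))
  }, numeric(1))
}

# within-layer kNN excluding self; ties by cell-id then index order
.knnSelf <- function(x, k) {
  nn <- .knnIndex(x, x, k + 1L)
  out <- matrix(0L, nrow(x), k)
  for (i in seq_len(nrow(x))) {
    row <- nn[i, ]
    row <- row[row != i]
    out[i, ] <- row[seq_len(k)]
  }
  out
}

#' Number-of-nearest-cells metric for matched embeddings
#'
#' For matched cell i, counts how many opposite-layer cells lie at distance
#' less than or equal to the distance to its own match
#' (the match itself always counts, so a perfectly aligned pair scores 1).
#' Also returns the cumulative curve M(x) = number of cells whose count is
#' at most x; uniformly higher curves indicate better cross-layer mixing.
#'
#' @inheritParams jaccardNeighborhood
#' @return List with `N` (per-cell counts, layer-1 cells against layer 2)
#'   and `M`, a data.frame with columns `x` and `M` for integer x from 1 to
#'   the maximum count.
#' @export
nearestCellsCurve <- function(layer1, layer2) {
  p <- .pairedCheck(layer1, layer2)
  n <- nrow(p$layer1)
  if (!n) stop("empty matching")
  N <- integer(n)
  l2sq <- rowSums(p$layer2^2)
  for (i in seq_len(n)) {
    d2 <- l2sq - 2 * drop(p$layer2 %*% p$layer1[i, ])   # + const
    N[i] <- sum(d2 <= d2[i] + 1e-10)
  }
  xs <- seq_len(max(N))
  M <- vapply(xs, function(x) sum(N <= x), integer(1))
  names(N) <- rownames(p$layer1)
  list(N = N, M = data.frame(x = xs, M = M))
}

#' Write per-cell metrics as tidy TSV plus a JSON summary
#'
#' @param values Named numeric vector of per-cell metric values.
#' @param metric Metric name recorded in the TSV.
#' @param file Output TSV path; a `.json` summary (mean and quartiles) is
#'   written alongside when \pkg{jsonlite} is available.
#' @return Invisibly, the TSV path.
#' @export
writeMetrics <- function(values, metric, file) {
  utils::write.table(data.frame(cell_id = names(values), metric = metric,
                                value = as.numeric(values)),
                     file, sep = "\t", quote = FALSE, row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    qs <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE)
    jsonlite::write_json(list(metric = metric, mean = mean(values),
                              q25 = qs[1], median = qs[2], q75 = qs[3]),
                         paste0(tools::file_path_sans_ext(file), ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(file)
}
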