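# Euclidean k-nearest neighbours of query rows among training rows.
# Returns an nq x k integer matrix of training-row indices, nearest first.
# Distance ties are broken by training cell-id order (then row order), so
# results are reproducible. Chunked over queries to bound memory.
.knnIndex <- function(train, query, k, chunk = 1024L) {
  train <- as.matrix(train); query <- as.matrix(query)
  nt <- nrow(train)
  if (k < 1L) stop("k must be at least 1")
  if (k > nt) stop("k (", k, ") exceeds the number of training cells (",
                   nt, ")")
  tid <- rownames(train)
  tieOrd <- if (is.null(tid)) seq_len(nt) else order(tid)
  tieRank <- integer(nt); tieRank[tieOrd] <- seq_len(nt)
  t2 <- rowSums(train^2)
  out <- matrix(0L, nrow(query), k)
  for (start in seq(1L, nrow(query), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(query))
    # squared distances up to a per-query constant; ranking is unaffected
    d2 <- matrix(t2, length(idx), nt, byrow = TRUE) -
      2 * query[idx, , drop = FALSE] %*% t(train)
    for (ii in seq_along(idx)) {
      ord <- order(round(d2[ii, ], 10), tieRank)[seq_len(k)]
      out[idx[ii], ] <- ord
    }
  }
  rownames(out) <- rownames(query)
  out
}

.embRows <- function(embedding, cells) {
  emb <- unclass(embedding)
  missing <- setdiff(cells, rownames(emb))
  if (length(missing)) {
    stop(length(missing), " cells absent from the embedding (e.g. ",
         paste(utils::head(missing, 3L), collapse = ", "), ")")
  }
  emb[cells, , drop = FALSE]
}

#' Transfer labels by k-nearest-neighbour majority vote
#'
#' Each query cell is assigned the majority label among its `k` nearest
#' labelled training cells in the joint embedding (Euclidean distance).
#' Vote ties are broken by the label of the nearest neighbour among the tied
#' classes; distance ties by cell-id order.
#'
#' @param embedding A `mosaic_embedding` (or any cells x dims matrix with
#'   cell identifiers as row names).
#' @param labels Named vector of training labels; its names define the
#'   training cell set.
#' @param queryCells Cell identifiers to classify.
#' @param k Neighbour count (default 5).
#' @return Named character vector of predicted labels.
#' @export
knnClassify <- function(embedding, labels, queryCells, k = 5) {
  if (!length(labels)) stop("empty training label set")
  trainCells <- names(labels)
  if (is.null(trainCells)) stop("'labels' must be named by cell identifier")
  train <- .embRows(embedding, trainCells)
  query <- .embRows(embedding, queryCells)
  nn <- .knnIndex(train, query, k)
  lab <- as.character(labels)
  pred <- vapply(seq_len(nrow(nn)), function(i) {
    votes <- lab[nn[i, ]]
    tab <- table(votes)
    winners <- names(tab)[tab == max(tab)]
    if (length(winners) == 1L) return(winners)
    votes[votes %in% winners][1L]      # nearest neighbour among tied classes
  }, character(1))
  stats::setNames(pred, queryCells)
}

#' Impute original features from the joint embedding
#'
#' For each query cell, returns the unweighted mean of the original
#' reference feature vectors of its `k` nearest reference cells in
#' embedding space. Queries are processed in chunks so memory stays bounded
#' by the chunk, not the full query set.
#'
#' @param embedding A `mosaic_embedding` containing both reference and
#'   query cells.
#' @param reference Feature x cell matrix whose cells are present in the
#'   embedding; its features are the ones imputed.
#' @param queryCells Cell identifiers to impute.
#' @param k Neighbour count (default 5).
#' @return Features x query-cells matrix.
#' @export
imputeFeatures <- function(embedding, reference, queryCells, k = 5) {
  refCells <- colnames(reference)
  if (k > length(refCells)) {
    stop("k (", k, ") exceeds the number of reference cells (",
         length(refCells), ")")
  }
  train <- .embRows(embedding, refCells)
  query <- .embRows(embedding, queryCells)
  nn <- .knnIndex(train, query, k)
  refX <- .asDense(reference)
  out <- matrix(0, nrow(refX), length(queryCells),
                dimnames = list(rownames(refX), queryCells))
  for (i in seq_along(queryCells)) {
    out[, i] <- rowMeans(refX[, nn[i, ], drop = FALSE])
  }
  out
}

#' Write predicted labels as a two-column TSV
#'
#' @param labels Named vector of labels.
#' @param file Output path.
#' @return Invisibly, the file path.
#' @export
writeLabels <- function(labels, file) {
  utils::write.table(data.frame(cell_id = names(labels),
                                label = as.character(labels)),
                     file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
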