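#' Fit a reference dimensionality reduction
#'
#' A reference dataset defines (part of) the joint coordinate space. With no
#' labels, principal components analysis on feature-centred data is used
#' (default 50 components); with discrete labels, linear discriminant
#' analysis (at most `n_classes - 1` dimensions). A precomputed reduction
#' (for example from a vertical integration method) can be supplied instead
#' via `loadings`/`scores`/`featureMeans`.
#'
#' The returned model stores the loadings matrix A (features x dims), the
#' per-feature centring means, and the reference scores S = (X - means)^T A.
#'
#' @param data Feature x cell matrix with dimnames.
#' @param ndims Requested number of dimensions (capped at what the data
#'   supports).
#' @param labels Optional named vector of discrete labels covering every
#'   reference cell; switches the fit to LDA.
#' @param loadings,scores,featureMeans Optional user-supplied reduction
#'   (mode `"user"`); `loadings` rows must be named by feature.
#' @param name Reference name used to label embedding columns.
#' @return Object of class `reference_model` with elements `name`, `mode`,
#'   `loadings`, `featureMeans`, `scores`, `dimNames`.
#' @export
fitReference <- function(data, ndims = 50, labels = NULL,
                         loadings = NULL, scores = NULL, featureMeans = NULL,
                         name = "reference") {
  if (is.null(rownames(data)) || is.null(colnames(data))) {
    stop("reference data must have feature and cell names")
  }
  if (!is.null(loadings)) {
    if (is.null(rownames(loadings))) stop("user loadings must name features")
    if (!all(rownames(loadings) %in% rownames(data))) {
      stop("user loadings contain features absent from the reference data")
    }
    if (is.null(featureMeans)) {
      featureMeans <- stats::setNames(rep(0, nrow(loadings)),
                                      rownames(loadings))
    }
    model <- structure(list(name = name, mode = "user",
                            loadings = as.matrix(loadings),
                            featureMeans = featureMeans[rownames(loadings)],
                            scores = NULL,
                            dimNames = colnames(loadings)),
                       class = "reference_model")
    model$scores <- if (is.null(scores)) projectDirect(data, model) else
      as.matrix(scores)
    if (is.null(model$dimNames)) {
      model$dimNames <- paste0(name, "_D", seq_len(ncol(model$loadings)))
    }
    colnames(model$loadings) <- colnames(model$scores) <- model$dimNames
    return(model)
  }
  X <- .asDense(data)
  n <- ncol(X)
  if (n < 2L) stop("reference dataset must have at least 2 cells")
  if (!is.null(labels)) {
    return(.fitReferenceLDA(X, ndims, labels, name))
  }
  mu <- rowMeans(X)
  Y <- t(X - mu)                                # cells x features, centred
  if (all(abs(Y) < .Machine$double.eps * 100)) {
    stop("reference dataset has zero variance in every feature")
  }
  d <- min(ndims, nrow(X), n - 1L)
  if (d < ndims) {
    warning("requested ", ndims, " dimensions; data supports only ", d,
            " - capping", call. = FALSE)
  }
  sv <- svd(Y, nu = d, nv = d)
  dimNames <- paste0(name, "_PC", seq_len(d))
  loadings <- sv$v
  scores <- sv$u %*% diag(sv$d[seq_len(d)], d, d)
  # sign convention: largest-magnitude loading entry positive, so the fit
  # does not depend on cell order
  for (j in seq_len(d)) {
    piv <- which.max(abs(loadings[, j]))
    if (loadings[piv, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  dimnames(loadings) <- list(rownames(X), dimNames)
  dimnames(scores) <- list(colnames(X), dimNames)
  structure(list(name = name, mode = "pca", loadings = loadings,
                 featureMeans = mu, scores = scores, dimNames = dimNames),
            class = "reference_model")
}

.fitReferenceLDA <- function(X, ndims, labels, name) {
  cells <- colnames(X)
  if (!all(cells %in% names(labels))) {
    stop("every reference cell must be labelled for an LDA reference")
  }
  grp <- factor(as.vector(labels[cells]))
  if (nlevels(grp) < 2L) stop("LDA reference needs at least 2 classes")
  fit <- MASS::lda(t(X), grouping = grp)
  d <- min(ndims, ncol(fit$scaling))
  loadings <- fit$scaling[, seq_len(d), drop = FALSE]
  # centre on the prior-weighted grand mean, as predict.lda does
  mu <- drop(fit$prior %*% fit$means)
  scores <- t(X - mu) %*% loadings
  dimNames <- paste0(name, "_LD", seq_len(d))
  colnames(loadings) <- colnames(scores) <- dimNames
  structure(list(name = name, mode = "lda", loadings = loadings,
                 featureMeans = mu, scores = scores, dimNames = dimNames),
            class = "reference_model")
}

#' @export
print.reference_model <- function(x, ...) {
  cat(sprintf("reference_model '%s' (%s): %d features -> %d dims, %d cells\n",
              x$name, x$mode, nrow(x$loadings), ncol(x$loadings),
              nrow(x$scores)))
  invisible(x)
}

#' Project a dataset directly onto reference loadings
#'
#' Computes (X - featureMeans)^T A for the dataset's submatrix restricted to
#' the model's loading features. Every loading feature must be present; a
#' dataset with a partial panel must be projected through a regression
#' bridge instead.
#'
#' @param data Feature x cell matrix.
#' @param model A `reference_model`.
#' @return Cells x dims score matrix.
#' @export
projectDirect <- function(data, model) {
  feats <- rownames(model$loadings)
  missing <- setdiff(feats, rownames(data))
  if (length(missing)) {
    stop(length(missing), " loading features absent from the dataset (e.g. ",
         paste(utils::head(missing, 3L), collapse = ", "),
         "); use a regression bridge (fitBridge/projectAlongPath) instead")
  }
  X <- .asDense(data[feats, , drop = FALSE])
  scores <- t(X - model$featureMeans[feats]) %*% model$loadings
  rownames(scores) <- colnames(data)
  scores
}

#' Fit a regression bridge from shared features to reference scores
#'
#' Ordinary least squares (with intercept) of each score dimension on the
#' shared-feature submatrix of the source dataset. The fitted coefficient
#' matrix predicts reference scores for any dataset carrying the shared
#' features. Rank-deficient shared panels fall back to minimum-norm least
#' squares with a warning, since shared panels smaller than the score
#' dimension are common in mosaic designs.
#'
#' @param scores Cells x dims score matrix for the source dataset's cells.
#' @param data Feature x cell matrix of the source dataset (same cells).
#' @param sharedFeatures Feature names used as predictors; must be present
#'   in `data`.
#' @return Object of class `regression_bridge` with `features`,
#'   `coefficients` ((1 + p) x dims, intercept first) and `fittedOn`.
#' @export
fitBridge <- function(scores, data, sharedFeatures) {
  if (!length(sharedFeatures)) stop("no shared features to fit a bridge on")
  missing <- setdiff(sharedFeatures, rownames(data))
  if (length(missing)) {
    stop("shared features absent from source data: ",
         paste(utils::head(missing, 3L), collapse = ", "))
  }
  X <- t(.asDense(data[sharedFeatures, , drop = FALSE]))   # cells x p
  scores <- as.matrix(scores)
  if (nrow(X) != nrow(scores)) {
    stop("scores and source data describe different numbers of cells")
  }
  design <- cbind(`(Intercept)` = 1, X)
  qrd <- qr(design)
  if (qrd$rank == ncol(design)) {
    coefs <- qr.coef(qrd, scores)
  } else {
    warning("rank-deficient shared panel (rank ", qrd$rank, " < ",
            ncol(design), "); using minimum-norm least squares",
            call. = FALSE)
    coefs <- MASS::ginv(design) %*% scores
    dimnames(coefs) <- list(colnames(design), colnames(scores))
  }
  structure(list(features = sharedFeatures, coefficients = coefs,
                 fittedOn = "source"),
            class = "regression_bridge")
}

#' Predict reference scores for a dataset through a fitted bridge
#'
#' @param bridge A `regression_bridge`.
#' @param data Feature x cell matrix carrying all bridge predictor features.
#' @return Cells x dims predicted score matrix.
#' @export
applyBridge <- function(bridge, data) {
  missing <- setdiff(bridge$features, rownames(data))
  if (length(missing)) {
    stop("bridge predictor features absent from target data: ",
         paste(utils::head(missing, 3L), collapse = ", "))
  }
  X <- t(.asDense(data[bridge$features, , drop = FALSE]))
  scores <- cbind(1, X) %*% bridge$coefficients
  rownames(scores) <- colnames(data)
  scores
}

#' Project a dataset onto a reference by chaining bridges along a path
#'
#' Walks an ordered dataset path starting at the reference. At each hop the
#' next dataset's scores are obtained directly (if it carries every loading
#' feature) or by regressing the previous dataset's estimated scores on the
#' features the two datasets share and predicting on the next dataset. The
#' terminal dataset's predicted scores are returned.
#'
#' @param path Character vector of dataset names; `path[1]` must equal the
#'   model's reference.
#' @param datasets Named list of feature x cell matrices containing every
#'   path dataset.
#' @param model A `reference_model` fitted on `path[1]`.
#' @return Cells x dims score matrix for the terminal dataset.
#' @export
projectAlongPath <- function(path, datasets, model) {
  if (path[1] != model$name) {
    stop("path must start at the model's reference dataset '",
         model$name, "'")
  }
  missing <- setdiff(path, names(datasets))
  if (length(missing)) stop("datasets absent: ", paste(missing, collapse = ", "))
  curScores <- model$scores
  curData <- datasets[[path[1]]]
  if (length(path) == 1L) return(curScores)
  loadFeats <- rownames(model$loadings)
  for (step in seq(2L, length(path))) {
    nxtData <- datasets[[path[step]]]
    if (all(loadFeats %in% rownames(nxtData))) {
      nxtScores <- projectDirect(nxtData, model)
    } else {
      shared <- intersect(rownames(curData), rownames(nxtData))
      if (!length(shared)) {
        stop("consecutive path datasets '", path[step - 1L], "' and '",
             path[step], "' share no features")
      }
      bridge <- fitBridge(curScores, curData, shared)
      nxtScores <- applyBridge(bridge, nxtData)
    }
    curScores <- nxtScores
    curData <- nxtData
  }
  curScores
}

#' Reweight reference score blocks
#'
#' Each block is divided by its own overall matrix norm (L1 by default: the
#' sum of absolute entries; optionally Frobenius/L2) and multiplied by its
#' weight, making blocks from different references commensurate before
#' column concatenation. With equal weights every block ends up with equal
#' norm; block norms are proportional to the weights.
#'
#' @param blocks List of score matrices.
#' @param weights Numeric vector in \[0, 1\], one per block.
#' @param norm `"L1"` (default) or `"L2"`.
#' @return List of rescaled blocks.
#' @export
reweightBlocks <- function(blocks, weights = rep(1, length(blocks)),
                           norm = c("L1", "L2")) {
  norm <- match.arg(norm)
  if (length(blocks) != length(weights)) {
    stop("need one weight per block")
  }
  if (any(weights < 0 | weights > 1)) stop("weights must lie in [0, 1]")
  lapply(seq_along(blocks), function(j) {
    b <- as.matrix(blocks[[j]])
    nv <- if (norm == "L1") sum(abs(b)) else sqrt(sum(b^2))
    if (nv == 0) stop("block ", j, " has zero norm (degenerate reference)")
    b * (weights[j] / nv)
  })
}

#' Mosaic integration into a joint low-dimensional embedding
#'
#' For every reference dataset, a PCA (or LDA, when labels are given)
#' reduction is fitted on all of that dataset's features, and every dataset
#' is projected onto those coordinates: the reference maps to its own
#' scores, a dataset carrying the full loading panel is projected directly,
#' and any other dataset is reached by chaining least-squares regression
#' bridges along the weighted shortest path of the mosaic data topology.
#' The per-reference score blocks are reweighted by their overall matrix
#' norm and a user weight, then concatenated column-wise.
#'
#' @param datasets Named list of feature x cell matrices
#'   (see [validateDatasets()]); the topology over them must be connected.
#' @param references Names of datasets to use as references (default all).
#' @param ndims Dimensions requested per reference (default 50).
#' @param labels Optional named label vector; references whose cells are
#'   fully covered are fitted with LDA, others with PCA.
#' @param weights Per-reference weights in \[0, 1\] (default 1).
#' @param norm Block-norm used for reweighting, `"L1"` or `"L2"`.
#' @param verbose Log chosen paths and dimension capping.
#' @return A `mosaic_embedding`: numeric matrix (total cells x total dims)
#'   with cell identifiers as row names, plus attributes `dataset` (factor,
#'   dataset of origin per row) and `block` (factor, originating reference
#'   per column).
#' @export
#' @examples
#' sc <- mosaicScenario(nCells = c(60, 60), seed = 1)
#' sim <- generateMosaic(sc)
#' emb <- mosaicEmbed(sim$datasets, ndims = 5)
#' dim(emb)
mosaicEmbed <- function(datasets, references = names(datasets), ndims = 50,
                        labels = NULL, weights = rep(1, length(references)),
                        norm = c("L1", "L2"), verbose = FALSE) {
  norm <- match.arg(norm)
  validateDatasets(datasets)
  if (!length(references)) stop("at least one reference dataset is required")
  missing <- setdiff(references, names(datasets))
  if (length(missing)) {
    stop("unknown reference datasets: ", paste(missing, collapse = ", "))
  }
  if (length(weights) == 1L) weights <- rep(weights, length(references))
  topology <- mosaicTopology(datasets)
  assertConnected(topology)
  cellIds <- unlist(lapply(datasets, colnames), use.names = FALSE)
  datasetOf <- factor(rep(names(datasets),
                          vapply(datasets, ncol, integer(1))),
                      levels = names(datasets))
  blocks <- vector("list", length(references))
  for (j in seq_along(references)) {
    r <- references[j]
    refLabels <- NULL
    if (!is.null(labels) && all(colnames(datasets[[r]]) %in% names(labels))) {
      refLabels <- labels
    }
    model <- fitReference(datasets[[r]], ndims = ndims, labels = refLabels,
                          name = r)
    block <- matrix(NA_real_, length(cellIds), length(model$dimNames),
                    dimnames = list(cellIds, model$dimNames))
    for (i in names(datasets)) {
      if (i == r) {
        sc <- model$scores
      } else if (all(rownames(model$loadings) %in% rownames(datasets[[i]]))) {
        sc <- projectDirect(datasets[[i]], model)
      } else {
        path <- topologyPath(topology, r, i)
        if (verbose) {
          message("reference ", r, " -> ", i, " via [",
                  paste(path, collapse = " -> "), "]")
        }
        sc <- projectAlongPath(path, datasets, model)
      }
      block[rownames(sc), ] <- sc
    }
    blocks[[j]] <- block
  }
  blocks <- reweightBlocks(blocks, weights, norm = norm)
  emb <- do.call(cbind, blocks)
  rownames(emb) <- cellIds
  structure(emb,
            dataset = datasetOf,
            block = factor(rep(references,
                               vapply(blocks, ncol, integer(1))),
                           levels = unique(references)),
            class = c("mosaic_embedding", class(emb)))
}

#' Dataset-of-origin of each embedding row
#' @param embedding A `mosaic_embedding`.
#' @return Factor with one level per input dataset.
#' @export
embeddingDataset <- function(embedding) attr(embedding, "dataset")

#' Originating reference of each embedding column
#' @param embedding A `mosaic_embedding`.
#' @return Factor with one level per reference.
#' @export
embeddingBlock <- function(embedding) attr(embedding, "block")

#' @export
print.mosaic_embedding <- function(x, ...) {
  cat(sprintf("mosaic_embedding: %d cells x %d dims (%d datasets, blocks: %s)\n",
              nrow(x), ncol(x), nlevels(embeddingDataset(x)),
              paste(levels(embeddingBlock(x)), collapse = ", ")))
  invisible(x)
}
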