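#' Build a symmetric spatial k-nearest-neighbour graph
#'
#' Connects each cell to its `k` nearest cells in 2-D space and symmetrises
#' the relation (an edge exists if either endpoint selects the other).
#' `k = 6` approximates the edge density of a Delaunay triangulation of a
#' planar point pattern.
#'
#' @param coords Cells x 2 numeric matrix (or data.frame) of spatial
#'   coordinates with cell identifiers as row names.
#' @param k Neighbour count used before symmetrisation (default 6).
#' @param edges Optional caller-supplied edge list (two-column matrix or
#'   data.frame of cell identifiers); when given, `k` is ignored.
#' @return Object of class `spatial_graph`: list with `cells`, `coords` and
#'   `adjacency` (a symmetric sparse 0/1 Matrix with empty diagonal).
#' @export
spatialGraph <- function(coords, k = 6, edges = NULL) {
  coords <- as.matrix(coords)
  cells <- rownames(coords)
  if (is.null(cells)) stop("'coords' must have cell identifiers as row names")
  n <- nrow(coords)
  if (is.null(edges)) {
    if (k >= n) stop("k must be smaller than the number of cells")
    nn <- .knnIndex(coords, coords, k + 1L)
    ii <- rep(seq_len(n), each = k + 1L)
    jj <- as.integer(t(nn))
    keep <- ii != jj
    A <- Matrix::sparseMatrix(i = ii[keep], j = jj[keep], x = 1,
                              dims = c(n, n))
  } else {
    edges <- as.matrix(edges)
    i <- match(edges[, 1], cells); j <- match(edges[, 2], cells)
    if (anyNA(i) || anyNA(j)) stop("edge list names cells absent from coords")
    keep <- i != j
    A <- Matrix::sparseMatrix(i = i[keep], j = j[keep], x = 1,
                              dims = c(n, n))
  }
  A <- A + Matrix::t(A)
  A@x <- rep(1, length(A@x))
  Matrix::diag(A) <- 0
  A <- Matrix::drop0(A)
  dimnames(A) <- list(cells, cells)
  structure(list(cells = cells, coords = coords, adjacency = A),
            class = "spatial_graph")
}

#' @export
print.spatial_graph <- function(x, ...) {
  cat(sprintf("spatial_graph: %d cells, %d edges\n", length(x$cells),
              Matrix::nnzero(x$adjacency) / 2))
  invisible(x)
}

#' Write or read a spatial graph edge list
#' @param graph A `spatial_graph`.
#' @param file TSV path.
#' @return Invisibly, the file path.
#' @export
writeSpatialGraph <- function(graph, file) {
  A <- methods::as(Matrix::triu(graph$adjacency), "TsparseMatrix")
  utils::write.table(data.frame(from = graph$cells[A@i + 1L],
                                to = graph$cells[A@j + 1L]),
                     file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Mean expression over spatial neighbourhoods
#'
#' For each gene g and cell i computes the mean expression of g among the
#' cells at most `maxSteps` hops from i in the spatial graph (excluding i
#' itself), yielding derived features that describe each cell's local
#' spatial context. Derived features are renamed with `suffix` so they can
#' be concatenated with the originals. An isolated cell keeps its own
#' expression as the fallback value, so the derived features stay defined.
#'
#' @param expression Feature x cell matrix; its cells must all be in the
#'   graph.
#' @param graph A `spatial_graph`.
#' @param maxSteps Neighbourhood radius in graph hops (default 2).
#' @param suffix Appended to each feature name (default `"_nbhd"`).
#' @return Feature x cell matrix of neighbourhood means, same shape as
#'   `expression`.
#' @export
neighborMeanFeatures <- function(expression, graph, maxSteps = 2,
                                 suffix = "_nbhd") {
  stopifnot(inherits(graph, "spatial_graph"))
  cells <- colnames(expression)
  missing <- setdiff(cells, graph$cells)
  if (length(missing)) {
    stop(length(missing), " expression cells absent from the spatial graph")
  }
  A <- graph$adjacency
  reach <- A
  hop <- A
  step <- 1L
  while (step < maxSteps) {
    hop <- hop %*% A
    reach <- reach + hop
    step <- step + 1L
  }
  reach <- 1 * (reach != 0)
  Matrix::diag(reach) <- 0
  reach <- reach[cells, graph$cells, drop = FALSE]
  counts <- Matrix::rowSums(reach)
  X <- .asDense(expression)
  full <- matrix(0, nrow(X), length(graph$cells),
                 dimnames = list(rownames(X), graph$cells))
  full[, cells] <- X
  out <- as.matrix(full %*% Matrix::t(reach))
  nonzero <- counts > 0
  out[, nonzero] <- sweep(out[, nonzero, drop = FALSE], 2, counts[nonzero],
                          "/")
  out[, !nonzero] <- X[, !nonzero]
  dimnames(out) <- list(paste0(rownames(X), suffix), cells)
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with monotonicity enforcement; missing values
#' propagate as missing and do not enter the ranking.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return Adjusted p-values, same length and names.
#' @export
adjustBH <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Local enrichment test on the joint embedding
#'
#' For each query cell, its `nNeighbors` nearest cells are drawn from every
#' perturbation sample (for example each chimera replicate) in embedding
#' space, and the fraction of marked (for example td-Tomato positive) cells
#' in each neighbourhood is computed. Those per-sample fractions are then
#' modelled with binomial logistic regression,
#' `logit(p) = b0 + b1 * x1 + b2 * x2`, where `x1` is each sample's overall
#' marked fraction (its baseline contribution rate) and `x2` indicates the
#' perturbed genotype; neighbourhood sizes enter as binomial weights. The
#' genotype coefficient `b2` measures local enrichment (positive) or
#' depletion (negative) of perturbed cells around the query cell, and is
#' tested with a likelihood-ratio chi-squared test (1 df) against the model
#' without `x2`. P-values are Benjamini-Hochberg adjusted across query
#' cells; cells whose fit does not converge get `NA` and are excluded from
#' the ranking.
#'
#' @param embedding A `mosaic_embedding` (or matrix with cell-id row names)
#'   containing the query cells and every sample's cells.
#' @param queryCells Cell identifiers tested one at a time.
#' @param sampleCells Named list: for each sample, the identifiers of its
#'   cells in the embedding.
#' @param positive Character vector of marked cell identifiers (or named
#'   logical vector over all sample cells).
#' @param genotype Named vector (one entry per sample) coercible to 0/1;
#'   1 marks the perturbed group.
#' @param nNeighbors Neighbourhood size per sample (default 1000).
#' @param baseline Optional named per-sample baseline marked proportions
#'   (`x1`); by default the observed marked fraction of each sample's
#'   cells.
#' @return data.frame with one row per query cell: `cell_id`, `beta2`,
#'   `stat`, `p`, `fdr`.
#' @export
localEnrichmentTest <- function(embedding, queryCells, sampleCells, positive,
                                genotype, nNeighbors = 1000,
                                baseline = NULL) {
  samples <- names(sampleCells)
  if (is.null(samples)) stop("'sampleCells' must be a named list")
  if (!all(samples %in% names(genotype))) {
    stop("'genotype' must name every sample")
  }
  x2 <- as.numeric(genotype[samples])
  if (!all(x2 %in% c(0, 1))) stop("'genotype' must be coercible to 0/1")
  if (is.logical(positive)) positive <- names(positive)[positive]
  query <- .embRows(embedding, queryCells)
  nPer <- vapply(sampleCells, length, integer(1))
  short <- samples[nPer < nNeighbors]
  if (length(short)) {
    stop("samples with fewer than nNeighbors cells: ",
         paste(short, collapse = ", "))
  }
  # per-sample: neighbourhood positive counts for all query cells at once
  posCount <- matrix(0, length(queryCells), length(samples),
                     dimnames = list(queryCells, samples))
  x1 <- numeric(length(samples))
  if (!is.null(baseline) && !all(samples %in% names(baseline))) {
    stop("'baseline' must name every sample")
  }
  for (s in seq_along(samples)) {
    cellsS <- sampleCells[[s]]
    x1[s] <- if (is.null(baseline)) mean(cellsS %in% positive) else
      baseline[[samples[s]]]
    nn <- .knnIndex(.embRows(embedding, cellsS), query, nNeighbors)
    isPos <- cellsS %in% positive
    posCount[, s] <- vapply(seq_len(nrow(nn)),
                            function(i) sum(isPos[nn[i, ]]), numeric(1))
  }
  res <- data.frame(cell_id = queryCells, beta2 = NA_real_,
                    stat = NA_real_, p = NA_real_, fdr = NA_real_,
                    stringsAsFactors = FALSE)
  Xfull <- cbind(1, x1, x2)
  Xred <- cbind(1, x1)
  wts <- rep(nNeighbors, length(samples))
  for (i in seq_along(queryCells)) {
    y <- posCount[i, ] / nNeighbors
    fit <- tryCatch({
      full <- suppressWarnings(
        stats::glm.fit(Xfull, y, weights = wts,
                       family = stats::binomial()))
      red <- suppressWarnings(
        stats::glm.fit(Xred, y, weights = wts,
                       family = stats::binomial()))
      if (!full$converged || !red$converged) NULL else list(full, red)
    }, error = function(e) NULL)
    if (is.null(fit)) next
    b2 <- fit[[1]]$coefficients[3]
    if (!is.finite(b2) || abs(b2) > 20) next      # separation guard
    stat <- max(0, fit[[2]]$deviance - fit[[1]]$deviance)
    res$beta2[i] <- b2
    res$stat[i] <- stat
    res$p[i] <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  res$fdr <- adjustBH(res$p)
  res
}

#' Write enrichment results as TSV
#' @param result data.frame from [localEnrichmentTest()].
#' @param file Output path.
#' @return Invisibly, the file path.
#' @export
writeEnrichment <- function(result, file) {
  utils::write.table(result, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
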