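#' Describe a synthetic mosaic integration scenario
#'
#' The generator draws cells from a shared low-dimensional latent space:
#' each cell type is a Gaussian mixture component in latent space, observed
#' features are linear combinations of the latent coordinates (a fixed
#' random loading matrix) plus Gaussian noise, and every dataset observes
#' only its own feature panel. Because the observation model is linear, the
#' projection algebra of the embedding is exactly recoverable, which gives
#' sharp oracles for testing. A fraction of features can be made
#' uninformative (near-zero loadings) to emulate panels dominated by
#' non-informative features.
#'
#' @param nDatasets Number of datasets (ignored when `panels` is given).
#' @param nCells Cells per dataset (recycled).
#' @param nFeatures Total feature pool size.
#' @param latentDim Latent dimension.
#' @param nTypes Number of cell types (mixture components).
#' @param proportions Mixture proportions (default equal).
#' @param separation Distance scale between type centroids in latent space.
#' @param noiseSd Observation noise standard deviation.
#' @param uninformativeFrac Fraction of pool features with near-zero
#'   loadings.
#' @param panels Optional list of feature-index or feature-name vectors,
#'   one per dataset; default: every dataset observes the full pool.
#' @param seed Integer seed; the scenario plus seed fully determines the
#'   draw.
#' @return Object of class `mosaic_scenario`.
#' @export
mosaicScenario <- function(nDatasets = 2, nCells = 200, nFeatures = 100,
                           latentDim = 10, nTypes = 3,
                           proportions = rep(1 / nTypes, nTypes),
                           separation = 5, noiseSd = 0.5,
                           uninformativeFrac = 0, panels = NULL,
                           seed = 1) {
  if (!is.null(panels)) nDatasets <- length(panels)
  nCells <- rep_len(nCells, nDatasets)
  stopifnot(nFeatures >= 1, latentDim >= 1, nTypes >= 1,
            abs(sum(proportions) - 1) < 1e-8, noiseSd >= 0,
            uninformativeFrac >= 0, uninformativeFrac <= 1)
  structure(list(nDatasets = nDatasets, nCells = nCells,
                 nFeatures = nFeatures, latentDim = latentDim,
                 nTypes = nTypes, proportions = proportions,
                 separation = separation, noiseSd = noiseSd,
                 uninformativeFrac = uninformativeFrac,
                 panels = panels, seed = as.integer(seed)),
            class = "mosaic_scenario")
}

#' Generate synthetic mosaic datasets with known ground truth
#'
#' @param scenario A `mosaic_scenario`.
#' @return List with `datasets` (named list of panel-restricted feature x
#'   cell matrices), `full` (the complete feature pool x all cells matrix),
#'   `latent` (latentDim x cells), `labels` (named cell-type factor) and
#'   `panels` (feature names per dataset).
#' @export
#' @examples
#' sim <- generateMosaic(mosaicScenario(nCells = 50, seed = 7))
#' names(sim$datasets)
generateMosaic <- function(scenario) {
  stopifnot(inherits(scenario, "mosaic_scenario"))
  sc <- scenario
  set.seed(sc$seed)
  featNames <- sprintf("g%04d", seq_len(sc$nFeatures))
  panels <- sc$panels
  if (is.null(panels)) {
    panels <- replicate(sc$nDatasets, featNames, simplify = FALSE)
  } else {
    panels <- lapply(panels, function(p) {
      if (is.numeric(p)) {
        if (any(p < 1 | p > sc$nFeatures)) stop("panel index out of range")
        featNames[p]
      } else {
        bad <- setdiff(p, featNames)
        if (length(bad)) stop("panel names outside the feature pool: ",
                              paste(utils::head(bad, 3), collapse = ", "))
        p
      }
    })
  }
  if (is.null(names(panels))) {
    names(panels) <- paste0("D", seq_along(panels))
  }
  total <- sum(sc$nCells)
  centroids <- matrix(stats::rnorm(sc$latentDim * sc$nTypes,
                                   sd = sc$separation),
                      sc$latentDim, sc$nTypes)
  types <- sample.int(sc$nTypes, total, replace = TRUE,
                      prob = sc$proportions)
  Z <- centroids[, types, drop = FALSE] +
    matrix(stats::rnorm(sc$latentDim * total), sc$latentDim, total)
  A <- matrix(stats::rnorm(sc$nFeatures * sc$latentDim,
                           sd = 1 / sqrt(sc$latentDim)),
              sc$nFeatures, sc$latentDim)
  if (sc$uninformativeFrac > 0) {
    nUninf <- floor(sc$uninformativeFrac * sc$nFeatures)
    if (nUninf > 0) {
      uninf <- sample.int(sc$nFeatures, nUninf)
      A[uninf, ] <- A[uninf, ] * 1e-3
    }
  }
  X <- A %*% Z
  if (sc$noiseSd > 0) {
    X <- X + matrix(stats::rnorm(length(X), sd = sc$noiseSd),
                    nrow(X), ncol(X))
  }
  cellIds <- sprintf("cell%05d", seq_len(total))
  dimnames(X) <- list(featNames, cellIds)
  colnames(Z) <- cellIds
  owner <- rep(names(panels), sc$nCells)
  datasets <- lapply(stats::setNames(names(panels), names(panels)),
                     function(nm) {
                       X[panels[[nm]], owner == nm, drop = FALSE]
                     })
  labels <- stats::setNames(factor(paste0("type", types)), cellIds)
  list(datasets = datasets, full = X, latent = Z, labels = labels,
       panels = panels, dataset = stats::setNames(owner, cellIds))
}

#' Reference/query split with a reduced query feature panel
#'
#' Splits the cells of a full dataset into two disjoint halves and restricts
#' the query half to a random feature subset, emulating integration of a
#' full-panel reference with a targeted-panel query.
#'
#' @param full Feature x cell matrix.
#' @param nQueryFeatures Number of features kept in the query panel.
#' @param seed Integer seed.
#' @return List with `reference` and `query` matrices and `queryFeatures`.
#' @export
featureSubsetScenario <- function(full, nQueryFeatures, seed = 1) {
  if (nQueryFeatures > nrow(full)) {
    stop("nQueryFeatures exceeds the number of available features")
  }
  set.seed(seed)
  n <- ncol(full)
  refIdx <- sort(sample.int(n, floor(n / 2)))
  qIdx <- setdiff(seq_len(n), refIdx)
  qFeats <- sort(sample(rownames(full), nQueryFeatures))
  list(reference = full[, refIdx, drop = FALSE],
       query = full[qFeats, qIdx, drop = FALSE],
       queryFeatures = qFeats)
}

#' Three-way multi-hop split of a paired two-modality dataset
#'
#' Allocates the common cells of two modality matrices into three disjoint
#' groups: modality-1 only, a bridge carrying both panels, and modality-2
#' only. The two single-modality datasets then share no features and can
#' only be co-embedded through the bridge.
#'
#' @param modality1,modality2 Feature x cell matrices over the same cells
#'   with disjoint feature names.
#' @param fractionBridge Fraction of cells allocated to the bridge; the
#'   remainder is split equally between the single-modality groups. May
#'   also be given as `nBridge`, an absolute cell count.
#' @param nBridge Optional absolute bridge size (overrides
#'   `fractionBridge`).
#' @param seed Integer seed.
#' @return Named list of three datasets (`mod1`, `bridge`, `mod2`) plus the
#'   allocation factor.
#' @export
multihopSplitScenario <- function(modality1, modality2, fractionBridge = 1 / 3,
                                  nBridge = NULL, seed = 1) {
  cells <- colnames(modality1)
  if (!identical(cells, colnames(modality2))) {
    stop("modalities must share an identical cell set and order")
  }
  if (length(intersect(rownames(modality1), rownames(modality2)))) {
    stop("modalities must have disjoint feature panels")
  }
  set.seed(seed)
  n <- length(cells)
  if (is.null(nBridge)) nBridge <- round(fractionBridge * n)
  if (nBridge <= 0) {
    warning("empty bridge: the two single-modality datasets will be ",
            "disconnected in the topology")
    nBridge <- 0L
  }
  perm <- sample(n)
  nSide <- floor((n - nBridge) / 2)
  alloc <- rep("mod2", n)
  alloc[perm[seq_len(nSide)]] <- "mod1"
  if (nBridge > 0) alloc[perm[nSide + seq_len(nBridge)]] <- "bridge"
  alloc <- stats::setNames(alloc, cells)
  # disjoint cell identifiers across datasets: suffix by allocation
  rename <- function(x, tag) {
    colnames(x) <- paste0(colnames(x), ".", tag); x
  }
  out <- list()
  out$mod1 <- rename(modality1[, alloc == "mod1", drop = FALSE], "m1")
  if (nBridge > 0) {
    out$bridge <- rename(rbind(modality1, modality2)[, alloc == "bridge",
                                                     drop = FALSE], "br")
  }
  out$mod2 <- rename(modality2[, alloc == "mod2", drop = FALSE], "m2")
  list(datasets = out, allocation = alloc)
}

#' Sequential chain of datasets with fixed pairwise feature overlap
#'
#' Splits cells into `nChain` groups and assigns each group a sliding
#' window over a shuffled feature pool so that dataset i shares features
#' only with datasets i - 1 and i + 1 (about `overlapFraction` of each
#' panel), making the topology a path graph - the extreme multi-hop
#' setting.
#'
#' @param full Feature x cell matrix (the feature pool).
#' @param nChain Number of datasets in the chain (default 8).
#' @param nFeatures Features per dataset panel.
#' @param overlapFraction Fraction of each panel shared with the next
#'   dataset (default 0.5).
#' @param cellsPerDataset Cells per chain dataset (default: equal split).
#' @param seed Integer seed.
#' @return Named list of datasets `chain1..chainN` plus `panels`.
#' @export
sequentialChainScenario <- function(full, nChain = 8, nFeatures,
                                    overlapFraction = 0.5,
                                    cellsPerDataset = NULL, seed = 1) {
  set.seed(seed)
  ov <- round(nFeatures * overlapFraction)
  stride <- nFeatures - ov
  poolNeeded <- nFeatures + (nChain - 1) * stride
  if (poolNeeded > nrow(full)) {
    stop("need ", poolNeeded, " pool features for the requested chain, ",
         "have ", nrow(full))
  }
  if (is.null(cellsPerDataset)) cellsPerDataset <- floor(ncol(full) / nChain)
  if (nChain * cellsPerDataset > ncol(full)) {
    stop("not enough cells for ", nChain, " datasets of ", cellsPerDataset)
  }
  pool <- sample(rownames(full), poolNeeded)
  cellPerm <- sample(ncol(full), nChain * cellsPerDataset)
  datasets <- list()
  panels <- list()
  for (i in seq_len(nChain)) {
    fIdx <- ((i - 1) * stride + 1):((i - 1) * stride + nFeatures)
    cIdx <- cellPerm[((i - 1) * cellsPerDataset + 1):(i * cellsPerDataset)]
    panels[[i]] <- pool[fIdx]
    datasets[[i]] <- full[pool[fIdx], cIdx, drop = FALSE]
  }
  names(datasets) <- names(panels) <- paste0("chain", seq_len(nChain))
  list(datasets = datasets, panels = panels)
}
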