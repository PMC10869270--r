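test_that("PCA reference fit matches a dense SVD oracle up to column sign", {
  set.seed(10)
  X <- randDataset(paste0("g", 1:30), 100)
  model <- fitReference(X, ndims = 8, name = "ref")
  Y <- t(X - rowMeans(X))
  sv <- svd(Y)
  oracleScores <- sv$u[, 1:8] %*% diag(sv$d[1:8])
  oracleLoad <- sv$v[, 1:8]
  for (j in 1:8) {
    s <- sign(sum(model$loadings[, j] * oracleLoad[, j]))
    expect_equal(unname(model$loadings[, j]), s * oracleLoad[, j],
                 tolerance = 1e-8)
    expect_equal(unname(model$scores[, j]), s * oracleScores[, j],
                 tolerance = 1e-8)
  }
  # scores are the centred data times loadings, by construction
  expect_equal(unname(model$scores),
               unname(Y %*% model$loadings), tolerance = 1e-10)
})

test_that("requested dimensions are honoured and capped", {
  set.seed(11)
  big <- randDataset(paste0("g", 1:200), 500)
  model <- fitReference(big, ndims = 50)
  expect_equal(ncol(model$scores), 50)
  small <- randDataset(paste0("g", 1:5), 20)
  expect_warning(m2 <- fitReference(small, ndims = 50), "capping")
  expect_equal(ncol(m2$scores), 5)
  tiny <- randDataset(paste0("g", 1:10), 3)
  expect_warning(m3 <- fitReference(tiny, ndims = 50), "capping")
  expect_equal(ncol(m3$scores), 2)   # n cells - 1
})

test_that("rank-1 data concentrates all variance on the first component", {
  v <- rnorm(40)
  X <- rbind(g1 = v, g2 = v)            # cells exactly on the line y = x
  colnames(X) <- paste0("c", seq_along(v))
  model <- fitReference(X, ndims = 2)
  vars <- apply(model$scores, 2, var)
  expect_equal(vars[1], sum(apply(t(X - rowMeans(X)), 2, var)),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_lt(max(abs(model$scores[, 2])), 1e-8)
  expect_error(fitReference(X * 0 + 3, ndims = 2), "zero variance")
})

test_that("LDA reference caps dimensions at classes minus one", {
  set.seed(12)
  sim <- generateMosaic(mosaicScenario(nDatasets = 1, nCells = 120,
                                       nFeatures = 20, nTypes = 3,
                                       noiseSd = 0.5, seed = 12))
  d <- sim$datasets[[1]]
  model <- fitReference(d, ndims = 50, labels = sim$labels, name = "r")
  expect_equal(model$mode, "lda")
  expect_equal(ncol(model$scores), 2)    # 3 classes - 1
  # round-trip: stored scores equal direct projection of the same data
  expect_equal(unname(projectDirect(d, model)), unname(model$scores),
               tolerance = 1e-10)
  oneClass <- setNames(rep("a", ncol(d)), colnames(d))
  expect_error(fitReference(d, labels = oneClass), "2 classes")
})

test_that("user-supplied reductions are accepted as reference models", {
  set.seed(13)
  X <- randDataset(paste0("g", 1:10), 30)
  L <- matrix(rnorm(30), 10, 3, dimnames = list(rownames(X), NULL))
  model <- fitReference(X, loadings = L, name = "usr")
  expect_equal(model$mode, "user")
  expect_equal(unname(model$scores), unname(t(X) %*% L), tolerance = 1e-10)
})

test_that("direct projection is the centred cross-product, and round-trips", {
  set.seed(14)
  X <- randDataset(paste0("g", 1:15), 40)
  model <- fitReference(X, ndims = 5)
  expect_equal(projectDirect(X, model), model$scores, tolerance = 1e-10)
  # a cell equal to the feature means projects to the origin
  mu <- matrix(rowMeans(X), ncol = 1,
               dimnames = list(rownames(X), "mcell"))
  expect_lt(max(abs(projectDirect(mu, model))), 1e-10)
  # naive triple-loop oracle on a random query
  Q <- randDataset(rownames(X), 7, prefix = "q")
  got <- projectDirect(Q, model)
  oracle <- matrix(0, 7, 5)
  for (i in 1:7) for (j in 1:5) {
    acc <- 0
    for (f in rownames(X)) {
      acc <- acc + (Q[f, i] - model$featureMeans[f]) * model$loadings[f, j]
    }
    oracle[i, j] <- acc
  }
  expect_equal(unname(got), oracle, tolerance = 1e-10)
  # partial panels are refused with a pointer to the bridge route
  expect_error(projectDirect(Q[1:3, , drop = FALSE], model), "bridge")
})

test_that("a full-panel bridge reproduces direct projection", {
  set.seed(15)
  X <- randDataset(paste0("g", 1:20), 80)
  model <- fitReference(X, ndims = 6)
  bridge <- fitBridge(model$scores, X, rownames(X))
  pred <- applyBridge(bridge, X)
  expect_equal(unname(pred), unname(model$scores), tolerance = 1e-7)
  # and on new data from the same space the two projections agree
  Q <- randDataset(rownames(X), 25, prefix = "q")
  relErr <- max(abs(applyBridge(bridge, Q) - projectDirect(Q, model))) /
    max(abs(model$scores))
  expect_lt(relErr, 1e-6)
})

test_that("bridge coefficients recover exact linear maps", {
  set.seed(16)
  X <- randDataset("g1", 30)
  scores <- t(X) * 2 + 1                  # score = 2 * feature + 1
  colnames(scores) <- "d1"
  bridge <- fitBridge(scores, X, "g1")
  expect_equal(unname(bridge$coefficients[, 1]), c(1, 2), tolerance = 1e-10)
  # identically zero scores give zero coefficients
  z <- fitBridge(scores * 0, X, "g1")
  expect_lt(max(abs(z$coefficients)), 1e-12)
  # applying a bridge to its own source returns OLS fitted values
  X2 <- randDataset(paste0("g", 1:4), 50)
  s2 <- matrix(rnorm(100), 50, 2,
               dimnames = list(colnames(X2), c("d1", "d2")))
  b2 <- fitBridge(s2, X2, rownames(X2))
  design <- cbind(1, t(X2))
  fitted <- design %*% qr.coef(qr(design), s2)
  expect_equal(unname(applyBridge(b2, X2)), unname(fitted),
               tolerance = 1e-10)
})

test_that("rank-deficient shared panels fall back to minimum-norm fits", {
  set.seed(17)
  X <- randDataset(paste0("g", 1:30), 10)   # more predictors than cells
  s <- matrix(rnorm(20), 10, 2, dimnames = list(colnames(X), NULL))
  expect_warning(b <- fitBridge(s, X, rownames(X)), "minimum-norm")
  expect_true(all(is.finite(b$coefficients)))
  # min-norm fit still interpolates the training scores
  expect_equal(unname(applyBridge(b, X)), unname(s), tolerance = 1e-6)
})

test_that("bridge prediction equals hand-rolled matrix arithmetic", {
  set.seed(18)
  X <- randDataset(paste0("g", 1:6), 40)
  s <- matrix(rnorm(120), 40, 3, dimnames = list(colnames(X), NULL))
  b <- fitBridge(s, X, rownames(X))
  Q <- randDataset(rownames(X), 9, prefix = "q")
  got <- applyBridge(b, Q)
  oracle <- matrix(0, 9, 3)
  for (i in 1:9) for (j in 1:3) {
    acc <- b$coefficients[1, j]
    for (fi in seq_along(b$features)) {
      acc <- acc + Q[b$features[fi], i] * b$coefficients[fi + 1, j]
    }
    oracle[i, j] <- acc
  }
  expect_equal(unname(got), oracle, tolerance = 1e-10)
})

test_that("multi-hop projection follows the path and preserves geometry", {
  set.seed(19)
  # noiseless rank-2 latent model; B shares informative panels with A and C
  sim <- generateMosaic(mosaicScenario(
    nCells = c(80, 80, 80), nFeatures = 60, latentDim = 2, nTypes = 2,
    noiseSd = 0, panels = list(A = 1:30, B = 11:50, C = 31:60), seed = 19))
  model <- fitReference(sim$datasets$A, ndims = 2, name = "A")
  expect_equal(projectAlongPath("A", sim$datasets, model), model$scores)
  # noiseless rank-2 data makes every shared panel rank deficient, so the
  # bridges legitimately fall back to minimum-norm fits
  twoHop <- suppressWarnings(
    projectAlongPath(c("A", "B", "C"), sim$datasets, model))
  # oracle: direct projection of C's cells using the full feature pool
  fullC <- sim$full[rownames(sim$datasets$A),
                    colnames(sim$datasets$C), drop = FALSE]
  direct <- projectDirect(fullC, model)
  for (j in 1:2) {
    expect_gt(abs(cor(twoHop[, j], direct[, j])), 0.99)
  }
  expect_error(projectAlongPath(c("B", "C"), sim$datasets, model),
               "must start")
})

test_that("block reweighting equalises norms and scales with weights", {
  set.seed(20)
  b1 <- matrix(rnorm(50), 10, 5)
  b2 <- matrix(rnorm(200, sd = 9), 20, 10)
  out <- reweightBlocks(list(b1, b2), c(1, 1))
  expect_equal(sum(abs(out[[1]])), sum(abs(out[[2]])), tolerance = 1e-12)
  out2 <- reweightBlocks(list(b1, b2), c(1, 0))
  expect_true(all(out2[[2]] == 0))
  out3 <- reweightBlocks(list(b1, b2), c(1, 0.5))
  expect_equal(sum(abs(out3[[1]])) / sum(abs(out3[[2]])), 2,
               tolerance = 1e-12)
  outL2 <- reweightBlocks(list(b1, b2), c(1, 1), norm = "L2")
  expect_equal(sqrt(sum(outL2[[1]]^2)), sqrt(sum(outL2[[2]]^2)),
               tolerance = 1e-12)
  expect_error(reweightBlocks(list(b1 * 0), 1), "zero norm")
})

test_that("single-reference embedding is the reference PCA up to scale", {
  set.seed(21)
  X <- randDataset(paste0("g", 1:20), 60)
  emb <- mosaicEmbed(list(solo = X), ndims = 5)
  model <- fitReference(X, ndims = 5, name = "solo")
  ratio <- unclass(emb) / model$scores
  expect_lt(diff(range(ratio)), 1e-10)
  expect_gt(ratio[1, 1], 0)
})

test_that("joint embedding has the expected shape, blocks and finiteness", {
  set.seed(22)
  sim <- generateMosaic(mosaicScenario(
    nCells = c(70, 70, 70), nFeatures = 90, latentDim = 5,
    panels = list(A = 1:40, B = 21:70, C = 51:90), noiseSd = 0.3,
    seed = 22))
  emb <- mosaicEmbed(sim$datasets, ndims = 6)
  expect_equal(nrow(emb), 210)
  expect_equal(ncol(emb), 18)                       # 3 references x 6 dims
  expect_true(all(is.finite(emb)))
  expect_equal(as.character(unique(embeddingBlock(emb))), c("A", "B", "C"))
  expect_equal(table(embeddingDataset(emb))[["B"]], 70L)
  expect_identical(rownames(emb),
                   unlist(lapply(sim$datasets, colnames),
                          use.names = FALSE))
})

test_that("embedding rows are equivariant to permuting cells within a dataset", {
  set.seed(23)
  sim <- generateMosaic(mosaicScenario(
    nCells = c(50, 50), nFeatures = 60, panels = list(A = 1:40, B = 21:60),
    noiseSd = 0.3, seed = 23))
  ds <- sim$datasets
  emb1 <- mosaicEmbed(ds, ndims = 4)
  perm <- sample(ncol(ds$B))
  ds2 <- ds; ds2$B <- ds$B[, perm]
  emb2 <- mosaicEmbed(ds2, ndims = 4)
  common <- rownames(emb1)
  expect_equal(unclass(emb2)[common, ], unclass(emb1)[common, ],
               tolerance = 1e-8)
})

test_that("embedding distances track latent-space distances on clean mosaics", {
  set.seed(24)
  sim <- generateMosaic(mosaicScenario(
    nCells = c(60, 60), nFeatures = 80, latentDim = 4, nTypes = 3,
    panels = list(A = 1:50, B = 31:80), noiseSd = 0.05, seed = 24))
  emb <- mosaicEmbed(sim$datasets, ndims = 4)
  sub <- sample(rownames(emb), 50)
  dEmb <- dist(unclass(emb)[sub, ])
  dLat <- dist(t(sim$latent[, sub]))
  expect_gt(cor(as.vector(dEmb), as.vector(dLat), method = "spearman"), 0.8)
})

test_that("disconnected collections are refused at embedding time", {
  set.seed(25)
  ds <- list(A = randDataset(c("f1", "f2"), 5, "a"),
             B = randDataset(c("f8", "f9"), 5, "b"))
  expect_error(mosaicEmbed(ds, ndims = 2), "disconnected")
  expect_error(mosaicEmbed(list(A = ds$A), references = character(0)),
               "at least one reference")
})
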