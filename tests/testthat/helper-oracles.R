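# Shared fixtures and independent oracles used across the suite.

# small named feature x cell matrix with the given feature panel
randDataset <- function(features, nCells, prefix = "c", sd = 1) {
  m <- matrix(rnorm(length(features) * nCells, sd = sd),
              length(features), nCells,
              dimnames = list(features,
                              paste0(prefix, seq_len(nCells))))
  m
}

# brute-force k nearest training rows per query row via base-R dist matrix;
# ties by training row name order
bruteKnn <- function(train, query, k) {
  dmat <- as.matrix(stats::dist(rbind(query, train)))
  nq <- nrow(query); nt <- nrow(train)
  d <- dmat[seq_len(nq), nq + seq_len(nt), drop = FALSE]
  tieOrd <- order(rownames(train))
  tieRank <- integer(nt); tieRank[tieOrd] <- seq_len(nt)
  t(vapply(seq_len(nq), function(i)
    order(round(d[i, ], 10), tieRank)[seq_len(k)], integer(k)))
}

# exhaustive enumeration of simple paths; returns minimal total cost
bruteMinPathCost <- function(topology, from, to) {
  adj <- lapply(setNames(topology$nodes, topology$nodes),
                function(v) {
                  e <- topology$edges
                  rows <- e$from == v | e$to == v
                  other <- ifelse(e$from[rows] == v, e$to[rows], e$from[rows])
                  setNames(e$cost[rows], other)
                })
  best <- Inf
  walk <- function(v, visited, cost) {
    if (cost >= best) return()
    if (v == to) { best <<- cost; return() }
    for (w in names(adj[[v]])) {
      if (!(w %in% visited)) walk(w, c(visited, w), cost + adj[[v]][[w]])
    }
  }
  walk(from, from, 0)
  best
}

# total cost of a node path under a topology's edge costs
pathCost <- function(topology, path) {
  if (length(path) < 2) return(0)
  e <- topology$edges
  sum(vapply(seq_len(length(path) - 1), function(i) {
    row <- (e$from == path[i] & e$to == path[i + 1]) |
      (e$to == path[i] & e$from == path[i + 1])
    if (!any(row)) stop("path uses a missing edge")
    e$cost[row]
  }, numeric(1)))
}

# random connected topology on n nodes: random spanning tree + extra edges,
# realised as datasets with feature panels engineering the shared counts
randomConnectedDatasets <- function(nNodes, extraEdges = 2) {
  nodes <- paste0("N", seq_len(nNodes))
  edges <- list()
  for (i in seq(2, nNodes)) {
    edges[[length(edges) + 1]] <- c(sample(i - 1, 1), i)
  }
  for (e in seq_len(extraEdges)) {
    ij <- sort(sample(nNodes, 2))
    edges[[length(edges) + 1]] <- ij
  }
  edges <- unique(edges)
  panels <- replicate(nNodes, character(0), simplify = FALSE)
  f <- 0
  for (k in seq_along(edges)) {
    w <- sample(1:5, 1)                      # shared-feature count
    shared <- paste0("f", f + seq_len(w)); f <- f + w
    i <- edges[[k]][1]; j <- edges[[k]][2]
    panels[[i]] <- c(panels[[i]], shared)
    panels[[j]] <- c(panels[[j]], shared)
  }
  # private features so no panel is empty or duplicated
  for (i in seq_len(nNodes)) {
    panels[[i]] <- unique(c(panels[[i]], paste0("p", i, "_", 1:2)))
  }
  ds <- lapply(seq_len(nNodes), function(i)
    randDataset(panels[[i]], 3, prefix = paste0("n", i, "c")))
  names(ds) <- nodes
  ds
}
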