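#' Build the mosaic data topology
#'
#' The mosaic data topology (MDT) is an undirected graph with one node per
#' dataset and an edge between two datasets whenever they share at least one
#' feature name. Edges are weighted by the absolute number of shared features;
#' the path-search cost of an edge is the reciprocal of its weight, so that
#' routes through large feature overlaps are preferred when chaining
#' projections between datasets.
#'
#' @param datasets Named list of feature x cell matrices
#'   (see [validateDatasets()]).
#' @return An object of class `mosaic_topology`: a list with `nodes`
#'   (dataset names), `edges` (data.frame with columns `from`, `to`,
#'   `weight`, `cost`) and `features` (list of feature-name vectors).
#' @export
#' @examples
#' fs <- function(f, n = 2) matrix(rnorm(length(f) * n), length(f), n,
#'   dimnames = list(f, paste0(f[1], seq_len(n))))
#' top <- mosaicTopology(list(A = fs(c("f1", "f2", "f3")),
#'                            B = fs(c("f2", "f3", "f4")),
#'                            C = fs(c("f4", "f5"))))
#' top$edges
mosaicTopology <- function(datasets) {
  validateDatasets(datasets)
  nodes <- names(datasets)
  feats <- lapply(datasets, rownames)
  from <- character(0); to <- character(0); weight <- integer(0)
  if (length(nodes) > 1L) {
    for (i in seq_len(length(nodes) - 1L)) {
      for (j in seq(i + 1L, length(nodes))) {
        w <- length(intersect(feats[[i]], feats[[j]]))
        if (w >= 1L) {
          from <- c(from, nodes[i]); to <- c(to, nodes[j])
          weight <- c(weight, w)
        }
      }
    }
  }
  edges <- data.frame(from = from, to = to, weight = weight,
                      cost = if (length(weight)) 1 / weight else numeric(0),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, features = feats),
            class = "mosaic_topology")
}

#' @export
print.mosaic_topology <- function(x, ...) {
  cat("mosaic_topology with", length(x$nodes), "datasets and",
      nrow(x$edges), "edges\n")
  if (nrow(x$edges)) {
    for (i in seq_len(nrow(x$edges))) {
      cat(sprintf("  %s -- %s  (%d shared features)\n",
                  x$edges$from[i], x$edges$to[i], x$edges$weight[i]))
    }
  }
  invisible(x)
}

# adjacency list: for each node, data.frame(node, cost)
.adjacency <- function(topology) {
  adj <- stats::setNames(vector("list", length(topology$nodes)),
                         topology$nodes)
  for (nm in topology$nodes) adj[[nm]] <- list(node = character(0),
                                               cost = numeric(0))
  e <- topology$edges
  for (i in seq_len(nrow(e))) {
    adj[[e$from[i]]]$node <- c(adj[[e$from[i]]]$node, e$to[i])
    adj[[e$from[i]]]$cost <- c(adj[[e$from[i]]]$cost, e$cost[i])
    adj[[e$to[i]]]$node <- c(adj[[e$to[i]]]$node, e$from[i])
    adj[[e$to[i]]]$cost <- c(adj[[e$to[i]]]$cost, e$cost[i])
  }
  adj
}

#' Connected components of a topology
#'
#' @param topology A `mosaic_topology`.
#' @return List of character vectors, one per connected component.
#' @export
topologyComponents <- function(topology) {
  stopifnot(inherits(topology, "mosaic_topology"))
  adj <- .adjacency(topology)
  seen <- stats::setNames(rep(FALSE, length(topology$nodes)), topology$nodes)
  comps <- list()
  for (start in topology$nodes) {
    if (seen[start]) next
    queue <- start; seen[start] <- TRUE; comp <- character(0)
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      comp <- c(comp, v)
      for (w in adj[[v]]$node) {
        if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
      }
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

#' Assert that the mosaic data topology is connected
#'
#' Integration requires a path between every pair of datasets; a disconnected
#' topology means some dataset shares no features, directly or indirectly,
#' with the rest and cannot be embedded.
#'
#' @param topology A `mosaic_topology`.
#' @return Invisibly `TRUE`; throws an error listing the connected
#'   components otherwise.
#' @export
assertConnected <- function(topology) {
  comps <- topologyComponents(topology)
  if (length(comps) > 1L) {
    desc <- vapply(comps, function(cc) paste0("{", paste(cc, collapse = ", "),
                                              "}"), character(1))
    stop("mosaic data topology is disconnected; components: ",
         paste(desc, collapse = " "))
  }
  invisible(TRUE)
}

#' Weighted shortest path between two datasets
#'
#' Dijkstra search minimising total edge cost (1 / shared-feature count), so
#' paths through large feature overlaps are preferred. Ties are broken
#' deterministically: lower total cost first, then fewer hops, then
#' lexicographically smaller node sequence.
#'
#' @param topology A `mosaic_topology`.
#' @param from,to Dataset names.
#' @return Character vector of dataset names from `from` to `to`.
#' @export
topologyPath <- function(topology, from, to) {
  stopifnot(inherits(topology, "mosaic_topology"))
  for (nm in c(from, to)) {
    if (!nm %in% topology$nodes) stop("unknown dataset name: ", nm)
  }
  if (from == to) return(from)
  adj <- .adjacency(topology)
  nodes <- topology$nodes
  dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
  hops <- stats::setNames(rep(Inf, length(nodes)), nodes)
  paths <- stats::setNames(vector("list", length(nodes)), nodes)
  done <- stats::setNames(rep(FALSE, length(nodes)), nodes)
  dist[from] <- 0; hops[from] <- 0; paths[[from]] <- from
  # (cost, hops, lexicographic path) is preserved under path extension, so a
  # plain O(n^2) Dijkstra with composite comparison stays optimal
  better <- function(c1, h1, p1, c2, h2, p2) {
    if (abs(c1 - c2) > 1e-12) return(c1 < c2)
    if (h1 != h2) return(h1 < h2)
    paste(p1, collapse = "\r") < paste(p2, collapse = "\r")
  }
  repeat {
    open <- nodes[!done & is.finite(dist)]
    if (!length(open)) break
    u <- open[1]
    for (v in open[-1]) {
      if (better(dist[v], hops[v], paths[[v]], dist[u], hops[u], paths[[u]]))
        u <- v
    }
    done[u] <- TRUE
    if (u == to) break
    a <- adj[[u]]
    for (k in seq_along(a$node)) {
      v <- a$node[k]
      if (done[v]) next
      ncost <- dist[u] + a$cost[k]
      nhops <- hops[u] + 1
      npath <- c(paths[[u]], v)
      if (better(ncost, nhops, npath, dist[v], hops[v], paths[[v]])) {
        dist[v] <- ncost; hops[v] <- nhops; paths[[v]] <- npath
      }
    }
  }
  if (!is.finite(dist[to])) {
    stop("no path between '", from, "' and '", to,
         "': topology is disconnected")
  }
  paths[[to]]
}

#' Export a topology as an edge list or DOT text
#'
#' @param topology A `mosaic_topology`.
#' @param file Output path.
#' @param format `"tsv"` for a three-column edge list
#'   (source, target, n_shared_features) or `"dot"` for Graphviz text.
#' @return Invisibly, the file path.
#' @export
writeTopology <- function(topology, file, format = c("tsv", "dot")) {
  format <- match.arg(format)
  stopifnot(inherits(topology, "mosaic_topology"))
  e <- topology$edges
  if (format == "tsv") {
    out <- data.frame(source = e$from, target = e$to,
                      n_shared_features = e$weight)
    utils::write.table(out, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    lines <- c("graph mosaic_topology {",
               paste0("  \"", topology$nodes, "\";"),
               if (nrow(e)) sprintf("  \"%s\" -- \"%s\" [label=%d];",
                                    e$from, e$to, e$weight),
               "}")
    writeLines(lines, file)
  }
  invisible(file)
}
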