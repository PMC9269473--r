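#' @include AllClasses.R
NULL

#' Threshold a weighted adjacency at a network cost
#'
#' The p% cost keeps every directed edge whose weight is at least
#' `(1 - p/100)` times the maximum weight in the matrix, so 1% retains
#' only edges within 99% of the strongest connection and 100% retains
#' every significant (nonzero) edge. Note this magnitude rule differs
#' from the "top p% of edges" convention.
#'
#' @param adj weighted adjacency matrix with `adj[i, j]` the weight of
#'   the directed edge i -> j (non-negative, self-loops ignored). Note
#'   DTF matrices are sink x source, so transpose a
#'   [adjacencyMatrix()] result before graph analysis.
#' @param cost cost level in percent, `0 < cost <= 100`.
#' @return A [DirectedNetwork-class] object.
#' @export
costThreshold <- function(adj, cost) {
  adj <- as.matrix(adj)
  stopifnot(cost > 0, cost <= 100)
  diag(adj) <- 0
  if (all(adj == 0)) stop("all-zero adjacency: nothing to threshold")
  if (any(adj < 0)) stop("edge weights must be non-negative")
  cut <- (1 - cost / 100) * max(adj)
  binary <- adj >= cut & adj > 0
  labs <- rownames(adj)
  if (is.null(labs)) labs <- paste0("Ch", seq_len(nrow(adj)))
  dimnames(binary) <- dimnames(adj) <- list(labs, labs)
  new("DirectedNetwork", weights = adj, binary = binary, cost = cost,
      labels = labs)
}

.asIgraph <- function(net) {
  igraph::graph_from_adjacency_matrix(net@binary * 1, mode = "directed")
}

#' Basic network measures: degree, density, strength
#'
#' In/out/total degree per node on the binarized graph, graph density
#' as a percentage of the `N (N - 1)` possible directed connections,
#' and in/out strength as the sum of incident edge weights (weights are
#' used for strength only; all path-based measures run on the binary
#' graph).
#'
#' @param net a [DirectedNetwork-class] object.
#' @return A list with `nodes` (per-node data.frame) and `density`
#'   (percent).
#' @export
basicMeasures <- function(net) {
  stopifnot(is(net, "DirectedNetwork"))
  A <- net@binary * 1
  N <- nrow(A)
  W <- net@weights * A          # weights restricted to retained edges
  nodes <- data.frame(
    node = net@labels,
    inDegree = colSums(A),
    outDegree = rowSums(A),
    degree = colSums(A) + rowSums(A),
    inStrength = colSums(W),
    outStrength = rowSums(W),
    stringsAsFactors = FALSE
  )
  rownames(nodes) <- NULL
  list(nodes = nodes, density = 100 * sum(A) / (N * (N - 1)))
}

#' Integration measures: characteristic path length, global efficiency
#'
#' Shortest paths on the binary directed graph. The characteristic
#' path length is the mean of the finite pairwise distances
#' (disconnected pairs are excluded so the mean does not diverge);
#' global efficiency is the mean of `1/d` over all ordered pairs with
#' `1/Inf = 0`, which is why it is preferred for non-fully-connected
#' significance-masked networks.
#'
#' @param net a [DirectedNetwork-class] object.
#' @return A list with `charPathLength` and `globalEfficiency`.
#' @export
integrationMeasures <- function(net) {
  stopifnot(is(net, "DirectedNetwork"))
  d <- igraph::distances(.asIgraph(net), mode = "out")
  off <- row(d) != col(d)
  finite <- off & is.finite(d)
  list(
    charPathLength = if (any(finite)) mean(d[finite]) else NA_real_,
    globalEfficiency = mean(ifelse(is.finite(d[off]), 1 / d[off], 0))
  )
}

# global efficiency of a binary adjacency (helper shared with the
# neighborhood computation in local efficiency)
.globalEfficiencyBinary <- function(A) {
  n <- nrow(A)
  if (n < 2) return(0)
  g <- igraph::graph_from_adjacency_matrix(A * 1, mode = "directed")
  d <- igraph::distances(g, mode = "out")
  off <- row(d) != col(d)
  mean(ifelse(is.finite(d[off]), 1 / d[off], 0))
}

#' Segregation measures: clustering coefficient, local efficiency
#'
#' Directed clustering follows Fagiolo's total-clustering formula on
#' the binary graph: for node i with total degree `d_tot` and `d_bi`
#' bilateral neighbors, `CC_i = ((A + A')^3)_ii / (2 (d_tot (d_tot -
#' 1) - 2 d_bi))`, counting all directed triangles through i. Local
#' efficiency of node i is the global efficiency of the subgraph
#' induced by i's neighbors (i removed). Nodes with fewer than 2
#' neighbors score 0 by convention.
#'
#' @param net a [DirectedNetwork-class] object.
#' @return A data.frame with per-node `clustering` and
#'   `localEfficiency`.
#' @export
segregationMeasures <- function(net) {
  stopifnot(is(net, "DirectedNetwork"))
  A <- net@binary * 1
  N <- nrow(A)
  S <- A + t(A)
  dtot <- rowSums(S)
  dbi <- diag(A %*% A)
  tri <- diag(S %*% S %*% S)
  denom <- 2 * (dtot * (dtot - 1) - 2 * dbi)
  clustering <- ifelse(denom > 0, tri / denom, 0)
  locEff <- vapply(seq_len(N), function(i) {
    nb <- which((A[i, ] + A[, i]) > 0)
    nb <- setdiff(nb, i)
    if (length(nb) < 2) return(0)
    .globalEfficiencyBinary(A[nb, nb, drop = FALSE])
  }, numeric(1))
  data.frame(node = net@labels, clustering = clustering,
             localEfficiency = locEff, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Betweenness centrality
#'
#' Fraction of all-pairs directed shortest paths passing through each
#' node, normalized by `(N - 1)(N - 2)`.
#'
#' @param net a [DirectedNetwork-class] object.
#' @return Named numeric vector of normalized centralities.
#' @export
betweennessCentrality <- function(net) {
  stopifnot(is(net, "DirectedNetwork"))
  N <- nrow(net@binary)
  if (N < 3) {
    out <- rep(0, N); names(out) <- net@labels
    return(out)
  }
  b <- igraph::betweenness(.asIgraph(net), directed = TRUE)
  out <- as.numeric(b) / ((N - 1) * (N - 2))
  names(out) <- net@labels
  out
}

#' Graph-metric report across network costs
#'
#' Computes all measures (degree, density, strength, characteristic
#' path length, global efficiency, clustering, local efficiency,
#' betweenness) at each requested cost, with cost as the independent
#' variable. Duplicate costs are collapsed with a warning.
#'
#' @param adj weighted adjacency matrix (significance-masked DTF).
#' @param costs numeric vector of cost percentages.
#' @return A list of class `"graphReport"`: one element per cost, each
#'   holding the network and its measures.
#' @export
metricsReport <- function(adj, costs) {
  if (length(costs) == 0) stop("'costs' must be nonempty")
  if (anyDuplicated(costs)) {
    warning("duplicate costs collapsed")
    costs <- unique(costs)
  }
  out <- lapply(costs, function(p) {
    net <- costThreshold(adj, p)
    basic <- basicMeasures(net)
    integ <- integrationMeasures(net)
    segr <- segregationMeasures(net)
    btw <- betweennessCentrality(net)
    list(cost = p,
         density = basic$density,
         nodes = cbind(basic$nodes, segr[, c("clustering",
                                             "localEfficiency")],
                       betweenness = unname(btw)),
         charPathLength = integ$charPathLength,
         globalEfficiency = integ$globalEfficiency,
         conventions = c(clustering = "fagiolo-total",
                         betweennessNorm = "(N-1)(N-2)",
                         paths = "binary graph at the given cost"))
  })
  names(out) <- paste0("cost_", costs)
  class(out) <- "graphReport"
  out
}

#' @export
print.graphReport <- function(x, ...) {
  cat("graphReport across", length(x), "cost levels\n")
  for (sec in x) {
    cat(sprintf(
      " cost %g%%: density %.1f%%, L = %.3g, Eglob = %.3g\n",
      sec$cost, sec$density, sec$charPathLength, sec$globalEfficiency))
  }
  invisible(x)
}
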