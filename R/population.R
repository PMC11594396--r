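#' Construct a population state
#'
#' The single mutable object of the simulation: an undirected simple graph on
#' `N` node slots (stored as a symmetric 0/1 adjacency matrix with empty
#' diagonal) plus one strategy per node. Node identifiers are the slot
#' indices `1..N`; when a newcomer replaces an incumbent it takes over the
#' incumbent's slot, so the population size never changes.
#'
#' @param adjacency Symmetric square 0/1 matrix with zero diagonal.
#' @param cooperator Logical vector, one entry per node: `TRUE` for a
#'   cooperator, `FALSE` for a defector.
#' @return An object of class `netcoop_state`.
#' @export
population_state <- function(adjacency, cooperator) {
  adjacency <- as.matrix(adjacency)
  storage.mode(adjacency) <- "integer"
  n <- nrow(adjacency)
  if (ncol(adjacency) != n) stop("adjacency matrix must be square")
  if (length(cooperator) != n) {
    stop("need exactly one strategy per node (", n, " nodes, ",
         length(cooperator), " strategies)")
  }
  if (anyNA(adjacency) || any(adjacency != 0L & adjacency != 1L)) {
    stop("adjacency entries must be 0 or 1")
  }
  if (any(diag(adjacency) != 0L)) stop("self-edges are not allowed")
  if (!identical(adjacency, t(adjacency))) {
    stop("adjacency must be symmetric (undirected graph)")
  }
  cooperator <- as.logical(cooperator)
  if (anyNA(cooperator)) stop("strategies must be TRUE/FALSE, no NA")
  structure(list(adj = adjacency, coop = cooperator),
            class = "netcoop_state")
}

#' Number of nodes in a population state
#' @param state A `netcoop_state`.
#' @return Integer population size.
#' @export
population_size <- function(state) nrow(state$adj)

#' Count the cooperators in a population
#'
#' Absorption has occurred when the count is 0 (all-defector, an invasion)
#' or `N` (all-cooperator, a recovery): strategy copying alone can never
#' re-introduce an extinct strategy.
#'
#' @param state A `netcoop_state`.
#' @return Integer number of cooperator nodes.
#' @export
count_cooperators <- function(state) sum(state$coop)

#' Node degrees
#' @param state A `netcoop_state`.
#' @return Integer vector of neighbour counts, one per node.
#' @export
node_degrees <- function(state) as.integer(rowSums(state$adj))

#' Edge list of the current graph
#'
#' @param state A `netcoop_state`.
#' @return A two-column integer matrix (`from`, `to`) with one row per
#'   undirected edge, `from < to`.
#' @export
edge_list <- function(state) {
  idx <- which(state$adj == 1L & upper.tri(state$adj), arr.ind = TRUE)
  colnames(idx) <- c("from", "to")
  idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
}

#' Convert a population state to an igraph object
#'
#' Convenience for plotting or cross-checking against igraph's centrality
#' routines; requires the igraph package.
#'
#' @param state A `netcoop_state`.
#' @return An igraph undirected graph with a logical vertex attribute
#'   `cooperator`.
#' @export
as_igraph <- function(state) {
  if (!requireNamespace("igraph", quietly = TRUE)) {
    stop("the igraph package is required for as_igraph()")
  }
  g <- igraph::graph_from_adjacency_matrix(state$adj, mode = "undirected")
  igraph::V(g)$cooperator <- state$coop
  g
}

#' @export
print.netcoop_state <- function(x, ...) {
  n <- population_size(x)
  m <- sum(x$adj) / 2L
  cat(sprintf("Population of %d nodes (%d cooperators, %d defectors), %d edges\n",
              n, count_cooperators(x), n - count_cooperators(x), m))
  invisible(x)
}

# internal consistency check used by property tests and the step driver
assert_valid_state <- function(state, n_expected = NULL) {
  stopifnot(inherits(state, "netcoop_state"))
  a <- state$adj
  if (!is.null(n_expected) && nrow(a) != n_expected) {
    stop("population size changed: expected ", n_expected, ", got ", nrow(a))
  }
  if (any(diag(a) != 0L)) stop("state invariant violated: self-edge present")
  if (!identical(a, t(a))) stop("state invariant violated: asymmetric adjacency")
  if (length(state$coop) != nrow(a) || anyNA(state$coop)) {
    stop("state invariant violated: incomplete strategy map")
  }
  invisible(TRUE)
}
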