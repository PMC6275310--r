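#' Construct an undirected affiliative network
#'
#' An affiliative network is a simple undirected graph over a classroom's
#' members: no self-loops, no multi-edges, every edge endpoint a known node.
#' Node identifiers are opaque strings; edges are stored in a canonical form
#' (endpoints sorted within a pair, pairs sorted), so two networks with the
#' same node and edge sets are `identical()`.
#'
#' @param nodes Character vector of node identifiers (unique, non-empty).
#' @param edges Edges as a two-column character matrix or data frame of
#'   endpoint pairs, or `NULL` for an edgeless network. Order within and
#'   between pairs is irrelevant; duplicates collapse.
#' @return An object of class `affiliative_network`.
#' @examples
#' net <- affiliative_network(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
#' n_edges(net)
#' @export
affiliative_network <- function(nodes, edges = NULL) {
  nodes <- if (length(nodes) == 0L) character() else check_ids(nodes, "node")
  if (anyDuplicated(nodes)) {
    dup <- unique(nodes[duplicated(nodes)])
    stop("duplicate node identifiers: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  nodes <- sort_c(nodes)
  if (is.null(edges)) {
    edges <- empty_edge_matrix()
  }
  if (is.data.frame(edges)) {
    edges <- as.matrix(edges)
  }
  if (is.character(edges) && is.null(dim(edges)) && length(edges) == 0L) {
    edges <- empty_edge_matrix()
  }
  if (!is.matrix(edges) || ncol(edges) != 2L) {
    stop("`edges` must be a two-column matrix of endpoint pairs (or NULL)",
         call. = FALSE)
  }
  storage.mode(edges) <- "character"
  if (nrow(edges) > 0L) {
    if (anyNA(edges)) stop("edge endpoints must not be missing", call. = FALSE)
    loops <- edges[, 1L] == edges[, 2L]
    if (any(loops)) {
      stop("self-loops are not allowed (node ",
           paste(unique(edges[loops, 1L]), collapse = ", "), ")",
           call. = FALSE)
    }
    unknown <- setdiff(as.vector(edges), nodes)
    if (length(unknown) > 0L) {
      stop("edge endpoints not in `nodes`: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }
  structure(
    list(nodes = nodes, edges = canonical_edge_matrix(edges)),
    class = "affiliative_network"
  )
}

#' @rdname affiliative_network
#' @param x,network An `affiliative_network`.
#' @export
network_nodes <- function(network) {
  stopifnot(inherits(network, "affiliative_network"))
  network$nodes
}

#' @rdname affiliative_network
#' @export
network_edges <- function(network) {
  stopifnot(inherits(network, "affiliative_network"))
  network$edges
}

#' @rdname affiliative_network
#' @export
n_nodes <- function(network) length(network_nodes(network))

#' @rdname affiliative_network
#' @export
n_edges <- function(network) nrow(network_edges(network))

#' Canonical dyad keys of a network's edges
#'
#' One string per edge, endpoints in canonical order joined by an internal
#' separator; set operations on keys are set operations on edges.
#'
#' @param network An `affiliative_network`.
#' @return Character vector, one key per edge, in canonical edge order.
#' @export
edge_keys <- function(network) {
  pair_keys(network_edges(network))
}

#' @rdname affiliative_network
#' @param a,b Node identifiers.
#' @export
has_edge <- function(network, a, b) {
  key <- pair_keys(canonical_edge_matrix(cbind(as.character(a), as.character(b))))
  key %in% edge_keys(network)
}

#' @rdname affiliative_network
#' @export
node_degrees <- function(network) {
  nodes <- network_nodes(network)
  deg <- stats::setNames(integer(length(nodes)), nodes)
  e <- network_edges(network)
  if (nrow(e) > 0L) {
    tab <- table(factor(as.vector(e), levels = nodes))
    deg[] <- as.integer(tab)
  }
  deg
}

# 0/1 numeric adjacency matrix with node dimnames.
adjacency_matrix <- function(network) {
  nodes <- network_nodes(network)
  n <- length(nodes)
  a <- matrix(0, n, n, dimnames = list(nodes, nodes))
  e <- network_edges(network)
  if (nrow(e) > 0L) {
    i <- match(e[, 1L], nodes)
    j <- match(e[, 2L], nodes)
    a[cbind(i, j)] <- 1
    a[cbind(j, i)] <- 1
  }
  a
}

# igraph view of a network (used for maximal-clique enumeration).
as_igraph <- function(network) {
  e <- network_edges(network)
  igraph::graph_from_data_frame(
    d = data.frame(from = e[, 1L], to = e[, 2L], stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = network_nodes(network), stringsAsFactors = FALSE)
  )
}

# Network from node set + canonical keys (internal fast path).
network_from_keys <- function(nodes, keys) {
  net <- structure(
    list(nodes = sort_c(nodes), edges = canonical_edge_matrix(keys_to_matrix(keys))),
    class = "affiliative_network"
  )
  net
}

#' @export
print.affiliative_network <- function(x, ...) {
  cat(sprintf("<affiliative_network> %d nodes, %d edges\n", n_nodes(x), n_edges(x)))
  e <- network_edges(x)
  if (nrow(e) > 0L) {
    show <- utils::head(paste(e[, 1L], e[, 2L], sep = "--"), 10L)
    cat("  ", paste(show, collapse = ", "),
        if (nrow(e) > 10L) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}
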