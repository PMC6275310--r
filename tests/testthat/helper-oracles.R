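# Shared fixtures and independent oracles, all built in code.

# Random labelled simple graph on n nodes with edge probability p.
rand_graph <- function(n, p = NULL) {
  nodes <- sprintf("n%02d", seq_len(n))
  if (is.null(p)) p <- stats::runif(1, 0.1, 0.9)
  pairs <- t(utils::combn(nodes, 2))
  keep <- stats::runif(nrow(pairs)) < p
  affiliative_network(nodes, pairs[keep, , drop = FALSE])
}

# Independent adjacency lookup built from the printed edge matrix only.
oracle_adjacency <- function(net) {
  nodes <- network_nodes(net)
  a <- matrix(FALSE, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  e <- network_edges(net)
  for (i in seq_len(nrow(e))) {
    a[e[i, 1], e[i, 2]] <- TRUE
    a[e[i, 2], e[i, 1]] <- TRUE
  }
  a
}

# Brute-force triple classification: count closed (3-edge) and open (2-edge)
# unordered triples by direct enumeration.
oracle_triples <- function(net) {
  nodes <- network_nodes(net)
  if (length(nodes) < 3) return(list(closed = 0L, open = 0L))
  a <- oracle_adjacency(net)
  trip <- utils::combn(length(nodes), 3)
  cnt <- a[cbind(trip[1, ], trip[2, ])] +
    a[cbind(trip[1, ], trip[3, ])] +
    a[cbind(trip[2, ], trip[3, ])]
  list(closed = sum(cnt == 3L), open = sum(cnt == 2L))
}

oracle_transitivity <- function(net) {
  o <- oracle_triples(net)
  denom <- 3 * o$closed + o$open
  if (denom == 0) NA_real_ else 3 * o$closed / denom
}

# Brute-force accuracy: dyads compared as unordered endpoint sets, no reuse of
# the package's canonical keys.
oracle_accuracy <- function(perc, truth) {
  pe <- network_edges(perc)
  te <- network_edges(truth)
  n_corr <- 0L
  for (i in seq_len(nrow(pe))) {
    for (j in seq_len(nrow(te))) {
      if (setequal(pe[i, ], te[j, ])) {
        n_corr <- n_corr + 1L
        break
      }
    }
  }
  if (nrow(pe) == 0L) return(0)
  (n_corr / nrow(pe)) * (n_corr / nrow(te))
}

# The published worked instance: 50 true dyads, 35 depicted of which 20 true,
# realised as labelled edge sets on 12 nodes (66 possible dyads).
worked_example <- function() {
  nodes <- sprintf("N%02d", 1:12)
  pairs <- t(utils::combn(nodes, 2))
  list(
    truth = affiliative_network(nodes, pairs[1:50, ]),
    perceived = affiliative_network(nodes, pairs[c(1:20, 51:65), ])
  )
}

# Tiny two-classroom roster + reports written to temp files.
write_fixture_roster <- function(path, rows) {
  writeLines(c("classroom_id,wave_id,member_id,participated", rows), path)
  path
}
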