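#' Precision, coverage and the accuracy index of a perceived network
#'
#' Precision is the number of correctly identified true ties divided by the
#' number of ties the perceiver depicted; coverage is the number of correctly
#' identified true ties divided by the total number of true ties; the accuracy
#' index is their product, computed on unrounded components. Accuracy equals 1
#' exactly when the perceiver depicts all true ties and nothing else.
#'
#' A perceiver who depicted no ties has undefined (0/0) precision —
#' `precision()` returns `NaN` — and is scored `accuracy = 0` by
#' [accuracy_index()], since omitting every true tie is the least accurate
#' possible report. An empty true network leaves coverage undefined:
#' `coverage()` and `accuracy_index()` raise an error of class
#' `scmnet_undefined_coverage`, and the classroom-wave should be excluded from
#' accuracy scoring.
#'
#' @param perceived,truth [affiliative_network()]s over the same node set.
#' @return A proportion in `[0, 1]` (`NaN` for 0/0 precision).
#' @examples
#' nodes <- LETTERS[1:4]
#' truth <- affiliative_network(nodes, rbind(c("A", "B"), c("B", "C")))
#' seen <- affiliative_network(nodes, rbind(c("A", "B"), c("A", "C")))
#' precision(seen, truth)  # 1 of 2 depicted ties is true
#' coverage(seen, truth)   # 1 of 2 true ties is depicted
#' accuracy_index(seen, truth)
#' @export
precision <- function(perceived, truth) {
  check_same_nodes(perceived, truth)
  nd <- n_edges(perceived)
  if (nd == 0L) return(NaN)
  length(intersect(edge_keys(perceived), edge_keys(truth))) / nd
}

#' @rdname precision
#' @export
coverage <- function(perceived, truth) {
  check_same_nodes(perceived, truth)
  nt <- n_edges(truth)
  if (nt == 0L) {
    stop(errorCondition(
      "coverage is undefined: the true network has no edges",
      class = c("scmnet_undefined_coverage", "error", "condition")
    ))
  }
  length(intersect(edge_keys(perceived), edge_keys(truth))) / nt
}

#' @rdname precision
#' @export
accuracy_index <- function(perceived, truth) {
  check_same_nodes(perceived, truth)
  if (n_edges(truth) == 0L) {
    coverage(perceived, truth)  # raises the undefined-coverage error
  }
  if (n_edges(perceived) == 0L) return(0)
  precision(perceived, truth) * coverage(perceived, truth)
}

check_same_nodes <- function(perceived, truth) {
  stopifnot(inherits(perceived, "affiliative_network"),
            inherits(truth, "affiliative_network"))
  if (!identical(network_nodes(perceived), network_nodes(truth))) {
    stop("perceived and true networks must share the same node set", call. = FALSE)
  }
  invisible(TRUE)
}

#' Triangle and two-path counts, and the transitivity index
#'
#' A transitive triad is three members pairwise tied (a triangle); a two-path
#' is an open triad — two ties sharing a middle member with the closing tie
#' absent. The transitivity index is `3T / (3T + P)` with `T` triangles and
#' `P` two-paths: the probability that a connected triple is closed. With no
#' connected triples at all the index carries no information and is returned
#' as `NA` rather than 0.
#'
#' @param network An [affiliative_network()].
#' @return `transitive_triads()` and `two_paths()` return integer counts;
#'   `transitivity_index()` returns a value in `[0, 1]` or `NA`.
#' @examples
#' tri <- affiliative_network(c("A", "B", "C"),
#'                            rbind(c("A", "B"), c("B", "C"), c("A", "C")))
#' transitivity_index(tri)  # 1
#' @export
transitive_triads <- function(network) {
  a <- adjacency_matrix(network)
  if (nrow(a) < 3L) return(0L)
  as.integer(round(sum(a * (a %*% a)) / 6))
}

#' @rdname transitive_triads
#' @export
two_paths <- function(network) {
  a <- adjacency_matrix(network)
  if (nrow(a) < 3L) return(0L)
  deg <- rowSums(a)
  centered <- sum(choose(deg, 2))  # connected triples by centre node
  as.integer(round(centered)) - 3L * transitive_triads(network)
}

#' @rdname transitive_triads
#' @export
transitivity_index <- function(network) {
  tt <- transitive_triads(network)
  tp <- two_paths(network)
  denom <- 3 * tt + tp
  if (denom == 0) return(NA_real_)
  3 * tt / denom
}

#' Per-perceiver accuracy records for a classroom-wave
#'
#' Scores every participant's perceived network against the classroom's true
#' network. When the true network has no edges no meaningful target exists:
#' the classroom-wave is excluded with a warning and a zero-row table is
#' returned.
#'
#' @param data An [classroom_wave()] object.
#' @param truth The true network; defaults to [true_network()] of `data`.
#' @return A data frame with one row per perceiver: `perceiver`,
#'   `classroom_id`, `wave_id`, `n_depicted`, `n_correct`, `n_true`,
#'   `precision`, `coverage`, `accuracy` and `zero_depicted` (flag for the 0/0
#'   precision convention).
#' @export
accuracy_table <- function(data, truth = NULL) {
  stopifnot(inherits(data, "scm_classroom_wave"))
  truth <- truth %||% true_network(data)
  empty <- data.frame(
    perceiver = character(), classroom_id = character(), wave_id = integer(),
    n_depicted = integer(), n_correct = integer(), n_true = integer(),
    precision = numeric(), coverage = numeric(), accuracy = numeric(),
    zero_depicted = logical(), stringsAsFactors = FALSE
  )
  if (n_edges(truth) == 0L) {
    warning(sprintf("classroom %s wave %d has an empty true network; excluded from accuracy scoring",
                    data$roster$classroom_id, data$roster$wave_id), call. = FALSE)
    return(structure(empty, excluded = TRUE))
  }
  true_keys <- edge_keys(truth)
  rows <- lapply(names(data$perceived), function(p) {
    net <- data$perceived[[p]]
    nd <- n_edges(net)
    nc <- length(intersect(edge_keys(net), true_keys))
    prec <- if (nd == 0L) NaN else nc / nd
    cov <- nc / length(true_keys)
    data.frame(
      perceiver = p,
      classroom_id = data$roster$classroom_id,
      wave_id = data$roster$wave_id,
      n_depicted = nd, n_correct = nc, n_true = length(true_keys),
      precision = prec, coverage = cov,
      accuracy = if (nd == 0L) 0 else prec * cov,
      zero_depicted = nd == 0L,
      stringsAsFactors = FALSE
    )
  })
  out <- if (length(rows) > 0L) do.call(rbind, rows) else empty
  out[order_c(out$perceiver), , drop = FALSE]
}

#' Classroom transitivity records
#'
#' One row per classroom-wave with triangle and two-path counts and the
#' transitivity index of the true network (`NA` when the network has no
#' connected triples).
#'
#' @param networks A named structure of true networks: either a list of
#'   [affiliative_network()]s with parallel `classroom_ids` and `wave_ids`
#'   vectors, or a list of lists with elements `classroom_id`, `wave_id`,
#'   `network`.
#' @param classroom_ids,wave_ids Labels parallel to `networks` (ignored when
#'   `networks` carries its own labels).
#' @return A data frame with columns `classroom_id`, `wave_id`,
#'   `n_transitive_triads`, `n_two_paths`, `transitivity`.
#' @export
transitivity_table <- function(networks, classroom_ids = NULL, wave_ids = NULL) {
  if (length(networks) == 0L) {
    return(data.frame(classroom_id = character(), wave_id = integer(),
                      n_transitive_triads = integer(), n_two_paths = integer(),
                      transitivity = numeric(), stringsAsFactors = FALSE))
  }
  if (inherits(networks[[1L]], "affiliative_network")) {
    stopifnot(length(classroom_ids) == length(networks),
              length(wave_ids) == length(networks))
    entries <- Map(function(n, c, w) list(classroom_id = c, wave_id = w, network = n),
                   networks, classroom_ids, wave_ids)
  } else {
    entries <- networks
  }
  rows <- lapply(entries, function(e) {
    tt <- transitive_triads(e$network)
    tp <- two_paths(e$network)
    data.frame(
      classroom_id = as.character(e$classroom_id),
      wave_id = as.integer(e$wave_id),
      n_transitive_triads = tt, n_two_paths = tp,
      transitivity = if (3 * tt + tp == 0) NA_real_ else 3 * tt / (3 * tt + tp),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out[order_c(out$classroom_id, out$wave_id), , drop = FALSE]
}
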