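# Synthetic-study generator: classrooms with transitivity-targeted true
# networks, wave-to-wave rewiring, and noisy perceiver reports with an
# optional transitivity -> report-quality coupling.

#' Configuration of a synthetic SCM study
#'
#' Defaults emulate the observed study conditions: classrooms of about 20
#' members followed over 3 waves, classroom transitivity spanning roughly
#' 0.3-0.8 and mean perceiver accuracy roughly 0.2-0.6.
#'
#' @param n_classrooms Number of classrooms.
#' @param class_size Members per classroom (15-30 typical).
#' @param n_waves Observation waves (2-3 typical).
#' @param edge_density True-network edge density (proportion of possible
#'   dyads).
#' @param target_transitivity Target transitivity per classroom-wave: a single
#'   value, a length-2 range `c(lo, hi)` sampled uniformly per classroom-wave,
#'   or an `n_classrooms x n_waves` matrix.
#' @param transitivity_tolerance Absolute tolerance for transitivity
#'   targeting.
#' @param p_hit_own Probability a perceiver reports each of their own true
#'   ties.
#' @param p_hit_other Probability of reporting each true tie not involving
#'   self, used when `coupling` is `NULL`.
#' @param p_false Probability of reporting each non-tie.
#' @param coupling Named numeric `c(a = ..., b = ...)` linking classroom
#'   transitivity `t` to the other-tie hit probability via
#'   `plogis(a + b * t)`, or `NULL` for no coupling. The coupling acts only on
#'   `p_hit_other`, so the planted true network is unaffected.
#' @param rewire_fraction Per-wave fraction of true-network edges rewired
#'   before re-targeting transitivity.
#' @param seed Integer seed governing all randomness of [simulate_study()].
#' @return An object of class `scm_sim_config`.
#' @export
simulation_config <- function(n_classrooms = 10L,
                              class_size = 20L,
                              n_waves = 3L,
                              edge_density = 0.18,
                              target_transitivity = c(0.35, 0.75),
                              transitivity_tolerance = 0.02,
                              p_hit_own = 0.95,
                              p_hit_other = 0.5,
                              p_false = 0.03,
                              coupling = c(a = -1.6, b = 3.2),
                              rewire_fraction = 0.3,
                              seed = 1L) {
  stopifnot(is_count(n_classrooms), is_count(class_size, min = 3L),
            is_count(n_waves), is_prob(edge_density), edge_density > 0,
            is.numeric(transitivity_tolerance), transitivity_tolerance > 0,
            is_prob(p_hit_own), is_prob(p_hit_other), is_prob(p_false),
            is_prob(rewire_fraction), is_count(seed, min = 0L))
  if (is.matrix(target_transitivity)) {
    stopifnot(nrow(target_transitivity) == n_classrooms,
              ncol(target_transitivity) == n_waves,
              all(target_transitivity >= 0 & target_transitivity <= 1))
  } else {
    stopifnot(length(target_transitivity) %in% c(1L, 2L),
              all(target_transitivity >= 0 & target_transitivity <= 1))
    if (length(target_transitivity) == 2L) {
      stopifnot(target_transitivity[1L] <= target_transitivity[2L])
    }
  }
  if (!is.null(coupling)) {
    stopifnot(is.numeric(coupling), all(c("a", "b") %in% names(coupling)))
  }
  structure(
    list(n_classrooms = as.integer(n_classrooms),
         class_size = as.integer(class_size),
         n_waves = as.integer(n_waves),
         edge_density = edge_density,
         target_transitivity = target_transitivity,
         transitivity_tolerance = transitivity_tolerance,
         p_hit_own = p_hit_own, p_hit_other = p_hit_other, p_false = p_false,
         coupling = coupling,
         rewire_fraction = rewire_fraction,
         seed = as.integer(seed)),
    class = "scm_sim_config"
  )
}

#' @export
print.scm_sim_config <- function(x, ...) {
  cat(sprintf("<scm_sim_config> %d classroom(s) x %d member(s) x %d wave(s), density %.2f, seed %d\n",
              x$n_classrooms, x$class_size, x$n_waves, x$edge_density, x$seed))
  invisible(x)
}

# Transitivity of a 0/1 adjacency matrix: 3T over connected triples.
adj_transitivity <- function(a) {
  tt <- sum(a * (a %*% a)) / 6
  deg <- rowSums(a)
  denom <- sum(deg * (deg - 1) / 2)
  if (denom == 0) NA_real_ else 3 * tt / denom
}

sample_one <- function(x) if (length(x) == 1L) x else sample(x, 1L)

# Hill-climb edge swaps towards a target transitivity at fixed edge count.
# Raise moves add an edge that closes a random two-path and remove a random
# edge; lower moves remove a random triangle edge and add a random quiet
# non-edge. A move is kept only if it shrinks |transitivity - target|; after a
# long run of rejected proposals (a local optimum of the coarse swap
# landscape, common in small sparse graphs) one random rewire is accepted
# unconditionally to hop basins. The best state seen is what is returned.
climb_to_target <- function(a, target, tol, max_iter, stall_limit = 150L) {
  n <- nrow(a)
  ut <- upper.tri(a)
  cur <- adj_transitivity(a)
  dist <- function(v) if (is.na(v)) Inf else abs(v - target)
  swaps <- 0L
  stall <- 0L
  best_a <- a
  best_v <- cur
  for (iter in seq_len(max_iter)) {
    if (dist(best_v) <= tol) break
    aa <- a %*% a
    raise <- is.na(cur) || cur < target
    force_move <- stall >= stall_limit
    if (force_move) {
      # burst perturbation: rewire several edges at once so the next greedy
      # descent starts from a genuinely different basin
      n_hop <- max(2L, as.integer(ceiling(0.1 * sum(a) / 2)))
      rem_pool <- which(ut & a == 1)
      add_pool <- which(ut & a == 0)
      n_hop <- min(n_hop, length(rem_pool), length(add_pool))
      if (n_hop > 1L) {
        rems <- sample(rem_pool, n_hop - 1L)
        a[rems] <- 0
        a[(rems - 1L) %/% n + 1L + n * ((rems - 1L) %% n)] <- 0
        adds <- sample(which(ut & a == 0), n_hop - 1L)
        a[adds] <- 1
        a[(adds - 1L) %/% n + 1L + n * ((adds - 1L) %% n)] <- 1
      }
      rem_pool <- which(ut & a == 1)
      add_pool <- which(ut & a == 0)
    } else if (raise) {
      add_pool <- which(ut & a == 0 & aa > 0)
      rem_pool <- which(ut & a == 1)
    } else {
      rem_pool <- which(ut & a == 1 & aa > 0)
      add_pool <- which(ut & a == 0 & aa == 0)
      if (length(add_pool) == 0L) add_pool <- which(ut & a == 0)
    }
    if (length(add_pool) == 0L || length(rem_pool) == 0L) {
      add_pool <- which(ut & a == 0)
      rem_pool <- which(ut & a == 1)
      if (length(add_pool) == 0L || length(rem_pool) == 0L) break
      force_move <- TRUE
    }
    add <- sample_one(add_pool)
    rem <- sample_one(rem_pool)
    a2 <- a
    a2[rem] <- 0
    a2[(rem - 1L) %/% n + 1L + n * ((rem - 1L) %% n)] <- 0  # mirror index
    a2[add] <- 1
    a2[(add - 1L) %/% n + 1L + n * ((add - 1L) %% n)] <- 1
    new_v <- adj_transitivity(a2)
    if (dist(new_v) < dist(cur) || force_move) {
      a <- a2
      cur <- new_v
      swaps <- swaps + 1L
      stall <- 0L
      if (dist(cur) < dist(best_v)) {
        best_a <- a
        best_v <- cur
      }
    } else {
      stall <- stall + 1L
    }
  }
  list(a = best_a, value = best_v, swaps = swaps, reached = dist(best_v) <= tol)
}

adj_to_network <- function(a, nodes, swaps) {
  ut <- which(upper.tri(a) & a == 1, arr.ind = TRUE)
  edges <- cbind(nodes[ut[, 1L]], nodes[ut[, 2L]])
  net <- affiliative_network(nodes, if (nrow(ut) > 0L) edges else NULL)
  attr(net, "n_swaps") <- swaps
  attr(net, "transitivity") <- transitivity_index(net)
  net
}

#' Generate a random true network with a target transitivity
#'
#' Draws a uniformly random simple graph with
#' `round(density * n * (n - 1) / 2)` edges, then hill-climbs by edge swaps —
#' adding edges that close random two-paths (to raise transitivity) or the
#' reverse move (to lower it), always keeping the edge count fixed — accepting
#' only swaps that move the transitivity index towards the target. If the
#' target cannot be approached within `tol` in `max_iter` proposals, an error
#' of class `scmnet_target_unreached` reports the best value achieved.
#'
#' @param n Number of nodes.
#' @param density Edge density (proportion of possible dyads).
#' @param target_t Target transitivity in `[0, 1]`.
#' @param tol Absolute tolerance.
#' @param seed Optional integer seed (the global RNG stream is used when
#'   `NULL`); the result is deterministic given a seed.
#' @param max_iter Maximum number of proposed swaps.
#' @param nodes Optional node names (length `n`).
#' @return An [affiliative_network()] with attributes `n_swaps` (accepted
#'   swaps) and `transitivity` (realised index).
#' @export
generate_true_network <- function(n, density, target_t, tol = 0.02,
                                  seed = NULL, max_iter = 20000L, nodes = NULL) {
  stopifnot(is_count(n, min = 3L), is_prob(density), density > 0,
            is_prob(target_t), is.numeric(tol), tol > 0, is_count(max_iter))
  if (is.null(nodes)) {
    nodes <- sprintf("M%0*d", max(2L, nchar(n)), seq_len(n))
  }
  nodes <- sort_c(check_ids(nodes, "node"))
  stopifnot(length(nodes) == n)
  n_pairs <- n * (n - 1L) / 2
  m <- round(density * n_pairs)
  if (m < 1L) stop("edge density too low: the network would have no edges", call. = FALSE)
  run <- function() {
    a <- matrix(0, n, n)
    ut_idx <- which(upper.tri(a))
    a[sample(ut_idx, m)] <- 1
    a <- a + t(a)
    res <- climb_to_target(a, target_t, tol, max_iter)
    if (!res$reached) {
      stop(errorCondition(
        sprintf("could not reach target transitivity %.3f within %d proposals (best achieved: %.3f)",
                target_t, max_iter, res$value),
        class = c("scmnet_target_unreached", "error", "condition"),
        best = res$value
      ))
    }
    adj_to_network(res$a, nodes, res$swaps)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Evolve a true network to the next wave
#'
#' Rewires `ceiling(rewire_fraction * n_edges)` randomly chosen edges to
#' random non-edges, then re-targets transitivity with the same swap
#' hill-climb as [generate_true_network()]. The edge count is preserved. With
#' `rewire_fraction = 0` and the current transitivity already within `tol` of
#' the target, the network is returned unchanged.
#'
#' @param network The current-wave [affiliative_network()].
#' @param rewire_fraction Fraction of edges to rewire, in `[0, 1]`.
#' @param target_t,tol,seed,max_iter As in [generate_true_network()].
#' @return An [affiliative_network()] with attributes `n_swaps` and
#'   `transitivity`.
#' @export
evolve_network <- function(network, rewire_fraction, target_t, tol = 0.02,
                           seed = NULL, max_iter = 20000L) {
  stopifnot(inherits(network, "affiliative_network"),
            is_prob(rewire_fraction), is_prob(target_t),
            is.numeric(tol), tol > 0, is_count(max_iter))
  m <- n_edges(network)
  if (m == 0L) stop("cannot evolve a network with no edges", call. = FALSE)
  k <- as.integer(ceiling(rewire_fraction * m))
  cur <- transitivity_index(network)
  if (k == 0L && !is.na(cur) && abs(cur - target_t) <= tol) {
    out <- network
    attr(out, "n_swaps") <- 0L
    attr(out, "transitivity") <- cur
    return(out)
  }
  nodes <- network_nodes(network)
  run <- function() {
    a <- adjacency_matrix(network)
    ut <- upper.tri(a)
    if (k > 0L) {
      rem <- sample(which(ut & a == 1), k)
      for (idx in rem) {
        a[idx] <- 0
        a[(idx - 1L) %/% nrow(a) + 1L + nrow(a) * ((idx - 1L) %% nrow(a))] <- 0
      }
      add <- sample(which(ut & a == 0), k)
      for (idx in add) {
        a[idx] <- 1
        a[(idx - 1L) %/% nrow(a) + 1L + nrow(a) * ((idx - 1L) %% nrow(a))] <- 1
      }
    }
    res <- climb_to_target(a, target_t, tol, max_iter)
    if (!res$reached) {
      stop(errorCondition(
        sprintf("could not reach target transitivity %.3f within %d proposals (best achieved: %.3f)",
                target_t, max_iter, res$value),
        class = c("scmnet_target_unreached", "error", "condition"),
        best = res$value
      ))
    }
    adj_to_network(res$a, nodes, res$swaps)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# Draw a perceiver's perceived network: own true ties kept with p_own, other
# true ties with p_other, non-ties added with p_false.
simulate_perceived <- function(truth, perceiver, p_own, p_other, p_false) {
  keys <- edge_keys(truth)
  e <- network_edges(truth)
  own <- if (nrow(e) > 0L) e[, 1L] == perceiver | e[, 2L] == perceiver else logical()
  keep <- logical(length(keys))
  if (any(own)) keep[own] <- stats::runif(sum(own)) < p_own
  if (any(!own)) keep[!own] <- stats::runif(sum(!own)) < p_other
  non <- setdiff(pair_keys(pairs_within(network_nodes(truth))), keys)
  false_keys <- non[stats::runif(length(non)) < p_false]
  network_from_keys(network_nodes(truth), c(keys[keep], false_keys))
}

#' Simulate one perceiver's SCM report of a true network
#'
#' Each true tie involving the perceiver is reported with probability
#' `p_hit_own`; each other true tie with probability
#' `plogis(a + b * classroom_transitivity)` when the coupling is enabled,
#' otherwise `p_hit_other`; each non-tie is reported with probability
#' `p_false`. The perceived edge set is then encoded as an SCM group listing
#' via [encode_as_groups()] (maximal cliques plus degree-zero isolates), or
#' returned as the raw network when `as_network = TRUE`.
#'
#' @param truth The classroom's true [affiliative_network()].
#' @param perceiver A node of `truth`.
#' @param config An [simulation_config()].
#' @param classroom_transitivity Classroom transitivity entering the coupling.
#' @param seed Optional integer seed; the global stream is used when `NULL`.
#' @param as_network Return the perceived network instead of a group report?
#' @return An `scm_group_report`, or an [affiliative_network()] when
#'   `as_network = TRUE`.
#' @export
simulate_report <- function(truth, perceiver, config, classroom_transitivity,
                            seed = NULL, as_network = FALSE) {
  stopifnot(inherits(truth, "affiliative_network"),
            inherits(config, "scm_sim_config"))
  if (!perceiver %in% network_nodes(truth)) {
    stop("perceiver ", perceiver, " is not a node of the true network", call. = FALSE)
  }
  p_other <- if (is.null(config$coupling)) {
    config$p_hit_other
  } else {
    stats::plogis(config$coupling[["a"]] +
                    config$coupling[["b"]] * classroom_transitivity)
  }
  run <- function() {
    perceived <- simulate_perceived(truth, perceiver,
                                    config$p_hit_own, p_other, config$p_false)
    if (as_network) perceived else encode_as_groups(perceived, perceiver = perceiver)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

resolve_targets <- function(config) {
  k <- config$n_classrooms
  w <- config$n_waves
  tt <- config$target_transitivity
  if (is.matrix(tt)) return(tt)
  if (length(tt) == 1L) return(matrix(tt, k, w))
  matrix(stats::runif(k * w, tt[1L], tt[2L]), k, w)
}

#' Simulate a complete synthetic SCM study
#'
#' Plants a true affiliative network per classroom at wave 0 (see
#' [generate_true_network()]), evolves it across waves (see
#' [evolve_network()]), and draws one noisy SCM report per participant per
#' wave (see [simulate_report()]). All members participate. Everything is
#' reproducible from `config$seed`; with a directory supplied, roster, report
#' and planted-truth files are written in the package's exchange formats and
#' equal configurations produce byte-identical files.
#'
#' @param config An [simulation_config()].
#' @param dir Optional output directory (created if needed) receiving
#'   `roster.csv`, `reports.json` and `truth.json`.
#' @return An object of class `scm_study`: a list with `rosters` (list of
#'   [roster()]), `reports` (list of `scm_group_report`), `planted` (per
#'   classroom-wave: `classroom_id`, `wave_id`, `network`, `transitivity`,
#'   `target`), `config` and `paths`.
#' @export
simulate_study <- function(config, dir = NULL) {
  stopifnot(inherits(config, "scm_sim_config"))
  run <- function() {
    k <- config$n_classrooms
    size <- config$class_size
    wv <- config$n_waves
    targets <- resolve_targets(config)
    cls <- sprintf("C%0*d", max(2L, nchar(k)), seq_len(k))
    rosters <- list()
    reports <- list()
    planted <- list()
    for (ci in seq_len(k)) {
      nodes <- sprintf("%s_M%0*d", cls[ci], max(2L, nchar(size)), seq_len(size))
      net <- NULL
      for (w in seq_len(wv) - 1L) {
        net <- if (w == 0L) {
          generate_true_network(size, config$edge_density, targets[ci, 1L],
                                tol = config$transitivity_tolerance, nodes = nodes)
        } else {
          evolve_network(net, config$rewire_fraction, targets[ci, w + 1L],
                         tol = config$transitivity_tolerance)
        }
        realized <- transitivity_index(net)
        rosters[[length(rosters) + 1L]] <- roster(cls[ci], w, nodes, nodes)
        planted[[length(planted) + 1L]] <- list(
          classroom_id = cls[ci], wave_id = w, network = net,
          transitivity = realized, target = targets[ci, w + 1L]
        )
        for (p in nodes) {
          rep_p <- simulate_report(net, p, config, realized)
          rep_p$classroom_id <- cls[ci]
          rep_p$wave_id <- w
          reports[[length(reports) + 1L]] <- rep_p
        }
      }
    }
    list(rosters = rosters, reports = reports, planted = planted)
  }
  out <- withr::with_seed(config$seed, run())
  study <- structure(
    c(out, list(config = config, paths = NULL)),
    class = "scm_study"
  )
  if (!is.null(dir)) {
    study$paths <- write_study(study, dir)
  }
  study
}

write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    roster = file.path(dir, "roster.csv"),
    reports = file.path(dir, "reports.json"),
    truth = file.path(dir, "truth.json")
  )
  write_roster(study$rosters, paths$roster)
  write_group_reports(study$reports, paths$reports)
  truth <- lapply(study$planted, function(p) {
    e <- network_edges(p$network)
    list(classroom_id = p$classroom_id, wave_id = p$wave_id,
         transitivity = p$transitivity, target = p$target,
         nodes = I(network_nodes(p$network)),
         edges = lapply(seq_len(nrow(e)), function(i) I(unname(e[i, ]))))
  })
  cfg <- study$config
  cfg$target_transitivity <- as.vector(cfg$target_transitivity)
  json <- jsonlite::toJSON(
    list(config = unclass(cfg)[setdiff(names(cfg), "coupling")],
         coupling = if (is.null(cfg$coupling)) NULL else as.list(cfg$coupling),
         planted = truth),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )
  write_lines_utf8(json, paths$truth)
  paths
}

#' @export
print.scm_study <- function(x, ...) {
  cat(sprintf("<scm_study> %d classroom-wave(s), %d report(s), seed %d\n",
              length(x$planted), length(x$reports), x$config$seed))
  invisible(x)
}

#' Simulate accuracy panels directly from the random-intercept model
#'
#' Draws balanced participant-wave data from
#' `accuracy = b0 + b1 * time + b2 * t0 + b3 * change + u_i + e_it` with
#' normal random intercepts and residuals. Baseline transitivity is uniform on
#' `t0_range`; wave deviations beyond the first are uniform on `change_range`
#' (zero at the first wave). Used for parameter-recovery and calibration
#' studies of [fit_random_intercept()]; accuracy is left on the linear-model
#' scale (not clamped to `[0, 1]`).
#'
#' @param n_participants Number of participants.
#' @param n_waves Waves per participant (times `0, ..., n_waves - 1`).
#' @param beta Fixed effects, in the order intercept, time, transitivity at
#'   the first observation, transitivity change.
#' @param sigma2_intercept,sigma2_residual Variance components.
#' @param t0_range,change_range Uniform ranges for the covariates.
#' @param seed Optional integer seed.
#' @return A data frame suitable for [fit_random_intercept()].
#' @export
simulate_from_model <- function(n_participants, n_waves = 3L,
                                beta = c(0.1, 0, 0.5, 0.5),
                                sigma2_intercept = 0.01,
                                sigma2_residual = 0.01,
                                t0_range = c(0.3, 0.8),
                                change_range = c(-0.2, 0.2),
                                seed = NULL) {
  stopifnot(is_count(n_participants, min = 2L), is_count(n_waves, min = 2L),
            length(beta) == 4L, sigma2_intercept >= 0, sigma2_residual >= 0)
  run <- function() {
    id <- sprintf("P%0*d", max(3L, nchar(n_participants)), seq_len(n_participants))
    time <- rep(seq_len(n_waves) - 1L, times = n_participants)
    participant <- rep(id, each = n_waves)
    t0 <- rep(stats::runif(n_participants, t0_range[1L], t0_range[2L]),
              each = n_waves)
    change <- stats::runif(length(time), change_range[1L], change_range[2L])
    change[time == 0L] <- 0
    u <- rep(stats::rnorm(n_participants, 0, sqrt(sigma2_intercept)),
             each = n_waves)
    eps <- stats::rnorm(length(time), 0, sqrt(sigma2_residual))
    acc <- beta[1L] + beta[2L] * time + beta[3L] * t0 + beta[4L] * change + u + eps
    data.frame(
      participant = participant, classroom_id = "sim",
      wave_id = time, time = time, accuracy = acc,
      transitivity = t0 + change, transitivity_t0 = t0,
      transitivity_change = change, stringsAsFactors = FALSE
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
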