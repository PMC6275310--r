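#' Bundle a roster with its wave's reports and perceived networks
#'
#' Expands each participant's report into their perceived network (see
#' [expand_report()]) and keeps roster, reports and perceived networks
#' together. All perceived networks share the roster's participant set as
#' their node set.
#'
#' @param roster An [roster()] object.
#' @param reports List of [group_report()] objects, at most one per perceiver,
#'   each by a participant of `roster`. Alternatively a named list of
#'   [affiliative_network()]s (names are the perceivers) holding already
#'   expanded perceived networks over the roster's participants.
#' @return An object of class `scm_classroom_wave` with elements `roster`,
#'   `reports` and `perceived` (a named list of networks, one per perceiver).
#' @export
classroom_wave <- function(roster, reports) {
  stopifnot(inherits(roster, "scm_roster"))
  if (inherits(reports, "scm_group_report")) reports <- list(reports)
  if (length(reports) > 0L && inherits(reports[[1L]], "affiliative_network")) {
    perceivers <- names(reports)
    if (is.null(perceivers) || anyNA(perceivers) || any(!nzchar(perceivers))) {
      stop("perceived networks must be named by their perceivers", call. = FALSE)
    }
    bad <- setdiff(perceivers, roster$participants)
    if (length(bad) > 0L) {
      stop("perceiver(s) not in participants: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    for (p in perceivers) {
      if (!identical(network_nodes(reports[[p]]), roster$participants)) {
        stop(sprintf("perceived network of %s is not defined over the roster's participants", p),
             call. = FALSE)
      }
    }
    return(structure(
      list(roster = roster, reports = NULL, perceived = reports),
      class = "scm_classroom_wave"
    ))
  }
  perceivers <- vapply(reports, function(r) r$perceiver, character(1L))
  if (anyDuplicated(perceivers)) {
    dup <- unique(perceivers[duplicated(perceivers)])
    stop(sprintf("more than one report by perceiver(s) %s in classroom %s wave %d",
                 paste(dup, collapse = ", "), roster$classroom_id, roster$wave_id),
         call. = FALSE)
  }
  perceived <- lapply(reports, expand_report, roster = roster)
  names(perceived) <- perceivers
  names(reports) <- perceivers
  structure(
    list(roster = roster, reports = reports, perceived = perceived),
    class = "scm_classroom_wave"
  )
}

#' @export
print.scm_classroom_wave <- function(x, ...) {
  cat(sprintf("<scm_classroom_wave> classroom %s wave %d: %d participants, %d report(s)\n",
              x$roster$classroom_id, x$roster$wave_id,
              length(x$roster$participants), length(x$reports)))
  invisible(x)
}

#' Participation rate of a classroom-wave
#'
#' @param roster An [roster()] object (an `scm_classroom_wave` is also
#'   accepted).
#' @return Proportion of members that participated, in `[0, 1]`.
#' @export
participation_rate <- function(roster) {
  if (inherits(roster, "scm_classroom_wave")) roster <- roster$roster
  stopifnot(inherits(roster, "scm_roster"))
  if (length(roster$members) == 0L) {
    stop(sprintf("classroom %s wave %d has no members; participation rate undefined",
                 roster$classroom_id, roster$wave_id), call. = FALSE)
  }
  length(roster$participants) / length(roster$members)
}

#' Keep classroom-waves whose participation rate exceeds a threshold
#'
#' Inclusion uses a strict inequality: a classroom-wave at exactly the
#' threshold is excluded. Exclusions are reported via `message()` and returned
#' in the `exclusions` attribute.
#'
#' @param classroom_waves List of [classroom_wave()] objects (or rosters).
#' @param threshold Participation-rate threshold in `[0, 1]`; default 0.60.
#' @param verbose Emit a message per exclusion?
#' @return The retained subset, with an `exclusions` attribute (data frame of
#'   classroom, wave and rate for each dropped classroom-wave).
#' @export
filter_eligible <- function(classroom_waves, threshold = 0.60, verbose = TRUE) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold >= 0, threshold <= 1)
  rates <- vapply(classroom_waves, participation_rate, numeric(1L))
  get_roster <- function(x) if (inherits(x, "scm_classroom_wave")) x$roster else x
  keep <- rates > threshold
  dropped <- classroom_waves[!keep]
  exclusions <- data.frame(
    classroom_id = vapply(dropped, function(x) get_roster(x)$classroom_id, character(1L)),
    wave_id = vapply(dropped, function(x) get_roster(x)$wave_id, integer(1L)),
    participation_rate = rates[!keep],
    stringsAsFactors = FALSE
  )
  if (verbose && nrow(exclusions) > 0L) {
    for (i in seq_len(nrow(exclusions))) {
      message(sprintf("excluding classroom %s wave %d: participation rate %.3f <= %.2f",
                      exclusions$classroom_id[i], exclusions$wave_id[i],
                      exclusions$participation_rate[i], threshold))
    }
  }
  structure(classroom_waves[keep], exclusions = exclusions)
}

#' Consensus ("true") affiliative network by the intersection rule
#'
#' A tie between i and j is counted as true if and only if both parties of the
#' dyad depict it in their own SCM: the edge must appear in i's perceived
#' network and in j's. Third-party depictions of a dyad carry no weight. This
#' is the locally-aggregated-structures intersection rule.
#'
#' @param data An [classroom_wave()] object whose participants all have
#'   perceived networks.
#' @return An [affiliative_network()] over the roster's participants.
#' @export
true_network <- function(data) {
  stopifnot(inherits(data, "scm_classroom_wave"))
  parts <- data$roster$participants
  absent <- setdiff(parts, names(data$perceived))
  if (length(absent) > 0L) {
    stop(sprintf("no perceived network for participant(s) %s in classroom %s wave %d",
                 paste(absent, collapse = ", "), data$roster$classroom_id,
                 data$roster$wave_id), call. = FALSE)
  }
  # Each participant contributes the dyads of their own map that involve
  # themselves; a dyad endorsed by both endpoints appears exactly twice.
  own_keys <- unlist(lapply(parts, function(p) {
    e <- network_edges(data$perceived[[p]])
    if (nrow(e) == 0L) return(character())
    pair_keys(e[e[, 1L] == p | e[, 2L] == p, , drop = FALSE])
  }), use.names = FALSE)
  counts <- table(own_keys)
  network_from_keys(parts, names(counts)[counts == 2L])
}
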