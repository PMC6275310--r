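#' Classroom roster for one observation wave
#'
#' A roster records who belonged to a classroom at a given wave and which of
#' those members completed the Social Cognitive Map (SCM) questionnaire.
#' Participants must be a subset of members, and member identifiers must be
#' unique within the classroom-wave.
#'
#' @param classroom_id Classroom identifier (string).
#' @param wave_id Ordinal wave index, 0-based integer.
#' @param members Character vector of member identifiers.
#' @param participants Character vector: the subset of `members` that completed
#'   an SCM report at this wave.
#' @return An object of class `scm_roster`.
#' @export
roster <- function(classroom_id, wave_id, members, participants) {
  classroom_id <- check_ids(classroom_id, "classroom")
  if (length(classroom_id) != 1L) stop("`classroom_id` must be a single id", call. = FALSE)
  wave_id <- as.integer(wave_id)
  if (length(wave_id) != 1L || is.na(wave_id) || wave_id < 0L) {
    stop("`wave_id` must be a single non-negative integer", call. = FALSE)
  }
  members <- check_ids(members, "member")
  if (anyDuplicated(members)) {
    dup <- unique(members[duplicated(members)])
    stop(sprintf("duplicate member(s) in classroom %s wave %d: %s",
                 classroom_id, wave_id, paste(dup, collapse = ", ")),
         call. = FALSE)
  }
  participants <- if (length(participants) == 0L) character() else
    check_ids(participants, "participant")
  participants <- unique(participants)
  outside <- setdiff(participants, members)
  if (length(outside) > 0L) {
    stop(sprintf("participant(s) not in members for classroom %s wave %d: %s",
                 classroom_id, wave_id, paste(outside, collapse = ", ")),
         call. = FALSE)
  }
  structure(
    list(classroom_id = classroom_id, wave_id = wave_id,
         members = sort_c(members), participants = sort_c(participants)),
    class = "scm_roster"
  )
}

#' @export
print.scm_roster <- function(x, ...) {
  cat(sprintf("<scm_roster> classroom %s, wave %d: %d members, %d participants\n",
              x$classroom_id, x$wave_id, length(x$members), length(x$participants)))
  invisible(x)
}

#' Read classroom rosters from a delimited file
#'
#' The file is comma-delimited with a header row and columns `classroom_id`,
#' `wave_id`, `member_id`, `participated` (0/1), one row per member per
#' classroom-wave. Identifiers are kept verbatim as strings.
#'
#' @param path Path to the roster file.
#' @return A list of [roster()] objects, one per (classroom, wave), in order of
#'   first appearance in the file.
#' @export
read_roster <- function(path) {
  if (!file.exists(path)) stop("roster file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character", check.names = TRUE,
                        fileEncoding = "UTF-8")
  required <- c("classroom_id", "wave_id", "member_id", "participated")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("roster file is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0L) return(list())
  for (i in seq_len(nrow(df))) {
    row <- df[i, required]
    bad <- vapply(row, function(v) is.na(v) || !nzchar(v), logical(1L))
    if (any(bad)) {
      stop(sprintf("malformed roster row at line %d: empty %s", i + 1L,
                   paste(required[bad], collapse = ", ")), call. = FALSE)
    }
    if (!grepl("^[0-9]+$", df$wave_id[i])) {
      stop(sprintf("malformed roster row at line %d: wave_id '%s' is not a non-negative integer",
                   i + 1L, df$wave_id[i]), call. = FALSE)
    }
    if (!df$participated[i] %in% c("0", "1")) {
      stop(sprintf("malformed roster row at line %d: participated must be 0 or 1, got '%s'",
                   i + 1L, df$participated[i]), call. = FALSE)
    }
  }
  key <- paste(df$classroom_id, df$wave_id, sep = .EDGE_SEP)
  dup <- duplicated(paste(key, df$member_id, sep = .EDGE_SEP))
  if (any(dup)) {
    i <- which(dup)[1L]
    stop(sprintf("duplicate member '%s' in classroom %s wave %s (line %d)",
                 df$member_id[i], df$classroom_id[i], df$wave_id[i], i + 1L),
         call. = FALSE)
  }
  out <- lapply(unique(key), function(k) {
    rows <- df[key == k, , drop = FALSE]
    roster(rows$classroom_id[1L], as.integer(rows$wave_id[1L]),
           members = rows$member_id,
           participants = rows$member_id[rows$participated == "1"])
  })
  out
}

#' Write classroom rosters to a delimited file
#'
#' Inverse of [read_roster()]: emits the comma-delimited roster format with a
#' header row. Output is deterministic (canonical row order) so equal inputs
#' produce byte-identical files.
#'
#' @param rosters A list of [roster()] objects (or a single one).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roster <- function(rosters, path) {
  if (inherits(rosters, "scm_roster")) rosters <- list(rosters)
  lines <- "classroom_id,wave_id,member_id,participated"
  ord <- order_c(
    vapply(rosters, function(r) r$classroom_id, character(1L)),
    vapply(rosters, function(r) r$wave_id, integer(1L))
  )
  for (r in rosters[ord]) {
    part <- as.integer(r$members %in% r$participants)
    lines <- c(lines, sprintf("%s,%d,%s,%d", r$classroom_id, r$wave_id,
                              r$members, part))
  }
  write_lines_utf8(lines, path)
}

#' One perceiver's Social Cognitive Map report
#'
#' A perceiver lists the groups of classmates who hang around together a lot,
#' plus the classmates who do not hang around with any particular group
#' (isolates). Every listed group must have at least two members — a singleton
#' belongs in `isolates` — and nobody may appear both in a group and as an
#' isolate within the same report.
#'
#' @param perceiver Identifier of the reporting member.
#' @param groups List of character vectors, each a listed group (size >= 2).
#' @param isolates Character vector of members reported as belonging to no
#'   group (may be empty).
#' @param classroom_id,wave_id Optional classroom-wave labels carried along for
#'   matching reports to rosters.
#' @return An object of class `scm_group_report`.
#' @export
group_report <- function(perceiver, groups = list(), isolates = character(),
                         classroom_id = NA_character_, wave_id = NA_integer_) {
  perceiver <- check_ids(perceiver, "perceiver")
  if (length(perceiver) != 1L) stop("`perceiver` must be a single id", call. = FALSE)
  if (!is.list(groups)) stop("`groups` must be a list of character vectors", call. = FALSE)
  groups <- lapply(groups, function(g) sort_c(unique(check_ids(g, "group member"))))
  small <- vapply(groups, length, integer(1L)) < 2L
  if (any(small)) {
    ids <- unlist(groups[small])
    stop(sprintf(paste0("report by %s lists a single-member group (%s); ",
                        "record lone members as isolates instead"),
                 perceiver, paste(ids, collapse = ", ")), call. = FALSE)
  }
  isolates <- if (length(isolates) == 0L) character() else
    sort_c(unique(check_ids(isolates, "isolate")))
  both <- intersect(unlist(groups), isolates)
  if (length(both) > 0L) {
    stop(sprintf("report by %s lists %s both in a group and as an isolate",
                 perceiver, paste(both, collapse = ", ")), call. = FALSE)
  }
  ord <- order_c(vapply(groups, paste, character(1L), collapse = .EDGE_SEP))
  structure(
    list(perceiver = perceiver, groups = groups[ord], isolates = isolates,
         classroom_id = as.character(classroom_id), wave_id = as.integer(wave_id)),
    class = "scm_group_report"
  )
}

#' @export
print.scm_group_report <- function(x, ...) {
  cat(sprintf("<scm_group_report> perceiver %s: %d group(s), %d isolate(s)\n",
              x$perceiver, length(x$groups), length(x$isolates)))
  invisible(x)
}

#' Validate a group report against a roster
#'
#' Checks that every identifier in the report resolves to a roster member and
#' that the perceiver is a participant at that wave.
#'
#' @param report An [group_report()] object.
#' @param roster An [roster()] object.
#' @return `report`, invisibly, or an error naming the perceiver and the
#'   offending token.
#' @export
validate_report <- function(report, roster) {
  stopifnot(inherits(report, "scm_group_report"), inherits(roster, "scm_roster"))
  tokens <- c(unlist(report$groups), report$isolates)
  unknown <- setdiff(tokens, roster$members)
  if (length(unknown) > 0L) {
    stop(sprintf("report by %s names unknown member(s): %s",
                 report$perceiver, paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  if (!report$perceiver %in% roster$participants) {
    stop(sprintf("perceiver %s is not a participant of classroom %s wave %d",
                 report$perceiver, roster$classroom_id, roster$wave_id),
         call. = FALSE)
  }
  invisible(report)
}

#' Read SCM group reports from a JSON file
#'
#' The file holds an array of records, each with keys `classroom_id`,
#' `wave_id`, `perceiver`, `groups` (list of lists of member ids) and
#' `isolates` (list of member ids). Each record is matched to its roster and
#' validated: all identifiers must resolve to roster members and the perceiver
#' must be a participant.
#'
#' @param path Path to the JSON report file.
#' @param rosters A single [roster()] or a list of them covering every
#'   classroom-wave referenced in the file.
#' @return A list of `scm_group_report` objects.
#' @export
read_group_reports <- function(path, rosters) {
  if (!file.exists(path)) stop("report file not found: ", path, call. = FALSE)
  if (inherits(rosters, "scm_roster")) rosters <- list(rosters)
  rkey <- vapply(rosters, function(r) paste(r$classroom_id, r$wave_id, sep = .EDGE_SEP),
                 character(1L))
  records <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  seen <- character()
  out <- vector("list", length(records))
  for (i in seq_along(records)) {
    rec <- records[[i]]
    need <- c("classroom_id", "wave_id", "perceiver", "groups", "isolates")
    absent <- setdiff(need, names(rec))
    if (length(absent) > 0L) {
      stop(sprintf("report record %d is missing key(s): %s", i,
                   paste(absent, collapse = ", ")), call. = FALSE)
    }
    key <- paste(as.character(rec$classroom_id), as.integer(rec$wave_id),
                 sep = .EDGE_SEP)
    ri <- match(key, rkey)
    if (is.na(ri)) {
      stop(sprintf("report record %d references unknown classroom-wave (%s, %s)",
                   i, rec$classroom_id, rec$wave_id), call. = FALSE)
    }
    rep_i <- group_report(
      perceiver = as.character(rec$perceiver),
      groups = lapply(rec$groups, function(g) vapply(g, as.character, character(1L))),
      isolates = vapply(rec$isolates, as.character, character(1L)),
      classroom_id = as.character(rec$classroom_id),
      wave_id = as.integer(rec$wave_id)
    )
    validate_report(rep_i, rosters[[ri]])
    pkey <- paste(key, rep_i$perceiver, sep = .EDGE_SEP)
    if (pkey %in% seen) {
      stop(sprintf("duplicate report by %s for classroom %s wave %s",
                   rep_i$perceiver, rec$classroom_id, rec$wave_id), call. = FALSE)
    }
    seen <- c(seen, pkey)
    out[[i]] <- rep_i
  }
  out
}

#' Write SCM group reports to a JSON file
#'
#' Inverse of [read_group_reports()]; output ordering is canonical, so equal
#' report sets serialise byte-identically.
#'
#' @param reports A list of [group_report()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_group_reports <- function(reports, path) {
  if (inherits(reports, "scm_group_report")) reports <- list(reports)
  ord <- order_c(
    vapply(reports, function(r) r$classroom_id, character(1L)),
    vapply(reports, function(r) r$wave_id, integer(1L)),
    vapply(reports, function(r) r$perceiver, character(1L))
  )
  records <- lapply(reports[ord], function(r) {
    list(
      classroom_id = r$classroom_id,
      wave_id = r$wave_id,
      perceiver = r$perceiver,
      groups = lapply(r$groups, I),
      isolates = I(r$isolates)
    )
  })
  json <- jsonlite::toJSON(records, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_lines_utf8(json, path)
}

#' Expand a group report into the perceiver's perceived network
#'
#' Every listed group implies ties among all pairs of its members (clique
#' expansion); overlapping groups are unioned at the edge level; isolates
#' contribute no ties. Only participants carry relational information in this
#' design, so the perceived network is defined over `roster$participants` and
#' pairs involving a non-participant are dropped.
#'
#' @param report An [group_report()] object.
#' @param roster The [roster()] the report was collected under.
#' @return An [affiliative_network()] over the roster's participants.
#' @export
expand_report <- function(report, roster) {
  validate_report(report, roster)
  parts <- roster$participants
  mats <- lapply(report$groups, function(g) pairs_within(intersect(g, parts)))
  edges <- if (length(mats) > 0L) do.call(rbind, mats) else empty_edge_matrix()
  affiliative_network(parts, edges)
}

#' Encode a network as an SCM-style group report
#'
#' The listed groups are the network's maximal cliques of size two or more and
#' the isolates are its degree-zero nodes, so that
#' `expand_report(encode_as_groups(g), ...)` reproduces `g` exactly (maximal
#' cliques cover every edge). Used by the synthetic-data generator to emit
#' SCM-format files losslessly.
#'
#' @param network An [affiliative_network()].
#' @param perceiver Perceiver identifier to attach to the report.
#' @param classroom_id,wave_id Optional labels carried into the report.
#' @return An `scm_group_report`.
#' @export
encode_as_groups <- function(network, perceiver = "observer",
                             classroom_id = NA_character_, wave_id = NA_integer_) {
  stopifnot(inherits(network, "affiliative_network"))
  groups <- list()
  if (n_edges(network) > 0L) {
    cliques <- igraph::max_cliques(as_igraph(network), min = 2L)
    groups <- lapply(cliques, function(v) sort_c(igraph::as_ids(v)))
  }
  isolates <- names(which(node_degrees(network) == 0L))
  group_report(perceiver, groups = groups, isolates = isolates,
               classroom_id = classroom_id, wave_id = wave_id)
}

#' Write a network as a canonical tab-separated edge list
#'
#' Two columns `node_a`, `node_b`, endpoints in canonical order within a line
#' and lines sorted, so equal networks always produce byte-identical files.
#'
#' @param network An [affiliative_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "affiliative_network"))
  e <- network_edges(network)
  lines <- c("node_a\tnode_b",
             if (nrow(e) > 0L) paste(e[, 1L], e[, 2L], sep = "\t"))
  write_lines_utf8(lines, path)
}

#' Read a tab-separated edge list written by [write_edge_list()]
#'
#' @param path Path to the edge-list file.
#' @param nodes Optional node set; defaults to the identifiers appearing in the
#'   file (degree-zero nodes are then absent).
#' @return An [affiliative_network()].
#' @export
read_edge_list <- function(path, nodes = NULL) {
  if (!file.exists(path)) stop("edge-list file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, colClasses = "character", fileEncoding = "UTF-8")
  if (!all(c("node_a", "node_b") %in% names(df))) {
    stop("edge-list file must have columns node_a, node_b", call. = FALSE)
  }
  edges <- if (nrow(df) > 0L) cbind(df$node_a, df$node_b) else empty_edge_matrix()
  affiliative_network(nodes %||% unique(as.vector(edges)), edges)
}
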