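# Orchestration: read -> consensus -> metrics -> model -> report, plus the
# simulation and recovery workflows.

# Group reports by classroom-wave and pair them with their rosters.
build_classroom_waves <- function(rosters, reports) {
  rkey <- vapply(rosters, function(r) paste(r$classroom_id, r$wave_id, sep = .EDGE_SEP),
                 character(1L))
  pkey <- vapply(reports, function(r) paste(r$classroom_id, r$wave_id, sep = .EDGE_SEP),
                 character(1L))
  dangling <- setdiff(pkey, rkey)
  if (length(dangling) > 0L) {
    stop("report(s) reference classroom-wave(s) with no roster: ",
         paste(gsub(.EDGE_SEP, " wave ", dangling, fixed = TRUE), collapse = "; "),
         call. = FALSE)
  }
  lapply(seq_along(rosters), function(i) {
    classroom_wave(rosters[[i]], reports[pkey == rkey[i]])
  })
}

#' Wave-level summary of accuracy and transitivity
#'
#' Means and standard deviations per wave: accuracy across perceivers,
#' transitivity across classrooms.
#'
#' @param accuracy Data frame from [accuracy_table()] (rows for all
#'   classroom-waves combined).
#' @param transitivity Data frame from [transitivity_table()].
#' @return A data frame with one row per wave.
#' @export
summarize_by_wave <- function(accuracy, transitivity) {
  waves <- sort(unique(c(accuracy$wave_id, transitivity$wave_id)))
  rows <- lapply(waves, function(w) {
    acc <- accuracy$accuracy[accuracy$wave_id == w]
    tr <- transitivity$transitivity[transitivity$wave_id == w]
    tr <- tr[!is.na(tr)]
    data.frame(
      wave_id = w,
      n_perceivers = length(acc),
      accuracy_mean = if (length(acc)) mean(acc) else NA_real_,
      accuracy_sd = if (length(acc) > 1L) stats::sd(acc) else NA_real_,
      n_classrooms = length(tr),
      transitivity_mean = if (length(tr)) mean(tr) else NA_real_,
      transitivity_sd = if (length(tr) > 1L) stats::sd(tr) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Run the full SCM analysis pipeline
#'
#' Reads (or accepts in memory) rosters and SCM reports, applies the
#' participation-rate filter, derives each classroom-wave's true network by
#' the intersection rule, scores per-perceiver accuracy and classroom
#' transitivity, assembles the longitudinal table and fits the
#' random-intercept model. Classroom-waves with an empty true network are
#' excluded from accuracy scoring (and logged), as are participants observed
#' on fewer than `min_waves` usable waves.
#'
#' @param roster_path,reports_path Paths to a roster file ([read_roster()])
#'   and a report file ([read_group_reports()]); alternatively supply
#'   `rosters` and `reports` directly.
#' @param rosters,reports In-memory inputs (lists of [roster()] and
#'   [group_report()] objects); ignored when paths are given.
#' @param out_dir Optional output directory. When given, writes one
#'   true-network edge list per classroom-wave under `true_networks/`, the
#'   accuracy and transitivity tables, a wave-level summary and the model
#'   report (all delimited text, 4-decimal presentation rounding). On error
#'   any partially written outputs are removed.
#' @param participation_threshold Strict participation-rate threshold
#'   (default 0.60).
#' @param min_waves Minimum usable waves per participant (default 2).
#' @param verbose Log filter counts via `message()`?
#' @return Invisibly, a list with `class_waves`, `true_networks`, `accuracy`,
#'   `transitivity`, `summary`, `long_table`, `fit` and `exclusions`.
#' @export
run_pipeline <- function(roster_path = NULL, reports_path = NULL,
                         rosters = NULL, reports = NULL, out_dir = NULL,
                         participation_threshold = 0.60, min_waves = 2L,
                         verbose = TRUE) {
  if (!is.null(roster_path)) {
    rosters <- read_roster(roster_path)
    if (length(rosters) == 0L) stop("roster file contains no rows", call. = FALSE)
    reports <- read_group_reports(reports_path, rosters)
  }
  if (is.null(rosters) || is.null(reports)) {
    stop("supply either file paths or in-memory rosters and reports", call. = FALSE)
  }
  waves <- build_classroom_waves(rosters, reports)
  eligible <- filter_eligible(waves, threshold = participation_threshold,
                              verbose = verbose)
  excl_rate <- attr(eligible, "exclusions")
  if (length(eligible) == 0L) {
    stop("no classroom-wave passed the participation-rate filter", call. = FALSE)
  }
  if (verbose) {
    message(sprintf("%d of %d classroom-wave(s) pass the participation filter (> %.2f)",
                    length(eligible), length(waves), participation_threshold))
  }

  truths <- lapply(eligible, true_network)
  cls <- vapply(eligible, function(cw) cw$roster$classroom_id, character(1L))
  wvs <- vapply(eligible, function(cw) cw$roster$wave_id, integer(1L))
  names(truths) <- paste0(cls, "_w", wvs)

  empty_truth <- vapply(truths, function(x) n_edges(x) == 0L, logical(1L))
  acc_parts <- vector("list", length(eligible))
  for (i in seq_along(eligible)) {
    if (empty_truth[i]) {
      if (verbose) {
        message(sprintf("excluding classroom %s wave %d from accuracy scoring: empty true network",
                        cls[i], wvs[i]))
      }
      next
    }
    acc_parts[[i]] <- accuracy_table(eligible[[i]], truths[[i]])
  }
  accuracy <- do.call(rbind, acc_parts[!vapply(acc_parts, is.null, logical(1L))])
  if (is.null(accuracy) || nrow(accuracy) == 0L) {
    stop("no classroom-wave yields a scorable (non-empty) true network", call. = FALSE)
  }
  transitivity <- transitivity_table(truths, classroom_ids = cls, wave_ids = wvs)

  long_table <- assemble_long_table(accuracy, transitivity,
                                    min_waves = min_waves, verbose = verbose)
  if (nrow(long_table) == 0L) {
    stop(sprintf("no participant was observed on %d or more waves", as.integer(min_waves)),
         call. = FALSE)
  }
  fit <- fit_random_intercept(long_table)

  result <- list(
    class_waves = eligible,
    true_networks = truths,
    accuracy = accuracy,
    transitivity = transitivity,
    summary = summarize_by_wave(accuracy, transitivity),
    long_table = long_table,
    fit = fit,
    exclusions = list(
      participation = excl_rate,
      empty_truth = data.frame(classroom_id = cls[empty_truth],
                               wave_id = wvs[empty_truth],
                               stringsAsFactors = FALSE),
      n_missing_transitivity = attr(long_table, "n_missing_transitivity"),
      n_single_wave_participants = attr(long_table, "n_excluded_participants")
    )
  )
  if (!is.null(out_dir)) {
    write_pipeline_outputs(result, out_dir)
  }
  invisible(result)
}

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.4f", x))
}

write_tsv <- function(df, path, digits_cols = NULL) {
  for (cn in digits_cols) df[[cn]] <- fmt_num(df[[cn]])
  lines <- c(paste(names(df), collapse = "\t"),
             if (nrow(df) > 0L) do.call(paste, c(unname(df), sep = "\t")))
  write_lines_utf8(lines, path)
}

write_pipeline_outputs <- function(result, out_dir) {
  created <- character()
  on_fail <- function(e) {
    unlink(created, recursive = TRUE)
    stop(e)
  }
  tryCatch({
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    net_dir <- file.path(out_dir, "true_networks")
    dir.create(net_dir, showWarnings = FALSE)
    created <<- c(created, net_dir)
    for (nm in names(result$true_networks)) {
      p <- file.path(net_dir, paste0(nm, ".tsv"))
      write_edge_list(result$true_networks[[nm]], p)
    }
    p_acc <- file.path(out_dir, "accuracy.tsv")
    write_tsv(result$accuracy, p_acc,
              digits_cols = c("precision", "coverage", "accuracy"))
    created <<- c(created, p_acc)
    p_tr <- file.path(out_dir, "transitivity.tsv")
    write_tsv(result$transitivity, p_tr, digits_cols = "transitivity")
    created <<- c(created, p_tr)
    p_sum <- file.path(out_dir, "summary_by_wave.tsv")
    write_tsv(result$summary, p_sum,
              digits_cols = c("accuracy_mean", "accuracy_sd",
                              "transitivity_mean", "transitivity_sd"))
    created <<- c(created, p_sum)
    p_mod <- file.path(out_dir, "model_report.tsv")
    fit <- result$fit
    fx <- fit$fixed
    rep_df <- data.frame(
      term = c(fx$term, "sigma2_intercept", "sigma2_residual",
               "n_participants", "n_observations"),
      estimate = fmt_num(c(fx$estimate, fit$sigma2_intercept, fit$sigma2_residual,
                           fit$n_participants, fit$n_observations)),
      se = c(fmt_num(fx$se), "", "", "", ""),
      df = c(fmt_num(fx$df), "", "", "", ""),
      p_value = c(fmt_num(fx$p_value), "", "", "", ""),
      stringsAsFactors = FALSE
    )
    write_tsv(rep_df, p_mod)
    created <<- c(created, p_mod)
  }, error = on_fail)
  invisible(out_dir)
}

#' Materialise a synthetic study on disk
#'
#' Runs [simulate_study()] and writes the roster, report and planted-truth
#' files. Validates that the configured number of waves can satisfy
#' `min_waves`.
#'
#' @param config An [simulation_config()].
#' @param out_dir Output directory.
#' @param min_waves Minimum waves the downstream analysis will require.
#' @return The `scm_study`, invisibly.
#' @export
run_simulation <- function(config, out_dir, min_waves = 2L) {
  stopifnot(inherits(config, "scm_sim_config"))
  if (config$n_waves < min_waves) {
    stop(sprintf("config has %d wave(s) but the analysis requires at least %d per participant",
                 config$n_waves, as.integer(min_waves)), call. = FALSE)
  }
  invisible(simulate_study(config, dir = out_dir))
}

#' Simulate, analyse and compare against the planted truth
#'
#' End-to-end recovery workflow: simulates a study, runs the analysis
#' pipeline on its reports, and compares each classroom-wave's recovered
#' (intersection) true network and transitivity against the planted ones.
#'
#' @param config An [simulation_config()].
#' @param out_dir Optional directory for the study and pipeline outputs.
#' @param participation_threshold,min_waves,verbose Passed to
#'   [run_pipeline()].
#' @return Invisibly, a list with the `study`, the pipeline `result`, and a
#'   `comparison` data frame (per classroom-wave: planted vs recovered edge
#'   counts, Jaccard overlap, planted vs recovered transitivity).
#' @export
recover_study <- function(config, out_dir = NULL,
                          participation_threshold = 0.60, min_waves = 2L,
                          verbose = TRUE) {
  study <- simulate_study(config,
                          dir = if (is.null(out_dir)) NULL else file.path(out_dir, "study"))
  result <- run_pipeline(
    rosters = study$rosters, reports = study$reports,
    out_dir = if (is.null(out_dir)) NULL else file.path(out_dir, "analysis"),
    participation_threshold = participation_threshold,
    min_waves = min_waves, verbose = verbose
  )
  comparison <- do.call(rbind, lapply(study$planted, function(p) {
    nm <- paste0(p$classroom_id, "_w", p$wave_id)
    rec <- result$true_networks[[nm]]
    pk <- edge_keys(p$network)
    rk <- if (is.null(rec)) character() else edge_keys(rec)
    data.frame(
      classroom_id = p$classroom_id, wave_id = p$wave_id,
      n_planted = length(pk), n_recovered = length(rk),
      jaccard = if (length(union(pk, rk)) == 0L) NA_real_ else
        length(intersect(pk, rk)) / length(union(pk, rk)),
      planted_transitivity = p$transitivity,
      recovered_transitivity = if (is.null(rec)) NA_real_ else transitivity_index(rec),
      stringsAsFactors = FALSE
    )
  }))
  invisible(list(study = study, result = result, comparison = comparison))
}
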