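# Data model: a response sequence is one participant's ordered decision
# events; a cohort is a named collection of sequences plus provenance.
# Canonical interchange columns, in order:
.cohort_columns <- c("participant_id", "task_index", "event_index",
                     "decision", "correct", "reaction_time_ms")
.decision_symbols <- c("Y", "N", "I")

#' Construct a response sequence
#'
#' One participant's ordered decision events. Each event is a symbolic
#' decision (`Y` = yes, `N` = no, `I` = ignore), a correctness flag, and a
#' positive reaction time in milliseconds, organized into one or more
#' session tasks whose within-task order is the collection order.
#'
#' @param participant_id Character scalar, unique within a cohort.
#' @param events Data frame with columns `task_index`, `event_index`,
#'   `decision`, `correct`, `reaction_time_ms`.
#' @return Object of class `response_sequence`.
#' @details The total event count is the participant's number of decisions
#'   (NoD). The test design targets NoD in \[200, 800\] over the two
#'   12-minute tasks; a sequence outside that range is valid but flagged
#'   with a warning at construction.
#' @export
#' @examples
#' ev <- data.frame(task_index = 1L, event_index = 1:3,
#'                  decision = c("Y", "N", "I"),
#'                  correct = c(TRUE, TRUE, FALSE),
#'                  reaction_time_ms = c(850, 900, 1200))
#' response_sequence("P001", ev)
response_sequence <- function(participant_id, events) {
  participant_id <- as.character(participant_id)
  stopifnot(length(participant_id) == 1L, is.data.frame(events))
  needed <- setdiff(.cohort_columns, "participant_id")
  missing <- setdiff(needed, names(events))
  if (length(missing)) {
    stop("events missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  events <- events[needed]
  events$task_index <- as.integer(events$task_index)
  events$event_index <- as.integer(events$event_index)
  events$decision <- as.character(events$decision)
  events$correct <- as.logical(events$correct)
  events$reaction_time_ms <- as.numeric(events$reaction_time_ms)
  if (nrow(events) == 0L) stop("a response sequence needs at least one task with events",
                               call. = FALSE)
  bad_sym <- !events$decision %in% .decision_symbols
  if (any(bad_sym)) {
    stop("invalid decision symbol(s): ",
         paste(unique(events$decision[bad_sym]), collapse = ", "),
         " (must be Y, N or I)", call. = FALSE)
  }
  if (anyNA(events$correct)) stop("correct must be TRUE/FALSE", call. = FALSE)
  if (anyNA(events$reaction_time_ms) || any(events$reaction_time_ms <= 0)) {
    stop("reaction_time_ms must be positive", call. = FALSE)
  }
  events <- events[order(events$task_index, events$event_index), , drop = FALSE]
  rownames(events) <- NULL
  nod <- nrow(events)
  if (nod < 200L || nod > 800L) {
    warning("participant ", participant_id, ": NoD = ", nod,
            " outside the design range [200, 800]", call. = FALSE)
  }
  structure(list(participant_id = participant_id, events = events),
            class = "response_sequence")
}

#' @export
print.response_sequence <- function(x, ...) {
  cat("Response sequence for participant", x$participant_id, "\n")
  cat("  tasks:", length(unique(x$events$task_index)),
      "  NoD:", nrow(x$events),
      "  error rate:", round(mean(!x$events$correct), 4), "\n")
  invisible(x)
}

#' Number of decisions of a sequence or cohort
#'
#' @param x A `response_sequence` or `ntt_cohort`.
#' @return Integer (scalar per sequence; named vector for a cohort).
#' @export
n_decisions <- function(x) UseMethod("n_decisions")

#' @export
n_decisions.response_sequence <- function(x) nrow(x$events)

#' @export
n_decisions.ntt_cohort <- function(x) {
  vapply(x$sequences, n_decisions, integer(1))
}

#' Reaction-time series of a participant
#'
#' @param x A `response_sequence`.
#' @param per_task If `FALSE` (default) the tasks are concatenated in task
#'   order into a single series, matching the treatment of the test as one
#'   24-minute session; if `TRUE`, a list with one series per task.
#' @return Numeric vector, or list of numeric vectors.
#' @export
reaction_times <- function(x, per_task = FALSE) {
  stopifnot(inherits(x, "response_sequence"))
  if (!per_task) return(x$events$reaction_time_ms)
  split(x$events$reaction_time_ms, x$events$task_index)
}

#' Construct a cohort of response sequences
#'
#' @param sequences List of [response_sequence()] objects with unique
#'   participant ids.
#' @param provenance Optional list of metadata (source file, cleaning log);
#'   free-form, carried along unchanged.
#' @return Object of class `ntt_cohort`.
#' @export
ntt_cohort <- function(sequences, provenance = list()) {
  stopifnot(is.list(sequences))
  ok <- vapply(sequences, inherits, logical(1), what = "response_sequence")
  if (!all(ok)) stop("all elements must be response_sequence objects", call. = FALSE)
  ids <- vapply(sequences, `[[`, character(1), "participant_id")
  if (anyDuplicated(ids)) {
    stop("duplicate participant_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  names(sequences) <- ids
  structure(list(sequences = sequences, provenance = provenance),
            class = "ntt_cohort")
}

#' @export
print.ntt_cohort <- function(x, ...) {
  nod <- n_decisions(x)
  cat("NTT cohort:", length(x$sequences), "participants\n")
  if (length(nod)) {
    cat("  NoD range:", min(nod), "-", max(nod),
        "  median:", stats::median(nod), "\n")
  }
  if (!is.null(x$provenance$source)) cat("  source:", x$provenance$source, "\n")
  if (!is.null(x$provenance$cleaning_log) && length(x$provenance$cleaning_log)) {
    cat("  cleaning log:", length(x$provenance$cleaning_log), "entr(y/ies)\n")
  }
  invisible(x)
}

#' @export
length.ntt_cohort <- function(x) length(x$sequences)

#' Participant ids of a cohort
#' @param cohort An `ntt_cohort`.
#' @return Character vector in cohort order.
#' @export
participant_ids <- function(cohort) {
  stopifnot(inherits(cohort, "ntt_cohort"))
  names(cohort$sequences)
}

#' @export
as.data.frame.ntt_cohort <- function(x, ...) {
  rows <- lapply(x$sequences, function(s) {
    cbind(participant_id = s$participant_id, s$events)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[.cohort_columns]
}

#' Read a cohort from a tabular interchange file
#'
#' The canonical format is a UTF-8 CSV with header and exactly the columns
#' `participant_id, task_index, event_index, decision, correct,
#' reaction_time_ms`. An XLSX sheet with the same columns is accepted
#' read-only (requires the readxl package).
#'
#' Row-level problems (decision symbol outside `{Y, N, I}`, non-positive
#' reaction time, unparseable numbers) are rejected and recorded in the
#' cleaning log, unless `strict = TRUE`, in which case the first offending
#' row aborts the read with its row number.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"csv"` or `"xlsx"`.
#' @param strict Abort on the first invalid row instead of dropping it.
#' @return An [ntt_cohort()]; `provenance$cleaning_log` lists dropped rows,
#'   `provenance$n_dropped_rows` has the per-participant drop counts.
#' @export
read_cohort <- function(path, format = c("auto", "csv", "xlsx"),
                        strict = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) "xlsx" else "csv"
  }
  raw <- if (format == "xlsx") {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading XLSX requires the readxl package", call. = FALSE)
    }
    as.data.frame(readxl::read_excel(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  missing <- setdiff(.cohort_columns, names(raw))
  if (length(missing)) {
    stop("format error: missing column(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  raw <- raw[.cohort_columns]
  raw$decision <- toupper(trimws(as.character(raw$decision)))
  raw$reaction_time_ms <- suppressWarnings(as.numeric(raw$reaction_time_ms))
  if (is.character(raw$correct)) {
    raw$correct <- toupper(trimws(raw$correct)) %in% c("TRUE", "T", "1", "YES")
  }
  raw$correct <- as.logical(raw$correct)

  bad_decision <- !raw$decision %in% .decision_symbols
  bad_rt <- is.na(raw$reaction_time_ms) | raw$reaction_time_ms <= 0
  bad_correct <- is.na(raw$correct)
  bad <- bad_decision | bad_rt | bad_correct
  log_lines <- character(0)
  if (any(bad)) {
    rows <- which(bad)
    reasons <- ifelse(bad_decision[rows], "invalid decision symbol",
                      ifelse(bad_rt[rows], "non-positive or missing reaction time",
                             "missing correctness flag"))
    if (strict) {
      stop("format error at data row ", rows[1], ": ", reasons[1], call. = FALSE)
    }
    log_lines <- sprintf("dropped row %d (participant %s): %s",
                         rows, raw$participant_id[rows], reasons)
    raw <- raw[!bad, , drop = FALSE]
  }
  if (nrow(raw) == 0L) {
    return(ntt_cohort(list(), provenance = list(
      source = path, cleaning_log = log_lines,
      n_dropped_rows = integer(0))))
  }
  split_rows <- split(raw, factor(raw$participant_id,
                                  levels = unique(raw$participant_id)))
  sequences <- lapply(split_rows, function(df) {
    response_sequence(df$participant_id[1],
                      df[setdiff(.cohort_columns, "participant_id")])
  })
  dropped <- table(factor(character(0), levels = names(split_rows)))
  if (length(log_lines)) {
    dcount <- table(factor(sub("^dropped row \\d+ \\(participant (.*)\\):.*$",
                               "\\1", log_lines),
                           levels = names(split_rows)))
    dropped <- dcount
  }
  ntt_cohort(unname(sequences),
             provenance = list(source = path, cleaning_log = log_lines,
                               n_dropped_rows = as.integer(dropped)))
}

#' Write a cohort to the canonical CSV format
#'
#' @param cohort An [ntt_cohort()].
#' @param path Output file path. Reaction times are written with full
#'   precision (15 significant digits) so a round trip is lossless well
#'   beyond 6 significant digits.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "ntt_cohort"))
  if (length(cohort$sequences) == 0L) {
    writeLines(paste(.cohort_columns, collapse = ","), con = path)
    return(invisible(path))
  }
  df <- as.data.frame(cohort)
  df$reaction_time_ms <- formatC(df$reaction_time_ms, digits = 15,
                                 format = "g")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Default cohort-cleaning rules
#'
#' The study's published cleaning rule is unstated; these defaults are a
#' documented stand-in: a participant is kept only with at least
#' `min_tasks` tasks, a total NoD of at least `min_nod`, and (when the
#' cohort's provenance records dropped rows) a dropped-row fraction at most
#' `max_dropped_frac`.
#'
#' @param min_nod Minimum total number of decisions (default 100).
#' @param min_tasks Minimum number of session tasks (default 2).
#' @param max_dropped_frac Maximum tolerated fraction of rejected rows for
#'   the participant (default 0.5).
#' @return A list of class `cleaning_rules`.
#' @export
cleaning_rules <- function(min_nod = 100L, min_tasks = 2L,
                           max_dropped_frac = 0.5) {
  stopifnot(min_nod >= 0, min_tasks >= 1, max_dropped_frac >= 0,
            max_dropped_frac <= 1)
  structure(list(min_nod = as.integer(min_nod),
                 min_tasks = as.integer(min_tasks),
                 max_dropped_frac = max_dropped_frac),
            class = "cleaning_rules")
}

#' Clean a cohort by rule
#'
#' Removes participants violating any [cleaning_rules()] rule and appends
#' one cleaning-log line per removal naming the rule. Idempotent: cleaning
#' an already-clean cohort is the identity.
#'
#' @param cohort An [ntt_cohort()].
#' @param rules A [cleaning_rules()] object.
#' @return The cleaned cohort; an empty result is allowed (with a warning).
#' @export
clean_cohort <- function(cohort, rules = cleaning_rules()) {
  stopifnot(inherits(cohort, "ntt_cohort"), inherits(rules, "cleaning_rules"))
  dropped_rows <- cohort$provenance$n_dropped_rows
  keep <- logical(length(cohort$sequences))
  log_lines <- character(0)
  for (i in seq_along(cohort$sequences)) {
    s <- cohort$sequences[[i]]
    nod <- nrow(s$events)
    ntasks <- length(unique(s$events$task_index))
    reason <- NULL
    if (ntasks < rules$min_tasks) {
      reason <- sprintf("only %d task(s), %d required", ntasks, rules$min_tasks)
    } else if (nod < rules$min_nod) {
      reason <- sprintf("NoD %d below minimum %d", nod, rules$min_nod)
    } else if (!is.null(dropped_rows) && length(dropped_rows) >= i &&
               !is.na(dropped_rows[i]) &&
               dropped_rows[i] / (dropped_rows[i] + nod) > rules$max_dropped_frac) {
      reason <- sprintf("dropped-row fraction %.2f above maximum %.2f",
                        dropped_rows[i] / (dropped_rows[i] + nod),
                        rules$max_dropped_frac)
    }
    keep[i] <- is.null(reason)
    if (!is.null(reason)) {
      log_lines <- c(log_lines,
                     sprintf("removed participant %s: %s",
                             s$participant_id, reason))
    }
  }
  if (!any(keep)) warning("cleaning removed every participant", call. = FALSE)
  prov <- cohort$provenance
  prov$cleaning_log <- c(prov$cleaning_log, log_lines)
  prov$n_dropped_rows <- dropped_rows[keep]
  ntt_cohort(cohort$sequences[keep], provenance = prov)
}
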