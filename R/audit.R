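## Append-only per-site command log, custodian-only export, and post-hoc
## detectors for known multi-step disclosure patterns. Single-step disclosure
## is indistinguishable from legitimate analysis in a command log, so the
## detectors target patterns that need two or more commands in sequence: the
## one-row difference attack and seeded-noise inference.

#' Create an empty audit log
#'
#' The log is an append-only store: events receive strictly increasing
#' sequence numbers and are never modified or removed once recorded.
#' Timestamps come from an injectable clock so that replayed workloads are
#' deterministic.
#'
#' @param clock A zero-argument function returning a timestamp; defaults to
#'   [Sys.time()].
#' @return An object of class `audit_log`.
#' @export
audit_log <- function(clock = Sys.time) {
  e <- new.env(parent = emptyenv())
  e$events <- list()
  e$clock <- clock
  class(e) <- "audit_log"
  e
}

#' Append one event to an audit log
#'
#' @param log An [audit_log()].
#' @param user,site,fun,kind Identify who ran what.
#' @param outcome One of `"executed"`, `"blocked:<rule>"`, `"error:<code>"`.
#' @param args Request argument list (stored as a digest, plus any predicate
#'   text verbatim for custodian-side review).
#' @param session_id Session identifier (groups events for the seed-abuse
#'   detector).
#' @param meta Custodian-only result metadata (e.g. `subset_size`, `source`,
#'   `target`, `table_dims`); never returned to analysts.
#' @return The event's sequence number, invisibly.
#' @export
audit_record <- function(log, user, site, fun, kind, outcome,
                         args = list(), session_id = NA_character_,
                         meta = list()) {
  stopifnot(inherits(log, "audit_log"))
  predicate <- NA_character_
  for (a in args) {
    if (is.list(a) && identical(a$type, "string")) { predicate <- a$value; break }
  }
  ev <- list(
    seq = length(log$events) + 1L,
    time = format(log$clock(), "%Y-%m-%dT%H:%M:%S"),
    user = user, site = site, fun = fun, kind = kind,
    args_digest = args_digest(args), predicate = predicate,
    outcome = outcome, session_id = session_id, meta = meta
  )
  log$events[[ev$seq]] <- ev
  invisible(ev$seq)
}

#' Number of events in a log
#' @param log An [audit_log()].
#' @return Integer count.
#' @export
audit_length <- function(log) length(log$events)

#' Read a copy of the recorded events
#'
#' Returns value copies; mutating the returned list cannot alter the log.
#' @param log An [audit_log()].
#' @return List of event records.
#' @export
audit_events <- function(log) log$events

#' Export a site's log (custodian only)
#'
#' The full log, including custodian-side metadata, is released only to the
#' holder of the site's custodian credential; analysts receive
#' `ACCESS_DENIED`.
#'
#' @param node A data-holding node.
#' @param credential The custodian credential configured for the site.
#' @param format `"list"` or `"ndjson"` (newline-delimited JSON, one event
#'   per line).
#' @return Event list or NDJSON character scalar.
#' @export
export_log <- function(node, credential, format = c("list", "ndjson")) {
  format <- match.arg(format)
  if (!is_scalar(credential, is.character) ||
      !identical(keyed_hash(credential, "token"), node$custodian_hash)) {
    stop_sdc("ACCESS_DENIED")
  }
  ev <- audit_events(node$log)
  if (format == "list") return(ev)
  if (length(ev) == 0L) return("")
  paste(vapply(ev, function(e) {
    as.character(jsonlite::toJSON(e, auto_unbox = TRUE, null = "null"))
  }, character(1)), collapse = "\n")
}

#' Parse an NDJSON log export back into an event list
#' @param text NDJSON character scalar or path to a log file.
#' @return List of event records.
#' @export
read_log_ndjson <- function(text) {
  if (length(text) == 1L && file.exists(text)) {
    lines <- readLines(text, warn = FALSE)
  } else {
    lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  lines <- lines[nzchar(lines)]
  lapply(lines, jsonlite::fromJSON, simplifyVector = FALSE)
}

.ev_field <- function(events, field, default = NA_character_) {
  vapply(events, function(e) {
    v <- e[[field]]
    if (is.null(v) || length(v) == 0L) default else as.character(v)
  }, character(1))
}

#' Detect one-row difference attacks in a command log
#'
#' A difference attack infers one individual's values by comparing statistics
#' computed on two subsets that differ by exactly one row. The detector
#' groups successful subset-creation events by (user, source symbol); for
#' each pair of subsets from the same source whose custodian-recorded sizes
#' differ by exactly 1, where each subset was later the input of an aggregate
#' request, it emits one alert citing the four events involved.
#'
#' @param events An event list (from [audit_events()] or
#'   [read_log_ndjson()]).
#' @return List of alerts: `list(type = "difference_attack", events =
#'   <sequence numbers>, explanation = <text>)`.
#' @export
detect_difference_attacks <- function(events) {
  alerts <- list()
  is_subset <- vapply(events, function(e) {
    identical(e$fun, "subsetDS") && identical(e$outcome, "executed")
  }, logical(1))
  subs <- events[is_subset]
  if (length(subs) < 2L) return(alerts)

  # first aggregate event on each symbol, per user
  agg_on <- function(user, symbol, after_seq) {
    for (e in events) {
      if (!identical(e$kind, "aggregate") || !identical(e$user, user)) next
      if (e$seq <= after_seq || !identical(e$outcome, "executed")) next
      src <- e$meta$source
      if (!is.null(src) && identical(src, symbol)) return(e$seq)
    }
    NA_integer_
  }

  key <- paste(.ev_field(subs, "user"),
               vapply(subs, function(e) as.character(e$meta$source), character(1)))
  for (grp in split(subs, key)) {
    if (length(grp) < 2L) next
    for (i in seq_len(length(grp) - 1L)) {
      for (j in seq(i + 1L, length(grp))) {
        a <- grp[[i]]; b <- grp[[j]]
        sa <- a$meta$subset_size; sb <- b$meta$subset_size
        if (is.null(sa) || is.null(sb)) next
        if (abs(as.numeric(sa) - as.numeric(sb)) != 1) next
        qa <- agg_on(a$user, a$meta$target, a$seq)
        qb <- agg_on(b$user, b$meta$target, b$seq)
        if (is.na(qa) || is.na(qb)) next
        alerts[[length(alerts) + 1L]] <- list(
          type = "difference_attack",
          events = sort(as.integer(c(a$seq, b$seq, qa, qb))),
          explanation = paste0(
            "user ", a$user, " created subsets of ", a$meta$source,
            " with sizes differing by one row and queried aggregates on both")
        )
      }
    }
  }
  alerts
}

#' Detect seeded-noise inference attempts
#'
#' Controlling the random seed lets an analyst subtract known noise draws
#' from obfuscated output, defeating noise obfuscation. The detector flags
#' every sequence in which a seed-setting request (`setSeedDS`, whether
#' executed or blocked) precedes a noise-obfuscation request by the same user
#' within the same session. Under permissive levels the alert is advisory:
#' the commands were allowed, but the pattern still merits custodian review.
#'
#' @param events An event list.
#' @return List of alerts: `list(type = "seed_abuse", events = <sequence
#'   numbers>, explanation = <text>)`.
#' @export
detect_seed_abuse <- function(events) {
  alerts <- list()
  seeds <- Filter(function(e) identical(e$fun, "setSeedDS"), events)
  for (se in seeds) {
    for (e in events) {
      if (e$seq <= se$seq) next
      if (!identical(e$fun, "scatterNoiseDS")) next
      if (!identical(e$user, se$user)) next
      if (!identical(e$session_id, se$session_id)) next
      alerts[[length(alerts) + 1L]] <- list(
        type = "seed_abuse",
        events = c(se$seq, e$seq),
        explanation = paste0("user ", se$user,
                             " requested seed control before noise obfuscation")
      )
      break # one alert per seed request
    }
  }
  alerts
}

#' Run all detectors over a log
#'
#' @param events An event list.
#' @return List of alerts from every detector, in log order.
#' @export
scan_log <- function(events) {
  c(detect_difference_attacks(events), detect_seed_abuse(events))
}

#' Simulate an analyst workload for detector benchmarking
#'
#' Replays a short scripted session against a fresh 40-row site and returns
#' its audit trail. With `attack = TRUE` the analyst creates two subsets of
#' the same parent differing by exactly one row and queries a summary on
#' each — the difference-attack signature. Benign workloads do the same but
#' keep a subset-size gap of at least two rows, which legitimate nested
#' analyses routinely produce and which the detector must not flag.
#'
#' @param seed Seed controlling the subset sizes.
#' @param attack Construct the one-row-difference pattern?
#' @return The node's audit event list.
#' @export
simulate_workload <- function(seed, attack = FALSE) {
  nd <- new_node("w", data.frame(v = as.numeric(1:40)),
                 accounts = list(list(user = "u", token = "t")),
                 custodian = "c",
                 clock = function() as.POSIXct("2026-01-01", tz = "UTC"))
  sess <- login(nd, "u", "t")
  with_seed(seed, {
    m <- sample(5:20, 1)
    gap <- if (attack) 1L else sample(2:5, 1)
    for (i in c(0L, gap)) {
      target <- paste0("s", i)
      dispatch(sess, ds_request("u", "subsetDS", "assign",
                                args = list("D",
                                            ds_arg_string(sprintf("v <= %d",
                                                                  m + i),
                                                          "long")),
                                target = target))
      dispatch(sess, ds_request("u", "summaryDS", "aggregate",
                                args = list(target, "v")))
    }
  })
  audit_events(nd$log)
}
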