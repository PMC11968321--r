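## Syntactic validation of incoming analyst commands: function whitelisting
## under the active privacy control level, argument well-formedness, and the
## string-length and character-set filters that stop code injection.

#' Permitted characters in string arguments
#'
#' A single constant defining the full set of characters a string argument may
#' contain: ASCII letters, digits, space, and
#' `. _ , ( ) = < > ! & | + - * / ~ ' "`. This is enough for variable
#' names, comparison predicates and model formulas while excluding the
#' characters that enable command injection (semicolon, backtick, `$`, `@`,
#' `#`, backslash, braces, brackets, control characters).
#' @format A character scalar (regex character class body).
#' @export
PERMITTED_CHARS <- "A-Za-z0-9 ._,()=<>!&|+*/~'\"-"

#' Construct an analyst request
#'
#' A request is the unit of interaction with a node: one whitelisted server
#' side function call, classified as `assign` (stores a derived object server
#' side, returns a status message only) or `aggregate` (returns a
#' low-dimensional statistical payload after disclosure checks).
#'
#' @param user Requesting user identifier.
#' @param fun Server-side function name (e.g. `"tableDS"`).
#' @param kind `"assign"` or `"aggregate"`.
#' @param args List of arguments; each is a list with `type` (`"symbol"`,
#'   `"string"`, `"number"`, `"flag"`), `value`, and for string-bearing types
#'   a `slot` (`"short"` for names/symbols, `"long"` for predicates and
#'   formulas). Convenience: bare character/numeric/logical values are
#'   auto-wrapped (character as short-slot symbols).
#' @param target Target symbol name (assign requests only).
#' @return An object of class `ds_request`.
#' @export
ds_request <- function(user, fun, kind = c("aggregate", "assign"),
                       args = list(), target = NULL) {
  kind <- match.arg(kind)
  args <- lapply(args, function(a) {
    if (is.list(a) && !is.null(a$type)) return(a)
    if (is.character(a)) list(type = "symbol", value = a, slot = "short")
    else if (is.numeric(a)) list(type = "number", value = a)
    else if (is.logical(a)) list(type = "flag", value = a)
    else stop_sdc("BAD_ARGUMENT")
  })
  structure(list(user = user, fun = fun, kind = kind, args = args,
                 target = target),
            class = "ds_request")
}

#' Tag a string argument for a request
#'
#' @param value The string.
#' @param slot `"long"` (predicates, formulas) or `"short"` (names).
#' @return An argument list suitable for [ds_request()].
#' @export
ds_arg_string <- function(value, slot = c("long", "short")) {
  list(type = "string", value = value, slot = match.arg(slot))
}

#' String-length filter
#'
#' Long-slot strings (predicates, formulas) are accepted up to
#' `s$string_max` characters; short-slot strings (variable names) up to
#' `s$string_short_max`. A string of exactly the threshold length passes;
#' strictly longer is blocked.
#'
#' @param v Character scalar.
#' @param slot `"long"` or `"short"`.
#' @param s Disclosure settings.
#' @return A `filter_decision`.
#' @export
check_string <- function(v, slot = c("long", "short"), s) {
  slot <- match.arg(slot)
  if (!is_scalar(v, is.character)) stop_sdc("BAD_ARGUMENT")
  lim <- if (slot == "long") s$string_max else s$string_short_max
  if (nchar(v) > lim) {
    filter_decision(FALSE,
                    if (slot == "long") "nfilter.string" else "nfilter.stringShort",
                    sprintf("length %d over %d", nchar(v), lim))
  } else filter_decision(TRUE)
}

#' Character-set filter
#'
#' Accepts a string iff every character belongs to [PERMITTED_CHARS]; reports
#' the first offending character otherwise. The empty string is vacuously
#' accepted.
#'
#' @param v Character scalar.
#' @return A `filter_decision`.
#' @export
check_charset <- function(v) {
  if (!is_scalar(v, is.character)) stop_sdc("BAD_ARGUMENT")
  bad <- regmatches(v, regexpr(sprintf("[^%s]", PERMITTED_CHARS), v))
  if (length(bad) && nzchar(bad)) {
    filter_decision(FALSE, "charset", sprintf("forbidden character '%s'", bad))
  } else filter_decision(TRUE)
}

#' Validate a request against the registry, privacy level and string filters
#'
#' All checks are evaluated and every failure is reported, not only the
#' first: function membership in the registry, privacy-level blocking, kind
#' agreement with the registry entry, target presence (assign requests carry
#' a target, aggregate requests must not), and per-argument string length and
#' character-set checks.
#'
#' @param r A [ds_request()].
#' @param reg A [function_registry()] data frame.
#' @param s Disclosure settings (supplies the string limits and the active
#'   privacy level).
#' @return A list with `accepted` (logical) and `reasons` (list of
#'   `list(code, arg)` entries; empty iff accepted).
#' @export
parse_and_validate <- function(r, reg = function_registry(),
                               s = default_settings()) {
  reasons <- list()
  flag <- function(code, arg = NA_character_) {
    reasons[[length(reasons) + 1L]] <<- list(code = code, arg = arg)
  }

  entry <- reg[reg$name == r$fun, , drop = FALSE]
  if (nrow(entry) == 0L) {
    flag("UNKNOWN_FUNCTION", r$fun)
  } else {
    if (r$fun %in% blocked_functions(s$privacy_level)) {
      flag("BLOCKED_BY_PRIVACY_LEVEL", r$fun)
    }
    if (entry$kind != r$kind) flag("KIND_MISMATCH", r$fun)
  }
  if (r$kind == "assign" && (is.null(r$target) || !nzchar(r$target))) {
    flag("MISSING_TARGET")
  }
  if (r$kind == "aggregate" && !is.null(r$target)) flag("UNEXPECTED_TARGET")

  for (i in seq_along(r$args)) {
    a <- r$args[[i]]
    if (!a$type %in% c("symbol", "string", "number", "flag")) {
      flag("BAD_ARGUMENT", sprintf("arg %d", i))
      next
    }
    if (a$type %in% c("symbol", "string")) {
      v <- a$value
      if (!is_scalar(v, is.character)) {
        flag("BAD_ARGUMENT", sprintf("arg %d", i))
        next
      }
      slot <- if (identical(a$slot, "long")) "long" else "short"
      if (!check_string(v, slot, s)$allowed) {
        flag("STRING_TOO_LONG", sprintf("arg %d", i))
      }
      if (!check_charset(v)$allowed) {
        flag("FORBIDDEN_CHARACTER", sprintf("arg %d", i))
      }
    }
  }
  # target is a short name too
  if (!is.null(r$target) && is_scalar(r$target, is.character)) {
    if (!check_string(r$target, "short", s)$allowed) {
      flag("STRING_TOO_LONG", "target")
    }
    if (!check_charset(r$target)$allowed) flag("FORBIDDEN_CHARACTER", "target")
  }

  list(accepted = length(reasons) == 0L, reasons = reasons)
}

#' Serialize a request to its JSON envelope
#'
#' @param r A [ds_request()].
#' @return A JSON string `{user, function, kind, args[], target}`.
#' @export
request_to_json <- function(r) {
  jsonlite::toJSON(list(user = r$user, `function` = r$fun, kind = r$kind,
                        args = r$args, target = r$target),
                   auto_unbox = TRUE, null = "null")
}

#' Rebuild a request from its JSON envelope
#'
#' @param json A JSON string produced by [request_to_json()].
#' @return A [ds_request()].
#' @export
request_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  ds_request(user = x$user, fun = x[["function"]], kind = x$kind,
             args = x$args, target = x$target)
}
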