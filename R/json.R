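# Response payload and canonical JSON ---------------------------------------

#' Finalize a session into the response payload
#'
#' Serializes the recorded responses under the response-JSON contract:
#' single-select and input answers map to scalars; multi-select answers map
#' to arrays preserving the document order of the option declarations; a
#' recorded string is typed as a JSON number iff it is an optional minus
#' sign followed by digits with no leading zero (plus plain `"0"`), so
#' answer codes like `"007"` survive as strings. Skipped questions do not
#' appear. The registered completion hook, if any, is invoked with the
#' payload — this mirrors the callback contract by which studies receive
#' results.
#'
#' @param state A finished `quest_session`.
#' @return A `quest_payload`: named list ordered by byte-sorted question id,
#'   with scalar or list values. Render it with [qst_response_json()].
#' @export
qst_finalize <- function(state) {
  stopifnot(inherits(state, "quest_session"))
  if (!state$finished) {
    qst_abort("session has not reached END", "quest_session_not_finished")
  }
  payload <- list()
  for (q in state$module$questions) {
    if (!(q$id %in% names(state$responses))) next
    raw <- state$responses[[q$id]]
    kind <- if (length(q$options) > 0L) q$options[[1]]$kind else "input"
    if (kind == "checkbox") {
      values <- vapply(q$options, `[[`, character(1), "value")
      ordered <- values[values %in% raw] # option declaration order
      payload[[q$id]] <- lapply(ordered, qst_json_scalar)
    } else {
      payload[[q$id]] <- qst_json_scalar(raw)
    }
  }
  if (length(payload) > 0L) {
    payload <- payload[sort(names(payload), method = "radix")]
  }
  payload <- structure(payload, class = "quest_payload")
  if (!is.null(state$on_complete)) {
    state$on_complete(payload)
  }
  payload
}

# JSON typing rule for a recorded scalar.
qst_json_scalar <- function(v) {
  if (is.numeric(v)) return(v)
  s <- as.character(v)
  if (grepl("^-?(0|[1-9][0-9]*)$", s)) as.numeric(s) else s
}

#' Canonical JSON serialization of a response payload
#'
#' Byte-identical for identical payloads: keys byte-sorted, compact
#' separators, UTF-8, numbers unquoted, multi-select answers as arrays
#' (including singletons).
#'
#' @param payload A `quest_payload` (or any named list shaped like one).
#' @return A single JSON string.
#' @examples
#' # qst_response_json(qst_finalize(state))
#' @export
qst_response_json <- function(payload) {
  payload <- unclass(payload)
  if (length(payload) == 0L) return("{}")
  payload <- payload[sort(names(payload), method = "radix")]
  boxed <- lapply(payload, function(v) {
    if (is.list(v)) lapply(v, jsonlite::unbox) else jsonlite::unbox(v)
  })
  as.character(jsonlite::toJSON(boxed, digits = NA, auto_unbox = FALSE))
}

#' @export
print.quest_payload <- function(x, ...) {
  cat(qst_response_json(x), "\n")
  invisible(x)
}

#' @export
format.quest_payload <- function(x, ...) qst_response_json(x)
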