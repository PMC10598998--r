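# Session persistence --------------------------------------------------------
#
# Sessions serialize to a small JSON document so a participant can stop and
# resume (the markup's deployment setting assumes intermittent
# connectivity). The document records a hash of the module's canonical
# markup; loading against a different module is refused rather than silently
# misinterpreting recorded values.

#' Save a session to an opaque JSON document
#'
#' @param state A `quest_session` (running or finished).
#' @param path Optional file path; when given the document is written there
#'   (UTF-8) and returned invisibly.
#' @return The session document as a JSON string.
#' @seealso [qst_load_session()]
#' @export
qst_save_session <- function(state, path = NULL) {
  stopifnot(inherits(state, "quest_session"))
  responses <- lapply(state$responses, function(v) {
    list(multi = jsonlite::unbox(length(v) != 1L || is.list(v)),
         value = lapply(as.list(v), jsonlite::unbox))
  })
  doc <- list(
    format = jsonlite::unbox("quest-session"),
    version = jsonlite::unbox(1L),
    module_hash = jsonlite::unbox(rlang::hash(qst_serialize(state$module))),
    current_id = jsonlite::unbox(state$current_id),
    finished = jsonlite::unbox(state$finished),
    steps = jsonlite::unbox(state$steps),
    step_cap = jsonlite::unbox(state$step_cap),
    allow_skip = jsonlite::unbox(state$allow_skip),
    stack = as.list(state$stack),
    trail = as.list(state$trail),
    responses = responses,
    prefill = lapply(state$prefill, jsonlite::unbox)
  )
  json <- as.character(jsonlite::toJSON(doc, digits = NA, auto_unbox = FALSE))
  if (!is.null(path)) {
    writeLines(json, path, useBytes = TRUE)
    return(invisible(json))
  }
  json
}

#' Restore a session from a saved document
#'
#' `qst_load_session(qst_save_session(s), module)` reproduces `s` exactly:
#' same current question, stack order, responses and step count, so the
#' continuation is indistinguishable from an uninterrupted session.
#'
#' @param document A session document string (or path to one).
#' @param module The `quest_module` the session was running. Its canonical
#'   markup must hash to the value stored in the document; a mismatch (an
#'   edited module) raises a version-mismatch error.
#' @param on_complete Optional completion hook to re-register (functions are
#'   not serialized).
#' @return A `quest_session`.
#' @export
qst_load_session <- function(document, module, on_complete = NULL) {
  stopifnot(inherits(module, "quest_module"))
  if (length(document) == 1L && !grepl("^\\s*\\{", document) &&
      file.exists(document)) {
    document <- paste(readLines(document, encoding = "UTF-8", warn = FALSE),
                      collapse = "\n")
  }
  doc <- jsonlite::fromJSON(document, simplifyVector = FALSE)
  if (!identical(doc$format, "quest-session")) {
    qst_abort("not a quest session document", "quest_version_mismatch")
  }
  if (!identical(doc$module_hash, rlang::hash(qst_serialize(module)))) {
    qst_abort("session was saved against a different module revision",
              "quest_version_mismatch")
  }
  responses <- lapply(doc$responses, function(r) {
    vals <- unlist(r$value, use.names = FALSE)
    if (isTRUE(r$multi)) {
      as.character(vals)
    } else if (is.numeric(vals)) {
      vals
    } else {
      as.character(vals)
    }
  })
  structure(
    list(
      module = module,
      step_cap = as.integer(doc$step_cap),
      allow_skip = isTRUE(doc$allow_skip),
      prefill = doc$prefill,
      current_id = doc$current_id,
      stack = as.character(unlist(doc$stack, use.names = FALSE)),
      responses = responses,
      finished = isTRUE(doc$finished),
      steps = as.integer(doc$steps),
      trail = as.character(unlist(doc$trail, use.names = FALSE)),
      on_complete = on_complete
    ),
    class = "quest_session"
  )
}
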