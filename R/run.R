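# Scripted (non-interactive) session replay ---------------------------------

#' Run a full session from an answer script
#'
#' Replays a session non-interactively: at each question the script's value
#' for that question id is submitted; informational questions continue
#' automatically; questions absent from the script are skipped (via their
#' `#NR` routing, or plainly when `config` allows skipping).
#'
#' @param module A valid `quest_module`, or a path to a markup file, or raw
#'   markup text containing a newline.
#' @param answers Named list/vector mapping question id to answer, or a path
#'   to a JSON file with that shape. Values are scalars, or vectors/lists
#'   for multi-select questions.
#' @param prefill Named list of prefill values (or JSON file path).
#' @param config A [qst_config()].
#' @param on_complete Optional completion hook passed to the session.
#' @return The finalized `quest_payload`. The final session state is
#'   attached as attribute `"session"` (its `$trail` records the visited
#'   question ids in order).
#' @examples
#' m <- qst_parse("[Q1] Feeling fine?\n(1) Yes -> END\n(0) No\n\n[END] Bye.")
#' p <- qst_run(m, list(Q1 = "1"))
#' qst_response_json(p)
#' @export
qst_run <- function(module, answers = list(), prefill = list(),
                    config = qst_config(), on_complete = NULL) {
  module <- qst_as_module(module)
  answers <- qst_as_mapping(answers)
  prefill <- qst_as_mapping(prefill)
  state <- qst_session(module, prefill = prefill, config = config,
                       on_complete = on_complete)
  while (!state$finished) {
    q <- qst_question(module, state$current_id)
    informational <- length(q$options) == 0L && length(q$inputs) == 0L
    if (informational) {
      state <- qst_submit(state, NULL)
    } else if (q$id %in% names(answers)) {
      state <- qst_submit(state, answers[[q$id]])
    } else {
      state <- qst_skip(state)
    }
  }
  payload <- qst_finalize(state)
  attr(payload, "session") <- state
  payload
}

qst_as_module <- function(module) {
  if (inherits(module, "quest_module")) return(module)
  if (is.character(module) && length(module) == 1L &&
      !grepl("\n", module, fixed = TRUE) && file.exists(module)) {
    return(qst_read(module))
  }
  qst_parse(module)
}

qst_as_mapping <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    x <- jsonlite::fromJSON(x, simplifyVector = TRUE)
  }
  as.list(x)
}

#' Simulate an answer script for a module
#'
#' Produces a script interoperable with [qst_run()] by walking a live
#' session under a fixed answering policy: `"first_option"` always selects
#' the first declared option (or the lower bound / a fixed token for input
#' fields), `"random"` samples uniformly (including random checkbox
#' subsets), and `"skip_all"` answers nothing anywhere. Used as the
#' workhorse of the property suite: under every policy a valid acyclic
#' module must terminate at END within the step bound.
#'
#' @param module A valid `quest_module`.
#' @param policy One of `"first_option"`, `"random"`, `"skip_all"`.
#' @param seed Integer seed making the `"random"` policy reproducible.
#' @return List with `answers` (the script, in session encounter order),
#'   `payload` (the finalized `quest_payload`) and `trail` (visited ids).
#' @export
qst_simulate_answers <- function(module,
                                 policy = c("first_option", "random",
                                            "skip_all"),
                                 seed = 0L) {
  policy <- match.arg(policy)
  module <- qst_as_module(module)
  qst_with_seed(seed, {
    state <- qst_session(module, config = qst_config(allow_skip = TRUE))
    answers <- list()
    while (!state$finished) {
      q <- qst_question(module, state$current_id)
      a <- qst_policy_answer(q, policy)
      if (is.null(a) && (length(q$options) > 0L || length(q$inputs) > 0L)) {
        state <- qst_skip(state)
      } else {
        if (!is.null(a)) answers[[q$id]] <- a
        state <- qst_submit(state, a)
      }
    }
    list(answers = answers, payload = qst_finalize(state),
         trail = state$trail)
  })
}

qst_policy_answer <- function(q, policy) {
  if (policy == "skip_all") return(NULL)
  values <- vapply(q$options, `[[`, character(1), "value")
  kind <- if (length(q$options) > 0L) q$options[[1]]$kind else NULL
  if (identical(kind, "radio")) {
    return(if (policy == "first_option") values[1] else sample(values, 1L))
  }
  if (identical(kind, "checkbox")) {
    if (policy == "first_option") return(values[1])
    k <- sample.int(length(values), 1L)
    return(sample(values, k))
  }
  if (length(q$inputs) == 0L) return(NULL)
  f <- q$inputs[[1]]
  switch(f$kind,
    numeric = {
      lo <- f$min %||% 0
      hi <- f$max %||% (lo + 100)
      if (policy == "first_option") lo else round(stats::runif(1, lo, hi), 1)
    },
    date = "2021-06-15",
    tel = "301-555-0142",
    ssn = "078-05-1120",
    if (policy == "first_option") "response" else
      paste0("response_", sample.int(1000L, 1L))
  )
}

# Run code under a temporary RNG state.
qst_with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
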