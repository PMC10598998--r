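# HTML renderer ---------------------------------------------------------------
#
# Questions map onto standard HTML form controls: radio options to
# <input type="radio"> sharing the question id as name, checkbox options to
# <input type="checkbox">, input fields to text/number/date/tel inputs (the
# numeric control carries min/max attributes; SSN becomes a
# pattern-constrained text input). Output is static — all questions are
# present, one <section> per question — and navigation is left to the
# embedding application; the session engine is the authoritative navigator.
# Styling comes only from an optional external stylesheet so the rendered
# form inherits the look of whatever application embeds it.

# Escape for HTML text content/attributes, letting an allowlisted inline
# subset (b, i, u, br) through.
qst_html_escape <- function(text, allow_inline = TRUE) {
  out <- gsub("&", "&amp;", text, fixed = TRUE)
  out <- gsub("<", "&lt;", out, fixed = TRUE)
  out <- gsub(">", "&gt;", out, fixed = TRUE)
  out <- gsub('"', "&quot;", out, fixed = TRUE)
  if (allow_inline) {
    out <- gsub("&lt;(/?)(b|i|u)&gt;", "<\\1\\2>", out)
    out <- gsub("&lt;br\\s*/?&gt;", "<br/>", out)
  }
  out
}

qst_attr_escape <- function(text) qst_html_escape(text, allow_inline = FALSE)

#' Render one question as an HTML fragment
#'
#' @param question A `quest_question`.
#' @param responses,prefill Session context used to resolve piped `{KEY}`
#'   placeholders in the question text (see [qst_resolve_piping()]).
#' @return A `<section>` fragment string, id-ed by the question id.
#' @examples
#' m <- qst_parse("[TEMP] Your temperature?\n|__|__| min=90 max=120\n\n[END] Bye")
#' cat(qst_render_question(qst_question(m, "TEMP")))
#' @export
qst_render_question <- function(question, responses = list(),
                                prefill = list()) {
  stopifnot(inherits(question, "quest_question"))
  if (length(question$options) > 0L && length(question$inputs) > 0L) {
    qst_abort(
      sprintf("[%s] mixes options and input fields and cannot be rendered",
              question$id),
      "quest_render_error"
    )
  }
  qid <- qst_attr_escape(question$id)
  text <- qst_html_escape(
    qst_resolve_piping(question$text, responses, prefill)
  )
  body <- character(0)

  for (k in seq_along(question$options)) {
    o <- question$options[[k]]
    type <- if (o$kind == "radio") "radio" else "checkbox"
    ctl_id <- sprintf("%s-%d", qid, k)
    body <- c(body, sprintf(
      '<div class="quest-option"><input type="%s" id="%s" name="%s" value="%s"/><label for="%s">%s</label></div>',
      type, ctl_id, qid, qst_attr_escape(o$value), ctl_id,
      qst_html_escape(o$label)
    ))
  }

  for (k in seq_along(question$inputs)) {
    f <- question$inputs[[k]]
    ctl_id <- sprintf("%s-in%d", qid, k)
    attrs <- switch(f$kind,
      numeric = {
        a <- 'type="number"'
        if (!is.null(f$min)) {
          a <- paste0(a, sprintf(' min="%s"', format(f$min, scientific = FALSE)))
        }
        if (!is.null(f$max)) {
          a <- paste0(a, sprintf(' max="%s"', format(f$max, scientific = FALSE)))
        }
        a
      },
      date = 'type="date"',
      tel = 'type="tel" pattern="[0-9]{3}-[0-9]{3}-[0-9]{4}"',
      ssn = 'type="text" pattern="[0-9]{3}-[0-9]{2}-[0-9]{4}"',
      'type="text"'
    )
    body <- c(body, sprintf(
      '<div class="quest-input"><input %s id="%s" name="%s"/></div>',
      attrs, ctl_id, qid
    ))
  }

  if (length(body) == 0L) {
    body <- sprintf(
      '<button type="button" class="quest-continue" name="%s">Continue</button>',
      qid
    )
  }

  paste0(
    sprintf('<section class="quest-question" id="%s">', qid),
    sprintf('<p class="quest-text">%s</p>', text),
    paste(body, collapse = ""),
    "</section>"
  )
}

#' Render a full module as an HTML document
#'
#' @param module A `quest_module` validating with zero errors.
#' @param stylesheet_ref Optional URL or path; when given, exactly one
#'   `<link rel="stylesheet">` referencing it is emitted. When absent no
#'   styling is included at all, so the embedding application's styles
#'   apply.
#' @param prefill Prefill values for text piping.
#' @return A complete HTML5 document string containing one section per
#'   question, in document order.
#' @export
qst_render_module <- function(module, stylesheet_ref = NULL,
                              prefill = list()) {
  stopifnot(inherits(module, "quest_module"))
  diag <- qst_validate(module)
  if (any(diag$severity == "error")) {
    qst_abort("module has validation errors; fix them before rendering",
              "quest_invalid_module", diagnostics = diag)
  }
  head <- c(
    "<!DOCTYPE html>",
    '<html lang="en">',
    "<head>",
    '<meta charset="utf-8"/>',
    sprintf("<title>%s</title>", qst_html_escape(module$source,
                                                 allow_inline = FALSE))
  )
  if (!is.null(stylesheet_ref)) {
    head <- c(head, sprintf('<link rel="stylesheet" href="%s"/>',
                            qst_attr_escape(stylesheet_ref)))
  }
  sections <- vapply(
    module$questions,
    function(q) qst_render_question(q, prefill = prefill),
    character(1)
  )
  paste(
    c(head, "</head>", "<body>", sections, "</body>", "</html>"),
    collapse = "\n"
  )
}
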