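# Quest markup parser --------------------------------------------------------
#
# Line-oriented grammar. A question block starts at every line whose first
# non-blank token is [ID] with ID a valid question id; everything up to the
# next such line belongs to the block. Within a block:
#   (v) label [-> TARGET]   radio option
#   [v] label [-> TARGET]   checkbox option (v is never a valid question id,
#                           otherwise the line would have started a block)
#   |__|  |__|__|  |date|  |tel|  |SSN|     input fields, one per line;
#                           |__|__| accepts min=<n> max=<n> annotations
#   < -> ID>  <#NR -> ID>  <displayif=expr>  logic directives
# Any other line continues the question text.

QST_HEADER_RE <- "^\\s*\\[([^]\\s]+)\\]\\s*(.*)$"

#' Parse Quest markup into a questionnaire module
#'
#' Converts plain-text Quest markup into a typed `quest_module`: an ordered
#' collection of question blocks, each carrying its display text, response
#' options or input fields, and skip-logic directives (option arrows,
#' default-next, no-response routing, displayif conditions).
#'
#' @param text Markup as a single string or a character vector of lines
#'   (UTF-8; CRLF is normalized to LF).
#' @param source_name Label used in diagnostics, conventionally the file name.
#' @return A `quest_module`: list with `questions` (ordered list of
#'   `quest_question`), `index` (named integer vector, id to position) and
#'   `source`.
#' @seealso [qst_read()] to parse a file, [qst_serialize()] for the inverse,
#'   [qst_validate()] for static checks.
#' @examples
#' m <- qst_parse("
#' [Q1] Do you like questionnaires?
#' (1) Yes -> END
#' (0) No
#'
#' [END] Thank you.
#' ")
#' m
#' @export
qst_parse <- function(text, source_name = "<text>") {
  stopifnot(is.character(text))
  text <- enc2utf8(paste(text, collapse = "\n"))
  text <- gsub("\r\n?", "\n", text)
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (length(lines) == 0L) {
    lines <- character(0)
  }

  # split into blocks at header lines
  header_id <- rep(NA_character_, length(lines))
  m <- regmatches(lines, regexec(QST_HEADER_RE, lines))
  for (i in seq_along(lines)) {
    if (length(m[[i]]) == 3L && qst_is_valid_id(m[[i]][2])) {
      header_id[i] <- m[[i]][2]
    }
  }
  headers <- which(!is.na(header_id))

  if (length(headers) == 0L) {
    if (any(grepl("\\S", lines))) {
      qst_abort_parse("text before the first question header",
                      which(grepl("\\S", lines))[1])
    }
    return(qst_new_module(list(), source_name))
  }
  pre <- lines[seq_len(headers[1] - 1L)]
  if (any(grepl("\\S", pre))) {
    qst_abort_parse("text before the first question header",
                    which(grepl("\\S", pre))[1])
  }

  bounds <- c(headers, length(lines) + 1L)
  questions <- vector("list", length(headers))
  seen <- character(0)
  for (k in seq_along(headers)) {
    at <- headers[k]
    id <- header_id[at]
    if (id %in% seen) {
      qst_abort_parse(sprintf("duplicate question id [%s]", id), at)
    }
    seen <- c(seen, id)
    body <- if (bounds[k + 1L] - 1L >= at + 1L) {
      (at + 1L):(bounds[k + 1L] - 1L)
    } else {
      integer(0)
    }
    questions[[k]] <- qst_parse_block(
      id = id,
      head_text = m[[at]][3],
      body_lines = lines[body],
      body_line_nos = body,
      header_line = at,
      position = k - 1L
    )
  }
  qst_new_module(questions, source_name)
}

#' Read and parse a Quest markup file
#'
#' @param path Path to a UTF-8 markup file (extension-agnostic).
#' @inherit qst_parse return
#' @export
qst_read <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  qst_parse(lines, source_name = basename(path))
}

qst_new_module <- function(questions, source_name) {
  ids <- vapply(questions, `[[`, character(1), "id")
  index <- seq_along(ids) - 1L
  names(index) <- ids
  structure(
    list(questions = questions, index = index, source = source_name),
    class = "quest_module"
  )
}

# Parse one block into a quest_question.
qst_parse_block <- function(id, head_text, body_lines, body_line_nos,
                            header_line, position) {
  q <- list(
    id = id,
    text = trimws(head_text),
    options = list(),
    inputs = list(),
    default_next = NULL,
    nr_target = NULL,
    displayif = NULL,
    position = position,
    source_line = header_line
  )
  text_parts <- if (nzchar(q$text)) q$text else character(0)

  for (j in seq_along(body_lines)) {
    line <- body_lines[j]
    ln <- body_line_nos[j]
    stripped <- trimws(line)
    if (!nzchar(stripped)) next

    first <- substr(stripped, 1L, 1L)
    if (first %in% c("(", "[")) {
      q$options[[length(q$options) + 1L]] <- qst_parse_option(line, line_no = ln)
    } else if (first == "|") {
      q$inputs[[length(q$inputs) + 1L]] <- qst_parse_input(line, line_no = ln)
    } else if (grepl("^(<[^<]*>\\s*)+$", stripped)) {
      # note: the fragment regex must tolerate the '>' inside '->'
      frags <- regmatches(stripped, gregexpr("<[^<]*>", stripped))[[1]]
      for (frag in frags) {
        d <- qst_parse_directive(frag, line_no = ln)
        if (!is.null(q[[d$field]])) {
          qst_abort_parse(
            sprintf("duplicate %s directive in block [%s]",
                    sub("_.*$", "", d$field), id),
            ln
          )
        }
        q[[d$field]] <- d$value
        q[[paste0(d$field, "_line")]] <- ln
      }
    } else {
      text_parts <- c(text_parts, stripped)
    }
  }

  q$text <- paste(text_parts, collapse = " ")

  if (length(q$options) > 0L && length(q$inputs) > 0L) {
    qst_abort_parse(
      sprintf("block [%s] mixes response options and input fields", id),
      header_line
    )
  }
  kinds <- unique(vapply(q$options, `[[`, character(1), "kind"))
  if (length(kinds) > 1L) {
    qst_abort_parse(
      sprintf("block [%s] mixes radio and checkbox options", id),
      header_line
    )
  }
  structure(q, class = "quest_question")
}

#' Parse a single response-option line
#'
#' `(value) label` is a single-select (radio) option; `[value] label` is a
#' multi-select (checkbox) option. An optional trailing arrow
#' `-> TARGET_ID` attaches skip logic: selecting the option routes the
#' session to `TARGET_ID`. Option values may not be valid question ids —
#' that restriction is what keeps `[...]` option lines distinguishable from
#' question headers.
#'
#' @param line The option line.
#' @param line_no Source line number carried into errors and diagnostics.
#' @return A `quest_option`: list with `kind` ("radio" or "checkbox"),
#'   `value`, `label`, `jump_target` (or `NULL`) and `line`.
#' @examples
#' qst_parse_option("(1) Yes -> DECON2")
#' qst_parse_option("[13] runny nose")
#' @export
qst_parse_option <- function(line, line_no = NA_integer_) {
  stripped <- trimws(line)
  mm <- regexec("^\\(([^)]*)\\)\\s*(.*)$", stripped)
  kind <- "radio"
  parts <- regmatches(stripped, mm)[[1]]
  if (length(parts) == 0L) {
    parts <- regmatches(stripped, regexec("^\\[([^]]*)\\]\\s*(.*)$", stripped))[[1]]
    kind <- "checkbox"
  }
  if (length(parts) != 3L) {
    qst_abort_parse(sprintf("malformed response option '%s'", stripped), line_no)
  }
  value <- trimws(parts[2])
  rest <- parts[3]
  if (!nzchar(value)) {
    qst_abort_parse("empty response-option value", line_no)
  }
  if (qst_is_valid_id(value)) {
    # [value] with a valid id never reaches here (it is a block header);
    # (value) with a valid id is ambiguous markup and rejected.
    qst_abort_parse(
      sprintf("option value '%s' is a valid question id; values may not be",
              value),
      line_no
    )
  }
  jump <- NULL
  am <- regmatches(rest, regexec("^(.*?)\\s*->\\s*(\\S+)\\s*$", rest))[[1]]
  if (length(am) == 3L) {
    if (!qst_is_valid_id(am[3])) {
      qst_abort_parse(
        sprintf("arrow target '%s' is not a valid question id", am[3]), line_no
      )
    }
    jump <- am[3]
    rest <- am[2]
  }
  structure(
    list(kind = kind, value = value, label = trimws(rest),
         jump_target = jump, line = line_no),
    class = "quest_option"
  )
}

#' Parse a logic directive
#'
#' Directives are angle-bracketed fragments, whitespace-tolerant inside the
#' brackets: `< -> ID>` declares the default next question (always pushed
#' onto the question stack when the question is answered), `<#NR -> ID>`
#' declares no-response routing, and `<displayif=expr>` attaches a display
#' condition.
#'
#' @param fragment One `<...>` fragment.
#' @param line_no Source line number for errors.
#' @return List with `field` (one of `"default_next"`, `"nr_target"`,
#'   `"displayif"`) and `value`.
#' @examples
#' qst_parse_directive("< -> END>")
#' qst_parse_directive("<#NR -> TEMP>")
#' @export
qst_parse_directive <- function(fragment, line_no = NA_integer_) {
  inner <- trimws(sub("^\\s*<", "", sub(">\\s*$", "", trimws(fragment))))
  target_of <- function(src, what) {
    id <- trimws(src)
    if (!qst_is_valid_id(id)) {
      qst_abort_parse(
        sprintf("%s target '%s' is not a valid question id", what, id), line_no
      )
    }
    id
  }
  if (grepl("^#NR\\s*->", inner)) {
    return(list(field = "nr_target",
                value = target_of(sub("^#NR\\s*->", "", inner), "#NR")))
  }
  if (grepl("^->", inner)) {
    return(list(field = "default_next",
                value = target_of(sub("^->", "", inner), "default-next")))
  }
  if (grepl("^displayif\\s*=", inner)) {
    src <- sub("^displayif\\s*=\\s*", "", inner)
    return(list(field = "displayif",
                value = qst_parse_displayif(src, line = line_no)))
  }
  qst_abort_parse(sprintf("unknown directive '<%s>'", inner), line_no)
}

#' Parse an input-field line
#'
#' Pipe tokens declare free-response HTML inputs: `|__|` text, `|__|__|`
#' numeric, `|date|`, `|tel|`, `|SSN|`. The numeric token accepts inclusive
#' bounds as `min=<n> max=<n>` annotations after the token.
#'
#' @param line The input-field line.
#' @param line_no Source line number for errors.
#' @return A `quest_input`: list with `kind` (one of "text", "numeric",
#'   "date", "tel", "ssn"), `min`, `max` and `line`.
#' @examples
#' qst_parse_input("|__|__| min=90 max=120")
#' qst_parse_input("|date|")
#' @export
qst_parse_input <- function(line, line_no = NA_integer_) {
  stripped <- trimws(line)
  tokens <- c(
    "|__|__|" = "numeric", "|__|" = "text",
    "|date|" = "date", "|tel|" = "tel", "|SSN|" = "ssn"
  )
  kind <- NULL
  rest <- NULL
  for (tok in names(tokens)) {
    if (startsWith(stripped, tok)) {
      kind <- tokens[[tok]]
      rest <- trimws(substr(stripped, nchar(tok) + 1L, nchar(stripped)))
      break
    }
  }
  if (is.null(kind)) {
    qst_abort_parse(sprintf("unknown input token '%s'", stripped), line_no)
  }
  min <- NULL
  max <- NULL
  if (nzchar(rest)) {
    if (kind != "numeric") {
      qst_abort_parse(
        sprintf("annotations are only allowed on |__|__|, got '%s'", rest),
        line_no
      )
    }
    words <- strsplit(rest, "\\s+")[[1]]
    for (w in words) {
      wm <- regmatches(w, regexec("^(min|max)=(-?[0-9]+(\\.[0-9]+)?)$", w))[[1]]
      if (length(wm) == 0L) {
        qst_abort_parse(sprintf("malformed bound annotation '%s'", w), line_no)
      }
      if (wm[2] == "min") min <- as.numeric(wm[3]) else max <- as.numeric(wm[3])
    }
  }
  structure(
    list(kind = kind, min = min, max = max, line = line_no),
    class = "quest_input"
  )
}

# Accessors -------------------------------------------------------------------

#' Look up a question by id
#'
#' @param module A `quest_module`.
#' @param id Question id.
#' @return The `quest_question`, or `NULL` when absent.
#' @export
qst_question <- function(module, id) {
  pos <- module$index[id]
  if (is.na(pos)) return(NULL)
  module$questions[[pos + 1L]]
}

#' Question ids of a module, in document order
#' @param module A `quest_module`.
#' @return Character vector of ids.
#' @export
qst_ids <- function(module) {
  vapply(module$questions, `[[`, character(1), "id")
}

# id of the question at the next document position, or NA at the end
qst_successor <- function(module, id) {
  pos <- module$index[[id]]
  if (pos + 2L > length(module$questions)) {
    return(NA_character_)
  }
  module$questions[[pos + 2L]]$id
}

#' @export
print.quest_module <- function(x, ...) {
  cat(sprintf("<quest_module> %s: %d question(s)\n", x$source,
              length(x$questions)))
  for (q in x$questions) {
    spec <- if (length(q$options) > 0L) {
      sprintf("%d %s option(s)", length(q$options), q$options[[1]]$kind)
    } else if (length(q$inputs) > 0L) {
      paste(vapply(q$inputs, `[[`, character(1), "kind"), collapse = "+")
    } else {
      "text only"
    }
    cat(sprintf("  [%s] %s\n", q$id, spec))
  }
  invisible(x)
}

#' @export
print.quest_question <- function(x, ...) {
  cat(sprintf("<quest_question> [%s] %s\n", x$id, x$text))
  invisible(x)
}

#' Tabulate a module's questions
#'
#' One row per question block, in document order — a convenient overview and
#' the basis of a codebook (id, response kind, permissible values).
#'
#' @param module A `quest_module`.
#' @return A tibble with columns `id`, `position`, `kind` (radio, checkbox,
#'   input kind, or "none"), `n_options`, `values` (comma-joined permissible
#'   values), `default_next`, `nr_target`, `has_displayif`, `text`.
#' @export
qst_questions_tbl <- function(module) {
  if (length(module$questions) == 0L) {
    return(tibble::tibble(
      id = character(0), position = integer(0), kind = character(0),
      n_options = integer(0), values = character(0),
      default_next = character(0), nr_target = character(0),
      has_displayif = logical(0), text = character(0)
    ))
  }
  rows <- lapply(module$questions, function(q) {
    kind <- if (length(q$options) > 0L) {
      q$options[[1]]$kind
    } else if (length(q$inputs) > 0L) {
      paste(vapply(q$inputs, `[[`, character(1), "kind"), collapse = "+")
    } else {
      "none"
    }
    tibble::tibble(
      id = q$id,
      position = q$position,
      kind = kind,
      n_options = length(q$options),
      values = paste(vapply(q$options, `[[`, character(1), "value"),
                     collapse = ","),
      default_next = q$default_next %||% NA_character_,
      nr_target = q$nr_target %||% NA_character_,
      has_displayif = !is.null(q$displayif),
      text = q$text
    )
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
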