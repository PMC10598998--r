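# Static validation ----------------------------------------------------------

#' Build the jump graph of a module
#'
#' Nodes are question ids; directed edges are every option arrow, every
#' default-next, every no-response target, plus a document-order fallthrough
#' edge from each non-END question to its successor. The fallthrough edges
#' make graph reachability an over-approximation of dynamic reachability:
#' any question a session can visit is reachable in this graph, so
#' "unreachable" findings are conservative.
#'
#' @param module A `quest_module`.
#' @return A tibble of edges with columns `from`, `to`, `type`
#'   (`"option"`, `"default"`, `"nr"` or `"fallthrough"`) and `line`.
#' @export
qst_jump_graph <- function(module) {
  from <- character(0); to <- character(0)
  type <- character(0); line <- integer(0)
  add <- function(f, t, ty, ln) {
    from <<- c(from, f); to <<- c(to, t)
    type <<- c(type, ty); line <<- c(line, as.integer(ln %||% NA_integer_))
  }
  for (q in module$questions) {
    for (o in q$options) {
      if (!is.null(o$jump_target)) add(q$id, o$jump_target, "option", o$line)
    }
    if (!is.null(q$default_next)) {
      add(q$id, q$default_next, "default", q$default_next_line %||% q$source_line)
    }
    if (!is.null(q$nr_target)) {
      add(q$id, q$nr_target, "nr", q$nr_target_line %||% q$source_line)
    }
    succ <- qst_successor(module, q$id)
    if (q$id != "END" && !is.na(succ)) {
      add(q$id, succ, "fallthrough", q$source_line)
    }
  }
  tibble::tibble(from = from, to = to, type = type, line = line)
}

qst_igraph <- function(module, edges = qst_jump_graph(module)) {
  ids <- qst_ids(module)
  keep <- edges$to %in% ids & edges$from %in% ids
  igraph::graph_from_data_frame(
    edges[keep, c("from", "to"), drop = FALSE],
    directed = TRUE,
    vertices = data.frame(name = ids)
  )
}

qst_diag <- function(severity, code, line, message) {
  tibble::tibble(
    severity = severity, code = code,
    line = as.integer(line), message = message
  )
}

#' Statically validate a parsed module
#'
#' Runs reference-integrity and structural checks and returns findings as a
#' diagnostics table; it never raises. Errors are findings that would crash
#' a session (dangling skip targets, duplicate option values, inverted
#' numeric bounds, a missing END question); warnings flag content that is
#' merely at risk of being dead or non-terminating (questions unreachable
#' from the first question in the jump graph, directed cycles among jump
#' edges).
#'
#' @param module A `quest_module`.
#' @return A tibble of diagnostics with columns `severity` ("error" or
#'   "warning"), `code`, `line` and `message`; zero rows when the module is
#'   clean.
#' @examples
#' m <- qst_parse("[A] Go\n(1) on -> NOWHERE\n\n[END] bye")
#' qst_validate(m)
#' @export
qst_validate <- function(module) {
  out <- list()
  emit <- function(...) out[[length(out) + 1L]] <<- qst_diag(...)
  ids <- qst_ids(module)

  # reference integrity over all jump edges
  edges <- qst_jump_graph(module)
  dangling <- edges[edges$type != "fallthrough" & !(edges$to %in% ids), ,
                    drop = FALSE]
  for (i in seq_len(nrow(dangling))) {
    emit("error", "dangling_target", dangling$line[i],
         sprintf("[%s]: %s target '%s' is not defined in the module",
                 dangling$from[i], dangling$type[i], dangling$to[i]))
  }

  for (q in module$questions) {
    vals <- vapply(q$options, `[[`, character(1), "value")
    dup <- unique(vals[duplicated(vals)])
    for (v in dup) {
      emit("error", "duplicate_value", q$source_line,
           sprintf("[%s]: duplicate option value '%s'", q$id, v))
    }
    for (f in q$inputs) {
      if (!is.null(f$min) && !is.null(f$max) && f$min > f$max) {
        emit("error", "bounds_inverted", f$line,
             sprintf("[%s]: numeric min (%s) exceeds max (%s)",
                     q$id, f$min, f$max))
      }
    }
  }

  if (!("END" %in% ids)) {
    emit("error", "no_end", NA_integer_,
         "module has no [END] question")
  }

  if (length(ids) > 0L) {
    g <- qst_igraph(module, edges)
    reachable <- names(igraph::subcomponent(g, ids[1], mode = "out"))
    for (q in module$questions) {
      if (!(q$id %in% reachable)) {
        emit("warning", "unreachable", q$source_line,
             sprintf("[%s] is unreachable from [%s]", q$id, ids[1]))
      }
    }
    if (!igraph::is_dag(g)) {
      comp <- igraph::components(g, mode = "strong")
      cyc <- names(comp$membership)[comp$membership %in%
                                      which(comp$csize > 1L)]
      loops <- igraph::which_loop(g)
      if (any(loops)) {
        cyc <- union(cyc, igraph::as_edgelist(g)[loops, 1])
      }
      emit("warning", "cycle", NA_integer_,
           sprintf("jump edges form a directed cycle involving: %s",
                   paste(sort(cyc), collapse = ", ")))
    }
  }

  if (length(out) == 0L) {
    return(qst_diag(character(0), character(0), integer(0), character(0)))
  }
  do.call(rbind, out)
}

#' Does a module pass validation with zero errors?
#' @param module A `quest_module`.
#' @return `TRUE` when [qst_validate()] reports no error-severity findings.
#' @export
qst_is_valid_module <- function(module) {
  d <- qst_validate(module)
  !any(d$severity == "error")
}
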