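# Seeded random-module generator --------------------------------------------
#
# Powers the property suite: modules are built question-by-question with
# every skip target pointing strictly forward in document order, so the jump
# graph is acyclic by construction and END is always reachable. Within one
# question all push-capable targets (option arrows plus the default-next)
# are distinct, keeping the visit count within the documented step bound.

#' Fixture generation profile
#'
#' Mixing weights and logic densities for [qst_random_module()]. Weights
#' need not sum to one.
#'
#' @param w_radio,w_checkbox,w_text,w_numeric,w_date,w_info Sampling weights
#'   for the question kinds ("info" is an informational block with neither
#'   options nor inputs).
#' @param max_options Upper bound (inclusive, at least 2) on options per
#'   option question.
#' @param arrow_density Probability that an option carries a skip arrow.
#' @param p_default Probability that a checkbox question declares a
#'   default-next directive.
#' @param p_nr Probability that a question declares `#NR` routing.
#' @param p_displayif Probability that a question (other than the first)
#'   carries a displayif condition on an earlier radio question.
#' @return A `quest_fixture_profile` list.
#' @export
qst_fixture_profile <- function(w_radio = 0.35, w_checkbox = 0.25,
                                w_text = 0.1, w_numeric = 0.15,
                                w_date = 0.05, w_info = 0.1,
                                max_options = 4L, arrow_density = 0.35,
                                p_default = 0.6, p_nr = 0.3,
                                p_displayif = 0.15) {
  w <- c(radio = w_radio, checkbox = w_checkbox, text = w_text,
         numeric = w_numeric, date = w_date, info = w_info)
  if (any(w < 0) || sum(w) <= 0) {
    qst_abort("kind weights must be non-negative and not all zero",
              "quest_config_error")
  }
  if (max_options < 2L) {
    qst_abort("max_options must be at least 2", "quest_config_error")
  }
  for (p in c(arrow_density, p_default, p_nr, p_displayif)) {
    if (p < 0 || p > 1) {
      qst_abort("probabilities must lie in [0, 1]", "quest_config_error")
    }
  }
  structure(
    list(weights = w, max_options = as.integer(max_options),
         arrow_density = arrow_density, p_default = p_default,
         p_nr = p_nr, p_displayif = p_displayif),
    class = "quest_fixture_profile"
  )
}

#' Generate a random, valid questionnaire module
#'
#' Emits Quest markup with exactly `n_questions` blocks plus `[END]`. Every
#' generated module parses, round-trips through [qst_serialize()], and
#' passes [qst_validate()] with zero errors and an acyclic jump graph; the
#' same seed always yields byte-identical markup.
#'
#' @param n_questions Number of question blocks before END (at least 1).
#' @param profile A [qst_fixture_profile()].
#' @param seed Integer seed.
#' @return Markup as a single string.
#' @examples
#' cat(qst_random_module(3, seed = 42))
#' @export
qst_random_module <- function(n_questions, profile = qst_fixture_profile(),
                              seed = 0L) {
  if (!is.numeric(n_questions) || length(n_questions) != 1L ||
      n_questions < 1) {
    qst_abort("n_questions must be a single integer >= 1",
              "quest_config_error")
  }
  n <- as.integer(n_questions)
  stopifnot(inherits(profile, "quest_fixture_profile"))

  qst_with_seed(seed, {
    ids <- c(sprintf("Q%d", seq_len(n)), "END")
    radio_values <- vector("list", n) # digit values of earlier radio questions
    blocks <- character(n)

    for (i in seq_len(n)) {
      kind <- sample(names(profile$weights), 1L, prob = profile$weights)
      later <- ids[(i + 1L):(n + 1L)]
      lines <- sprintf("[%s] Question %d: please answer (%s).", ids[i], i, kind)

      pushable <- character(0) # targets already used by this block
      pick_target <- function() {
        avail <- setdiff(later, pushable)
        if (length(avail) == 0L) return(NULL)
        t <- if (length(avail) == 1L) avail else sample(avail, 1L)
        pushable <<- c(pushable, t)
        t
      }

      if (kind %in% c("radio", "checkbox")) {
        k <- sample(2L:profile$max_options, 1L)
        style <- sample(c("digit", "padded", "word"), 1L)
        values <- switch(style,
          digit = as.character(seq_len(k)),
          padded = sprintf("%02d", seq_len(k)),
          word = sprintf("v%d", seq_len(k))
        )
        if (kind == "radio" && style == "digit") {
          radio_values[[i]] <- values
        }
        wrap <- if (kind == "radio") c("(", ")") else c("[", "]")
        for (v in values) {
          line <- sprintf("%s%s%s option %s", wrap[1], v, wrap[2], v)
          if (stats::runif(1) < profile$arrow_density) {
            t <- pick_target()
            if (!is.null(t)) line <- sprintf("%s -> %s", line, t)
          }
          lines <- c(lines, line)
        }
        if (kind == "checkbox" && stats::runif(1) < profile$p_default) {
          t <- pick_target()
          if (!is.null(t)) lines <- c(lines, sprintf("< -> %s>", t))
        }
      } else if (kind == "numeric") {
        lo <- sample(0:50, 1L)
        hi <- lo + sample(10:100, 1L)
        lines <- c(lines, sprintf("|__|__| min=%d max=%d", lo, hi))
      } else if (kind == "text") {
        lines <- c(lines, "|__|")
      } else if (kind == "date") {
        lines <- c(lines, "|date|")
      } # info: no response spec

      if (kind != "info" && stats::runif(1) < profile$p_nr) {
        t <- sample(later, 1L)
        lines <- c(lines, sprintf("<#NR -> %s>", t))
      }

      earlier_radio <- which(!vapply(radio_values[seq_len(i - 1L)], is.null,
                                     logical(1)))
      if (i > 1L && length(earlier_radio) > 0L &&
          stats::runif(1) < profile$p_displayif) {
        j <- if (length(earlier_radio) == 1L) earlier_radio else
          sample(earlier_radio, 1L)
        v <- sample(radio_values[[j]], 1L)
        cond <- if (stats::runif(1) < 0.5) {
          sprintf("equals(%s,%s)", ids[j], v)
        } else {
          sprintf("exists(%s)", ids[j])
        }
        lines <- c(lines, sprintf("<displayif=%s>", cond))
      }

      blocks[i] <- paste(lines, collapse = "\n")
    }
    paste0(paste(c(blocks, "[END] Thank you for your answers."),
                 collapse = "\n\n"), "\n")
  })
}
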