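#' The packaged example module
#'
#' A seven-question symptom-screening module exercising every core markup
#' feature: a radio question whose first option jumps straight to END, a
#' multi-select question whose selected options push follow-up questions
#' onto the stack ahead of a default-next, a Yes/No branch, free-text and
#' bounded numeric inputs. The markup is a synthetic reconstruction of the
#' format's canonical worked example (the follow-up question for the
#' unnamed third symptom is this package's own addition).
#'
#' @param parse Return the parsed `quest_module` (default) or the file path
#'   when `FALSE`.
#' @return A `quest_module`, or the path to the markup file.
#' @examples
#' m <- qst_example_module()
#' qst_questions_tbl(m)
#' @export
qst_example_module <- function(parse = TRUE) {
  path <- system.file("extdata", "symptom_module_synthetic.quest",
                      package = "questr", mustWork = TRUE)
  if (parse) qst_read(path) else path
}
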