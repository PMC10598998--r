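#' Test whether a token is a valid Quest question id
#'
#' A question id starts with a capital letter `A`-`Z`; every following
#' character is a capital letter, digit, underscore or octothorp (`#`).
#' Response option values are required *not* to be valid question ids, which
#' is what makes the line grammar unambiguous: a line-leading `[X]` token is
#' a question header exactly when `X` passes this test, and a checkbox
#' option otherwise.
#'
#' @param token Character vector of candidate tokens.
#' @return Logical vector, `TRUE` where the token is a valid question id.
#'   The function is total: non-character or empty input yields `FALSE`,
#'   never an error.
#' @examples
#' qst_is_valid_id(c("Q", "Q1", "Q#1", "THIS_IS_VALID", "q1", "1A"))
#' @export
qst_is_valid_id <- function(token) {
  if (length(token) == 0L) {
    return(logical(0))
  }
  if (!is.character(token)) {
    token <- as.character(token)
  }
  !is.na(token) & grepl("^[A-Z][A-Z0-9_#]*$", token)
}
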