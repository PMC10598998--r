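test_that("question-id grammar accepts capitals, digits, underscore, hash", {
  valid <- c("Q", "Q1", "Q#1", "THIS_IS_VALID", "END", "A#_9")
  invalid <- c("q1", "1A", "", "_Q", "#Q", "Q-1", "Q 1", "Ωx")
  expect_true(all(qst_is_valid_id(valid)))
  expect_false(any(qst_is_valid_id(invalid)))
  expect_identical(qst_is_valid_id(character(0)), logical(0))
  expect_false(qst_is_valid_id(NA_character_))
})

test_that("modules split into blocks at header lines, in document order", {
  m <- qst_example_module()
  expect_s3_class(m, "quest_module")
  expect_identical(
    qst_ids(m),
    c("QUESTION_1", "QUESTION_2", "DECON1", "DECON2", "ACHE1", "TEMP", "END")
  )
  expect_identical(unname(m$index), 0:6)
  expect_identical(names(m$index), qst_ids(m))

  expect_length(qst_parse("")$questions, 0L)
  expect_length(qst_parse("  \n\n \n")$questions, 0L)

  one <- qst_parse("[END] Thanks.")
  expect_length(one$questions, 1L)
  expect_identical(one$questions[[1]]$id, "END")
})

test_that("parse errors carry line numbers and fire on malformed input", {
  expect_error(qst_parse("hello\n[A] q"), class = "quest_parse_error")
  err <- tryCatch(qst_parse("[A] q\n\n[A] again"), condition = identity)
  expect_s3_class(err, "quest_parse_error")
  expect_identical(err$line, 3L)

  # (value) where value is a valid question id is ambiguous markup
  expect_error(qst_parse("[A] q\n(B) option"), class = "quest_parse_error")
  # arrow to an invalid id
  expect_error(qst_parse("[A] q\n(1) x -> end"), class = "quest_parse_error")
  # mixed options and inputs in one block
  expect_error(qst_parse("[A] q\n(1) x\n|__|"), class = "quest_parse_error")
  # mixed radio and checkbox options
  expect_error(qst_parse("[A] q\n(1) x\n[z] y"), class = "quest_parse_error")
  # duplicate directive
  expect_error(qst_parse("[A] q\n< -> B>\n< -> C>\n\n[B] b\n\n[C] c"),
               class = "quest_parse_error")
})

test_that("response-option lines parse kind, value, label and jump", {
  o <- qst_parse_option("(1) Yes -> DECON2")
  expect_identical(o[c("kind", "value", "label", "jump_target")],
                   list(kind = "radio", value = "1", label = "Yes",
                        jump_target = "DECON2"))
  o <- qst_parse_option("[13] runny nose")
  expect_identical(o$kind, "checkbox")
  expect_identical(o$value, "13")
  expect_identical(o$label, "runny nose")
  expect_null(o$jump_target)
  o <- qst_parse_option("(0) No")
  expect_identical(o$value, "0")
  expect_null(o$jump_target)
  expect_error(qst_parse_option("(Q1) looks like an id"),
               class = "quest_parse_error")
})

test_that("directives parse default-next, #NR and displayif, whitespace-insensitively", {
  expect_identical(qst_parse_directive("< -> END>"),
                   list(field = "default_next", value = "END"))
  expect_identical(qst_parse_directive("<->END>"),
                   list(field = "default_next", value = "END"))
  expect_identical(qst_parse_directive("< -> END >"),
                   list(field = "default_next", value = "END"))
  expect_identical(qst_parse_directive("<#NR -> TEMP>"),
                   list(field = "nr_target", value = "TEMP"))
  expect_identical(qst_parse_directive("<#NR->TEMP>"),
                   list(field = "nr_target", value = "TEMP"))
  expect_error(qst_parse_directive("< -> end>"), class = "quest_parse_error")
  expect_error(qst_parse_directive("<#XX -> A>"), class = "quest_parse_error")

  d <- qst_parse_directive("<displayif=and(equals(Q1,2),exists(TEMP))>")
  expect_identical(d$field, "displayif")
  expect_s3_class(d$value, "quest_displayif")
  expect_identical(d$value$func, "and")
  expect_length(d$value$args, 2L)
  expect_error(qst_parse_directive("<displayif=exists(A,B)>"),
               class = "quest_parse_error") # arity
  expect_error(qst_parse_directive("<displayif=frobnicate(A)>"),
               class = "quest_parse_error")
})

test_that("input-field tokens map to their kinds with numeric bounds", {
  expect_identical(qst_parse_input("|__|")$kind, "text")
  f <- qst_parse_input("|__|__| min=90 max=120")
  expect_identical(f$kind, "numeric")
  expect_identical(f$min, 90)
  expect_identical(f$max, 120)
  expect_identical(qst_parse_input("|__|__|")$kind, "numeric")
  expect_identical(qst_parse_input("|date|")$kind, "date")
  expect_identical(qst_parse_input("|tel|")$kind, "tel")
  expect_identical(qst_parse_input("|SSN|")$kind, "ssn")
  expect_error(qst_parse_input("|radio|"), class = "quest_parse_error")
  expect_error(qst_parse_input("|__| min=1"), class = "quest_parse_error")
})

test_that("serialize/parse is a structural fixed point", {
  for (m in list(qst_example_module(), branchy_module(), qst_parse(""))) {
    expect_module_equal(qst_parse(qst_serialize(m)), m)
  }
  expect_identical(qst_serialize(qst_parse("")), "")
})

test_that("parsing is deterministic", {
  a <- qst_parse(branchy_markup)
  b <- qst_parse(branchy_markup)
  expect_identical(a, b)
  expect_identical(qst_serialize(a), qst_serialize(b))
})

test_that("CRLF input and option-line [v] disambiguation are handled", {
  crlf <- gsub("\n", "\r\n", branchy_markup, fixed = TRUE)
  expect_module_equal(qst_parse(crlf), qst_parse(branchy_markup))
  # a line-leading [token] is a header iff the token is a valid id
  m <- qst_parse("[A] q\n[not_an_id] option label\n\n[END] done")
  expect_identical(qst_ids(m), c("A", "END"))
  expect_identical(qst_question(m, "A")$options[[1]]$value, "not_an_id")
})

test_that("questions tabulate into a codebook-style tibble", {
  tbl <- qst_questions_tbl(qst_example_module())
  expect_s3_class(tbl, "tbl_df")
  expect_identical(nrow(tbl), 7L)
  expect_identical(tbl$kind[tbl$id == "QUESTION_2"], "checkbox")
  expect_identical(tbl$values[tbl$id == "QUESTION_2"], "13,14,15")
  expect_identical(tbl$default_next[tbl$id == "QUESTION_2"], "END")
})
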