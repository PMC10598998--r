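walkthrough <- function() {
  s <- qst_session(qst_example_module())
  s <- qst_submit(s, "2")
  s <- qst_submit(s, c("13", "15"))
  s <- qst_submit(s, "0")
  qst_submit(s, 98)
}

test_that("sessions start at the first displayable question", {
  s <- qst_session(qst_example_module())
  expect_identical(s$current_id, "QUESTION_1")
  expect_length(s$stack, 0L)
  expect_length(s$responses, 0L)

  s <- qst_session(qst_parse("[END] Thanks."))
  expect_true(s$finished)

  # first question hidden by a prefill-driven displayif -> start at second
  m <- qst_parse(paste(
    "[A] only for adults",
    "(1) ok",
    "<displayif=greaterThan(AGE,17)>",
    "",
    "[B] for everyone",
    "(1) ok",
    "",
    "[END] bye", sep = "\n"))
  expect_identical(qst_session(m, prefill = list(AGE = 12))$current_id, "B")
  expect_identical(qst_session(m, prefill = list(AGE = 63))$current_id, "A")

  expect_error(qst_session(qst_parse("[A] q\n(1) x -> GONE\n\n[END] e")),
               class = "quest_invalid_module")
})

test_that("multi-select pushes pop in declaration order ahead of default-next", {
  s <- qst_session(qst_example_module())
  s <- qst_submit(s, "2")
  s <- qst_submit(s, c("13", "15"))
  expect_identical(s$current_id, "DECON1")
  expect_identical(s$stack, c("END", "TEMP"))
  # selection order does not matter
  s2 <- qst_session(qst_example_module())
  s2 <- qst_submit(s2, "2")
  s2 <- qst_submit(s2, c("15", "13"))
  expect_identical(s2$current_id, "DECON1")
  expect_identical(s2$stack, c("END", "TEMP"))
})

test_that("radio jumps transfer directly; otherwise the stack pops", {
  # DECON1 answered Yes -> DECON2 immediately, TEMP stays pending
  s <- qst_session(qst_example_module())
  s <- qst_submit(s, "2")
  s <- qst_submit(s, c("13", "15"))
  s <- qst_submit(s, "1")
  expect_identical(s$current_id, "DECON2")
  expect_identical(s$stack, c("END", "TEMP"))
  s <- qst_submit(s, "saline spray")
  expect_identical(s$current_id, "TEMP")

  # DECON1 answered No -> pop straight to TEMP
  s <- qst_session(qst_example_module())
  s <- qst_submit(s, "2")
  s <- qst_submit(s, c("13", "15"))
  s <- qst_submit(s, "0")
  expect_identical(s$current_id, "TEMP")
  expect_identical(s$trail,
                   c("QUESTION_1", "QUESTION_2", "DECON1", "TEMP"))
})

test_that("empty stack falls through in document order", {
  m <- qst_parse("[A] a\n(1) x\n\n[B] b\n(1) x\n\n[END] bye")
  s <- qst_session(m)
  s <- qst_submit(s, "1")
  expect_identical(s$current_id, "B")
  s <- qst_submit(s, "1")
  expect_true(s$finished)
})

test_that("answer validation enforces the response specification", {
  s <- qst_session(qst_example_module())
  expect_error(qst_submit(s, "7"), class = "quest_answer_error")
  expect_error(qst_submit(s, c("1", "2")), class = "quest_answer_error")
  s <- qst_submit(s, "2")
  expect_error(qst_submit(s, c("13", "99")), class = "quest_answer_error")
  s <- qst_submit(s, "15") # fever only -> TEMP next
  expect_identical(s$current_id, "TEMP")
  expect_error(qst_submit(s, 89), class = "quest_answer_error")
  expect_error(qst_submit(s, 121), class = "quest_answer_error")
  expect_error(qst_submit(s, "warm"), class = "quest_answer_error")
  expect_true(qst_submit(s, 90)$finished)  # closed interval
  expect_true(qst_submit(s, 120)$finished)
  expect_true(qst_submit(s, 98)$finished)

  m <- qst_parse("[D] when\n|date|\n\n[T] tel\n|tel|\n\n[S] ssn\n|SSN|\n\n[END] e")
  s <- qst_session(m)
  expect_error(qst_submit(s, "15/06/2021"), class = "quest_answer_error")
  expect_error(qst_submit(s, "2021-13-40"), class = "quest_answer_error")
  s <- qst_submit(s, "2021-06-15")
  expect_error(qst_submit(s, "5551234"), class = "quest_answer_error")
  s <- qst_submit(s, "301-555-0142")
  expect_error(qst_submit(s, "078051120"), class = "quest_answer_error")
  s <- qst_submit(s, "078-05-1120")
  expect_true(s$finished)
})

test_that("no-response routing and skip policy behave as configured", {
  m <- branchy_module()
  s <- qst_session(m)
  s <- qst_submit(s, NULL) # INTRO is informational
  s <- qst_submit(s, "2")
  expect_identical(s$current_id, "SYMPTOMS")
  s2 <- qst_skip(s) # declared <#NR -> WRAP>
  expect_identical(s2$current_id, "WRAP")
  expect_false("SYMPTOMS" %in% names(s2$responses))

  # required question without #NR: skipping refused unless configured
  s3 <- qst_session(qst_example_module())
  expect_error(qst_skip(s3), class = "quest_skip_not_allowed")
  s4 <- qst_session(qst_example_module(), config = qst_config(allow_skip = TRUE))
  s4 <- qst_skip(s4) # QUESTION_1 -> fallthrough
  expect_identical(s4$current_id, "QUESTION_2")
  s4 <- qst_skip(s4) # empty selection still pushes the default-next END
  expect_true(s4$finished)
  expect_identical(qst_response_json(qst_finalize(s4)), "{}")
})

test_that("displayif evaluation follows the unanswered-is-false contract", {
  di <- function(src) qst_parse_directive(sprintf("<displayif=%s>", src))$value
  expect_true(qst_evaluate_displayif(di("equals(DECON1,1)"),
                                     responses = list(DECON1 = "1")))
  expect_false(qst_evaluate_displayif(di("equals(DECON1,1)"),
                                      responses = list(DECON1 = "0")))
  expect_false(qst_evaluate_displayif(di("equals(DECON1,1)")))
  expect_false(qst_evaluate_displayif(di("notEquals(DECON1,1)")))
  expect_false(qst_evaluate_displayif(di("exists(TEMP)")))
  expect_true(qst_evaluate_displayif(di("exists(AGE)"),
                                     prefill = list(AGE = 63)))
  # frozen expectation: hand evaluation over the walkthrough responses
  expect_true(qst_evaluate_displayif(
    di("and(equals(QUESTION_1,2),greaterThan(TEMP,90))"),
    responses = list(QUESTION_1 = "2", TEMP = 98)
  ))
  # membership semantics for multi-select responses
  expect_true(qst_evaluate_displayif(di("equals(SYM,13)"),
                                     responses = list(SYM = c("13", "15"))))
  expect_false(qst_evaluate_displayif(di("equals(SYM,14)"),
                                      responses = list(SYM = c("13", "15"))))
  expect_error(
    qst_evaluate_displayif(di("greaterThan(A,'x')"),
                           responses = list(A = "hot")),
    class = "quest_expression_error"
  )
})

test_that("displayif-false questions are skipped transparently", {
  m <- branchy_module()
  ans <- list(START = "2", SYMPTOMS = "b", FEV1 = 101, CHECK = "1")
  p <- qst_run(m, ans)
  expect_true("CHECK" %in% attr(p, "session")$trail)
  expect_identical(unclass(p)$CHECK, 1)
  ans$FEV1 <- 99
  p <- qst_run(m, ans)
  expect_false("CHECK" %in% attr(p, "session")$trail)
  expect_false("CHECK" %in% names(p))
})

test_that("text piping substitutes responses, then prefill, else verbatim", {
  expect_identical(
    qst_resolve_piping("You are {AGE} years old", prefill = list(AGE = 63)),
    "You are 63 years old"
  )
  expect_identical(qst_resolve_piping("no placeholders"), "no placeholders")
  expect_identical(qst_resolve_piping("{MISSING}"), "{MISSING}")
  s <- walkthrough()
  expect_identical(qst_resolve_piping("{TEMP}", s$responses), "98")
  expect_identical(
    qst_resolve_piping("{X} and {X}", responses = list(X = "a"),
                       prefill = list(X = "b")),
    "a and a"
  )
})

test_that("finalization types values and orders multi-select answers", {
  p <- qst_finalize(walkthrough())
  expect_identical(
    qst_response_json(p),
    '{"DECON1":0,"QUESTION_1":2,"QUESTION_2":[13,15],"TEMP":98}'
  )
  expect_identical(unclass(p)$QUESTION_2, list(13, 15))

  # digit strings become numbers, but leading zeros survive as strings
  m <- qst_parse("[A] code\n(007) agent\n(0) none\n(-2) odd\n\n[END] e")
  for (v in c("007", "0", "-2")) {
    p <- qst_run(m, list(A = v))
    got <- unclass(p)$A
    if (v == "007") expect_identical(got, "007")
    if (v == "0") expect_identical(got, 0)
    if (v == "-2") expect_identical(got, -2)
  }

  expect_error(qst_finalize(qst_session(qst_example_module())),
               class = "quest_session_not_finished")
  expect_identical(qst_response_json(qst_finalize(qst_session(qst_parse("[END] e")))),
                   "{}")
})

test_that("the completion hook receives the payload exactly once", {
  seen <- list()
  s <- qst_session(qst_parse("[A] q\n(1) x -> END\n\n[END] e"),
                   on_complete = function(p) seen[[length(seen) + 1L]] <<- p)
  s <- qst_submit(s, "1")
  p <- qst_finalize(s)
  expect_length(seen, 1L)
  expect_identical(qst_response_json(seen[[1]]), qst_response_json(p))
})

test_that("step cap guards runaway sessions", {
  m <- qst_parse("[A] a\n(1) x\n\n[B] b\n(1) x\n\n[END] e")
  s <- qst_session(m, config = qst_config(step_cap = 1))
  s <- qst_submit(s, "1")
  expect_error(qst_submit(s, "1"), class = "quest_step_cap")
  expect_error(qst_config(step_cap = -1), class = "quest_config_error")
})

test_that("sessions save and load to an identical continuation", {
  s <- qst_session(qst_example_module())
  s <- qst_submit(s, "2")
  s <- qst_submit(s, c("13", "15"))
  doc <- qst_save_session(s)
  s2 <- qst_load_session(doc, qst_example_module())
  expect_identical(s2$current_id, s$current_id)
  expect_identical(s2$stack, s$stack)
  expect_identical(s2$responses, s$responses)
  expect_identical(s2$steps, s$steps)
  a <- qst_submit(qst_submit(s, "0"), 98)
  b <- qst_submit(qst_submit(s2, "0"), 98)
  expect_identical(qst_response_json(qst_finalize(a)),
                   qst_response_json(qst_finalize(b)))

  # editing the module invalidates the document
  edited <- qst_parse(sub("fever", "chills", qst_serialize(qst_example_module())))
  expect_error(qst_load_session(doc, edited), class = "quest_version_mismatch")

  # file round trip
  path <- tempfile(fileext = ".json")
  qst_save_session(s, path)
  expect_identical(qst_load_session(path, qst_example_module())$current_id,
                   s$current_id)
})

test_that("scripted replay conserves answered questions exactly once", {
  ans <- list(QUESTION_1 = "2", QUESTION_2 = c("13", "15"),
              DECON1 = "0", TEMP = 98)
  p <- qst_run(qst_example_module(), ans)
  expect_identical(sort(names(p)), unique(sort(names(p))))
  expect_setequal(names(p), names(ans))
  trail <- attr(p, "session")$trail
  expect_identical(trail[length(trail)], "END")
  # determinism: identical module + script => byte-identical payload
  p2 <- qst_run(qst_example_module(), ans)
  expect_identical(qst_response_json(p), qst_response_json(p2))
})
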