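# Shared fixtures and structural-equality helper.

# Drop source-position bookkeeping so parse(serialize(m)) can be compared
# field-by-field against m.
strip_positions <- function(module) {
  module$questions <- lapply(module$questions, function(q) {
    q <- unclass(q)
    q[grep("(^|_)line$", names(q))] <- NULL
    q$source_line <- NULL
    q$options <- lapply(q$options, function(o) {
      o <- unclass(o); o$line <- NULL; o
    })
    q$inputs <- lapply(q$inputs, function(f) {
      f <- unclass(f); f$line <- NULL; f
    })
    q
  })
  module$source <- NULL
  unclass(module)
}

expect_module_equal <- function(a, b) {
  expect_identical(strip_positions(a), strip_positions(b))
}

# A two-branch module exercising radio jumps, checkbox pushes, default-next,
# #NR and displayif; used across engine tests.
branchy_markup <- paste(
  "[INTRO] Welcome.",
  "",
  "[START] Any symptoms?",
  "(1) No -> END",
  "(2) Yes",
  "",
  "[SYMPTOMS] Which ones?",
  "[a] cough -> COUGH1",
  "[b] fever -> FEV1",
  "< -> CHECK>",
  "<#NR -> WRAP>",
  "",
  "[COUGH1] Cough severity?",
  "(1) mild",
  "(2) bad",
  "",
  "[FEV1] Temperature?",
  "|__|__| min=95 max=110",
  "<#NR -> WRAP>",
  "",
  "[CHECK] Shown only after a high fever.",
  "(1) ok",
  "<displayif=greaterThan(FEV1,100)>",
  "",
  "[WRAP] Done with symptoms.",
  "",
  "[END] Thanks.",
  sep = "\n"
)

branchy_module <- function() qst_parse(branchy_markup, "branchy")
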