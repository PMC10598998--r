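---
title: "The Quest markup model: parsing, skip logic and the session engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Quest markup model: parsing, skip logic and the session engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(questr)
```

`questr` implements a plain-text questionnaire markup used in web-based
epidemiologic data collection. This vignette is the package's account of
the model it implements: the grammar, the navigation semantics, the
choices made where the format leaves room, and what the test surface does
and does not demonstrate.

## The document model

A module is a flat sequence of question blocks. A block starts at every
line whose first non-blank token is `[ID]` with `ID` matching the id
grammar — a capital letter followed by capitals, digits, `_` or `#` — and
runs to the next such line. Everything in a block is classified
line-by-line: `(v) …` and `[v] …` lines are options, lines starting with
`|` are input fields, lines consisting of `<…>` fragments are directives,
and anything else continues the question text. Because option values are
required *not* to be valid question ids, the header/option ambiguity for
`[…]` tokens is decidable for every line; a parenthesised value that *is*
a valid id is rejected outright as ambiguous markup. The final question
is `[END]`.

Two grammar corners are under-documented in the format and are fixed here
as explicit dialects, each isolated in one function so an alternative
convention can be swapped in:

* **Numeric bounds.** The format demonstrates enforcement of a closed
  interval on numeric inputs but not its token syntax; `questr` accepts
  `|__|__| min=90 max=120`, parsed in `qst_parse_input()`.
* **displayif and piping.** The display-condition vocabulary is
  implemented as `<displayif=func(arg, …)>` with seven functions
  (`equals`, `notEquals`, `exists`, `greaterThan`, `lessThan`, `and`,
  `or`); piped text uses `{KEY}` placeholders. Both are minimal cores,
  not the full grammar of the reference renderer.

Mixed blocks — options *and* input fields together — are rejected at
parse time: the format never exhibits one and guessing submit semantics
would be worse than refusing. Serialization (`qst_serialize()`) emits a
canonical layout (header, options, inputs, directives, one blank line
between blocks) and is a parse fixed point, which the property suite
checks on 200 generated modules.

## Navigation: the question stack

Session state is the current question, a LIFO stack of pending question
ids, and the recorded responses. The rules, in the order the engine
applies them after an answer:

1. A declared default next (`< -> ID>`) is always pushed.
2. A selected radio option with an arrow transfers control directly.
3. A multi-select answer pushes the arrow targets of the selected options
   in *reverse declaration order*, then pops the stack. Reverse push
   order is the only order under which pending follow-ups pop in
   declaration order ahead of the default next, which is the documented
   behaviour of the format's worked example (runny-nose follow-up, then
   temperature, then END).
4. Otherwise the stack pops; on an empty stack the next question is the
   document successor. Running off the end of the document resolves to
   `END`.

Direct transfer for radio arrows (rule 2) is observationally equivalent
to push-then-pop; the implementation transfers directly because a single
selected arrow has nothing else to sequence against. A question whose
`displayif` is false at arrival is skipped transparently — nothing is
recorded, and the engine continues with rule 4 from the skipped question.
`END` is deliberately exempt from `displayif` so a session always has a
terminal state. `<#NR -> ID>` routes a no-response directly to its target
without pushing the default next: no-response routing is an override, not
an answer; a skip on a question *without* `#NR` (permitted only when the
session is configured with `allow_skip`) behaves as an empty selection,
so the default next is still honoured. Unanswered references inside
`displayif` compare as false rather than raising, because skipping via
`#NR` is a legitimate participant action.

Write-once responses: there is no back-navigation in v1, and a question
revisited through multiple pushes simply overwrites its earlier answer.

### Termination

Forward progress is not syntactically guaranteed — arrows may point
backwards — so the validator warns on directed cycles in the jump graph
(nodes: question ids; edges: option arrows, default-next, `#NR`, plus
document-order fallthrough), and the engine enforces a step cap,
defaulting to 10× the question count, raising a classed error beyond it.
On modules whose jump graph is acyclic, every session terminates at
`END`; the property suite additionally checks the stronger empirical
bound of (questions + jump edges) visited questions on all generated
fixtures. Graph reachability is computed with fallthrough edges included,
making it an over-approximation of dynamic reachability: "unreachable"
warnings are conservative and never fire for a question some session can
visit. Proving termination in the presence of `displayif` is not
attempted; the step cap handles it dynamically.

## The response payload

Finalizing a session produces a mapping from answered question id to
value, serialized canonically: keys byte-sorted, UTF-8, compact. A
recorded string becomes a JSON number iff it matches an optional minus
sign followed by digits without a leading zero (plus plain `"0"`); this
reproduces unquoted numeric codes in the worked example while keeping
codes like `"007"` intact as strings. Multi-select answers serialize as
arrays ordered by option declaration, singletons included, so the
payload's shape depends only on the question type, never on how many
boxes were ticked. Skipped questions are omitted entirely rather than
recorded with a marker — only answered keys appear, matching the format's
published payloads; a codebook for the absent keys is derivable from the
module itself (`qst_questions_tbl()`).

Sessions persist to a JSON document embedding a hash of the module's
canonical markup; loading against an edited module fails with a version
mismatch rather than reinterpreting recorded values. The property suite
interrupts sessions with a save/load round trip at every step and checks
the final payload is unchanged.

## Validation severities

Anything that can crash a running session is an error: skip targets not
defined in the module, duplicate option values within a question,
inverted numeric bounds, a missing `END`. Content that is merely at risk
of being dead or non-terminating is a warning: unreachable questions,
cycles. `qst_session()` refuses modules with errors; warnings are the
author's to judge (the CLI's `--strict` flag promotes them to a failing
exit).

## The fixture generator

`qst_random_module()` emulates the population of modules a questionnaire
author would write: a mix of radio, checkbox, numeric, date, free-text
and informational blocks (default weights 0.35/0.25/0.15/0.05/0.1/0.1),
2–4 options per question, roughly a third of options carrying arrows,
most checkbox questions declaring a default next, occasional `#NR` and
`displayif` directives. All generated arrows point strictly forward in
document order, so every fixture is acyclic and END-reachable by
construction, and within one question all push-capable targets are
distinct. Sizes used in the shipped tests are 2–8 questions with 200
seeds for round-trip/termination properties and a handful of ≤5-question
modules for exhaustive answer-combination enumeration against an
independent brute-force walker.

What passing these suites shows: the parser, serializer, validator and
engine agree with one another and with a naive re-implementation of the
stated semantics across a broad, unbiased sample of *valid, acyclic*
modules. What it does not show: behaviour on the expert-level grammar
(loops, grids) which is out of scope here, pixel-level parity with the
reference renderer's DOM, or robustness to adversarially malformed markup
beyond the classified parse errors.

## Rendering

`qst_render_question()` maps the model onto standard form controls —
radio/checkbox inputs named by question id, `type="number"` with
`min`/`max` attributes, `date`/`tel` inputs, SSN as a
pattern-constrained text input — and `qst_render_module()` emits a
static HTML5 document with one `<section id="…">` per question. Question
text is HTML-escaped with a small inline allowlist (`b`, `i`, `u`,
`br`): a safe default that is easy to widen. Styling is external by
design: a stylesheet is linked only when the caller provides one, so an
embedding application's own styles apply otherwise. The renderer does not
reimplement in-browser navigation; the session engine is the
authoritative navigator, and the static document leaves show/hide
behaviour to the embedding application.

## The worked example module

The packaged seven-question module
(`qst_example_module()`) is a synthetic reconstruction of the format's
canonical symptom-screening example, rebuilt from its documented
walkthrough: the first question's option (1) jumps straight to END;
the multi-select symptom question routes runny nose to a decongestant
follow-up and fever to a bounded temperature question with END as the
default next; the decongestant branch is a Yes/No fork. The walkthrough
names six questions while the module is stated to have seven; the
seventh block here is a severity follow-up for the remaining symptom
option, chosen so that it leaves every documented path and the published
payload untouched. The headline checks — the payload
`{"DECON1":0,"QUESTION_1":2,"QUESTION_2":[13,15],"TEMP":98}`, the
seven-block count, closed-interval bounds at TEMP, and the three
navigation branches — are computed end-to-end in
`tests/testthat/test-acceptance.R` and recomputed by
`scripts/acceptance.R`.
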