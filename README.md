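# questr

Parse, validate, run and render **Quest questionnaire markup** in R.

Epidemiologic studies collect most of their data through web
questionnaires with non-trivial routing: "if the participant reports a
runny nose, ask about decongestants; after all selected follow-ups, resume
at the temperature question". Quest is a plain-text markup language for
exactly this: each question block carries a bracketed id, display text,
response options and logic directives, so a questionnaire is an ordinary
UTF-8 file that can be versioned, shared across studies and rendered to
HTML by any conforming implementation. `questr` is a complete toolchain
for the format: a parser into a typed model, a static validator, a session
engine implementing the navigation semantics, an HTML form renderer, a
seeded fixture generator for property testing, and a small CLI.

## The markup and its semantics

```
[QUESTION_1] In the last 7 days, have you had any cold or flu symptoms?
(1) No -> END
(2) Yes

[QUESTION_2] Which symptoms have you had? Select all that apply.
[13] runny nose -> DECON1
[15] fever -> TEMP
< -> END>

[TEMP] What was your highest temperature, in degrees Fahrenheit?
|__|__| min=90 max=120

[END] Thank you.
```

* `(v) label` is a single-select (radio) option, `[v] label` a
  multi-select (checkbox) option; option values are never valid question
  ids, which keeps `[...]` option lines distinguishable from `[ID]`
  headers. `|__|`, `|__|__|`, `|date|`, `|tel|`, `|SSN|` declare free
  inputs.
* `label -> TARGET` is skip logic. Navigation is governed by a LIFO
  **question stack**: answering a multi-select question pushes the
  declared default next (`< -> ID>`, always pushed) and then the arrow
  targets of the selected options, in reverse declaration order, so
  pending follow-ups pop in declaration order with the default next
  visited last. A selected radio arrow transfers directly. When nothing
  routes explicitly the stack pops; when the stack is empty, the next
  question is the one immediately following in the document.
* `<#NR -> ID>` routes participants who answer nothing;
  `<displayif=expr>` hides a question unless a condition on earlier
  responses holds; `{KEY}` in question text pipes in a previous response
  or prefilled datum.

On completion a session serializes to a response JSON object mapping each
answered question id to a scalar, or to an array for multi-select answers;
plain integer strings are emitted as numbers. The payload is handed to a
registered completion hook, so studies decide where results are stored.

## Worked example

The package ships a seven-question symptom-screening module (a synthetic
reconstruction of the format's canonical worked example):

```r
library(questr)
m <- qst_example_module()
qst_validate(m)      # 0 rows: no findings

s <- qst_session(m)
s <- qst_submit(s, "2")            # any symptoms? -> Yes
s <- qst_submit(s, c("13", "15"))  # runny nose + fever
s                                  # now at DECON1; TEMP and END pending
#> <quest_session> at [DECON1]; 2 answered, stack: TEMP < END
s <- qst_submit(s, "0")            # decongestant? -> No (pops TEMP)
s <- qst_submit(s, 98)             # temperature (90..120 enforced)
qst_finalize(s)
#> {"DECON1":0,"QUESTION_1":2,"QUESTION_2":[13,15],"TEMP":98}
```

Selecting the two symptoms pushed `END` (the default next), then `TEMP`
and `DECON1`, so the follow-ups pop in declaration order; answering "No"
at `DECON1` adds nothing and the stack resumes at `TEMP`. The payload
types every plain-integer answer as a JSON number and keeps the
multi-select answer in option order.

The same pipeline is scriptable:

```r
qst_run(m, list(QUESTION_1 = "1"))        # option (1) jumps straight to END
#> {"QUESTION_1":1}
qst_render_module(m, stylesheet_ref = "study.css")  # HTML5 document
```

and available from a shell via the installed CLI:

```sh
$(Rscript -e 'cat(system.file("cli", "quest", package = "questr"))') \
  run module.quest --answers answers.json -o responses.json
```

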