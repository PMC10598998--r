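Package: questr
Title: Parse, Validate, Run and Render Quest Questionnaire Markup
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for the Quest plain-text questionnaire markup language
    used in web-based epidemiologic data collection. Parses markup modules
    into a typed questionnaire model, statically validates skip-logic
    references and reachability, executes participant sessions under the
    stack-based (last-in, first-out) navigation semantics including arrow
    skip logic, default-next, no-response routing and displayif conditions,
    renders questions to standard HTML form elements, and serializes
    completed sessions to the canonical response JSON contract. Includes a
    seeded random-module generator and answer-script simulator for
    property-style testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    rlang,
    stats,
    tibble
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
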