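Package: cdmbench
Title: Simulated Clinical Decision-Making Evaluation Harness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An interactive simulated clinical environment for evaluating
    text-in/text-out agents on abdominal-pain emergency cases. An agent
    gathers information (physical examination, laboratory tests, imaging)
    turn by turn and must issue a diagnosis and treatment plan, which the
    package scores for diagnostic accuracy, guideline adherence, treatment
    appropriateness, laboratory interpretation and instruction following.
    Includes a dataset-construction pipeline for MIMIC-IV-style relational
    tables, a synthetic case generator so every component is testable
    without protected data, deterministic scripted agents, and drivers for
    robustness experiments (information order, quantity and instruction
    phrasing perturbations).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
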