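# cdmbench

An R package that simulates a clinical decision-making (CDM) environment
for evaluating text agents on emergency abdominal-pain cases. A patient
presents with one of four hidden pathologies — appendicitis,
cholecystitis, diverticulitis or pancreatitis — and the agent, starting
from the history of present illness alone, must request physical
examination, laboratory tests and imaging turn by turn, then commit to a
diagnosis and treatment plan. The package is aimed at clinical-NLP and
evaluation researchers who need the *harness* — dataset construction,
interaction protocol, scoring, robustness perturbations — fully testable
without protected data or model weights.

It provides:

* **Case model and store** — validated patient cases (labs with reference
  ranges, findings-only radiology reports, procedures, censored
  narratives) serialized one-per-line as JSON records (`write_cases()` /
  `read_cases()`).
* **Dataset builder** — turns MIMIC-IV-style relational tables into cases,
  applying target-code filtering, the primary-discharge-diagnosis rule,
  section extraction, a 24-hour pre-admission inclusion window,
  first-entry deduplication, findings-only report extraction and `___`
  censoring, with a telescoping `build_report` (`build_dataset()`).
* **Interactive environment** — tolerant action grammar, observation
  serving, token-budget summarization with forced diagnosis, and
  instruction-following error tallies (`run_episode()`), plus the
  single-shot full-information task (`run_fi()`, `build_fi_record()`).
* **Scoring** — first-mention diagnosis matching, required-lab-category
  adherence, essential vs case-specific treatment scoring conditioned on
  correct diagnosis, per-label reference-range interpretation, per-class
  accuracy, and Welch t-tests with Bonferroni correction.
* **Synthetic generator and scripted agents** — deterministic cases, raw
  tables with plantable exclusion violations, labeled interpretation
  items, and scripted/omniscient/randomized agents, all seeded (default
  2023).
* **Robustness drivers** — the six information-order permutations, three
  single-exam ablations, instruction rephrasings, abnormal-lab filtering,
  and a resumable case × variant × seed run matrix (`run_matrix()`).

The headline metric is per-class accuracy: correct diagnoses divided by
the number of patients of that pathology. With four fixed classes and no
negative class, pooled accuracy would be misleading; comparisons between
agents use Welch's t-test, p-values Bonferroni-corrected as
`min(1, p × m)`.

## Worked example

```r
library(cdmbench)

case <- generate_case(case_profile("pancreatitis", "uncomplicated", seed = 2023))
case
#> <patient_case> SYN-PANC-u-002023 [pancreatitis]
#>   labs: 21  reports: 2  procedures: 0

ep <- run_episode(case, omniscient_agent(case))
ep
#> <episode> case SYN-PANC-u-002023: 4 turns, 3 observations, terminated by model_diagnosis
#>   final diagnosis: Acute pancreatitis

summarize_scores(list(score_episode(ep, case)))
#>      pathology n diagnostic_accuracy pe_first_rate pe_rate lab_categories_met
#> 1 pancreatitis 1                 100           100     100                100
#>   treatments_recommended mean_errors
#> 1                    100           0
```

The guideline-following agent examined the patient first, requested at
least one test from every required category (inflammation, pancreatic
enzymes, severity markers), imaged the abdomen, and recommended the full
expected treatment — so every rate is 100 and no instruction-following
errors were tallied. Replace `omniscient_agent()` with any callable
`(prompt, stop_phrases) -> text` to evaluate a real model.

The builder reports exactly why admissions drop:

```r
tabs <- generate_raw_tables(2, seed = 2023,
                            violation_plan = c("pathology_in_hpi", "no_labs"))
build_dataset(tabs)$report
#> <build_report> 10 admissions -> 8 cases
#>                stage n_in n_kept
#>        target_filter   10     10
#>  discharge_diagnosis   10     10
#>             assembly   10      8
#> exclusions:
#>   ...
#>   pathology_in_hpi: 1
#>   no_labs: 1
#>   ...
```

## Configuration

All domain vocabulary ships as editable YAML under `inst/extdata/`: the
laboratory synonym/panel dictionary, imaging keyword lists and special
exams, accepted diagnosis phrasings, guideline categories and treatment
rules, reference ranges, ICD code prefixes, and the synthetic case
templates. Prompt templates live under `inst/templates/`. Each loader
takes a `path` argument pointing at replacements.

## Raw table conventions

`build_dataset()` accepts a named list of data frames or a directory of
CSV files: `admissions` (subject_id, hadm_id, admittime),
`diagnoses_icd` (hadm_id, seq_num, icd_code, icd_version), `d_labitems`
(itemid, label), `labevents` (subject_id, hadm_id — may be empty —,
itemid, charttime, value, valuenum, valueuom, ref_range_lower,
ref_range_upper), `microbiologyevents` (…, test_name, result),
`procedures_icd`, `discharge` (hadm_id, text) and `radiology`
(subject_id, hadm_id, exam_name, charttime, text). Timestamps are
ISO-8601 text; only relative order matters.
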