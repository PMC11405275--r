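---
title: "Evaluating agents on simulated clinical decision-making"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating agents on simulated clinical decision-making}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdmbench)
```

## The task

`cdmbench` simulates the diagnostic workup of a patient presenting to the
emergency department with acute abdominal pain. An agent — any callable
that maps conversation text to response text — starts from the history of
present illness (HPI) alone and must actively gather evidence before
committing to a diagnosis and treatment plan. Four target pathologies are
covered: appendicitis, cholecystitis, diverticulitis and pancreatitis.
These share a chief complaint but are separable with standard tests, which
makes them a good closed-world benchmark: there is no realistic negative
class, so the headline metric is per-class accuracy (correct diagnoses
over all patients of one pathology), never pooled accuracy.

The harness evaluates two regimes:

* **Interactive (CDM)**: the agent alternates between requesting
  information and receiving observations until it states a final
  diagnosis, or until the context budget forces one.
* **Full information (FI)**: all relevant information is presented
  upfront in one prompt — HPI, physical examination, relevant laboratory
  results, abdominal imaging, in that canonical order — and the agent
  answers once. The FI task is the substrate of the robustness
  experiments (order permutations, single-exam ablations, instruction
  rephrasings, abnormal-lab filtering).

## The interaction protocol

Agents act through a closed tool set: *physical examination*, *laboratory
tests*, *imaging*. Responses are parsed with a labeled-field grammar
(`Thoughts:` / `Action:` / `Action Input:`, or `Final Diagnosis:` /
`Treatment:`), truncated at the first `Observation:` marker so an agent
cannot hallucinate its own observations. The parser is deliberately
tolerant, because instruction-following is itself a measured outcome
rather than a precondition:

* a recognizable tool named in prose ("I would like to perform a physical
  examination") is honored, and tallied as a next-action format error;
* an unknown tool ("Action: Colonoscopy") draws a reminder of the
  available tools and a tool-hallucination tally;
* a final turn missing its treatment field terminates the episode and is
  tallied as a diagnosis-format error.

Observation serving follows fixed rules. A physical-examination request
returns the entire examination regardless of the action input: partial
examinations are not considered good practice and the free-form text does
not decompose reliably. Laboratory requests are resolved against a
synonym-and-panel dictionary; panel names (CBC, BMP, liver/renal function
panels, urinalysis) expand to member tests; anything unmatched, or matched
but not recorded for the patient, renders as `NA`. Imaging requests are
classified to a (modality, region) pair through uniquely identifying
keyword lists with a special-exam map (MRCP and CT-urography resolve to
MRI and CT of the abdomen); repeated requests for the same pair walk
through the patient's reports in chart-time order and then report
exhaustion.

### Context budget and summarization

All bundled models of interest share a context window of about 4,096
tokens (roughly 2,400 words), so the environment enforces a token budget.
Without a bundled tokenizer the default counter is `words × 1.71`, the
ratio implied by those two numbers; a real tokenizer can be plugged in via
the `counter` field of `token_budget()`. When a conversation exceeds 90%
of the limit (configurable; the exact trigger is a design choice), served
observations are replaced one by one with summaries produced by the
agent's own summarizer, leaving the instructions and the initial HPI
untouched. If everything summarizable is summarized and the conversation
is still too long, the environment forces a final diagnosis. Before each
agent call the conversation is additionally hard-capped at
`limit − reserve`, with 25 tokens (about 20 words) reserved so a
diagnosis always fits. A safety cap of 15 action turns (a design choice;
non-terminating agents must not hang the harness) routes runaway episodes
into the same forced-diagnosis path.

## Dataset construction

The builder consumes MIMIC-IV-shaped relational tables — real credentialed
exports or the synthetic ones this package generates — and applies, in
order:

1. **Target filter**: keep admissions carrying diagnosis codes of exactly
   one target pathology (configured ICD-9/ICD-10 prefix families; the
   shipped lists are documented reconstructions and replaceable).
2. **Primary discharge diagnosis**: the first diagnosis listed in the
   discharge-diagnosis section must be the candidate pathology; any other
   diagnosis written before it removes the case.
3. **Sections**: HPI and physical examination are cut from the discharge
   summary by configurable header patterns; a missing physical
   examination, or a pathology mention inside the HPI, removes the case.
4. **Laboratory and microbiology events**: events linked to the admission
   plus unlinked events up to 24 hours before admission (closed interval;
   the bracket detail is a design choice), provided they belong to no
   other admission. Repeated tests keep only the chronologically first
   entry — a therapy-naive snapshot — with ties broken by source row
   order. Microbiology is deduplicated by the same first-entry rule.
5. **Radiology**: same 24-hour rule; each note's exam name is classified
   to (modality, region); only the findings section is kept, because
   impression/conclusion sections contain the radiologist's diagnosis and
   would trivialize the task.
6. **Final cleaning**: cases without laboratory tests or without
   abdominal imaging are removed; remaining mentions of the gold
   pathology in served text are censored to `___`, the de-identification
   placeholder already used by the source data.

Every drop is attributed to exactly one reason and the resulting
`build_report` telescopes: each stage's kept count is the next stage's
input, and exclusion reasons sum to the dropped total. The builder is
deterministic — identical tables yield a byte-identical case store.

## Scoring

**Diagnosis.** Free-text diagnoses are segmented on list markers,
newlines, semicolons, sentence breaks and the connectives *and*/*with*;
only the first segment is examined, case-insensitively, against the
pathology name and a configured list of medically equivalent phrasings.
Partial findings without an inflammatory term ("gallstones" for
cholecystitis) intentionally do not match.

**Guideline adherence.** Each pathology defines required laboratory
categories (inflammation markers for all four; hepatobiliary panel for
cholecystitis; pancreatic enzymes and severity markers for pancreatitis);
a category is met when at least one member test was requested, directly or
through a panel. Imaging behaviour is recorded but never penalized.

**Treatment.** Scored only for correctly diagnosed patients, since a
treatment plan for the wrong diagnosis is not interpretable. Essential
treatments (e.g. antibiotics) are always expected; case-specific
treatments (appendectomy, cholecystectomy, colectomy, drainage, ERCP) are
expected only when the patient's procedure records show they actually
happened, and are `not_applicable` otherwise. Supportive care requires a
mention of fluids, pain management or monitoring — any one for
appendicitis, cholecystitis and diverticulitis, all three for
pancreatitis, where supportive care is the mainstay of treatment.
Matching is surface-level keywords with a negation guard ("no
antibiotics" does not count); the guard's three-word window is a design
choice.

**Laboratory interpretation.** `classify_lab_value()` classifies a value
as below, within or above its reference range with inclusive bounds — a
value equal to a bound is within range. A missing low bound means a value
can never be "below"; non-numeric values are not classifiable. Accuracy is
reported per label, because errors on low results are clinically the most
dangerous and pooled accuracy would hide them.

**Statistics.** Group comparisons use the two-sided Welch t-test
(`stats::t.test` with `var.equal = FALSE`) with Bonferroni correction
`min(1, p × m)`. The test suite checks the implementation against an
independently coded textbook Welch formula at `1e-10`.

## The synthetic generator

The generator is first-class, tested code, not a fixture dump. It
emulates the *structure* the pipeline consumes: per-pathology templated
HPI and examination texts (the HPI never names the pathology), laboratory
panels drawn around standard adult reference ranges with each pathology's
textbook derangements (leukocytosis and CRP elevation everywhere;
cholestatic liver pattern for cholecystitis; lipase roughly eight
reference-widths above the upper bound for pancreatitis; hemoconcentration,
azotemia and hypocalcemia for complicated pancreatitis), abdominal imaging
whose findings use descriptive vocabulary only (the word "diverticula" can
appear, the word "diverticulitis" cannot), and severity-consistent
procedure records. Magnitudes were fixed once as moderate multiples of the
reference-interval width — large enough to be unambiguous, small enough to
stay physiological — and are not tuned thereafter. The default seed is
2023 everywhere, and every generator is a pure function of its seed.

What the generator does **not** emulate: clinical prose style,
abbreviation noise, demographic structure, temporal evolution of lab
values, contradictory findings, or the long tail of MIMIC section-header
variants. Green tests therefore demonstrate that the machinery is correct
under controlled conditions, not that any particular language model is
good at medicine, and not that the shipped header patterns or synonym
dictionary cover every real-world discharge summary.

## Numerical and design choices

* Lexicon normalization is lowercase, punctuation stripped, whitespace
  collapsed; "best match" resolves exact alias, then panel name, then
  longest non-overlapping alias substrings on word boundaries, so a
  request listing several tests resolves each.
* The imaging lexicon loader rejects any keyword listed under two
  modalities or two regions (keywords must be uniquely identifying). If a
  free-text request nevertheless contains keywords of two modalities, the
  earliest occurrence wins — a deterministic tie-break preferred here over
  refusing to answer, since the environment must always serve something.
* Chronological ties (labs, reports) break by source row order.
* Lab values arriving as text (`"<0.1"`, `"NEGATIVE"`) keep their raw
  form for transcripts and carry a parsed number when one exists.
* `physical_exam_first` is true iff the first parsed action turn —
  malformed turns included — requests the physical examination.
* A final turn with a missing treatment field still terminates the
  episode (the diagnosis was given); the deviation is tallied rather than
  re-prompted.
* Timestamps are ISO-8601 text; the year-shifted de-identified dates of
  the source data are accepted as-is since only relative order matters.

## Problem sizes

The shipped test suite exercises 200 randomized interactive episodes for
protocol conformance, 100 synthetic cases for the perfect-agent control,
3,000 items for the interpretation task, and 1,000 random labs for the
abnormal-filter check — sizes chosen so the whole suite runs in well under
a minute on one CPU while keeping every binomial check far away from
boundary flakiness. `scripts/acceptance.R` recomputes the same quantities
from scratch at the same sizes.

## Limitations

* The shipped synonym dictionary, ICD prefix lists, header patterns,
  guideline category contents and treatment keywords are reconstructions
  of standard clinical vocabulary; all are YAML configuration intended to
  be replaced wholesale for serious use against real exports.
* Prompt templates paraphrase the described task structure; swap in your
  own via `template_dir` for exact replication of any particular study.
* No LLM backend ships with the package. The agent contract
  (`function(prompt, stop_phrases) -> text`, optional `summarizer`
  attribute) is the integration point; scripted agents exist to make every
  protocol path testable deterministically.
* Non-numeric laboratory results (cultures, qualitative urinalysis) are
  stored and served as raw text; how a model should interpret them is left
  to the model.
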