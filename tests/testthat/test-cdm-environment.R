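test_that("turn parsing covers the labeled grammar and tolerant fallbacks", {
  t1 <- parse_turn("Thoughts: check bloods\nAction: Laboratory Tests\nAction Input: CBC")
  expect_identical(t1$outcome, "action")
  expect_identical(t1$kind, "laboratory_tests")
  expect_identical(t1$input_text, "CBC")
  expect_length(t1$format_flags, 0)

  t2 <- parse_turn("I would like to perform a physical examination")
  expect_identical(t2$kind, "physical_examination")
  expect_true("free_text_action" %in% t2$format_flags)

  t3 <- parse_turn("Thoughts: hmm\nAction: Colonoscopy\nAction Input: colon")
  expect_true("hallucinated_tool" %in% t3$format_flags)
  expect_true(is.na(t3$kind))

  t4 <- parse_turn("Thoughts: done\nFinal Diagnosis: Acute appendicitis\nTreatment: appendectomy and antibiotics")
  expect_identical(t4$outcome, "final")
  expect_identical(t4$diagnosis_text, "Acute appendicitis")
  expect_match(t4$treatment_text, "appendectomy")
  expect_length(t4$format_flags, 0)

  t5 <- parse_turn("Final Diagnosis: pancreatitis")
  expect_identical(t5$outcome, "final")
  expect_true("malformed_final" %in% t5$format_flags)

  t6 <- parse_turn("")
  expect_true("missing_action_field" %in% t6$format_flags)

  # text after an observation marker is cut before parsing
  t7 <- parse_turn("Action: Imaging\nAction Input: CT abdomen\nObservation: I imagine the scan shows...")
  expect_identical(t7$kind, "imaging")
  expect_identical(t7$input_text, "CT abdomen")
})

test_that("imaging observations advance chronologically and then exhaust", {
  case <- tiny_case(n_abdominal_ct = 2)
  req <- "Thoughts: scan\nAction: Imaging\nAction Input: CT abdomen"
  ag <- scripted_agent(c(req, req, req,
                         "Final Diagnosis: acute appendicitis\nTreatment: appendectomy, antibiotics, fluids"))
  ep <- run_episode(case, ag)
  expect_length(ep$observations, 3)
  expect_match(ep$observations[1], "scan number 1")
  expect_match(ep$observations[2], "scan number 2")
  expect_match(ep$observations[3], "no longer provide reports")
})

test_that("physical examination is served whole regardless of action input", {
  case <- tiny_case()
  ag <- scripted_agent(c(
    "Thoughts: partial\nAction: Physical Examination\nAction Input: palpate RLQ only",
    "Final Diagnosis: acute appendicitis\nTreatment: appendectomy"))
  ep <- run_episode(case, ag)
  expect_identical(ep$observations[1], case$physical_exam_text)
  expect_true(ep$physical_exam_requested)
  expect_true(ep$physical_exam_first)
})

test_that("unmatched and unavailable lab requests render as NA", {
  case <- tiny_case()
  ag <- scripted_agent(c(
    "Thoughts: odd\nAction: Laboratory Tests\nAction Input: quantum flux assay",
    "Thoughts: real\nAction: Laboratory Tests\nAction Input: lactate",
    "Final Diagnosis: acute appendicitis\nTreatment: appendectomy"))
  ep <- run_episode(case, ag)
  expect_identical(ep$observations[1], "NA")
  expect_match(ep$observations[2], "lactate: NA")  # matched but not recorded
})

test_that("summarization replaces only observations and can force a diagnosis", {
  config <- cdm_config(budget = token_budget(limit = 120, reserve = 25),
                       summarize_threshold = 0.9)
  long_obs <- paste(rep("finding", 80), collapse = " ")
  spans <- list(
    list(name = "instructions", text = "Instructions here.", summarizable = FALSE),
    list(name = "hpi", text = "HPI here.", summarizable = FALSE),
    list(name = "observation", text = long_obs, summarizable = TRUE),
    list(name = "observation", text = long_obs, summarizable = TRUE))
  out <- maybe_summarize(spans, config, function(text) trim_words(text, 5))
  expect_identical(out$spans[[1]]$text, "Instructions here.")
  expect_identical(out$spans[[2]]$text, "HPI here.")
  expect_true(out$spans[[3]]$summarized)
  expect_lt(nchar(out$spans[[3]]$text), nchar(long_obs))

  # under threshold: untouched
  small <- list(list(name = "instructions", text = "short", summarizable = FALSE))
  out2 <- maybe_summarize(small, cdm_config(), function(text) stop("never called"))
  expect_identical(out2$spans, small)
  expect_false(out2$force)
})

test_that("an agent that never concludes is forced to a diagnosis", {
  case <- tiny_case()
  req <- "Thoughts: more\nAction: Laboratory Tests\nAction Input: CBC"
  ag <- scripted_agent(rep(req, 5), fallback_diagnosis = "appendicitis")
  config <- cdm_config(max_turns = 5)
  ep <- run_episode(case, ag, config)
  expect_identical(ep$terminated_by, "forced_diagnosis")
  expect_length(ep$observations, 5)
  expect_match(ep$final_diagnosis_text, "appendicitis")
})

test_that("an agent that emits nothing accrues one action error per turn", {
  case <- tiny_case()
  ag <- scripted_agent(rep("", 50), fallback_diagnosis = "unsure")
  config <- cdm_config(max_turns = 6)
  ep <- run_episode(case, ag, config)
  expect_equal(ep$error_counts$next_action_errors, 6)
  expect_identical(ep$terminated_by, "forced_diagnosis")
})

test_that("episodes are deterministic and isolated across cases", {
  case <- generate_case(case_profile("cholecystitis", "uncomplicated", 12))
  e1 <- run_episode(case, omniscient_agent(case))
  e2 <- run_episode(case, omniscient_agent(case))
  expect_identical(e1, e2)
  other <- generate_case(case_profile("pancreatitis", "uncomplicated", 12))
  e3 <- run_episode(other, omniscient_agent(other))
  # fresh state: the cholecystitis episode left no imaging cursor behind
  expect_match(e3$observations[3], "pancreas|abdomen")
})

test_that("every prompt handed to the agent respects the token budget", {
  case <- generate_case(case_profile("diverticulitis", "complicated", 3))
  budget <- token_budget(limit = 400, reserve = 25)
  config <- cdm_config(budget = budget, max_turns = 8)
  inner <- scripted_agent(rep(
    "Thoughts: scan\nAction: Imaging\nAction Input: CT abdomen", 10),
    fallback_diagnosis = "diverticulitis")
  rec <- recording_agent(inner)
  ep <- run_episode(case, rec, config)
  sizes <- attr(rec, "prompt_sizes")()
  expect_true(all(sizes <= budget$limit - budget$reserve))
  expect_gt(length(sizes), 1)
})

test_that("single-shot full-information runs extract the diagnosis", {
  case <- tiny_case()
  ag <- scripted_agent("Final Diagnosis: acute appendicitis")
  res <- run_fi(case, ag)
  expect_identical(res$diagnosis_text, "acute appendicitis")
  expect_match(res$prompt, "History of Present Illness")
  expect_true(match_diagnosis(res$diagnosis_text, "appendicitis"))
})
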