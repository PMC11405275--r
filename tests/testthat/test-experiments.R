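test_that("exactly six order permutations preserve content spans", {
  perms <- make_order_permutations()
  expect_length(perms, 6)
  orders <- lapply(perms, function(v) v$parameters$order)
  expect_equal(length(unique(lapply(orders, paste, collapse = ","))), 6)
  case <- tiny_case(n_abdominal_ct = 2)
  parts <- build_fi_parts(case)
  baseline <- assemble_fi_prompt(parts, instructions = "Inspect the case.")
  base_spans <- sort(c("Inspect the case.", parts$hpi, parts$pe, parts$labs,
                       parts$imaging))
  for (v in perms) {
    prompt <- assemble_fi_prompt(parts, instructions = "Inspect the case.",
                                 order = v$parameters$order)
    got_spans <- sort(strsplit(prompt, "\n\n", fixed = TRUE)[[1]])
    expect_identical(got_spans, base_spans, info = v$variant_id)
  }
  # the canonical permutation reproduces the baseline byte-for-byte
  canonical <- assemble_fi_prompt(parts, instructions = "Inspect the case.",
                                  order = perms[[1]]$parameters$order)
  expect_identical(canonical, baseline)
})

test_that("single-exam variants keep exactly one diagnostic section", {
  variants <- make_single_exam_variants()
  expect_length(variants, 3)
  case <- tiny_case()
  for (v in variants) {
    prompt <- cdmbench:::fi_prompt_for_variant(case, v)
    expect_match(prompt, "History of Present Illness")
    keep <- v$parameters$keep
    expect_identical(grepl("Physical Examination", prompt), keep == "pe")
    expect_identical(grepl("Laboratory Results", prompt), keep == "labs")
    expect_identical(grepl("scan number", prompt), keep == "imaging")
  }
})

test_that("abnormal-lab filtering is idempotent and agrees with classification", {
  case <- tiny_case()  # wbc above range, lipase within
  once <- filter_abnormal_labs(case)
  expect_identical(vapply(once$labs, function(l) l$canonical_name, character(1)),
                   "white blood cell count")
  expect_identical(filter_abnormal_labs(once), once)

  set.seed(33)
  for (i in 1:1000) {
    lo <- runif(1, 0, 50)
    hi <- lo + runif(1, 0.1, 50)
    val <- runif(1, lo - 20, hi + 20)
    l <- lab_result("probe", value = val, ref_low = lo, ref_high = hi,
                    chart_time = "2023-01-01T00:00:00")
    case$labs <- list(l)
    kept <- length(filter_abnormal_labs(case)$labs) == 1
    expect_identical(kept, classify_lab_value(val, lo, hi) != "within")
  }
  # qualitative labs without bounds survive the filter
  case$labs <- list(lab_result("urine nitrite", value = "NEGATIVE",
                               chart_time = "2023-01-01T00:00:00"))
  expect_length(filter_abnormal_labs(case)$labs, 1)
})

test_that("instruction variants change only what their kind names", {
  case <- tiny_case()
  baseline <- cdmbench:::fi_prompt_for_variant(case, NULL)
  main <- cdmbench:::fi_prompt_for_variant(
    case, experiment_variant("phrase_main", "instruction_phrasing",
                             list(phrase = "main diagnosis")))
  expect_false(grepl("final diagnosis", main, ignore.case = TRUE))
  expect_true(grepl("main diagnosis", main, ignore.case = TRUE))
  expect_identical(gsub("(?i)main diagnosis", "final diagnosis", main, perl = TRUE),
                   gsub("(?i)final diagnosis", "final diagnosis", baseline, perl = TRUE))

  naked <- cdmbench:::fi_prompt_for_variant(
    case, experiment_variant("nosys", "remove_system_instructions"))
  expect_false(grepl("You are a physician", naked))
  expect_match(naked, "History of Present Illness")

  plain <- cdmbench:::fi_prompt_for_variant(
    case, experiment_variant("noterms", "remove_medical_terms"))
  expect_false(grepl("physician", substr(plain, 1, 300)))

  none <- make_instruction_variants(character(0))
  expect_length(none, 1)
  expect_identical(none[[1]]$kind, "baseline")
})

test_that("the run matrix is a full factorial and aggregates deltas", {
  cases <- lapply(1:4, function(i)
    generate_case(case_profile(pathologies()[i], "uncomplicated", 40 + i)))
  variants <- list(experiment_variant("baseline", "baseline"),
                   make_order_permutations()[[2]])
  factory <- function(case, seed) {
    scripted_agent(paste0("Final Diagnosis: acute ", case$pathology))
  }
  m <- run_matrix(cases, factory, variants, seeds = 1:3)
  expect_equal(nrow(m), 4 * 2 * 3)
  expect_true(all(m$correct))
  expect_false(any(m$failed))
  # deterministic agent: identical across seeds
  for (s in split(m, list(m$case_id, m$variant_id))) {
    expect_equal(length(unique(s$diagnosis_text)), 1)
  }
  agg <- aggregate_matrix(m)
  expect_true(all(agg$mean_accuracy == 100))
  expect_true(all(agg$delta_vs_baseline == 0))
})

test_that("an order-sensitive agent shows up as an order effect in the aggregate", {
  cases <- list(tiny_case())
  perms <- make_order_permutations()
  # agent succeeds only when the labs section comes directly after the HPI
  factory <- function(case, seed) {
    function(prompt, stop_phrases = character(0)) {
      pos_labs <- regexpr("Laboratory Results", prompt, fixed = TRUE)[1]
      pos_pe <- regexpr("Physical Examination", prompt, fixed = TRUE)[1]
      pos_img <- regexpr("scan number", prompt, fixed = TRUE)[1]
      if (pos_labs < pos_pe && pos_labs < pos_img) {
        "Final Diagnosis: acute appendicitis"
      } else {
        "Final Diagnosis: unclear abdominal process"
      }
    }
  }
  m <- run_matrix(cases, factory, perms, seeds = 1)
  agg <- aggregate_matrix(m, baseline_id = "order_pe_labs_imaging")
  labs_first <- grepl("^order_labs", agg$variant_id)
  expect_true(all(agg$mean_accuracy[labs_first] == 100))
  expect_true(all(agg$mean_accuracy[!labs_first] == 0))
})

test_that("run matrices resume from a checkpoint without recomputation", {
  cases <- list(generate_case(case_profile("cholecystitis", "uncomplicated", 60)))
  variants <- list(experiment_variant("baseline", "baseline"))
  calls <- 0L
  factory <- function(case, seed) {
    calls <<- calls + 1L
    scripted_agent("Final Diagnosis: acute cholecystitis")
  }
  ck <- withr::local_tempfile(fileext = ".jsonl")
  m1 <- run_matrix(cases, factory, variants, seeds = 1:2, checkpoint_path = ck)
  expect_equal(calls, 2L)
  m2 <- run_matrix(cases, factory, variants, seeds = 1:2, checkpoint_path = ck)
  expect_equal(calls, 2L)  # all cells came from the checkpoint
  expect_equal(m2$correct, m1$correct)
})
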