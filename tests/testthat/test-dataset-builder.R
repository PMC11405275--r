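make_summary <- function(hpi = "Right lower quadrant pain for two days.",
                         pe = "Tender abdomen, guarding.",
                         dd = "1. Acute appendicitis\n2. Hypertension",
                         include_pe = TRUE) {
  paste(c(
    "Admission Date: ___\nService: SURGERY",
    paste0("History of Present Illness:\n", hpi),
    if (include_pe) paste0("Physical Exam:\n", pe),
    paste0("Discharge Diagnosis:\n", dd),
    "Discharge Condition:\nStable"), collapse = "\n\n")
}

test_that("section extraction finds headers and tolerates absences", {
  s <- extract_sections(make_summary())
  expect_match(s$hpi, "Right lower quadrant")
  expect_match(s$physical_exam, "Tender abdomen")
  expect_match(s$discharge_diagnosis, "Acute appendicitis")
  s2 <- extract_sections(make_summary(include_pe = FALSE))
  expect_true(is.na(s2$physical_exam))
  s3 <- extract_sections("free text with no headers at all")
  expect_true(all(is.na(unlist(s3))))
})

test_that("primary discharge diagnosis rule keeps only first-listed targets", {
  ok <- check_primary_discharge_diagnosis(
    "1. Acute cholecystitis\n2. Hypertension", "cholecystitis")
  expect_true(ok$keep)
  bad <- check_primary_discharge_diagnosis(
    "1. Sepsis\n2. Cholecystitis", "cholecystitis")
  expect_false(bad$keep)
  expect_identical(bad$reason, "secondary_discharge_diagnosis")
  none <- check_primary_discharge_diagnosis("  ", "cholecystitis")
  expect_identical(none$reason, "no_discharge_diagnosis")
})

test_that("lab collection applies the 24-hour window and first-entry rule", {
  mk_lab <- function(hadm, time, itemid = 1L, value = 12) {
    data.frame(subject_id = 1L, hadm_id = hadm, itemid = itemid,
               charttime = time, value = as.character(value), valuenum = value,
               valueuom = "K/uL", ref_range_lower = 4, ref_range_upper = 11,
               stringsAsFactors = FALSE)
  }
  linked <- rbind(mk_lab(100L, "2023-03-01T09:00:00", value = 15),
                  mk_lab(100L, "2023-03-01T14:00:00", value = 9))
  unlinked <- rbind(
    mk_lab(NA_integer_, "2023-03-01T05:00:00", itemid = 2L, value = 2.1),
    mk_lab(NA_integer_, "2023-02-28T01:00:00", itemid = 3L, value = 7))  # 31 h before
  bundle <- list(
    admit_time = "2023-03-01T08:00:00",
    lab_events = list(linked = linked, unlinked = unlinked),
    microbiology_events = list(
      linked = data.frame(),
      unlinked = data.frame(subject_id = integer(0), hadm_id = integer(0),
                            charttime = character(0), test_name = character(0),
                            result = character(0))),
    d_labitems = data.frame(itemid = 1:3,
                            label = c("White Blood Cells", "Lactate", "Glucose"),
                            stringsAsFactors = FALSE))
  labs <- collect_labs(bundle)
  names_got <- vapply(labs, function(l) l$canonical_name, character(1))
  # repeated WBC: only the chronologically first entry survives
  expect_equal(sum(names_got == "white blood cell count"), 1)
  wbc <- labs[[which(names_got == "white blood cell count")]]
  expect_equal(wbc$value_num, 15)
  # unlinked lactate 3 h before admission is included; 31 h is not
  expect_true("lactate" %in% names_got)
  expect_false("glucose" %in% names_got)
})

test_that("events linked to a different admission never join a bundle", {
  tabs <- generate_raw_tables(1, seed = 5)
  # plant a lab linked to admission B 5 h before admission A's admit time
  other <- tabs$labevents[1, ]
  other$hadm_id <- tabs$admissions$hadm_id[2]
  other$subject_id <- tabs$admissions$subject_id[1]
  other$itemid <- 999L
  other$charttime <- "2023-03-01T03:00:00"
  tabs$labevents <- rbind(tabs$labevents, other)
  tabs$d_labitems <- rbind(tabs$d_labitems,
                           data.frame(itemid = 999L, label = "Planted Foreign Test"))
  bundleA <- as_bundles(tabs)[[1]]
  labsA <- collect_labs(bundleA)
  expect_false(any(grepl("planted foreign", vapply(labsA, function(l) l$raw_name,
                                                   character(1)), ignore.case = TRUE)))
})

test_that("findings extraction keeps findings and drops impression", {
  note <- "EXAMINATION: CT ABD\n\nFINDINGS:\nDilated appendix with stranding.\n\nIMPRESSION:\nAcute appendicitis."
  fx <- extract_findings(note)
  expect_match(fx, "Dilated appendix")
  expect_false(grepl("IMPRESSION|Acute appendicitis", fx))
  expect_true(is.na(extract_findings("No structured sections here.")))
})

test_that("planted violations each trip exactly one exclusion rule", {
  plan <- violation_reasons()
  tabs <- generate_raw_tables(1, seed = 2023, violation_plan = plan)
  res <- build_dataset(tabs)
  expect_equal(res$report$n_cases, 4)
  expect_equal(res$report$n_input, 4 + length(plan))
  for (r in plan) {
    expect_equal(unname(res$report$exclusions[[r]]), 1L, info = r)
  }
  expect_equal(sum(res$report$exclusions), length(plan))
  expect_silent(validate_build_report(res$report))
})

test_that("builder is deterministic: identical tables give byte-identical stores", {
  t1 <- withr::local_tempfile(fileext = ".jsonl")
  t2 <- withr::local_tempfile(fileext = ".jsonl")
  write_cases(build_dataset(generate_raw_tables(2, seed = 9))$cases, t1)
  write_cases(build_dataset(generate_raw_tables(2, seed = 9))$cases, t2)
  expect_identical(readLines(t1), readLines(t2))
})

test_that("gold pathology mentions are censored out of served text", {
  tabs <- generate_raw_tables(1, seed = 4)
  # plant a mention in the physical exam section of the first admission
  tabs$discharge$text[1] <- sub("Physical Exam:\n",
                                "Physical Exam:\nFindings consistent with appendicitis. ",
                                tabs$discharge$text[1], fixed = TRUE)
  res <- build_dataset(tabs)
  case <- res$cases[[which(vapply(res$cases, function(x) x$pathology, character(1))
                           == "appendicitis")[1]]]
  expect_false(grepl("appendicitis", case$physical_exam_text, ignore.case = TRUE))
  expect_match(case$physical_exam_text, "___")
})

test_that("full-information record follows canonical order and chart-time sorting", {
  case <- tiny_case(n_abdominal_ct = 2)
  parts <- build_fi_parts(case)
  expect_length(parts$imaging, 2)
  expect_true(grepl("scan number 1", parts$imaging[1]))
  expect_true(grepl("scan number 2", parts$imaging[2]))
  prompt <- assemble_fi_prompt(parts, instructions = "Read the case.")
  pos <- vapply(c("History of Present Illness", "Physical Examination",
                  "Laboratory Results", "scan number 1", "scan number 2"),
                function(x) regexpr(x, prompt, fixed = TRUE)[1], numeric(1))
  expect_true(all(diff(pos) > 0))
})

test_that("over-budget full-information prompts stay under limit minus reserve", {
  case <- tiny_case(n_abdominal_ct = 2)
  # inflate findings so the prompt must be summarized and then trimmed
  case$reports <- lapply(case$reports, function(r) {
    r$findings_text <- paste(rep(r$findings_text, 80), collapse = " ")
    r
  })
  budget <- token_budget(limit = 300, reserve = 25)
  prompt <- assemble_fi_prompt(build_fi_parts(case), instructions = "Read.",
                               budget = budget,
                               summarizer = function(text) trim_words(text, 50))
  expect_lte(count_tokens(prompt), 300 - 25)
})
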