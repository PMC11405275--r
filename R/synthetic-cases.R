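# Synthetic case generator: ready-made patient cases, MIMIC-IV-shaped raw
# tables for the dataset builder, labeled fixtures for the laboratory
# interpretation task, and deterministic scripted agents. Everything is
# reproducible under a fixed seed (default 2023 throughout the package).

default_seed <- function() 2023L

# Evaluate code under a given RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

load_case_templates <- function(path = NULL) {
  key <- path %||% "default_templates"
  if (!is.null(.lexicon_cache[[key]])) return(.lexicon_cache[[key]])
  .lexicon_cache[[key]] <- yaml::read_yaml(path %||% config_path("case_templates.yaml"))
  .lexicon_cache[[key]]
}

load_reference_ranges <- function(path = NULL) {
  key <- path %||% "default_ranges"
  if (!is.null(.lexicon_cache[[key]])) return(.lexicon_cache[[key]])
  .lexicon_cache[[key]] <- yaml::read_yaml(path %||% config_path("reference_ranges.yaml"))
  .lexicon_cache[[key]]
}

# Lab derangements per pathology: direction and magnitude (in units of the
# reference-interval width beyond the bound). Moderate, unambiguous values
# chosen once to give each pathology its textbook laboratory signature.
derangement_spec <- function(pathology, severity) {
  base <- switch(pathology,
    appendicitis = list(
      "white blood cell count" = c(dir = 1, mag = 0.6),
      "c-reactive protein" = c(dir = 1, mag = 4.0)),
    cholecystitis = list(
      "white blood cell count" = c(dir = 1, mag = 0.5),
      "c-reactive protein" = c(dir = 1, mag = 3.0),
      "total bilirubin" = c(dir = 1, mag = 1.0),
      "alkaline phosphatase" = c(dir = 1, mag = 0.8),
      "aspartate aminotransferase" = c(dir = 1, mag = 1.2),
      "alanine aminotransferase" = c(dir = 1, mag = 1.0)),
    diverticulitis = list(
      "white blood cell count" = c(dir = 1, mag = 0.5),
      "c-reactive protein" = c(dir = 1, mag = 5.0)),
    pancreatitis = list(
      "lipase" = c(dir = 1, mag = 8.0),
      "amylase" = c(dir = 1, mag = 3.0),
      "white blood cell count" = c(dir = 1, mag = 0.7),
      "c-reactive protein" = c(dir = 1, mag = 6.0)))
  if (severity == "complicated") {
    extra <- switch(pathology,
      appendicitis = list("lactate" = c(dir = 1, mag = 1.0)),
      cholecystitis = list("total bilirubin" = c(dir = 1, mag = 2.5)),
      diverticulitis = list("lactate" = c(dir = 1, mag = 1.0)),
      pancreatitis = list(
        "hematocrit" = c(dir = 1, mag = 0.3),
        "urea nitrogen" = c(dir = 1, mag = 1.5),
        "calcium" = c(dir = -1, mag = 0.5),
        "lactate" = c(dir = 1, mag = 1.5)))
    base <- utils::modifyList(base, extra)
  }
  base
}

# Tests every synthetic admission receives (a standard abdominal-pain
# workup panel).
synthetic_workup_tests <- function() {
  c("white blood cell count", "hemoglobin", "hematocrit", "platelet count",
    "sodium", "potassium", "chloride", "bicarbonate", "urea nitrogen",
    "creatinine", "glucose", "calcium", "total bilirubin",
    "alkaline phosphatase", "aspartate aminotransferase",
    "alanine aminotransferase", "albumin", "lipase", "amylase",
    "c-reactive protein", "lactate")
}

#' Synthetic case profile
#'
#' @param pathology one of [pathologies()].
#' @param severity `"uncomplicated"` or `"complicated"`; complicated
#'   profiles add the pathology's case-specific procedures (perforation,
#'   abscess) and their procedure records.
#' @param seed integer; the same (pathology, severity, seed) always
#'   produces an identical case.
#' @return a `case_profile` object.
#' @export
case_profile <- function(pathology, severity = c("uncomplicated", "complicated"),
                         seed = default_seed()) {
  structure(list(pathology = match.arg(pathology, pathologies()),
                 severity = match.arg(severity), seed = as.integer(seed)),
            class = "case_profile")
}

profile_rng_seed <- function(profile) {
  (profile$seed * 8L +
     2L * (match(profile$pathology, pathologies()) - 1L) +
     (profile$severity == "complicated")) %% .Machine$integer.max
}

fill_template <- function(tpl, values) {
  for (nm in names(values)) {
    tpl <- gsub(paste0("{", nm, "}"), values[[nm]], tpl, fixed = TRUE)
  }
  tpl
}

sample_lab_value <- function(lo, hi, derangement = NULL) {
  width <- hi - lo
  if (is.null(derangement)) {
    return(round(stats::runif(1, lo + 0.1 * width, hi - 0.1 * width), 2))
  }
  mag <- derangement[["mag"]] * stats::runif(1, 0.8, 1.4)
  if (derangement[["dir"]] > 0) {
    round(hi + mag * width, 2)
  } else {
    max(round(lo - mag * width, 2), round(0.05 * lo, 2))
  }
}

synthetic_procedures <- function(pathology, severity) {
  uncomplicated <- switch(pathology,
    appendicitis = list(procedure_record(code = "0DTJ4ZZ",
      free_text = "Laparoscopic appendectomy", source = "coded_table")),
    cholecystitis = list(procedure_record(code = "0FT44ZZ",
      free_text = "Laparoscopic cholecystectomy", source = "coded_table")),
    diverticulitis = list(),
    pancreatitis = list())
  if (severity == "uncomplicated") return(uncomplicated)
  extra <- switch(pathology,
    appendicitis = list(procedure_record(code = "0W9G30Z",
      free_text = "Percutaneous drainage of abdominal abscess", source = "coded_table")),
    cholecystitis = list(procedure_record(code = "0F9440Z",
      free_text = "Percutaneous cholecystostomy drain placement", source = "coded_table")),
    diverticulitis = list(
      procedure_record(code = "0DTN0ZZ",
        free_text = "Sigmoid colectomy (Hartmann procedure)", source = "coded_table"),
      procedure_record(code = "0W9G30Z",
        free_text = "Percutaneous drainage of pelvic abscess", source = "coded_table")),
    pancreatitis = list(procedure_record(code = "0F9G30Z",
      free_text = "Percutaneous drainage of peripancreatic collection", source = "coded_table")))
  c(uncomplicated, extra)
}

#' Generate one synthetic patient case
#'
#' Texts come from parameterized templates (the history of present illness
#' never names the pathology); laboratory values are drawn around the
#' configured reference ranges with the pathology's textbook derangements
#' (e.g. lipase far above its upper bound for pancreatitis); at least one
#' abdominal report carries pathology-consistent findings; procedures match
#' the severity. Fully deterministic given the profile.
#'
#' @param profile a [case_profile()].
#' @return a `patient_case`.
#' @export
generate_case <- function(profile) {
  stopifnot(inherits(profile, "case_profile"))
  tpls <- load_case_templates()
  tpl <- tpls[[profile$pathology]]
  if (is.null(tpl)) stop("no template for pathology ", profile$pathology, call. = FALSE)
  ranges <- load_reference_ranges()
  with_seed(profile_rng_seed(profile), {
    vals <- list(
      duration = sample(1:4, 1), fever = sprintf("%.1f", stats::runif(1, 100.0, 102.5)),
      quality = sample(c("sharp", "constant", "cramping", "dull"), 1),
      temp = sprintf("%.1f", stats::runif(1, 99.5, 102.0)),
      hr = sample(85:115, 1), appendix_mm = sample(9:15, 1),
      gb_wall = sample(4:8, 1), cbd = sample(4:6, 1),
      segment_cm = sample(4:9, 1), abscess_cm = sample(3:6, 1),
      necrosis_pct = sample(c(30, 40, 50), 1))
    hpi <- fill_template(tpl$hpi, vals)
    pe <- fill_template(tpl$pe, vals)
    der <- derangement_spec(profile$pathology, profile$severity)
    admit <- as.POSIXct("2023-03-01 08:00:00", tz = "UTC")
    labs <- list()
    for (test in synthetic_workup_tests()) {
      rr <- ranges[[test]]
      labs[[length(labs) + 1L]] <- lab_result(
        canonical_name = test, raw_name = test,
        value = sample_lab_value(rr$low, rr$high, der[[test]]),
        unit = rr$unit %||% "", ref_low = rr$low, ref_high = rr$high,
        chart_time = admit + 60 * sample(10:90, 1), source = "laboratory")
    }
    fkey <- if (profile$severity == "complicated") "findings_complicated" else "findings"
    reports <- list(radiology_report(
      exam_name = tpl$exam_name, modality = tpl$modality, region = "abdomen",
      chart_time = admit + 3600 * 2, findings_text = fill_template(tpl[[fkey]], vals)))
    if (profile$severity == "complicated") {
      reports[[2]] <- radiology_report(
        exam_name = tpl$exam_name, modality = tpl$modality, region = "abdomen",
        chart_time = admit + 3600 * 30,
        findings_text = paste("Interval follow-up.", fill_template(tpl[[fkey]], vals)))
    }
    reports[[length(reports) + 1L]] <- radiology_report(
      exam_name = tpls$chest_radiograph$exam_name, modality = "Radiograph",
      region = "chest", chart_time = admit + 3600,
      findings_text = tpls$chest_radiograph$findings)
    patient_case(
      case_id = sprintf("SYN-%s-%s-%06d", toupper(substr(profile$pathology, 1, 4)),
                        substr(profile$severity, 1, 1), profile$seed),
      pathology = profile$pathology, hpi_text = hpi, physical_exam_text = pe,
      labs = labs, reports = reports,
      procedures = synthetic_procedures(profile$pathology, profile$severity),
      discharge_diagnosis_text = paste0("1. Acute ", profile$pathology,
                                        "\n2. Hypertension"))
  })
}

#' Generate a set of synthetic cases
#'
#' @param n_per_pathology cases per pathology.
#' @param seed base seed; case i of a pathology uses `seed + i - 1`.
#' @param severity severity for all cases, or `"mixed"` to alternate.
#' @return list of `patient_case` objects.
#' @export
generate_cases <- function(n_per_pathology, seed = default_seed(),
                           severity = "mixed") {
  out <- list()
  for (p in pathologies()) {
    for (i in seq_len(n_per_pathology)) {
      sev <- if (severity == "mixed") {
        if (i %% 2 == 0) "complicated" else "uncomplicated"
      } else severity
      out[[length(out) + 1L]] <- generate_case(case_profile(p, sev, seed + i - 1L))
    }
  }
  out
}

# ---- raw tables ---------------------------------------------------------

synthetic_icd10 <- function(pathology) {
  switch(pathology, appendicitis = "K3580", cholecystitis = "K8100",
         diverticulitis = "K5732", pancreatitis = "K8590")
}

case_to_raw_rows <- function(case, subject_id, hadm_id, icd_codes,
                             hpi_override = NULL, drop_pe = FALSE,
                             dd_override = NULL, drop_labs = FALSE,
                             drop_abdominal = FALSE) {
  admit <- "2023-03-01T08:00:00"
  dd <- dd_override %||% case$discharge_diagnosis_text
  sections <- c(
    paste0("Admission Date: ___\nService: SURGERY\n\nHistory of Present Illness:\n",
           hpi_override %||% case$hpi_text),
    if (!drop_pe) paste0("Physical Exam:\n", case$physical_exam_text),
    {
      ft <- Filter(function(p) !is.na(p$free_text), case$procedures)
      if (length(ft)) paste0("Major Surgical or Invasive Procedure:\n",
                             paste(vapply(ft, function(p) p$free_text, character(1)),
                                   collapse = "\n"))
    },
    paste0("Discharge Diagnosis:\n", dd),
    "Discharge Condition:\nStable")
  discharge_text <- paste(unlist(sections), collapse = "\n\n")
  dx <- data.frame(subject_id = rep(subject_id, length(icd_codes)),
                   hadm_id = rep(hadm_id, length(icd_codes)),
                   seq_num = seq_along(icd_codes), icd_code = icd_codes,
                   icd_version = rep(10L, length(icd_codes)),
                   stringsAsFactors = FALSE)
  dx <- rbind(dx, data.frame(subject_id = subject_id, hadm_id = hadm_id,
                             seq_num = nrow(dx) + 1L, icd_code = "I10",
                             icd_version = 10L, stringsAsFactors = FALSE))
  labev <- NULL
  if (!drop_labs) {
    labev <- do.call(rbind, lapply(seq_along(case$labs), function(i) {
      l <- case$labs[[i]]
      # first test arrives pre-admission and unlinked, exercising the
      # 24-hour joining rule; a duplicate later entry exercises dedup
      unlinked <- i == 1L
      data.frame(subject_id = subject_id,
                 hadm_id = if (unlinked) NA_integer_ else hadm_id,
                 itemid = i, charttime = if (unlinked) "2023-03-01T06:00:00" else l$chart_time,
                 value = as.character(l$value), valuenum = parse_lab_value(l$value),
                 valueuom = l$unit, ref_range_lower = l$ref_low,
                 ref_range_upper = l$ref_high, stringsAsFactors = FALSE)
    }))
    l1 <- case$labs[[1]]
    labev <- rbind(labev, data.frame(
      subject_id = subject_id, hadm_id = hadm_id, itemid = 1L,
      charttime = "2023-03-01T20:00:00", value = as.character(parse_lab_value(l1$value) * 0.9),
      valuenum = parse_lab_value(l1$value) * 0.9, valueuom = l1$unit,
      ref_range_lower = l1$ref_low, ref_range_upper = l1$ref_high,
      stringsAsFactors = FALSE))
  }
  d_labitems <- data.frame(itemid = seq_along(case$labs),
                           label = vapply(case$labs, function(l) l$raw_name, character(1)),
                           stringsAsFactors = FALSE)
  reports <- if (drop_abdominal) Filter(function(r) r$region != "abdomen", case$reports)
             else case$reports
  rad <- do.call(rbind, lapply(reports, function(r) {
    data.frame(subject_id = subject_id, hadm_id = hadm_id,
               exam_name = r$exam_name, charttime = r$chart_time,
               text = paste0("EXAMINATION: ", r$exam_name, "\n\nFINDINGS:\n",
                             r$findings_text,
                             "\n\nIMPRESSION:\nClinical correlation recommended."),
               stringsAsFactors = FALSE)
  }))
  coded <- Filter(function(p) !is.na(p$code), case$procedures)
  proc <- if (length(coded)) {
    data.frame(subject_id = subject_id, hadm_id = hadm_id,
               icd_code = vapply(coded, function(p) p$code, character(1)),
               icd_version = 10L, stringsAsFactors = FALSE)
  } else NULL
  list(
    admissions = data.frame(subject_id = subject_id, hadm_id = hadm_id,
                            admittime = admit, stringsAsFactors = FALSE),
    diagnoses_icd = dx, labevents = labev, d_labitems = d_labitems,
    radiology = rad, procedures_icd = proc,
    discharge_text = discharge_text)
}

empty_raw_tables <- function() {
  list(
    admissions = data.frame(subject_id = integer(0), hadm_id = integer(0),
                            admittime = character(0), stringsAsFactors = FALSE),
    diagnoses_icd = data.frame(subject_id = integer(0), hadm_id = integer(0),
                               seq_num = integer(0), icd_code = character(0),
                               icd_version = integer(0), stringsAsFactors = FALSE),
    d_labitems = data.frame(itemid = integer(0), label = character(0),
                            stringsAsFactors = FALSE),
    labevents = data.frame(subject_id = integer(0), hadm_id = integer(0),
                           itemid = integer(0), charttime = character(0),
                           value = character(0), valuenum = numeric(0),
                           valueuom = character(0), ref_range_lower = numeric(0),
                           ref_range_upper = numeric(0), stringsAsFactors = FALSE),
    microbiologyevents = data.frame(subject_id = integer(0), hadm_id = integer(0),
                                    charttime = character(0), test_name = character(0),
                                    result = character(0), stringsAsFactors = FALSE),
    procedures_icd = data.frame(subject_id = integer(0), hadm_id = integer(0),
                                icd_code = character(0), icd_version = integer(0),
                                stringsAsFactors = FALSE),
    discharge = data.frame(subject_id = integer(0), hadm_id = integer(0),
                           text = character(0), stringsAsFactors = FALSE),
    radiology = data.frame(subject_id = integer(0), hadm_id = integer(0),
                           exam_name = character(0), charttime = character(0),
                           text = character(0), stringsAsFactors = FALSE)
  )
}

#' Exclusion-rule reasons a violation plan can plant
#'
#' @return character vector of plantable drop reasons.
#' @export
violation_reasons <- function() {
  c("no_target_code", "multiple_target_codes", "no_discharge_diagnosis",
    "secondary_discharge_diagnosis", "no_physical_exam", "pathology_in_hpi",
    "no_labs", "no_abdominal_imaging")
}

#' Generate MIMIC-IV-shaped raw tables
#'
#' Emits a set of relational tables that the dataset builder consumes. The
#' clean admissions (n per pathology) survive every filter; each entry of
#' `violation_plan` plants one extra admission that trips exactly the named
#' exclusion rule and no other.
#'
#' @param n_per_pathology clean admissions per pathology.
#' @param seed base seed.
#' @param violation_plan optional character vector of reasons from
#'   [violation_reasons()].
#' @return named list of data frames (see [as_bundles()]).
#' @export
generate_raw_tables <- function(n_per_pathology, seed = default_seed(),
                                violation_plan = NULL) {
  stopifnot(n_per_pathology >= 0)
  if (!is.null(violation_plan)) {
    bad <- setdiff(violation_plan, violation_reasons())
    if (length(bad)) stop("unknown violation reason(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  tabs <- empty_raw_tables()
  add <- function(rows) {
    for (nm in c("admissions", "diagnoses_icd", "labevents", "radiology",
                 "procedures_icd")) {
      if (!is.null(rows[[nm]])) tabs[[nm]] <<- rbind(tabs[[nm]], rows[[nm]])
    }
    # lab item dictionary is shared across admissions; keep the union
    if (!is.null(rows$d_labitems)) {
      di <- rbind(tabs$d_labitems, rows$d_labitems)
      tabs$d_labitems <<- di[!duplicated(di$itemid), , drop = FALSE]
    }
    invisible(NULL)
  }
  next_id <- 1L
  for (p in pathologies()) {
    for (i in seq_len(n_per_pathology)) {
      sev <- if (i %% 2 == 0) "complicated" else "uncomplicated"
      case <- generate_case(case_profile(p, sev, seed + i - 1L))
      rows <- case_to_raw_rows(case, subject_id = next_id,
                               hadm_id = 10000L + next_id,
                               icd_codes = synthetic_icd10(p))
      disc <- build_discharge_row(rows, case, next_id, 10000L + next_id)
      add(rows)
      tabs$discharge <- rbind(tabs$discharge, disc)
      next_id <- next_id + 1L
    }
  }
  for (reason in violation_plan) {
    case <- generate_case(case_profile("appendicitis", "uncomplicated",
                                       seed + 500L + next_id))
    hadm <- 10000L + next_id
    args <- list(case = case, subject_id = next_id, hadm_id = hadm,
                 icd_codes = synthetic_icd10("appendicitis"))
    if (reason == "no_target_code") args$icd_codes <- character(0)
    if (reason == "multiple_target_codes") {
      args$icd_codes <- c(synthetic_icd10("appendicitis"), synthetic_icd10("pancreatitis"))
    }
    if (reason == "no_discharge_diagnosis") args$dd_override <- " "
    if (reason == "secondary_discharge_diagnosis") {
      args$dd_override <- "1. Sepsis\n2. Acute appendicitis"
    }
    if (reason == "no_physical_exam") args$drop_pe <- TRUE
    if (reason == "pathology_in_hpi") {
      args$hpi_override <- paste(case$hpi_text,
                                 "Prior episode of appendicitis suspected.")
    }
    if (reason == "no_labs") args$drop_labs <- TRUE
    if (reason == "no_abdominal_imaging") args$drop_abdominal <- TRUE
    rows <- do.call(case_to_raw_rows, args)
    if (reason == "no_target_code") {
      rows$diagnoses_icd <- rows$diagnoses_icd[rows$diagnoses_icd$icd_code == "I10", ,
                                               drop = FALSE]
    }
    disc <- build_discharge_row(rows, case, next_id, hadm)
    add(rows)
    tabs$discharge <- rbind(tabs$discharge, disc)
    next_id <- next_id + 1L
  }
  tabs
}

build_discharge_row <- function(rows, case, subject_id, hadm_id) {
  data.frame(subject_id = subject_id, hadm_id = hadm_id,
             text = rows$discharge_text, stringsAsFactors = FALSE)
}

#' Write raw tables as a directory of CSV files
#'
#' @param tables from [generate_raw_tables()].
#' @param dir destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_raw_tables <- function(tables, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(tables)) {
    utils::write.csv(tables[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE, na = "")
  }
  invisible(dir)
}

# ---- interpretation items ----------------------------------------------

#' Generate labeled laboratory interpretation items
#'
#' Items ask whether a value lies below, within or above its reference
#' range (inclusive bounds). Labels are balanced by construction and the
#' set includes exact-boundary items (value equal to a bound), which are
#' labeled "within" under the inclusive convention.
#'
#' @param n number of items.
#' @param seed RNG seed.
#' @return data frame: test, value, ref_low, ref_high, gold_label.
#' @export
generate_interpretation_set <- function(n, seed = default_seed()) {
  stopifnot(n >= 0)
  ranges <- load_reference_ranges()
  numeric_tests <- names(Filter(function(r) !is.null(r$low) && !is.null(r$high), ranges))
  if (n == 0L) {
    return(data.frame(test = character(0), value = numeric(0),
                      ref_low = numeric(0), ref_high = numeric(0),
                      gold_label = character(0), stringsAsFactors = FALSE))
  }
  with_seed(seed, {
    labels <- sample(rep(c("below", "within", "above"), length.out = n))
    rows <- lapply(seq_len(n), function(i) {
      test <- sample(numeric_tests, 1)
      rr <- ranges[[test]]
      lo <- rr$low
      hi <- rr$high
      w <- max(hi - lo, 0.1)
      value <- switch(labels[i],
        below = round(lo - stats::runif(1, 0.01, 1) * w, 3),
        above = round(hi + stats::runif(1, 0.01, 1) * w, 3),
        within = {
          u <- stats::runif(1)
          # one in five "within" items sits exactly on a bound
          if (u < 0.1) lo else if (u < 0.2) hi
          else round(stats::runif(1, lo, hi), 3)
        })
      data.frame(test = test, value = value, ref_low = lo, ref_high = hi,
                 gold_label = labels[i], stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

# ---- scripted agents ----------------------------------------------------

#' Deterministic scripted agent
#'
#' Returns the scripted response strings in order, ignoring the prompt —
#' a stand-in for a language model that makes episodes exactly
#' reproducible. When the script runs out before the episode ends, the
#' agent emits a final-diagnosis turn with the configured fallback. The
#' agent exposes a trivial first-words summarizer for the summarization
#' protocol.
#'
#' @param script character vector of raw responses (well-formed or
#'   deliberately malformed).
#' @param fallback_diagnosis diagnosis used when the script is exhausted.
#' @param summary_words words kept by the exposed summarizer.
#' @return agent callable `(prompt, stop_phrases) -> text`.
#' @export
scripted_agent <- function(script, fallback_diagnosis = "undifferentiated abdominal pain",
                           summary_words = 30) {
  i <- 0L
  agent <- function(prompt, stop_phrases = character(0)) {
    i <<- i + 1L
    if (i <= length(script)) {
      script[[i]]
    } else {
      paste0("Final Diagnosis: ", fallback_diagnosis,
             "\nTreatment: supportive care with fluids and monitoring")
    }
  }
  attr(agent, "summarizer") <- function(text) trim_words(text, summary_words)
  agent
}

#' Guideline-following ("omniscient") scripted agent for a case
#'
#' Requests the physical examination first, then at least one test from
#' every required laboratory category of the case's pathology, then
#' abdominal imaging, and finally states the gold pathology with the full
#' expected treatment text. Used as a positive control: it must score 100%
#' on every metric.
#'
#' @param case a `patient_case`.
#' @param guideline from [load_guidelines()].
#' @return agent callable.
#' @export
omniscient_agent <- function(case, guideline = load_guidelines()) {
  g <- guideline$pathologies[[case$pathology]]
  tests <- unlist(lapply(g$required_lab_categories, function(ms) ms))
  script <- c(
    "Thoughts: I will examine the patient first.\nAction: Physical Examination\nAction Input:",
    paste0("Thoughts: I need the guideline laboratory workup.\nAction: Laboratory Tests\nAction Input: ",
           paste(unique(tests), collapse = ", ")),
    "Thoughts: Imaging will confirm the diagnosis.\nAction: Imaging\nAction Input: CT abdomen",
    paste0("Thoughts: The findings are conclusive.\nFinal Diagnosis: Acute ",
           case$pathology, "\nTreatment: ",
           expected_treatment_text(case, guideline)))
  scripted_agent(script)
}

#' Full expected treatment text for a case
#'
#' Concatenates every treatment the guideline expects for this patient:
#' all essential treatments, the case-specific treatments the patient
#' actually received (matched against the procedure records), and all
#' three supportive-care elements.
#'
#' @param case a `patient_case`.
#' @param guideline from [load_guidelines()].
#' @return treatment text.
#' @export
expected_treatment_text <- function(case, guideline = load_guidelines()) {
  g <- guideline$pathologies[[case$pathology]]
  parts <- character(0)
  for (nm in names(g$essential_treatments)) {
    parts <- c(parts, g$essential_treatments[[nm]]$keywords[[1]])
  }
  for (nm in names(g$case_specific_treatments)) {
    ct <- g$case_specific_treatments[[nm]]
    if (patient_received(case$procedures, ct$procedure_pattern)) {
      parts <- c(parts, ct$keywords[[1]])
    }
  }
  paste0(paste(parts, collapse = ", "),
         if (length(parts)) ", " else "",
         "IV fluids, pain management with analgesia, and close monitoring of vital signs")
}

#' Random imperfect scripted agent
#'
#' Draws a randomized action script (valid requests, free-text requests,
#' hallucinated tools, malformed turns) followed by a diagnosis attempt;
#' used to stress protocol conformance.
#'
#' @param case a `patient_case` (the diagnosis attempt may or may not be
#'   correct).
#' @param seed RNG seed.
#' @param n_actions number of action turns before the final turn.
#' @return agent callable.
#' @export
random_scripted_agent <- function(case, seed, n_actions = 4) {
  with_seed(seed, {
    pool <- c(
      "Thoughts: exam\nAction: Physical Examination\nAction Input:",
      "Thoughts: labs\nAction: Laboratory Tests\nAction Input: CBC, lipase and lactate",
      "Thoughts: labs\nAction: Laboratory Tests\nAction Input: quantum flux assay",
      "Thoughts: scan\nAction: Imaging\nAction Input: CT abdomen",
      "Thoughts: scan\nAction: Imaging\nAction Input: abdominal ultrasound",
      "I would like to perform a physical examination now.",
      "Thoughts: hmm\nAction: Crystal Ball\nAction Input: future",
      "",
      "Thoughts: more labs\nAction: Laboratory Tests\nAction Input: liver function panel")
    script <- sample(pool, n_actions, replace = TRUE)
    diag <- sample(c(paste0("Final Diagnosis: acute ", case$pathology,
                            "\nTreatment: antibiotics, fluids, monitoring"),
                     "Final Diagnosis: gastroenteritis\nTreatment: fluids",
                     "Final Diagnosis: appendicitis"), 1)
    scripted_agent(c(script, diag))
  })
}
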