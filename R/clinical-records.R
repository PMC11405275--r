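# Core data model: patient cases, their component records, and episode
# transcripts, with validation and line-oriented (JSON lines) storage.

#' Construct a laboratory result
#'
#' @param canonical_name canonical test name (lexicon vocabulary).
#' @param raw_name the name as it appeared in the source table.
#' @param value the raw value, numeric or text (qualitative results and
#'   censored values such as `"<0.1"` keep their text form).
#' @param unit unit string, possibly empty.
#' @param ref_low,ref_high optional numeric reference bounds (inclusive).
#' @param chart_time ISO-8601 timestamp string (or POSIXct).
#' @param source `"laboratory"` or `"microbiology"`.
#'
#' @details A parsed numeric value is carried alongside the raw value when
#' the text is parseable (a leading `<` or `>` is tolerated), so that
#' interpretation code sees numbers while transcripts keep fidelity.
#'
#' @return A `lab_result` object.
#' @export
lab_result <- function(canonical_name, raw_name = canonical_name, value,
                       unit = "", ref_low = NA_real_, ref_high = NA_real_,
                       chart_time, source = "laboratory") {
  source <- match.arg(source, c("laboratory", "microbiology"))
  ref_low <- suppressWarnings(as.numeric(ref_low %||% NA_real_))
  ref_high <- suppressWarnings(as.numeric(ref_high %||% NA_real_))
  if (!is.na(ref_low) && !is.na(ref_high) && ref_low > ref_high) {
    stop("lab_result '", canonical_name, "': ref_low > ref_high", call. = FALSE)
  }
  if (missing(chart_time) || is.null(chart_time) || is.na(chart_time)) {
    stop("lab_result '", canonical_name, "': chart_time is required", call. = FALSE)
  }
  structure(list(
    canonical_name = as.character(canonical_name),
    raw_name = as.character(raw_name),
    value = if (is.numeric(value)) as.numeric(value) else as.character(value),
    value_num = parse_lab_value(value),
    unit = as.character(unit %||% ""),
    ref_low = ref_low,
    ref_high = ref_high,
    chart_time = as_iso_time(chart_time),
    source = source
  ), class = "lab_result")
}

#' Parse a possibly textual lab value to a number
#'
#' @param value numeric or character scalar.
#' @return numeric scalar, `NA` when not parseable (qualitative results).
#' @export
parse_lab_value <- function(value) {
  if (is.numeric(value)) return(as.numeric(value))
  v <- trimws(as.character(value))
  v <- sub("^[<>]=?\\s*", "", v)
  suppressWarnings(as.numeric(v))
}

as_iso_time <- function(t) {
  if (inherits(t, "POSIXt")) return(format(t, "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
  as.character(t)
}

parse_iso_time <- function(t) {
  as.POSIXct(t, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
}

#' Construct a radiology report
#'
#' Only the findings section of a report is retained; impression and
#' conclusion sections carry the radiologist's diagnosis and are excluded
#' upstream so the diagnostic task stays non-trivial.
#'
#' @param exam_name source exam name, e.g. `"CT ABDOMEN W/O CONTRAST"`.
#' @param modality one of CT, Ultrasound, MRI, Radiograph.
#' @param region anatomical region keyword (e.g. `"abdomen"`, `"chest"`).
#' @param chart_time ISO-8601 timestamp string (or POSIXct).
#' @param findings_text non-empty findings section text.
#' @return A `radiology_report` object.
#' @export
radiology_report <- function(exam_name, modality, region, chart_time, findings_text) {
  modality <- match.arg(modality, c("CT", "Ultrasound", "MRI", "Radiograph"))
  if (!nzchar(trimws(findings_text))) {
    stop("radiology_report '", exam_name, "': findings_text must be non-empty", call. = FALSE)
  }
  structure(list(
    exam_name = as.character(exam_name),
    modality = modality,
    region = as.character(region),
    chart_time = as_iso_time(chart_time),
    findings_text = as.character(findings_text)
  ), class = "radiology_report")
}

#' Construct a procedure record
#'
#' @param code optional ICD-9/ICD-10 procedure code.
#' @param free_text optional free-text procedure description.
#' @param source `"coded_table"` or `"discharge_summary"`.
#' @return A `procedure_record` object.
#' @export
procedure_record <- function(code = NULL, free_text = NULL, source = "coded_table") {
  source <- match.arg(source, c("coded_table", "discharge_summary"))
  has_code <- length(code) == 1 && !is.na(code) && nzchar(code)
  has_text <- length(free_text) == 1 && !is.na(free_text) && nzchar(free_text)
  if (!has_code && !has_text) {
    stop("procedure_record: at least one of code/free_text is required", call. = FALSE)
  }
  structure(list(
    code = if (has_code) as.character(code) else NA_character_,
    free_text = if (has_text) as.character(free_text) else NA_character_,
    source = source
  ), class = "procedure_record")
}

#' Construct a patient case
#'
#' One emergency-department admission: the hidden gold pathology plus all
#' information the environment may serve to an agent. Invariants are
#' enforced at construction: labs non-empty, at least one abdominal report,
#' a non-empty physical examination, and a history of present illness free
#' of any mention of the gold pathology (such mentions must have been
#' censored to `"___"` upstream).
#'
#' @param case_id unique identifier.
#' @param pathology one of [pathologies()]; hidden from agents.
#' @param hpi_text history of present illness.
#' @param physical_exam_text physical examination section.
#' @param labs list of [lab_result()] objects (non-empty).
#' @param reports list of [radiology_report()] objects (at least one with
#'   region `"abdomen"`).
#' @param procedures list of [procedure_record()] objects.
#' @param discharge_diagnosis_text discharge diagnosis section; hidden.
#' @param synonyms optional extra phrasings scanned for in the censoring
#'   check, in addition to the pathology name itself (defaults to the
#'   shipped diagnosis lexicon's phrasings for the pathology).
#' @return A `patient_case` object.
#' @export
patient_case <- function(case_id, pathology, hpi_text, physical_exam_text,
                         labs, reports, procedures = list(),
                         discharge_diagnosis_text = "", synonyms = NULL) {
  case <- structure(list(
    case_id = as.character(case_id),
    pathology = match.arg(pathology, pathologies()),
    hpi_text = as.character(hpi_text),
    physical_exam_text = as.character(physical_exam_text),
    labs = labs,
    reports = reports,
    procedures = procedures,
    discharge_diagnosis_text = as.character(discharge_diagnosis_text)
  ), class = "patient_case")
  validate_case(case, synonyms = synonyms)
  case
}

#' Validate a patient case
#'
#' @param case a `patient_case`.
#' @param synonyms optional phrasings for the censoring scan (see
#'   [patient_case()]).
#' @return the case, invisibly; errors describe the violated invariant.
#' @export
validate_case <- function(case, synonyms = NULL) {
  if (!length(case$labs)) {
    stop("case ", case$case_id, ": labs must be non-empty", call. = FALSE)
  }
  for (l in case$labs) {
    if (!is.na(l$ref_low) && !is.na(l$ref_high) && l$ref_low > l$ref_high) {
      stop("case ", case$case_id, ": lab '", l$canonical_name,
           "' has ref_low > ref_high", call. = FALSE)
    }
  }
  regions <- vapply(case$reports, function(r) r$region, character(1))
  if (!any(regions == "abdomen")) {
    stop("case ", case$case_id, ": at least one abdominal report is required",
         call. = FALSE)
  }
  if (!nzchar(trimws(case$physical_exam_text))) {
    stop("case ", case$case_id, ": physical_exam_text must be non-empty",
         call. = FALSE)
  }
  terms <- synonyms %||% tryCatch(
    default_diagnosis_lexicon()[[case$pathology]], error = function(e) NULL)
  terms <- unique(c(case$pathology, terms))
  hpi_norm <- normalize_text(case$hpi_text)
  for (term in terms) {
    if (contains_term(hpi_norm, normalize_text(term))) {
      stop("case ", case$case_id, ": hpi_text mentions the gold pathology ('",
           term, "'); mentions must be censored to '___'", call. = FALSE)
    }
  }
  invisible(case)
}

#' @export
print.patient_case <- function(x, ...) {
  cat("<patient_case> ", x$case_id, " [", x$pathology, "]\n",
      "  labs: ", length(x$labs),
      "  reports: ", length(x$reports),
      "  procedures: ", length(x$procedures), "\n", sep = "")
  invisible(x)
}

# ---- line-oriented case store -------------------------------------------

case_to_record <- function(case) {
  list(
    case_id = case$case_id,
    hpi_text = case$hpi_text,
    physical_exam_text = case$physical_exam_text,
    labs = lapply(case$labs, unclass),
    reports = lapply(case$reports, unclass),
    procedures = lapply(case$procedures, unclass),
    # hidden fields live under one clearly marked key so serving code can
    # withhold them wholesale
    hidden = list(
      pathology = case$pathology,
      discharge_diagnosis_text = case$discharge_diagnosis_text
    )
  )
}

record_to_case <- function(rec, index) {
  need <- c("case_id", "hpi_text", "physical_exam_text", "labs", "reports", "hidden")
  missing_f <- setdiff(need, names(rec))
  if (length(missing_f)) {
    stop("record ", index, ": missing field(s) ", paste(missing_f, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(rec$physical_exam_text) || !nzchar(trimws(rec$physical_exam_text))) {
    stop("record ", index, ": field physical_exam_text is empty", call. = FALSE)
  }
  labs <- lapply(rec$labs, function(l) {
    lab_result(l$canonical_name, l$raw_name, l$value, l$unit %||% "",
               l$ref_low %||% NA_real_, l$ref_high %||% NA_real_,
               l$chart_time, l$source %||% "laboratory")
  })
  reports <- lapply(rec$reports, function(r) {
    radiology_report(r$exam_name, r$modality, r$region, r$chart_time, r$findings_text)
  })
  procedures <- lapply(rec$procedures %||% list(), function(p) {
    procedure_record(p$code, p$free_text, p$source %||% "coded_table")
  })
  patient_case(rec$case_id, rec$hidden$pathology, rec$hpi_text,
               rec$physical_exam_text, labs, reports, procedures,
               rec$hidden$discharge_diagnosis_text %||% "")
}

#' Write patient cases to a line-oriented record file
#'
#' One JSON record per line, so large case sets can stream without loading
#' everything to serve one case. A `.gz` destination is written compressed.
#' Every case is validated before anything is written; hidden fields
#' (pathology, discharge diagnosis) are stored under the `hidden` key.
#'
#' @param cases list of `patient_case` objects.
#' @param destination file path (`.jsonl` or `.jsonl.gz`).
#' @return number of records written, invisibly.
#' @export
write_cases <- function(cases, destination) {
  for (case in cases) validate_case(case)
  lines <- vapply(cases, function(case) {
    tryCatch(
      as.character(jsonlite::toJSON(case_to_record(case), auto_unbox = TRUE,
                                    null = "null", na = "null", digits = NA)),
      error = function(e) stop("case ", case$case_id, ": not serializable: ",
                               conditionMessage(e), call. = FALSE))
  }, character(1))
  con <- if (grepl("\\.gz$", destination)) gzfile(destination, "wb") else file(destination, "wb")
  on.exit(close(con))
  if (length(lines)) writeLines(lines, con) else writeLines(character(0), con)
  invisible(length(lines))
}

#' Read patient cases from a record file
#'
#' Re-validates every invariant on load, including the censoring scan of
#' the history of present illness for the gold pathology name.
#'
#' @param source path written by [write_cases()] (gzip accepted).
#' @return list of `patient_case` objects.
#' @export
read_cases <- function(source) {
  con <- if (grepl("\\.gz$", source)) gzfile(source, "rb") else file(source, "rb")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(i) {
    rec <- jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE)
    record_to_case(rec, i)
  })
}

# ---- episodes -----------------------------------------------------------

#' Write episode transcripts to a line-oriented log file
#'
#' @param episodes list of `episode` objects from [run_episode()].
#' @param destination file path.
#' @return number of records written, invisibly.
#' @export
write_episodes <- function(episodes, destination) {
  lines <- vapply(episodes, function(ep) {
    as.character(jsonlite::toJSON(unclass(ep), auto_unbox = TRUE, null = "null",
                                  na = "null", digits = NA))
  }, character(1))
  writeLines(lines, destination)
  invisible(length(lines))
}

#' Read episode transcripts written by [write_episodes()]
#'
#' @param source file path.
#' @return list of `episode` objects.
#' @export
read_episodes <- function(source) {
  lines <- readLines(source, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(l) {
    ep <- jsonlite::fromJSON(l, simplifyVector = FALSE)
    ep$turns <- lapply(ep$turns, function(t) {
      t$format_flags <- as.character(unlist(t$format_flags))
      t
    })
    ep$observations <- as.character(unlist(ep$observations))
    ep$requested_labs <- as.character(unlist(ep$requested_labs))
    ep$error_counts <- lapply(ep$error_counts, as.integer)
    structure(ep, class = "episode")
  })
}
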