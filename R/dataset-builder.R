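# Dataset builder: turns MIMIC-IV-style relational tables (real exports or
# synthetic ones from generate_raw_tables()) into validated patient cases,
# applying the inclusion window, deduplication, censoring and exclusion
# rules, and producing a telescoping build report.

#' Load ICD code prefixes for the target pathologies
#'
#' @param path YAML file; default is the shipped, replaceable reconstruction
#'   of the ICD-9/ICD-10 families for the four pathologies.
#' @return named list: pathology -> list(icd9 =, icd10 =) of code prefixes.
#' @export
load_icd_codes <- function(path = NULL) {
  cfg <- yaml::read_yaml(path %||% config_path("icd_codes.yaml"))
  for (p in pathologies()) {
    if (is.null(cfg[[p]]) || (!length(cfg[[p]]$icd9) && !length(cfg[[p]]$icd10))) {
      stop("icd code configuration: empty code set for ", p, call. = FALSE)
    }
  }
  cfg
}

# Match one admission's coded diagnoses against the target code prefixes.
matched_pathologies <- function(icd_codes, icd_versions, code_sets) {
  codes <- toupper(gsub(".", "", as.character(icd_codes), fixed = TRUE))
  hit <- character(0)
  for (p in names(code_sets)) {
    pre <- toupper(gsub(".", "", c(unlist(code_sets[[p]]$icd9),
                                   unlist(code_sets[[p]]$icd10)), fixed = TRUE))
    if (any(vapply(codes, function(cd) any(startsWith(cd, pre)), logical(1)))) {
      hit <- c(hit, p)
    }
  }
  hit
}

#' Group raw tables into per-admission bundles
#'
#' @param tables named list of MIMIC-IV-shaped data frames: `admissions`,
#'   `diagnoses_icd`, `d_labitems`, `labevents`, `microbiologyevents`,
#'   `procedures_icd`, `discharge`, `radiology` (column conventions are
#'   documented in the package README). Lab and radiology rows may have a
#'   missing `hadm_id`: they are attached to an admission only when the
#'   subject matches and the timestamp falls in the pre-admission window.
#' @return list of raw admission bundles.
#' @export
as_bundles <- function(tables) {
  adm <- tables$admissions
  lapply(seq_len(nrow(adm)), function(i) {
    hadm <- adm$hadm_id[i]
    subj <- adm$subject_id[i]
    dx <- tables$diagnoses_icd[tables$diagnoses_icd$hadm_id == hadm, , drop = FALSE]
    dx <- dx[order(dx$seq_num), , drop = FALSE]
    disc <- tables$discharge[tables$discharge$hadm_id == hadm, , drop = FALSE]
    le <- tables$labevents
    le_link <- le[!is.na(le$hadm_id) & le$hadm_id == hadm, , drop = FALSE]
    le_unlk <- le[is.na(le$hadm_id) & le$subject_id == subj, , drop = FALSE]
    mb <- tables$microbiologyevents
    mb_link <- mb[!is.na(mb$hadm_id) & mb$hadm_id == hadm, , drop = FALSE]
    mb_unlk <- mb[is.na(mb$hadm_id) & mb$subject_id == subj, , drop = FALSE]
    rad <- tables$radiology
    rad_link <- rad[!is.na(rad$hadm_id) & rad$hadm_id == hadm, , drop = FALSE]
    rad_unlk <- rad[is.na(rad$hadm_id) & rad$subject_id == subj, , drop = FALSE]
    pr <- tables$procedures_icd[tables$procedures_icd$hadm_id == hadm, , drop = FALSE]
    list(
      patient_id = subj,
      admission_id = hadm,
      admit_time = adm$admittime[i],
      icd_diagnoses = dx,
      discharge_summary_text = if (nrow(disc)) disc$text[1] else "",
      lab_events = list(linked = le_link, unlinked = le_unlk),
      microbiology_events = list(linked = mb_link, unlinked = mb_unlk),
      radiology_notes = list(linked = rad_link, unlinked = rad_unlk),
      coded_procedures = pr,
      d_labitems = tables$d_labitems
    )
  })
}

#' Filter admissions to single-target-pathology candidates
#'
#' Keeps admissions carrying at least one diagnosis code of exactly one
#' target pathology; admissions coded for more than one target are dropped
#' (ambiguous gold label), as are admissions with no target code.
#'
#' @param bundles list from [as_bundles()].
#' @param icd_code_sets from [load_icd_codes()].
#' @return list with `kept` (bundles, each gaining a `candidate_pathology`
#'   field) and `reasons` (named drop counts).
#' @export
filter_target_admissions <- function(bundles, icd_code_sets = load_icd_codes()) {
  kept <- list()
  reasons <- c(no_target_code = 0L, multiple_target_codes = 0L)
  for (b in bundles) {
    hits <- matched_pathologies(b$icd_diagnoses$icd_code,
                                b$icd_diagnoses$icd_version, icd_code_sets)
    if (length(hits) == 0L) {
      reasons[["no_target_code"]] <- reasons[["no_target_code"]] + 1L
    } else if (length(hits) > 1L) {
      reasons[["multiple_target_codes"]] <- reasons[["multiple_target_codes"]] + 1L
    } else {
      b$candidate_pathology <- hits
      kept[[length(kept) + 1L]] <- b
    }
  }
  list(kept = kept, reasons = reasons)
}

default_section_patterns <- function() {
  list(
    hpi = "history of present illness",
    physical_exam = "physical exam(?:ination)?(?: on admission)?",
    discharge_diagnosis = "discharge diagnos(?:is|es)",
    free_text_procedures = "major surgical or invasive procedure"
  )
}

# All header patterns used to delimit section ends, targets included.
all_header_patterns <- function(section_patterns) {
  unique(c(unlist(section_patterns),
           "chief complaint", "past medical history", "social history",
           "family history", "allergies", "medications on admission",
           "discharge medications", "brief hospital course",
           "pertinent results", "discharge condition",
           "discharge disposition", "discharge instructions",
           "followup instructions", "admission date", "service", "attending",
           "impression", "imaging", "labs on admission"))
}

#' Split a discharge summary into its sections
#'
#' Locates configurable header patterns (matched case-insensitively at line
#' starts, followed by a colon) and returns the text span from each target
#' header to the next recognized header. Absent sections come back as `NA`;
#' absence is handled by the exclusion rules downstream.
#'
#' @param text full discharge summary.
#' @param patterns named list of regex patterns for the target sections
#'   (defaults cover common discharge-summary conventions).
#' @return named list: `hpi`, `physical_exam`, `discharge_diagnosis`,
#'   `free_text_procedures` (character or `NA`).
#' @export
extract_sections <- function(text, patterns = default_section_patterns()) {
  headers <- all_header_patterns(patterns)
  master <- paste0("(?im)^[ \t]*(", paste(headers, collapse = "|"), ")[ \t]*:")
  m <- gregexpr(master, text, perl = TRUE)[[1]]
  out <- stats::setNames(vector("list", length(patterns)), names(patterns))
  for (nm in names(patterns)) out[[nm]] <- NA_character_
  if (m[1] == -1) return(out)
  starts <- as.integer(m)
  ends <- starts + attr(m, "match.length") - 1L
  next_start <- c(starts[-1] - 1L, nchar(text))
  for (nm in names(patterns)) {
    pat <- paste0("(?i)^[ \t]*", patterns[[nm]], "[ \t]*:")
    for (j in seq_along(starts)) {
      hdr <- substr(text, starts[j], ends[j])
      if (grepl(pat, sub("^\n+", "", hdr), perl = TRUE)) {
        span <- substr(text, ends[j] + 1L, next_start[j])
        span <- trimws(span)
        out[[nm]] <- if (nzchar(span)) span else NA_character_
        break
      }
    }
  }
  out
}

#' Check that the first discharge diagnosis is the candidate pathology
#'
#' The discharge-diagnosis section is segmented; the very first diagnosis
#' listed must match the candidate pathology. Any other diagnosis written
#' before a target means the admission is removed.
#'
#' @param discharge_diagnosis_text section text (or `NA`).
#' @param candidate the candidate pathology from the code filter.
#' @param lexicon diagnosis lexicon.
#' @return list(keep = flag, reason = NA or drop reason).
#' @export
check_primary_discharge_diagnosis <- function(discharge_diagnosis_text, candidate,
                                              lexicon = load_diagnosis_lexicon()) {
  if (is.null(discharge_diagnosis_text) || is.na(discharge_diagnosis_text) ||
      !nzchar(trimws(discharge_diagnosis_text))) {
    return(list(keep = FALSE, reason = "no_discharge_diagnosis"))
  }
  segs <- segment_diagnoses(discharge_diagnosis_text)
  if (!length(segs)) {
    return(list(keep = FALSE, reason = "no_discharge_diagnosis"))
  }
  if (match_diagnosis(segs[[1]], candidate, lexicon)) {
    list(keep = TRUE, reason = NA_character_)
  } else {
    list(keep = FALSE, reason = "secondary_discharge_diagnosis")
  }
}

in_window <- function(chart_time, admit_time, window_hours) {
  ct <- parse_iso_time(as_iso_time(chart_time))
  at <- parse_iso_time(as_iso_time(admit_time))
  !is.na(ct) & ct >= (at - window_hours * 3600) & ct <= at
}

#' Collect a bundle's laboratory and microbiology results
#'
#' Includes events linked to the admission plus unlinked events (no
#' admission id) up to `window_hours` before admission — events linked to a
#' different admission never appear in the bundle's unlinked pool. When a
#' test was recorded repeatedly, only the chronologically first entry is
#' kept (therapy-naive snapshot); ties are broken by source row order.
#'
#' @param bundle a raw admission bundle.
#' @param window_hours pre-admission inclusion window (default 24, both
#'   ends included).
#' @param lab_lexicon used to canonicalize test labels when possible.
#' @return list of [lab_result()] objects.
#' @export
collect_labs <- function(bundle, window_hours = 24, lab_lexicon = load_lab_lexicon()) {
  items <- bundle$d_labitems
  label_of <- function(itemid) {
    i <- match(itemid, items$itemid)
    if (is.na(i)) paste0("item ", itemid) else items$label[i]
  }
  rows <- list()
  add_rows <- function(df, source) {
    for (i in seq_len(nrow(df))) {
      if (source == "laboratory") {
        raw <- label_of(df$itemid[i])
        val <- if (!is.na(df$valuenum[i])) df$valuenum[i] else df$value[i]
        unit <- df$valueuom[i] %||% ""
        lo <- df$ref_range_lower[i]
        hi <- df$ref_range_upper[i]
      } else {
        raw <- df$test_name[i]
        val <- df$result[i]
        unit <- ""
        lo <- NA_real_
        hi <- NA_real_
      }
      canon <- match_lab_request(raw, lab_lexicon)
      canon <- if (length(canon) == 1L) canon else normalize_text(raw)
      rows[[length(rows) + 1L]] <<- lab_result(
        canonical_name = canon, raw_name = raw, value = val,
        unit = if (is.na(unit)) "" else unit, ref_low = lo, ref_high = hi,
        chart_time = df$charttime[i], source = source)
    }
  }
  le <- bundle$lab_events
  add_rows(le$linked, "laboratory")
  add_rows(le$unlinked[in_window(le$unlinked$charttime, bundle$admit_time, window_hours), ,
                       drop = FALSE], "laboratory")
  mb <- bundle$microbiology_events
  if (nrow(mb$linked)) add_rows(mb$linked, "microbiology")
  keep_mb <- in_window(mb$unlinked$charttime, bundle$admit_time, window_hours)
  if (any(keep_mb)) add_rows(mb$unlinked[keep_mb, , drop = FALSE], "microbiology")
  dedupe_first_entry(rows)
}

# First chronological entry per canonical test; stable for ties.
dedupe_first_entry <- function(rows) {
  if (!length(rows)) return(rows)
  key <- vapply(rows, function(r) r$canonical_name, character(1))
  tm <- vapply(rows, function(r) r$chart_time, character(1))
  ord <- order(tm, seq_along(rows))
  seen <- character(0)
  out <- list()
  for (i in ord) {
    if (!(key[i] %in% seen)) {
      seen <- c(seen, key[i])
      out[[length(out) + 1L]] <- rows[[i]]
    }
  }
  out
}

#' Extract the findings section of a radiology report
#'
#' Everything from a FINDINGS header to the next IMPRESSION/CONCLUSION
#' header (or end of note). Impression and conclusion are discarded: they
#' contain the radiologist's diagnosis.
#'
#' @param text full radiology note text.
#' @return findings text, or `NA` when there is none.
#' @export
extract_findings <- function(text) {
  m <- regexpr("(?im)^[ \t]*findings?[ \t]*:", text, perl = TRUE)
  if (m[1] == -1) return(NA_character_)
  rest <- substr(text, m[1] + attr(m, "match.length"), nchar(text))
  e <- regexpr("(?im)^[ \t]*(impression|conclusion)s?[ \t]*:", rest, perl = TRUE)
  if (e[1] != -1) rest <- substr(rest, 1, e[1] - 1L)
  rest <- trimws(rest)
  if (nzchar(rest)) rest else NA_character_
}

#' Collect a bundle's radiology reports
#'
#' Applies the same 24-hour pre-admission inclusion rule as the labs,
#' classifies each note's exam name to (modality, region), and keeps only
#' the findings section. Unclassifiable notes and notes without findings
#' are dropped with a logged reason.
#'
#' @param bundle a raw admission bundle.
#' @param lexicon imaging lexicon.
#' @param window_hours pre-admission window (default 24).
#' @return list(reports = list of [radiology_report()], dropped = data frame
#'   of exam_name/reason).
#' @export
collect_reports <- function(bundle, lexicon = load_imaging_lexicon(), window_hours = 24) {
  rn <- bundle$radiology_notes
  keep_u <- in_window(rn$unlinked$charttime, bundle$admit_time, window_hours)
  notes <- rbind(rn$linked, rn$unlinked[keep_u, , drop = FALSE])
  reports <- list()
  dropped <- list()
  for (i in seq_len(nrow(notes))) {
    cls <- classify_imaging_request(notes$exam_name[i], lexicon)
    if (is.null(cls)) {
      dropped[[length(dropped) + 1L]] <- c(notes$exam_name[i], "unclassifiable_exam_name")
      next
    }
    fx <- extract_findings(notes$text[i])
    if (is.na(fx)) {
      dropped[[length(dropped) + 1L]] <- c(notes$exam_name[i], "no_findings_section")
      next
    }
    reports[[length(reports) + 1L]] <- radiology_report(
      notes$exam_name[i], cls$modality, cls$region, notes$charttime[i], fx)
  }
  dropped_df <- if (length(dropped)) {
    data.frame(exam_name = vapply(dropped, `[`, character(1), 1),
               reason = vapply(dropped, `[`, character(1), 2),
               stringsAsFactors = FALSE)
  } else {
    data.frame(exam_name = character(0), reason = character(0))
  }
  list(reports = reports, dropped = dropped_df)
}

#' Censor pathology mentions in text
#'
#' Replaces every mention of the pathology name or an accepted phrasing
#' with `"___"`, the de-identification placeholder.
#'
#' @param text character scalar.
#' @param pathology one of [pathologies()].
#' @param lexicon diagnosis lexicon supplying the phrasings.
#' @return censored text.
#' @export
censor_mentions <- function(text, pathology, lexicon = load_diagnosis_lexicon()) {
  terms <- unique(c(pathology, lexicon[[pathology]]))
  terms <- terms[order(-nchar(terms))]
  for (tm in terms) {
    pat <- paste0("(?i)", gsub("\\s+", "[\\\\s-]+", regex_escape(tm)))
    text <- gsub(pat, "___", text, perl = TRUE)
  }
  text
}

#' Assemble a patient case from collected pieces
#'
#' Applies the final exclusion rules — no physical examination, pathology
#' mentioned in the history of present illness, no laboratory tests, no
#' abdominal imaging — then censors remaining mentions of the gold
#' pathology in the served text fields and merges coded with free-text
#' procedures.
#'
#' @param bundle candidate bundle (with `candidate_pathology`).
#' @param sections from [extract_sections()].
#' @param labs from [collect_labs()].
#' @param reports from [collect_reports()]`$reports`.
#' @param lexicon diagnosis lexicon (censoring scan).
#' @return list(case = `patient_case` or NULL, reason = NA or drop reason).
#' @export
assemble_case <- function(bundle, sections, labs, reports,
                          lexicon = load_diagnosis_lexicon()) {
  gold <- bundle$candidate_pathology
  if (is.na(sections$physical_exam)) {
    return(list(case = NULL, reason = "no_physical_exam"))
  }
  hpi <- sections$hpi
  if (is.null(hpi) || is.na(hpi)) hpi <- ""
  terms <- unique(c(gold, lexicon[[gold]]))
  hpi_norm <- normalize_text(hpi)
  if (any(vapply(terms, function(tm) contains_term(hpi_norm, normalize_text(tm)),
                 logical(1)))) {
    return(list(case = NULL, reason = "pathology_in_hpi"))
  }
  if (!length(labs)) {
    return(list(case = NULL, reason = "no_labs"))
  }
  regions <- vapply(reports, function(r) r$region, character(1))
  if (!any(regions == "abdomen")) {
    return(list(case = NULL, reason = "no_abdominal_imaging"))
  }
  pe <- censor_mentions(sections$physical_exam, gold, lexicon)
  reports <- lapply(reports, function(r) {
    r$findings_text <- censor_mentions(r$findings_text, gold, lexicon)
    r
  })
  procedures <- list()
  pr <- bundle$coded_procedures
  for (i in seq_len(nrow(pr))) {
    procedures[[length(procedures) + 1L]] <-
      procedure_record(code = pr$icd_code[i], source = "coded_table")
  }
  ft <- sections$free_text_procedures
  if (!is.null(ft) && !is.na(ft) && nzchar(trimws(ft))) {
    procedures[[length(procedures) + 1L]] <-
      procedure_record(free_text = trimws(ft), source = "discharge_summary")
  }
  case <- patient_case(
    case_id = as.character(bundle$admission_id), pathology = gold,
    hpi_text = hpi, physical_exam_text = pe, labs = labs, reports = reports,
    procedures = procedures,
    discharge_diagnosis_text = sections$discharge_diagnosis %||% "")
  list(case = case, reason = NA_character_)
}

#' Build the case dataset from raw tables
#'
#' Runs the full pipeline: target-code filter, discharge-diagnosis check,
#' section extraction, lab/report collection, exclusion rules and
#' censoring. Deterministic: identical input tables give an identical case
#' set and report.
#'
#' @param tables named list of raw tables (see [as_bundles()]) or a
#'   directory of CSV files with those names (`.csv` or `.csv.gz`).
#' @param icd_code_sets from [load_icd_codes()].
#' @param window_hours pre-admission inclusion window.
#' @param section_patterns see [extract_sections()].
#' @return list(cases = list of `patient_case`, report = `build_report`).
#' @export
build_dataset <- function(tables, icd_code_sets = load_icd_codes(),
                          window_hours = 24,
                          section_patterns = default_section_patterns()) {
  if (is.character(tables)) tables <- read_mimic_tables(tables)
  bundles <- as_bundles(tables)
  n_total <- length(bundles)
  flt <- filter_target_admissions(bundles, icd_code_sets)
  reasons <- flt$reasons
  stage <- data.frame(stage = "target_filter", n_in = n_total,
                      n_kept = length(flt$kept), stringsAsFactors = FALSE)
  more <- c(no_discharge_diagnosis = 0L, secondary_discharge_diagnosis = 0L,
            no_physical_exam = 0L, pathology_in_hpi = 0L, no_labs = 0L,
            no_abdominal_imaging = 0L)
  cases <- list()
  n_in_assembly <- 0L
  for (b in flt$kept) {
    sections <- extract_sections(b$discharge_summary_text, section_patterns)
    chk <- check_primary_discharge_diagnosis(sections$discharge_diagnosis,
                                             b$candidate_pathology)
    if (!chk$keep) {
      more[[chk$reason]] <- more[[chk$reason]] + 1L
      next
    }
    n_in_assembly <- n_in_assembly + 1L
    labs <- collect_labs(b, window_hours)
    rep_out <- collect_reports(b, window_hours = window_hours)
    asm <- assemble_case(b, sections, labs, rep_out$reports)
    if (is.null(asm$case)) {
      more[[asm$reason]] <- more[[asm$reason]] + 1L
    } else {
      cases[[length(cases) + 1L]] <- asm$case
    }
  }
  stage <- rbind(stage,
    data.frame(stage = "discharge_diagnosis", n_in = length(flt$kept),
               n_kept = n_in_assembly, stringsAsFactors = FALSE),
    data.frame(stage = "assembly", n_in = n_in_assembly,
               n_kept = length(cases), stringsAsFactors = FALSE))
  reasons <- c(reasons, more)
  report <- structure(list(stages = stage, exclusions = reasons,
                           n_input = n_total, n_cases = length(cases)),
                      class = "build_report")
  validate_build_report(report)
  list(cases = cases, report = report)
}

#' Validate the telescoping property of a build report
#'
#' Stage counts must telescope (each stage's kept count is the next
#' stage's input) and the summed exclusion reasons must equal the total
#' number of dropped admissions.
#'
#' @param report a `build_report`.
#' @return the report, invisibly.
#' @export
validate_build_report <- function(report) {
  s <- report$stages
  if (nrow(s) > 1 && any(s$n_kept[-nrow(s)] != s$n_in[-1])) {
    stop("build report counts do not telescope", call. = FALSE)
  }
  if (sum(report$exclusions) != report$n_input - report$n_cases) {
    stop("exclusion reasons do not sum to dropped count", call. = FALSE)
  }
  invisible(report)
}

#' @export
print.build_report <- function(x, ...) {
  cat("<build_report> ", x$n_input, " admissions -> ", x$n_cases, " cases\n", sep = "")
  print(x$stages, row.names = FALSE)
  cat("exclusions:\n")
  for (r in names(x$exclusions)) cat("  ", r, ": ", x$exclusions[[r]], "\n", sep = "")
  invisible(x)
}

#' Read MIMIC-IV-style tables from a directory of CSV files
#'
#' @param dir directory containing `admissions`, `diagnoses_icd`,
#'   `d_labitems`, `labevents`, `microbiologyevents`, `procedures_icd`,
#'   `discharge` and `radiology` as `.csv` or `.csv.gz`.
#' @return named list of data frames.
#' @export
read_mimic_tables <- function(dir) {
  need <- c("admissions", "diagnoses_icd", "d_labitems", "labevents",
            "microbiologyevents", "procedures_icd", "discharge", "radiology")
  out <- list()
  for (nm in need) {
    p <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(p)) p <- paste0(p, ".gz")
    if (!file.exists(p)) stop("missing table file: ", nm, " in ", dir, call. = FALSE)
    out[[nm]] <- utils::read.csv(p, stringsAsFactors = FALSE)
  }
  # empty character columns read as logical NA need coercion
  chr_cols <- list(labevents = c("charttime", "value", "valueuom"),
                   microbiologyevents = c("charttime", "test_name", "result"),
                   radiology = c("charttime", "exam_name", "text"),
                   discharge = "text")
  for (nm in names(chr_cols)) {
    for (cc in chr_cols[[nm]]) {
      if (cc %in% names(out[[nm]])) out[[nm]][[cc]] <- as.character(out[[nm]][[cc]])
    }
  }
  out
}
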