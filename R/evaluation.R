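# Scoring: diagnostic accuracy, guideline adherence (requested lab
# categories), treatment appropriateness, laboratory interpretation,
# instruction-following tallies, and the statistical comparisons.

#' Load the guideline specification
#'
#' Per pathology: required laboratory categories (a category is met when at
#' least one member test was requested), essential treatments (expected for
#' every correctly diagnosed patient), case-specific treatments (expected
#' only when the patient actually received the corresponding procedure) and
#' the supportive-care requirement — any one of fluids / pain management /
#' monitoring, except pancreatitis, where supportive care is the mainstay
#' and all three are expected.
#'
#' @param path YAML file; default is the shipped, replaceable
#'   reconstruction.
#' @return a `guideline_spec` object.
#' @export
load_guidelines <- function(path = NULL) {
  key <- path %||% "default_guidelines"
  if (!is.null(.lexicon_cache[[key]])) return(.lexicon_cache[[key]])
  cfg <- yaml::read_yaml(path %||% config_path("guidelines.yaml"))
  support_terms <- cfg$support_terms
  cfg$support_terms <- NULL
  for (p in pathologies()) {
    g <- cfg[[p]]
    if (is.null(g)) stop("guideline configuration: missing pathology ", p, call. = FALSE)
    if (!length(g$required_lab_categories) ||
        any(!vapply(g$required_lab_categories, length, integer(1)))) {
      stop("guideline configuration: empty lab category for ", p, call. = FALSE)
    }
    mode <- g$support$mode
    expected_mode <- if (p == "pancreatitis") "all" else "any"
    if (!identical(mode, expected_mode)) {
      stop("guideline configuration: support mode for ", p, " must be '",
           expected_mode, "'", call. = FALSE)
    }
  }
  spec <- structure(list(pathologies = cfg[pathologies()],
                         support_terms = support_terms),
                    class = "guideline_spec")
  .lexicon_cache[[key]] <- spec
  spec
}

#' Did the patient actually receive a procedure?
#'
#' @param procedures list of [procedure_record()] objects.
#' @param pattern case-insensitive regular expression matched against both
#'   codes and free text.
#' @return logical flag.
#' @export
patient_received <- function(procedures, pattern) {
  any(vapply(procedures, function(p) {
    (!is.na(p$code) && grepl(pattern, p$code, ignore.case = TRUE)) ||
      (!is.na(p$free_text) && grepl(pattern, p$free_text, ignore.case = TRUE))
  }, logical(1)))
}

# Keyword mention with a small negation guard: a keyword preceded within
# three words by no/not/without/avoid does not count as a recommendation.
mentions_keyword <- function(text_norm, keywords) {
  for (kw in normalize_text(keywords)) {
    pat <- paste0("\\b", regex_escape(kw), "\\b")
    m <- gregexpr(pat, text_norm, perl = TRUE)[[1]]
    if (m[1] == -1) next
    for (pos in as.integer(m)) {
      before <- substr(text_norm, max(1, pos - 40), pos - 1)
      wb <- strsplit(trimws(before), "\\s+")[[1]]
      tail3 <- utils::tail(wb, 3)
      if (!any(tail3 %in% c("no", "not", "without", "avoid", "avoiding", "hold"))) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Score a treatment plan against the guideline
#'
#' Surface keyword matching with a negation guard. Essential treatments
#' are always expected; case-specific treatments are scored only for
#' patients who actually received the corresponding procedure (otherwise
#' `not_applicable`). Supportive care requires a fluids / pain management /
#' monitoring mention — any one for appendicitis, cholecystitis and
#' diverticulitis, all three for pancreatitis.
#'
#' @param treatment_text the agent's treatment plan.
#' @param pathology the (correctly diagnosed) pathology.
#' @param procedures the patient's [procedure_record()]s.
#' @param guideline from [load_guidelines()].
#' @return named character vector: treatment -> one of `recommended`,
#'   `missed`, `not_applicable` (supportive care appears as `support`).
#' @export
score_treatment_text <- function(treatment_text, pathology, procedures,
                                 guideline = load_guidelines()) {
  g <- guideline$pathologies[[pathology]]
  if (is.null(g)) stop("pathology missing from guideline: ", pathology, call. = FALSE)
  txt <- normalize_text(treatment_text %||% "")
  flags <- character(0)
  for (nm in names(g$essential_treatments)) {
    hit <- nzchar(txt) && mentions_keyword(txt, g$essential_treatments[[nm]]$keywords)
    flags[[nm]] <- if (hit) "recommended" else "missed"
  }
  for (nm in names(g$case_specific_treatments)) {
    ct <- g$case_specific_treatments[[nm]]
    if (!patient_received(procedures, ct$procedure_pattern)) {
      flags[[nm]] <- "not_applicable"
    } else {
      hit <- nzchar(txt) && mentions_keyword(txt, ct$keywords)
      flags[[nm]] <- if (hit) "recommended" else "missed"
    }
  }
  elems <- vapply(names(guideline$support_terms), function(el) {
    nzchar(txt) && mentions_keyword(txt, guideline$support_terms[[el]])
  }, logical(1))
  ok <- if (identical(g$support$mode, "all")) all(elems) else any(elems)
  flags[["support"]] <- if (ok) "recommended" else "missed"
  flags
}

#' Score one episode against its case and the guideline
#'
#' Diagnostic correctness uses the first-diagnosis rule of
#' [match_diagnosis()]. Each required laboratory category of the case's
#' pathology is met when at least one member test was requested. Treatment
#' flags are populated only for correctly diagnosed cases (an inaccurate
#' diagnosis makes the treatment plan unscorable). Imaging requests are
#' recorded but never penalized.
#'
#' @param episode an `episode` from [run_episode()].
#' @param case the matching `patient_case`.
#' @param guideline from [load_guidelines()].
#' @param diagnosis_lexicon diagnosis lexicon.
#' @return a `case_score` object.
#' @export
score_episode <- function(episode, case, guideline = load_guidelines(),
                          diagnosis_lexicon = load_diagnosis_lexicon()) {
  stopifnot(identical(episode$case_id, case$case_id))
  g <- guideline$pathologies[[case$pathology]]
  if (is.null(g)) stop("pathology missing from guideline: ", case$pathology, call. = FALSE)
  correct <- match_diagnosis(episode$final_diagnosis_text, case$pathology,
                             diagnosis_lexicon)
  cats <- vapply(names(g$required_lab_categories), function(cat) {
    any(g$required_lab_categories[[cat]] %in% episode$requested_labs)
  }, logical(1))
  treatment_flags <- if (correct) {
    score_treatment_text(episode$treatment_text, case$pathology,
                         case$procedures, guideline)
  } else {
    character(0)
  }
  structure(list(
    case_id = case$case_id,
    pathology = case$pathology,
    diagnosed_correctly = correct,
    pe_first = isTRUE(episode$physical_exam_first),
    pe_at_all = isTRUE(episode$physical_exam_requested),
    lab_categories_met = cats,
    imaging_requested = episode$requested_imaging,
    treatment_flags = treatment_flags,
    error_counts = episode$error_counts
  ), class = "case_score")
}

#' Classify a laboratory value against its reference range
#'
#' Bounds are inclusive: a value equal to a bound is within range. With a
#' missing low bound a value is never "below"; with a missing high bound
#' never "above". Non-numeric values are not classifiable.
#'
#' @param value numeric value (or text; parsed when possible).
#' @param ref_low,ref_high reference bounds (either may be `NA`).
#' @return `"below"`, `"within"`, `"above"` or `"not_classifiable"`.
#' @export
classify_lab_value <- function(value, ref_low = NA_real_, ref_high = NA_real_) {
  v <- parse_lab_value(value)
  if (is.na(v) || (is.na(ref_low) && is.na(ref_high))) return("not_classifiable")
  if (!is.na(ref_low) && v < ref_low) return("below")
  if (!is.na(ref_high) && v > ref_high) return("above")
  "within"
}

#' Per-label accuracy on the interpretation task
#'
#' @param model_labels labels produced by an agent, aligned with the items.
#' @param gold_items data frame from [generate_interpretation_set()].
#' @return named numeric vector: percentage correct for below, within and
#'   above.
#' @export
score_interpretations <- function(model_labels, gold_items) {
  stopifnot(length(model_labels) == nrow(gold_items))
  vapply(c("below", "within", "above"), function(lab) {
    idx <- gold_items$gold_label == lab
    if (!any(idx)) return(NA_real_)
    100 * mean(model_labels[idx] == lab)
  }, numeric(1))
}

#' Per-class diagnostic accuracy
#'
#' Correct diagnoses divided by the total number of patients with the
#' pathology, in percent. No pooling across classes: the dataset has no
#' realistic negative class, so per-class accuracy is the headline metric.
#'
#' @param scores list of `case_score` objects.
#' @param pathology one of [pathologies()].
#' @return percentage (numeric scalar).
#' @export
per_class_accuracy <- function(scores, pathology) {
  pathology <- match.arg(pathology, pathologies())
  sel <- Filter(function(s) s$pathology == pathology, scores)
  if (!length(sel)) stop("no cases of pathology ", pathology, call. = FALSE)
  100 * mean(vapply(sel, function(s) isTRUE(s$diagnosed_correctly), logical(1)))
}

#' Compare two accuracy samples (Welch t-test, Bonferroni corrected)
#'
#' Two-sided Student's t-test with unequal variances, with the p-value
#' multiplied by the number of comparisons and capped at 1. Two constant,
#' identical samples compare with p = 1.
#'
#' @param a,b numeric samples (each of length >= 2).
#' @param n_comparisons Bonferroni multiplier (default 1 = no correction).
#' @return list(p_value, p_corrected, t_statistic, df).
#' @export
compare_groups <- function(a, b, n_comparisons = 1) {
  stopifnot(length(a) >= 2, length(b) >= 2, n_comparisons >= 1)
  res <- tryCatch(stats::t.test(a, b, var.equal = FALSE),
                  error = function(e) NULL)
  if (is.null(res)) {
    # degenerate: both samples constant
    p <- if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
    t_stat <- if (p == 1) 0 else Inf
    df <- length(a) + length(b) - 2
  } else {
    p <- res$p.value
    t_stat <- unname(res$statistic)
    df <- unname(res$parameter)
  }
  list(p_value = p, p_corrected = min(1, p * n_comparisons),
       t_statistic = t_stat, df = df)
}

#' Aggregate case scores per pathology
#'
#' @param scores list of `case_score` objects.
#' @return data frame with one row per pathology present: n, diagnostic
#'   accuracy (%), physical-exam rates, mean share of lab categories met,
#'   share of expected treatments recommended (correctly diagnosed cases
#'   only), and mean error counts.
#' @export
summarize_scores <- function(scores) {
  paths <- unique(vapply(scores, function(s) s$pathology, character(1)))
  rows <- lapply(paths, function(p) {
    sel <- Filter(function(s) s$pathology == p, scores)
    correct <- vapply(sel, function(s) isTRUE(s$diagnosed_correctly), logical(1))
    cats <- vapply(sel, function(s) mean(s$lab_categories_met), numeric(1))
    tx <- unlist(lapply(sel, function(s) {
      fl <- s$treatment_flags
      fl <- fl[fl != "not_applicable"]
      if (length(fl)) fl == "recommended" else NULL
    }))
    errs <- vapply(sel, function(s) sum(unlist(s$error_counts)), numeric(1))
    data.frame(
      pathology = p, n = length(sel),
      diagnostic_accuracy = 100 * mean(correct),
      pe_first_rate = 100 * mean(vapply(sel, function(s) s$pe_first, logical(1))),
      pe_rate = 100 * mean(vapply(sel, function(s) s$pe_at_all, logical(1))),
      lab_categories_met = 100 * mean(cats),
      treatments_recommended = if (length(tx)) 100 * mean(tx) else NA_real_,
      mean_errors = mean(errs),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
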