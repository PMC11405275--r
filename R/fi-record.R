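# Full-information (FI) record assembly: the single-shot variant of the
# task, where all relevant information is presented upfront in canonical
# order (HPI, physical examination, laboratory results, imaging) under a
# token budget with staged summarization.

#' Decompose a case into full-information content spans
#'
#' Laboratory results are restricted to tests in the union of the
#' guideline categories over all four pathologies (the diagnosis and its
#' differentials); imaging is restricted to abdominal reports, ordered by
#' chart time from earliest to latest.
#'
#' @param case a `patient_case`.
#' @param guideline from [load_guidelines()].
#' @return list(hpi, pe, labs, imaging): character spans (`imaging` is a
#'   vector with one span per report).
#' @export
build_fi_parts <- function(case, guideline = load_guidelines()) {
  relevant <- unique(unlist(lapply(guideline$pathologies, function(g)
    unlist(g$required_lab_categories))))
  labs <- Filter(function(l) l$canonical_name %in% relevant, case$labs)
  lab_lines <- vapply(labs, render_lab_line, character(1))
  abd <- Filter(function(r) r$region == "abdomen", case$reports)
  abd <- abd[order(vapply(abd, function(r) r$chart_time, character(1)))]
  imaging <- vapply(abd, function(r) {
    paste0(r$modality, " ", r$region, " (", r$chart_time, "):\n", r$findings_text)
  }, character(1))
  list(
    hpi = paste0("History of Present Illness:\n", case$hpi_text),
    pe = paste0("Physical Examination:\n", case$physical_exam_text),
    labs = paste0("Laboratory Results:\n", paste(lab_lines, collapse = "\n")),
    imaging = imaging
  )
}

render_lab_line <- function(l) {
  ref <- if (!is.na(l$ref_low) || !is.na(l$ref_high)) {
    paste0(" (reference: ", ifelse(is.na(l$ref_low), "", l$ref_low), "-",
           ifelse(is.na(l$ref_high), "", l$ref_high), ")")
  } else ""
  val <- if (is.numeric(l$value)) format(l$value) else l$value
  paste0(l$canonical_name, ": ", val,
         if (nzchar(l$unit)) paste0(" ", l$unit) else "", ref)
}

#' Token budget for prompt assembly
#'
#' @param limit context limit in tokens (default 4096).
#' @param counter text -> token count function; must be monotone under
#'   concatenation. Default is the word-ratio counter [count_tokens()].
#' @param reserve tokens held back for the diagnosis (default 25, about 20
#'   words).
#' @return a `token_budget` object.
#' @export
token_budget <- function(limit = 4096, counter = count_tokens, reserve = 25) {
  stopifnot(limit > reserve)
  structure(list(limit = limit, counter = counter, reserve = reserve),
            class = "token_budget")
}

#' Trim a text to at most `n_words` words
#'
#' Used as the last summarization resort (word removal) and as the trivial
#' summarizer exposed by scripted agents.
#'
#' @param text input text.
#' @param n_words maximum words kept.
#' @return trimmed text.
#' @export
trim_words <- function(text, n_words) {
  w <- strsplit(trimws(text), "\\s+")[[1]]
  if (length(w) <= n_words) return(trimws(text))
  paste(w[seq_len(max(0L, n_words))], collapse = " ")
}

apply_summarizer <- function(summarizer, text, fallback_words = 40) {
  out <- tryCatch(summarizer(text), error = function(e) NULL)
  if (is.null(out) || !is.character(out) || !nzchar(trimws(out))) {
    out <- trim_words(text, fallback_words)
  }
  out
}

#' Assemble the full-information prompt under a token budget
#'
#' Content order is HPI, then the remaining spans in `order` (canonical:
#' physical examination, laboratory results, imaging; HPI is always
#' first). When the assembled prompt exceeds `limit - reserve`, each
#' imaging report is summarized individually; if still over, all imaging
#' is summarized at once; if still over, words are removed from the final
#' imaging summary until the diagnosis reserve fits.
#'
#' @param parts from [build_fi_parts()].
#' @param instructions instruction span (may be empty).
#' @param order permutation of `c("pe", "labs", "imaging")`.
#' @param budget a [token_budget()].
#' @param summarizer text -> summary function (an agent's summarizer).
#' @return prompt text whose counted length is at most `limit - reserve`.
#' @export
assemble_fi_prompt <- function(parts, instructions = "",
                               order = c("pe", "labs", "imaging"),
                               budget = token_budget(),
                               summarizer = function(text) trim_words(text, 40)) {
  stopifnot(setequal(order, c("pe", "labs", "imaging")) || all(order %in% c("pe", "labs", "imaging")))
  compose <- function(imaging_spans) {
    spans <- character(0)
    if (nzchar(instructions)) spans <- c(spans, instructions)
    spans <- c(spans, parts$hpi)
    for (o in order) {
      spans <- c(spans, if (o == "imaging") imaging_spans else parts[[o]])
    }
    paste(spans, collapse = "\n\n")
  }
  cap <- budget$limit - budget$reserve
  imaging <- parts$imaging
  prompt <- compose(imaging)
  if (budget$counter(prompt) <= cap) return(prompt)
  # stage 1: summarize each report individually
  imaging <- vapply(imaging, function(s) apply_summarizer(summarizer, s),
                    character(1), USE.NAMES = FALSE)
  prompt <- compose(imaging)
  if (budget$counter(prompt) <= cap) return(prompt)
  # stage 2: summarize all imaging at once
  if (length(imaging)) {
    imaging <- apply_summarizer(summarizer, paste(imaging, collapse = "\n\n"))
    prompt <- compose(imaging)
    if (budget$counter(prompt) <= cap) return(prompt)
  }
  # stage 3: remove words from the final imaging summary
  while (length(imaging) && budget$counter(prompt) > cap) {
    n <- word_count(imaging)
    if (n <= 1L) {
      imaging <- character(0)
    } else {
      imaging <- trim_words(imaging, n - 1L)
    }
    prompt <- compose(imaging)
  }
  # degenerate: other spans alone exceed the cap; trim the tail hard
  while (budget$counter(prompt) > cap) {
    prompt <- trim_words(prompt, word_count(prompt) - 10L)
  }
  prompt
}

#' Build the full-information prompt for a case
#'
#' @param case a `patient_case`.
#' @param guideline from [load_guidelines()].
#' @param budget a [token_budget()].
#' @param summarizer text -> summary function.
#' @param template_dir optional directory overriding shipped templates.
#' @return full-information prompt text.
#' @export
build_fi_record <- function(case, guideline = load_guidelines(),
                            budget = token_budget(),
                            summarizer = function(text) trim_words(text, 40),
                            template_dir = NULL) {
  parts <- build_fi_parts(case, guideline)
  instructions <- read_template("fi_instructions", template_dir)
  assemble_fi_prompt(parts, instructions, budget = budget, summarizer = summarizer)
}
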