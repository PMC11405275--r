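# Shared fixtures: a tiny hand-built case, an agent wrapper that records
# prompt sizes, and a textbook Welch t-test used as independent oracle.

tiny_case <- function(case_id = "T1", pathology = "appendicitis",
                      n_abdominal_ct = 1) {
  t0 <- "2023-03-01T08:00:00"
  reports <- list()
  for (i in seq_len(n_abdominal_ct)) {
    reports[[i]] <- radiology_report(
      exam_name = "CT ABDOMEN", modality = "CT", region = "abdomen",
      chart_time = sprintf("2023-03-01T%02d:00:00", 9 + i),
      findings_text = paste0("Findings of scan number ", i,
                             ": inflamed structure with fat stranding."))
  }
  patient_case(
    case_id = case_id, pathology = pathology,
    hpi_text = "Two days of right lower quadrant pain with anorexia.",
    physical_exam_text = "Tender right lower quadrant, guarding present.",
    labs = list(
      lab_result("white blood cell count", value = 15.2, unit = "K/uL",
                 ref_low = 4, ref_high = 11, chart_time = t0),
      lab_result("lipase", value = 30, unit = "IU/L", ref_low = 13,
                 ref_high = 60, chart_time = t0)),
    reports = reports,
    procedures = list(procedure_record(free_text = "Laparoscopic appendectomy",
                                       source = "discharge_summary")))
}

recording_agent <- function(inner, counter = count_tokens) {
  sizes <- numeric(0)
  f <- function(prompt, stop_phrases = character(0)) {
    sizes[length(sizes) + 1L] <<- counter(prompt)
    inner(prompt, stop_phrases)
  }
  attr(f, "summarizer") <- attr(inner, "summarizer")
  attr(f, "prompt_sizes") <- function() sizes
  f
}

welch_oracle <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  t_stat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  2 * stats::pt(-abs(t_stat), df)
}
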