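#' @keywords internal
"_PACKAGE"

#' Target pathologies
#'
#' The four abdominal pathologies the harness covers. Every patient case
#' carries exactly one of them as its hidden gold label.
#'
#' @return Character vector of the four pathology names.
#' @export
pathologies <- function() {
  c("appendicitis", "cholecystitis", "diverticulitis", "pancreatitis")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Normalize free text for lexicon matching
#'
#' Lowercases, replaces punctuation with spaces and collapses whitespace.
#' All lexicon lookups operate on normalized text so that letter case,
#' hyphenation and stray punctuation never defeat a match.
#'
#' @param x character vector.
#' @return normalized character vector.
#' @export
normalize_text <- function(x) {
  x <- tolower(x)
  x <- gsub("[^a-z0-9]+", " ", x)
  trimws(gsub("\\s+", " ", x))
}

# Escape regex metacharacters so a literal string can be embedded in a
# perl-compatible pattern.
regex_escape <- function(x) {
  gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)
}

# Word-boundary containment of a (already normalized) term in normalized text.
contains_term <- function(text_norm, term_norm) {
  if (!nzchar(term_norm)) return(FALSE)
  grepl(paste0("\\b", regex_escape(term_norm), "\\b"),
        text_norm, perl = TRUE)
}

word_count <- function(x) {
  x <- trimws(x)
  if (!nzchar(x)) return(0L)
  length(strsplit(x, "\\s+")[[1]])
}

#' Default token counter
#'
#' Approximates token counts as word count times 1.71, the ratio between a
#' 4,096-token context window and roughly 2,400 words. A real tokenizer can
#' be plugged in anywhere a `counter` argument is accepted.
#'
#' @param text character scalar.
#' @return estimated token count (numeric scalar).
#' @export
count_tokens <- function(text) {
  ceiling(word_count(paste(text, collapse = " ")) * 1.71)
}

# Read a shipped template (inst/templates) or a user-supplied override file.
read_template <- function(name, template_dir = NULL) {
  path <- if (!is.null(template_dir)) file.path(template_dir, paste0(name, ".txt")) else
    system.file("templates", paste0(name, ".txt"), package = "cdmbench")
  if (!nzchar(path) || !file.exists(path)) {
    stop("template not found: ", name, call. = FALSE)
  }
  paste(readLines(path, warn = FALSE), collapse = "\n")
}

config_path <- function(name) {
  p <- system.file("extdata", name, package = "cdmbench")
  if (!nzchar(p)) stop("missing shipped configuration file: ", name, call. = FALSE)
  p
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x == floor(x)
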