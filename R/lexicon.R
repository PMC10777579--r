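#' Built-in symptom lexicon
#'
#' A small multi-word symptom lexicon covering the four target diagnoses,
#' drawn from typical neurology referral-letter language. Class-specific
#' phrase lists are pairwise disjoint; the `distractor` list holds symptoms
#' that occur across classes (or typically as negated mentions) and carries
#' no class signal.
#'
#' @return Named list with one character vector of phrases per ICD code plus
#'   a `distractor` vector.
#' @export
#' @examples
#' lex <- builtin_lexicon()
#' lex$R51
builtin_lexicon <- function() {
  list(
    G40 = c(
      "tonic-colonic seizures", "seizure", "left-sided weakness",
      "fatigued", "epilepsy", "head-injury", "jerking movements"
    ),
    R51 = c(
      "tunnel vision", "pass out", "falling down", "dizziness",
      "diplopia", "headache", "photophobia"
    ),
    M54 = c(
      "leg pain", "numbness", "back pain", "decreased sensation",
      "chronic back pain", "unable to flex her hips", "sciatica"
    ),
    I63 = c(
      "left arm weakness", "muscular dystrophy", "subdural haematomas",
      "volume loss", "intracranial acute abnormality",
      "lack of transverse veins", "slurred speech"
    ),
    distractor = c(
      "lose consciousness", "nausea", "vomiting", "fever",
      "blurred vision", "weight loss", "chest pain", "shortness of breath"
    )
  )
}

#' Flatten a lexicon into its tabular form
#'
#' The extractor consumes a table with columns `surface_phrase`, `canonical`
#' and `class_hint`; `class_hint` is `NA` for shared (distractor) phrases and
#' is only used by the corpus generator.
#'
#' @param lexicon named list as returned by [builtin_lexicon()], or already a
#'   data.frame in tabular form (returned unchanged after validation).
#' @return data.frame with columns `surface_phrase`, `canonical`, `class_hint`.
#' @export
lexicon_table <- function(lexicon = builtin_lexicon()) {
  if (is.data.frame(lexicon)) {
    need <- c("surface_phrase", "canonical")
    if (!all(need %in% names(lexicon))) {
      stop("lexicon table must have columns surface_phrase and canonical",
           call. = FALSE)
    }
    if (is.null(lexicon$class_hint)) lexicon$class_hint <- NA_character_
    return(lexicon[, c("surface_phrase", "canonical", "class_hint")])
  }
  if (!is.list(lexicon) || length(lexicon) == 0) {
    stop("lexicon is empty or not a list/table", call. = FALSE)
  }
  rows <- lapply(names(lexicon), function(cls) {
    hint <- if (identical(cls, "distractor")) NA_character_ else cls
    data.frame(
      surface_phrase = lexicon[[cls]],
      canonical = tolower(lexicon[[cls]]),
      class_hint = hint,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read / write a lexicon file
#'
#' Plain TSV with header `surface_phrase`, `canonical`, `class_hint`
#' (`class_hint` may be empty for shared phrases).
#'
#' @param path file path.
#' @param lexicon data.frame in the [lexicon_table()] layout.
#' @return `read_lexicon` returns the lexicon data.frame.
#' @export
read_lexicon <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  lexicon_table(tab)
}

#' @rdname read_lexicon
#' @export
write_lexicon <- function(lexicon, path) {
  tab <- lexicon_table(lexicon)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
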