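#' Save / load a model checkpoint
#'
#' A checkpoint is a single-file archive holding the model (branch weights,
#' fusion state, tokenizer and embedding table) plus an optional config
#' snapshot and its hash. Loading restores the model exactly:
#' `model_predict` output is bit-identical across a save/load round trip.
#'
#' @param model a `refdx_model`.
#' @param path file path.
#' @param config optional resolved run configuration to embed.
#' @return `load_checkpoint` returns a list with `model`, `config`,
#'   `config_hash`.
#' @export
save_checkpoint <- function(model, path, config = NULL) {
  stopifnot(inherits(model, "refdx_model"))
  obj <- list(format = "refdx-checkpoint-1", model = model,
              config = config,
              config_hash = if (is.null(config)) NA_character_
              else config_hash(config))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- tryCatch(suppressWarnings(readRDS(path)), error = function(e) {
    stop(errorCondition(
      paste0("unreadable checkpoint '", path, "': ", conditionMessage(e)),
      class = c("refdx_checkpoint_error", "error")
    ))
  })
  if (!is.list(obj) || !identical(obj$format, "refdx-checkpoint-1")) {
    stop(errorCondition(
      paste0("'", path, "' is not a refdx checkpoint"),
      class = c("refdx_checkpoint_error", "error")
    ))
  }
  obj[c("model", "config", "config_hash")]
}

#' Digest of a resolved configuration
#'
#' FNV-1a hash of the canonical JSON serialisation; all defaults must be
#' materialised in `config` before hashing, so equal hashes mean equal
#' effective runs.
#'
#' @param config a list.
#' @return 8-hex-digit character scalar.
#' @export
config_hash <- function(config) {
  txt <- as.character(jsonlite::toJSON(config, auto_unbox = TRUE,
                                       digits = NA, force = TRUE))
  bytes <- utf8ToInt(txt)
  # 31-polynomial rolling hash mod 2^31-1, exact in double precision
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Predict the diagnosis for one referral letter
#'
#' The programmatic core of the assistant: cleans the letter, extracts
#' symptom mentions with negation flags, builds the integrated
#' complaint-symptoms input, and runs the model. The extracted positive and
#' negated symptoms are returned alongside the ranking as the
#' explainability surface.
#'
#' @param model a `refdx_model` (typically from [load_checkpoint()]).
#' @param letter_text raw complaint text.
#' @param lexicon symptom lexicon.
#' @return list with `ranking` (data.frame: `code`, `name`, `probability`,
#'   sorted decreasing), `symptoms` (positive canonical phrases), `negated`
#'   (negated canonical phrases), `input_text` (the integrated text fed to
#'   the model).
#' @export
predict_letter <- function(model, letter_text, lexicon = builtin_lexicon()) {
  cleaned <- clean_text(letter_text)
  if (!nzchar(cleaned)) {
    stop(errorCondition("letter text is empty after cleaning",
                        class = c("refdx_empty_input", "error")))
  }
  mentions <- extract_symptoms(cleaned, lexicon)
  symptoms_text <- dot_separate(mentions)
  input_text <- integrate_complaint(cleaned, symptoms_text)
  pr <- model_predict(model, input_text)
  ord <- order(pr$probs, decreasing = TRUE)
  list(
    ranking = data.frame(
      code = disease_codes()[ord],
      name = unname(disease_labels()[ord]),
      probability = unname(pr$probs[ord]),
      stringsAsFactors = FALSE
    ),
    symptoms = mentions$canonical[!mentions$negated],
    negated = mentions$canonical[mentions$negated],
    input_text = input_text
  )
}
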