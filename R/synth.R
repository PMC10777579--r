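#' Configuration for the synthetic referral-letter generator
#'
#' The generator emulates the statistical structure of a neurology
#' referral-letter corpus: long free-text complaints with greeting
#' boilerplate, a handful of class-indicative multi-word symptom phrases,
#' negated mentions of off-class symptoms, shared "distractor" symptoms
#' carrying no class signal, and stray junk characters. Defaults reflect a
#' corpus of roughly 260 letters over 4 classes with 3 positive symptom
#' mentions and 1 negated off-class mention per letter, mild junk noise and
#' occasional cross-class distractor symptoms.
#'
#' @param n_per_class letters per class (>= 1).
#' @param signal_phrases_per_letter class-lexicon phrases per letter (>= 1).
#' @param negated_phrases_per_letter off-class phrases per letter, each
#'   injected directly after a negation trigger (>= 0).
#' @param junk_token_rate probability of inserting a junk token
#'   (`$$ ** Å ?? XXX`) after any word, in \[0, 1\].
#' @param distractor_rate probability that a letter additionally mentions a
#'   shared distractor symptom positively, in \[0, 1\].
#' @param seed integer seed; the generator threads a single seeded stream
#'   through all draws and never touches global RNG state.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_per_class = 65,
                         signal_phrases_per_letter = 3,
                         negated_phrases_per_letter = 1,
                         junk_token_rate = 0.05,
                         distractor_rate = 0.3,
                         seed = 1L) {
  stopifnot(
    length(n_per_class) == 1, n_per_class >= 1,
    length(signal_phrases_per_letter) == 1, signal_phrases_per_letter >= 1,
    length(negated_phrases_per_letter) == 1, negated_phrases_per_letter >= 0,
    length(junk_token_rate) == 1, junk_token_rate >= 0, junk_token_rate <= 1,
    length(distractor_rate) == 1, distractor_rate >= 0, distractor_rate <= 1,
    length(seed) == 1, is.finite(seed)
  )
  structure(
    list(
      n_per_class = as.integer(n_per_class),
      signal_phrases_per_letter = as.integer(signal_phrases_per_letter),
      negated_phrases_per_letter = as.integer(negated_phrases_per_letter),
      junk_token_rate = junk_token_rate,
      distractor_rate = distractor_rate,
      seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

#' Junk tokens the generator may inject and the cleaner removes
#' @return character vector of junk tokens.
#' @export
junk_tokens <- function() c("$$", "**", "Å", "??", "XXX")

#' Negation triggers shared by the generator and the extractor
#' @return character vector of trigger phrases.
#' @export
negation_triggers <- function() {
  c("no", "not", "did not", "denies", "without", "never")
}

#' Default greeting/closing boilerplate phrases removed by cleaning
#' @return character vector of greeting phrases.
#' @export
default_greetings <- function() {
  c("Dear Dr", "Dear Doctor",
    "We would be grateful if you could review",
    "Thank you for seeing",
    "Kind regards", "Yours sincerely")
}

# one synthetic complaint; all randomness from the current RNG stream
synth_letter_text <- function(code, lexicon, cfg) {
  lex <- lexicon
  cls_phr <- lex[[code]]
  other <- unlist(lex[setdiff(names(lex), c(code, "distractor"))],
                  use.names = FALSE)

  sex <- sample(c("gentleman", "lady"), 1)
  pro <- if (sex == "gentleman") "He" else "She"
  age <- sample(18:90, 1)

  greeting <- sample(c(
    "Dear Dr XXX,",
    "Dear Doctor,",
    "We would be grateful if you could review this patient."
  ), 1)
  demo <- sprintf("This %d-year-old %s was admitted on %d-%02d-%02d.",
                  age, sex, sample(1:28, 1), sample(1:12, 1), sample(15:22, 1))

  k <- cfg$signal_phrases_per_letter
  signal <- sample(cls_phr, k, replace = k > length(cls_phr))
  sig_sent <- vapply(signal, function(p) {
    tpl <- sample(1:4, 1)
    switch(tpl,
      sprintf("%s reports %s over recent weeks.", pro, p),
      sprintf("%s has developed %s.", pro, p),
      sprintf("Examination revealed %s.", p),
      sprintf("There is a clear history of %s.", p)
    )
  }, character(1))

  neg_sent <- character(0)
  if (cfg$negated_phrases_per_letter > 0) {
    nn <- cfg$negated_phrases_per_letter
    negp <- sample(other, nn, replace = nn > length(other))
    neg_sent <- vapply(negp, function(p) {
      tpl <- sample(1:4, 1)
      switch(tpl,
        sprintf("%s denies %s.", pro, p),
        sprintf("There was no %s.", p),
        sprintf("%s did not report %s.", pro, p),
        sprintf("This occurred without %s.", p)
      )
    }, character(1))
  }

  dis_sent <- character(0)
  if (stats::runif(1) < cfg$distractor_rate) {
    d <- sample(lex$distractor, 1)
    dis_sent <- sprintf("%s also reports %s.", pro, d)
  }

  closing <- sample(c("We would appreciate your assessment.",
                      "Kind regards,"), 1)

  body <- paste(c(greeting, demo, sig_sent, neg_sent, dis_sent, closing),
                collapse = " ")

  if (cfg$junk_token_rate > 0) {
    toks <- strsplit(body, " ", fixed = TRUE)[[1]]
    ins <- stats::runif(length(toks)) < cfg$junk_token_rate
    if (any(ins)) {
      junk <- sample(junk_tokens(), sum(ins), replace = TRUE)
      out <- character(0)
      j <- 1
      for (i in seq_along(toks)) {
        out <- c(out, toks[i])
        if (ins[i]) {
          out <- c(out, junk[j])
          j <- j + 1
        }
      }
      body <- paste(out, collapse = " ")
    }
  }
  body
}

#' Generate a synthetic referral-letter corpus
#'
#' Produces `4 * n_per_class` labelled letters. Each complaint is a greeting
#' sentence, a demographics sentence, one sentence per class-lexicon symptom
#' phrase, optional negated off-class mentions (each phrase immediately
#' preceded by a negation trigger), an optional shared distractor symptom,
#' and a closing sentence, with junk tokens injected as standalone
#' whitespace-delimited tokens. Two calls with an equal config are identical.
#'
#' @param cfg a [synth_config()].
#' @param lexicon lexicon list as from [builtin_lexicon()].
#' @return data.frame with columns `id`, `complaint`, `label`.
#' @export
#' @examples
#' corpus <- generate_corpus(synth_config(n_per_class = 2, seed = 7))
#' nrow(corpus)
generate_corpus <- function(cfg = synth_config(), lexicon = builtin_lexicon()) {
  if (!inherits(cfg, "synth_config")) {
    stop("cfg must be a synth_config object", call. = FALSE)
  }
  codes <- disease_codes()
  withr::with_seed(cfg$seed, {
    rows <- lapply(codes, function(code) {
      data.frame(
        id = sprintf("%s-%04d", code, seq_len(cfg$n_per_class)),
        complaint = vapply(seq_len(cfg$n_per_class), function(i) {
          synth_letter_text(code, lexicon, cfg)
        }, character(1)),
        label = code,
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Write / read a referral-letter corpus
#'
#' Supported dialects: delimited table (TSV or CSV, header
#' `id,complaint,label`) and JSON-lines (keys `id`, `complaint`, `label`),
#' chosen from the file extension (`.tsv`, `.csv`, `.jsonl`/`.ndjson`) or
#' forced via `format`. Round trips are lossless. UTF-8 throughout.
#'
#' @param letters data.frame with columns `id`, `complaint`, `label`.
#' @param path file path.
#' @param format one of `"auto"`, `"tsv"`, `"csv"`, `"jsonl"`.
#' @return `read_corpus` returns the corpus data.frame; malformed rows
#'   (missing label, inadmissible code) raise an error naming the file line.
#' @export
write_corpus <- function(letters, path, format = "auto") {
  format <- corpus_format(path, format)
  stopifnot(all(c("id", "complaint", "label") %in% names(letters)))
  letters <- letters[, c("id", "complaint", "label")]
  assert_labels(letters$label)
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(letters)), function(i) {
      jsonlite::toJSON(as.list(letters[i, ]), auto_unbox = TRUE)
    }, character(1))
    writeLines(lines, path, useBytes = FALSE)
  } else {
    sep <- if (format == "tsv") "\t" else ","
    bad <- grepl("[\t\n\r]", letters$complaint)
    if (any(bad)) stop("complaint text may not contain tabs or newlines",
                       call. = FALSE)
    utils::write.table(letters, path, sep = sep, row.names = FALSE,
                       qmethod = "double", fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path, format = "auto") {
  format <- corpus_format(path, format)
  empty <- data.frame(id = character(0), complaint = character(0),
                      label = character(0), stringsAsFactors = FALSE)
  raw_lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(raw_lines) == 0 ||
      (format != "jsonl" && length(raw_lines) == 1)) {
    warning("empty corpus file: ", path, call. = FALSE)
    return(empty)
  }
  if (format == "jsonl") {
    rows <- lapply(seq_along(raw_lines), function(i) {
      if (!nzchar(trimws(raw_lines[i]))) return(NULL)
      rec <- tryCatch(jsonlite::fromJSON(raw_lines[i]),
                      error = function(e) {
                        stop("parse error at line ", i, " of ", path, ": ",
                             conditionMessage(e), call. = FALSE)
                      })
      if (is.null(rec$label) || !nzchar(rec$label %||% "")) {
        stop("parse error at line ", i, " of ", path, ": missing label",
             call. = FALSE)
      }
      if (!rec$label %in% disease_codes()) {
        stop("parse error at line ", i, " of ", path,
             ": unknown disease code '", rec$label, "'", call. = FALSE)
      }
      data.frame(id = rec$id %||% "", complaint = rec$complaint %||% "",
                 label = rec$label, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) {
      warning("empty corpus file: ", path, call. = FALSE)
      return(empty)
    }
    rownames(out) <- NULL
    return(out)
  }
  sep <- if (format == "tsv") "\t" else ","
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, quote = "\"",
                           fill = TRUE, encoding = "UTF-8",
                           colClasses = "character")
  if (!all(c("id", "complaint", "label") %in% names(tab))) {
    stop("corpus file ", path, " must have header id,complaint,label",
         call. = FALSE)
  }
  for (i in seq_len(nrow(tab))) {
    lab <- tab$label[i]
    if (is.na(lab) || !nzchar(lab)) {
      stop("parse error at line ", i + 1, " of ", path, ": missing label",
           call. = FALSE)
    }
    if (!lab %in% disease_codes()) {
      stop("parse error at line ", i + 1, " of ", path,
           ": unknown disease code '", lab, "'", call. = FALSE)
    }
  }
  tab[, c("id", "complaint", "label")]
}

corpus_format <- function(path, format) {
  format <- match.arg(format, c("auto", "tsv", "csv", "jsonl"))
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tsv = "tsv", tab = "tsv", csv = "csv",
    jsonl = "jsonl", ndjson = "jsonl", json = "jsonl",
    stop("cannot infer corpus format from extension '.", ext,
         "'; pass format=", call. = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
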