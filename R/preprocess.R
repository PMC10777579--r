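#' Clean a raw complaint text
#'
#' Removes junk character tokens (`$$`, `**`, `Å`, `??`, `XXX`, matched
#' case-insensitively) and configured greeting boilerplate phrases (each with
#' a dangling trailing comma/colon, so "Dear Dr," disappears wholly), then
#' collapses whitespace runs to single spaces and strips the ends. Removal is
#' iterated to a fixed point, which makes the operation idempotent even when
#' deleting one junk token spells out another. No other characters are
#' altered.
#'
#' @param raw character scalar (or vector; cleaned element-wise).
#' @param greetings character vector of greeting phrases to delete.
#' @param junk character vector of junk tokens to delete.
#' @return cleaned character vector; empty output is allowed.
#' @export
#' @examples
#' clean_text("Dear Dr XXX, $$ sudden onset headache **")
clean_text <- function(raw, greetings = default_greetings(),
                       junk = junk_tokens()) {
  vapply(raw, function(x) clean_one(x, greetings, junk), character(1),
         USE.NAMES = FALSE)
}

clean_one <- function(x, greetings, junk) {
  if (is.na(x)) return(NA_character_)
  repeat {
    before <- x
    for (j in junk) {
      x <- gsub(j, "", x, fixed = TRUE)
      lj <- tolower(j)
      if (!identical(lj, j)) x <- gsub(lj, "", x, fixed = TRUE)
    }
    for (g in greetings) {
      words <- strsplit(trimws(g), "\\s+")[[1]]
      pat <- paste0("(?i)", paste(vapply(words, escape_regex, character(1)),
                                  collapse = "\\s+"), "\\s*[,:]?")
      x <- gsub(pat, "", x, perl = TRUE)
    }
    if (identical(x, before)) break
  }
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

#' Extract symptom mentions with negation flags
#'
#' Deterministic longest-match lexicon extraction: all case-insensitive
#' occurrences of lexicon surface phrases are located at word boundaries and
#' resolved left to right, preferring the longest match at each position and
#' discarding overlaps. A mention is flagged negated when a negation trigger
#' ends within `window` whitespace tokens before the mention inside the same
#' sentence (no intervening token ending in `.`, `;`, `?` or `!`), in the
#' style of NegEx forward triggers.
#'
#' @param cleaned cleaned complaint text (a character scalar).
#' @param lexicon lexicon in list or tabular form (see [lexicon_table()]).
#' @param triggers negation trigger phrases.
#' @param window number of tokens after a trigger within which a mention
#'   counts as negated.
#' @return data.frame with columns `phrase` (text as matched), `canonical`
#'   (lexicon headword, lower case), `start`, `end` (0-based half-open
#'   character offsets into `cleaned`) and `negated` (logical), in
#'   left-to-right order.
#' @export
#' @examples
#' extract_symptoms("headache but did not lose consciousness")
extract_symptoms <- function(cleaned, lexicon = builtin_lexicon(),
                             triggers = negation_triggers(), window = 5L) {
  tab <- lexicon_table(lexicon)
  if (nrow(tab) == 0) stop("lexicon is empty", call. = FALSE)
  stopifnot(length(cleaned) == 1)
  empty <- data.frame(phrase = character(0), canonical = character(0),
                      start = integer(0), end = integer(0),
                      negated = logical(0), stringsAsFactors = FALSE)
  if (is.na(cleaned) || !nzchar(cleaned)) return(empty)
  low <- tolower(cleaned)

  hits <- list()
  for (i in seq_len(nrow(tab))) {
    pat <- paste0("\\b", escape_regex(tolower(tab$surface_phrase[i])), "\\b")
    m <- gregexpr(pat, low, perl = TRUE)[[1]]
    if (m[1] == -1) next
    len <- attr(m, "match.length")
    hits[[length(hits) + 1]] <- data.frame(
      start1 = as.integer(m), len = as.integer(len),
      canonical = tab$canonical[i], stringsAsFactors = FALSE
    )
  }
  if (length(hits) == 0) return(empty)
  h <- do.call(rbind, hits)
  h <- h[order(h$start1, -h$len), , drop = FALSE]

  keep <- logical(nrow(h))
  last_end <- 0L
  for (i in seq_len(nrow(h))) {
    if (h$start1[i] > last_end) {
      keep[i] <- TRUE
      last_end <- h$start1[i] + h$len[i] - 1L
    }
  }
  h <- h[keep, , drop = FALSE]

  toks <- token_offsets(cleaned)
  trig_end <- trigger_token_ends(toks$token, triggers)
  boundary <- grepl("[.;?!]$", toks$token)

  negated <- vapply(seq_len(nrow(h)), function(i) {
    s <- h$start1[i]
    ti <- findInterval(s, toks$start1)
    if (ti < 1) return(FALSE)
    cand <- trig_end[trig_end < ti & ti - trig_end <= window]
    if (length(cand) == 0) return(FALSE)
    any(vapply(cand, function(te) {
      span <- seq.int(te, ti - 1L)
      !any(boundary[span])
    }, logical(1)))
  }, logical(1))

  data.frame(
    phrase = substr(rep(cleaned, nrow(h)), h$start1, h$start1 + h$len - 1L),
    canonical = h$canonical,
    start = h$start1 - 1L,
    end = h$start1 + h$len - 1L,
    negated = negated,
    stringsAsFactors = FALSE
  )
}

# whitespace tokens with 1-based character offsets
token_offsets <- function(text) {
  m <- gregexpr("\\S+", text, perl = TRUE)[[1]]
  if (m[1] == -1) {
    return(data.frame(token = character(0), start1 = integer(0)))
  }
  len <- attr(m, "match.length")
  data.frame(
    token = tolower(substring(text, m, m + len - 1L)),
    start1 = as.integer(m),
    stringsAsFactors = FALSE
  )
}

# token indices at which a trigger occurrence ends
trigger_token_ends <- function(tokens, triggers) {
  stripped <- gsub("[[:punct:]]+$", "", tokens)
  ends <- integer(0)
  for (tr in triggers) {
    parts <- strsplit(tolower(tr), "\\s+")[[1]]
    k <- length(parts)
    n <- length(stripped)
    if (n < k) next
    for (s in seq_len(n - k + 1L)) {
      if (all(stripped[s:(s + k - 1L)] == parts)) {
        ends <- c(ends, s + k - 1L)
      }
    }
  }
  sort(unique(ends))
}

#' Join positive symptoms with the dot separator
#'
#' The dot is a semantically empty separator inserted between extracted
#' symptoms so that adjacent phrases form no spurious word-to-word
#' dependencies when fed to a sequence model. Negated mentions are dropped.
#' Canonical (lower-case headword) forms are emitted so that splitting on
#' the dot recovers the positive phrase list exactly.
#'
#' @param mentions data.frame as returned by [extract_symptoms()], or a
#'   character vector of already-positive canonical phrases.
#' @param dot if `FALSE`, join with plain spaces instead (the dot-ablation
#'   condition).
#' @param placeholder token emitted when no positive symptom remains.
#' @return a single string, e.g. `"falling down. dizziness. pass out."`.
#' @export
dot_separate <- function(mentions, dot = TRUE, placeholder = "[NOSYM]") {
  if (is.data.frame(mentions)) {
    phrases <- mentions$canonical[!mentions$negated]
  } else {
    phrases <- as.character(mentions)
  }
  if (length(phrases) == 0) return(placeholder)
  if (dot) paste0(paste(phrases, collapse = ". "), ".")
  else paste(phrases, collapse = " ")
}

#' Split a dot-separated symptoms string back into phrases
#'
#' Inverse of [dot_separate()] for non-placeholder output.
#'
#' @param symptoms_text dot-separated string.
#' @param placeholder the empty-symptom placeholder.
#' @return character vector of canonical phrases (possibly empty).
#' @export
split_symptoms <- function(symptoms_text, placeholder = "[NOSYM]") {
  if (identical(symptoms_text, placeholder)) return(character(0))
  parts <- trimws(strsplit(symptoms_text, ".", fixed = TRUE)[[1]])
  parts[nzchar(parts)]
}

#' Integrate complaint and symptoms into one network input
#'
#' Concatenates the cleaned complaint and the dot-separated symptoms with
#' the `[SEP]` connector used by sentence-pair encoders, keeping the original
#' context while highlighting the key information.
#'
#' @param cleaned cleaned complaint text.
#' @param symptoms_text output of [dot_separate()].
#' @return `cleaned [SEP] symptoms_text`; contains exactly one `[SEP]`
#'   whenever the inputs are free of it.
#' @export
integrate_complaint <- function(cleaned, symptoms_text) {
  stopifnot(is.character(cleaned), is.character(symptoms_text))
  paste(cleaned, "[SEP]", symptoms_text)
}

#' Run the full preprocessing pipeline over a corpus
#'
#' Applies cleaning, negation-aware symptom extraction, dot separating and
#' complaint-symptoms integration to every letter, and materialises the three
#' dataset variants used by the experiments: `Symptoms` (dot-separated
#' positive symptoms only), `Complaints` (cleaned complaint only) and
#' `Integration` (complaint `[SEP]` symptoms).
#'
#' @param letters corpus data.frame (`id`, `complaint`, `label`).
#' @param lexicon lexicon (list or table form).
#' @param dot use the dot separator in the Symptoms/Integration texts
#'   (`FALSE` gives the ablation condition).
#' @param greetings,triggers,window forwarded to [clean_text()] /
#'   [extract_symptoms()].
#' @return list with `processed` (data.frame: `id`, `label`,
#'   `cleaned_complaint`, `symptoms_text`, `integration_text`, plus a
#'   `mentions` list-column) and `variants` (named list of data.frames
#'   `text`,`label` for `Symptoms`, `Complaints`, `Integration`).
#' @export
build_variants <- function(letters, lexicon = builtin_lexicon(), dot = TRUE,
                           greetings = default_greetings(),
                           triggers = negation_triggers(), window = 5L) {
  stopifnot(is.data.frame(letters), nrow(letters) > 0)
  assert_labels(letters$label)
  n <- nrow(letters)
  cleaned <- clean_text(letters$complaint, greetings = greetings)
  mentions <- lapply(cleaned, extract_symptoms, lexicon = lexicon,
                     triggers = triggers, window = window)
  symptoms <- vapply(mentions, dot_separate, character(1), dot = dot)
  integration <- integrate_complaint(cleaned, symptoms)

  processed <- data.frame(
    id = letters$id, label = letters$label,
    cleaned_complaint = cleaned,
    symptoms_text = symptoms,
    integration_text = integration,
    stringsAsFactors = FALSE
  )
  processed$mentions <- mentions

  variants <- list(
    Symptoms = data.frame(text = symptoms, label = letters$label,
                          stringsAsFactors = FALSE),
    Complaints = data.frame(text = cleaned, label = letters$label,
                            stringsAsFactors = FALSE),
    Integration = data.frame(text = integration, label = letters$label,
                             stringsAsFactors = FALSE)
  )
  stopifnot(all(vapply(variants, nrow, integer(1)) == n))
  list(processed = processed, variants = variants)
}
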