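PAD_TOKEN <- "[PAD]"
UNK_TOKEN <- "[UNK]"
CLS_TOKEN <- "[CLS]"
SEP_TOKEN <- "[SEP]"

#' Whitespace tokenizer for the CNN branch
#'
#' Lower-cases, keeps `[SEP]` and `.` as standalone tokens, splits on
#' whitespace, truncates to `max_length` and (optionally) pads with the pad
#' token. The attention mask marks real tokens with 1 and padding with 0.
#'
#' @param text character scalar.
#' @param max_length maximum token count (>= 1).
#' @param pad pad the sequence to `max_length`.
#' @return object of class `token_sequence`: list with `tokens`, `m`
#'   (unpadded length), `attention_mask`, `truncated`.
#' @export
#' @examples
#' whitespace_tokenize("Headache. dizziness", 8)$tokens
whitespace_tokenize <- function(text, max_length = 256L, pad = FALSE) {
  stopifnot(max_length >= 1)
  x <- gsub(SEP_TOKEN, " \x01 ", text, fixed = TRUE)
  x <- tolower(x)
  x <- gsub(".", " . ", x, fixed = TRUE)
  x <- gsub("\x01", SEP_TOKEN, x, fixed = TRUE)
  toks <- strsplit(trimws(gsub("\\s+", " ", x)), " ", fixed = TRUE)[[1]]
  toks <- toks[nzchar(toks)]
  truncated <- length(toks) > max_length
  if (truncated) toks <- toks[seq_len(max_length)]
  m <- length(toks)
  if (pad && m < max_length) {
    toks <- c(toks, rep(PAD_TOKEN, max_length - m))
  }
  structure(
    list(tokens = toks, m = m,
         attention_mask = as.integer(seq_along(toks) <= m),
         truncated = truncated),
    class = "token_sequence"
  )
}

#' @export
print.token_sequence <- function(x, ...) {
  cat("<token_sequence> m=", x$m, ": ",
      paste(utils::head(x$tokens, 12), collapse = " "),
      if (length(x$tokens) > 12) " ..." else "", "\n", sep = "")
  invisible(x)
}

new_embedding_table <- function(vocabulary, matrix, oov_policy, frozen,
                                seed = NA_integer_) {
  stopifnot(is.matrix(matrix), length(vocabulary) == nrow(matrix),
            all(is.finite(matrix)))
  structure(
    list(vocabulary = vocabulary, matrix = matrix,
         d = ncol(matrix), oov_policy = oov_policy, frozen = frozen,
         seed = seed, oov_cache = new.env(parent = emptyenv())),
    class = "embedding_table"
  )
}

#' @export
print.embedding_table <- function(x, ...) {
  cat("<embedding_table> |V|=", length(x$vocabulary), " d=", x$d,
      " oov=", x$oov_policy, if (x$frozen) " (frozen)" else "", "\n", sep = "")
  invisible(x)
}

#' Load word vectors in word2vec text format
#'
#' Expects a header line `count dim` followed by one `token v1 ... v_dim`
#' line per word (the layout of fastText `.vec` files). Dedicated all-zero
#' pad and OOV rows are appended. Tables are frozen (static word vectors) by
#' default.
#'
#' @param path vector file path.
#' @param oov_policy `"random"` (seeded random vector per unknown type,
#'   cached) or `"zero"`.
#' @param frozen keep the table fixed during training.
#' @return object of class `embedding_table`.
#' @export
load_vectors <- function(path, oov_policy = c("random", "zero"),
                         frozen = TRUE) {
  oov_policy <- match.arg(oov_policy)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) < 1) stop("empty vector file: ", path, call. = FALSE)
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hdr) != 2 || anyNA(suppressWarnings(as.integer(hdr)))) {
    stop("line 1: expected header 'count dim'", call. = FALSE)
  }
  count <- as.integer(hdr[1]); d <- as.integer(hdr[2])
  if (length(lines) - 1 < count) {
    stop("vector file declares ", count, " rows but has ",
         length(lines) - 1, call. = FALSE)
  }
  vocab <- character(count)
  mat <- matrix(0, nrow = count + 2L, ncol = d)
  for (i in seq_len(count)) {
    parts <- strsplit(trimws(lines[i + 1]), "\\s+")[[1]]
    if (length(parts) != d + 1) {
      stop("line ", i + 1, ": expected ", d, " values, found ",
           length(parts) - 1, call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(parts[-1]))
    if (anyNA(vals)) stop("line ", i + 1, ": non-numeric value",
                          call. = FALSE)
    vocab[i] <- parts[1]
    mat[i, ] <- vals
  }
  vocabulary <- stats::setNames(seq_len(count + 2L),
                                c(vocab, PAD_TOKEN, UNK_TOKEN))
  new_embedding_table(vocabulary, mat, oov_policy, frozen)
}

#' Random embedding table over a fixed vocabulary
#'
#' Rows are drawn i.i.d. N(0, 1/sqrt(d)) deterministically from `seed`; the
#' pad and OOV rows are all-zero. Used in place of a large pretrained vector
#' file at desk scale.
#'
#' @param vocab character vector of token types.
#' @param d embedding dimension.
#' @param seed integer seed.
#' @inheritParams load_vectors
#' @return object of class `embedding_table`.
#' @export
random_table <- function(vocab, d = 300L, seed = 1L,
                         oov_policy = c("random", "zero"), frozen = TRUE) {
  oov_policy <- match.arg(oov_policy)
  vocab <- setdiff(unique(vocab), c(PAD_TOKEN, UNK_TOKEN))
  n <- length(vocab)
  mat <- withr::with_seed(seed, {
    m <- matrix(stats::rnorm(n * d, sd = 1 / sqrt(d)), nrow = n, ncol = d)
    rbind(m, matrix(0, 2L, d))
  })
  vocabulary <- stats::setNames(seq_len(n + 2L),
                                c(vocab, PAD_TOKEN, UNK_TOKEN))
  new_embedding_table(vocabulary, mat, oov_policy, frozen, seed = seed)
}

#' Map a token sequence to word vectors
#'
#' Pure lookup: known tokens get their stored rows exactly, pad tokens the
#' all-zero pad row, and unknown tokens follow the table's OOV policy
#' (seeded random vector cached per type, or zero).
#'
#' @param seq a `token_sequence`.
#' @param table an `embedding_table`.
#' @return object of class `embedded_sequence`: list with `vectors`
#'   (length(tokens) x d matrix), `d`, `mask`, `m`.
#' @export
embed_tokens <- function(seq, table) {
  stopifnot(inherits(seq, "token_sequence"), inherits(table, "embedding_table"))
  toks <- seq$tokens
  out <- matrix(0, nrow = length(toks), ncol = table$d)
  idx <- table$vocabulary[toks]
  known <- !is.na(idx)
  if (any(known)) out[known, ] <- table$matrix[idx[known], , drop = FALSE]
  oov <- which(!known & toks != PAD_TOKEN)
  for (i in oov) out[i, ] <- oov_lookup(table, toks[i])
  structure(list(vectors = out, d = table$d, mask = seq$attention_mask,
                 m = seq$m),
            class = "embedded_sequence")
}

oov_lookup <- function(table, token) {
  if (table$oov_policy == "zero") return(numeric(table$d))
  cached <- table$oov_cache[[token]]
  if (!is.null(cached)) return(cached)
  codes <- utf8ToInt(token)
  seed_base <- if (is.na(table$seed)) 777L else table$seed
  h <- (sum(codes * seq_along(codes)) * 31L + seed_base) %% 2147483647L
  v <- withr::with_seed(h, stats::rnorm(table$d, sd = 1 / sqrt(table$d)))
  assign(token, v, envir = table$oov_cache)
  v
}

# ---- subword tokenizer (attention branch) ----------------------------------

tokenizer_registry <- new.env(parent = emptyenv())

#' Register / fetch a subword tokenizer
#'
#' The attention branch encodes text through a named tokenizer registry so a
#' pretrained tokenizer can be swapped in behind the same interface. The
#' package ships a tiny WordPiece-style tokenizer built from a corpus (see
#' [make_tiny_tokenizer()]).
#'
#' @param name registry key.
#' @param tokenizer object of class `subword_tokenizer`.
#' @return `get_tokenizer` returns the registered tokenizer or errors for an
#'   unknown name.
#' @export
register_tokenizer <- function(name, tokenizer) {
  stopifnot(is.character(name), inherits(tokenizer, "subword_tokenizer"))
  assign(name, tokenizer, envir = tokenizer_registry)
  invisible(tokenizer)
}

#' @rdname register_tokenizer
#' @export
get_tokenizer <- function(name) {
  if (inherits(name, "subword_tokenizer")) return(name)
  if (!exists(name, envir = tokenizer_registry, inherits = FALSE)) {
    stop("unknown tokenizer '", name, "'; register it first", call. = FALSE)
  }
  get(name, envir = tokenizer_registry, inherits = FALSE)
}

#' Build the tiny WordPiece-style tokenizer from a corpus
#'
#' Vocabulary = specials (`[PAD]`, `[UNK]`, `[CLS]`, `[SEP]`) + all word
#' types observed in the texts + all single characters + `##`-prefixed
#' continuation characters. Encoding is greedy longest-prefix WordPiece, so
#' unseen words decompose into character pieces instead of collapsing to one
#' unknown id.
#'
#' @param texts character vector used to harvest the vocabulary.
#' @param max_length maximum encoded length including specials.
#' @param name if non-NULL, also register the tokenizer under this name.
#' @return object of class `subword_tokenizer` with fields `vocab`
#'   (token -> id), `pad_id`, `unk_id`, `cls_id`, `sep_id`, `max_length`.
#' @export
make_tiny_tokenizer <- function(texts, max_length = 256L, name = NULL) {
  words <- unique(unlist(lapply(texts, function(t) {
    whitespace_tokenize(t, max_length = 100000L)$tokens
  })))
  words <- setdiff(words, c(PAD_TOKEN, UNK_TOKEN, CLS_TOKEN, SEP_TOKEN))
  chars <- unique(unlist(strsplit(words, "")))
  pieces <- c(chars, paste0("##", chars))
  all_tokens <- c(PAD_TOKEN, UNK_TOKEN, CLS_TOKEN, SEP_TOKEN,
                  sort(words), sort(pieces))
  vocab <- stats::setNames(seq_along(all_tokens), all_tokens)
  tok <- structure(
    list(vocab = vocab,
         inv_vocab = all_tokens,
         pad_id = vocab[[PAD_TOKEN]], unk_id = vocab[[UNK_TOKEN]],
         cls_id = vocab[[CLS_TOKEN]], sep_id = vocab[[SEP_TOKEN]],
         max_length = as.integer(max_length)),
    class = "subword_tokenizer"
  )
  if (!is.null(name)) register_tokenizer(name, tok)
  tok
}

#' @export
print.subword_tokenizer <- function(x, ...) {
  cat("<subword_tokenizer> |V|=", length(x$vocab),
      " max_length=", x$max_length, "\n", sep = "")
  invisible(x)
}

wordpiece_word <- function(word, vocab, unk_id) {
  id <- unname(vocab[word])
  if (!is.na(id)) return(id)
  chars <- strsplit(word, "")[[1]]
  ids <- unname(vocab[ifelse(seq_along(chars) == 1, chars,
                             paste0("##", chars))])
  ids[is.na(ids)] <- unk_id
  ids
}

#' Encode a text for the attention branch
#'
#' Greedy WordPiece encoding wrapped in the tokenizer's start/end specials:
#' `[CLS] pieces... [SEP]`. A literal `[SEP]` inside the text maps to the
#' separator id, so integrated complaint/symptoms inputs look like
#' sentence-pair inputs. Truncation keeps the leading tokens and always
#' retains the final separator.
#'
#' @param text character scalar.
#' @param encoder_spec tokenizer name (registry key) or a
#'   `subword_tokenizer` object.
#' @param max_length optional override of the tokenizer's max length.
#' @return object of class `token_sequence` with integer `ids` alongside
#'   `tokens`, plus `m` and `attention_mask`.
#' @export
subword_encode <- function(text, encoder_spec, max_length = NULL) {
  tok <- get_tokenizer(encoder_spec)
  max_length <- as.integer(max_length %||% tok$max_length)
  words <- whitespace_tokenize(text, max_length = 100000L)$tokens
  ids <- c(tok$cls_id,
           unlist(lapply(words, function(w) {
             if (identical(w, SEP_TOKEN)) tok$sep_id
             else wordpiece_word(w, tok$vocab, tok$unk_id)
           })),
           tok$sep_id)
  if (length(ids) > max_length) {
    ids <- c(ids[seq_len(max_length - 1L)], tok$sep_id)
  }
  m <- length(ids)
  structure(
    list(ids = as.integer(ids), tokens = tok$inv_vocab[ids], m = m,
         attention_mask = rep(1L, m), truncated = m == max_length),
    class = "token_sequence"
  )
}
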