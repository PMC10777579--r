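#' Class probability container
#'
#' @param logits numeric vector of pre-softmax scores, one per class.
#' @param probs optional probabilities; computed from `logits` when missing.
#' @return object of class `class_probabilities` with `probs` and `logits`.
#' @keywords internal
class_probabilities <- function(logits, probs = NULL) {
  logits <- as.numeric(logits)
  if (is.null(probs)) {
    mx <- max(logits)
    e <- exp(logits - mx)
    probs <- e / sum(e)
  }
  structure(list(probs = stats::setNames(probs, disease_codes()),
                 logits = stats::setNames(logits, disease_codes())),
            class = "class_probabilities")
}

#' @export
print.class_probabilities <- function(x, ...) {
  cat("<class_probabilities>\n")
  print(round(x$probs, 4))
  invisible(x)
}

#' Fusion state of the hybrid loss
#'
#' Holds the scalar fusion weight alpha that convexly combines the CNN-branch
#' and attention-branch losses, the learning rate of its rule-based update,
#' the update counter, and the clamp bounds that keep alpha a convex weight.
#'
#' @param alpha initial fusion weight (default 0.3).
#' @param alpha_lr learning rate of the alpha update rule (default 1e-5).
#' @param clamp_bounds length-2 numeric within \[0, 1\].
#' @param step update counter.
#' @return object of class `fusion_state`.
#' @export
fusion_state <- function(alpha = 0.3, alpha_lr = 1e-5,
                         clamp_bounds = c(0.01, 0.99), step = 0L) {
  stopifnot(length(clamp_bounds) == 2, clamp_bounds[1] <= clamp_bounds[2],
            clamp_bounds[1] >= 0, clamp_bounds[2] <= 1,
            alpha >= clamp_bounds[1], alpha <= clamp_bounds[2], step >= 0)
  structure(list(alpha = alpha, alpha_lr = alpha_lr,
                 clamp_bounds = clamp_bounds, step = as.integer(step)),
            class = "fusion_state")
}

#' @export
print.fusion_state <- function(x, ...) {
  cat(sprintf("<fusion_state> alpha=%.6g lr=%.3g step=%d bounds=[%g, %g]\n",
              x$alpha, x$alpha_lr, x$step,
              x$clamp_bounds[1], x$clamp_bounds[2]))
  invisible(x)
}

#' Fuse the two branch losses
#'
#' `alpha * loss_cnn + (1 - alpha) * loss_attn`: the fused objective is
#' affine in alpha with slope `loss_cnn - loss_attn`, and the endpoints
#' alpha = 0 / 1 return the single-branch losses exactly.
#'
#' @param losses list with `loss_cnn` and `loss_attn` (nonnegative reals).
#' @param fs a [fusion_state()].
#' @return fused scalar loss.
#' @export
#' @examples
#' fuse_losses(list(loss_cnn = 1, loss_attn = 2), fusion_state(alpha = 0.3))
fuse_losses <- function(losses, fs) {
  stopifnot(inherits(fs, "fusion_state"))
  fs$alpha * losses$loss_cnn + (1 - fs$alpha) * losses$loss_attn
}

#' Rule-based update of the fusion weight
#'
#' Applies the multiplicative recurrence
#' `alpha <- alpha - (loss_cnn - loss_attn) * alpha_lr * alpha`, then clamps
#' to the state's bounds and increments the step counter. Alpha is never part
#' of any gradient graph; this is the only way it changes. Non-finite losses
#' leave the state unchanged with a warning.
#'
#' @param fs a [fusion_state()].
#' @param losses list with `loss_cnn` and `loss_attn`.
#' @return updated `fusion_state`.
#' @export
#' @examples
#' update_alpha(fusion_state(0.3, 1e-5),
#'              list(loss_cnn = 0.9, loss_attn = 0.5))$alpha
update_alpha <- function(fs, losses) {
  stopifnot(inherits(fs, "fusion_state"))
  gap <- losses$loss_cnn - losses$loss_attn
  if (!is.finite(gap)) {
    warning("non-finite branch losses; fusion state left unchanged",
            call. = FALSE)
    return(fs)
  }
  a <- fs$alpha - gap * fs$alpha_lr * fs$alpha
  a_cl <- min(max(a, fs$clamp_bounds[1]), fs$clamp_bounds[2])
  fs$alpha <- a_cl
  fs$step <- fs$step + 1L
  fs
}

#' Cross-entropy loss of predicted probabilities
#'
#' `-log p[label]`, computed from the stored logits via log-sum-exp so a
#' vanishing probability never produces `-log 0`. A list of predictions (a
#' batch) yields the mean loss.
#'
#' @param probs a `class_probabilities` object (or list of them).
#' @param label ICD code(s).
#' @return nonnegative scalar loss.
#' @export
cross_entropy <- function(probs, label) {
  if (inherits(probs, "class_probabilities")) probs <- list(probs)
  y <- label_index(label)
  stopifnot(length(probs) == length(y))
  mean(vapply(seq_along(probs), function(i) {
    softmax_ce(probs[[i]]$logits, y[i])$loss
  }, numeric(1)))
}

# ---- model constructors ----------------------------------------------------

#' Construct the CNN branch model
#'
#' Word-level tokens are looked up in a frozen (static) embedding table and
#' passed through parallel 1-D convolutions over time (kernel widths 2/3/4,
#' two filters each by default), max-pooled over time per filter,
#' concatenated, dropped out and linearly mapped to the 4 classes.
#'
#' @param table an `embedding_table` ([random_table()] or [load_vectors()]).
#' @param kernel_sizes integer kernel widths.
#' @param filters filters per kernel.
#' @param max_length token truncation length.
#' @param dropout dropout probability on the pooled vector (training only).
#' @param seed weight-initialisation seed.
#' @return object of class `refdx_model`, type `"cnn"`.
#' @export
new_cnn_model <- function(table, kernel_sizes = c(2L, 3L, 4L), filters = 2L,
                          max_length = 256L, dropout = 0.5, seed = 1L) {
  stopifnot(inherits(table, "embedding_table"))
  hp <- cnn_head_hp(table$d, kernel_sizes, filters)
  params <- withr::with_seed(seed, cnn_head_init(hp))
  structure(
    list(type = "cnn", params = params, hp = hp, table = table,
         max_length = as.integer(max_length), dropout = dropout, seed = seed),
    class = "refdx_model"
  )
}

#' Construct the attention-branch model
#'
#' A small transformer encoder (token + learned position embeddings,
#' post-layernorm blocks with multi-head self-attention and a GELU
#' feed-forward) whose first-position hidden state H summarises the input;
#' a dropout + linear head maps H to the 4 classes.
#'
#' @param tokenizer a `subword_tokenizer` or registry name.
#' @param hidden,layers,heads,ff encoder dimensions.
#' @param max_length encoder sequence limit.
#' @param dropout dropout probability on H (training only).
#' @param seed weight-initialisation seed.
#' @return object of class `refdx_model`, type `"attn"`.
#' @export
new_attn_model <- function(tokenizer, hidden = 32L, layers = 2L, heads = 2L,
                           ff = 64L, max_length = 256L, dropout = 0.5,
                           seed = 1L) {
  tok <- get_tokenizer(tokenizer)
  hp <- encoder_hp(length(tok$vocab), hidden, layers, heads, ff, max_length)
  params <- withr::with_seed(seed, {
    p <- encoder_init(hp)
    p$W_cls <- init_mat(hp$hidden, 4L)
    p$b_cls <- numeric(4L)
    p
  })
  structure(
    list(type = "attn", params = params, hp = hp, tokenizer = tok,
         max_length = as.integer(max_length), dropout = dropout, seed = seed),
    class = "refdx_model"
  )
}

#' Construct the hybrid two-branch model
#'
#' Both branches read the same text through their own tokenizers and are
#' coupled only through the alpha-weighted joint loss (training) and the
#' alpha-weighted convex combination of branch probabilities (inference).
#' Gradients never cross branches and alpha receives no gradient.
#'
#' @param attn an attention-branch model ([new_attn_model()]).
#' @param cnn a CNN-branch model ([new_cnn_model()]).
#' @param alpha0 initial fusion weight.
#' @param alpha_lr learning rate of the alpha update rule.
#' @param clamp_bounds clamp interval for alpha.
#' @param inference_rule `"fusion"` (convex combination), `"attn"` or
#'   `"cnn"` (single-branch ablations).
#' @return object of class `refdx_model`, type `"hybrid"`.
#' @export
new_hybrid_model <- function(attn, cnn, alpha0 = 0.3, alpha_lr = 1e-5,
                             clamp_bounds = c(0.01, 0.99),
                             inference_rule = c("fusion", "attn", "cnn")) {
  stopifnot(identical(attn$type, "attn"), identical(cnn$type, "cnn"))
  structure(
    list(type = "hybrid", attn = attn, cnn = cnn,
         fusion = fusion_state(alpha0, alpha_lr, clamp_bounds),
         inference_rule = match.arg(inference_rule)),
    class = "refdx_model"
  )
}

#' Construct the sequential encoder-to-CNN model
#'
#' The encoder's full per-token hidden-state matrix replaces the static
#' embedding layer of the CNN head (conv input channels = encoder hidden
#' size), forming one chained network trained end-to-end with a single
#' cross-entropy loss. No fusion weight exists in this model.
#'
#' @inheritParams new_attn_model
#' @param kernel_sizes,filters CNN head shape.
#' @return object of class `refdx_model`, type `"sequential"`.
#' @export
new_sequential_model <- function(tokenizer, hidden = 32L, layers = 2L,
                                 heads = 2L, ff = 64L,
                                 kernel_sizes = c(2L, 3L, 4L), filters = 2L,
                                 max_length = 256L, dropout = 0.5,
                                 seed = 1L) {
  tok <- get_tokenizer(tokenizer)
  enc_hp <- encoder_hp(length(tok$vocab), hidden, layers, heads, ff,
                       max_length)
  head_hp <- cnn_head_hp(hidden, kernel_sizes, filters)
  params <- withr::with_seed(seed, {
    c(encoder_init(enc_hp), cnn_head_init(head_hp))
  })
  structure(
    list(type = "sequential", params = params, enc_hp = enc_hp,
         head_hp = head_hp, tokenizer = tok,
         max_length = as.integer(max_length), dropout = dropout, seed = seed),
    class = "refdx_model"
  )
}

#' @export
print.refdx_model <- function(x, ...) {
  cat("<refdx_model> type=", x$type, sep = "")
  if (x$type == "hybrid") {
    cat(sprintf(" alpha=%.4f (rule=%s)", x$fusion$alpha, x$inference_rule))
  }
  cat("\n")
  invisible(x)
}

# ---- forward passes --------------------------------------------------------

#' Attention-branch forward pass
#'
#' @param model an `"attn"` model (or the `attn` part of a hybrid).
#' @param input text (character) or an encoded `token_sequence`.
#' @return a `class_probabilities` over the 4 classes.
#' @export
attn_branch_forward <- function(model, input) {
  if (model$type == "hybrid") model <- model$attn
  stopifnot(model$type == "attn")
  seq <- if (is.character(input)) {
    subword_encode(input, model$tokenizer, model$max_length)
  } else input
  fwd <- encoder_forward(model$params, seq$ids, model$hp)
  H <- fwd$X[1, ]
  logits <- drop(H %*% model$params$W_cls) + model$params$b_cls
  class_probabilities(logits)
}

#' CNN-branch forward pass
#'
#' @param model a `"cnn"` model (or the `cnn` part of a hybrid).
#' @param input text (character) or an `embedded_sequence`.
#' @return a `class_probabilities`; the full feature maps are attached as
#'   attribute `"features"` (`conv_maps`, `pooled`).
#' @export
cnn_branch_forward <- function(model, input) {
  if (model$type == "hybrid") model <- model$cnn
  stopifnot(model$type == "cnn")
  emb <- if (is.character(input)) {
    embed_tokens(whitespace_tokenize(input, model$max_length), model$table)
  } else input
  fwd <- cnn_head_forward(model$params, model$hp, emb$vectors,
                          valid_len = emb$m)
  out <- class_probabilities(fwd$logits)
  attr(out, "features") <- list(conv_maps = fwd$conv_maps,
                                pooled = fwd$pooled)
  out
}

#' Hybrid forward pass
#'
#' Runs both branches on the same text (each through its own tokenizer) and
#' combines them with the current fusion weight:
#' `combined = alpha * cnn + (1 - alpha) * attn` (probability space).
#'
#' @param model a `"hybrid"` model.
#' @param text character scalar.
#' @return list with `attn`, `cnn` and `combined` `class_probabilities`.
#' @export
hybrid_forward <- function(model, text) {
  stopifnot(model$type == "hybrid")
  pa <- attn_branch_forward(model$attn, text)
  pc <- cnn_branch_forward(model$cnn, text)
  a <- model$fusion$alpha
  probs <- switch(model$inference_rule,
    fusion = a * pc$probs + (1 - a) * pa$probs,
    attn = pa$probs,
    cnn = pc$probs
  )
  combined <- class_probabilities(log(pmax(probs, 1e-12)), probs = probs)
  list(attn = pa, cnn = pc, combined = combined)
}

#' Sequential model forward pass
#'
#' @param model a `"sequential"` model.
#' @param text character scalar.
#' @return a `class_probabilities`.
#' @export
sequential_forward <- function(model, text) {
  stopifnot(model$type == "sequential")
  seq <- subword_encode(text, model$tokenizer, model$max_length)
  fwd <- encoder_forward(model$params, seq$ids, model$enc_hp)
  head <- cnn_head_forward(model$params, model$head_hp, fwd$X,
                           valid_len = fwd$T_)
  class_probabilities(head$logits)
}

#' Model prediction on raw text
#'
#' @param model any `refdx_model`.
#' @param text character scalar.
#' @return a `class_probabilities` (the combined one for hybrids).
#' @export
model_predict <- function(model, text) {
  switch(model$type,
    hybrid = hybrid_forward(model, text)$combined,
    sequential = sequential_forward(model, text),
    attn = attn_branch_forward(model, text),
    cnn = cnn_branch_forward(model, text)
  )
}
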