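#' Training configuration
#'
#' Defaults follow the reference protocol: mini-batch Adam with batch size 8,
#' learning rate 1e-6, 200 epochs, dropout 0.5 and a stratified 7:2:1
#' train/validation/test split. [desk_profile()] swaps in a configuration
#' sized for laptop-scale runs on the synthetic corpus.
#'
#' @param batch_size mini-batch size.
#' @param learning_rate Adam learning rate (standard moments/epsilon).
#' @param epochs training epochs (>= 0; 0 returns the untrained model).
#' @param dropout dropout probability (pooled CNN vector and H).
#' @param seed seed controlling shuffling, dropout and initialisation.
#' @param split_ratio length-3 positive weights, normalised internally.
#' @param alpha_update `"step"` (after every optimisation step, the default)
#'   or `"epoch"` for the fusion-weight update granularity.
#' @param shuffle reshuffle training order each epoch.
#' @return object of class `train_config`.
#' @export
train_config <- function(batch_size = 8L, learning_rate = 1e-6,
                         epochs = 200L, dropout = 0.5, seed = 1L,
                         split_ratio = c(7, 2, 1),
                         alpha_update = c("step", "epoch"), shuffle = TRUE) {
  stopifnot(batch_size >= 1, learning_rate > 0, epochs >= 0,
            dropout >= 0, dropout < 1, length(split_ratio) == 3,
            all(split_ratio > 0))
  structure(
    list(batch_size = as.integer(batch_size),
         learning_rate = learning_rate, epochs = as.integer(epochs),
         dropout = dropout, seed = as.integer(seed),
         split_ratio = split_ratio,
         alpha_update = match.arg(alpha_update), shuffle = shuffle),
    class = "train_config"
  )
}

#' Model-size configuration
#'
#' @param hidden,layers,heads,ff encoder dimensions.
#' @param embedding_dim static word-vector dimension of the CNN branch.
#' @param max_length truncation length for both branches.
#' @param kernel_sizes,filters CNN head shape.
#' @param alpha0,alpha_lr fusion-weight initial value and update rate.
#' @param inference_rule hybrid inference combination rule.
#' @return plain list of model hyperparameters.
#' @export
model_config <- function(hidden = 32L, layers = 2L, heads = 2L, ff = 64L,
                         embedding_dim = 300L, max_length = 256L,
                         kernel_sizes = c(2L, 3L, 4L), filters = 2L,
                         alpha0 = 0.3, alpha_lr = 1e-5,
                         inference_rule = "fusion") {
  list(hidden = hidden, layers = layers, heads = heads, ff = ff,
       embedding_dim = embedding_dim, max_length = max_length,
       kernel_sizes = kernel_sizes, filters = filters,
       alpha0 = alpha0, alpha_lr = alpha_lr,
       inference_rule = inference_rule)
}

#' Named experiment profiles
#'
#' `desk_profile()` is the laptop-scale configuration used throughout the
#' tests and examples: the tiny encoder (hidden 32, 2 layers, 2 heads), a
#' 50-dimensional random static embedding table, 96-token truncation,
#' learning rate 1e-3 and 50 epochs. `paper_profile()` carries the
#' full-scale protocol verbatim (300-d static vectors, learning rate 1e-6,
#' 200 epochs, 256-token truncation) for use with a pretrained encoder and
#' vector file.
#'
#' @param seed seed stored in the training part of the profile.
#' @return list with elements `train` ([train_config()]) and `model`
#'   ([model_config()]).
#' @export
desk_profile <- function(seed = 1L) {
  list(
    train = train_config(batch_size = 8L, learning_rate = 1e-3,
                         epochs = 50L, dropout = 0.5, seed = seed),
    model = model_config(embedding_dim = 50L, max_length = 96L)
  )
}

#' @rdname desk_profile
#' @export
paper_profile <- function(seed = 1L) {
  list(
    train = train_config(batch_size = 8L, learning_rate = 1e-6,
                         epochs = 200L, dropout = 0.5, seed = seed),
    model = model_config(embedding_dim = 300L, max_length = 256L)
  )
}

#' Stratified train/validation/test split
#'
#' Within every class the ratio is apportioned by largest remainder (ties
#' broken toward the part with the smaller floor allocation, so no part is
#' starved), records are shuffled deterministically by `seed`, and the three
#' partitions are disjoint with union equal to the input.
#'
#' @param records data.frame with a `label` column.
#' @param ratio length-3 positive weights (default 7:2:1).
#' @param seed shuffle seed.
#' @return list with data.frames `train`, `val`, `test`.
#' @export
split_dataset <- function(records, ratio = c(7, 2, 1), seed = 1L) {
  stopifnot(is.data.frame(records), nrow(records) >= 10,
            length(ratio) == 3, all(ratio > 0))
  assert_labels(records$label)
  counts <- table(records$label)
  if (any(counts < 3)) {
    stop("class(es) with fewer than 3 records: ",
         paste(names(counts)[counts < 3], collapse = ", "),
         "; generate a larger corpus", call. = FALSE)
  }
  ratio <- ratio / sum(ratio)
  parts <- list(train = integer(0), val = integer(0), test = integer(0))
  withr::with_seed(seed, {
    for (cls in names(counts)) {
      idx <- which(records$label == cls)
      idx <- idx[sample.int(length(idx))]
      n_c <- length(idx)
      q <- n_c * ratio
      fl <- floor(q)
      extra <- n_c - sum(fl)
      if (extra > 0) {
        ord <- order(-(q - fl), fl, seq_along(fl))
        fl[ord[seq_len(extra)]] <- fl[ord[seq_len(extra)]] + 1
      }
      cuts <- cumsum(fl)
      parts$train <- c(parts$train, idx[seq_len(fl[1])])
      parts$val <- c(parts$val,
                     if (fl[2] > 0) idx[(cuts[1] + 1):cuts[2]] else integer(0))
      parts$test <- c(parts$test,
                      if (fl[3] > 0) idx[(cuts[2] + 1):cuts[3]] else integer(0))
    }
  })
  lapply(parts, function(i) {
    out <- records[sort(i), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Classification accuracy
#'
#' Fraction of predictions whose argmax class equals the label; argmax ties
#' resolve to the lowest class index (a message is emitted when a tie
#' occurs).
#'
#' @param predictions list of `class_probabilities`, or a numeric matrix of
#'   probabilities with one row per prediction (columns in canonical class
#'   order).
#' @param labels ICD codes of the same length.
#' @return accuracy in \[0, 1\].
#' @export
accuracy <- function(predictions, labels) {
  P <- if (is.matrix(predictions)) predictions else {
    do.call(rbind, lapply(predictions, function(p) p$probs))
  }
  y <- label_index(labels)
  stopifnot(nrow(P) == length(y), length(y) > 0)
  ties <- apply(P, 1, function(r) sum(r == max(r)) > 1)
  if (any(ties)) {
    message(sum(ties), " argmax tie(s) broken toward the lowest class index")
  }
  pred <- apply(P, 1, which.max)
  mean(pred == y)
}

# ---- per-sample gradient steps --------------------------------------------

attn_sample_step <- function(params, hp, ids, y, dropout) {
  fwd <- encoder_forward(params, ids, hp)
  H <- fwd$X[1, ]
  mask <- if (dropout > 0) {
    (stats::runif(hp$hidden) >= dropout) / (1 - dropout)
  } else rep(1, hp$hidden)
  Hd <- H * mask
  logits <- drop(Hd %*% params$W_cls) + params$b_cls
  ce <- softmax_ce(logits, y)
  g <- list(W_cls = outer(Hd, ce$dlogits), b_cls = ce$dlogits)
  dH <- drop(params$W_cls %*% ce$dlogits) * mask
  dX <- matrix(0, fwd$T_, hp$hidden)
  dX[1, ] <- dH
  g <- c(g, encoder_backward(params, fwd, hp, dX))
  list(loss = ce$loss, grads = g, pred = which.max(ce$probs),
       probs = ce$probs)
}

cnn_sample_step <- function(params, hp, emb, y, dropout) {
  fwd <- cnn_head_forward(params, hp, emb$vectors, valid_len = emb$m,
                          dropout_p = dropout)
  ce <- softmax_ce(fwd$logits, y)
  bwd <- cnn_head_backward(params, hp, fwd, ce$dlogits, need_dX = FALSE)
  list(loss = ce$loss, grads = bwd$grads, pred = which.max(ce$probs),
       probs = ce$probs)
}

seq_sample_step <- function(params, enc_hp, head_hp, ids, y, dropout) {
  fwd <- encoder_forward(params, ids, enc_hp)
  head <- cnn_head_forward(params, head_hp, fwd$X, valid_len = fwd$T_,
                           dropout_p = dropout)
  ce <- softmax_ce(head$logits, y)
  bwd <- cnn_head_backward(params, head_hp, head, ce$dlogits, need_dX = TRUE)
  dX <- bwd$dX[seq_len(fwd$T_), , drop = FALSE]
  g <- c(bwd$grads, encoder_backward(params, fwd, enc_hp, dX))
  list(loss = ce$loss, grads = g, pred = which.max(ce$probs),
       probs = ce$probs)
}

env_to_grads <- function(env, scale = 1) {
  out <- as.list(env)
  lapply(out, function(x) x * scale)
}

# ---- training --------------------------------------------------------------

#' Train a model
#'
#' Mini-batch Adam on the model's objective: the alpha-fused joint
#' cross-entropy for hybrids (with the rule-based alpha update once per step
#' or per epoch), a single cross-entropy otherwise. Gradients never cross
#' the hybrid's branches. Under a fixed seed the run is bit-reproducible on
#' the same platform.
#'
#' @param model a `refdx_model`.
#' @param data data.frame with `text` and `label` columns.
#' @param cfg a [train_config()].
#' @param val_data optional validation data.frame evaluated after every
#'   epoch.
#' @return list with `model` (trained) and `history` (list: `epochs`
#'   data.frame, `steps` data.frame with per-step losses and — for hybrids —
#'   the alpha trace).
#' @export
train_model <- function(model, data, cfg = train_config(), val_data = NULL) {
  stopifnot(inherits(model, "refdx_model"), is.data.frame(data),
            nrow(data) > 0, inherits(cfg, "train_config"))
  y <- label_index(data$label)
  n <- nrow(data)
  if (cfg$epochs == 0) {
    return(list(model = model,
                history = list(epochs = empty_epoch_history(),
                               steps = empty_step_history(model$type))))
  }

  enc <- precompute_inputs(model, data$text)
  ep_rows <- vector("list", cfg$epochs)
  st_rows <- list()
  step_i <- 0L

  withr::with_seed(cfg$seed, {
    opt <- init_optimizers(model)
    for (epoch in seq_len(cfg$epochs)) {
      ord <- if (cfg$shuffle) sample.int(n) else seq_len(n)
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      ep_loss <- 0; ep_correct <- 0L
      epoch_losses <- c(cnn = 0, attn = 0); n_steps_epoch <- 0L
      for (b in batches) {
        step_i <- step_i + 1L
        res <- train_step(model, opt, enc, y, b, cfg)
        model <- res$model; opt <- res$opt
        if (!all(is.finite(unlist(res$losses)))) {
          stop("non-finite loss at step ", step_i, " (batch ids: ",
               paste(b, collapse = ","), ")", call. = FALSE)
        }
        ep_loss <- ep_loss + res$losses$loss * length(b)
        ep_correct <- ep_correct + res$correct
        st_rows[[step_i]] <- data.frame(
          step = step_i, epoch = epoch, loss = res$losses$loss,
          loss_cnn = res$losses$loss_cnn %||% NA_real_,
          loss_attn = res$losses$loss_attn %||% NA_real_,
          alpha = if (model$type == "hybrid") model$fusion$alpha else NA_real_
        )
        if (model$type == "hybrid") {
          epoch_losses <- epoch_losses +
            c(res$losses$loss_cnn, res$losses$loss_attn)
          n_steps_epoch <- n_steps_epoch + 1L
        }
      }
      if (model$type == "hybrid" && cfg$alpha_update == "epoch") {
        ml <- epoch_losses / n_steps_epoch
        model$fusion <- update_alpha(model$fusion,
                                     list(loss_cnn = ml[["cnn"]],
                                          loss_attn = ml[["attn"]]))
      }
      val_loss <- NA_real_; val_acc <- NA_real_
      if (!is.null(val_data)) {
        ev <- evaluate_model(model, val_data)
        val_loss <- ev$loss; val_acc <- ev$accuracy
      }
      ep_rows[[epoch]] <- data.frame(
        epoch = epoch, train_loss = ep_loss / n,
        train_acc = ep_correct / n, val_loss = val_loss, val_acc = val_acc
      )
    }
  })
  list(model = model,
       history = list(epochs = do.call(rbind, ep_rows),
                      steps = do.call(rbind, st_rows)))
}

empty_epoch_history <- function() {
  data.frame(epoch = integer(0), train_loss = numeric(0),
             train_acc = numeric(0), val_loss = numeric(0),
             val_acc = numeric(0))
}

empty_step_history <- function(type) {
  data.frame(step = integer(0), epoch = integer(0), loss = numeric(0),
             loss_cnn = numeric(0), loss_attn = numeric(0),
             alpha = numeric(0))
}

precompute_inputs <- function(model, texts) {
  switch(model$type,
    attn = list(ids = lapply(texts, function(t) {
      subword_encode(t, model$tokenizer, model$max_length)$ids
    })),
    sequential = list(ids = lapply(texts, function(t) {
      subword_encode(t, model$tokenizer, model$max_length)$ids
    })),
    cnn = list(emb = lapply(texts, function(t) {
      e <- embed_tokens(whitespace_tokenize(t, model$max_length), model$table)
      list(vectors = e$vectors, m = e$m)
    })),
    hybrid = list(
      ids = lapply(texts, function(t) {
        subword_encode(t, model$attn$tokenizer, model$attn$max_length)$ids
      }),
      emb = lapply(texts, function(t) {
        e <- embed_tokens(whitespace_tokenize(t, model$cnn$max_length),
                          model$cnn$table)
        list(vectors = e$vectors, m = e$m)
      })
    )
  )
}

init_optimizers <- function(model) {
  switch(model$type,
    hybrid = list(attn = adam_init(model$attn$params),
                  cnn = adam_init(model$cnn$params)),
    list(main = adam_init(model$params))
  )
}

train_step <- function(model, opt, enc, y, b, cfg) {
  B <- length(b)
  if (model$type == "hybrid") {
    a <- model$fusion$alpha
    ga <- new.env(parent = emptyenv())
    gc_ <- new.env(parent = emptyenv())
    la <- 0; lc <- 0; correct <- 0L
    for (i in b) {
      ra <- attn_sample_step(model$attn$params, model$attn$hp,
                             enc$ids[[i]], y[i], cfg$dropout)
      rc <- cnn_sample_step(model$cnn$params, model$cnn$hp,
                            enc$emb[[i]], y[i], cfg$dropout)
      acc_grads(ga, ra$grads, (1 - a) / B)
      acc_grads(gc_, rc$grads, a / B)
      la <- la + ra$loss / B
      lc <- lc + rc$loss / B
      comb <- a * rc$probs + (1 - a) * ra$probs
      if (which.max(comb) == y[i]) correct <- correct + 1L
    }
    sa <- adam_step(model$attn$params, as.list(ga), opt$attn,
                    cfg$learning_rate)
    sc <- adam_step(model$cnn$params, as.list(gc_), opt$cnn,
                    cfg$learning_rate)
    model$attn$params <- sa$params; opt$attn <- sa$state
    model$cnn$params <- sc$params; opt$cnn <- sc$state
    losses <- list(loss_cnn = lc, loss_attn = la,
                   loss = a * lc + (1 - a) * la)
    if (cfg$alpha_update == "step") {
      model$fusion <- update_alpha(model$fusion, losses)
    }
    return(list(model = model, opt = opt, losses = losses,
                correct = correct))
  }
  genv <- new.env(parent = emptyenv())
  loss <- 0; correct <- 0L
  for (i in b) {
    r <- switch(model$type,
      attn = attn_sample_step(model$params, model$hp, enc$ids[[i]], y[i],
                              cfg$dropout),
      cnn = cnn_sample_step(model$params, model$hp, enc$emb[[i]], y[i],
                            cfg$dropout),
      sequential = seq_sample_step(model$params, model$enc_hp,
                                   model$head_hp, enc$ids[[i]], y[i],
                                   cfg$dropout)
    )
    acc_grads(genv, r$grads, 1 / B)
    loss <- loss + r$loss / B
    if (r$pred == y[i]) correct <- correct + 1L
  }
  st <- adam_step(model$params, as.list(genv), opt$main, cfg$learning_rate)
  model$params <- st$params; opt$main <- st$state
  list(model = model, opt = opt, losses = list(loss = loss),
       correct = correct)
}

#' Evaluate a model on labelled data
#'
#' Eval-mode forward (no dropout) over every record.
#'
#' @param model a `refdx_model`.
#' @param data data.frame with `text`, `label`.
#' @return list with `accuracy`, `loss` (mean cross-entropy), `per_class`
#'   (named accuracy per ICD code) and `predictions`.
#' @export
evaluate_model <- function(model, data) {
  preds <- lapply(data$text, function(t) model_predict(model, t))
  y <- label_index(data$label)
  P <- do.call(rbind, lapply(preds, function(p) p$probs))
  pred_idx <- apply(P, 1, which.max)
  losses <- vapply(seq_along(preds), function(i) {
    softmax_ce(preds[[i]]$logits, y[i])$loss
  }, numeric(1))
  per_class <- vapply(seq_along(disease_codes()), function(k) {
    sel <- y == k
    if (!any(sel)) return(NA_real_)
    mean(pred_idx[sel] == k)
  }, numeric(1))
  list(accuracy = mean(pred_idx == y), loss = mean(losses),
       per_class = stats::setNames(per_class, disease_codes()),
       predictions = preds)
}

#' Build a model for an architecture from training texts
#'
#' Constructs the tokenizer (tiny WordPiece harvested from the training
#' texts), the frozen random embedding table for the CNN branch, and the
#' requested architecture.
#'
#' @param arch one of `"hybrid"`, `"sequential"`, `"attn"`, `"cnn"`.
#' @param texts training texts (used for vocabulary harvesting only).
#' @param mc a [model_config()].
#' @param dropout dropout probability stored on the model.
#' @param seed initialisation seed.
#' @return a `refdx_model`.
#' @export
build_model <- function(arch = c("hybrid", "sequential", "attn", "cnn"),
                        texts, mc = model_config(), dropout = 0.5,
                        seed = 1L) {
  arch <- match.arg(arch)
  tok <- make_tiny_tokenizer(texts, max_length = mc$max_length)
  word_vocab <- unique(unlist(lapply(texts, function(t) {
    whitespace_tokenize(t, max_length = 100000L)$tokens
  })))
  make_cnn <- function() {
    tab <- random_table(word_vocab, d = mc$embedding_dim, seed = seed)
    new_cnn_model(tab, kernel_sizes = mc$kernel_sizes, filters = mc$filters,
                  max_length = mc$max_length, dropout = dropout, seed = seed)
  }
  make_attn <- function() {
    new_attn_model(tok, hidden = mc$hidden, layers = mc$layers,
                   heads = mc$heads, ff = mc$ff,
                   max_length = mc$max_length, dropout = dropout,
                   seed = seed)
  }
  switch(arch,
    cnn = make_cnn(),
    attn = make_attn(),
    hybrid = new_hybrid_model(make_attn(), make_cnn(), alpha0 = mc$alpha0,
                              alpha_lr = mc$alpha_lr,
                              inference_rule = mc$inference_rule),
    sequential = new_sequential_model(tok, hidden = mc$hidden,
                                      layers = mc$layers, heads = mc$heads,
                                      ff = mc$ff,
                                      kernel_sizes = mc$kernel_sizes,
                                      filters = mc$filters,
                                      max_length = mc$max_length,
                                      dropout = dropout, seed = seed)
  )
}

#' Run the architecture-by-variant experiment grid
#'
#' Preprocesses the corpus into the dataset variants, splits once per seed
#' (the same partition is reused across variants so accuracies are
#' comparable), trains every (architecture, variant) pair and evaluates on
#' the held-out test split. When `dot_ablation` is TRUE the grid also
#' includes the `Symptoms` and `Integration` texts rebuilt without the dot
#' separator (`SymptomsNoDot`, `IntegrationNoDot`).
#'
#' @param corpus letters data.frame (`id`, `complaint`, `label`).
#' @param architectures character vector of architecture names.
#' @param variants character vector of variant names to run.
#' @param profile list with `train` and `model` configs (see
#'   [desk_profile()]).
#' @param n_seeds number of seeds; run `s` uses `profile$train$seed + s - 1`.
#' @param lexicon lexicon used for preprocessing.
#' @param dot_ablation include the no-dot ablation variants.
#' @return object of class `experiment_report`: list with `grid`
#'   (data.frame: architecture, variant, seed, accuracy, one `acc_<code>`
#'   column per class), `seeds`, `profile`. Failed runs are recorded with
#'   `NA` accuracy and the grid continues.
#' @export
run_grid <- function(corpus, architectures = c("hybrid", "attn", "cnn"),
                     variants = c("Symptoms", "Complaints", "Integration"),
                     profile = desk_profile(), n_seeds = 1L,
                     lexicon = builtin_lexicon(), dot_ablation = FALSE) {
  built <- build_variants(corpus, lexicon = lexicon)
  vars <- built$variants
  if (dot_ablation) {
    nodot <- build_variants(corpus, lexicon = lexicon, dot = FALSE)$variants
    vars$SymptomsNoDot <- nodot$Symptoms
    vars$IntegrationNoDot <- nodot$Integration
  }
  missing_v <- setdiff(variants, names(vars))
  if (length(missing_v) > 0) {
    stop("unknown variant(s): ", paste(missing_v, collapse = ", "),
         call. = FALSE)
  }
  seeds <- profile$train$seed + seq_len(n_seeds) - 1L
  rows <- list()
  for (s in seeds) {
    cfg <- profile$train
    cfg$seed <- as.integer(s)
    parts <- split_dataset(corpus, ratio = cfg$split_ratio, seed = s)
    part_idx <- lapply(parts, function(p) match(p$id, corpus$id))
    for (arch in architectures) {
      for (v in variants) {
        dat <- vars[[v]]
        tr <- dat[part_idx$train, , drop = FALSE]
        te <- dat[part_idx$test, , drop = FALSE]
        row <- tryCatch({
          mdl <- build_model(arch, tr$text, profile$model,
                             dropout = cfg$dropout, seed = s)
          fit <- train_model(mdl, tr, cfg)
          ev <- evaluate_model(fit$model, te)
          cbind(
            data.frame(architecture = arch, variant = v, seed = s,
                       accuracy = ev$accuracy, stringsAsFactors = FALSE),
            as.data.frame(as.list(stats::setNames(
              ev$per_class, paste0("acc_", names(ev$per_class)))))
          )
        }, error = function(e) {
          warning("grid run failed (", arch, ", ", v, ", seed ", s, "): ",
                  conditionMessage(e), call. = FALSE)
          data.frame(architecture = arch, variant = v, seed = s,
                     accuracy = NA_real_, acc_G40 = NA_real_,
                     acc_R51 = NA_real_, acc_M54 = NA_real_,
                     acc_I63 = NA_real_, stringsAsFactors = FALSE)
        })
        rows[[length(rows) + 1]] <- row
      }
    }
  }
  structure(
    list(grid = do.call(rbind, rows), seeds = seeds, profile = profile),
    class = "experiment_report"
  )
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report> seeds:", paste(x$seeds, collapse = ", "), "\n")
  agg <- stats::aggregate(accuracy ~ architecture + variant, data = x$grid,
                          FUN = mean)
  print(agg, row.names = FALSE)
  invisible(x)
}
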