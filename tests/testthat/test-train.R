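test_that("stratified split apportions 7:2:1 by largest remainder", {
  one_class <- data.frame(id = as.character(1:10),
                          label = rep("G40", 10))
  parts <- split_dataset(one_class, seed = 1)
  expect_equal(vapply(parts, nrow, integer(1)),
               c(train = 7L, val = 2L, test = 1L))

  per5 <- data.frame(id = as.character(1:20),
                     label = rep(disease_codes(), each = 5))
  p5 <- split_dataset(per5, seed = 2)
  for (cls in disease_codes()) {
    sizes <- vapply(p5, function(p) sum(p$label == cls), integer(1))
    expect_equal(sizes, c(train = 3L, val = 1L, test = 1L))
  }
  # partition: disjoint with union equal to the input
  all_ids <- unlist(lapply(p5, `[[`, "id"))
  expect_setequal(all_ids, per5$id)
  expect_equal(anyDuplicated(all_ids), 0)

  expect_identical(split_dataset(per5, seed = 2), p5)
  expect_false(identical(split_dataset(per5, seed = 3), p5))

  tiny <- data.frame(id = as.character(1:10),
                     label = c(rep("G40", 8), "R51", "R51"))
  expect_error(split_dataset(tiny, seed = 1), "larger corpus")
})

test_that("split stays within one record per class per part of the quota", {
  corpus <- generate_corpus(synth_config(n_per_class = 13, seed = 5))
  parts <- split_dataset(corpus, seed = 5)
  ratio <- c(7, 2, 1) / 10
  for (cls in disease_codes()) {
    sizes <- vapply(parts, function(p) sum(p$label == cls), integer(1))
    expect_true(all(abs(sizes - 13 * ratio) <= 1))
  }
})

test_that("accuracy counts argmax agreement with deterministic ties", {
  P <- matrix(0, 27, 4)
  truth <- rep(disease_codes(), length.out = 27)
  for (i in 1:27) P[i, refdx:::label_index(truth[i])] <- 1
  wrong <- 25:27
  P[wrong, ] <- 0
  P[wrong, 1] <- 1   # G40 guesses
  truth[wrong] <- "R51"
  expect_equal(accuracy(P, truth), 24 / 27, tolerance = 1e-12)
  expect_equal(round(accuracy(P, truth), 4), 0.8889)

  # tie -> lowest class index, with a message
  tie <- matrix(0.25, 1, 4)
  expect_message(a <- accuracy(tie, "G40"), "tie")
  expect_equal(a, 1)

  # random predictor on balanced labels concentrates near 0.25
  withr::with_seed(123, {
    n <- 4000
    R <- matrix(stats::runif(n * 4), n, 4)
    R <- R / rowSums(R)
    lab <- sample(disease_codes(), n, replace = TRUE)
    expect_lt(abs(accuracy(R, lab) - 0.25), 0.02)
  })
})

test_that("zero epochs returns the untrained model and empty history", {
  tok <- tiny_tokenizer()
  am <- new_attn_model(tok, hidden = 8, layers = 1, heads = 2, ff = 12,
                       max_length = 48, seed = 1)
  dat <- data.frame(text = tiny_texts(),
                    label = disease_codes(), stringsAsFactors = FALSE)
  cfg <- train_config(epochs = 0, seed = 1)
  fit <- train_model(am, dat, cfg)
  expect_identical(fit$model$params, am$params)
  expect_equal(nrow(fit$history$epochs), 0)
})

test_that("a tiny hybrid memorises eight separable letters", {
  corpus <- generate_corpus(separable_config(2, seed = 8))
  built <- build_variants(corpus)
  dat <- built$variants$Integration
  mc <- model_config(hidden = 16, ff = 32, embedding_dim = 16,
                     max_length = 96)
  mdl <- build_model("hybrid", dat$text, mc, dropout = 0.5, seed = 8)
  cfg <- train_config(batch_size = 8, learning_rate = 1e-3, epochs = 200,
                      dropout = 0.5, seed = 8)
  fit <- train_model(mdl, dat, cfg)
  expect_equal(evaluate_model(fit$model, dat)$accuracy, 1.0)
})

test_that("training is bit-reproducible under a fixed seed", {
  corpus <- generate_corpus(separable_config(3, seed = 9))
  built <- build_variants(corpus)
  dat <- built$variants$Symptoms
  mc <- model_config(hidden = 8, ff = 16, embedding_dim = 8, max_length = 48)
  cfg <- train_config(learning_rate = 1e-3, epochs = 3, seed = 11)
  run <- function() {
    mdl <- build_model("hybrid", dat$text, mc, dropout = 0.5, seed = 11)
    train_model(mdl, dat, cfg)
  }
  f1 <- run(); f2 <- run()
  expect_identical(f1$history$steps, f2$history$steps)
  expect_identical(f1$model$fusion$alpha, f2$model$fusion$alpha)
})

test_that("the alpha trace replays exactly from the logged step losses", {
  fit <- learnability_fit()$fit
  steps <- fit$history$steps
  fs <- fusion_state(alpha = 0.3, alpha_lr = 1e-5)
  replay <- numeric(nrow(steps))
  for (i in seq_len(nrow(steps))) {
    fs <- update_alpha(fs, list(loss_cnn = steps$loss_cnn[i],
                                loss_attn = steps$loss_attn[i]))
    replay[i] <- fs$alpha
  }
  expect_equal(replay, steps$alpha, tolerance = 1e-15)
  expect_equal(steps$alpha[1],
               update_alpha(fusion_state(0.3, 1e-5),
                            list(loss_cnn = steps$loss_cnn[1],
                                 loss_attn = steps$loss_attn[1]))$alpha)
  # fused loss is exactly the recorded convex combination
  a_before <- c(0.3, steps$alpha[-nrow(steps)])
  expect_equal(steps$loss,
               a_before * steps$loss_cnn + (1 - a_before) * steps$loss_attn,
               tolerance = 1e-12)
})

test_that("train loss trends downward on the learnable corpus", {
  fit <- learnability_fit()$fit
  h <- fit$history$epochs$train_loss
  expect_true(all(is.finite(h)))
  ma <- stats::filter(h, rep(1 / 10, 10), sides = 1)
  ma <- ma[!is.na(ma)]
  expect_true(all(diff(ma) <= 1e-3))
  expect_lt(ma[length(ma)], ma[1])
})

test_that("run_grid reports one accuracy per architecture-variant pair", {
  corpus <- generate_corpus(synth_config(n_per_class = 5, seed = 4))
  prof <- desk_profile(seed = 4)
  prof$train$epochs <- 2L
  prof$model <- model_config(hidden = 8, ff = 16, embedding_dim = 8,
                             max_length = 96)
  rep <- run_grid(corpus, architectures = c("cnn", "attn"),
                  variants = c("Symptoms", "Complaints", "Integration"),
                  profile = prof, n_seeds = 1)
  expect_equal(nrow(rep$grid), 6)
  expect_true(all(rep$grid$accuracy >= 0 & rep$grid$accuracy <= 1))
  expect_setequal(unique(rep$grid$architecture), c("cnn", "attn"))

  # dot ablation variants are available on demand
  rep2 <- run_grid(corpus, architectures = "cnn",
                   variants = c("Symptoms", "SymptomsNoDot"),
                   profile = prof, n_seeds = 1, dot_ablation = TRUE)
  expect_equal(nrow(rep2$grid), 2)
})
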