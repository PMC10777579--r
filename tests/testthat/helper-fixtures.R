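# Shared fixtures. Heavy training runs are memoized so several test files
# can assert different properties of the same fit without re-training.

.fixtures <- new.env(parent = emptyenv())

example_letters <- function() {
  path <- system.file("extdata", "example_letters.tsv", package = "refdx")
  read_corpus(path)
}

example_letter <- function(code) {
  ex <- example_letters()
  ex$complaint[ex$label == code]
}

# zero-noise, fully separable study conditions
separable_config <- function(n_per_class, seed = 42L) {
  synth_config(n_per_class = n_per_class, junk_token_rate = 0,
               distractor_rate = 0, negated_phrases_per_letter = 0,
               seed = seed)
}

tiny_texts <- function() {
  c("headache and dizziness today", "seizure with fatigued state",
    "back pain and leg pain", "left arm weakness noted")
}

tiny_tokenizer <- function() {
  if (is.null(.fixtures$tok)) {
    .fixtures$tok <- make_tiny_tokenizer(tiny_texts(), max_length = 48)
  }
  .fixtures$tok
}

# hybrid trained on the 400-letter separable corpus under the desk profile;
# used by the learnability, convergence and alpha-replay checks
learnability_fit <- function() {
  if (is.null(.fixtures$learn)) {
    corpus <- generate_corpus(separable_config(100, seed = 42))
    built <- build_variants(corpus)
    parts <- split_dataset(corpus, seed = 42)
    idx <- lapply(parts, function(p) match(p$id, corpus$id))
    dat <- built$variants$Integration
    prof <- desk_profile(seed = 42)
    mdl <- build_model("hybrid", dat$text[idx$train], prof$model,
                       dropout = prof$train$dropout, seed = 42)
    fit <- train_model(mdl, dat[idx$train, ], prof$train)
    test_acc <- evaluate_model(fit$model, dat[idx$test, ])$accuracy
    .fixtures$learn <- list(fit = fit, test_accuracy = test_acc,
                            n_train = length(idx$train),
                            n_test = length(idx$test))
  }
  .fixtures$learn
}

# hybrid accuracy per variant on the default (noisy) corpus, 3 seeds
variant_grid <- function() {
  if (is.null(.fixtures$grid)) {
    corpus <- generate_corpus(synth_config(seed = 42))
    .fixtures$grid <- run_grid(
      corpus, architectures = "hybrid",
      variants = c("Symptoms", "Complaints", "Integration"),
      profile = desk_profile(seed = 42), n_seeds = 3
    )
  }
  .fixtures$grid
}

# brute-force lexicon-overlap label oracle: argmax of class phrase hits
overlap_oracle <- function(complaint, lexicon = builtin_lexicon()) {
  low <- tolower(complaint)
  hits <- vapply(disease_codes(), function(cls) {
    sum(vapply(lexicon[[cls]], function(p) {
      m <- gregexpr(p, low, fixed = TRUE)[[1]]
      if (m[1] == -1) 0L else length(m)
    }, integer(1)))
  }, integer(1))
  disease_codes()[which.max(hits)]
}
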