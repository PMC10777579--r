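# refdx — hybrid attention-CNN classification of GP referral letters

When a general practitioner refers a patient, the referral letter's
free-text complaint already contains most of what a specialist needs for a
primary diagnosis. `refdx` turns that letter into a 4-way classification
over common neurological ICD codes — **G40** (epilepsy-recurrent seizures),
**R51** (headache), **M54** (dorsalgia), **I63** (cerebral infarction) —
for researchers and engineers building triage/decision-support tools on
clinical free text.

The package implements the full chain in R, with every network written and
back-propagated in base matrix code:

* **Preprocessing** — cleaning (junk tokens `$$ ** Å ?? XXX`, greeting
  boilerplate), negation-aware longest-match symptom extraction
  (NegEx-style triggers `no, not, did not, denies, without, never`, 5-token
  window), *symptom dot separating* (`"falling down. dizziness. pass
  out."`), and *complaint-symptoms integration*
  (`complaint [SEP] symptoms`). These yield the three dataset views
  **Symptoms**, **Complaints**, **Integration**.
* **The hybrid classifier** — two branches over the same text: a small
  transformer encoder (first-position state `H`, softmax head
  `p_attn = Softmax(Linear(H))`) and a 1-D CNN over frozen word vectors
  (kernel widths 2/3/4, two filters each, max-pool to a 6-vector,
  `p_cnn = Softmax(Linear(MaxPool(conv1d(X_vec))))`). Training minimises
  the adaptively fused objective

  ```
  Loss = α·Loss_CNN + (1−α)·Loss_attn
  α ← α − (Loss_CNN − Loss_attn)·lr·α        (α₀ = 0.3, lr = 1e−5)
  ```

  with gradient-isolated branches (α receives no gradient); inference
  combines the branch probabilities with the final α. Single-branch and
  sequential (encoder-as-embedding → CNN) baselines are included.
* **Protocol** — stratified 7:2:1 split (largest-remainder per class),
  mini-batch Adam, accuracy metric, an architecture × variant experiment
  grid with a dot-separation ablation, and a synthetic referral-letter
  generator so everything is testable without clinical data.

## Worked example

```r
library(refdx)

letters <- read_corpus(system.file("extdata", "example_letters.tsv",
                                   package = "refdx"))
letter  <- letters$complaint[letters$label == "R51"]

cleaned  <- clean_text(letter)
mentions <- extract_symptoms(cleaned)
mentions[, c("phrase", "canonical", "negated")]
#>               phrase          canonical negated
#> 1       falling down       falling down   FALSE
#> 2          dizziness          dizziness   FALSE
#> 3           pass out           pass out   FALSE
#> 4 lose consciousness lose consciousness    TRUE
#> 5           headache           headache   FALSE
#> 6      tunnel vision      tunnel vision   FALSE
#> 7           diplopia           diplopia   FALSE
```

The extractor found seven symptom mentions in the headache letter;
`lose consciousness` is flagged negated because it follows "did not" within
the negation window, so it is excluded from the symptom summary:

```r
symptoms <- dot_separate(mentions)
symptoms
#> [1] "falling down. dizziness. pass out. headache. tunnel vision. diplopia."
integrate_complaint(cleaned, symptoms)   # the Integration network input
#> [1] "this 56-year-old gentleman. He was admitted on 27-11-18 after falling
#>      down the stairs. ... [SEP] falling down. dizziness. pass out. ..."
```

The fusion arithmetic is exactly the two equations above:

```r
fs <- fusion_state(alpha = 0.3, alpha_lr = 1e-5)
fuse_losses(list(loss_cnn = 1.0, loss_attn = 2.0), fs)
#> [1] 1.7
update_alpha(fs, list(loss_cnn = 0.9, loss_attn = 0.5))$alpha
#> [1] 0.2999988
```

Training end-to-end on synthetic letters (desk profile: tiny encoder,
50-d random static vectors, lr 1e-3, 50 epochs):

```r
corpus <- generate_corpus(synth_config(n_per_class = 100, seed = 42,
                                       junk_token_rate = 0,
                                       distractor_rate = 0,
                                       negated_phrases_per_letter = 0))
built  <- build_variants(corpus)
parts  <- split_dataset(corpus, seed = 42)
idx    <- lapply(parts, function(p) match(p$id, corpus$id))
dat    <- built$variants$Integration
prof   <- desk_profile(seed = 42)
model  <- build_model("hybrid", dat$text[idx$train], prof$model, seed = 42)
fit    <- train_model(model, dat[idx$train, ], prof$train)
evaluate_model(fit$model, dat[idx$test, ])$accuracy
#> [1] 1
fit$model$fusion$alpha
#> [1] 0.2966332
```

A perfectly separable 400-letter corpus is memorised to test accuracy 1.0
within 50 epochs, and α drifts slightly below its 0.3 start because the CNN
branch's loss stays above the attention branch's early in training.

A command-line front end wraps the same functions
(`inst/cli/refdx synth|preprocess|train|evaluate|grid|predict`); see
`cli_main()`.

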