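test_that("attention branch yields valid, deterministic distributions", {
  tok <- tiny_tokenizer()
  am <- new_attn_model(tok, hidden = 8, layers = 2, heads = 2, ff = 12,
                       max_length = 48, seed = 3)
  p1 <- attn_branch_forward(am, "headache and dizziness")
  p2 <- attn_branch_forward(am, "headache and dizziness")
  expect_identical(p1$probs, p2$probs)
  expect_equal(sum(p1$probs), 1, tolerance = 1e-6)
  expect_true(all(p1$probs >= 0 & p1$probs <= 1))
  # zero classification head -> uniform probabilities
  am$params$W_cls[] <- 0
  am$params$b_cls[] <- 0
  expect_equal(unname(attn_branch_forward(am, "back pain")$probs),
               rep(0.25, 4))
  # sequences beyond the encoder limit are an input error
  long_seq <- subword_encode(paste(rep("w", 80), collapse = " "),
                             tiny_tokenizer(), max_length = 120)
  expect_error(attn_branch_forward(am, long_seq), "exceeds")
})

test_that("CNN branch has the documented feature-map geometry", {
  tab <- random_table(letters, d = 300, seed = 1)
  cm <- new_cnn_model(tab, max_length = 16, seed = 2)
  txt <- paste(letters[1:10], collapse = " ")   # m = 10
  pr <- cnn_branch_forward(cm, txt)
  feats <- attr(pr, "features")
  expect_equal(vapply(feats$conv_maps, nrow, integer(1)),
               c("2" = 9L, "3" = 8L, "4" = 7L))
  expect_length(feats$pooled, 6)
  expect_equal(sum(pr$probs), 1, tolerance = 1e-6)
})

test_that("CNN branch is uniform on zero embeddings and ignores padding", {
  tab <- random_table("tok", d = 12, seed = 3, oov_policy = "zero")
  cm <- new_cnn_model(tab, max_length = 16, seed = 4)
  # every token unknown under the zero policy -> all-zero embeddings
  pr <- cnn_branch_forward(cm, "alpha beta gamma delta epsilon")
  expect_equal(unname(pr$probs), rep(0.25, 4))

  # appending pad rows after real activations leaves the pooled vector
  # unchanged because windows touching padding are masked from the max
  withr::local_seed(5)
  X <- matrix(rnorm(8 * 12), 8, 12)
  f1 <- refdx:::cnn_head_forward(cm$params, cm$hp, X, valid_len = 8)
  Xp <- rbind(X, matrix(0, 4, 12))
  f2 <- refdx:::cnn_head_forward(cm$params, cm$hp, Xp, valid_len = 8)
  expect_identical(f1$pooled, f2$pooled)

  # shorter-than-kernel input is padded up with a warning
  expect_warning(
    refdx:::cnn_head_forward(cm$params, cm$hp, X[1:2, , drop = FALSE],
                             valid_len = 2),
    "padding up"
  )
})

test_that("cross-entropy agrees with direct softmax summation", {
  uni <- class_probabilities(c(0, 0, 0, 0))
  expect_equal(cross_entropy(uni, "G40"), log(4), tolerance = 1e-12)
  sure <- class_probabilities(c(1e6, 0, 0, 0))
  expect_equal(cross_entropy(sure, "G40"), 0, tolerance = 1e-9)
  z <- c(2, 0, 0, 0)
  oracle <- -log(exp(z[1]) / sum(exp(z)))
  expect_equal(cross_entropy(class_probabilities(z), "G40"), oracle,
               tolerance = 1e-12)
  # batch reduction is the mean
  expect_equal(cross_entropy(list(uni, sure), c("R51", "G40")),
               mean(c(log(4), 0)), tolerance = 1e-9)
})

test_that("loss fusion is the affine combination with exact endpoints", {
  losses <- list(loss_cnn = 1.0, loss_attn = 2.0)
  expect_identical(fuse_losses(losses, fusion_state(alpha = 0.3)), 1.7)
  fs0 <- fusion_state(alpha = 0, clamp_bounds = c(0, 1))
  fs1 <- fusion_state(alpha = 1, clamp_bounds = c(0, 1))
  expect_identical(fuse_losses(losses, fs0), losses$loss_attn)
  expect_identical(fuse_losses(losses, fs1), losses$loss_cnn)
  # affine in alpha with slope loss_cnn - loss_attn (finite difference)
  f <- function(a) fuse_losses(losses, fusion_state(a, clamp_bounds = c(0, 1)))
  slope <- (f(0.8) - f(0.2)) / 0.6
  expect_equal(slope, losses$loss_cnn - losses$loss_attn, tolerance = 1e-12)
})

test_that("alpha update follows the multiplicative recurrence", {
  fs <- fusion_state(alpha = 0.3, alpha_lr = 1e-5)
  up <- update_alpha(fs, list(loss_cnn = 0.9, loss_attn = 0.5))
  expect_equal(up$alpha, 0.3 - 0.4 * 1e-5 * 0.3, tolerance = 1e-15)
  expect_equal(up$alpha, 0.2999988)
  expect_equal(up$step, 1L)
  # equal losses are a fixed point
  same <- update_alpha(fs, list(loss_cnn = 1.2, loss_attn = 1.2))
  expect_identical(same$alpha, fs$alpha)
  # clamping keeps alpha inside its bounds
  tight <- fusion_state(alpha = 0.02, alpha_lr = 0.5,
                        clamp_bounds = c(0.01, 0.99))
  down <- update_alpha(tight, list(loss_cnn = 10, loss_attn = 0))
  expect_gte(down$alpha, 0.01)
  # non-finite losses leave the state unchanged with a warning
  expect_warning(bad <- update_alpha(fs, list(loss_cnn = NaN,
                                              loss_attn = 1)))
  expect_identical(bad$alpha, fs$alpha)
})

test_that("iterated alpha updates match the closed form under constant gap", {
  d <- 0.4; lr <- 1e-5; a0 <- 0.3
  fs <- fusion_state(alpha = a0, alpha_lr = lr)
  losses <- list(loss_cnn = 0.9, loss_attn = 0.5)
  for (m in 1:1000) fs <- update_alpha(fs, losses)
  expect_equal(fs$alpha, a0 * (1 - d * lr)^1000, tolerance = 1e-10)
  expect_equal(fs$step, 1000L)
})

test_that("hybrid inference is the alpha-weighted convex combination", {
  tok <- tiny_tokenizer()
  am <- new_attn_model(tok, hidden = 8, layers = 1, heads = 2, ff = 12,
                       max_length = 48, seed = 6)
  tab <- random_table(c("headache", "and", "dizziness"), d = 10, seed = 7)
  cm <- new_cnn_model(tab, max_length = 16, seed = 8)
  hm <- new_hybrid_model(am, cm, alpha0 = 0.3)
  out <- hybrid_forward(hm, "headache and dizziness today")
  expect_equal(unname(out$combined$probs),
               unname(0.3 * out$cnn$probs + 0.7 * out$attn$probs),
               tolerance = 1e-12)
  expect_equal(sum(out$combined$probs), 1, tolerance = 1e-9)

  h0 <- new_hybrid_model(am, cm, alpha0 = 0, clamp_bounds = c(0, 1))
  out0 <- hybrid_forward(h0, "headache and dizziness today")
  expect_equal(out0$combined$probs, out0$attn$probs, tolerance = 1e-12)

  hc <- new_hybrid_model(am, cm, inference_rule = "cnn")
  outc <- hybrid_forward(hc, "headache and dizziness today")
  expect_equal(outc$combined$probs, outc$cnn$probs, tolerance = 1e-12)
})

test_that("sequential model keeps the CNN geometry over encoder states", {
  tok <- tiny_tokenizer()
  sm <- new_sequential_model(tok, hidden = 32, layers = 1, heads = 2,
                             ff = 24, max_length = 48, seed = 9)
  ids <- subword_encode("back pain and leg pain", tok)$ids
  fwd <- refdx:::encoder_forward(sm$params, ids, sm$enc_hp)
  head <- refdx:::cnn_head_forward(sm$params, sm$head_hp, fwd$X,
                                   valid_len = fwd$T_)
  m <- length(ids)
  expect_equal(vapply(head$cache$caches, function(c) nrow(c$Z), integer(1)),
               c("2" = m - 1L, "3" = m - 2L, "4" = m - 3L))
  pr <- sequential_forward(sm, "back pain and leg pain")
  expect_equal(sum(pr$probs), 1, tolerance = 1e-6)
  # structurally distinct from the hybrid: single network, no fusion state
  expect_null(sm$fusion)
  expect_identical(sm$type, "sequential")
})

test_that("checkpoints round-trip models exactly", {
  tok <- tiny_tokenizer()
  am <- new_attn_model(tok, hidden = 8, layers = 1, heads = 2, ff = 12,
                       max_length = 48, seed = 10)
  tab <- random_table(c("headache", "and"), d = 6, seed = 11)
  cm <- new_cnn_model(tab, max_length = 16, seed = 12)
  hm <- new_hybrid_model(am, cm)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(hm, path, config = list(arch = "hybrid", note = "t"))
  back <- load_checkpoint(path)
  expect_identical(
    hybrid_forward(back$model, "headache and dizziness today")$combined$probs,
    hybrid_forward(hm, "headache and dizziness today")$combined$probs
  )
  expect_match(back$config_hash, "^[0-9a-f]{8}$")
  expect_error(load_checkpoint(withr::local_tempfile(fileext = ".rds")),
               class = "refdx_checkpoint_error")
})
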