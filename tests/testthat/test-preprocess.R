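test_that("clean_text removes junk and greetings and is idempotent", {
  expect_equal(clean_text("Dear Dr XXX, $$ sudden onset headache **"),
               "sudden onset headache")
  expect_equal(clean_text("no junk  here"), "no junk here")
  corpus <- generate_corpus(synth_config(n_per_class = 5, seed = 13))
  cleaned <- clean_text(corpus$complaint)
  expect_identical(clean_text(cleaned), cleaned)
  # junk tokens gone, cleaning is non-generative (alphabet shrinks)
  for (j in junk_tokens()) {
    expect_false(any(grepl(j, cleaned, fixed = TRUE)))
  }
  for (i in seq_along(cleaned)) {
    in_chars <- unique(strsplit(corpus$complaint[i], "")[[1]])
    out_chars <- unique(strsplit(cleaned[i], "")[[1]])
    expect_true(all(out_chars %in% c(in_chars, " ")))
  }
})

test_that("extraction on the reference R51 letter matches the worked example", {
  cleaned <- clean_text(example_letter("R51"))
  m <- extract_symptoms(cleaned)
  positives <- m$canonical[!m$negated]
  expect_true(all(c("falling down", "dizziness", "pass out", "headache",
                    "tunnel vision", "diplopia") %in% positives))
  expect_identical(m$canonical[m$negated], "lose consciousness")
  # span contract: cleaned[start, end) equals the phrase, case-insensitively
  for (i in seq_len(nrow(m))) {
    expect_gt(m$end[i], m$start[i])
    expect_equal(tolower(substr(cleaned, m$start[i] + 1, m$end[i])),
                 tolower(m$phrase[i]))
  }
  # mentions come back in left-to-right order
  expect_identical(m$start, sort(m$start))
})

test_that("negation triggers respect the token window and sentence bounds", {
  m <- extract_symptoms("headache. no headache later")
  expect_equal(m$negated, c(FALSE, TRUE))
  # boundary punctuation blocks the trigger
  m2 <- extract_symptoms("not positional. tunnel vision seen")
  expect_false(m2$negated[m2$canonical == "tunnel vision"])
  # trigger beyond the 5-token window does not negate
  m3 <- extract_symptoms("no sign that anything else could explain headache")
  expect_false(m3$negated[m3$canonical == "headache"])
  # multiword trigger
  m4 <- extract_symptoms("did not lose consciousness")
  expect_true(m4$negated[1])
})

test_that("extraction prefers the longest match and handles degenerate input", {
  m <- extract_symptoms("severe chronic back pain today")
  expect_identical(m$canonical, "chronic back pain")
  expect_equal(nrow(extract_symptoms("nothing clinical in this text")), 0)
  expect_error(extract_symptoms("headache", lexicon = list()), "empty")
})

test_that("dot separation drops negated phrases and round-trips", {
  expect_equal(dot_separate(c("falling down", "dizziness", "pass out")),
               "falling down. dizziness. pass out.")
  m <- data.frame(canonical = c("headache", "lose consciousness"),
                  negated = c(FALSE, TRUE))
  expect_equal(dot_separate(m), "headache.")
  expect_equal(dot_separate(character(0)), "[NOSYM]")
  expect_equal(dot_separate(m, dot = FALSE), "headache")

  # randomized round-trip property
  phrases <- lexicon_table(builtin_lexicon())$canonical
  withr::with_seed(99, {
    for (rep in 1:200) {
      k <- sample(0:6, 1)
      sel <- sample(phrases, k)
      txt <- dot_separate(sel)
      expect_identical(split_symptoms(txt), as.character(sel))
    }
  })
})

test_that("integration inserts exactly one [SEP]", {
  expect_equal(integrate_complaint("sudden onset headache", "headache."),
               "sudden onset headache [SEP] headache.")
  expect_equal(integrate_complaint("a", "[NOSYM]"), "a [SEP] [NOSYM]")
  out <- integrate_complaint("x y z", "p. q.")
  expect_equal(lengths(regmatches(out, gregexpr("\\[SEP\\]", out))), 1)
})

test_that("build_variants conserves counts and excludes negated symptoms", {
  corpus <- generate_corpus(synth_config(n_per_class = 5, seed = 21))
  built <- build_variants(corpus)
  expect_equal(nrow(built$processed), 20)
  for (v in built$variants) expect_equal(nrow(v), 20)
  expect_identical(built$variants$Complaints$label, corpus$label)

  for (i in seq_len(nrow(built$processed))) {
    m <- built$processed$mentions[[i]]
    neg <- setdiff(m$canonical[m$negated], m$canonical[!m$negated])
    for (p in neg) {
      expect_false(grepl(p, built$processed$symptoms_text[i], fixed = TRUE))
    }
    expect_equal(lengths(regmatches(
      built$processed$integration_text[i],
      gregexpr("\\[SEP\\]", built$processed$integration_text[i]))), 1)
  }
})

test_that("integration text carries the complaint and the symptom fragment", {
  r51 <- example_letters()[example_letters()$label == "R51", ]
  built <- build_variants(r51)
  integ <- built$variants$Integration$text
  expect_true(grepl("tunnel vision", sub("\\[SEP\\].*", "", integ),
                    fixed = TRUE))
  expect_true(grepl("tunnel vision.", sub(".*\\[SEP\\]", "", integ),
                    fixed = TRUE))
})

test_that("zero-noise Symptoms texts contain only lexicon phrases", {
  corpus <- generate_corpus(separable_config(5, seed = 31))
  built <- build_variants(corpus)
  canon <- lexicon_table(builtin_lexicon())$canonical
  for (i in seq_len(nrow(corpus))) {
    parts <- split_symptoms(built$variants$Symptoms$text[i])
    expect_gt(length(parts), 0)
    expect_true(all(parts %in% canon))
  }
})
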