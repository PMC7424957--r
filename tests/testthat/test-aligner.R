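toy_corpus <- function(...) {
  structure(lapply(list(...), function(p)
    list(visual = p[[1]], linguistic = p[[2]], observer = "o",
         origin = "full", window_start = NA_real_)),
    class = "parallel_corpus")
}

test_that("Model 1 EM learns co-occurrence translation probabilities", {
  # two-sentence lexicon-acquisition setup: the shared word pins the shared
  # region, the second sentence disambiguates the rest
  corp <- toy_corpus(list("ghar", "house"),
                     list(c("chhota", "ghar"), c("small", "house")))
  m <- train_model1(corp, "forward", iters = 15)
  row <- m$t[match("ghar", m$src_vocab), ]
  expect_equal(m$tgt_vocab[which.max(row)], "house")
  expect_gt(row[match("house", m$tgt_vocab)],
            row[match("small", m$tgt_vocab)])

  # every row of the translation table is a distribution
  expect_equal(unname(rowSums(m$t)), rep(1, nrow(m$t)), tolerance = 1e-9)

  expect_error(train_model1(structure(list(), class = "parallel_corpus")),
               "empty")
})

test_that("Model 1 with a single 1x1 pair assigns the word to both sources by hand-EM", {
  corp <- toy_corpus(list("r1", "bear"))
  m <- train_model1(corp, "forward", iters = 1)
  # E-step from uniform: posterior 1/2 lexical, 1/2 NULL. The M-step
  # renormalizes each source row over the one-word target vocabulary, so both
  # rows end at t(bear | .) = 1; the alignment posterior stays split.
  expect_equal(m$t[match("r1", m$src_vocab), 1], 1, tolerance = 1e-9)
  expect_equal(m$t[length(m$src_vocab) + 1L, 1], 1, tolerance = 1e-9)
  P <- model1_posteriors(list(visual = "r1", linguistic = "bear"), m)
  expect_equal(P[1, ], c(0.5, 0.5), tolerance = 1e-9)
})

test_that("Model 1 resolves an ambiguous two-pair corpus at convergence", {
  corp <- toy_corpus(list(c("r1", "r2"), c("bear", "log")),
                     list("r1", "bear"))
  m <- train_model1(corp, "forward", iters = 60)
  t_of <- function(s, w) m$t[match(s, m$src_vocab), match(w, m$tgt_vocab)]
  expect_gt(t_of("r1", "bear"), t_of("r1", "log"))
  expect_gt(t_of("r2", "log"), t_of("r2", "bear"))
})

test_that("Model 1 posteriors equal brute-force enumeration over alignment functions", {
  set.seed(101)
  for (i in 1:12) {
    sv <- paste0("r", 1:sample(2:4, 1))
    tv <- paste0("w", 1:sample(2:4, 1))
    model <- random_alignment_model(sv, tv, with_hmm = FALSE)
    pair <- list(visual = sample(sv, sample.int(4, 1), replace = TRUE),
                 linguistic = sample(tv, sample.int(4, 1), replace = TRUE))
    P <- model1_posteriors(pair, model)
    O <- oracle_model1_posteriors(table_lookup(model), pair$visual,
                                  pair$linguistic)
    expect_lt(max(abs(P - O)), 1e-10)
    expect_equal(unname(rowSums(P)), rep(1, nrow(P)), tolerance = 1e-12)
  }
})

test_that("out-of-vocabulary target tokens fall back to NULL", {
  model <- random_alignment_model(c("r1", "r2"), c("w1", "w2"),
                                  with_hmm = FALSE)
  P <- model1_posteriors(list(visual = c("r1", "r2"),
                              linguistic = c("w1", "unseen")), model)
  expect_equal(P[2, ], c(0, 0, 1))
})

test_that("HMM posteriors equal exhaustive path enumeration including NULL states", {
  set.seed(202)
  for (i in 1:8) {
    sv <- paste0("r", 1:sample(2:3, 1))
    tv <- paste0("w", 1:sample(2:3, 1))
    model <- random_alignment_model(sv, tv, max_jump = 2)
    pair <- list(visual = sample(sv, sample.int(3, 1) + 1, replace = TRUE),
                 linguistic = sample(tv, sample.int(3, 1) + 1, replace = TRUE))
    P <- hmm_posteriors(pair, model)
    O <- oracle_hmm_posteriors(table_lookup(model), pair$visual,
                               pair$linguistic, model$hmm$jump,
                               model$hmm$p_null, model$hmm$max_jump)
    expect_lt(max(abs(P - O)), 1e-8)
  }
  # one 5x5 case at full criterion size
  model <- random_alignment_model(paste0("r", 1:5), paste0("w", 1:5),
                                  max_jump = 3)
  pair <- list(visual = paste0("r", c(1, 3, 2, 5, 4)),
               linguistic = paste0("w", c(2, 1, 4, 3, 5)))
  P <- hmm_posteriors(pair, model)
  O <- oracle_hmm_posteriors(table_lookup(model), pair$visual, pair$linguistic,
                             model$hmm$jump, model$hmm$p_null,
                             model$hmm$max_jump)
  expect_lt(max(abs(P - O)), 1e-8)
})

test_that("HMM on 1x1 pairs reduces to Model 1 when the NULL weights match", {
  model <- random_alignment_model("r1", c("w1", "w2"), with_hmm = TRUE)
  model$hmm$p_null <- 0.5           # Model 1 gives NULL weight 1/(I+1) = 1/2
  pair <- list(visual = "r1", linguistic = "w1")
  expect_equal(hmm_posteriors(pair, model), model1_posteriors(pair, model),
               tolerance = 1e-12)
})

test_that("a monotone corpus concentrates the learned jump distribution on +1", {
  set.seed(7)
  lex <- paste0("w", 1:6)
  corp <- structure(lapply(1:40, function(i) {
    idx <- sort(sample.int(6, 4))
    list(visual = paste0("r", idx), linguistic = lex[idx], observer = "o",
         origin = "window", window_start = 0)
  }), class = "parallel_corpus")
  m1 <- train_model1(corp, "forward", iters = 3)
  mh <- train_hmm(corp, "forward", m1, iters = 4, config = aligner_config())
  expect_equal(names(which.max(mh$hmm$jump)), "1")
})

test_that("corpus log-likelihood is non-decreasing for Model 1 and Baum-Welch", {
  set.seed(303)
  for (i in 1:10) {
    corp <- random_toy_corpus(sample(3:8, 1), paste0("r", 1:3), paste0("w", 1:4))
    m1 <- train_model1(corp, "forward", iters = 5)
    expect_true(all(diff(attr(m1, "loglik")) >= -1e-9))
    mh <- train_hmm(corp, "forward", m1, iters = 5)
    expect_true(all(diff(attr(mh, "loglik")) >= -1e-9))
  }
})

test_that("agreement combination multiplies matched links and renormalizes rows", {
  # one target, one source: p_f = (0.6 real, 0.4 NULL); transposed direction
  # q = 0.4 for the same link
  P_f <- matrix(c(0.6, 0.4), 1)
  P_r <- matrix(c(0.4, 0.6), 1)
  C <- gazealign:::combine_agreement(P_f, P_r)
  expect_equal(C[1, 1], 0.24 / (0.24 + 0.4))  # product rule, NULL kept as-is
  expect_equal(sum(C), 1)

  # when the directions already agree with certainty the product is a fixed point
  P1 <- matrix(c(1, 0), 1)
  expect_equal(gazealign:::combine_agreement(P1, matrix(c(1, 0), 1)), P1)
})

test_that("joint training is deterministic and recovers a planted one-to-one lexicon", {
  set.seed(17)
  regions <- paste0("r", 1:12)
  words <- paste0("word", 1:12)
  noise <- paste0("n", 1:6)
  corp <- structure(lapply(1:150, function(i) {
    idx <- sample.int(12, sample(3:5, 1))
    lw <- words[idx]
    if (runif(1) < 0.3) lw <- append(lw, sample(noise, 1),
                                     after = sample(0:length(lw), 1))
    list(visual = regions[idx], linguistic = lw, observer = "o",
         origin = "window", window_start = 0)
  }), class = "parallel_corpus")
  models <- train_joint(corp, aligner_config())
  models2 <- train_joint(corp, aligner_config())
  expect_identical(models$forward$t, models2$forward$t)
  fwd <- models$forward
  hit <- vapply(seq_along(regions), function(i) {
    row <- fwd$t[match(regions[i], fwd$src_vocab), ]
    fwd$tgt_vocab[which.max(row)] == words[i]
  }, logical(1))
  expect_gte(mean(hit), 0.9)
})

test_that("posterior decoding is monotone in the threshold", {
  set.seed(23)
  corp <- random_toy_corpus(25, paste0("r", 1:4), paste0("w", 1:5))
  models <- train_joint(corp, aligner_config())
  pair <- corp[[1]]
  keys <- function(d) paste(d$j, d$i)
  l_0 <- decode(pair, models, delta = 0)
  l_lo <- decode(pair, models, delta = 0.1)
  l_hi <- decode(pair, models, delta = 0.4)
  expect_true(all(keys(l_hi) %in% keys(l_lo)))
  expect_true(all(keys(l_lo) %in% keys(l_0)))
  # delta = 0 keeps every non-NULL cell
  expect_equal(nrow(l_0), length(pair$visual) * length(pair$linguistic))
  expect_true(all(l_lo$posterior >= 0.1))
})

test_that("image-level alignment pools distinct links with their maximum posterior", {
  set.seed(29)
  corp <- structure(list(
    list(visual = c("r1", "r2"), linguistic = c("bear", "log"),
         observer = "o1", origin = "full", window_start = NA_real_),
    list(visual = c("r1", "r2"), linguistic = c("bear", "log"),
         observer = "o2", origin = "full", window_start = NA_real_),
    list(visual = c("r1", "r1", "r2"), linguistic = c("bear", "log"),
         observer = "o3", origin = "window", window_start = 0)),
    class = "parallel_corpus")
  models <- train_joint(corp, aligner_config())
  A <- align_image(corpus = corp, models = models, delta = 0)
  expect_false(any(duplicated(A[c("word", "region")])))
  links <- attr(A, "links")
  # o1 and o2 decode the same full pair, so A keeps each pair once with the
  # maximum over the duplicated links
  for (k in seq_len(nrow(A))) {
    sub <- links[links$word == A$word[k] & links$region == A$region[k], ]
    expect_equal(A$posterior[k], max(sub$posterior))
  }
})

test_that("trained models serialize to JSON and back", {
  set.seed(31)
  corp <- random_toy_corpus(12, paste0("r", 1:3), paste0("w", 1:3))
  models <- train_joint(corp, aligner_config())
  path <- withr::local_tempfile(fileext = ".json")
  write_models(models, path)
  back <- read_models(path)
  expect_equal(back$forward$t, models$forward$t, tolerance = 1e-12)
  expect_equal(back$reverse$src_vocab, models$reverse$src_vocab)
  expect_equal(back$forward$hmm$jump, models$forward$hmm$jump,
               tolerance = 1e-12)
  pair <- corp[[1]]
  expect_equal(decode(pair, back), decode(pair, models), tolerance = 1e-9)
})
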