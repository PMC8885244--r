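test_that("uniform one-step CRF has NLL log(2) and non-negative loss everywhere", {
  crf <- new_crf(2)
  crf$trans[] <- 0
  em <- matrix(0, 1, 2)
  expect_equal(crf_nll(em, 1L, crf), log(2), tolerance = 1e-12)
  withr::with_seed(2, {
    for (i in 1:10) {
      m <- sample(1:4, 1); K <- sample(2:4, 1)
      crf <- new_crf(K, seed = i)
      crf$trans <- matrix(rnorm((K + 2)^2), K + 2)
      em <- matrix(rnorm(m * K), m, K)
      expect_gte(crf_nll(em, sample(K, m, replace = TRUE), crf), 0)
    }
  })
})

test_that("CRF NLL and Viterbi agree with exhaustive path enumeration", {
  withr::with_seed(42, {
    for (i in 1:100) {
      m <- sample(1:5, 1)
      K <- sample(2:4, 1)
      crf <- new_crf(K, seed = i)
      crf$trans <- matrix(rnorm((K + 2)^2), K + 2)
      em <- matrix(rnorm(m * K), m, K)
      b <- crf_brute(em, crf)
      gold <- sample(K, m, replace = TRUE)
      expect_equal(crf_nll(em, gold, crf),
                   b$logZ - relcascade:::crf_path_score(em, gold, crf),
                   tolerance = 1e-6)
      expect_equal(unname(crf_viterbi(em, crf)), unname(b$best))
    }
  })
})

test_that("path probabilities exp(-nll) sum to one on tiny instances", {
  withr::with_seed(7, {
    for (i in 1:5) {
      m <- sample(2:4, 1); K <- sample(2:3, 1)
      crf <- new_crf(K, seed = 10 + i)
      crf$trans <- matrix(rnorm((K + 2)^2) * 0.5, K + 2)
      em <- matrix(rnorm(m * K), m, K)
      paths <- as.matrix(expand.grid(rep(list(seq_len(K)), m)))
      total <- sum(apply(paths, 1, function(p) exp(-crf_nll(em, p, crf))))
      expect_equal(total, 1, tolerance = 1e-6)
    }
  })
})

test_that("Viterbi decoupled/degenerate cases and deterministic tie-breaks", {
  crf <- new_crf(3)
  crf$trans[] <- 0
  em <- matrix(c(0.3, 2.0, 0.1,
                 1.5, 0.2, 0.9), 2, 3, byrow = TRUE)
  expect_equal(crf_viterbi(em, crf), c(2L, 1L))   # per-position argmax
  ## M = 1: argmax of emission + start/stop
  expect_equal(crf_viterbi(matrix(c(1, 5, 2), 1, 3), crf), 2L)
  ## ties resolve to the lowest tag index
  expect_equal(crf_viterbi(matrix(0, 3, 3), crf), c(1L, 1L, 1L))
  expect_error(crf_viterbi(matrix(0, 0, 3), crf), "empty")
  expect_error(crf_nll(matrix(0, 2, 3), c(1L, 4L), crf), "out of range")
})

test_that("CRF analytic gradients match finite differences", {
  withr::with_seed(5, {
    m <- 4; K <- 3
    crf <- new_crf(K, seed = 2)
    crf$trans <- matrix(rnorm((K + 2)^2) * 0.3, K + 2)
    em <- matrix(rnorm(m * K), m, K)
    gold <- c(1L, 3L, 2L, 2L)
    g <- relcascade:::crf_nll_grad(em, gold, crf)
    eps <- 1e-6
    base <- crf_nll(em, gold, crf)
    for (probe in list(c(1, 1), c(2, 3), c(4, 2))) {
      e2 <- em; e2[probe[1], probe[2]] <- e2[probe[1], probe[2]] + eps
      expect_equal((crf_nll(e2, gold, crf) - base) / eps,
                   g$dEm[probe[1], probe[2]], tolerance = 1e-4)
    }
    for (probe in list(c(1, 2), c(K + 1, 1), c(2, K + 2))) {
      c2 <- crf; c2$trans[probe[1], probe[2]] <- c2$trans[probe[1], probe[2]] + eps
      expect_equal((crf_nll(em, gold, c2) - base) / eps,
                   g$dTr[probe[1], probe[2]], tolerance = 1e-4)
    }
  })
})

test_that("bilstm_encode has the right shape and directional information flow", {
  p <- bilstm_params(6, 8, layers = 1, seed = 3)
  withr::with_seed(1, X <- matrix(rnorm(5 * 6), 5, 6))
  H <- bilstm_encode(X, p)
  expect_equal(dim(H$vectors), c(5L, 16L))
  expect_identical(H$vectors, bilstm_encode(X, p)$vectors)
  ## the forward half of row 1 depends only on the first input
  X2 <- X
  X2[2:5, ] <- X2[5:2, ]
  H2 <- bilstm_encode(X2, p)
  expect_equal(H$vectors[1, 1:8], H2$vectors[1, 1:8], tolerance = 1e-12)
  ## ... while the backward half sees the whole (changed) suffix
  expect_gt(max(abs(H$vectors[1, 9:16] - H2$vectors[1, 9:16])), 1e-8)
})

test_that("a small BiLSTM-CRF denoiser learns its training corpus", {
  ## trainability at micro scale; the full-scale accuracy invariant
  ## (200 sentences, >= 0.9) lives in test-training.R
  lang <- toy_lang()
  corp <- generate_corpus(lang, gen_config(60, noise_triple_prob = 0.4, seed = 51))
  den <- train_denoiser(corp, epochs = 18, lr = 3e-3, seed = 2)
  expect_length(den$loss_log, 18)
  expect_lt(den$loss_log[18], den$loss_log[1] / 2)
  expect_gte(denoiser_accuracy(den, corp), 0.75)
  ## determinism of training given the seed
  den2 <- train_denoiser(corp[1:10], epochs = 2, seed = 9)
  den3 <- train_denoiser(corp[1:10], epochs = 2, seed = 9)
  expect_identical(den2$loss_log, den3$loss_log)
  pred <- predict_tags(den, corp[[1]])
  expect_length(pred, nchar(corp[[1]]$text))
  expect_true(all(as.character(pred) %in% tag_alphabet()))
})
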