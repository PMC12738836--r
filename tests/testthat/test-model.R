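# Architecture contracts: shapes, determinism, softmax, channel-attention
# gates, parameter counts, attention arithmetic, gradient correctness.

random_batch <- function(n, L, seed = 1, labels = NULL) {
  set.seed(seed)
  d <- tibble::tibble(
    id = paste0("s", seq_len(n)),
    sequence = vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, character(1))
  )
  if (!is.null(labels)) d$label <- labels
  encode_leaders(d)
}

test_that("forward pass satisfies the shape and softmax contracts", {
  cfg <- tiny_model_config()
  m <- build_model(cfg)
  b <- random_batch(8, 30)
  fw <- chloroleadr:::model_forward(m, b$data)
  expect_equal(dim(fw$logits), c(8, 2))
  expect_equal(rowSums(fw$probs), rep(1, 8), tolerance = 1e-6)
  expect_error(chloroleadr:::model_forward(m, random_batch(2, 28, 2)$data),
               "seq_length")
})

test_that("evaluation is bitwise deterministic and init is seed-pure", {
  cfg <- tiny_model_config(seed = 99)
  m1 <- build_model(cfg)
  m2 <- build_model(cfg)
  expect_identical(m1$params, m2$params)
  b <- random_batch(4, 30)
  f1 <- chloroleadr:::model_forward(m1, b$data)
  f2 <- chloroleadr:::model_forward(m1, b$data)
  expect_identical(f1$logits, f2$logits)
})

test_that("the classifier is permutation-equivariant over batch order", {
  m <- build_model(tiny_model_config())
  b <- random_batch(6, 30, seed = 5)
  perm <- c(4, 1, 6, 2, 5, 3)
  f1 <- chloroleadr:::model_forward(m, b$data)
  f2 <- chloroleadr:::model_forward(m, b$data[perm, , , drop = FALSE])
  expect_equal(f2$logits, f1$logits[perm, ], tolerance = 1e-12)
})

test_that("channel-attention gates lie in (0,1) and ablation reduces to plain convolution", {
  m <- build_model(tiny_model_config(seed = 3))
  b <- random_batch(4, 30, seed = 7)
  # forcing all gates to 1 (saturated sigmoid) must equal the ablation switch
  f_abl <- chloroleadr:::model_forward(m, b$data, ablate_channel_attention = TRUE)
  m_one <- m
  # saturate the gate sigmoid: huge positive bias, zero weights
  m_one$params$se_W1[] <- 0; m_one$params$se_b1[] <- 0
  m_one$params$se_W2[] <- 0; m_one$params$se_b2[] <- 1e4
  f_one <- chloroleadr:::model_forward(m_one, b$data)
  expect_equal(f_abl$logits, f_one$logits, tolerance = 1e-9)

  # and the live gates are strictly inside (0,1)
  fw <- chloroleadr:::model_forward(m, b$data, keep_cache = TRUE)
  g <- fw$cache$se$g
  expect_true(all(g > 0 & g < 1))
})

test_that("config ablation flag matches the per-call switch", {
  cfg_off <- tiny_model_config(channel_attention = FALSE)
  m_off <- build_model(cfg_off)
  b <- random_batch(3, 30, seed = 11)
  f1 <- chloroleadr:::model_forward(m_off, b$data)
  m_on_cfg <- m_off; m_on_cfg$config$channel_attention <- TRUE
  f2 <- chloroleadr:::model_forward(m_on_cfg, b$data,
                                    ablate_channel_attention = TRUE)
  expect_identical(f1$logits, f2$logits)
})

test_that("parameter counts are reproducible, monotone, and match a hand tally", {
  cfg <- tiny_model_config()
  expect_equal(count_parameters(build_model(cfg)),
               count_parameters(build_model(cfg)))
  cfg_big <- tiny_model_config(); cfg_big$conv_channels <- 8L
  expect_gt(count_parameters(build_model(cfg_big)),
            count_parameters(build_model(cfg)))

  # hand tally for the smallest legal config
  cfg1 <- model_config(
    seq_length = 10, conv_channels = 1, lstm_hidden = 1, attention_heads = 1,
    fc_sizes = c(1, 1), channel_attention_reduction = 1, seed = 1
  )
  C <- 1; M <- 3; H <- 1; D <- 2; F1 <- 1; F2 <- 1; K <- 2; Mr <- 3
  tally <-
    (3 * 5 * C + C) +        # conv1
    2 * C +                  # bn1
    (5 * C + C) +            # residual projection 1
    (3 * C * C + C) + (5 * C * C + C) + (7 * C * C + C) + # branches
    (M * Mr + Mr) + (Mr * M + M) + # squeeze-and-excitation
    2 * M +                  # bn2
    (C * M + M) +            # residual projection 2
    2 * (M * 4 * H + H * 4 * H + 4 * H) + # bidirectional LSTM
    4 * (D * D + D) +        # attention Q,K,V,O
    (D * F1 + F1) + 2 * F1 + # fc1 + its batch norm
    (F1 * F2 + F2) + 2 * F2 + # fc2 + its batch norm
    (F2 * K + K)             # head
  expect_equal(count_parameters(build_model(cfg1)), tally)
})

test_that("forward_trace exposes row-stochastic attention and pre-pool features", {
  m <- build_model(tiny_model_config(seed = 21))
  b <- random_batch(5, 30, seed = 3, labels = rep(c("a", "b"), c(3, 2)))
  tr <- forward_trace(m, b)
  expect_s3_class(tr, "forward_trace")
  expect_equal(dim(tr$conv_features), c(5, 30, 12)) # length preserved pre-pool
  expect_equal(dim(tr$alpha), c(5, 2, 15, 15))
  for (i in 1:5) for (h in 1:2) {
    expect_equal(rowSums(tr$alpha[i, h, , ]), rep(1, 15), tolerance = 1e-5)
  }
  expect_equal(rowSums(tr$probabilities), rep(1, 5), tolerance = 1e-6)
})

test_that("a zero-weight output head yields uniform class probabilities", {
  m <- build_model(tiny_model_config())
  m$params$head_W[] <- 0
  m$params$head_b[] <- 0
  b <- random_batch(4, 30, seed = 13)
  fw <- chloroleadr:::model_forward(m, b$data)
  expect_equal(fw$probs, matrix(0.5, 4, 2), ignore_attr = TRUE)
})

test_that("single-head attention matches a hand-computed scaled dot-product softmax", {
  # length-4 toy, one head, D = 2; Q = K = V = identity maps of the input
  T_ <- 4; D <- 2
  Hm <- matrix(c(0.5, -1, 2, 0.3, 1, 0.7, -0.2, 0.1), T_, D) # one sample
  I2 <- diag(2)
  att <- chloroleadr:::attention_forward(
    Hm, n = 1, T_ = T_, heads = 1,
    Wq = I2, bq = c(0, 0), Wk = I2, bk = c(0, 0), Wv = I2, bv = c(0, 0),
    Wo = I2, bo = c(0, 0), need_alpha = TRUE
  )
  S <- (Hm %*% t(Hm)) / sqrt(2)
  manual <- t(apply(S, 1, function(r) exp(r) / sum(exp(r))))
  expect_equal(matrix(att$alpha[1, 1, , ], 4, 4), manual, tolerance = 1e-12)
  expect_equal(att$out, manual %*% Hm, tolerance = 1e-12)
})

test_that("analytic gradients match finite differences through the full graph", {
  cfg <- model_config(
    seq_length = 12, conv_channels = 2, lstm_hidden = 3, attention_heads = 2,
    fc_sizes = c(4, 4), conv_dropout = 0, fc_dropout = 0,
    channel_attention_reduction = 2, seed = 42
  )
  m <- build_model(cfg)
  set.seed(1)
  n <- 3
  X <- array(0, c(n, 12, 5))
  for (i in 1:n) for (j in 1:12) X[i, j, sample(5, 1)] <- 1
  y <- c(1L, 2L, 1L)
  fw <- chloroleadr:::model_forward(m, X, training = TRUE, keep_cache = TRUE)
  dlog <- fw$probs
  dlog[cbind(1:n, y)] <- dlog[cbind(1:n, y)] - 1
  dlog <- dlog / n
  bk <- chloroleadr:::model_backward(m, fw$cache, dlog)
  loss_fn <- function(model) {
    f <- chloroleadr:::model_forward(model, X, training = TRUE,
                                     update_state = FALSE)
    -mean(log(f$probs[cbind(1:n, y)]))
  }
  eps <- 1e-5
  for (nm in names(m$params)) {
    P <- m$params[[nm]]
    idx <- sample(length(P), min(2, length(P)))
    for (ii in idx) {
      m2 <- m
      m2$params[[nm]][ii] <- P[ii] + eps
      l1 <- loss_fn(m2)
      m2$params[[nm]][ii] <- P[ii] - eps
      l0 <- loss_fn(m2)
      num <- (l1 - l0) / (2 * eps)
      expect_equal(bk$grads[[nm]][ii], num, tolerance = 1e-3,
                   label = paste("grad", nm))
    }
  }
})

test_that("invalid configurations are rejected", {
  expect_error(model_config(lstm_hidden = 5, attention_heads = 4),
               "divisible")
  expect_error(model_config(multi_kernels = c(3, 4, 7)), "odd")
  expect_error(model_config(seq_length = 301), "divisible")
})
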