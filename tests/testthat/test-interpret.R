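# Interpretability formulas: attention profiles, saliency, group means,
# smoothing, perturbation importance.

fake_trace <- function(conv_features = NULL, alpha = NULL, L,
                       ids = NULL, labels = NULL) {
  n <- if (!is.null(conv_features)) dim(conv_features)[1] else dim(alpha)[1]
  structure(
    list(
      conv_features = conv_features, alpha = alpha, seq_length = L,
      ids = ids %||% paste0("s", seq_len(n)), labels = labels
    ),
    class = "forward_trace"
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("cnn_attention is the channel mean of absolute activations", {
  # two channels holding +3 and -3 at one position
  Fm <- array(0, c(1, 5, 2))
  Fm[1, 3, ] <- c(3, -3)
  prof <- cnn_attention(fake_trace(conv_features = Fm, L = 5))
  expect_equal(prof$values[1, ], c(0, 0, 3, 0, 0))

  # all-zero features give an all-zero profile
  z <- cnn_attention(fake_trace(conv_features = array(0, c(2, 5, 3)), L = 5))
  expect_true(all(z$values == 0))

  # a constant map is a fixed point of the interpolation (length 5 -> 10)
  const <- cnn_attention(fake_trace(
    conv_features = array(2, c(1, 5, 3)), L = 10
  ))
  expect_equal(const$values[1, ], rep(2, 10))
})

test_that("lstm_attention averages heads then columns of row-stochastic alpha", {
  T_ <- 4
  # uniform attention: constant profile 1/T
  al <- array(1 / T_, c(1, 2, T_, T_))
  prof <- lstm_attention(fake_trace(alpha = al, L = T_))
  expect_equal(prof$values[1, ], rep(1 / T_, T_))

  # all queries attend position 1: mass concentrates there (loop oracle)
  one <- array(0, c(1, 1, T_, T_))
  one[1, 1, , 1] <- 1
  p2 <- lstm_attention(fake_trace(alpha = one, L = T_))
  A <- matrix(one[1, 1, , ], T_, T_)
  oracle <- vapply(seq_len(T_), function(j) mean(A[, j]), numeric(1))
  expect_equal(p2$values[1, ], oracle)
  expect_equal(p2$values[1, ], c(1, 0, 0, 0))

  # malformed rows are rejected
  bad <- array(0.3, c(1, 1, T_, T_))
  expect_error(lstm_attention(fake_trace(alpha = bad, L = T_)), "normalised")

  # single-position sequence
  p1 <- lstm_attention(fake_trace(alpha = array(1, c(1, 1, 1, 1)), L = 1))
  expect_equal(p1$values[1, ], 1)
})

test_that("group_profile equals a column-mean loop oracle to 1e-12", {
  set.seed(5)
  vals <- matrix(runif(50 * 20), 50, 20)
  labels <- sample(c("a", "b"), 50, replace = TRUE)
  ps <- chloroleadr:::new_profile_set(vals, paste0("s", 1:50), "saliency", 20)
  gp <- group_profile(ps, labels)
  for (cl in c("a", "b")) {
    rows <- which(labels == cl)
    oracle <- numeric(20)
    for (j in 1:20) oracle[j] <- sum(vals[rows, j]) / length(rows)
    expect_equal(gp$value[gp$class == cl], oracle, tolerance = 1e-12)
  }
  expect_equal(unname(attr(gp, "n_aggregated")),
               unname(table(labels)[c("a", "b")]), ignore_attr = TRUE)

  # identical profiles aggregate to themselves; 0/2 average to 1
  two <- chloroleadr:::new_profile_set(rbind(rep(0, 4), rep(2, 4)),
                                       c("x", "y"), "saliency", 4)
  g2 <- group_profile(two, c("k", "k"))
  expect_equal(g2$value, rep(1, 4))
  one_per_class <- group_profile(two, c("p", "q"))
  expect_equal(one_per_class$value[one_per_class$class == "p"], rep(0, 4))
  expect_equal(one_per_class$value[one_per_class$class == "q"], rep(2, 4))
})

test_that("saliency on a linear toy scorer equals channel-summed |w|", {
  set.seed(6)
  L <- 12
  W <- array(rnorm(L * 5 * 2), c(L, 5, 2))
  scorer <- linear_scorer(W, bias = c(5, 0)) # bias forces predicted class 1
  d <- random_at_rich(3, length = L, seed = 3)
  b <- encode_leaders(d)
  sal <- saliency_map(scorer, b)
  expected <- rowSums(abs(W[, , 1]))
  for (i in 1:3) expect_equal(sal$values[i, ], expected, tolerance = 1e-6)
})

test_that("saliency of the trained model head ignoring the input is zero", {
  m <- build_model(tiny_model_config())
  m$params$head_W[] <- 0
  m$params$head_b[] <- 0
  d <- random_at_rich(2, length = 30, seed = 4)
  b <- encode_leaders(d)
  sal <- saliency_map(m, b)
  expect_true(all(abs(sal$values) < 1e-12))
})

test_that("saliency respects batch order (permutation of samples permutes profiles)", {
  m <- build_model(tiny_model_config(seed = 5))
  d <- random_at_rich(4, length = 30, seed = 9)
  b <- encode_leaders(d)
  s1 <- saliency_map(m, b)
  perm <- c(3, 1, 4, 2)
  bperm <- chloroleadr:::batch_subset(b, perm)
  s2 <- saliency_map(m, bperm)
  expect_equal(s2$values, s1$values[perm, ], tolerance = 1e-10)
})

test_that("moving average matches a loop oracle and handles edges by shrinking", {
  set.seed(7)
  x <- rnorm(50)
  w <- 5
  got <- moving_average(x, w)
  oracle <- vapply(seq_along(x), function(i) {
    lo <- max(1, i - 2); hi <- min(50, i + 2)
    mean(x[lo:hi])
  }, numeric(1))
  expect_equal(got, oracle, tolerance = 1e-9)
  # even window
  got4 <- moving_average(x, 4)
  oracle4 <- vapply(seq_along(x), function(i) {
    lo <- max(1, i - 2); hi <- min(50, i + 1)
    mean(x[lo:hi])
  }, numeric(1))
  expect_equal(got4, oracle4, tolerance = 1e-9)
  expect_equal(moving_average(x, 1), x)
})

test_that("perturbation importance of a constant-output model is identically zero", {
  const <- function(X) rep(1L, dim(X)[1])
  d <- random_at_rich(10, length = 30, seed = 8)
  d$label <- rep(c("x", "y"), 5)
  b <- encode_leaders(d)
  imp <- perturbation_importance(const, b, window_sizes = c(1, 4),
                                 seed = 2)
  expect_true(all(imp$value == 0))
  expect_true(all(imp$raw == 0))
})

test_that("perturbation importance matches an enumeration oracle on a motif classifier", {
  # oracle classifier: class 2 iff AGGAGG occurs in the proximal 20 nt
  clf <- function(X) {
    n <- dim(X)[1]; L <- dim(X)[2]
    vapply(seq_len(n), function(i) {
      idx <- apply(matrix(X[i, , ], L, 5), 1, which.max)
      s <- paste(c("A", "T", "C", "G", "N")[idx], collapse = "")
      if (grepl("AGGAGG", substr(s, L - 19, L))) 2L else 1L
    }, integer(1))
  }
  L <- 20
  with_motif <- as.character(plant_motif(strrep("T", L), "AGGAGG",
                                         c(-12L, -7L), seed = 1))
  d <- tibble::tibble(
    id = c("m", "bg"),
    sequence = c(with_motif, strrep("T", L)),
    label = c("pos", "neg") # levels: neg=1, pos=2
  )
  b <- encode_leaders(d)
  expect_identical(clf(b$data), c(2L, 1L)) # classified perfectly

  k <- 2
  n_rand <- 400
  imp <- perturbation_importance(clf, b, window_sizes = k, coarse_step = 1,
                                 smooth_window = 1, n_random = n_rand,
                                 seed = 33)
  # exact enumeration: mutating positions i..i+1 with uniform bases destroys
  # the motif unless the replacement restores it; background never gains one.
  motif_idx <- 9:14 # AGGAGG at -12..-7 of a 20-nt string
  exact <- vapply(seq_len(L - k + 1), function(i) {
    cols <- i:(i + k - 1)
    ov <- intersect(cols, motif_idx)
    if (length(ov) == 0) return(0)
    # P(replacement equals the motif bases) = (1/4)^overlap
    (1 - 0.25^length(ov)) * 0.5 # only the motif sequence can flip
  }, numeric(1))
  got <- imp$value[imp$scanned]
  # Monte-Carlo tolerance: 4 sd of a binomial mean over n_rand draws
  tol <- 4 * sqrt(0.25 / n_rand) * 0.5
  expect_true(all(abs(got - exact) <= tol + 1e-12))
  # windows fully outside the decision region have exactly zero importance
  expect_true(all(got[1:6] == 0))
})

test_that("profiles tidy into anchored upstream coordinates", {
  vals <- matrix(1:8, 2, 4)
  ps <- chloroleadr:::new_profile_set(vals, c("a", "b"), "saliency", 4)
  td <- tidy(ps)
  expect_equal(unique(td$position), c(-4, -3, -2, -1))
  expect_equal(td$value[td$id == "a"], vals[1, ])
})
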