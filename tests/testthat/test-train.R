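# Training recipe: splits, folds, reproducibility, metric formulas,
# cross-validation aggregation.

make_labelled <- function(n_a, n_b, L = 30, seed = 1) {
  d <- random_at_rich(n_a + n_b, length = L, seed = seed)
  d$label <- rep(c("a", "b"), c(n_a, n_b))
  d
}

test_that("stratified_split preserves class proportions and is seeded", {
  d <- make_labelled(100, 100)
  sp <- stratified_split(d, 0.2, seed = 4)
  expect_equal(unname(table(sp$train$label)), c(80L, 80L), ignore_attr = TRUE)
  expect_equal(unname(table(sp$test$label)), c(20L, 20L), ignore_attr = TRUE)
  expect_length(intersect(sp$train$id, sp$test$id), 0)
  sp2 <- stratified_split(d, 0.2, seed = 4)
  expect_identical(sp$test$id, sp2$test$id)

  imb <- make_labelled(150, 50)
  spi <- stratified_split(imb, 0.2, seed = 9)
  counts <- table(spi$test$label)
  expect_lte(abs(counts[["a"]] - 30), 1)
  expect_lte(abs(counts[["b"]] - 10), 1)
})

test_that("kfold_indices partitions with per-fold class balance", {
  d <- make_labelled(100, 100)
  folds <- kfold_indices(d$label, k = 5, seed = 2)
  expect_setequal(unique(folds), 1:5)
  expect_equal(length(folds), 200)
  for (f in 1:5) {
    tab <- table(d$label[folds == f])
    expect_equal(unname(tab), c(20L, 20L), ignore_attr = TRUE)
  }
  # brute-force counting oracle on an uneven case
  d2 <- make_labelled(53, 47, seed = 3)
  f2 <- kfold_indices(d2$label, k = 5, seed = 3)
  for (f in 1:5) {
    cnt_a <- sum(d2$label == "a" & f2 == f)
    expect_lte(abs(cnt_a - 53 / 5), 1)
  }
  expect_error(kfold_indices(rep(c("a", "b"), c(3, 100)), k = 5), "exceeds")
})

test_that("zero training epochs leave the model at its initialisation", {
  d <- make_labelled(20, 20)
  cfg <- tiny_model_config()
  fit <- fit_leader_model(d, cfg, train_config(epochs = 0, seed = 1))
  expect_identical(fit$model$params, build_model(cfg)$params)
  expect_equal(nrow(fit$history), 0)
})

test_that("training is reproducible under the seed", {
  d <- make_labelled(40, 40)
  cfg <- tiny_model_config()
  tc <- train_config(epochs = 2, batch_size = 16, seed = 8)
  f1 <- fit_leader_model(d, cfg, tc)
  f2 <- fit_leader_model(d, cfg, tc)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("a separable planted-motif task is learned within ten epochs", {
  spec <- synthetic_spec(
    n_per_class = 200, length = 60, at_fraction = 0.70,
    class_motifs = list(
      a = list(motif = "GCGGCCGC", window = c(-35L, -10L), prob = 1),
      b = list(motif = NULL, window = NULL, prob = 0)
    ),
    seed = 19
  )
  d <- generate_leaders(spec)
  sp <- stratified_split(d, 0.2, seed = 5)
  fit <- fit_leader_model(
    sp$train, desk_model_config(seq_length = 60, seed = 2),
    train_config(epochs = 10, batch_size = 16, seed = 6)
  )
  rep <- evaluate_model(fit, sp$test)
  expect_gte(rep$accuracy, 0.95)
  expect_lte(nrow(fit$history), 10)
})

test_that("separable-task accuracy is stable across training seeds", {
  spec <- synthetic_spec(
    n_per_class = 200, length = 60, at_fraction = 0.70,
    class_motifs = list(
      a = list(motif = "GCGGCCGC", window = c(-35L, -10L), prob = 1),
      b = list(motif = NULL, window = NULL, prob = 0)
    ),
    seed = 19
  )
  d <- generate_leaders(spec)
  sp <- stratified_split(d, 0.2, seed = 5)
  accs <- vapply(c(6, 7, 8), function(s) {
    fit <- fit_leader_model(
      sp$train, desk_model_config(seq_length = 60, seed = 2),
      train_config(epochs = 10, batch_size = 16, seed = s)
    )
    evaluate_model(fit, sp$test)$accuracy
  }, numeric(1))
  expect_lt(max(accs) - min(accs), 0.05)
  expect_true(all(accs >= 0.9))
})

test_that("metric suite matches independent from-formula oracles to 1e-9", {
  set.seed(12)
  n <- 500
  truth <- sample(c("neg", "pos"), n, replace = TRUE)
  score <- runif(n) # random scores
  pred <- ifelse(score > 0.5, "pos", "neg")
  m <- compute_metrics(truth, pred, score_positive = score,
                       classes = c("neg", "pos"))

  # confusion-count oracles
  tp <- sum(truth == "pos" & pred == "pos")
  tn <- sum(truth == "neg" & pred == "neg")
  fp <- sum(truth == "neg" & pred == "pos")
  fn <- sum(truth == "pos" & pred == "neg")
  expect_equal(m$accuracy, (tp + tn) / n, tolerance = 1e-12)
  mcc_o <- (tp * tn - fp * fn) /
    sqrt((tp + fp)) / sqrt((tp + fn)) / sqrt((tn + fp)) / sqrt((tn + fn))
  expect_equal(m$mcc, mcc_o, tolerance = 1e-9)

  prec_pos <- tp / (tp + fp); rec_pos <- tp / (tp + fn)
  f1_pos <- 2 * prec_pos * rec_pos / (prec_pos + rec_pos)
  prec_neg <- tn / (tn + fn); rec_neg <- tn / (tn + fp)
  f1_neg <- 2 * prec_neg * rec_neg / (prec_neg + rec_neg)
  w_pos <- sum(truth == "pos") / n
  expect_equal(m$f1_weighted, (1 - w_pos) * f1_neg + w_pos * f1_pos,
               tolerance = 1e-9)
  expect_equal(m$f1_macro, (f1_neg + f1_pos) / 2, tolerance = 1e-9)

  # ROC-AUC by pairwise concordance counting
  pos_scores <- score[truth == "pos"]
  neg_scores <- score[truth == "neg"]
  cmp <- outer(pos_scores, neg_scores, function(a, b) {
    (a > b) + 0.5 * (a == b)
  })
  expect_equal(m$roc_auc, mean(cmp), tolerance = 1e-9)

  # average precision: rank-based oracle (precision at each positive's rank)
  ord <- order(score, decreasing = TRUE)
  y <- as.integer(truth[ord] == "pos")
  ap_o <- sum((cumsum(y) / seq_len(n))[y == 1]) / sum(y)
  expect_equal(m$average_precision, ap_o, tolerance = 1e-9)
})

test_that("degenerate predictors give the expected metric values", {
  truth <- rep(c("a", "b"), each = 50)
  perfect <- compute_metrics(truth, truth,
                             score_positive = as.integer(truth == "b"),
                             classes = c("a", "b"))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$roc_auc, 1)

  allsame <- compute_metrics(truth, rep("a", 100),
                             score_positive = rep(0.5, 100),
                             classes = c("a", "b"))
  expect_equal(allsame$accuracy, 0.5)
  expect_equal(allsame$mcc, 0)

  single <- compute_metrics(rep("a", 10), rep("a", 10),
                            score_positive = runif(10),
                            classes = c("a", "b"))
  expect_true(single$single_class)
  expect_true(is.na(single$roc_auc))
})

test_that("cross-validation aggregates fold metrics as mean and sd", {
  d <- make_labelled(30, 30, L = 30, seed = 7)
  cv <- run_cv_experiment(
    d, tiny_model_config(),
    train_config(epochs = 1, cv_folds = 3, batch_size = 32, seed = 2,
                 val_fraction = 0)
  )
  expect_equal(length(unique(cv$per_fold$fold)), 3)
  acc <- cv$per_fold$value[cv$per_fold$metric == "accuracy"]
  agg <- cv$summary[cv$summary$metric == "accuracy", ]
  expect_equal(agg$mean, mean(acc), tolerance = 1e-12)
  expect_equal(agg$sd, sd(acc), tolerance = 1e-12)
})

test_that("model checkpoints round-trip with a JSON config sidecar", {
  cfg <- tiny_model_config(seed = 31)
  m <- build_model(cfg)
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  back <- load_model(path)
  expect_identical(back$params, m$params)
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$seq_length, cfg$seq_length)
  expect_equal(side$lstm_hidden, cfg$lstm_hidden)
  expect_equal(side$seed, cfg$seed)
  # restored model predicts identically
  b <- encode_leaders(random_at_rich(3, length = 30, seed = 1))
  expect_identical(chloroleadr:::model_forward(back, b$data)$logits,
                   chloroleadr:::model_forward(m, b$data)$logits)
})

test_that("metrics exports carry the scalar metrics and curve points", {
  truth <- rep(c("a", "b"), each = 25)
  score <- c(runif(25, 0, 0.6), runif(25, 0.4, 1))
  pred <- ifelse(score > 0.5, "b", "a")
  rep_ <- compute_metrics(truth, pred, score, classes = c("a", "b"))
  prefix <- tempfile()
  write_metrics(rep_, prefix)
  j <- jsonlite::read_json(paste0(prefix, ".json"))
  expect_equal(j$accuracy, rep_$accuracy)
  expect_equal(j$mcc, rep_$mcc, tolerance = 1e-12)
  roc <- read.table(paste0(prefix, "_roc.tsv"), header = TRUE, sep = "\t")
  expect_equal(nrow(roc), nrow(rep_$roc_curve))
})

test_that("a zero-removal truncation experiment yields identical arms", {
  d <- make_labelled(30, 30, L = 30, seed = 15)
  res <- truncation_experiment(
    d, remove = 0,
    model_cfg = tiny_model_config(),
    train_cfg = train_config(epochs = 1, batch_size = 32, seed = 3)
  )
  expect_identical(res$full$metrics$accuracy, res$truncated$metrics$accuracy)
  expect_identical(res$comparison$f1[1], res$comparison$f1[2])
})
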