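# Training recipe: Adam + cross-entropy with L2 weight decay, plateau LR
# halving, early stopping with best-weight restoration, stratified splits and
# k-fold cross-validation, and the proximal-truncation experiment.

#' Configure the training recipe
#'
#' Defaults follow the reference recipe: cross-entropy loss, Adam with
#' learning rate 0.001 and weight decay 1e-5, up to 50 epochs at batch size
#' 64, 80/20 stratified train/test split, 5-fold stratified cross-validation,
#' early stopping (patience 5, best weights restored) and plateau LR halving
#' (factor 0.5, patience 2, floor 1e-5). Gradient clipping is available but
#' off by default.
#'
#' @param learning_rate Adam learning rate.
#' @param weight_decay L2 regularisation strength.
#' @param epochs Maximum number of epochs.
#' @param batch_size Minibatch size.
#' @param test_fraction Held-out test fraction for [stratified_split()].
#' @param cv_folds Folds for [run_cv_experiment()].
#' @param early_stopping_patience Epochs without validation-loss improvement
#'   before stopping.
#' @param lr_factor,lr_patience,lr_floor Plateau schedule: multiply the rate
#'   by `lr_factor` after `lr_patience` stagnant epochs, never below
#'   `lr_floor`.
#' @param grad_clip_norm Optional global gradient-norm clip (`NULL` = off).
#' @param val_fraction Fraction of the training set carved out for validation
#'   when no explicit validation set is supplied.
#' @param seed Integer seed governing shuffling, dropout and splits.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.001,
                         weight_decay = 1e-5,
                         epochs = 50L,
                         batch_size = 64L,
                         test_fraction = 0.2,
                         cv_folds = 5L,
                         early_stopping_patience = 5L,
                         lr_factor = 0.5,
                         lr_patience = 2L,
                         lr_floor = 1e-5,
                         grad_clip_norm = NULL,
                         val_fraction = 0.1,
                         seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1, cv_folds >= 2)
  structure(
    list(
      learning_rate = learning_rate, weight_decay = weight_decay,
      epochs = as.integer(epochs), batch_size = as.integer(batch_size),
      test_fraction = test_fraction, cv_folds = as.integer(cv_folds),
      early_stopping_patience = as.integer(early_stopping_patience),
      lr_factor = lr_factor, lr_patience = as.integer(lr_patience),
      lr_floor = lr_floor, grad_clip_norm = grad_clip_norm,
      val_fraction = val_fraction, seed = as.integer(seed)
    ),
    class = "train_config"
  )
}

#' Stratified train/test split
#'
#' Splits a labelled table so that class proportions are preserved within
#' rounding; deterministic under `seed`.
#'
#' @param leaders Labelled tibble (column `label`).
#' @param test_fraction Fraction per class assigned to the test set.
#' @param seed Integer seed.
#' @return List with `train` and `test` tibbles.
#' @export
stratified_split <- function(leaders, test_fraction = 0.2, seed = 1L) {
  assert_leader_tbl(leaders, require_label = TRUE)
  labs <- leaders$label
  sizes <- table(labs)
  if (any(sizes < 2)) abort("every class needs at least 2 members")
  test_idx <- withr::with_seed(seed, {
    unlist(lapply(names(sizes), function(lab) {
      idx <- which(labs == lab)
      sample(idx, round(length(idx) * test_fraction))
    }))
  })
  list(
    train = leaders[-test_idx, , drop = FALSE],
    test = leaders[sort(test_idx), , drop = FALSE]
  )
}

#' Stratified k-fold assignment
#'
#' Assigns every row to one of `k` folds so that each fold's class ratio
#' matches the whole within one member.
#'
#' @param labels Vector of class labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in 1..k.
#' @export
kfold_indices <- function(labels, k = 5L, seed = 1L) {
  labels <- as.character(labels)
  sizes <- table(labels)
  if (any(sizes < k)) {
    abort(paste0("k (", k, ") exceeds the size of class '",
                 names(sizes)[sizes < k][1], "'"))
  }
  folds <- integer(length(labels))
  withr::with_seed(seed, {
    for (lab in names(sizes)) {
      idx <- sample(which(labels == lab))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

adam_init <- function(params) {
  list(
    m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
    v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
    t = 0L
  )
}

adam_step <- function(params, grads, opt, lr, weight_decay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      clip_norm = NULL) {
  if (!is.null(clip_norm)) {
    total <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
    if (total > clip_norm) {
      grads <- lapply(grads, function(g) g * (clip_norm / total))
    }
  }
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]] + weight_decay * params[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}

as_batch <- function(x, target_length = NULL) {
  if (inherits(x, "encoded_batch")) return(x)
  encode_leaders(x, target_length = target_length)
}

eval_loss_acc <- function(model, batch, y) {
  fw <- model_forward(model, batch$data, training = FALSE)
  n <- nrow(fw$probs)
  loss <- -mean(log(pmax(fw$probs[cbind(seq_len(n), y)], 1e-12)))
  acc <- mean(max.col(fw$probs, ties.method = "first") == y)
  list(loss = loss, acc = acc)
}

#' Fit the classifier
#'
#' Trains with minibatch Adam under the supplied recipe. When `validation` is
#' `NULL`, a stratified `val_fraction` of the training data is carved out for
#' early stopping and LR scheduling. Training is fully reproducible under
#' `train_cfg$seed`; the parameters achieving the best validation loss are
#' restored at the end.
#'
#' @param train Labelled leader tibble or `encoded_batch`.
#' @param model_cfg A [model_config()] (its `seq_length` must match the data).
#' @param train_cfg A [train_config()].
#' @param validation Optional validation set (tibble or `encoded_batch`).
#' @return A `leader_fit`: `model`, `history` (per-epoch tibble), `classes`,
#'   `train_config`.
#' @export
fit_leader_model <- function(train, model_cfg = model_config(),
                             train_cfg = train_config(),
                             validation = NULL) {
  if (!inherits(train, "encoded_batch") && is.null(validation) &&
      train_cfg$val_fraction > 0) {
    sp <- stratified_split(train, train_cfg$val_fraction,
                           seed = child_seed(train_cfg$seed, 77L))
    validation <- sp$test
    train <- sp$train
  }
  tb <- as_batch(train, model_cfg$seq_length)
  if (is.null(tb$labels)) abort("training data must be labelled")
  vb <- if (!is.null(validation)) as_batch(validation, model_cfg$seq_length)
  y <- as.integer(tb$labels)
  yv <- if (!is.null(vb)) as.integer(factor(as.character(vb$labels),
                                            levels = tb$classes))

  model <- build_model(model_cfg)
  opt <- adam_init(model$params)
  lr <- train_cfg$learning_rate
  n <- dim(tb$data)[1]
  history <- list()
  best <- list(loss = Inf, params = model$params, state = model$state,
               epoch = 0L)
  stale <- 0L; lr_stale <- 0L

  for (epoch in seq_len(train_cfg$epochs)) {
    ep <- withr::with_seed(child_seed(train_cfg$seed, epoch), {
      ord <- sample(n)
      n_batches <- ceiling(n / train_cfg$batch_size)
      tl <- 0; tc <- 0
      for (bi in seq_len(n_batches)) {
        take <- ord[(((bi - 1L) * train_cfg$batch_size) + 1L):
                      min(bi * train_cfg$batch_size, n)]
        Xb <- tb$data[take, , , drop = FALSE]
        yb <- y[take]
        nb <- length(take)
        fw <- model_forward(model, Xb, training = TRUE, keep_cache = TRUE)
        model$state <- fw$new_state
        pb <- pmax(fw$probs[cbind(seq_len(nb), yb)], 1e-12)
        loss <- -mean(log(pb))
        if (!is.finite(loss)) {
          abort(paste0("non-finite training loss at epoch ", epoch))
        }
        tl <- tl + loss * nb
        tc <- tc + sum(max.col(fw$probs, ties.method = "first") == yb)
        dlogits <- fw$probs
        dlogits[cbind(seq_len(nb), yb)] <- dlogits[cbind(seq_len(nb), yb)] - 1
        dlogits <- dlogits / nb
        bk <- model_backward(model, fw$cache, dlogits)
        upd <- adam_step(model$params, bk$grads, opt, lr,
                         train_cfg$weight_decay,
                         clip_norm = train_cfg$grad_clip_norm)
        model$params <- upd$params
        opt <- upd$opt
      }
      list(model = model, opt = opt, train_loss = tl / n, train_acc = tc / n)
    })
    model <- ep$model; opt <- ep$opt

    val <- if (!is.null(vb)) eval_loss_acc(model, vb, yv) else
      list(loss = NA_real_, acc = NA_real_)
    history[[epoch]] <- tibble(
      epoch = epoch, train_loss = ep$train_loss, train_acc = ep$train_acc,
      val_loss = val$loss, val_acc = val$acc, lr = lr
    )

    if (!is.null(vb)) {
      if (val$loss < best$loss - 1e-8) {
        best <- list(loss = val$loss, params = model$params,
                     state = model$state, epoch = epoch)
        stale <- 0L; lr_stale <- 0L
      } else {
        stale <- stale + 1L
        lr_stale <- lr_stale + 1L
        if (lr_stale >= train_cfg$lr_patience) {
          lr <- max(lr * train_cfg$lr_factor, train_cfg$lr_floor)
          lr_stale <- 0L
        }
        if (stale >= train_cfg$early_stopping_patience) break
      }
    }
  }
  if (!is.null(vb) && is.finite(best$loss)) {
    model$params <- best$params
    model$state <- best$state
  }
  structure(
    list(
      model = model, history = bind_rows(history), classes = tb$classes,
      train_config = train_cfg, best_epoch = best$epoch
    ),
    class = "leader_fit"
  )
}

#' @export
print.leader_fit <- function(x, ...) {
  h <- x$history
  cat("<leader_fit> classes:", paste(x$classes, collapse = " vs "), "|",
      nrow(h), "epochs")
  if (nrow(h) > 0 && !all(is.na(h$val_acc))) {
    cat(sprintf(" | best val loss %.4f (epoch %d)",
                min(h$val_loss, na.rm = TRUE), x$best_epoch))
  }
  cat("\n")
  invisible(x)
}

#' @describeIn fit_leader_model Per-epoch training history.
#' @param x A `leader_fit`.
#' @param ... Unused.
#' @export
tidy.leader_fit <- function(x, ...) x$history

#' @describeIn fit_leader_model One-row fit summary.
#' @export
glance.leader_fit <- function(x, ...) {
  h <- x$history
  tibble(
    epochs_run = nrow(h),
    best_epoch = x$best_epoch,
    final_train_acc = if (nrow(h)) h$train_acc[nrow(h)] else NA_real_,
    best_val_loss = if (nrow(h) && !all(is.na(h$val_loss)))
      min(h$val_loss, na.rm = TRUE) else NA_real_,
    parameters = count_parameters(x$model)
  )
}

#' Evaluate a fitted model on a test set
#'
#' @param fit A `leader_fit` (or bare `leader_model` plus `classes`).
#' @param test Labelled leader tibble or `encoded_batch`, disjoint from the
#'   training data (caller contract; [stratified_split()] guarantees it).
#' @param classes Class levels, needed only when `fit` is a bare model.
#' @return A `metrics_report` with an added `predictions` tibble attribute.
#' @export
evaluate_model <- function(fit, test, classes = NULL) {
  model <- if (inherits(fit, "leader_fit")) fit$model else fit
  classes <- if (inherits(fit, "leader_fit")) fit$classes else classes
  batch <- as_batch(test, model$config$seq_length)
  if (is.null(batch$labels)) abort("test data must be labelled")
  fw <- model_forward(model, batch$data, training = FALSE)
  probs <- fw$probs
  pred <- classes[max.col(probs, ties.method = "first")]
  truth <- as.character(batch$labels)
  rep <- compute_metrics(truth, pred, score_positive = probs[, 2],
                         classes = classes)
  attr(rep, "predictions") <- tibble(
    id = batch$ids, truth = truth, predicted = pred,
    score = probs[, 2]
  )
  rep
}

#' Stratified k-fold cross-validation experiment
#'
#' Trains and evaluates once per fold (the held-out fold serves as both
#' early-stopping validation set and evaluation set) and aggregates every
#' scalar metric as mean and standard deviation over folds.
#'
#' @param leaders Labelled leader tibble.
#' @param model_cfg A [model_config()].
#' @param train_cfg A [train_config()] (`cv_folds` folds; fold assignment is
#'   seeded by `seed`).
#' @param keep_models Keep the per-fold `leader_fit` objects.
#' @return A `cv_result`: `summary` (metric, mean, sd), `per_fold` tibble,
#'   `fits` (list or `NULL`).
#' @export
run_cv_experiment <- function(leaders, model_cfg = model_config(),
                              train_cfg = train_config(),
                              keep_models = FALSE) {
  assert_leader_tbl(leaders, require_label = TRUE)
  folds <- kfold_indices(leaders$label, train_cfg$cv_folds, train_cfg$seed)
  per_fold <- list()
  fits <- list()
  for (fold in seq_len(train_cfg$cv_folds)) {
    tr <- leaders[folds != fold, , drop = FALSE]
    va <- leaders[folds == fold, , drop = FALSE]
    cfg_f <- train_cfg
    cfg_f$seed <- child_seed(train_cfg$seed, fold)
    fit <- fit_leader_model(tr, model_cfg, cfg_f, validation = va)
    rep <- evaluate_model(fit, va)
    per_fold[[fold]] <- tidy(rep) %>% mutate(fold = fold)
    if (keep_models) fits[[fold]] <- fit
  }
  per_fold <- bind_rows(per_fold)
  summary <- per_fold %>%
    group_by(.data$metric) %>%
    summarise(
      mean = mean(.data$value), sd = sd(.data$value), .groups = "drop"
    )
  structure(
    list(summary = summary, per_fold = per_fold,
         fits = if (keep_models) fits else NULL,
         aggregation = "over folds"),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> aggregation", x$aggregation, "\n")
  print(as.data.frame(x$summary))
  invisible(x)
}

#' Proximal-truncation experiment
#'
#' Trains and evaluates the identical recipe on (a) full-length leaders and
#' (b) leaders with the `remove` 3'-most nucleotides deleted (positions
#' -1..-remove), quantifying how much classification signal the proximal
#' window carries. The comparison table reports per-class inputs, weighted
#' precision/recall/F1 and misclassified counts broken down by SD status.
#'
#' @param leaders Labelled leader tibble.
#' @param remove Proximal nucleotides removed in the truncated arm.
#' @param model_cfg,train_cfg Configurations applied identically to both arms
#'   (the truncated arm's `seq_length` is reduced by `remove`).
#' @param motifs,sd_window SD annotation used for the misclassified breakdown.
#' @return A `truncation_result`: `full` and `truncated` (each with `fit`,
#'   `metrics`, `misclassified`), and `comparison` tibble.
#' @export
truncation_experiment <- function(leaders, remove = 30L,
                                  model_cfg = model_config(),
                                  train_cfg = train_config(),
                                  motifs = sd_motifs(), sd_window = 20L) {
  assert_leader_tbl(leaders, require_label = TRUE)
  if (any(nchar(leaders$sequence) <= remove)) {
    abort("leaders must be longer than `remove`")
  }
  sp <- stratified_split(leaders, train_cfg$test_fraction, train_cfg$seed)

  run_arm <- function(train, test, cfg) {
    fit <- fit_leader_model(train, cfg, train_cfg)
    rep <- evaluate_model(fit, test)
    preds <- attr(rep, "predictions")
    harvest <- harvest_misclassified(preds$predicted, preds$truth, test,
                                     motifs = motifs, window = sd_window)
    list(fit = fit, metrics = rep, misclassified = harvest)
  }

  full <- run_arm(sp$train, sp$test, model_cfg)
  if (remove > 0) {
    cfg_t <- model_cfg
    cfg_t$seq_length <- model_cfg$seq_length - as.integer(remove)
    trunc_arm <- run_arm(
      truncate_leaders(sp$train, remove), truncate_leaders(sp$test, remove),
      cfg_t
    )
  } else {
    trunc_arm <- full
  }

  arm_row <- function(arm, name) {
    m <- arm$metrics
    sum_tbl <- arm$misclassified$summary
    tibble(
      input = name,
      n_inputs = m$n,
      precision = m$precision_weighted,
      recall = m$recall_weighted,
      f1 = m$f1_weighted,
      accuracy = m$accuracy,
      misclassified_total = sum(sum_tbl$total),
      misclassified_with_sd = sum(sum_tbl$with_sd),
      misclassified_without_sd = sum(sum_tbl$without_sd)
    )
  }
  comparison <- bind_rows(
    arm_row(full, "full"),
    arm_row(trunc_arm, paste0("truncated_", remove))
  )
  structure(
    list(full = full, truncated = trunc_arm, comparison = comparison,
         remove = remove),
    class = "truncation_result"
  )
}

#' @export
print.truncation_result <- function(x, ...) {
  cat("<truncation_result> remove =", x$remove, "nt\n")
  print(as.data.frame(x$comparison))
  invisible(x)
}
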