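# The hybrid CNN-BiLSTM-attention-residual classifier.
#
# Layer graph (L preserved by same-padding until the single max-pool):
#   stage 1: conv(k=3) -> batch norm -> ReLU, residual 1x1 projection of the
#            input added to the stage output
#   stage 2: three parallel convs (k = 3,5,7) on the stage-1 output,
#            concatenated; squeeze-and-excitation channel attention;
#            batch norm; residual 1x1 projection of the stage input added
#            (this pre-pool activation is the trace's conv feature map F);
#            max-pool (2); dropout 0.5
#   bidirectional LSTM (lstm_hidden units per direction)
#   multi-head self-attention (scaled dot product, learned Q/K/V + output
#            projection); sequence-mean context vector
#   fc1 -> BN -> ReLU -> dropout 0.3; fc2 -> BN -> ReLU -> dropout 0.3
#   linear head -> softmax

#' Configure the leader-sequence classifier
#'
#' Defaults follow the reference architecture (kernels 3/5/7, 64 channels per
#' branch, BiLSTM with 256 units per direction, 4 attention heads, fully
#' connected 256 and 512, dropout 0.5 after the convolutions and 0.3 in the
#' dense block). Tests and desk-scale experiments typically shrink
#' `conv_channels`, `lstm_hidden` and `fc_sizes`; the graph is unchanged.
#'
#' @param seq_length Input length L (default 300).
#' @param conv_channels Channels per convolutional branch (default 64).
#' @param multi_kernels Kernel sizes of the parallel branch (must be odd).
#' @param channel_attention_reduction Squeeze-and-excitation bottleneck ratio.
#' @param lstm_hidden Hidden units per LSTM direction (default 256).
#' @param attention_heads Number of self-attention heads; must divide
#'   `2 * lstm_hidden`.
#' @param fc_sizes Widths of the two fully connected layers.
#' @param conv_dropout,fc_dropout Dropout rates (0.5 / 0.3).
#' @param pool_size Max-pool kernel and stride (2).
#' @param n_classes Number of output classes (2).
#' @param channel_attention Ablation switch: `FALSE` fixes all channel gates
#'   at 1, reducing stage 2 to plain convolution.
#' @param seed Seed controlling parameter initialisation.
#' @return A `model_config` list.
#' @export
model_config <- function(seq_length = 300L,
                         conv_channels = 64L,
                         multi_kernels = c(3L, 5L, 7L),
                         channel_attention_reduction = 16L,
                         lstm_hidden = 256L,
                         attention_heads = 4L,
                         fc_sizes = c(256L, 512L),
                         conv_dropout = 0.5,
                         fc_dropout = 0.3,
                         pool_size = 2L,
                         n_classes = 2L,
                         channel_attention = TRUE,
                         seed = 1L) {
  D <- 2L * lstm_hidden
  if (D %% attention_heads != 0) {
    abort("2 * lstm_hidden must be divisible by attention_heads")
  }
  if (any(c(3L, multi_kernels) %% 2L == 0L)) {
    abort("kernel sizes must be odd for exact same-length padding")
  }
  if (seq_length %% pool_size != 0) {
    abort("seq_length must be divisible by pool_size")
  }
  structure(
    list(
      input_channels = 5L, seq_length = as.integer(seq_length),
      conv1_kernel = 3L, multi_kernels = as.integer(multi_kernels),
      conv_channels = as.integer(conv_channels),
      channel_attention_reduction = as.integer(channel_attention_reduction),
      lstm_hidden = as.integer(lstm_hidden),
      attention_heads = as.integer(attention_heads),
      fc_sizes = as.integer(fc_sizes),
      conv_dropout = conv_dropout, fc_dropout = fc_dropout,
      pool_size = as.integer(pool_size), n_classes = as.integer(n_classes),
      channel_attention = isTRUE(channel_attention),
      seed = as.integer(seed)
    ),
    class = "model_config"
  )
}

init_mat <- function(nr, nc, scale) matrix(rnorm(nr * nc, sd = scale), nr, nc)

init_conv <- function(k, cin, cout) {
  array(rnorm(k * cin * cout, sd = sqrt(2 / (k * cin))), c(k, cin, cout))
}

#' Build an initialised classifier from a configuration
#'
#' Parameter initialisation is a pure function of `config$seed` (He-scaled
#' normal for convolutions and dense layers, uniform +/- 1/sqrt(H) for the
#' LSTM, forget-gate bias 1).
#'
#' @param config A [model_config()].
#' @return A `leader_model` (list of `config`, flat parameter list `params`,
#'   and batch-norm running state `state`).
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  C <- config$conv_channels
  M <- 3L * C
  H <- config$lstm_hidden
  D <- 2L * H
  Mr <- max(1L, M %/% config$channel_attention_reduction)
  F1 <- config$fc_sizes[1]; F2 <- config$fc_sizes[2]
  K <- config$n_classes
  withr::with_seed(config$seed, {
    u <- 1 / sqrt(H)
    params <- list(
      conv1_W = init_conv(3L, 5L, C), conv1_b = numeric(C),
      bn1_gamma = rep(1, C), bn1_beta = numeric(C),
      res1_W = init_mat(5L, C, sqrt(2 / 5)), res1_b = numeric(C),
      b3_W = init_conv(config$multi_kernels[1], C, C), b3_b = numeric(C),
      b5_W = init_conv(config$multi_kernels[2], C, C), b5_b = numeric(C),
      b7_W = init_conv(config$multi_kernels[3], C, C), b7_b = numeric(C),
      se_W1 = init_mat(M, Mr, sqrt(2 / M)), se_b1 = numeric(Mr),
      se_W2 = init_mat(Mr, M, sqrt(2 / Mr)), se_b2 = numeric(M),
      bn2_gamma = rep(1, M), bn2_beta = numeric(M),
      res2_W = init_mat(C, M, sqrt(2 / C)), res2_b = numeric(M),
      lstm_f_Wx = matrix(runif(M * 4 * H, -u, u), M, 4 * H),
      lstm_f_Wh = matrix(runif(H * 4 * H, -u, u), H, 4 * H),
      lstm_f_b = rep(c(0, 1, 0, 0), each = H),
      lstm_b_Wx = matrix(runif(M * 4 * H, -u, u), M, 4 * H),
      lstm_b_Wh = matrix(runif(H * 4 * H, -u, u), H, 4 * H),
      lstm_b_b = rep(c(0, 1, 0, 0), each = H),
      att_Wq = init_mat(D, D, sqrt(1 / D)), att_bq = numeric(D),
      att_Wk = init_mat(D, D, sqrt(1 / D)), att_bk = numeric(D),
      att_Wv = init_mat(D, D, sqrt(1 / D)), att_bv = numeric(D),
      att_Wo = init_mat(D, D, sqrt(1 / D)), att_bo = numeric(D),
      fc1_W = init_mat(D, F1, sqrt(2 / D)), fc1_b = numeric(F1),
      bnf1_gamma = rep(1, F1), bnf1_beta = numeric(F1),
      fc2_W = init_mat(F1, F2, sqrt(2 / F1)), fc2_b = numeric(F2),
      bnf2_gamma = rep(1, F2), bnf2_beta = numeric(F2),
      head_W = init_mat(F2, K, sqrt(1 / F2)), head_b = numeric(K)
    )
  })
  state <- list(
    bn1_rm = numeric(C), bn1_rv = rep(1, C),
    bn2_rm = numeric(M), bn2_rv = rep(1, M),
    bnf1_rm = numeric(F1), bnf1_rv = rep(1, F1),
    bnf2_rm = numeric(F2), bnf2_rv = rep(1, F2)
  )
  structure(list(config = config, params = params, state = state),
            class = "leader_model")
}

#' Count trainable parameters
#'
#' @param model A `leader_model`.
#' @return Integer count of trainable scalars.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

#' @export
print.leader_model <- function(x, ...) {
  cfg <- x$config
  cat("<leader_model> L=", cfg$seq_length, ", conv ", cfg$conv_channels,
      "x3 branches, BiLSTM ", cfg$lstm_hidden, "/dir, ",
      cfg$attention_heads, " attention heads, fc ",
      paste(cfg$fc_sizes, collapse = "/"), ", ",
      count_parameters(x), " parameters\n", sep = "")
  invisible(x)
}

# Full forward pass. X: array (n, L, 5). Returns logits, probs and (optionally)
# the cache required by model_backward() and the trace quantities.
model_forward <- function(model, X, training = FALSE, keep_cache = FALSE,
                          ablate_channel_attention = !model$config$channel_attention,
                          update_state = training, need_alpha = FALSE) {
  cfg <- model$config
  p <- model$params
  st <- model$state
  n <- dim(X)[1]; L <- dim(X)[2]
  if (L != cfg$seq_length) {
    abort(paste0("batch length ", L, " != config seq_length ", cfg$seq_length))
  }
  Xm <- matrix(X, n * L, 5L) # position-major
  cache <- list(n = n, L = L, training = training)

  ## stage 1
  cv1 <- conv1d_forward(Xm, n, L, p$conv1_W, p$conv1_b)
  bn1 <- bn_forward(cv1$out, p$bn1_gamma, p$bn1_beta, st$bn1_rm, st$bn1_rv,
                    training)
  a1 <- pmax(bn1$out, 0)
  res1 <- Xm %*% p$res1_W + matrix(p$res1_b, n * L, length(p$res1_b),
                                   byrow = TRUE)
  s1 <- a1 + res1

  ## stage 2
  cv3 <- conv1d_forward(s1, n, L, p$b3_W, p$b3_b)
  cv5 <- conv1d_forward(s1, n, L, p$b5_W, p$b5_b)
  cv7 <- conv1d_forward(s1, n, L, p$b7_W, p$b7_b)
  zc <- cbind(cv3$out, cv5$out, cv7$out)
  se <- se_forward(zc, n, L, p$se_W1, p$se_b1, p$se_W2, p$se_b2,
                   ablate = ablate_channel_attention)
  bn2 <- bn_forward(se$out, p$bn2_gamma, p$bn2_beta, st$bn2_rm, st$bn2_rv,
                    training)
  res2 <- s1 %*% p$res2_W + matrix(p$res2_b, n * L, length(p$res2_b),
                                   byrow = TRUE)
  f_pre_pool <- bn2$out + res2 # trace conv feature map F, length L
  mp <- maxpool_forward(f_pre_pool, n, L, cfg$pool_size)
  T_ <- L %/% cfg$pool_size
  dp1 <- dropout_forward(mp$out, cfg$conv_dropout, training)

  ## recurrent encoder
  lf <- lstm_dir_forward(dp1$out, n, T_, p$lstm_f_Wx, p$lstm_f_Wh, p$lstm_f_b,
                         reverse = FALSE)
  lb <- lstm_dir_forward(dp1$out, n, T_, p$lstm_b_Wx, p$lstm_b_Wh, p$lstm_b_b,
                         reverse = TRUE)
  hseq <- cbind(lf$out, lb$out)

  ## self-attention + mean context
  att <- attention_forward(hseq, n, T_, cfg$attention_heads,
                           p$att_Wq, p$att_bq, p$att_Wk, p$att_bk,
                           p$att_Wv, p$att_bv, p$att_Wo, p$att_bo,
                           need_alpha = need_alpha)
  D <- ncol(hseq)
  ctx <- matrix(0, n, D)
  for (t in seq_len(T_)) {
    ctx <- ctx + att$out[((t - 1L) * n + 1L):(t * n), , drop = FALSE]
  }
  ctx <- ctx / T_

  ## dense head
  z1 <- ctx %*% p$fc1_W + matrix(p$fc1_b, n, length(p$fc1_b), byrow = TRUE)
  bf1 <- bn_forward(z1, p$bnf1_gamma, p$bnf1_beta, st$bnf1_rm, st$bnf1_rv,
                    training)
  a_f1 <- pmax(bf1$out, 0)
  dpf1 <- dropout_forward(a_f1, cfg$fc_dropout, training)
  z2 <- dpf1$out %*% p$fc2_W + matrix(p$fc2_b, n, length(p$fc2_b), byrow = TRUE)
  bf2 <- bn_forward(z2, p$bnf2_gamma, p$bnf2_beta, st$bnf2_rm, st$bnf2_rv,
                    training)
  a_f2 <- pmax(bf2$out, 0)
  dpf2 <- dropout_forward(a_f2, cfg$fc_dropout, training)
  logits <- dpf2$out %*% p$head_W + matrix(p$head_b, n, cfg$n_classes,
                                           byrow = TRUE)
  probs <- softmax_rows(logits)

  new_state <- if (update_state) {
    list(bn1_rm = bn1$rm, bn1_rv = bn1$rv, bn2_rm = bn2$rm, bn2_rv = bn2$rv,
         bnf1_rm = bf1$rm, bnf1_rv = bf1$rv, bnf2_rm = bf2$rm,
         bnf2_rv = bf2$rv)
  } else {
    st
  }

  out <- list(
    logits = logits, probs = probs, new_state = new_state,
    conv_features = f_pre_pool, alpha = att$alpha, context = ctx,
    n = n, L = L, T_ = T_
  )
  if (keep_cache) {
    out$cache <- list(
      n = n, L = L, T_ = T_, Xm = Xm, training = training,
      cv1 = cv1$cache, bn1 = bn1$cache, bn1_pre = bn1$out,
      cv3 = cv3$cache, cv5 = cv5$cache, cv7 = cv7$cache,
      se = se$cache, bn2 = bn2$cache, s1 = s1,
      mp = mp$cache, dp1 = dp1$cache,
      lf = lf$cache, lb = lb$cache, att = att$cache,
      bf1 = bf1$cache, bf1_pre = bf1$out, dpf1 = dpf1$cache,
      bf2 = bf2$cache, bf2_pre = bf2$out, dpf2 = dpf2$cache,
      ctx = ctx, dpf1_out = dpf1$out, dpf2_out = dpf2$out
    )
  }
  out
}

# Backward pass; dlogits (n, K). Returns flat gradient list (same names as
# params) and the input gradient dX (n, L, 5).
model_backward <- function(model, cache, dlogits) {
  p <- model$params
  n <- cache$n; L <- cache$L; T_ <- cache$T_
  g <- list()

  g$head_W <- crossprod(cache$dpf2_out, dlogits)
  g$head_b <- colSums(dlogits)
  d <- dlogits %*% t(p$head_W)
  d <- dropout_backward(d, cache$dpf2)
  d <- d * (cache$bf2_pre > 0)
  bb2 <- bn_backward(d, cache$bf2)
  g$bnf2_gamma <- bb2$dgamma; g$bnf2_beta <- bb2$dbeta
  g$fc2_W <- crossprod(cache$dpf1_out, bb2$dX)
  g$fc2_b <- colSums(bb2$dX)
  d <- bb2$dX %*% t(p$fc2_W)
  d <- dropout_backward(d, cache$dpf1)
  d <- d * (cache$bf1_pre > 0)
  bb1 <- bn_backward(d, cache$bf1)
  g$bnf1_gamma <- bb1$dgamma; g$bnf1_beta <- bb1$dbeta
  g$fc1_W <- crossprod(cache$ctx, bb1$dX)
  g$fc1_b <- colSums(bb1$dX)
  dctx <- bb1$dX %*% t(p$fc1_W)

  ## mean over time -> attention output
  D <- ncol(dctx)
  dAtt <- matrix(0, n * T_, D)
  for (t in seq_len(T_)) {
    dAtt[((t - 1L) * n + 1L):(t * n), ] <- dctx / T_
  }
  ab <- attention_backward(dAtt, cache$att)
  for (nm in c("Wq", "bq", "Wk", "bk", "Wv", "bv", "Wo", "bo")) {
    g[[paste0("att_", nm)]] <- ab[[paste0("d", nm)]]
  }
  dhseq <- ab$dX

  H <- ncol(dhseq) %/% 2L
  lfb <- lstm_dir_backward(dhseq[, 1:H, drop = FALSE], cache$lf)
  lbb <- lstm_dir_backward(dhseq[, (H + 1):(2 * H), drop = FALSE], cache$lb)
  g$lstm_f_Wx <- lfb$dWx; g$lstm_f_Wh <- lfb$dWh; g$lstm_f_b <- lfb$db
  g$lstm_b_Wx <- lbb$dWx; g$lstm_b_Wh <- lbb$dWh; g$lstm_b_b <- lbb$db
  d <- lfb$dX + lbb$dX

  d <- dropout_backward(d, cache$dp1)
  d_pre_pool <- maxpool_backward(d, cache$mp)

  ## stage 2 backward: d_pre_pool splits into BN2 path and residual path
  g$res2_W <- crossprod(cache$s1, d_pre_pool)
  g$res2_b <- colSums(d_pre_pool)
  ds1_res <- d_pre_pool %*% t(p$res2_W)
  bb <- bn_backward(d_pre_pool, cache$bn2)
  g$bn2_gamma <- bb$dgamma; g$bn2_beta <- bb$dbeta
  seb <- se_backward(bb$dX, cache$se)
  if (!is.null(seb$dW1)) {
    g$se_W1 <- seb$dW1; g$se_b1 <- seb$db1
    g$se_W2 <- seb$dW2; g$se_b2 <- seb$db2
  } else {
    g$se_W1 <- array(0, dim(p$se_W1)); g$se_b1 <- numeric(length(p$se_b1))
    g$se_W2 <- array(0, dim(p$se_W2)); g$se_b2 <- numeric(length(p$se_b2))
  }
  C <- ncol(cache$s1)
  d3 <- seb$dX[, 1:C, drop = FALSE]
  d5 <- seb$dX[, (C + 1):(2 * C), drop = FALSE]
  d7 <- seb$dX[, (2 * C + 1):(3 * C), drop = FALSE]
  c3b <- conv1d_backward(d3, cache$cv3)
  c5b <- conv1d_backward(d5, cache$cv5)
  c7b <- conv1d_backward(d7, cache$cv7)
  g$b3_W <- c3b$dW; g$b3_b <- c3b$db
  g$b5_W <- c5b$dW; g$b5_b <- c5b$db
  g$b7_W <- c7b$dW; g$b7_b <- c7b$db
  ds1 <- ds1_res + c3b$dX + c5b$dX + c7b$dX

  ## stage 1 backward
  g$res1_W <- crossprod(cache$Xm, ds1)
  g$res1_b <- colSums(ds1)
  dX_res <- ds1 %*% t(p$res1_W)
  da1 <- ds1 * (cache$bn1_pre > 0)
  bb0 <- bn_backward(da1, cache$bn1)
  g$bn1_gamma <- bb0$dgamma; g$bn1_beta <- bb0$dbeta
  c1b <- conv1d_backward(bb0$dX, cache$cv1)
  g$conv1_W <- c1b$dW; g$conv1_b <- c1b$db
  dXm <- dX_res + c1b$dX

  list(grads = g, dX = array(dXm, c(n, L, 5L)))
}

#' Run the model and collect the interpretability trace
#'
#' Evaluation-mode forward pass that exposes the intermediate quantities the
#' interpretability functions consume: the pre-pool convolutional feature maps
#' F (after channel attention, before pooling; length L), the per-head
#' row-stochastic self-attention matrices, the context vector, logits and
#' probabilities.
#'
#' @param model A `leader_model`.
#' @param batch An `encoded_batch` of length `config$seq_length`.
#' @return A `forward_trace` list: `logits`, `probabilities`, `conv_features`
#'   (array n x L x 3C), `alpha` (array n x heads x T x T), `context`, `ids`,
#'   `labels`, `seq_length`.
#' @export
forward_trace <- function(model, batch) {
  stopifnot(inherits(model, "leader_model"), inherits(batch, "encoded_batch"))
  fw <- model_forward(model, batch$data, training = FALSE, need_alpha = TRUE)
  n <- fw$n; L <- fw$L
  structure(
    list(
      logits = fw$logits,
      probabilities = fw$probs,
      conv_features = array(fw$conv_features, c(n, L, ncol(fw$conv_features))),
      alpha = fw$alpha,
      context = fw$context,
      ids = batch$ids,
      labels = batch$labels,
      seq_length = L
    ),
    class = "forward_trace"
  )
}

#' Save and restore a model checkpoint
#'
#' The parameters and batch-norm state go into an RDS file; the
#' configuration (the portable contract) is written alongside as JSON at
#' `<path>.json`.
#'
#' @param model A `leader_model` (or a `leader_fit`, whose model is saved).
#' @param path Checkpoint path (e.g. `"model.rds"`).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  if (inherits(model, "leader_fit")) model <- model$model
  stopifnot(inherits(model, "leader_model"))
  saveRDS(model, path)
  jsonlite::write_json(unclass(model$config), paste0(path, ".json"),
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "leader_model"))
  model
}

#' Predict class probabilities or labels for encoded leaders
#'
#' @param object A `leader_model`.
#' @param batch An `encoded_batch`.
#' @param type `"prob"` for the softmax matrix, `"class"` for labels.
#' @param ... Unused.
#' @return Matrix of probabilities (columns named by class) or a character
#'   vector of predicted labels.
#' @export
predict.leader_model <- function(object, batch, type = c("prob", "class"),
                                 ...) {
  type <- match.arg(type)
  fw <- model_forward(object, batch$data, training = FALSE)
  probs <- fw$probs
  classes <- batch$classes %||% paste0("class", seq_len(ncol(probs)))
  colnames(probs) <- classes
  if (type == "prob") return(probs)
  classes[max.col(probs, ties.method = "first")]
}
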