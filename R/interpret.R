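# Model-explanation procedures: spatial CNN attention, self-attention
# position profiles, gradient saliency, group-level aggregation and
# perturbation (in silico mutagenesis) importance.
#
# All profiles are anchored like the encoder: vector index j (1-based)
# corresponds to upstream position -(L - j + 1), so index L is position -1.

new_profile_set <- function(values, ids, kind, L, labels = NULL,
                            window_size = NA_integer_) {
  structure(
    list(values = values, ids = ids, kind = kind, seq_length = L,
         labels = labels, window_size = window_size),
    class = "profile_set"
  )
}

#' @export
print.profile_set <- function(x, ...) {
  cat("<profile_set> kind:", x$kind, "|", nrow(x$values), "samples x",
      x$seq_length, "positions\n")
  invisible(x)
}

#' Tidy a set of per-sample position profiles
#'
#' @param x A `profile_set` from [cnn_attention()], [lstm_attention()] or
#'   [saliency_map()].
#' @param ... Unused.
#' @return Long tibble (`id`, `position`, `value`, `kind`).
#' @export
tidy.profile_set <- function(x, ...) {
  L <- x$seq_length
  tibble(
    id = rep(x$ids, each = L),
    position = rep(index_to_upstream(seq_len(L), L), times = length(x$ids)),
    value = as.vector(t(x$values)),
    kind = x$kind
  )
}

#' Spatial attention profile from the convolutional feature maps
#'
#' For every sample, the mean absolute activation over channels of the final
#' convolutional feature map F (taken after channel attention and before
#' pooling), linearly interpolated to the input length L.
#'
#' @param trace A [forward_trace()].
#' @return A `profile_set` of kind `"cnn_attention"` (matrix n x L).
#' @export
cnn_attention <- function(trace) {
  stopifnot(inherits(trace, "forward_trace"))
  Fm <- trace$conv_features
  if (length(Fm) == 0) abort("trace carries an empty feature map")
  n <- dim(Fm)[1]; Lf <- dim(Fm)[2]
  L <- trace$seq_length
  vals <- t(vapply(seq_len(n), function(i) {
    interp_linear(rowMeans(abs(matrix(Fm[i, , ], Lf))), L)
  }, numeric(L)))
  new_profile_set(vals, trace$ids, "cnn_attention", L, trace$labels)
}

#' Position profile from the self-attention matrices
#'
#' Heads are averaged first; the profile value at position j is the mean
#' attention that position receives across query positions (columns of the
#' row-stochastic attention matrix), linearly interpolated from the recurrent
#' length T to the input length L. For a uniform attention matrix the profile
#' is constant 1/T.
#'
#' @param trace A [forward_trace()].
#' @param tol Row-normalisation tolerance.
#' @return A `profile_set` of kind `"lstm_attention"`.
#' @export
lstm_attention <- function(trace, tol = 1e-4) {
  stopifnot(inherits(trace, "forward_trace"))
  al <- trace$alpha
  n <- dim(al)[1]; heads <- dim(al)[2]; T_ <- dim(al)[3]
  L <- trace$seq_length
  vals <- matrix(0, n, L)
  for (i in seq_len(n)) {
    A <- matrix(0, T_, T_)
    for (h in seq_len(heads)) A <- A + matrix(al[i, h, , ], T_, T_)
    A <- A / heads
    rs <- rowSums(A)
    if (any(abs(rs - 1) > tol)) {
      abort("attention rows are not normalised")
    }
    vals[i, ] <- interp_linear(colMeans(A), L)
  }
  new_profile_set(vals, trace$ids, "lstm_attention", L, trace$labels)
}

#' Aggregate per-sample profiles by class
#'
#' Arithmetic mean of the (already interpolated) per-sample profiles within
#' each class.
#'
#' @param profiles A `profile_set`.
#' @param labels Class labels aligned with the profiles; defaults to the
#'   labels stored in the set.
#' @return A `position_profile` tibble: `class`, `position`, `value`, with
#'   attributes `kind` and `n_aggregated` (named per class).
#' @export
group_profile <- function(profiles, labels = NULL) {
  stopifnot(inherits(profiles, "profile_set"))
  labels <- labels %||% profiles$labels
  if (is.null(labels)) abort("no labels available for grouping")
  labels <- as.character(labels)
  if (length(labels) != nrow(profiles$values)) {
    abort("labels are not aligned with the profiles")
  }
  L <- profiles$seq_length
  classes <- sort(unique(labels))
  out <- lapply(classes, function(cl) {
    rows <- which(labels == cl)
    tibble(
      class = cl,
      position = index_to_upstream(seq_len(L), L),
      value = colMeans(profiles$values[rows, , drop = FALSE]),
      kind = profiles$kind
    )
  })
  res <- bind_rows(out)
  attr(res, "kind") <- profiles$kind
  attr(res, "n_aggregated") <- setNames(
    vapply(classes, function(cl) sum(labels == cl), integer(1)), classes
  )
  class(res) <- c("position_profile", class(res))
  res
}

#' Gradient saliency maps
#'
#' For each sequence, the absolute gradient of the predicted-class pre-softmax
#' logit with respect to the one-hot input, summed across the five nucleotide
#' channels. Computed in evaluation mode.
#'
#' @param model A `leader_model` (or a [linear_scorer()] toy).
#' @param batch An `encoded_batch`.
#' @param ... Passed to methods.
#' @return A `profile_set` of kind `"saliency"` (matrix n x L).
#' @export
saliency_map <- function(model, batch, ...) UseMethod("saliency_map")

#' @export
saliency_map.leader_model <- function(model, batch, ...) {
  stopifnot(inherits(batch, "encoded_batch"))
  fw <- model_forward(model, batch$data, training = FALSE, keep_cache = TRUE)
  n <- fw$n; L <- fw$L
  sel <- max.col(fw$logits, ties.method = "first")
  dlogits <- matrix(0, n, ncol(fw$logits))
  dlogits[cbind(seq_len(n), sel)] <- 1
  bk <- model_backward(model, fw$cache, dlogits)
  sal <- matrix(rowSums(abs(matrix(bk$dX, n * L, 5L))), n, L)
  new_profile_set(sal, batch$ids, "saliency", L, batch$labels)
}

#' A hand-weighted linear toy scorer
#'
#' Minimal reference model whose class scores are linear in the flattened
#' one-hot input: `logit[k] = sum_{j,c} W[j,c,k] * x[j,c] + b[k]`. Its
#' saliency has the closed form `sum_c |W[j,c,k*]|`, which makes it the
#' analytic oracle for validating gradient-attribution code.
#'
#' @param weights Array (L, 5, n_classes).
#' @param bias Numeric vector length `n_classes` (default 0).
#' @return A `linear_scorer` object usable with [saliency_map()] and
#'   [perturbation_importance()].
#' @export
linear_scorer <- function(weights, bias = NULL) {
  stopifnot(length(dim(weights)) == 3, dim(weights)[2] == 5)
  K <- dim(weights)[3]
  structure(
    list(W = weights, b = bias %||% numeric(K)),
    class = "linear_scorer"
  )
}

linear_scorer_logits <- function(model, X) {
  n <- dim(X)[1]; L <- dim(X)[2]
  K <- dim(model$W)[3]
  Xf <- matrix(X, n, L * 5L)
  Wf <- matrix(model$W, L * 5L, K)
  Xf %*% Wf + matrix(model$b, n, K, byrow = TRUE)
}

#' @export
saliency_map.linear_scorer <- function(model, batch, ...) {
  X <- batch$data
  n <- dim(X)[1]; L <- dim(X)[2]
  logits <- linear_scorer_logits(model, X)
  sel <- max.col(logits, ties.method = "first")
  vals <- t(vapply(seq_len(n), function(i) {
    rowSums(abs(matrix(model$W[, , sel[i]], L, 5L)))
  }, numeric(L)))
  new_profile_set(matrix(vals, n, L), batch$ids, "saliency", L, batch$labels)
}

#' Group-level saliency profiles
#'
#' Convenience wrapper: [saliency_map()] followed by [group_profile()].
#'
#' @inheritParams saliency_map
#' @param labels Optional labels overriding those in the batch.
#' @return A `position_profile` tibble.
#' @export
group_saliency <- function(model, batch, labels = NULL) {
  group_profile(saliency_map(model, batch), labels)
}

# Classifier dispatch for perturbation probing: a fitted leader_model, a
# linear_scorer toy, or a plain function X(array n,L,5) -> class indices
# (useful for oracle classifiers in validation).
predict_classes <- function(model, X) {
  if (is.function(model)) return(model(X))
  logits <- if (inherits(model, "linear_scorer")) {
    linear_scorer_logits(model, X)
  } else {
    model_forward(model, X, training = FALSE)$logits
  }
  max.col(logits, ties.method = "first")
}

#' Perturbation (in silico mutagenesis) importance profile
#'
#' For every window size k, windows of k nucleotides are replaced with
#' i.i.d. uniform random bases (A/T/C/G) in every sequence and the importance
#' of start position i is the resulting drop in accuracy:
#' `I_i = mean(1(y == yhat)) - mean(1(y == yhat'))`. The scan is
#' hierarchical: a coarse pass every `coarse_step` positions, then
#' single-position refinement around coarse positions whose importance
#' exceeds `refine_threshold`. Unscanned positions are filled by linear
#' interpolation (flagged in the `scanned` column) and the final track is
#' smoothed with a moving average of width L/10 (shrink-to-valid edges).
#'
#' @param model A `leader_model` or [linear_scorer()].
#' @param batch Labelled `encoded_batch` of sequences the model is probed on.
#' @param window_sizes Integer vector of mutation window sizes (default
#'   `c(1, 4, 8, 12)`).
#' @param coarse_step Coarse-scan stride (default 3).
#' @param refine_threshold Importance level triggering refinement (default
#'   0.1).
#' @param smooth_window Moving-average width; default `L/10`. Set to 1 to
#'   disable smoothing.
#' @param n_random Independent random mutation draws averaged per position.
#' @param seed Integer seed for the replacement draws.
#' @return Tibble with columns `window_size`, `position`, `value` (smoothed),
#'   `raw` (pre-smoothing), `scanned`; class `importance_profile`.
#' @export
perturbation_importance <- function(model, batch,
                                    window_sizes = c(1L, 4L, 8L, 12L),
                                    coarse_step = 3L,
                                    refine_threshold = 0.1,
                                    smooth_window = NULL,
                                    n_random = 1L,
                                    seed = 1L) {
  stopifnot(inherits(batch, "encoded_batch"))
  X <- batch$data
  n <- dim(X)[1]; L <- dim(X)[2]
  if (n == 0) abort("empty dataset")
  if (any(window_sizes > L)) abort("window size exceeds sequence length")
  if (is.null(batch$labels)) abort("batch must be labelled")
  y <- as.integer(batch$labels)
  base_correct <- predict_classes(model, X) == y
  base_acc <- mean(base_correct)

  # eye rows for the 4 real bases in channel order (A,T,C,G,N)
  base_rows <- diag(5)[1:4, , drop = FALSE]

  measure <- function(start, k, draw_seed) {
    cols <- start:(start + k - 1L)
    accs <- numeric(n_random)
    for (r in seq_len(n_random)) {
      Xm <- X
      repl <- withr::with_seed(child_seed(draw_seed, r), {
        matrix(sample.int(4L, n * k, replace = TRUE), n, k)
      })
      for (jj in seq_along(cols)) {
        Xm[, cols[jj], ] <- base_rows[repl[, jj], ]
      }
      accs[r] <- mean(predict_classes(model, Xm) == y)
    }
    base_acc - mean(accs)
  }

  out <- list()
  for (k in as.integer(window_sizes)) {
    max_start <- L - k + 1L
    coarse <- seq(1L, max_start, by = coarse_step)
    I <- rep(NA_real_, L)
    for (s in coarse) I[s] <- measure(s, k, child_seed(seed, k * 100000L + s))
    hot <- coarse[I[coarse] > refine_threshold]
    refine <- unique(unlist(lapply(hot, function(s) {
      max(1L, s - coarse_step + 1L):min(max_start, s + coarse_step - 1L)
    })))
    refine <- setdiff(refine, coarse)
    for (s in refine) I[s] <- measure(s, k, child_seed(seed, k * 100000L + s))
    scanned <- !is.na(I)
    # fill unscanned positions (incl. the k-1 tail starts) by interpolation
    filled <- approx(which(scanned), I[scanned], xout = seq_len(L),
                     rule = 2)$y
    sw <- if (is.null(smooth_window)) max(1L, L %/% 10L) else
      as.integer(smooth_window)
    smoothed <- moving_average(filled, sw)
    out[[length(out) + 1L]] <- tibble(
      window_size = k,
      position = index_to_upstream(seq_len(L), L),
      value = smoothed,
      raw = filled,
      scanned = scanned
    )
  }
  res <- bind_rows(out)
  class(res) <- c("importance_profile", class(res))
  attr(res, "coarse_step") <- coarse_step
  attr(res, "refine_threshold") <- refine_threshold
  attr(res, "n") <- n
  res
}

#' Export a position profile as TSV (and optionally JSON)
#'
#' @param profile A `position_profile` or `importance_profile` tibble.
#' @param path Output TSV path.
#' @param json Optional JSON output path.
#' @return The profile, invisibly.
#' @export
write_profile <- function(profile, path, json = NULL) {
  write.table(as.data.frame(profile), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(json)) {
    jsonlite::write_json(as.data.frame(profile), json, digits = NA)
  }
  invisible(profile)
}
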