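# One-hot encoding of leader sequences into the model's input tensor.
#
# Channel order is (A, T, C, G, N) — fixed, and deliberately not alphabetical:
#   A: 1 0 0 0 0   T: 0 1 0 0 0   C: 0 0 1 0 0   G: 0 0 0 1 0   N: 0 0 0 0 1
# The array is (n, L, 5); column L of the position axis always holds the base
# at upstream position -1, so sequences shorter than the target length are
# left-padded (5' side) with N. Array position j (1-based) corresponds to
# upstream position -(L - j + 1).

#' One-hot encode leader sequences
#'
#' @param leaders Leader tibble (columns `id`, `sequence`, optionally `label`).
#' @param target_length Common length L of the batch; defaults to the longest
#'   sequence. Shorter sequences are 5'-padded with N; longer ones are an
#'   error.
#' @return An `encoded_batch`: list with `data` (array n x L x 5, channels
#'   A,T,C,G,N), `ids`, `labels` (factor or `NULL`), `classes`, and
#'   `orig_length` (pre-padding lengths, used by [decode_batch()]).
#' @export
#' @examples
#' b <- encode_leaders(tibble::tibble(id = "x", sequence = "ATCGN"))
#' b$data[1, , ] # the five mapping rows in order
encode_leaders <- function(leaders, target_length = NULL) {
  assert_leader_tbl(leaders)
  seqs <- toupper(leaders$sequence)
  check_alphabet(seqs)
  lens <- nchar(seqs)
  L <- if (is.null(target_length)) max(lens) else as.integer(target_length)
  if (any(lens > L)) {
    abort(paste0("sequence longer than target_length (", L, "): ",
                 leaders$id[which(lens > L)[1]]))
  }
  n <- length(seqs)
  padded <- paste0(strrep("N", L - lens), seqs)
  # chars as integer channel index 1..5
  mat <- matrix(
    match(unlist(strsplit(padded, ""), use.names = FALSE), CHANNELS),
    nrow = L, ncol = n
  ) # column per sequence
  data <- array(0, dim = c(n, L, 5))
  pos <- rep(seq_len(L), times = n)
  samp <- rep(seq_len(n), each = L)
  data[cbind(samp, pos, as.vector(mat))] <- 1
  labels <- if ("label" %in% names(leaders)) factor(leaders$label) else NULL
  structure(
    list(
      data = data, ids = leaders$id, labels = labels,
      classes = if (!is.null(labels)) levels(labels) else NULL,
      orig_length = lens
    ),
    class = "encoded_batch"
  )
}

#' Decode a one-hot batch back to nucleotide strings
#'
#' Inverse of [encode_leaders()]: every length-5 channel row must be exactly
#' one-hot; 5' N-padding introduced by encoding is stripped using the recorded
#' original lengths.
#'
#' @param batch An `encoded_batch`.
#' @return Character vector of sequences.
#' @export
decode_batch <- function(batch) {
  stopifnot(inherits(batch, "encoded_batch"))
  d <- batch$data
  n <- dim(d)[1]; L <- dim(d)[2]
  sums <- apply(d, c(1, 2), sum)
  ones <- apply(d, c(1, 2), max)
  if (any(abs(sums - 1) > 1e-12) || any(abs(ones - 1) > 1e-12) || any(d < 0)) {
    abort("non-one-hot channel row in batch")
  }
  idx <- apply(d, c(1, 2), which.max)
  out <- vapply(seq_len(n), function(i) {
    paste(CHANNELS[idx[i, ]], collapse = "")
  }, character(1))
  keep <- batch$orig_length %||% rep(L, n)
  substr(out, L - keep + 1L, L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.encoded_batch <- function(x, ...) {
  d <- dim(x$data)
  cat("<encoded_batch> ", d[1], " sequences x ", d[2],
      " positions x 5 channels (A,T,C,G,N)\n", sep = "")
  if (!is.null(x$labels)) {
    cat("classes:", paste(x$classes, collapse = ", "), "\n")
  }
  invisible(x)
}

# subset an encoded batch by sample index (internal)
batch_subset <- function(batch, idx) {
  structure(
    list(
      data = batch$data[idx, , , drop = FALSE],
      ids = batch$ids[idx],
      labels = if (!is.null(batch$labels)) refactor_keep_levels(batch$labels[idx], batch$classes) else NULL,
      classes = batch$classes,
      orig_length = batch$orig_length[idx]
    ),
    class = "encoded_batch"
  )
}

# keep the full class set when subsetting (never drop levels)
refactor_keep_levels <- function(f, classes) factor(as.character(f), levels = classes)
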