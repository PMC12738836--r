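# Shared helpers: coordinate conventions and input validation.
#
# Upstream positions use the -k convention: -1 is the base immediately 5' of
# the start codon, -L the 5'-most base of an L-nt leader. For a string of
# length L, upstream position p corresponds to 1-based string index L + p + 1.

#' Convert upstream positions to 1-based string indices
#'
#' Leaders are anchored at the start codon: position -1 is the 3'-most base of
#' the leader, position -L its 5' end. This helper converts between that
#' convention and ordinary 1-based string indexing.
#'
#' @param position Integer vector of upstream positions (negative).
#' @param length Leader length L.
#' @return Integer vector of 1-based string indices.
#' @export
#' @examples
#' upstream_to_index(-1, 300) # 300
#' upstream_to_index(-300, 300) # 1
upstream_to_index <- function(position, length) {
  stopifnot(all(position <= -1), all(position >= -length))
  as.integer(length + position + 1)
}

#' @rdname upstream_to_index
#' @param index Integer vector of 1-based string indices.
#' @export
index_to_upstream <- function(index, length) {
  stopifnot(all(index >= 1), all(index <= length))
  as.integer(index - length - 1L)
}

DNA_BASES <- c("A", "C", "G", "T")
CHANNELS <- c("A", "T", "C", "G", "N") # model channel order (not alphabetical)

assert_leader_tbl <- function(x, require_label = FALSE) {
  if (!is.data.frame(x)) {
    abort("expected a data frame of leaders with columns `id` and `sequence`")
  }
  missing <- setdiff(c("id", "sequence"), names(x))
  if (length(missing) > 0) {
    abort(paste0("leader table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (require_label && !"label" %in% names(x)) {
    abort("leader table lacks a `label` column")
  }
  invisible(x)
}

check_alphabet <- function(sequences, allow_n = TRUE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, sequences)
  if (any(bad)) {
    abort(paste0(
      "sequence(s) contain characters outside {A,C,G,T",
      if (allow_n) ",N", "}: first offender at index ", which(bad)[1]
    ))
  }
  invisible(sequences)
}

# Map IUPAC ambiguity codes other than N to N, with a warning.
normalise_ambiguity <- function(sequences) {
  up <- toupper(sequences)
  has_amb <- grepl("[^ACGTN]", up)
  if (any(has_amb)) {
    warn(paste0(
      sum(has_amb), " sequence(s) contain ambiguity codes other than N; ",
      "mapped to N"
    ))
    up[has_amb] <- gsub("[^ACGTN]", "N", up[has_amb])
  }
  up
}

# Deterministic child seed derivation, kept below 2^31.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103 + as.numeric(offset) * 12289) %%
               2147483562)
}
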