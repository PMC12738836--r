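# Shine-Dalgarno scanning and dataset surgery on leader tables.

#' The consensus Shine-Dalgarno(-like) motif set
#'
#' The purine-rich ribosome-binding motifs scanned for in the proximal window:
#' AGGAGG and its derived variants, ordered longest first. Duplicates in the
#' conventional listing (GAAG appears twice) are removed; matching elsewhere in
#' the package is case-insensitive and N never matches.
#'
#' @return Character vector of motifs over {A,C,G,T}.
#' @export
sd_motifs <- function() {
  unique(c(
    "AGGAGG", "GAAGGAG", "AAGGAG", "AGGAG", "AAGGA", "AGGAAG", "AGGA",
    "GGAGG", "GAAG", "GGAG", "GAAG", "GAGG", "GGA", "AGG"
  ))
}

# scan a single window substring; returns list(motif, start_in_window) or NULL
# start_in_window is the 1-based index within the window substring
scan_window <- function(window_seq, motifs) {
  best <- NULL
  for (m in motifs) {
    hits <- gregexpr(m, window_seq, fixed = TRUE)[[1]]
    if (hits[1] == -1) next
    start <- max(hits) # 3'-most occurrence
    if (is.null(best) ||
        nchar(m) > nchar(best$motif) ||
        (nchar(m) == nchar(best$motif) && start > best$start)) {
      best <- list(motif = m, start = start)
    }
  }
  best
}

#' Scan leaders for Shine-Dalgarno motifs in the proximal window
#'
#' A leader "has SD" iff at least one motif of `motifs` occurs entirely within
#' its last `window` nucleotides (positions -1..-window). For reporting, the
#' longest matching motif is kept, ties broken by the 3'-most start; `has_sd`
#' itself does not depend on the tie-break.
#'
#' @param leaders Tibble with columns `id`, `sequence` (and optionally more).
#' @param motifs Character vector of motifs, default [sd_motifs()].
#' @param window Width of the proximal scan window in nt (default 20).
#' @return The input tibble with columns `has_sd` (logical), `matched_motif`
#'   (character, `NA` when absent) and `match_start` (upstream position of the
#'   match's 5' end, `NA` when absent).
#' @export
#' @examples
#' leaders <- tibble::tibble(id = "x", sequence = strrep("A", 300))
#' scan_sd(leaders)$has_sd
scan_sd <- function(leaders, motifs = sd_motifs(), window = 20L) {
  assert_leader_tbl(leaders)
  motifs <- unique(toupper(motifs))
  seqs <- toupper(leaders$sequence)
  lens <- nchar(seqs)
  if (any(lens < window)) {
    abort(paste0("window (", window, ") exceeds leader length (min ",
                 min(lens), ")"))
  }
  res <- lapply(seq_along(seqs), function(i) {
    L <- lens[i]
    win <- substr(seqs[i], L - window + 1L, L)
    hit <- scan_window(win, motifs)
    if (is.null(hit)) {
      list(has_sd = FALSE, matched_motif = NA_character_,
           match_start = NA_integer_)
    } else {
      # index within window -> index within sequence -> upstream position
      idx <- L - window + hit$start
      list(has_sd = TRUE, matched_motif = hit$motif,
           match_start = index_to_upstream(idx, L))
    }
  })
  leaders$has_sd <- vapply(res, `[[`, logical(1), "has_sd")
  leaders$matched_motif <- vapply(res, `[[`, character(1), "matched_motif")
  leaders$match_start <- vapply(res, `[[`, integer(1), "match_start")
  leaders
}

#' Partition leaders by Shine-Dalgarno status
#'
#' Disjoint, exhaustive split of a leader table by [scan_sd()].
#'
#' @inheritParams scan_sd
#' @return List with elements `with_sd` and `without_sd` (annotated tibbles)
#'   and `counts` (tibble of per-class counts in each partition).
#' @export
partition_by_sd <- function(leaders, motifs = sd_motifs(), window = 20L) {
  ann <- scan_sd(leaders, motifs, window)
  with_sd <- ann[ann$has_sd, , drop = FALSE]
  without_sd <- ann[!ann$has_sd, , drop = FALSE]
  counts <- if ("label" %in% names(ann) && nrow(ann) > 0) {
    ann %>%
      group_by(.data$label, .data$has_sd) %>%
      summarise(n = n(), .groups = "drop")
  } else {
    tibble(has_sd = c(TRUE, FALSE), n = c(nrow(with_sd), nrow(without_sd)))
  }
  list(with_sd = with_sd, without_sd = without_sd, counts = counts)
}

#' Build a balanced dataset by per-class subsampling
#'
#' Samples `n_per_class` members uniformly without replacement from every
#' class; deterministic under `seed`.
#'
#' @param leaders Labelled leader tibble.
#' @param n_per_class Sample size per class.
#' @param seed Integer seed.
#' @param label_col Name of the class column (default `"label"`).
#' @return Shuffled balanced tibble.
#' @export
balance_classes <- function(leaders, n_per_class, seed = 1L,
                            label_col = "label") {
  if (!label_col %in% names(leaders)) {
    abort(paste0("no column `", label_col, "` in `leaders`"))
  }
  labs <- leaders[[label_col]]
  sizes <- table(labs)
  if (any(sizes < n_per_class)) {
    small <- names(sizes)[sizes < n_per_class][1]
    abort(paste0("class '", small, "' has only ", sizes[small],
                 " members; ", n_per_class, " requested"))
  }
  withr::with_seed(seed, {
    keep <- unlist(lapply(names(sizes), function(lab) {
      idx <- which(labs == lab)
      sample(idx, n_per_class)
    }))
    leaders[sample(keep), , drop = FALSE]
  })
}

#' Remove the proximal end of every leader
#'
#' Deletes the `remove` 3'-most nucleotides (positions -1..-remove), e.g.
#' turning 300-nt leaders into 270-nt leaders spanning -30..-300. Provenance
#' and labels are retained.
#'
#' @param leaders Leader tibble.
#' @param remove Number of proximal nucleotides to delete (default 30).
#' @return Tibble of truncated leaders.
#' @export
truncate_leaders <- function(leaders, remove = 30L) {
  assert_leader_tbl(leaders)
  lens <- nchar(leaders$sequence)
  if (any(remove >= lens)) {
    abort(paste0("remove (", remove, ") must be smaller than the leader length"))
  }
  leaders$sequence <- substr(leaders$sequence, 1L, lens - remove)
  leaders
}

#' Construct hybrid leaders by fusing proximal and distal donors
#'
#' The output takes its `junction` 3'-most nucleotides (positions
#' -1..-junction) from the proximal donor and the remainder (positions
#' -(junction+1)..-L) from the distal donor — the construct proposed for
#' combining algae-specific proximal regions with plant-origin distal
#' sequence. Both tables are matched row by row and must carry sequences of
#' equal length.
#'
#' @param proximal_donor,distal_donor Leader tibbles of equal row count and
#'   sequence length.
#' @param junction Fusion point in nt upstream of the start codon (default 30).
#' @return Tibble of hybrid leaders; `provenance` records both donors.
#' @export
make_hybrid <- function(proximal_donor, distal_donor, junction = 30L) {
  assert_leader_tbl(proximal_donor)
  assert_leader_tbl(distal_donor)
  if (nrow(proximal_donor) != nrow(distal_donor)) {
    abort("donor tables must have the same number of rows")
  }
  lp <- nchar(proximal_donor$sequence)
  ld <- nchar(distal_donor$sequence)
  if (any(lp != ld)) abort("donor sequences must have identical lengths")
  if (any(junction > lp)) abort("junction exceeds donor length")
  L <- lp
  hybrid <- paste0(
    substr(distal_donor$sequence, 1L, L - junction),
    substr(proximal_donor$sequence, L - junction + 1L, L)
  )
  tibble(
    id = paste0("hybrid_", proximal_donor$id, "_", distal_donor$id),
    sequence = hybrid,
    label = if ("label" %in% names(proximal_donor)) proximal_donor$label else NA_character_,
    provenance = paste0("proximal=", proximal_donor$id, ";distal=", distal_donor$id)
  )
}

#' Harvest misclassified leaders, stratified by SD status
#'
#' For every ordered pair of classes, collects the leaders of the true class
#' that the model predicted as the other class, and annotates each with
#' [scan_sd()] — the per-dataset breakdown of misclassified outputs into
#' with-SD / without-SD counts.
#'
#' @param predictions Character/factor vector of predicted class labels.
#' @param true_labels Character/factor vector of true labels, same length.
#' @param leaders Leader tibble aligned with the two vectors.
#' @inheritParams scan_sd
#' @return List with `misclassified` (annotated tibble with `true_label` and
#'   `predicted_label`) and `summary` (per class-pair counts with SD
#'   breakdown).
#' @export
harvest_misclassified <- function(predictions, true_labels, leaders,
                                  motifs = sd_motifs(), window = 20L) {
  assert_leader_tbl(leaders)
  predictions <- as.character(predictions)
  true_labels <- as.character(true_labels)
  if (length(predictions) != nrow(leaders) ||
      length(true_labels) != nrow(leaders)) {
    abort("`predictions`, `true_labels` and `leaders` must be aligned")
  }
  wrong <- which(predictions != true_labels)
  mis <- leaders[wrong, , drop = FALSE]
  mis$true_label <- true_labels[wrong]
  mis$predicted_label <- predictions[wrong]
  mis <- scan_sd(mis, motifs, window)
  summary <- if (nrow(mis) > 0) {
    mis %>%
      group_by(.data$true_label, .data$predicted_label) %>%
      summarise(
        total = n(),
        with_sd = sum(.data$has_sd),
        without_sd = sum(!.data$has_sd),
        .groups = "drop"
      )
  } else {
    tibble(
      true_label = character(), predicted_label = character(),
      total = integer(), with_sd = integer(), without_sd = integer()
    )
  }
  list(misclassified = mis, summary = summary)
}
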