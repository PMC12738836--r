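# Synthetic leader-sequence generator with planted-motif ground truth.
#
# The generator emulates the summary statistics of chloroplast leader corpora:
# ~70% AT content, oligo-A/oligo-T tracts, optional Shine-Dalgarno motifs
# restricted to the proximal -1..-20 window, and class-discriminative motifs
# planted in declared windows. Ground truth (what was planted where) travels
# with the dataset so interpretability methods can be scored against it.

CANONICAL_SD <- "AGGAGG"
SD_PLANT_WINDOW <- c(-20L, -1L)

#' Specify a synthetic leader dataset
#'
#' Builds the specification object consumed by [generate_leaders()]. The
#' background model draws bases i.i.d. per position with
#' P(A) = P(T) = `at_fraction / 2` and P(C) = P(G) = `(1 - at_fraction) / 2`;
#' oligo-A/oligo-T tracts and motifs are planted on top of that background.
#'
#' @param n_per_class Number of sequences generated for every class.
#' @param length Leader length in nt (default 300).
#' @param at_fraction Expected A+T fraction of the background (default 0.70,
#'   the typical AT content of plastid leader corpora).
#' @param class_motifs Named list, one element per class label. Each element is
#'   a list with fields `motif` (string over A/C/G/T, may be `NULL` for a
#'   motif-free class), `window` (length-2 integer vector `c(lo, hi)` of
#'   upstream positions; the planted motif must lie entirely within it) and
#'   `prob` (planting probability, default 1). A class's declared motif is
#'   guaranteed absent from every other class's sequences (spurious occurrences
#'   are resampled) so class labels are exact.
#' @param sd_planting_rate Probability that the canonical Shine-Dalgarno motif
#'   `AGGAGG` is planted inside the proximal -1..-20 window. Sequences not
#'   selected for planting are resampled until that window is free of every
#'   motif in [sd_motifs()], so the planted fraction is exact.
#' @param oligo_tract_rate Expected number of oligo-A/oligo-T tracts (length
#'   6-12 nt) planted per sequence (Poisson-distributed count).
#' @param seed Integer seed; generation is a pure function of the spec.
#' @return An object of class `synthetic_spec`.
#' @seealso [generate_leaders()], [plant_motif()]
#' @export
synthetic_spec <- function(n_per_class,
                           length = 300L,
                           at_fraction = 0.70,
                           class_motifs = list(
                             class_a = list(motif = NULL, window = NULL, prob = 0),
                             class_b = list(motif = NULL, window = NULL, prob = 0)
                           ),
                           sd_planting_rate = 0,
                           oligo_tract_rate = 0,
                           seed = 1L) {
  stopifnot(
    n_per_class >= 1, length >= 1,
    at_fraction >= 0, at_fraction <= 1,
    sd_planting_rate >= 0, sd_planting_rate <= 1,
    oligo_tract_rate >= 0
  )
  if (is.null(names(class_motifs)) || any(names(class_motifs) == "")) {
    abort("`class_motifs` must be a named list (names are the class labels)")
  }
  for (lab in names(class_motifs)) {
    cm <- class_motifs[[lab]]
    if (is.null(cm$motif)) next
    check_alphabet(cm$motif, allow_n = FALSE)
    if (is.null(cm$window)) {
      abort(paste0("class '", lab, "': motif '", cm$motif, "' needs a window"))
    }
    w <- as.integer(cm$window)
    if (w[1] > w[2] || w[2] > -1L || w[1] < -length) {
      abort(paste0("class '", lab, "': window must lie within [-", length, ", -1]"))
    }
    if (nchar(cm$motif) > w[2] - w[1] + 1L) {
      abort(paste0(
        "window too small for motif '", cm$motif, "' in class '", lab, "'"
      ))
    }
    prob <- if (is.null(cm$prob)) 1 else cm$prob
    stopifnot(prob >= 0, prob <= 1)
    class_motifs[[lab]]$prob <- prob
  }
  structure(
    list(
      n_per_class = as.integer(n_per_class), length = as.integer(length),
      at_fraction = at_fraction, class_motifs = class_motifs,
      sd_planting_rate = sd_planting_rate, oligo_tract_rate = oligo_tract_rate,
      seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

# one i.i.d. background sequence as a character vector of bases
random_background <- function(length, at_fraction) {
  p <- c(at_fraction / 2, (1 - at_fraction) / 2,
         (1 - at_fraction) / 2, at_fraction / 2)
  sample(DNA_BASES, length, replace = TRUE, prob = p)
}

plant_tracts <- function(bases, rate) {
  n_tracts <- rpois(1, rate)
  if (n_tracts == 0) return(bases)
  L <- length(bases)
  for (i in seq_len(n_tracts)) {
    len <- sample(6:12, 1)
    if (len > L) next
    start <- sample.int(L - len + 1L, 1)
    bases[start:(start + len - 1L)] <- sample(c("A", "T"), 1)
  }
  bases
}

#' Plant a motif at a uniform position inside an upstream window
#'
#' Overwrites a uniformly chosen placement of `motif` wholly inside the window
#' `c(lo, hi)` of upstream positions. The returned string differs from the
#' input only at the placement; attributes `motif_start` / `motif_end` record
#' the placement in the -k convention.
#'
#' @param sequence A single nucleotide string.
#' @param motif Motif string over A/C/G/T; an empty motif returns the input
#'   unchanged.
#' @param window Length-2 integer vector `c(lo, hi)` of upstream positions
#'   (e.g. `c(-20, -1)`); the motif must fit entirely within it.
#' @param seed Optional integer seed for the placement draw.
#' @return The modified sequence with placement attributes.
#' @export
#' @examples
#' s <- plant_motif(strrep("A", 50), "AGGAGG", c(-20, -1), seed = 1)
#' attr(s, "motif_start")
plant_motif <- function(sequence, motif, window, seed = NULL) {
  stopifnot(length(sequence) == 1)
  if (is.null(motif) || nchar(motif) == 0) return(sequence)
  L <- nchar(sequence)
  w <- as.integer(window)
  span <- w[2] - w[1] + 1L
  if (nchar(motif) > span) {
    abort(paste0("motif '", motif, "' (", nchar(motif),
                 " nt) does not fit in a ", span, "-nt window"))
  }
  draw <- function() {
    # legal upstream start positions for the motif 5' end
    starts <- w[1]:(w[2] - nchar(motif) + 1L)
    starts[sample.int(length(starts), 1)]
  }
  start_up <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  i <- upstream_to_index(start_up, L)
  out <- paste0(
    substr(sequence, 1, i - 1L), motif,
    substr(sequence, i + nchar(motif), L)
  )
  attr(out, "motif_start") <- start_up
  attr(out, "motif_end") <- start_up + nchar(motif) - 1L
  out
}

# TRUE when any of `motifs` occurs in `bases` (character vector) anywhere
contains_motif <- function(seq_string, motifs) {
  any(vapply(motifs, function(m) grepl(m, seq_string, fixed = TRUE), logical(1)))
}

# TRUE when any SD motif lies fully inside the proximal window
window_has_sd <- function(seq_string, window = 20L) {
  L <- nchar(seq_string)
  tail_seq <- substr(seq_string, L - window + 1L, L)
  contains_motif(tail_seq, sd_motifs())
}

#' Generate a labelled synthetic leader dataset
#'
#' Draws `n_per_class` background sequences per class, plants oligo-tracts,
#' class motifs and (optionally) Shine-Dalgarno motifs, and returns a tibble of
#' leaders. Generation is a pure function of `spec$seed`: identical specs give
#' byte-identical output. The planted ground truth is attached as attribute
#' `"ground_truth"` and retrievable with [ground_truth()].
#'
#' Two collision rules keep class labels exact: a sequence of one class is
#' resampled (up to 100 times) if another class's declared motif occurs
#' anywhere in it, and a sequence not selected for SD planting is resampled
#' until its -1..-20 window is free of every SD motif.
#'
#' @param spec A [synthetic_spec()] object.
#' @return A tibble with columns `id`, `sequence`, `label`, `provenance`, and
#'   attribute `ground_truth` (tibble: `id`, `label`, `element`, `motif`,
#'   `start`, `end` in the -k convention).
#' @export
generate_leaders <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  labels <- names(spec$class_motifs)
  other_motifs <- lapply(labels, function(lab) {
    ms <- unlist(lapply(spec$class_motifs[setdiff(labels, lab)], `[[`, "motif"))
    own <- spec$class_motifs[[lab]]$motif
    setdiff(ms, own)
  })
  names(other_motifs) <- labels

  withr::with_seed(spec$seed, {
    rows <- list()
    gt <- list()
    for (lab in labels) {
      cm <- spec$class_motifs[[lab]]
      for (j in seq_len(spec$n_per_class)) {
        id <- paste0(lab, "_", j)
        plant_class <- !is.null(cm$motif) && runif(1) < cm$prob
        plant_sd <- spec$sd_planting_rate > 0 && runif(1) < spec$sd_planting_rate
        ok <- FALSE
        for (attempt in seq_len(100L)) {
          bases <- random_background(spec$length, spec$at_fraction)
          bases <- plant_tracts(bases, spec$oligo_tract_rate)
          s <- paste(bases, collapse = "")
          if (length(other_motifs[[lab]]) > 0 &&
              contains_motif(s, other_motifs[[lab]])) next
          if (!is.null(cm$motif) && !plant_class &&
              contains_motif(s, cm$motif)) next
          if (spec$sd_planting_rate > 0 && !plant_sd && window_has_sd(s)) next
          ok <- TRUE
          break
        }
        if (!ok) {
          abort(paste0(
            "could not draw a collision-free background for '", id,
            "' in 100 attempts"
          ))
        }
        if (plant_class) {
          s <- plant_motif(s, cm$motif, cm$window)
          gt[[length(gt) + 1L]] <- tibble(
            id = id, label = lab, element = "class_motif", motif = cm$motif,
            start = attr(s, "motif_start"), end = attr(s, "motif_end")
          )
        }
        if (plant_sd) {
          s <- plant_motif(s, CANONICAL_SD, SD_PLANT_WINDOW)
          gt[[length(gt) + 1L]] <- tibble(
            id = id, label = lab, element = "sd", motif = CANONICAL_SD,
            start = attr(s, "motif_start"), end = attr(s, "motif_end")
          )
        }
        rows[[length(rows) + 1L]] <- tibble(
          id = id, sequence = as.character(s), label = lab,
          provenance = "synthetic"
        )
      }
    }
    out <- bind_rows(rows)
    gt_tbl <- if (length(gt) > 0) {
      bind_rows(gt)
    } else {
      tibble(
        id = character(), label = character(), element = character(),
        motif = character(), start = integer(), end = integer()
      )
    }
    attr(out, "ground_truth") <- gt_tbl
    attr(out, "synthetic_spec") <- spec
    out
  })
}

#' Retrieve planted-motif ground truth from a synthetic dataset
#'
#' @param leaders A tibble produced by [generate_leaders()].
#' @return Tibble of planted elements (`id`, `label`, `element`, `motif`,
#'   `start`, `end`; positions in the -k convention).
#' @export
ground_truth <- function(leaders) {
  gt <- attr(leaders, "ground_truth")
  if (is.null(gt)) abort("no ground-truth attribute; was this generated by generate_leaders()?")
  gt
}
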