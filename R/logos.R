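# Position-frequency matrices, sequence logos and k-mer abundance for leader
# regions (default region: the proximal -1..-30 window).

parse_region <- function(region) {
  region <- as.integer(region)
  stopifnot(length(region) == 2)
  lo <- min(region); hi <- max(region)
  if (hi > -1L) abort("region positions must be negative (-k convention)")
  c(lo, hi)
}

#' Build a position-frequency matrix over an upstream region
#'
#' Per-position base counts and fractions over {A,C,G,T} within the region
#' (positions in the -k convention). N bases are excluded from the
#' denominators and tracked as a separate per-position N-fraction. Information
#' content is Shannon-style: 2 - entropy in bits, in [0, 2].
#'
#' @param leaders Leader tibble; every sequence must cover the region.
#' @param region Length-2 vector of upstream positions, default `c(-30, -1)`.
#' @return A `pfm` object: `positions` (upstream coordinates, 5' to 3'),
#'   `counts` (4 x width), `frequencies`, `information` (bits), `n_fraction`,
#'   `n_sequences`.
#' @export
build_pfm <- function(leaders, region = c(-30L, -1L)) {
  assert_leader_tbl(leaders)
  reg <- parse_region(region)
  seqs <- toupper(leaders$sequence)
  lens <- nchar(seqs)
  if (any(lens < -reg[1])) {
    abort(paste0("region extends to ", reg[1], " but shortest leader is ",
                 min(lens), " nt"))
  }
  positions <- reg[1]:reg[2]
  width <- length(positions)
  sub <- substr(seqs, lens + reg[1] + 1L, lens + reg[2] + 1L)
  mat <- matrix(unlist(strsplit(sub, ""), use.names = FALSE), nrow = width)
  counts <- matrix(0L, 4, width, dimnames = list(DNA_BASES, NULL))
  for (b in DNA_BASES) counts[b, ] <- rowSums(matrix(mat == b, width))
  n_count <- rowSums(matrix(mat == "N", width))
  denom <- pmax(colSums(counts), 1L)
  freq <- sweep(counts, 2, denom, "/")
  ent <- apply(freq, 2, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  info <- ifelse(colSums(counts) > 0, 2 - ent, 0)
  structure(
    list(
      positions = positions, counts = counts, frequencies = freq,
      information = as.numeric(info),
      n_fraction = as.numeric(n_count) / length(seqs),
      n_sequences = length(seqs), region = reg
    ),
    class = "pfm"
  )
}

#' @export
print.pfm <- function(x, ...) {
  cat("<pfm> region ", x$region[1], "..", x$region[2], ", ",
      x$n_sequences, " sequences\n", sep = "")
  invisible(x)
}

#' @describeIn build_pfm Long tibble (`position`, `base`, `count`,
#'   `frequency`, `information`).
#' @param x A `pfm`.
#' @param ... Unused.
#' @export
tidy.pfm <- function(x, ...) {
  w <- length(x$positions)
  tibble(
    position = rep(x$positions, each = 4),
    base = rep(DNA_BASES, w),
    count = as.vector(x$counts),
    frequency = as.vector(x$frequencies),
    information = rep(x$information, each = 4)
  )
}

#' Overlapping k-mer abundance within an upstream region
#'
#' Counts every overlapping k-nt window inside the region, aggregated over
#' sequences; windows containing N are skipped. The table is ranked by
#' descending count with lexicographic tie-break.
#'
#' @param leaders Leader tibble.
#' @param k Word size (default 6).
#' @param region Upstream region, default `c(-30, -1)`.
#' @return Tibble (`kmer`, `count`, `frequency`) where `frequency` is the
#'   count divided by the number of counted (N-free) windows.
#' @export
kmer_abundance <- function(leaders, k = 6L, region = c(-30L, -1L)) {
  assert_leader_tbl(leaders)
  reg <- parse_region(region)
  span <- reg[2] - reg[1] + 1L
  if (k > span) abort(paste0("k (", k, ") exceeds region span (", span, ")"))
  seqs <- toupper(leaders$sequence)
  lens <- nchar(seqs)
  if (any(lens < -reg[1])) abort("region outside leader length")
  sub <- substr(seqs, lens + reg[1] + 1L, lens + reg[2] + 1L)
  starts <- seq_len(span - k + 1L)
  words <- unlist(lapply(sub, function(s) {
    substring(s, starts, starts + k - 1L)
  }), use.names = FALSE)
  words <- words[!grepl("N", words, fixed = TRUE)]
  if (length(words) == 0) {
    return(tibble(kmer = character(), count = integer(), frequency = numeric()))
  }
  tab <- table(words)
  out <- tibble(
    kmer = names(tab), count = as.integer(tab),
    frequency = as.integer(tab) / length(words)
  )
  out[order(-out$count, out$kmer), ]
}

#' Render a sequence logo and export its matrix
#'
#' Letter stack heights follow the classic information-content convention
#' (fraction x per-position information, in bits) or plain base fractions.
#' The numeric matrix is the authoritative output; [export_logo()] writes it
#' as TSV next to an optional image.
#'
#' @param pfm A [build_pfm()] result.
#' @param scale `"information"` (default) or `"frequency"`.
#' @return A ggplot object.
#' @export
plot_logo <- function(pfm, scale = c("information", "frequency")) {
  scale <- match.arg(scale)
  td <- tidy(pfm)
  td$height <- if (scale == "information") {
    td$frequency * td$information
  } else {
    td$frequency
  }
  td <- td %>%
    group_by(.data$position) %>%
    arrange(.data$height, .by_group = TRUE) %>%
    mutate(ymax = cumsum(.data$height), ymin = .data$ymax - .data$height,
           ymid = (.data$ymin + .data$ymax) / 2) %>%
    ungroup()
  base_cols <- c(A = "#109648", C = "#255C99", G = "#F7B32B", T = "#D62839")
  ggplot2::ggplot(td, ggplot2::aes(x = .data$position)) +
    ggplot2::geom_rect(
      ggplot2::aes(
        xmin = .data$position - 0.45, xmax = .data$position + 0.45,
        ymin = .data$ymin, ymax = .data$ymax, fill = .data$base
      ),
      alpha = 0.25
    ) +
    ggplot2::geom_text(
      data = td[td$height > 0.01, ],
      ggplot2::aes(y = .data$ymid, label = .data$base, colour = .data$base,
                   size = .data$height),
      fontface = "bold", show.legend = FALSE
    ) +
    ggplot2::scale_size_continuous(range = c(1.5, 6)) +
    ggplot2::scale_fill_manual(values = base_cols) +
    ggplot2::scale_colour_manual(values = base_cols) +
    ggplot2::labs(
      x = "position upstream of start codon",
      y = if (scale == "information") "bits" else "fraction",
      fill = "base"
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_logo Write the PFM as TSV (and optionally the logo image).
#' @param matrix_path Output TSV path for the per-position matrix.
#' @param image_path Optional image path (written with [ggplot2::ggsave()]).
#' @param ... Passed to [plot_logo()].
#' @export
export_logo <- function(pfm, matrix_path, image_path = NULL, ...) {
  td <- tidy(pfm)
  write.table(as.data.frame(td), matrix_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(image_path)) {
    ggplot2::ggsave(image_path, plot_logo(pfm, ...), width = 8, height = 3)
  }
  invisible(pfm)
}

#' Re-read an exported PFM matrix
#'
#' Round-trip companion to [export_logo()].
#'
#' @param matrix_path TSV written by [export_logo()].
#' @return Tibble in the layout of `tidy(pfm)`.
#' @export
read_logo_matrix <- function(matrix_path) {
  as_tibble(read.table(matrix_path, sep = "\t", header = TRUE,
                       stringsAsFactors = FALSE))
}
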