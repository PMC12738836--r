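# Leader extraction from annotated chloroplast genome records.

#' Create a genome record
#'
#' Container for one (chloro)plast genome: sequence plus CDS feature table.
#' Coordinates are 1-based inclusive on the forward strand (GenBank
#' convention). Ambiguity codes other than N are mapped to N with a warning.
#'
#' @param accession Identifier string.
#' @param sequence Nucleotide string.
#' @param features Tibble with columns `gene_id`, `start`, `end`, `strand`
#'   (`"+"` or `"-"`).
#' @param circular Is the molecule circular? Upstream windows then wrap around
#'   the origin.
#' @return An object of class `genome_record`.
#' @export
genome_record <- function(accession, sequence, features, circular = FALSE) {
  sequence <- normalise_ambiguity(sequence)
  check_alphabet(sequence)
  if (nchar(sequence) < 1) abort("genome sequence is empty")
  features <- as_tibble(features)
  need <- c("gene_id", "start", "end", "strand")
  if (!all(need %in% names(features))) {
    abort(paste0("features must have columns: ", paste(need, collapse = ", ")))
  }
  L <- nchar(sequence)
  bad <- features$start < 1 | features$end > L | features$start > features$end
  if (any(bad)) {
    abort(paste0("feature coordinates outside genome: ",
                 features$gene_id[bad][1]))
  }
  if (!all(features$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  structure(
    list(accession = accession, sequence = sequence, features = features,
         circular = isTRUE(circular)),
    class = "genome_record"
  )
}

#' Filter genome records by minimum length
#'
#' Keeps exactly the records whose sequence length is at least `min_length`
#' (default 5 kb, the conventional inclusion threshold for partial plastomes),
#' preserving order.
#'
#' @param records List of [genome_record()] objects.
#' @param min_length Minimum genome length in nt.
#' @return Filtered list.
#' @export
filter_genomes <- function(records, min_length = 5000L) {
  keep <- vapply(records, function(r) nchar(r$sequence) >= min_length, logical(1))
  records[keep]
}

reverse_complement <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# substring with optional circular wrap; positions may run outside 1..L
genome_substring <- function(sequence, from, to, circular) {
  L <- nchar(sequence)
  idx <- from:to
  if (circular) idx <- ((idx - 1L) %% L) + 1L
  if (any(idx < 1L | idx > L)) return(NULL)
  paste(strsplit(sequence, "")[[1]][idx], collapse = "")
}

#' Extract the upstream leader of one CDS feature
#'
#' Returns the `length`-nt window immediately 5' of the start codon, read
#' 5'->3' on the coding strand, so the final character of the leader is the
#' base at position -1. For `-` strand features this is the reverse complement
#' of `[end+1, end+length]`. Features with fewer than `length` upstream bases
#' are skipped (`NULL`) under the default policy, or N-left-padded when
#' `pad = TRUE`; circular genomes wrap around the origin instead.
#'
#' @param record A [genome_record()].
#' @param cds One row of `record$features` (or a gene_id string).
#' @param length Leader length in nt (default 300).
#' @param pad Pad short upstream regions with 5' Ns instead of skipping.
#' @return A one-row leader tibble, or `NULL` (skip-signal).
#' @export
extract_leader <- function(record, cds, length = 300L, pad = FALSE) {
  stopifnot(inherits(record, "genome_record"))
  if (is.character(cds)) {
    cds <- record$features[record$features$gene_id == cds, , drop = FALSE]
    if (nrow(cds) == 0) abort("gene_id not found in record features")
    cds <- cds[1, ]
  }
  L <- nchar(record$sequence)
  if (cds$start < 1 || cds$end > L) abort("CDS coordinates outside genome")
  if (cds$strand == "+") {
    from <- cds$start - length
    to <- cds$start - 1L
    if (from >= 1L) {
      raw <- substr(record$sequence, from, to)
    } else if (record$circular) {
      raw <- genome_substring(record$sequence, from, to, TRUE)
    } else if (pad) {
      raw <- paste0(strrep("N", 1L - from), substr(record$sequence, 1L, to))
    } else {
      return(NULL)
    }
    leader <- raw
  } else {
    from <- cds$end + 1L
    to <- cds$end + length
    if (to <= L) {
      raw <- substr(record$sequence, from, to)
    } else if (record$circular) {
      raw <- genome_substring(record$sequence, from, to, TRUE)
    } else if (pad) {
      raw <- paste0(substr(record$sequence, from, L), strrep("N", to - L))
    } else {
      return(NULL)
    }
    leader <- reverse_complement(raw)
  }
  tibble(
    id = paste0(record$accession, "|", cds$gene_id),
    sequence = leader,
    label = NA_character_,
    provenance = paste0(record$accession, ":", cds$gene_id)
  )
}

#' Extract leaders for every CDS of one or several genome records
#'
#' @param records A [genome_record()] or list of them.
#' @param length Leader length in nt.
#' @param label Optional class label assigned to every extracted leader.
#' @param pad See [extract_leader()].
#' @return Leader tibble (skipped features omitted).
#' @export
extract_leaders <- function(records, length = 300L, label = NA_character_,
                            pad = FALSE) {
  if (inherits(records, "genome_record")) records <- list(records)
  rows <- list()
  for (rec in records) {
    for (i in seq_len(nrow(rec$features))) {
      lead <- extract_leader(rec, rec$features[i, ], length = length, pad = pad)
      if (!is.null(lead)) rows[[length(rows) + 1L]] <- lead
    }
  }
  out <- if (length(rows) > 0) bind_rows(rows) else {
    tibble(id = character(), sequence = character(),
           label = character(), provenance = character())
  }
  out$label <- label
  out
}

#' Remove exact duplicate leader sequences
#'
#' Exact-string duplicates are dropped, keeping the first occurrence and
#' otherwise preserving order. Deduplication is applied within each class,
#' never across classes (identical sequences carrying different labels both
#' survive).
#'
#' @param leaders Leader tibble.
#' @return Deduplicated tibble.
#' @export
deduplicate_leaders <- function(leaders) {
  assert_leader_tbl(leaders)
  if (nrow(leaders) == 0) return(leaders)
  key <- if ("label" %in% names(leaders)) {
    paste0(leaders$label, "\r", leaders$sequence)
  } else {
    leaders$sequence
  }
  leaders[!duplicated(key), , drop = FALSE]
}

#' Read genome records from FASTA plus GFF3 annotation
#'
#' Loads genome sequences with Biostrings and CDS features with rtracklayer,
#' producing one [genome_record()] per FASTA entry that carries at least one
#' CDS feature.
#'
#' @param fasta Path to a (multi-)FASTA genome file.
#' @param gff Path to a GFF3 file; only features of type `CDS` are used. For
#'   multi-segment CDS groups (same ID), only the first segment is kept.
#' @param circular Logical, recycled over records.
#' @return List of `genome_record` objects.
#' @export
read_genomes <- function(fasta, gff, circular = FALSE) {
  if (!requireNamespace("Biostrings", quietly = TRUE) ||
      !requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("read_genomes() needs the Biostrings and rtracklayer packages")
  }
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  gr <- rtracklayer::import(gff)
  gr <- gr[gr$type == "CDS"]
  circular <- rep_len(circular, length(seqs))
  records <- list()
  for (i in seq_along(seqs)) {
    acc <- names(seqs)[i]
    sub <- gr[as.character(GenomicRanges::seqnames(gr)) == acc]
    if (length(sub) == 0) next
    ids <- if (!is.null(sub$ID)) as.character(sub$ID) else
      paste0("cds", seq_along(sub))
    ids[is.na(ids)] <- paste0("cds", which(is.na(ids)))
    first <- !duplicated(ids) # first segment only for multi-segment CDS
    sub <- sub[first]
    feats <- tibble(
      gene_id = ids[first],
      start = GenomicRanges::start(sub),
      end = GenomicRanges::end(sub),
      strand = as.character(GenomicRanges::strand(sub))
    )
    feats$strand[!feats$strand %in% c("+", "-")] <- "+"
    records[[length(records) + 1L]] <- genome_record(
      acc, as.character(seqs[[i]]), feats, circular = circular[i]
    )
  }
  records
}

#' Write leaders to FASTA with a TSV label table
#'
#' Headers carry `id` and `label`; the sidecar TSV records id, label and
#' provenance (plus planted ground truth for synthetic data).
#'
#' @param leaders Leader tibble.
#' @param fasta Output FASTA path.
#' @param tsv Optional output TSV path.
#' @param spec_json Optional path; when the table was made by
#'   [generate_leaders()], its generating spec is written there as JSON.
#' @return `leaders`, invisibly.
#' @export
write_leaders <- function(leaders, fasta, tsv = NULL, spec_json = NULL) {
  assert_leader_tbl(leaders)
  label <- if ("label" %in% names(leaders)) leaders$label else NA
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::DNAStringSet(leaders$sequence)
    names(x) <- paste0(leaders$id, " label=", label)
    Biostrings::writeXStringSet(x, fasta)
  } else {
    writeLines(
      as.vector(rbind(paste0(">", leaders$id, " label=", label),
                      leaders$sequence)),
      fasta
    )
  }
  if (!is.null(tsv)) {
    tab <- leaders[, intersect(c("id", "label", "provenance"), names(leaders))]
    gt <- attr(leaders, "ground_truth")
    if (!is.null(gt) && nrow(gt) > 0) {
      tab <- dplyr::left_join(
        tab, gt[, c("id", "motif", "start", "end")], by = "id"
      )
    }
    write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(spec_json)) {
    spec <- attr(leaders, "synthetic_spec")
    if (is.null(spec)) abort("no synthetic spec attached to these leaders")
    jsonlite::write_json(unclass(spec), spec_json, auto_unbox = TRUE,
                         null = "null")
  }
  invisible(leaders)
}

#' Read leaders from FASTA (with optional label table)
#'
#' @param fasta FASTA path; if headers carry `label=...` tokens they are used.
#' @param tsv Optional TSV with columns `id` and `label`, overriding headers.
#' @return Leader tibble.
#' @export
read_leaders <- function(fasta, tsv = NULL) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::readDNAStringSet(fasta)
    headers <- names(x)
    seqs <- unname(as.character(x))
  } else {
    lines <- readLines(fasta)
    hdr_idx <- grep("^>", lines)
    headers <- sub("^>", "", lines[hdr_idx])
    bounds <- c(hdr_idx, length(lines) + 1L)
    seqs <- vapply(seq_along(hdr_idx), function(i) {
      paste(lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)], collapse = "")
    }, character(1))
  }
  ids <- sub("\\s.*$", "", headers)
  label <- ifelse(
    grepl("label=", headers),
    sub("^.*label=(\\S+).*$", "\\1", headers),
    NA_character_
  )
  out <- tibble(
    id = ids, sequence = normalise_ambiguity(seqs),
    label = label, provenance = fasta
  )
  if (!is.null(tsv)) {
    tab <- read.table(tsv, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
    out$label <- tab$label[match(out$id, tab$id)]
  }
  out
}
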