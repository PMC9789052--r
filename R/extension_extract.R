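#' Extract theoretical N-terminal extensions
#'
#' For each transcript with a complete, AUG-initiated CDS, walks upstream
#' from the annotated start codon in steps of three nucleotides until an
#' in-frame stop codon (TAA/TAG/TGA) is reached; the extension starts one
#' codon 3' of that stop (`boundary = "stop_bounded"`). If no in-frame stop
#' exists, the extension starts at the 5'-most complete in-frame codon
#' (`boundary = "edge_bounded"`; a sub-codon 5' leftover is never part of a
#' codon). This maximal in-frame upstream region is the primary
#' (theoretical) extension. Codons containing N never match a stop codon.
#'
#' Transcripts failing the gates (incomplete CDS, annotated non-AUG start
#' unless `include_non_atg`) and transcripts with a zero-length extension
#' (stop codon immediately upstream of the start, or fewer than three
#' upstream nucleotides) are recorded in the `"dropped"` attribute with a
#' reason code rather than silently discarded.
#'
#' @param transcripts Tibble from [parse_transcript_fasta()].
#' @param include_non_atg Also extract for transcripts whose annotated CDS
#'   starts at a non-ATG codon? Default `FALSE`.
#' @return Tibble with columns `transcript_id`, `gene_id`, `ext_start`,
#'   `length_codons`, `boundary`, `cds_start`. Attribute `"dropped"`:
#'   tibble (`transcript_id`, `reason`).
#' @export
extract_extensions <- function(transcripts, include_non_atg = FALSE) {
  gate_reason <- rep(NA_character_, nrow(transcripts))
  gate_reason[has_flag(transcripts$flags, "cds_incomplete")] <- "cds_incomplete"
  if (!include_non_atg) {
    non_atg <- has_flag(transcripts$flags, "non_atg_annotated")
    gate_reason[is.na(gate_reason) & non_atg] <- "non_atg_annotated"
  }

  n <- nrow(transcripts)
  ext_start <- integer(n)
  boundary <- character(n)
  reason <- gate_reason
  for (i in seq_len(n)) {
    if (!is.na(reason[[i]])) next
    seq_i <- transcripts$sequence[[i]]
    cs <- transcripts$cds_start[[i]]
    res <- extension_walk(seq_i, cs)
    if (is.null(res)) {
      reason[[i]] <- "zero_length"
    } else {
      ext_start[[i]] <- res$ext_start
      boundary[[i]] <- res$boundary
    }
  }
  keep <- is.na(reason)
  out <- tibble(
    transcript_id = transcripts$transcript_id[keep],
    gene_id = transcripts$gene_id[keep],
    ext_start = ext_start[keep],
    length_codons = (transcripts$cds_start[keep] - ext_start[keep]) %/% 3L,
    boundary = boundary[keep],
    cds_start = transcripts$cds_start[keep]
  )
  attr(out, "dropped") <- tibble(
    transcript_id = transcripts$transcript_id[!keep],
    reason = reason[!keep]
  )
  out
}

# Core upstream walk for one transcript. Returns NULL for zero-length
# extensions.
extension_walk <- function(sequence, cds_start) {
  if (cds_start < 3L) return(NULL)
  n_up <- cds_start %/% 3L
  starts <- cds_start - 3L * seq_len(n_up)  # candidate codon starts, 3'->5'
  codons <- substring(sequence, starts + 1L, starts + 3L)
  stop_idx <- which(codons %in% STOP_CODONS)
  if (length(stop_idx) && stop_idx[[1L]] == 1L) return(NULL)
  if (length(stop_idx)) {
    list(ext_start = starts[[stop_idx[[1L]]]] + 3L, boundary = "stop_bounded")
  } else {
    list(ext_start = starts[[n_up]], boundary = "edge_bounded")
  }
}

#' Clip extensions to analysis windows
#'
#' The analysis window is the 3'-most `max_codons` codons of the theoretical
#' extension (the whole extension when shorter), abutting the annotated
#' start. The window sequence and, when exon structures are available, its
#' genomic blocks are populated.
#'
#' @param extensions Tibble from [extract_extensions()].
#' @param transcripts Transcript tibble (with `exons` if genomic blocks are
#'   wanted).
#' @param max_codons Window size in codons, default 50.
#' @return `extensions` with added `win_start`, `win_codons`, `win_seq` and
#'   list column `blocks` (genomic intervals; zero-row tibble when no
#'   usable structure).
#' @export
clip_windows <- function(extensions, transcripts, max_codons = 50L) {
  idx <- match(extensions$transcript_id, transcripts$transcript_id)
  win_codons <- pmin(extensions$length_codons, max_codons)
  win_start <- extensions$cds_start - 3L * win_codons
  win_seq <- substring(transcripts$sequence[idx], win_start + 1L,
                       extensions$cds_start)
  has_struct <- "exons" %in% names(transcripts)
  blocks <- vector("list", nrow(extensions))
  for (i in seq_along(blocks)) {
    j <- idx[[i]]
    usable <- has_struct && !is.null(transcripts$exons[[j]]) &&
      identical(transcripts$structure[[j]], "ok")
    blocks[[i]] <- if (usable) {
      map_to_genome(transcripts$exons[[j]], win_start[[i]], extensions$cds_start[[i]])
    } else {
      tibble(chrom = character(), start = integer(), end = integer(),
             strand = character())
    }
  }
  extensions$win_start <- win_start
  extensions$win_codons <- win_codons
  extensions$win_seq <- win_seq
  extensions$blocks <- blocks
  extensions
}

#' Filter extensions by minimum length
#'
#' Extensions shorter than `min_codons` (default 20) are discarded. The
#' decision for every input row is kept in the `"decisions"` attribute.
#'
#' @param extensions Extension tibble.
#' @param min_codons Minimum length in codons; an extension of exactly
#'   `min_codons` is kept.
#' @return The kept rows; attribute `"decisions"` is a tibble
#'   (`transcript_id`, `length_codons`, `keep`).
#' @export
filter_min_length <- function(extensions, min_codons = 20L) {
  keep <- extensions$length_codons >= min_codons
  out <- extensions[keep, , drop = FALSE]
  attr(out, "decisions") <- tibble(
    transcript_id = extensions$transcript_id,
    length_codons = extensions$length_codons,
    keep = keep
  )
  out
}

#' Drop windows overlapping annotated coding exons
#'
#' A window is excluded when any of its genomic blocks overlaps, by at least
#' one base and (by default) on the same strand, a coding exon from any
#' supplied annotation catalog — excluding the transcript's own CDS exons.
#' The first offending catalog and interval are reported per dropped window.
#'
#' @param windows Window tibble from [clip_windows()] (needs `blocks`).
#' @param coding_exons Tibble of coding exons: `chrom`, `start`, `end`,
#'   `strand`, `catalog`, `transcript_id` (owner, used for self-exemption).
#' @param same_strand Only count same-strand overlaps (default `TRUE`).
#' @return The kept windows. Attribute `"overlaps"`: tibble of dropped
#'   windows (`transcript_id`, `catalog`, `chrom`, `start`, `end`).
#' @export
filter_coding_overlap <- function(windows, coding_exons, same_strand = TRUE) {
  assert_cols(coding_exons, c("chrom", "start", "end", "strand", "catalog",
                              "transcript_id"))
  n <- nrow(windows)
  drop <- logical(n)
  offending <- vector("list", n)
  for (i in seq_len(n)) {
    blk <- windows$blocks[[i]]
    if (nrow(blk) == 0L) stop("no_structure: window ", windows$transcript_id[[i]],
                              " lacks genomic blocks", call. = FALSE)
    subj <- coding_exons[coding_exons$transcript_id != windows$transcript_id[[i]], ,
                         drop = FALSE]
    hits <- intersect_intervals(blk, subj, same_strand = same_strand)
    if (nrow(hits)) {
      drop[[i]] <- TRUE
      first <- hits[order(hits$query, subj$start[hits$subject]), ][1L, ]
      offending[[i]] <- tibble(
        transcript_id = windows$transcript_id[[i]],
        catalog = subj$catalog[[first$subject]],
        chrom = subj$chrom[[first$subject]],
        start = subj$start[[first$subject]],
        end = subj$end[[first$subject]]
      )
    }
  }
  out <- windows[!drop, , drop = FALSE]
  attr(out, "overlaps") <- bind_rows(offending)
  out
}

#' Collapse extensions to one representative per gene
#'
#' Keeps, per gene, the transcript with the longest theoretical extension;
#' ties are broken by the lexicographically smallest transcript id, so the
#' collapse is deterministic.
#'
#' @param extensions Extension tibble (any stage).
#' @return The per-gene representative rows.
#' @export
collapse_genes <- function(extensions) {
  extensions |>
    arrange(.data$gene_id, dplyr::desc(.data$length_codons), .data$transcript_id) |>
    group_by(.data$gene_id) |>
    slice(1L) |>
    ungroup()
}

#' Enumerate candidate start codons in extension windows
#'
#' Returns every in-frame occurrence of an allowed start codon within each
#' window, in 5'->3' order. The default palette is AUG plus the nine
#' near-cognate codons (CUG, GUG, UUG, AUA, AUU, AUC, ACG, AGG, AAG), DNA
#' spelling.
#'
#' @param windows Window tibble from [clip_windows()].
#' @param allowed Character vector of allowed codons (DNA alphabet).
#' @return Tibble `transcript_id`, `gene_id`, `position` (transcript
#'   coordinate of the codon's first base), `codon`, `codon_class`
#'   (`"AUG"` or `"near_cognate"`).
#' @export
enumerate_candidate_starts <- function(windows, allowed = START_PALETTE) {
  res <- purrr::pmap(
    list(windows$transcript_id, windows$gene_id, windows$win_start,
         windows$win_codons, windows$win_seq),
    function(tx, gene, ws, wc, seq) {
      cods <- codons_of(seq, 0L, wc)
      hit <- which(cods %in% allowed)
      if (!length(hit)) return(NULL)
      tibble(
        transcript_id = tx,
        gene_id = gene,
        position = ws + 3L * (hit - 1L),
        codon = cods[hit],
        codon_class = ifelse(cods[hit] == "ATG", "AUG", "near_cognate")
      )
    }
  )
  out <- bind_rows(res)
  if (nrow(out) == 0L) {
    out <- tibble(transcript_id = character(), gene_id = character(),
                  position = integer(), codon = character(),
                  codon_class = character())
  }
  out
}

#' Export extensions as TSV
#'
#' Transcript-coordinate export: one row per extension with the analysis
#' window sequence.
#' @param extensions Window tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_extensions_tsv <- function(extensions, path) {
  df <- extensions |>
    select(dplyr::any_of(c("transcript_id", "gene_id", "ext_start",
                           "length_codons", "boundary", "win_start",
                           "win_codons", "win_seq")))
  readr::write_tsv(df, path)
  invisible(path)
}
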