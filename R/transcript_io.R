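#' Parse a protein-coding transcript FASTA
#'
#' Reads spliced transcript sequences together with their CDS coordinates.
#' Two header dialects are supported: `"gencode_pc"`, the pipe-separated
#' protein-coding transcript header carrying a `CDS:u-v` field (1-based,
#' inclusive), and `"plain"`, bare identifiers with CDS coordinates supplied
#' in a sidecar TSV (`transcript_id`, `gene_id`, `cds_start`, `cds_end`,
#' 1-based inclusive).
#'
#' Coordinates are converted to the package-internal 0-based half-open
#' convention at this boundary. Records violating the transcript invariants
#' (missing CDS, CDS length not a multiple of three, CDS outside the
#' sequence) are skipped and reported, with a reason code, in the
#' `"skipped"` attribute of the returned tibble. Transcripts whose annotated
#' CDS does not begin with ATG are retained but flagged
#' `non_atg_annotated`; transcripts carrying `cds_start_NF`/`cds_end_NF`
#' tags are flagged `cds_incomplete`. Both flags gate extension extraction
#' downstream.
#'
#' @param fasta_path Path to the transcript FASTA file.
#' @param dialect Header dialect, `"gencode_pc"` (default) or `"plain"`.
#' @param sidecar_path For `dialect = "plain"`, path to the CDS sidecar TSV.
#'
#' @return A tibble with columns `transcript_id`, `gene_id`, `sequence`,
#'   `cds_start`, `cds_end`, `length` and `flags` (list column of character
#'   tags). Attribute `"skipped"` holds a tibble of skipped records
#'   (`transcript_id`, `reason`).
#' @export
parse_transcript_fasta <- function(fasta_path,
                                   dialect = c("gencode_pc", "plain"),
                                   sidecar_path = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(fasta_path)) {
    stop("cannot read FASTA file: ", fasta_path, call. = FALSE)
  }
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  headers <- names(seqs)
  sequence <- unname(toupper(as.character(seqs)))

  if (dialect == "gencode_pc") {
    fields <- strsplit(headers, "|", fixed = TRUE)
    transcript_id <- vapply(fields, `[[`, "", 1L)
    gene_id <- vapply(fields, function(f) if (length(f) >= 2L) f[[2L]] else NA_character_, "")
    cds_field <- vapply(fields, function(f) {
      hit <- grep("^CDS:[0-9]+-[0-9]+$", f, value = TRUE)
      if (length(hit)) hit[[1L]] else NA_character_
    }, "")
    u <- as.integer(sub("^CDS:([0-9]+)-[0-9]+$", "\\1", cds_field))
    v <- as.integer(sub("^CDS:[0-9]+-([0-9]+)$", "\\1", cds_field))
    nf <- vapply(fields, function(f) any(f %in% c("cds_start_NF", "cds_end_NF")), TRUE)
  } else {
    if (is.null(sidecar_path)) {
      stop("dialect 'plain' requires a sidecar_path", call. = FALSE)
    }
    side <- readr::read_tsv(sidecar_path, show_col_types = FALSE, comment = "#")
    assert_cols(side, c("transcript_id", "gene_id", "cds_start", "cds_end"), "sidecar")
    transcript_id <- sub("\\s.*$", "", headers)
    idx <- match(transcript_id, side$transcript_id)
    gene_id <- side$gene_id[idx]
    u <- as.integer(side$cds_start[idx])
    v <- as.integer(side$cds_end[idx])
    nf <- rep(FALSE, length(u))
  }

  # 1-based inclusive -> 0-based half-open
  cds_start <- u - 1L
  cds_end <- v
  len <- nchar(sequence)

  reason <- rep(NA_character_, length(sequence))
  reason[is.na(cds_start) | is.na(cds_end)] <- "no_cds"
  bad_range <- !is.na(cds_start) & !is.na(cds_end) &
    (cds_start < 0L | cds_start >= cds_end | cds_end > len)
  reason[bad_range] <- "bad_cds_range"
  bad_triplet <- is.na(reason) & ((cds_end - cds_start) %% 3L != 0L)
  reason[bad_triplet] <- "cds_not_triplet"

  keep <- is.na(reason)
  skipped <- tibble(transcript_id = transcript_id[!keep], reason = reason[!keep])

  out <- tibble(
    transcript_id = transcript_id[keep],
    gene_id = gene_id[keep],
    sequence = sequence[keep],
    cds_start = cds_start[keep],
    cds_end = cds_end[keep],
    length = len[keep]
  )
  start_codon <- substring(out$sequence, out$cds_start + 1L, out$cds_start + 3L)
  out$flags <- purrr::pmap(
    list(start_codon != "ATG", nf[keep]),
    function(non_atg, incomplete) {
      c(if (non_atg) "non_atg_annotated", if (incomplete) "cds_incomplete",
        if (!incomplete) "complete_cds")
    }
  )
  attr(out, "skipped") <- skipped
  out
}

has_flag <- function(flags, tag) {
  vapply(flags, function(f) tag %in% f, TRUE)
}

#' Attach genomic exon structures from a GTF file
#'
#' Populates each transcript with its ordered exon list from the GTF's
#' `exon` features. GTF coordinates (1-based inclusive) are converted to the
#' internal 0-based half-open convention. Exons are ordered 5'->3' along the
#' transcript, i.e. descending genomic coordinates on the minus strand.
#'
#' Transcripts absent from the GTF are flagged `no_structure`; transcripts
#' whose exon lengths do not sum to the sequence length are flagged
#' `exon_mismatch`. Both are retained for transcript-only analyses but carry
#' no usable genomic map.
#'
#' @param transcripts Tibble from [parse_transcript_fasta()].
#' @param gtf_path Path to a GTF file with exon features.
#' @return The input tibble with added list column `exons` (each a tibble
#'   `chrom`, `start`, `end`, `strand` in transcript order) and character
#'   column `structure` (`"ok"`, `"no_structure"` or `"exon_mismatch"`).
#' @export
attach_exons <- function(transcripts, gtf_path) {
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  ex <- tibble(
    transcript_id = as.character(gr$transcript_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
  ex_by_tx <- split(ex, ex$transcript_id)

  exons <- vector("list", nrow(transcripts))
  structure <- character(nrow(transcripts))
  for (i in seq_len(nrow(transcripts))) {
    tx <- transcripts$transcript_id[[i]]
    e <- ex_by_tx[[tx]]
    if (is.null(e)) {
      exons[[i]] <- tibble(chrom = character(), start = integer(),
                           end = integer(), strand = character())
      structure[[i]] <- "no_structure"
      next
    }
    minus <- e$strand[[1L]] == "-"
    e <- e[order(e$start, decreasing = minus), c("chrom", "start", "end", "strand")]
    exons[[i]] <- as_tibble(e)
    structure[[i]] <-
      if (sum(e$end - e$start) != transcripts$length[[i]]) "exon_mismatch" else "ok"
  }
  transcripts$exons <- exons
  transcripts$structure <- structure
  transcripts
}

#' Map a transcript interval to genomic intervals
#'
#' Projects the 0-based half-open transcript interval `[t_start, t_end)`
#' through the transcript's exon structure. The returned intervals are in
#' transcript (5'->3') order, split at exon junctions; their lengths always
#' sum to `t_end - t_start`.
#'
#' @param exons Exon tibble in transcript order, as produced by
#'   [attach_exons()] (columns `chrom`, `start`, `end`, `strand`).
#' @param t_start,t_end Transcript interval, 0-based half-open.
#' @return Tibble of genomic intervals (`chrom`, `start`, `end`, `strand`).
#' @export
map_to_genome <- function(exons, t_start, t_end) {
  tx_len <- sum(exons$end - exons$start)
  if (t_start < 0L || t_start >= t_end || t_end > tx_len) {
    stop("range: transcript interval out of bounds", call. = FALSE)
  }
  widths <- exons$end - exons$start
  offs <- cumsum(c(0L, widths))  # transcript offset at each exon start
  out <- vector("list", nrow(exons))
  for (i in seq_len(nrow(exons))) {
    a <- max(t_start, offs[[i]])
    b <- min(t_end, offs[[i + 1L]])
    if (a >= b) next
    s <- a - offs[[i]]  # offsets within the exon, transcript orientation
    e <- b - offs[[i]]
    if (exons$strand[[i]] == "+") {
      g1 <- exons$start[[i]] + s
      g2 <- exons$start[[i]] + e
    } else {
      g1 <- exons$end[[i]] - e
      g2 <- exons$end[[i]] - s
    }
    out[[i]] <- tibble(chrom = exons$chrom[[i]], start = g1, end = g2,
                       strand = exons$strand[[i]])
  }
  bind_rows(out)
}

#' Map a genomic position to a transcript position
#'
#' Inverse of [map_to_genome()] for a single exon-covered base.
#'
#' @param exons Exon tibble in transcript order.
#' @param gpos 0-based genomic position.
#' @return 0-based transcript position, or `NA` if the base is intronic or
#'   outside the transcript.
#' @export
map_to_transcript <- function(exons, gpos) {
  widths <- exons$end - exons$start
  offs <- cumsum(c(0L, widths))
  for (i in seq_len(nrow(exons))) {
    if (gpos >= exons$start[[i]] && gpos < exons$end[[i]]) {
      within <- if (exons$strand[[i]] == "+") gpos - exons$start[[i]]
                else exons$end[[i]] - 1L - gpos
      return(offs[[i]] + within)
    }
  }
  NA_integer_
}

#' All pairwise overlaps between two interval sets
#'
#' Reports every (query, subject) pair overlapping by at least one base,
#' with the overlap length. With `same_strand = TRUE`, pairs on opposite
#' strands are not reported.
#'
#' @param query,subject Tibbles of genomic intervals (`chrom`, `start`,
#'   `end`, `strand`; 0-based half-open).
#' @param same_strand Require matching strands? Default `FALSE`.
#' @return Tibble with columns `query`, `subject` (row indices) and
#'   `overlap` (bases).
#' @export
intersect_intervals <- function(query, subject, same_strand = FALSE) {
  empty <- tibble(query = integer(), subject = integer(), overlap = integer())
  if (nrow(query) == 0L || nrow(subject) == 0L) return(empty)
  as_gr <- function(x) {
    GenomicRanges::GRanges(
      seqnames = x$chrom,
      ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
      strand = x$strand
    )
  }
  gq <- as_gr(query)
  gs <- as_gr(subject)
  hits <- GenomicRanges::findOverlaps(gq, gs, ignore.strand = !same_strand)
  if (length(hits) == 0L) return(empty)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- pmin(query$end[qi], subject$end[si]) - pmax(query$start[qi], subject$start[si])
  tibble(query = qi, subject = si, overlap = as.integer(ov)) |>
    arrange(.data$query, .data$subject)
}

#' Write genomic intervals as BED6
#'
#' @param intervals Tibble of genomic intervals (0-based half-open, matching
#'   BED's native convention).
#' @param path Output path.
#' @param name,score Optional per-interval name and score vectors.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path, name = ".", score = 0L) {
  df <- data.frame(
    chrom = intervals$chrom,
    start = intervals$start,
    end = intervals$end,
    name = name,
    score = score,
    strand = intervals$strand
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
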