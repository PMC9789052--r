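# Characterisation of called starts: translation-initiation-site (TIS)
# efficiency lookup, positional context matrices, and a windowed scan of
# downstream RNA-structure potential.

OPTIMAL_TIS <- "CACCATGG"  # scale-defining context, efficiency 100

#' Read a TIS efficiency table
#'
#' TSV with columns `context` (8-mer: 4 nt upstream, the start codon, 1 nt
#' downstream; RNA or DNA spelling) and `score`, on the scale where the
#' optimal context CACCAUGG scores 100. Spelling is normalised to DNA
#' internally.
#'
#' @param path TSV path.
#' @return Named numeric vector keyed by normalised 8-mer context.
#' @export
read_tis_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, comment = "#",
                        col_types = readr::cols(
                          context = readr::col_character(),
                          score = readr::col_double()
                        ))
  assert_cols(df, c("context", "score"))
  ctx <- norm_dna(df$context)
  if (any(df$score < 0)) stop("TIS scores must be non-negative", call. = FALSE)
  if (!(OPTIMAL_TIS %in% ctx)) {
    warning("optimal context ", OPTIMAL_TIS, " absent from the TIS table")
  }
  setNames(df$score, ctx)
}

#' Look up TIS efficiency scores
#'
#' Exact lookup of 8-mer contexts in a TIS table; contexts absent from the
#' table are reported as `NA`, never imputed.
#'
#' @param contexts Character vector of 8-mer contexts (RNA or DNA
#'   spelling).
#' @param table Named score vector from [read_tis_table()].
#' @return Numeric vector of scores (`NA` for missing contexts).
#' @export
tis_score <- function(contexts, table) {
  ctx <- norm_dna(contexts)
  bad <- nchar(ctx) != 8L | grepl("[^ACGTN]", ctx)
  if (any(bad)) {
    stop("malformed context(s): ", paste(head(contexts[bad]), collapse = ", "),
         call. = FALSE)
  }
  unname(table[ctx])
}

#' Extract start-codon contexts from transcripts
#'
#' For each start, extracts the 8-mer context (positions -4..-1, the codon,
#' +4). Starts too close to the transcript 5' end (or 3' end) for a full
#' context are dropped and tallied in the `"dropped"` attribute.
#'
#' @param starts Tibble with `transcript_id`, `position` (codon first
#'   base), e.g. candidate starts or ranked calls.
#' @param transcripts Transcript tibble.
#' @return `starts` with an added `context` column (dropped rows removed);
#'   attribute `"dropped"` counts the starts lacking flanks.
#' @export
start_contexts <- function(starts, transcripts) {
  idx <- match(starts$transcript_id, transcripts$transcript_id)
  seqs <- transcripts$sequence[idx]
  lens <- transcripts$length[idx]
  ok <- starts$position >= 4L & starts$position + 4L <= lens
  ctx <- rep(NA_character_, nrow(starts))
  ctx[ok] <- substring(seqs[ok], starts$position[ok] - 3L,
                       starts$position[ok] + 4L)
  out <- starts[ok, , drop = FALSE]
  out$context <- ctx[ok]
  attr(out, "dropped") <- sum(!ok)
  out
}

#' Positional nucleotide context matrix
#'
#' Counts and frequencies per context position, labelled -4..-1 (upstream),
#' +1..+3 (the start codon) and +4. Kozak-relevant summaries — the purine
#' fraction at -3 and the G fraction at +4 — are attached as attributes.
#'
#' @param contexts Character vector of 8-mer contexts (DNA or RNA).
#' @param include_codon Include the codon-interior positions +1..+3?
#'   Default `TRUE`.
#' @return Tibble `position`, `base`, `count`, `freq`; frequencies sum to
#'   1 per position. Attributes `"purine_minus3"` and `"g_plus4"`.
#' @export
context_matrix <- function(contexts, include_codon = TRUE) {
  ctx <- norm_dna(contexts)
  stopifnot(all(nchar(ctx) == 8L))
  labels <- c("-4", "-3", "-2", "-1", "+1", "+2", "+3", "+4")
  keep <- if (include_codon) 1:8 else c(1:4, 8L)
  rows <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    p <- keep[[k]]
    bases <- substring(ctx, p, p)
    cnt <- table(factor(bases, levels = c("A", "C", "G", "T")))
    rows[[k]] <- tibble(position = labels[[p]],
                        base = names(cnt),
                        count = as.integer(cnt),
                        freq = if (length(ctx)) as.integer(cnt) / length(ctx)
                               else NA_real_)
  }
  out <- bind_rows(rows)
  out$position <- factor(out$position, levels = labels[keep])
  minus3 <- substring(ctx, 2L, 2L)
  plus4 <- substring(ctx, 8L, 8L)
  attr(out, "purine_minus3") <- mean(minus3 %in% c("A", "G"))
  attr(out, "g_plus4") <- mean(plus4 == "G")
  class(out) <- c("context_matrix", class(out))
  out
}

# Maximum number of nested base pairs (minimum hairpin loop 3, G-U wobble
# allowed) by dynamic programming. Input may be DNA or RNA spelling.
pairmax_energy <- function(seq, min_loop = 3L) {
  s <- strsplit(norm_dna(seq), "")[[1L]]
  n <- length(s)
  can_pair <- function(a, b) {
    paste0(a, b) %in% c("AT", "TA", "GC", "CG", "GT", "TG")
  }
  if (n < min_loop + 2L) return(0)
  N <- matrix(0L, n, n)
  for (span in (min_loop + 1L):(n - 1L)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      best <- N[i, j - 1L]
      for (k in i:(j - min_loop - 1L)) {
        if (can_pair(s[[k]], s[[j]])) {
          left <- if (k > i) N[i, k - 1L] else 0L
          inner <- if (k + 1L <= j - 1L) N[k + 1L, j - 1L] else 0L
          best <- max(best, left + inner + 1L)
        }
      }
      N[i, j] <- best
    }
  }
  -as.numeric(N[1L, n])
}

#' Windowed downstream-structure scan
#'
#' Slides a `window`-nt window at 1-nt steps over the region from
#' `region[1]` nt upstream to `region[2]` nt downstream of a start codon
#' and evaluates a structure-stability energy for each window (more
#' negative = more stable). The built-in energy is the negated maximum
#' number of nested base pairs (minimum hairpin loop 3, G-U allowed) — a
#' pair-maximisation stand-in, not a thermodynamic model; external folding
#' engines plug in via `energy_fn`, and every profile carries
#' `energy_model_id` so models are never silently mixed.
#'
#' @param sequence Transcript sequence.
#' @param start_pos Start-codon position (0-based).
#' @param window Window width in nt, default 22.
#' @param region Length-2 vector: nt upstream and downstream bounds
#'   relative to the start codon, default `c(-10, 100)`.
#' @param energy_fn Function taking a window sequence and returning an
#'   energy; default the built-in pair-maximisation score.
#' @param energy_model_id Identifier recorded on the profile.
#' @return A `fold_profile` tibble `offset`, `energy`; attributes
#'   `"energy_model_id"` and `"truncated"` (windows that would run outside
#'   the sequence are omitted and flagged).
#' @export
fold_scan <- function(sequence, start_pos, window = 22L,
                      region = c(-10L, 100L), energy_fn = NULL,
                      energy_model_id = NULL) {
  if (is.null(energy_fn)) {
    energy_fn <- pairmax_energy
    energy_model_id <- energy_model_id %||% "pairmax_v1"
  } else {
    energy_model_id <- energy_model_id %||% "custom"
  }
  n <- nchar(sequence)
  offsets <- seq.int(region[[1L]], region[[2L]] - window + 1L)
  starts <- start_pos + offsets
  ok <- starts >= 0L & starts + window <= n
  energy <- vapply(starts[ok], function(a) {
    energy_fn(substring(sequence, a + 1L, a + window))
  }, 0)
  out <- tibble(offset = offsets[ok], energy = energy)
  attr(out, "energy_model_id") <- energy_model_id
  attr(out, "truncated") <- sum(!ok)
  class(out) <- c("fold_profile", class(out))
  out
}

#' Two-sample distribution comparison (Kolmogorov-Smirnov)
#'
#' @param x,y Numeric score samples (both non-empty).
#' @return One-row tibble `ks_stat`, `p_value`, `method` (`"exact"` or
#'   `"asymptotic"`, as chosen by sample size and ties).
#' @export
compare_distributions <- function(x, y) {
  if (!length(x) || !length(y)) stop("empty sample", call. = FALSE)
  kt <- suppressWarnings(ks.test(x, y))
  tibble(ks_stat = unname(kt$statistic), p_value = kt$p.value,
         method = if (grepl("exact", kt$method, ignore.case = TRUE) ||
                        kt$exact %||% FALSE) "exact" else "asymptotic")
}
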