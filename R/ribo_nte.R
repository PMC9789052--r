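# Detection and ranking of translated N-terminal extensions from P-site
# count profiles. The detector reads four signals: triplet periodicity at
# the read level (binomial tail on frame totals), periodicity consistency
# at the codon level (strict-maximum wins), the density step at the
# candidate start, and coverage/average density. Read- and codon-level
# p-values are combined by a dependence-robust minimum rule (see
# combine_pvalues).

#' Load P-site profile TSVs
#'
#' Reads one or more profile files with columns `transcript_id`, `position`
#' (0-based transcript coordinate), `count` and `channel` (`elong` or
#' `init`), and sums counts per (transcript, channel, position) across
#' files. Lines with an unknown channel or non-finite fields are skipped
#' and tallied in the `"report"` attribute; a negative count is corrupt and
#' fatal.
#'
#' @param paths Character vector of TSV paths.
#' @return Tibble `transcript_id`, `channel`, `position`, `count`, with a
#'   `"report"` attribute (`file`, `lines`, `skipped`).
#' @export
read_ribo_profiles <- function(paths) {
  pieces <- vector("list", length(paths))
  report <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    df <- readr::read_tsv(paths[[i]], show_col_types = FALSE, comment = "#",
                          col_types = readr::cols(
                            transcript_id = readr::col_character(),
                            position = readr::col_integer(),
                            count = readr::col_double(),
                            channel = readr::col_character()
                          ))
    assert_cols(df, c("transcript_id", "position", "count", "channel"))
    ok <- df$channel %in% c("elong", "init") &
      !is.na(df$position) & !is.na(df$count) & df$position >= 0L
    if (any(df$count[ok] < 0)) {
      stop("corrupt_profile: negative count in ", paths[[i]], call. = FALSE)
    }
    report[[i]] <- tibble(file = paths[[i]], lines = nrow(df),
                          skipped = sum(!ok))
    pieces[[i]] <- df[ok, ]
  }
  out <- bind_rows(pieces) |>
    group_by(.data$transcript_id, .data$channel, .data$position) |>
    summarise(count = sum(.data$count), .groups = "drop")
  attr(out, "report") <- bind_rows(report)
  out
}

#' Frame-resolved counts over a region
#'
#' Sums counts by reading frame relative to `start` over the transcript
#' region `[start, end)` and tallies codon-level periodicity: `occupied` is
#' the number of codons holding at least one read, `wins` the number of
#' occupied codons whose frame-0 position holds the strict maximum of the
#' codon (ties never win).
#'
#' @param positions,counts Integer vectors of P-site positions and counts
#'   for one transcript's elongating channel.
#' @param start,end Region bounds, 0-based half-open; `end - start` must be
#'   a multiple of 3.
#' @return One-row tibble `F0`, `F1`, `F2`, `occupied`, `wins`, `L`.
#' @export
frame_counts <- function(positions, counts, start, end) {
  stopifnot(start < end, (end - start) %% 3L == 0L)
  L <- (end - start) %/% 3L
  sel <- positions >= start & positions < end
  pos <- positions[sel]
  cnt <- counts[sel]
  if (!length(pos)) {
    return(tibble(F0 = 0, F1 = 0, F2 = 0, occupied = 0L, wins = 0L, L = L))
  }
  off <- pos - start
  frame <- off %% 3L
  codon <- off %/% 3L
  fsum <- vapply(0:2, function(f) sum(cnt[frame == f]), 0)
  # per-codon frame counts as an L x 3 tally
  m <- matrix(0, nrow = L, ncol = 3L)
  key <- codon * 3L + frame
  agg <- rowsum(cnt, key)
  ks <- as.integer(rownames(agg))
  m[cbind(ks %/% 3L + 1L, ks %% 3L + 1L)] <- agg
  tot <- rowSums(m)
  occ <- tot > 0
  wins <- sum(occ & m[, 1L] > pmax(m[, 2L], m[, 3L]))
  tibble(F0 = fsum[[1L]], F1 = fsum[[2L]], F2 = fsum[[3L]],
         occupied = sum(occ), wins = as.integer(wins), L = L,
         codon_totals = list(tot[occ]))
}

# Null probability that frame 0 holds the strict maximum of a codon with c
# reads thrown uniformly over the three frames; exact trinomial enumeration
# for c <= 30, 1/3 beyond (tie probability is negligible there).
null_win_prob <- local({
  cache <- NULL
  function(c_reads) {
    if (is.null(cache)) {
      tab <- numeric(30L)
      for (cc in 1:30) {
        p <- 0
        for (x0 in 0:cc) for (x1 in 0:(cc - x0)) {
          x2 <- cc - x0 - x1
          if (x0 > max(x1, x2)) {
            p <- p + exp(lgamma(cc + 1) - lgamma(x0 + 1) - lgamma(x1 + 1) -
                           lgamma(x2 + 1) - cc * log(3))
          }
        }
        tab[[cc]] <- p
      }
      cache <<- tab
    }
    ifelse(c_reads >= 1 & c_reads <= 30, cache[pmin(pmax(c_reads, 1), 30)], 1 / 3)
  }
})

#' Triplet-periodicity p-values
#'
#' `p_read` is the upper-tail binomial probability of observing at least
#' `F0` frame-0 reads among all reads in the region under the equal-frames
#' null (success probability 1/3). `p_codon` is the upper-tail binomial
#' probability of at least `wins` strict-maximum codons among the occupied
#' codons, with the null win probability taken as the mean exact trinomial
#' win probability at each occupied codon's read total. Both are 1 for an
#' empty region.
#'
#' @param fc One-row tibble from [frame_counts()].
#' @return Named list `p_read`, `p_codon`.
#' @export
periodicity_pvalues <- function(fc) {
  N <- fc$F0 + fc$F1 + fc$F2
  if (N == 0) return(list(p_read = 1, p_codon = 1))
  p_read <- pbinom(fc$F0 - 1, size = round(N), prob = 1 / 3, lower.tail = FALSE)
  if (fc$occupied == 0L) {
    p_codon <- 1
  } else {
    p0 <- mean(null_win_prob(fc$codon_totals[[1L]]))
    p_codon <- pbinom(fc$wins - 1, size = fc$occupied, prob = p0,
                      lower.tail = FALSE)
  }
  list(p_read = max(p_read, .Machine$double.xmin),
       p_codon = max(p_codon, .Machine$double.xmin))
}

#' Combine the two periodicity p-values
#'
#' The read-level and codon-level p-values are computed from the same
#' frame-0 counts and are positively correlated, so the default
#' combination is the Bonferroni-style minimum rule
#' `min(1, 2 min(p1, p2))`, which is valid under arbitrary dependence.
#' Fisher's method (chi-square with 4 df) is available for independent
#' inputs but is anticonservative here.
#'
#' @param p1,p2 P-values in (0, 1].
#' @param method `"bonferroni"` (default) or `"fisher"`.
#' @return Combined p-value.
#' @export
combine_pvalues <- function(p1, p2, method = c("bonferroni", "fisher")) {
  method <- match.arg(method)
  if (method == "fisher") {
    pchisq(-2 * (log(p1) + log(p2)), df = 4, lower.tail = FALSE)
  } else {
    pmin(1, 2 * pmin(p1, p2))
  }
}

#' Start step-increase and initiation-peak scores
#'
#' `sigma` is the ratio of regularised in-frame densities downstream versus
#' upstream of the candidate: `(mu_down + eps) / (mu_up + eps)`, where
#' `mu_down` is in-frame reads per codon on `[cand, cds_start)` and `mu_up`
#' the same over the up-to-`up_codons` in-frame codons upstream of the
#' candidate but inside the extension (0 when none exist). `iota` is the
#' initiating-channel read count within one codon of the candidate divided
#' by the regularised transcript-wide mean initiating reads per codon.
#'
#' @param elong_pos,elong_cnt Elongating-channel positions/counts.
#' @param init_pos,init_cnt Initiating-channel positions/counts.
#' @param cand_pos Candidate start position.
#' @param ext_start Extension 5' bound.
#' @param cds_start Annotated CDS start.
#' @param tx_len Transcript length (for the initiating-channel baseline).
#' @param eps Regulariser, default 0.1.
#' @param up_codons Upstream comparison window in codons, default 15.
#' @return Named list `sigma`, `iota`, `mu_down`, `mu_up`.
#' @export
start_step_score <- function(elong_pos, elong_cnt, init_pos, init_cnt,
                             cand_pos, ext_start, cds_start, tx_len,
                             eps = 0.1, up_codons = 15L) {
  inframe_density <- function(a, b) {
    if (a >= b) return(c(0, 0))
    sel <- elong_pos >= a & elong_pos < b & (elong_pos - a) %% 3L == 0L
    c(sum(elong_cnt[sel]), (b - a) / 3)
  }
  dn <- inframe_density(cand_pos, cds_start)
  mu_down <- if (dn[[2L]] > 0) dn[[1L]] / dn[[2L]] else 0
  up_start <- max(ext_start, cand_pos - 3L * up_codons)
  up <- inframe_density(up_start, cand_pos)
  mu_up <- if (up[[2L]] > 0) up[[1L]] / up[[2L]] else 0
  sigma <- (mu_down + eps) / (mu_up + eps)

  near <- init_pos >= cand_pos - 3L & init_pos < cand_pos + 6L
  base <- sum(init_cnt) / max(tx_len / 3, 1)
  iota <- sum(init_cnt[near]) / (base + eps)
  list(sigma = sigma, iota = iota, mu_down = mu_down, mu_up = mu_up)
}

#' Score, call and rank candidate extensions
#'
#' For every transcript, each candidate start passing the gates (at least
#' `min_inframe_reads` in-frame reads and coverage fraction above
#' `min_gamma` on its region `[cand, cds_start)`) is scored; the
#' transcript's call is the candidate with the smallest combined p-value
#' (ties: larger `sigma`, then 5'-most position). Calls are then ranked
#' transcriptome-wide by combined p-value ascending, mean density
#' descending, transcript id. Transcripts with no passing candidate receive
#' no call; zero-read regions are never called.
#'
#' @param profiles Profile tibble from [read_ribo_profiles()].
#' @param extensions Extension tibble (needs `ext_start`, `cds_start`).
#' @param candidates Candidate tibble from [enumerate_candidate_starts()].
#' @param transcripts Transcript tibble (for transcript lengths).
#' @param config List of detector parameters; see [nte_config()].
#' @return Tibble of calls, one row per called transcript: all scores plus
#'   `aug_called` and the global `rank`.
#' @export
call_and_rank <- function(profiles, extensions, candidates, transcripts,
                          config = nte_config()) {
  elong <- profiles[profiles$channel == "elong", ]
  init <- profiles[profiles$channel == "init", ]
  elong_by <- split(elong[c("position", "count")], elong$transcript_id)
  init_by <- split(init[c("position", "count")], init$transcript_id)
  tx_len <- setNames(transcripts$length, transcripts$transcript_id)
  cand_by <- split(candidates, candidates$transcript_id)

  rows <- vector("list", nrow(extensions))
  for (i in seq_len(nrow(extensions))) {
    tx <- extensions$transcript_id[[i]]
    cands <- cand_by[[tx]]
    if (is.null(cands) || nrow(cands) == 0L) next
    e <- elong_by[[tx]]
    if (is.null(e) || nrow(e) == 0L) next  # non-zero coverage gate
    ip <- init_by[[tx]] %||% tibble(position = integer(), count = numeric())
    cs <- extensions$cds_start[[i]]
    es <- extensions$ext_start[[i]]
    scored <- vector("list", nrow(cands))
    for (k in seq_len(nrow(cands))) {
      cp <- cands$position[[k]]
      fc <- frame_counts(e$position, e$count, cp, cs)
      gamma <- fc$occupied / fc$L
      if (fc$F0 < config$min_inframe_reads || gamma <= config$min_gamma) next
      pv <- periodicity_pvalues(fc)
      st <- start_step_score(e$position, e$count, ip$position, ip$count,
                             cp, es, cs, tx_len[[tx]],
                             eps = config$eps, up_codons = config$up_codons)
      scored[[k]] <- tibble(
        transcript_id = tx,
        gene_id = extensions$gene_id[[i]],
        position = cp, codon = cands$codon[[k]],
        codon_class = cands$codon_class[[k]],
        phi = (fc$F0 + fc$F1 + fc$F2 > 0) * fc$F0 / max(fc$F0 + fc$F1 + fc$F2, 1),
        p_read = pv$p_read, p_codon = pv$p_codon,
        p_comb = combine_pvalues(pv$p_read, pv$p_codon, config$combine),
        gamma = gamma, mu = (fc$F0 + fc$F1 + fc$F2) / fc$L,
        sigma = st$sigma, iota = st$iota
      )
    }
    scored <- bind_rows(scored)
    if (nrow(scored) == 0L) next
    ord <- order(scored$p_comb, -scored$sigma, scored$position)
    rows[[i]] <- scored[ord[[1L]], ]
  }
  calls <- bind_rows(rows)
  if (nrow(calls) == 0L) {
    return(tibble(transcript_id = character(), gene_id = character(),
                  position = integer(), codon = character(),
                  codon_class = character(), phi = numeric(),
                  p_read = numeric(), p_codon = numeric(), p_comb = numeric(),
                  gamma = numeric(), mu = numeric(), sigma = numeric(),
                  iota = numeric(), aug_called = logical(), rank = integer()))
  }
  calls$aug_called <- calls$codon == "ATG"
  keys <- if (isTRUE(config$use_iota)) {
    order(calls$p_comb, -calls$mu, -calls$iota, calls$transcript_id)
  } else {
    order(calls$p_comb, -calls$mu, calls$transcript_id)
  }
  calls <- calls[keys, ]
  calls$rank <- seq_len(nrow(calls))
  class(calls) <- c("nte_ranking", class(calls))
  calls
}

#' Detector configuration
#'
#' @param min_inframe_reads Minimum in-frame reads on the candidate region
#'   (default 10).
#' @param min_gamma Minimum coverage fraction, exclusive (default 0: the
#'   region must have non-zero coverage).
#' @param eps Density regulariser for the step score (default 0.1).
#' @param up_codons Upstream window for the step score, codons (default 15).
#' @param use_iota Use the initiation-peak score as a secondary ranking key
#'   (default `FALSE`; initiating data is noisy, so the peak score is
#'   reported but not ranked on).
#' @param combine P-value combination rule, see [combine_pvalues()].
#' @return Named list of parameters.
#' @export
nte_config <- function(min_inframe_reads = 10, min_gamma = 0, eps = 0.1,
                       up_codons = 15L, use_iota = FALSE,
                       combine = "bonferroni") {
  list(min_inframe_reads = min_inframe_reads, min_gamma = min_gamma,
       eps = eps, up_codons = up_codons, use_iota = use_iota,
       combine = combine)
}

#' Score whole extensions for periodicity
#'
#' Convenience scorer used for calibration and power summaries: computes
#' the frame counts, periodicity p-values and the combined p-value over
#' each transcript's full region `[region_start, cds_start)`, with no
#' candidate selection.
#'
#' @param profiles Profile tibble.
#' @param extensions Extension tibble; scored region is
#'   `[ext_start, cds_start)`.
#' @return Tibble with one row per extension: frame counts, `p_read`,
#'   `p_codon`, `p_comb`, `gamma`, `mu`.
#' @export
score_extension_regions <- function(profiles, extensions,
                                    combine = "bonferroni") {
  elong <- profiles[profiles$channel == "elong", ]
  elong_by <- split(elong[c("position", "count")], elong$transcript_id)
  rows <- vector("list", nrow(extensions))
  for (i in seq_len(nrow(extensions))) {
    tx <- extensions$transcript_id[[i]]
    e <- elong_by[[tx]] %||% tibble(position = integer(), count = numeric())
    fc <- frame_counts(e$position, e$count,
                       extensions$ext_start[[i]], extensions$cds_start[[i]])
    pv <- periodicity_pvalues(fc)
    rows[[i]] <- tibble(
      transcript_id = tx,
      F0 = fc$F0, F1 = fc$F1, F2 = fc$F2,
      occupied = fc$occupied, wins = fc$wins, L = fc$L,
      p_read = pv$p_read, p_codon = pv$p_codon,
      p_comb = combine_pvalues(pv$p_read, pv$p_codon, combine),
      gamma = fc$occupied / fc$L,
      mu = (fc$F0 + fc$F1 + fc$F2) / fc$L
    )
  }
  bind_rows(rows)
}

#' Per-sample periodicity QC metric
#'
#' Fraction of elongating reads falling in frame 0 over all annotated CDS
#' regions; emitted for information only.
#'
#' @param profiles Profile tibble.
#' @param transcripts Transcript tibble.
#' @return One-row tibble `inframe_fraction`, `n_reads`.
#' @export
periodicity_qc <- function(profiles, transcripts) {
  elong <- profiles[profiles$channel == "elong", ]
  idx <- match(elong$transcript_id, transcripts$transcript_id)
  cs <- transcripts$cds_start[idx]
  ce <- transcripts$cds_end[idx]
  sel <- !is.na(cs) & elong$position >= cs & elong$position < ce
  fr <- (elong$position[sel] - cs[sel]) %% 3L
  n <- sum(elong$count[sel])
  tibble(inframe_fraction = if (n > 0) sum(elong$count[sel][fr == 0]) / n else NA_real_,
         n_reads = n)
}
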