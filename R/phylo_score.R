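# Codon-alignment window extraction from reference-anchored MAF and
# coding-evolution scoring. The built-in scorer is a deliberately simple
# substitution-type log-likelihood-ratio scorer (Nei-Gojobori path
# counting against the reference under a star topology); full empirical
# codon models are external, and their per-codon outputs can be read in
# via read_external_scores().

#' Read a reference-anchored MAF file
#'
#' Minimal Multiple Alignment Format reader: parses alignment blocks and
#' their `s` lines. Only the fields the window extractor needs are kept.
#'
#' @param path Path to a MAF file.
#' @return List of blocks; each block is a tibble with columns `src`,
#'   `assembly`, `chrom`, `start`, `size`, `strand`, `src_size`, `text`.
#' @export
read_maf <- function(path) {
  lines <- readLines(path)
  blocks <- list()
  cur <- list()
  flush <- function() {
    if (length(cur)) blocks[[length(blocks) + 1L]] <<- bind_rows(cur)
    cur <<- list()
  }
  for (ln in lines) {
    if (startsWith(ln, "a")) {
      flush()
    } else if (startsWith(ln, "s ")) {
      f <- strsplit(trimws(ln), "\\s+")[[1L]]
      src <- f[[2L]]
      dot <- regexpr(".", src, fixed = TRUE)
      cur[[length(cur) + 1L]] <- tibble(
        src = src,
        assembly = if (dot > 0) substr(src, 1L, dot - 1L) else src,
        chrom = if (dot > 0) substr(src, dot + 1L, nchar(src)) else NA_character_,
        start = as.integer(f[[3L]]),
        size = as.integer(f[[4L]]),
        strand = f[[5L]],
        src_size = as.integer(f[[6L]]),
        text = toupper(f[[7L]])
      )
    }
  }
  flush()
  blocks
}

#' Write alignment blocks as MAF
#'
#' @param blocks List of block tibbles in [read_maf()] layout.
#' @param path Output path.
#' @param header_comment Optional comment line(s) written after the version
#'   line (e.g. a config hash).
#' @return `path`, invisibly.
#' @export
write_maf <- function(blocks, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  for (b in blocks) {
    writeLines("a score=0.0", con)
    writeLines(sprintf("s %s %d %d %s %d %s",
                       b$src, b$start, b$size, b$strand, b$src_size, b$text), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Extract a spliced codon-alignment window from a MAF
#'
#' Pulls, for every reference base of the window's genomic blocks, the
#' aligned column from the covering MAF block (columns that are insertions
#' relative to the reference are dropped), stitches the columns across exon
#' blocks in transcript order, reverse-complements minus-strand blocks, and
#' groups the result into codons in the window's reading frame. Reference
#' bases covered by no MAF block, and species absent from a covering block,
#' receive the missing marker `"."` at those columns.
#'
#' @param maf Block list from [read_maf()].
#' @param blocks Window genomic blocks (tibble in transcript order).
#' @param ref_assembly Reference assembly name (MAF `src` prefix).
#' @param window_seq The window's transcript-oriented sequence; the
#'   stitched reference row must match it exactly, else the function stops
#'   with `"ref_mismatch"`.
#' @param transcript_id Identifier carried on the result.
#' @return A `codon_alignment` object: list with `transcript_id`, `species`
#'   (reference first) and `codons`, a species-by-codon character matrix of
#'   3-mers (codons containing `-` or `.` are non-informative).
#' @export
extract_alignment_window <- function(maf, blocks, ref_assembly, window_seq,
                                     transcript_id = NA_character_) {
  ref_rows <- lapply(maf, function(b) b[b$assembly == ref_assembly, , drop = FALSE])
  species <- unique(unlist(lapply(maf, function(b) b$assembly)))
  species <- c(ref_assembly, setdiff(species, ref_assembly))

  per_block <- vector("list", nrow(blocks))
  for (bi in seq_len(nrow(blocks))) {
    wb <- blocks[bi, ]
    width <- wb$end - wb$start
    m <- matrix(".", nrow = length(species), ncol = width,
                dimnames = list(species, NULL))
    for (mi in seq_along(maf)) {
      rr <- ref_rows[[mi]]
      if (nrow(rr) == 0L || rr$chrom[[1L]] != wb$chrom) next
      chars <- strsplit(rr$text[[1L]], "")[[1L]]
      ref_cols <- which(chars != "-")
      gpos <- rr$start[[1L]] + seq_along(ref_cols) - 1L
      sel <- gpos >= wb$start & gpos < wb$end
      if (!any(sel)) next
      cols <- ref_cols[sel]
      tgt <- gpos[sel] - wb$start + 1L
      for (sp in seq_len(nrow(maf[[mi]]))) {
        row_chars <- strsplit(maf[[mi]]$text[[sp]], "")[[1L]]
        m[maf[[mi]]$assembly[[sp]], tgt] <- row_chars[cols]
      }
    }
    if (wb$strand == "-") {
      m <- matrix(complement_chars(m), nrow = nrow(m),
                  dimnames = dimnames(m))[, rev(seq_len(ncol(m))), drop = FALSE]
    }
    per_block[[bi]] <- m
  }
  full <- do.call(cbind, per_block)
  ref_seq <- paste(full[1L, ], collapse = "")
  if (!identical(ref_seq, window_seq)) {
    stop("ref_mismatch: MAF reference row disagrees with window sequence",
         call. = FALSE)
  }
  n_codons <- ncol(full) %/% 3L
  codons <- matrix("", nrow = length(species), ncol = n_codons,
                   dimnames = list(species, NULL))
  for (ci in seq_len(n_codons)) {
    cols <- (3L * (ci - 1L) + 1L):(3L * ci)
    codons[, ci] <- apply(full[, cols, drop = FALSE], 1L, paste, collapse = "")
  }
  structure(list(transcript_id = transcript_id, species = species,
                 codons = codons),
            class = "codon_alignment")
}

# Fraction of the 9 single-nucleotide neighbours of each codon that are
# synonymous (stops count as nonsynonymous neighbours).
syn_neighbour_frac <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      bases <- c("A", "C", "G", "T")
      f <- setNames(numeric(length(ALL_CODONS)), ALL_CODONS)
      for (r in ALL_CODONS) {
        aa <- codon_aa[[r]]
        syn <- 0L
        for (p in 1:3) for (b in bases) {
          if (b == substr(r, p, p)) next
          q <- r
          substr(q, p, p) <- b
          if (codon_aa[[q]] == aa && codon_aa[[q]] != "*") syn <- syn + 1L
        }
        f[[r]] <- syn / 9
      }
      cache <<- f
    }
    cache
  }
})

# Expected synonymous / nonsynonymous single-nucleotide step counts along
# the mutational paths from codon r to codon q, averaged over all orderings
# of the differing positions; paths passing through a stop codon are
# excluded (all orderings are used if every path hits a stop). Cached per
# codon pair.
ng_path_env <- new.env(parent = emptyenv())
ng_step_counts <- function(r, q) {
  key <- paste0(r, q)
  hit <- ng_path_env[[key]]
  if (!is.null(hit)) return(hit)
  d <- which(strsplit(r, "")[[1L]] != strsplit(q, "")[[1L]])
  perms <- switch(as.character(length(d)),
                  "1" = list(d),
                  "2" = list(d, rev(d)),
                  "3" = {
                    p <- list()
                    for (a in 1:3) for (b in 1:3) for (cc in 1:3) {
                      if (length(unique(c(a, b, cc))) == 3L) {
                        p[[length(p) + 1L]] <- d[c(a, b, cc)]
                      }
                    }
                    p
                  })
  walk <- function(order_) {
    cur <- r
    syn <- 0
    nonsyn <- 0
    valid <- TRUE
    for (j in seq_along(order_)) {
      nxt <- cur
      substr(nxt, order_[[j]], order_[[j]]) <- substr(q, order_[[j]], order_[[j]])
      if (codon_aa[[nxt]] == "*" && j < length(order_)) valid <- FALSE
      if (codon_aa[[nxt]] == codon_aa[[cur]] && codon_aa[[nxt]] != "*") {
        syn <- syn + 1
      } else {
        nonsyn <- nonsyn + 1
      }
      cur <- nxt
    }
    c(syn = syn, nonsyn = nonsyn, valid = as.numeric(valid))
  }
  res <- vapply(perms, walk, c(syn = 0, nonsyn = 0, valid = 0))
  use <- if (any(res["valid", ] > 0)) res[, res["valid", ] > 0, drop = FALSE] else res
  out <- c(syn = mean(use["syn", ]), nonsyn = mean(use["nonsyn", ]))
  ng_path_env[[key]] <- out
  out
}

#' Scorer configuration for the built-in coding scorer
#'
#' @param omega_coding Assumed nonsynonymous/synonymous rate ratio under
#'   the coding hypothesis, in (0, 1); default 0.1 (strong purifying
#'   selection).
#' @param stop_penalty Score contributed by a species codon that is an
#'   in-frame stop; default -10.
#' @param min_species Minimum number of species (rows with informative
#'   codons, reference included) for a usable track; default 3.
#' @return Named list of parameters.
#' @export
scorer_config <- function(omega_coding = 0.1, stop_penalty = -10,
                          min_species = 3L) {
  stopifnot(omega_coding > 0, omega_coding < 1)
  list(omega_coding = omega_coding, stop_penalty = stop_penalty,
       min_species = min_species)
}

#' Built-in per-codon coding-evolution score
#'
#' For each codon column, every non-reference species codon differing from
#' the reference codon is decomposed into single-nucleotide steps
#' (Nei-Gojobori path counting) and each step contributes the
#' log-likelihood ratio of a coding model (nonsynonymous changes suppressed
#' by `omega_coding`) against a neutral model, with the synonymous
#' opportunity taken from the reference codon's single-nucleotide
#' neighbourhood. Species codons that are in-frame stops contribute
#' `stop_penalty`; identical, gapped or missing codons contribute 0. A
#' positive total indicates coding-like evolution.
#'
#' @param win A `codon_alignment` from [extract_alignment_window()].
#' @param cfg Scorer parameters from [scorer_config()].
#' @return One-row tibble: `transcript_id`, `n_codons`, `per_codon` (list
#'   column), `total`, `n_species`, `flag` (`"ok"` or `"low_species"`;
#'   `total` is `NA` when flagged), `scorer_id`.
#' @export
builtin_coding_score <- function(win, cfg = scorer_config()) {
  codons <- win$codons
  informative <- apply(codons, 1L, function(x) any(grepl("^[ACGT]{3}$", x)))
  n_sp <- sum(informative)
  n_codons <- ncol(codons)
  fs_tab <- syn_neighbour_frac()
  omega <- cfg$omega_coding

  per_codon <- numeric(n_codons)
  for (ci in seq_len(n_codons)) {
    r <- codons[1L, ci]
    if (!grepl("^[ACGT]{3}$", r)) next
    fs <- fs_tab[[r]]
    denom <- fs + omega * (1 - fs)
    syn_llr <- -log(denom)
    nonsyn_llr <- log(omega) - log(denom)
    s <- 0
    for (sp in seq_len(nrow(codons))[-1L]) {
      q <- codons[sp, ci]
      if (!grepl("^[ACGT]{3}$", q) || q == r) next
      if (is_stop_codon(q)) {
        s <- s + cfg$stop_penalty
        next
      }
      steps <- ng_step_counts(r, q)
      s <- s + steps[["syn"]] * syn_llr + steps[["nonsyn"]] * nonsyn_llr
    }
    per_codon[[ci]] <- s
  }
  low <- n_sp < cfg$min_species
  total <- if (low) NA_real_ else sum(per_codon)
  tibble(
    transcript_id = win$transcript_id,
    n_codons = n_codons,
    per_codon = list(per_codon),
    total = total,
    n_species = n_sp,
    flag = if (low) "low_species" else "ok",
    scorer_id = sprintf("ng_llr_omega%.3g", omega)
  )
}

#' Read externally computed per-codon coding scores
#'
#' Format: TSV with columns `transcript_id`, `codon_index`, `score`;
#' per-codon rows carry integer indices (1-based) and each transcript may
#' carry one `total` row (`codon_index == "total"`). Totals are
#' cross-checked against the per-codon sums within 1e-6; on disagreement a
#' warning is raised and the per-codon sum wins.
#'
#' @param path TSV path.
#' @return Tibble: `transcript_id`, `n_codons`, `per_codon` (list column),
#'   `total`, `flag`, `scorer_id = "external"`.
#' @export
read_external_scores <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, comment = "#",
                        col_types = readr::cols(
                          transcript_id = readr::col_character(),
                          codon_index = readr::col_character(),
                          score = readr::col_double()
                        ))
  assert_cols(df, c("transcript_id", "codon_index", "score"))
  if (any(is.na(df$score))) stop("malformed score file: ", path, call. = FALSE)
  out <- lapply(split(df, df$transcript_id), function(d) {
    per <- d[d$codon_index != "total", ]
    per <- per[order(as.integer(per$codon_index)), ]
    total_sum <- sum(per$score)
    stated <- d$score[d$codon_index == "total"]
    if (length(stated) && abs(stated[[1L]] - total_sum) > 1e-6) {
      warning(sprintf("total mismatch for %s (stated %.6g, sum %.6g); using sum",
                      d$transcript_id[[1L]], stated[[1L]], total_sum))
    }
    tibble(transcript_id = d$transcript_id[[1L]],
           n_codons = nrow(per),
           per_codon = list(per$score),
           total = total_sum,
           flag = "ok",
           scorer_id = "external")
  })
  bind_rows(out)
}

#' Classify score tracks as conserved (strictly positive)
#'
#' @param tracks Tibble of score tracks ([builtin_coding_score()] or
#'   [read_external_scores()] output rows).
#' @return `tracks` with added logical `conserved` (`total > 0`, strict;
#'   `NA` totals are not conserved).
#' @export
classify_positive <- function(tracks) {
  tracks$conserved <- !is.na(tracks$total) & tracks$total > 0
  tracks
}

#' Write score tracks as TSV
#'
#' Inverse of [read_external_scores()]: per-codon rows plus a `total` row
#' per transcript.
#' @param tracks Score-track tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_tracks <- function(tracks, path) {
  rows <- purrr::pmap(
    list(tracks$transcript_id, tracks$per_codon, tracks$total),
    function(tx, per, total) {
      bind_rows(
        tibble(transcript_id = tx, codon_index = as.character(seq_along(per)),
               score = per),
        tibble(transcript_id = tx, codon_index = "total",
               score = if (is.na(total)) sum(per) else total)
      )
    }
  )
  readr::write_tsv(bind_rows(rows), path)
  invisible(path)
}

#' @exportS3Method generics::tidy
tidy.codon_alignment <- function(x, ...) {
  tibble(
    species = rep(x$species, times = ncol(x$codons)),
    codon_index = rep(seq_len(ncol(x$codons)), each = length(x$species)),
    codon = as.vector(x$codons)
  )
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("<codon_alignment> %s: %d species x %d codons\n",
              x$transcript_id, length(x$species), ncol(x$codons)))
  invisible(x)
}
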