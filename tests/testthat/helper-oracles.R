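# Independent brute-force oracles. These deliberately re-derive results
# by enumeration or per-base scanning, sharing no code with the package
# implementations they check.

# Exhaustive upstream scan: test every in-frame upstream codon for a stop
# and take the region after the 3'-most stop (or from the 5'-most full
# in-frame codon).
oracle_extension <- function(sequence, cds_start) {
  if (cds_start < 3) return(NULL)
  starts <- seq.int(cds_start %% 3, cds_start - 3, by = 3)
  codons <- vapply(starts, function(k) substr(sequence, k + 1, k + 3), "")
  stops <- starts[codons %in% c("TAA", "TAG", "TGA")]
  if (length(stops)) {
    ext_start <- max(stops) + 3
    boundary <- "stop_bounded"
  } else {
    ext_start <- starts[[1]]
    boundary <- "edge_bounded"
  }
  if (ext_start >= cds_start) return(NULL)
  list(ext_start = ext_start, length_codons = (cds_start - ext_start) / 3,
       boundary = boundary)
}

# Per-base genomic lookup table for an exon map (transcript order).
oracle_base_table <- function(exons) {
  unlist(lapply(seq_len(nrow(exons)), function(i) {
    g <- seq.int(exons$start[[i]], exons$end[[i]] - 1)
    if (exons$strand[[i]] == "-") rev(g) else g
  }))
}

# All-pairs interval overlap scan.
oracle_intersect <- function(query, subject, same_strand = FALSE) {
  out <- list()
  for (i in seq_len(nrow(query))) for (j in seq_len(nrow(subject))) {
    if (query$chrom[[i]] != subject$chrom[[j]]) next
    if (same_strand && query$strand[[i]] != subject$strand[[j]]) next
    ov <- min(query$end[[i]], subject$end[[j]]) -
      max(query$start[[i]], subject$start[[j]])
    if (ov >= 1) out[[length(out) + 1]] <- c(i, j, ov)
  }
  if (!length(out)) {
    return(data.frame(query = integer(), subject = integer(),
                      overlap = integer()))
  }
  m <- do.call(rbind, out)
  df <- data.frame(query = m[, 1], subject = m[, 2], overlap = m[, 3])
  df[order(df$query, df$subject), ]
}

# Exact binomial upper tail by log-factorial summation.
oracle_binom_tail <- function(k, n, p) {
  if (k <= 0) return(1)
  kk <- k:n
  sum(exp(lgamma(n + 1) - lgamma(kk + 1) - lgamma(n - kk + 1) +
            kk * log(p) + (n - kk) * log(1 - p)))
}

# Exact trinomial strict-max probability by triple enumeration.
oracle_win_prob <- function(c_reads) {
  p <- 0
  for (x0 in 0:c_reads) for (x1 in 0:(c_reads - x0)) {
    x2 <- c_reads - x0 - x1
    if (x0 > x1 && x0 > x2) {
      p <- p + factorial(c_reads) / (factorial(x0) * factorial(x1) *
                                       factorial(x2)) * (1 / 3)^c_reads
    }
  }
  p
}

# Exhaustive nested-structure enumeration (maximum pairs, min loop 3,
# G-U allowed) by recursion over the last position's pairing choices.
oracle_max_pairs <- function(seq) {
  s <- strsplit(chartr("Uu", "TT", toupper(seq)), "")[[1]]
  pairs_ok <- function(a, b) paste0(a, b) %in%
    c("AT", "TA", "GC", "CG", "GT", "TG")
  rec <- function(i, j) {
    if (j - i < 4) return(0)
    best <- rec(i, j - 1)
    for (k in i:(j - 4)) {
      if (pairs_ok(s[[k]], s[[j]])) {
        left <- if (k > i) rec(i, k - 1) else 0
        best <- max(best, left + 1 + rec(k + 1, j - 1))
      }
    }
    best
  }
  if (length(s) < 5) return(0)
  rec(1, length(s))
}

# Random genomic interval set.
random_intervals <- function(n, span = 2000, strands = c("+", "-")) {
  start <- sample.int(span, n, replace = TRUE)
  width <- sample.int(30, n, replace = TRUE)
  tibble::tibble(chrom = "chr1", start = start, end = start + width,
                 strand = sample(strands, n, replace = TRUE))
}

# Random multi-exon map on one strand (transcript order).
random_exon_map <- function(n_exons = NULL, strand = NULL) {
  n_exons <- n_exons %||% sample(1:4, 1)
  strand <- strand %||% sample(c("+", "-"), 1)
  widths <- sample(5:60, n_exons, replace = TRUE)
  gaps <- sample(50:200, n_exons, replace = TRUE)
  starts <- 1000 + cumsum(gaps) + cumsum(c(0, head(widths, -1)))
  ex <- tibble::tibble(chrom = "chr1", start = starts,
                       end = starts + widths, strand = strand)
  if (strand == "-") ex <- ex[rev(seq_len(n_exons)), ]
  ex
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random transcript with a complete AUG-initiated CDS at a random frame.
random_transcript <- function(min_lead = 0, max_lead = 90) {
  lead <- paste(sample(c("A", "C", "G", "T"),
                       sample(min_lead:max_lead, 1), replace = TRUE),
                collapse = "")
  n_cds <- sample(3:20, 1)
  body <- c("ATG",
            sample(setdiff(names(Biostrings::GENETIC_CODE),
                           c("TAA", "TAG", "TGA")), n_cds - 2, replace = TRUE),
            sample(c("TAA", "TAG", "TGA"), 1))
  tibble::tibble(
    transcript_id = "tx", gene_id = "g",
    sequence = paste0(lead, paste(body, collapse = "")),
    cds_start = nchar(lead), cds_end = nchar(lead) + 3 * n_cds,
    length = nchar(lead) + 3 * n_cds,
    flags = list("complete_cds")
  )
}
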