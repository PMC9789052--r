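# Theoretical extension extraction, clipping, filtering, candidate starts.

tx_row <- function(sequence, cds_start, id = "tx", gene = "g",
                   flags = "complete_cds") {
  tibble::tibble(transcript_id = id, gene_id = gene, sequence = sequence,
                 cds_start = cds_start,
                 cds_end = cds_start +
                   3L * ((nchar(sequence) - cds_start) %/% 3L),
                 length = nchar(sequence), flags = list(flags))
}

test_that("upstream walk stops one codon 3' of the first in-frame stop", {
  ext <- extract_extensions(tx_row("TAACTGGCAATGGGG", 9L))
  expect_equal(ext$ext_start, 3L)
  expect_equal(ext$length_codons, 2L)
  expect_equal(ext$boundary, "stop_bounded")
})

test_that("without an in-frame stop the walk reaches the 5'-most full codon", {
  ext <- extract_extensions(tx_row("CCTGGCAATGGGG", 7L))
  expect_equal(ext$ext_start, 1L)
  expect_equal(ext$length_codons, 2L)
  expect_equal(ext$boundary, "edge_bounded")
})

test_that("zero-length extensions and gated transcripts are reported, not returned", {
  # stop codon immediately upstream of the start
  ext <- extract_extensions(tx_row("TAAATGGGGTAA", 3L))
  expect_equal(nrow(ext), 0L)
  expect_equal(attr(ext, "dropped")$reason, "zero_length")
  # too little 5' leader for a codon
  ext2 <- extract_extensions(tx_row("CCATGAAATAA", 2L))
  expect_equal(attr(ext2, "dropped")$reason, "zero_length")
  # non-AUG annotated start excluded by default, included on request
  nonatg <- tx_row("GGGCTGAAATAA", 3L,
                   flags = c("complete_cds", "non_atg_annotated"))
  expect_equal(attr(extract_extensions(nonatg), "dropped")$reason,
               "non_atg_annotated")
  expect_equal(nrow(extract_extensions(nonatg, include_non_atg = TRUE)), 1L)
})

test_that("extraction matches the exhaustive upstream-scan oracle on random transcripts", {
  set.seed(17)
  for (i in 1:300) {
    r <- random_transcript()
    got <- extract_extensions(r)
    want <- oracle_extension(r$sequence, r$cds_start)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(got$ext_start, want$ext_start)
      expect_equal(got$length_codons, want$length_codons)
      expect_equal(got$boundary, want$boundary)
    }
  }
})

test_that("extensions never contain an in-frame stop and extract+clip is idempotent", {
  set.seed(19)
  cfg <- sim_config(seed = 19, n_genes = 60)
  sim <- sim_transcriptome(cfg)
  ext <- clip_windows(extract_extensions(sim$transcripts), sim$transcripts)
  for (i in seq_len(nrow(ext))) {
    seq_i <- sim$transcripts$sequence[[
      match(ext$transcript_id[[i]], sim$transcripts$transcript_id)]]
    cods <- substring(seq_i,
                      seq(ext$ext_start[[i]] + 1, ext$cds_start[[i]] - 2, 3),
                      seq(ext$ext_start[[i]] + 3, ext$cds_start[[i]], 3))
    expect_false(any(cods %in% c("TAA", "TAG", "TGA")))
  }
  again <- clip_windows(extract_extensions(sim$transcripts), sim$transcripts)
  expect_identical(ext, again)
})

test_that("windows clip to at most 50 codons, abutting the annotated start", {
  lead <- paste(rep("GGC", 120), collapse = "")       # 120 codons, no stop
  seq_str <- paste0("TAA", lead, "ATG", strrep("AAA", 5), "TAA")
  ext <- extract_extensions(tx_row(seq_str, 3L + 360L))
  win <- clip_windows(ext, tx_row(seq_str, 3L + 360L))
  expect_equal(win$win_codons, 50L)
  expect_equal(win$win_start + 150L, win$cds_start)
  short <- extract_extensions(tx_row("TAACTGGCAATGGGG", 9L))
  expect_equal(clip_windows(short,
                            tx_row("TAACTGGCAATGGGG", 9L))$win_codons, 2L)
})

test_that("window genomic blocks conserve length over spliced structures", {
  cfg <- sim_config(seed = 23, n_genes = 40, spliced_fraction = 1)
  sim <- sim_transcriptome(cfg)
  win <- clip_windows(extract_extensions(sim$transcripts), sim$transcripts)
  for (i in seq_len(nrow(win))) {
    expect_equal(sum(win$blocks[[i]]$end - win$blocks[[i]]$start),
                 3L * win$win_codons[[i]])
  }
})

test_that("minimum-length filter keeps exactly the boundary", {
  ext <- tibble::tibble(transcript_id = c("a", "b"), gene_id = c("a", "b"),
                        ext_start = 0L, length_codons = c(19L, 20L),
                        boundary = "stop_bounded", cds_start = c(57L, 60L))
  kept <- filter_min_length(ext)
  expect_equal(kept$transcript_id, "b")
  expect_equal(attr(kept, "decisions")$keep, c(FALSE, TRUE))
})

test_that("coding-exon overlap drops on >= 1 shared same-strand base only", {
  win <- tibble::tibble(
    transcript_id = "tx", gene_id = "g",
    blocks = list(tibble::tibble(chrom = "chr1", start = 5000L, end = 5060L,
                                 strand = "+"))
  )
  foreign <- tibble::tibble(chrom = "chr1", start = 5059L, end = 5200L,
                            strand = "+", catalog = "other",
                            transcript_id = "other_tx")
  expect_equal(nrow(filter_coding_overlap(win, foreign)), 0L)
  ov <- attr(filter_coding_overlap(win, foreign), "overlaps")
  expect_equal(ov$catalog, "other")
  foreign$strand <- "-"
  expect_equal(nrow(filter_coding_overlap(win, foreign)), 1L)
  expect_equal(nrow(filter_coding_overlap(win, foreign,
                                          same_strand = FALSE)), 0L)
  # the transcript's own CDS exons are exempt
  own <- foreign
  own$strand <- "+"
  own$transcript_id <- "tx"
  expect_equal(nrow(filter_coding_overlap(win, own)), 1L)
})

test_that("planted overlap decoys are exactly the windows dropped", {
  cfg <- sim_config(seed = 29, n_genes = 80, n_overlap_decoys = 12,
                    n_short_ext = 0, n_zero_cov = 0)
  sim <- sim_transcriptome(cfg)
  win <- clip_windows(filter_min_length(extract_extensions(sim$transcripts)),
                      sim$transcripts)
  kept <- filter_coding_overlap(win, sim$coding_exons)
  victims <- sim$truth$transcript_id[sim$truth$class == "overlap_victim"]
  expect_setequal(setdiff(win$transcript_id, kept$transcript_id), victims)
})

test_that("gene collapse keeps the longest extension with deterministic ties", {
  ext <- tibble::tibble(
    transcript_id = c("t2", "t1", "t3"), gene_id = c("g", "g", "g"),
    ext_start = 0L, length_codons = c(30L, 30L, 10L),
    boundary = "stop_bounded", cds_start = c(90L, 90L, 30L)
  )
  expect_equal(collapse_genes(ext)$transcript_id, "t1")
})

test_that("candidate enumeration finds every in-frame palette codon 5' to 3'", {
  win <- tibble::tibble(transcript_id = "tx", gene_id = "g", win_start = 12L,
                        win_codons = 3L, win_seq = "CTGGCAACG")
  got <- enumerate_candidate_starts(win)
  expect_equal(got$position, c(12L, 18L))
  expect_equal(got$codon, c("CTG", "ACG"))
  expect_equal(got$codon_class, c("near_cognate", "near_cognate"))
  none <- win
  none$win_seq <- "GGGCCCGGG"
  expect_equal(nrow(enumerate_candidate_starts(none)), 0L)
})

test_that("candidate positions equal a sliding-frame oracle on random windows", {
  set.seed(37)
  pal <- c("ATG", "CTG", "GTG", "TTG", "ATA", "ATT", "ATC", "ACG", "AGG",
           "AAG")
  for (i in 1:50) {
    wc <- sample(5:40, 1)
    seq_i <- paste(sample(c("A", "C", "G", "T"), 3 * wc, replace = TRUE),
                   collapse = "")
    win <- tibble::tibble(transcript_id = "tx", gene_id = "g",
                          win_start = 0L, win_codons = wc, win_seq = seq_i)
    got <- enumerate_candidate_starts(win)$position
    want <- (which(vapply(seq_len(wc), function(k) {
      substr(seq_i, 3 * k - 2, 3 * k) %in% pal
    }, TRUE)) - 1L) * 3L
    expect_identical(got, want)
  }
})
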