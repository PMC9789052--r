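# Triplet-periodicity detector: profile I/O, frame counts, p-values,
# step score, calling and ranking.

test_that("profile loading aggregates across files and screens bad lines", {
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("transcript_id\tposition\tcount\tchannel",
               "tx1\t5\t3\telong",
               "tx1\t6\t1\tweird"), p1)
  writeLines(c("transcript_id\tposition\tcount\tchannel",
               "tx1\t5\t3\telong"), p2)
  prof <- read_ribo_profiles(c(p1, p2))
  expect_equal(prof$count[prof$position == 5], 6)
  expect_equal(sum(attr(prof, "report")$skipped), 1L)
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("transcript_id\tposition\tcount\tchannel",
               "tx1\t5\t-3\telong"), bad)
  expect_error(read_ribo_profiles(bad), "corrupt_profile")
})

test_that("frame counts honour the strict-maximum tie rule", {
  # 10 codons with (9,0,0)
  pos <- seq(0, 27, by = 3)
  fc <- frame_counts(pos, rep(9, 10), 0L, 30L)
  expect_equal(c(fc$F0, fc$F1, fc$F2), c(90, 0, 0))
  expect_equal(fc$occupied, 10L)
  expect_equal(fc$wins, 10L)
  # 10 codons with (3,3,3): all ties, no wins
  pos2 <- 0:29
  fc2 <- frame_counts(pos2, rep(3, 30), 0L, 30L)
  expect_equal(c(fc2$F0, fc2$F1, fc2$F2), c(30, 30, 30))
  expect_equal(fc2$wins, 0L)
})

test_that("frame counts equal a per-position brute-force tally on random profiles", {
  set.seed(41)
  for (i in 1:60) {
    L <- sample(3:30, 1)
    n <- sample(0:60, 1)
    pos <- sample(0:(3 * L + 20), n, replace = TRUE)
    cnt <- sample(1:5, n, replace = TRUE)
    fc <- frame_counts(pos, cnt, 0L, 3L * L)
    inside <- pos < 3 * L
    tally <- matrix(0, L, 3)
    for (k in which(inside)) {
      tally[pos[k] %/% 3 + 1, pos[k] %% 3 + 1] <-
        tally[pos[k] %/% 3 + 1, pos[k] %% 3 + 1] + cnt[k]
    }
    expect_equal(c(fc$F0, fc$F1, fc$F2), unname(colSums(tally)))
    expect_equal(fc$occupied, sum(rowSums(tally) > 0))
    expect_equal(fc$wins,
                 sum(rowSums(tally) > 0 &
                       tally[, 1] > pmax(tally[, 2], tally[, 3])))
  }
})

test_that("periodicity p-values match closed forms and exact enumeration", {
  fc <- frame_counts(seq(0, 27, 3), rep(9, 10), 0L, 30L)
  pv <- periodicity_pvalues(fc)
  expect_equal(pv$p_read, (1 / 3)^90, tolerance = 1e-12)
  # zero reads: defined null behaviour
  empty <- frame_counts(integer(), numeric(), 0L, 30L)
  expect_equal(periodicity_pvalues(empty), list(p_read = 1, p_codon = 1))
  # uniform (3,3,3) per codon: read tail at F0=30 of N=90, win prob at c=9
  fc3 <- frame_counts(0:29, rep(3, 30), 0L, 30L)
  pv3 <- periodicity_pvalues(fc3)
  expect_equal(pv3$p_read, oracle_binom_tail(30, 90, 1 / 3),
               tolerance = 1e-10)
  expect_equal(pv3$p_codon, 1, tolerance = 1e-10)  # wins = 0
})

test_that("null codon-win probabilities agree with independent enumeration", {
  for (c_reads in c(1, 2, 3, 7, 12)) {
    expect_equal(ntescan:::null_win_prob(c_reads), oracle_win_prob(c_reads),
                 tolerance = 1e-10)
  }
  expect_equal(ntescan:::null_win_prob(31), 1 / 3)
})

test_that("step score follows the regularised density-ratio formula", {
  # mu_down = 5 in-frame reads/codon over 4 codons, nothing upstream
  elong_pos <- seq(12, 21, by = 3)
  st <- start_step_score(elong_pos, rep(5, 4), integer(), numeric(),
                         cand_pos = 12L, ext_start = 12L, cds_start = 24L,
                         tx_len = 60L)
  expect_equal(st$sigma, 5.1 / 0.1)
  # uniform density: no step
  st2 <- start_step_score(seq(0, 21, 3), rep(2, 8), integer(), numeric(),
                          cand_pos = 12L, ext_start = 0L, cds_start = 24L,
                          tx_len = 60L)
  expect_equal(st2$sigma, 1)
})

test_that("sigma increases monotonically with the planted step multiplier", {
  meds <- vapply(c(1, 2, 5, 10), function(sm) {
    cfg <- sim_config(seed = 43, n_genes = 80, frac_true_nte = 1,
                      step_mult = sm, n_short_ext = 0, n_zero_cov = 0,
                      n_overlap_decoys = 0)
    sim <- sim_transcriptome(cfg)
    prof <- sim_ribo_profiles(sim, cfg)
    ext <- clip_windows(extract_extensions(sim$transcripts), sim$transcripts)
    cands <- enumerate_candidate_starts(ext)
    rk <- call_and_rank(prof, ext, cands, sim$transcripts)
    median(rk$sigma)
  }, 0)
  expect_true(all(diff(meds) > 0))
})

test_that("median combined p-value never increases with frame bias", {
  meds <- vapply(c(0.34, 0.5, 0.65, 0.8), function(pf) {
    cfg <- sim_config(seed = 47, n_genes = 60, frac_true_nte = 1,
                      p_frame = pf, depth = 8, noise_rate = 0,
                      n_short_ext = 0, n_zero_cov = 0, n_overlap_decoys = 0)
    sim <- sim_transcriptome(cfg)
    prof <- sim_ribo_profiles(sim, cfg)
    ext <- extract_extensions(sim$transcripts)
    # score the translated part of each extension (planted start to AUG)
    m <- match(ext$transcript_id, sim$truth$transcript_id)
    ext$ext_start <- sim$truth$true_start[m]
    sc <- score_extension_regions(prof, ext)
    median(sc$p_comb)
  }, 0)
  expect_true(all(diff(meds) <= 0))
})

test_that("calling prefers the periodic candidate and ranking breaks ties by density", {
  # transcript: ext codons 0..29 (10 codons), CDS at 30
  ext <- tibble::tibble(transcript_id = c("txA", "txB"),
                        gene_id = c("gA", "gB"),
                        ext_start = 0L, length_codons = 10L,
                        boundary = "stop_bounded", cds_start = 30L)
  cands <- tibble::tibble(
    transcript_id = c("txA", "txA", "txB"),
    gene_id = c("gA", "gA", "gB"),
    position = c(0L, 15L, 0L),
    codon = c("CTG", "GTG", "CTG"),
    codon_class = "near_cognate"
  )
  transcripts <- tibble::tibble(transcript_id = c("txA", "txB"),
                                length = 90L)
  # txA: strongly periodic from 15, noisy before; txB periodic from 0
  prof <- tibble::tibble(
    transcript_id = c(rep("txA", 5 + 3), rep("txB", 10)),
    channel = "elong",
    position = c(c(1, 4, 8, 11, 13), seq(15, 21, 3),
                 seq(0, 27, 3)),
    count = c(rep(1, 5), rep(20, 3), rep(20, 10))
  )
  rk <- call_and_rank(prof, ext, cands, transcripts,
                      config = nte_config(min_inframe_reads = 3))
  expect_equal(rk$position[rk$transcript_id == "txA"], 15L)
  # ranks are a permutation and order by p_comb then density
  expect_setequal(rk$rank, seq_len(nrow(rk)))
  expect_true(rk$rank[rk$transcript_id == "txB"] <
                rk$rank[rk$transcript_id == "txA"] ||
                rk$p_comb[rk$transcript_id == "txB"] >
                rk$p_comb[rk$transcript_id == "txA"])
})

test_that("zero-coverage transcripts are never called", {
  cfg <- sim_config(seed = 53, n_genes = 40, n_zero_cov = 10,
                    n_short_ext = 0, n_overlap_decoys = 0)
  sim <- sim_transcriptome(cfg)
  prof <- sim_ribo_profiles(sim, cfg)
  ext <- clip_windows(extract_extensions(sim$transcripts), sim$transcripts)
  rk <- call_and_rank(prof, ext, enumerate_candidate_starts(ext),
                      sim$transcripts)
  zero <- sim$truth$transcript_id[sim$truth$class == "zero_cov"]
  expect_length(intersect(rk$transcript_id, zero), 0L)
  expect_setequal(rk$rank, seq_len(nrow(rk)))
})
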