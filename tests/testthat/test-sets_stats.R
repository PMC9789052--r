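# Gene-set construction and comparison statistics.

test_that("ribosome-supported set respects the rank threshold and AUG exclusion", {
  set.seed(67)
  n <- 620
  ranked <- tibble::tibble(
    transcript_id = sprintf("t%03d", 1:n),
    gene_id = sprintf("g%03d", 1:n),
    codon = "CTG", aug_called = FALSE, rank = 1:n
  )
  aug_rows <- sample(500, 30)
  ranked$aug_called[aug_rows] <- TRUE
  ranked$codon[aug_rows] <- "ATG"
  rs <- build_riboset(ranked, top_n = 500)
  expect_length(rs$members, 470L)
  expect_equal(rs$params$top_n, 500)
  expect_equal(rs$params$post_filter_n, 470L)
  expect_warning(build_riboset(ranked, top_n = 5000), "using all")
  expect_warning(empty <- build_riboset(ranked[0, ]), "empty")
  expect_length(empty$members, 0L)
})

test_that("hypergeometric overlap matches exact enumeration and enforces the universe", {
  universe <- sprintf("g%02d", 1:10)
  a <- gene_set("A", universe[1:4])
  b <- gene_set("B", universe[c(1, 2, 3, 7, 8)])   # overlap 3
  res <- hypergeom_overlap(list(a, b), universe)
  expect_equal(res$overlap, 3L)
  expect_equal(res$p_raw, 66 / 252, tolerance = 1e-12)
  # degenerate empty set
  res0 <- hypergeom_overlap(list(a, gene_set("E", character())), universe)
  expect_equal(res0$p_raw, 1)
  expect_error(
    hypergeom_overlap(list(gene_set("X", "not_in_universe"), b), universe),
    "universe_violation")
})

test_that("hypergeometric tail agrees with Monte-Carlo sampling within 3 SE", {
  set.seed(71)
  for (i in 1:4) {
    U <- sample(20:60, 1)
    na <- sample(3:10, 1)
    nb <- sample(3:12, 1)
    universe <- sprintf("u%03d", 1:U)
    a_m <- sample(universe, na)
    b_m <- sample(universe, nb)
    k <- length(intersect(a_m, b_m))
    p <- hypergeom_overlap(list(gene_set("a", a_m), gene_set("b", b_m)),
                           universe)$p_raw
    draws <- 1e5
    sim <- vapply(seq_len(draws), function(j) {
      length(intersect(sample(U, na), sample(U, nb))) >= k
    }, TRUE)
    mc <- mean(sim)
    se <- sqrt(mc * (1 - mc) / draws)
    expect_lt(abs(p - mc), 3 * max(se, 1e-4))
  }
})

test_that("BH adjustment is monotone in the raw p-values", {
  set.seed(73)
  universe <- sprintf("u%03d", 1:50)
  sets <- lapply(1:5, function(i) gene_set(paste0("s", i),
                                           sample(universe, sample(5:15, 1))))
  res <- hypergeom_overlap(sets, universe)
  ord <- order(res$p_raw)
  expect_true(all(diff(res$p_adj[ord]) >= -1e-12))
  expect_true(all(res$p_adj >= res$p_raw))
})

test_that("rank sweep increments sum to the total overlap and handle edge placements", {
  ranked <- tibble::tibble(
    transcript_id = sprintf("t%03d", 1:40),
    gene_id = sprintf("g%03d", 1:40),
    aug_called = FALSE, rank = 1:40
  )
  ref_in_bin1 <- gene_set("ref", sprintf("g%03d", 1:6))
  rs <- rank_sweep(ranked, ref_in_bin1, step = 10)
  expect_equal(rs$observed, c(6L, 0L, 0L, 0L))
  expect_equal(sum(rs$observed), rs$overlap_total)
  absent <- gene_set("ref", sprintf("x%03d", 1:6))
  expect_equal(rank_sweep(ranked, absent, step = 10)$observed, rep(0L, 4))
})

test_that("planted rank enrichment is detected by the sweep test", {
  set.seed(79)
  n <- 10000
  ranked <- tibble::tibble(
    transcript_id = sprintf("t%05d", 1:n),
    gene_id = sprintf("g%05d", 1:n),
    aug_called = FALSE, rank = 1:n
  )
  # rank-decaying placement: most reference genes land in the swept range,
  # so per-bin gains sit above the uniform expectation throughout it
  ref_genes <- c(ranked$gene_id[sample(5000, 180)],
                 ranked$gene_id[5000 + sample(5000, 20)])
  rs <- rank_sweep(ranked, gene_set("ref", ref_genes), step = 500,
                   max_rank = 5000)
  expect_lt(rs$test_p, 0.05)
  expect_gt(rs$observed[1], rs$expected[1])
  expect_equal(sum(rs$observed), 180L)
})

test_that("rank/coverage correlation recovers planted anti-monotonicity and rejects degenerate input", {
  dens <- tibble::tibble(transcript_id = sprintf("t%02d", 1:20),
                         density = 2^(20:1))
  ranked <- tibble::tibble(transcript_id = sprintf("t%02d", 1:20),
                           rank = 1:20)
  res <- rank_vs_coverage(ranked, dens)
  expect_equal(res$rho, -1)
  expect_error(rank_vs_coverage(ranked[1:3, ], dens), "insufficient_n")
  dens$density <- 5
  expect_error(rank_vs_coverage(ranked, dens), "degenerate")
})

test_that("lower-expressed genes rank lower: generated cohorts give strong negative rank/coverage correlation", {
  cfg <- sim_config(seed = 163, n_genes = 200, frac_true_nte = 0.3,
                    n_short_ext = 0, n_zero_cov = 0, n_overlap_decoys = 0)
  sim <- sim_transcriptome(cfg)
  prof <- sim_ribo_profiles(sim, cfg)
  ext <- clip_windows(extract_extensions(sim$transcripts), sim$transcripts)
  rk <- call_and_rank(prof, ext, enumerate_candidate_starts(ext),
                      sim$transcripts)
  rc <- rank_vs_coverage(rk, cds_coverage(prof, sim$transcripts))
  expect_lt(rc$rho, -0.5)
})

test_that("untranslated-set rules fire in order with boundary-exact thresholds", {
  # 9 transcripts: one failing each rule 1..7 plus two clean ones
  mk_tx <- function(id, gene, flags = "complete_cds") {
    tibble::tibble(transcript_id = id, gene_id = gene,
                   sequence = NA_character_, cds_start = 60L, cds_end = 360L,
                   length = 400L, flags = list(flags))
  }
  tx <- dplyr::bind_rows(
    mk_tx("f1", "G1", flags = c("cds_incomplete")),
    mk_tx("f2", "G2"), mk_tx("f3", "G3"), mk_tx("f4", "G4"),
    mk_tx("f5", "G5"), mk_tx("f6", "G6"), mk_tx("f7", "G7"),
    mk_tx("ok1", "G8"), mk_tx("ok2", "G8")
  )
  ext <- tibble::tibble(
    transcript_id = c("f1", "f2", "f4", "f5", "f6", "f7", "ok1", "ok2"),
    gene_id = c("G1", "G2", "G4", "G5", "G6", "G7", "G8", "G8"),
    ext_start = 0L,
    length_codons = 20L,     # exactly the threshold: rule 3 passes
    boundary = "stop_bounded", cds_start = 60L
  )                           # f3 has no extension record -> fails rule 3
  cds_len <- 300L
  n_codons <- 100L
  prof_rows <- list()
  add <- function(tx_id, pos, cnt) {
    prof_rows[[length(prof_rows) + 1L]] <<-
      tibble::tibble(transcript_id = tx_id, channel = "elong",
                     position = pos, count = cnt)
  }
  # well-translated CDS: 100 in-frame reads (density exactly 1.0, rule 6
  # boundary) over >= 30% of CDS positions (exactly 0.3: 90 covered)
  covered_cds <- function(tx_id) {
    pos <- 60L + seq(0L, by = 3L, length.out = 90L)    # 90 distinct in-frame
    add(tx_id, pos, c(rep(2, 10), rep(1, 80)))          # 100 reads
  }
  for (id in c("f1", "f2", "f3", "f4", "ok1", "ok2")) covered_cds(id)
  # f5: extension coverage fraction just above 0.0005 (1 covered / 60 nt)
  covered_cds("f5"); add("f5", 5L, 1)
  # f6: CDS density just below 1 (99 reads / 100 codons)
  add("f6", 60L + seq(0L, by = 3L, length.out = 99L), rep(1, 99))
  add("f6", 61L, 200)  # keeps covered fraction >= 0.3 without in-frame reads
  # f7: density fine but covered fraction below 0.3
  add("f7", 60L + seq(0L, by = 3L, length.out = 50L), rep(3, 50))
  profiles <- dplyr::bind_rows(prof_rows)
  us <- build_untranslset(
    tx, ext, profiles,
    predicted = tibble::tibble(transcript_id = "f4", gene_id = "G4"),
    overlapping_ids = "f2"
  )
  att <- attr(us, "attrition")
  expect_equal(att$failed, rep(1L, 7))
  expect_equal(att$remaining[7], 2L)
  # exactly one transcript per gene survives, highest CDS coverage first
  expect_equal(us$members, "G8")
  expect_equal(nrow(attr(us, "selected")), 1L)
})

test_that("boundary values 0.0005, 1.0 and 0.3 are themselves accepted", {
  tx <- tibble::tibble(transcript_id = "t", gene_id = "G",
                       sequence = NA_character_, cds_start = 6000L,
                       cds_end = 6300L, length = 6400L,
                       flags = list("complete_cds"))
  ext <- tibble::tibble(transcript_id = "t", gene_id = "G", ext_start = 0L,
                        length_codons = 2000L, boundary = "stop_bounded",
                        cds_start = 6000L)
  # extension: exactly 3 covered positions / 6000 nt = 0.0005
  prof <- dplyr::bind_rows(
    tibble::tibble(transcript_id = "t", channel = "elong",
                   position = c(7L, 13L, 22L), count = 1),
    tibble::tibble(transcript_id = "t", channel = "elong",
                   position = 6000L + seq(0L, by = 3L, length.out = 90L),
                   count = c(rep(2, 10), rep(1, 80)))
  )
  us <- build_untranslset(tx, ext, prof,
                          predicted = tibble::tibble(transcript_id = character(),
                                                     gene_id = character()))
  expect_equal(us$members, "G")
})

test_that("set construction is pure: same inputs give identical sets", {
  ranked <- tibble::tibble(transcript_id = sprintf("t%02d", 1:30),
                           gene_id = sprintf("g%02d", 1:30),
                           aug_called = rep(c(FALSE, TRUE), 15), rank = 1:30)
  s1 <- build_riboset(ranked, top_n = 20)
  s2 <- build_riboset(ranked, top_n = 20)
  expect_identical(s1, s2)
})

test_that("variant overlap converts VCF positions and honours the class filter", {
  win <- tibble::tibble(
    transcript_id = "tx", gene_id = "g",
    blocks = list(tibble::tibble(chrom = "chr1", start = 5000L, end = 5060L,
                                 strand = "+"))
  )
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=CLNSIG,Number=.,Type=String,Description=\"x\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr1\t5001\tv1\tA\tG\t.\t.\tCLNSIG=Pathogenic",
               "chr1\t5061\tv2\tA\tG\t.\t.\tCLNSIG=Pathogenic",
               "chr1\t5010\tv3\tA\tG\t.\t.\tCLNSIG=Benign"), vcf)
  hits <- intersect_variants(win, vcf)
  expect_setequal(hits$variant_id, c("v1", "v3"))  # 5061 -> 0-based 5060, outside
  path_only <- intersect_variants(win, vcf, classes = "Pathogenic")
  expect_equal(path_only$variant_id, "v1")
})

test_that("planted variants inside windows are recovered exactly", {
  cfg <- sim_config(seed = 83, n_genes = 50)
  sim <- sim_transcriptome(cfg)
  win <- clip_windows(filter_min_length(extract_extensions(sim$transcripts)),
                      sim$transcripts)
  vars <- sim_variants(win, cfg, n_inside = 25L, n_outside = 25L)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_file(vars, vcf)
  hits <- intersect_variants(win, vcf)
  expect_setequal(hits$variant_id, vars$variant_id[vars$inside])
})
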