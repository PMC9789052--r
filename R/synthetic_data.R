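# Seeded synthetic-data generator. Emits every input dialect the pipeline
# consumes (gencode_pc FASTA, GTF, P-site profile TSV, reference-anchored
# MAF, VCF, TIS table TSV) together with ground truth for every gene, so
# detector calibration, power, and scorer separation can be measured
# against known truth. Read counts are drawn per codon and then
# distributed over the three frames, which directly parameterises the
# periodicity signal the detector tests. The alignment simulator uses a
# star topology; it exercises the pairwise-to-reference scorer and is not
# a phylogeny emulator.

#' Simulation configuration
#'
#' Defaults are the package's reference study conditions: a cohort of 500
#' genes, 10% carrying a genuine near-cognate extension, elongating depth
#' 10 reads/codon at frame-0 probability 0.8, a 5-fold density step at the
#' true start, and 10-species alignments at 0.3 substitutions per codon
#' per branch evolved under strong purifying selection (omega 0.1) for
#' true extensions and neutrally (omega 1) otherwise.
#'
#' @param seed Integer seed; all generator functions derive their RNG
#'   stream from it, so every output is byte-reproducible.
#' @param n_genes Number of genes.
#' @param frac_true_nte Fraction of genes with a planted true extension.
#' @param start_palette Named weights over non-AUG start codons for
#'   planted true starts.
#' @param ext_len_range Theoretical extension length range, codons.
#' @param cds_len_range CDS length range, codons (incl. start and stop).
#' @param depth Elongating reads per codon in translated regions.
#' @param depth_spread Per-gene expression variation: each gene's depth is
#'   scaled by a mean-1 log-normal multiplier with this log-scale standard
#'   deviation (0 = uniform expression). Drives the coverage-dependent
#'   ranking the rank/coverage statistics measure.
#' @param p_frame Frame-0 probability for translated reads.
#' @param step_mult Density step at the true start: upstream-of-start leak
#'   depth is `depth / step_mult`.
#' @param init_peak Initiating-channel reads placed at each used start.
#' @param noise_rate Poisson background reads per nucleotide.
#' @param decoy_ext_depth Equal-frame reads per codon filling the
#'   extensions of non-true genes (0 = noise only; used for null
#'   calibration cohorts).
#' @param n_species,t_branch,omega_coding,omega_neutral Alignment
#'   simulator parameters (star tree; per-branch substitutions/codon).
#' @param n_short_ext,n_zero_cov,n_overlap_decoys Planted decoy counts:
#'   short-extension genes, zero-coverage genes, and genes whose window is
#'   overlapped by a decoy coding exon.
#' @param strong_context_prob Probability that a planted true start gets a
#'   favourable initiation context (G at position +4), against the uniform
#'   0.25 background.
#' @param spliced_fraction Fraction of genes given multi-exon structures.
#' @param maf_split Split each MAF block mid-window (exercises stitching)?
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 500L,
                       frac_true_nte = 0.1,
                       start_palette = c(CTG = 0.35, GTG = 0.20, ACG = 0.12,
                                         TTG = 0.10, ATT = 0.06, ATA = 0.05,
                                         ATC = 0.05, AGG = 0.035, AAG = 0.035),
                       ext_len_range = c(20L, 120L),
                       cds_len_range = c(60L, 200L),
                       depth = 10,
                       depth_spread = 0.5,
                       p_frame = 0.8,
                       step_mult = 5,
                       init_peak = 20,
                       noise_rate = 0.02,
                       decoy_ext_depth = 0,
                       n_species = 10L,
                       t_branch = 0.3,
                       omega_coding = 0.1,
                       omega_neutral = 1.0,
                       n_short_ext = 20L,
                       n_zero_cov = 10L,
                       n_overlap_decoys = 10L,
                       strong_context_prob = 0.8,
                       spliced_fraction = 0.3,
                       maf_split = FALSE) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              frac_true_nte = frac_true_nte, start_palette = start_palette,
              ext_len_range = ext_len_range, cds_len_range = cds_len_range,
              depth = depth, depth_spread = depth_spread,
              p_frame = p_frame, step_mult = step_mult,
              init_peak = init_peak, noise_rate = noise_rate,
              decoy_ext_depth = decoy_ext_depth,
              n_species = as.integer(n_species), t_branch = t_branch,
              omega_coding = omega_coding, omega_neutral = omega_neutral,
              n_short_ext = as.integer(n_short_ext),
              n_zero_cov = as.integer(n_zero_cov),
              n_overlap_decoys = as.integer(n_overlap_decoys),
              strong_context_prob = strong_context_prob,
              spliced_fraction = spliced_fraction, maf_split = maf_split)
  stopifnot(cfg$frac_true_nte >= 0, cfg$frac_true_nte <= 1,
            cfg$p_frame >= 0, cfg$p_frame <= 1)
  cfg$hash <- config_hash(cfg[setdiff(names(cfg), "hash")])
  class(cfg) <- "sim_config"
  cfg
}

NONSTOP_CODONS <- setdiff(ALL_CODONS, STOP_CODONS)

random_codons <- function(n, exclude = character()) {
  pool <- setdiff(NONSTOP_CODONS, exclude)
  sample(pool, n, replace = TRUE)
}

# Lay a transcript of total length len onto the genome starting at
# `offset`, as `n_exons` exons separated by 200-nt introns. Returns the
# exon tibble in transcript (5'->3') order.
layout_exons <- function(len, offset, strand, n_exons, chrom = "chr1") {
  cuts <- if (n_exons > 1L) {
    sort(sample(seq_len(len - 1L), n_exons - 1L))
  } else integer()
  widths <- diff(c(0L, cuts, len))
  intron <- 200L
  if (strand == "+") {
    starts <- offset + cumsum(c(0L, head(widths, -1L) + intron))
    tibble(chrom = chrom, start = starts, end = starts + widths,
           strand = strand)
  } else {
    # transcript 5' end sits at the highest genomic coordinates
    span <- sum(widths) + intron * (n_exons - 1L)
    ends <- offset + span - cumsum(c(0L, head(widths, -1L) + intron))
    tibble(chrom = chrom, start = ends - widths, end = ends, strand = strand)
  }
}

#' Generate a synthetic transcriptome with ground truth
#'
#' Builds `n_genes` protein-coding transcripts, each with a complete
#' AUG-initiated CDS, a stop-bounded theoretical extension of known
#' length, and genomic exon structures (a mix of single- and multi-exon
#' genes on both strands). True-extension genes carry a planted in-frame
#' near-cognate start with no intervening in-frame stop before the AUG.
#' Decoy classes are planted per the configuration: short extensions
#' (below the length filter), zero-coverage genes, and decoy genes whose
#' coding exon overlaps a victim's extension window on the same strand.
#'
#' @param cfg A [sim_config()].
#' @return List: `transcripts` (parse-compatible tibble with `exons` and
#'   `structure`), `truth` (per-gene ground truth), `coding_exons`
#'   (catalog tibble for the overlap filter).
#' @export
sim_transcriptome <- function(cfg) {
  set.seed(cfg$seed + 101L)
  n <- cfg$n_genes
  classes <- rep("null", n)
  n_true <- round(cfg$frac_true_nte * n)
  special <- sample(n, min(n, n_true + cfg$n_short_ext + cfg$n_zero_cov +
                             cfg$n_overlap_decoys))
  classes[special[seq_len(n_true)]] <- "true"
  used <- n_true
  take <- function(k) {
    idx <- special[used + seq_len(min(k, length(special) - used))]
    used <<- used + length(idx)
    idx
  }
  classes[take(cfg$n_short_ext)] <- "short_ext"
  classes[take(cfg$n_zero_cov)] <- "zero_cov"
  classes[take(cfg$n_overlap_decoys)] <- "overlap_victim"

  tx_rows <- vector("list", n)
  truth_rows <- vector("list", n)
  extra_rows <- list()   # decoy genes added for overlap victims
  gene_pitch <- 20000L

  for (i in seq_len(n)) {
    cls <- classes[[i]]
    gid <- sprintf("GENE%04d", i)
    tid <- sprintf("TX%04d", i)
    ext_len <- if (cls == "short_ext") {
      sample(5:(min(cfg$ext_len_range[[1L]], 20L) - 1L), 1L)
    } else {
      sample(cfg$ext_len_range[[1L]]:cfg$ext_len_range[[2L]], 1L)
    }
    cds_len <- sample(cfg$cds_len_range[[1L]]:cfg$cds_len_range[[2L]], 1L)
    pad <- sample(0:2, 1L)
    # extension codons never AUG (keeps planted starts unambiguous at the
    # gene level); near-cognates may occur by chance
    ext_cod <- random_codons(ext_len, exclude = "ATG")
    is_true <- cls == "true"
    true_up <- NA_integer_
    true_codon <- NA_character_
    if (is_true) {
      true_up <- sample(8:min(ext_len, 50L), 1L)  # codons upstream of AUG
      true_codon <- sample(names(cfg$start_palette), 1L,
                           prob = cfg$start_palette)
      ext_cod[[ext_len - true_up + 1L]] <- true_codon
      # favourable Kozak-like context: G at +4 (first base of next codon)
      if (runif(1) < cfg$strong_context_prob) {
        nxt_i <- ext_len - true_up + 2L
        g_pool <- grep("^G", setdiff(NONSTOP_CODONS, "ATG"), value = TRUE)
        if (nxt_i <= ext_len) {
          ext_cod[[nxt_i]] <- sample(g_pool, 1L)
        }
      }
    }
    cds_cod <- c("ATG", random_codons(cds_len - 2L), sample(STOP_CODONS, 1L))
    utr3 <- paste(sample(c("A", "C", "G", "T"), 30L, replace = TRUE),
                  collapse = "")
    seq_str <- paste0(
      paste(sample(c("A", "C", "G", "T"), pad, replace = TRUE), collapse = ""),
      "TAA", paste(ext_cod, collapse = ""), paste(cds_cod, collapse = ""),
      utr3
    )
    ext_start <- pad + 3L
    cds_start <- ext_start + 3L * ext_len
    cds_end <- cds_start + 3L * cds_len
    len <- nchar(seq_str)
    strand <- if (i %% 2L == 0L) "-" else "+"
    n_exons <- if (runif(1) < cfg$spliced_fraction) sample(2:3, 1L) else 1L
    exons <- layout_exons(len, (i - 1L) * gene_pitch + 1000L, strand, n_exons)

    tx_rows[[i]] <- tibble(
      transcript_id = tid, gene_id = gid, sequence = seq_str,
      cds_start = cds_start, cds_end = cds_end, length = len,
      flags = list("complete_cds"), exons = list(exons), structure = "ok"
    )
    truth_rows[[i]] <- tibble(
      gene_id = gid, transcript_id = tid, class = cls, is_true_nte = is_true,
      true_start = if (is_true) cds_start - 3L * true_up else NA_integer_,
      true_codon = true_codon, ext_start = ext_start,
      ext_len_codons = ext_len, cds_start = cds_start, cds_end = cds_end,
      strand = strand, regime = if (is_true) "coding" else "neutral"
    )

    if (cls == "overlap_victim") {
      # decoy gene whose CDS exon overlaps this window's 3'-most block
      win_start <- cds_start - 3L * min(ext_len, 50L)
      blocks <- map_to_genome(exons, win_start, cds_start)
      tgt <- blocks[nrow(blocks), ]
      d_gid <- sprintf("DECOY%04d", i)
      d_tid <- sprintf("DTX%04d", i)
      d_cds_len <- 40L
      d_seq <- paste0(
        paste(c("ATG", random_codons(d_cds_len - 2L),
                sample(STOP_CODONS, 1L)), collapse = ""))
      d_len <- nchar(d_seq)
      d_start <- max(tgt$start - 60L, 0L)
      d_ex <- tibble(chrom = tgt$chrom, start = d_start,
                     end = d_start + d_len, strand = tgt$strand)
      extra_rows[[length(extra_rows) + 1L]] <- tibble(
        transcript_id = d_tid, gene_id = d_gid, sequence = d_seq,
        cds_start = 0L, cds_end = d_len - (d_len %% 3L),
        length = d_len, flags = list("complete_cds"),
        exons = list(d_ex), structure = "ok"
      )
    }
  }

  transcripts <- bind_rows(c(tx_rows, extra_rows))
  # decoy CDS length must be a triplet; trim sequence bookkeeping
  transcripts$cds_end <- pmin(transcripts$cds_end, transcripts$length)
  truth <- bind_rows(truth_rows)
  truth$config_hash <- cfg$hash

  cds_blocks <- vector("list", nrow(transcripts))
  for (i in seq_len(nrow(transcripts))) {
    cds_blocks[[i]] <- map_to_genome(transcripts$exons[[i]],
                                     transcripts$cds_start[[i]],
                                     transcripts$cds_end[[i]]) |>
      mutate(catalog = "sim_v1",
             transcript_id = transcripts$transcript_id[[i]])
  }
  list(transcripts = transcripts, truth = truth,
       coding_exons = bind_rows(cds_blocks))
}

# Draw frame-distributed per-codon reads over codon starts `starts`
# (transcript positions) and return a position->count tibble.
draw_codon_reads <- function(starts, depth, p_frame) {
  n_reads <- rpois(length(starts), depth)
  keep <- n_reads > 0
  if (!any(keep)) return(list(position = integer(), count = numeric()))
  s <- starts[keep]
  nr <- n_reads[keep]
  # vectorised multinomial split over the three frames
  p0 <- p_frame
  p1 <- (1 - p_frame) / 2
  x0 <- stats::rbinom(length(nr), nr, p0)
  x1 <- stats::rbinom(length(nr), nr - x0, ifelse(p0 < 1, p1 / (1 - p0), 0))
  x2 <- nr - x0 - x1
  pos <- c(s, s + 1L, s + 2L)
  cnt <- c(x0, x1, x2)
  nz <- cnt > 0
  list(position = pos[nz], count = cnt[nz])
}

#' Generate P-site profiles for a synthetic transcriptome
#'
#' Translated regions (each CDS; for true-extension genes also the region
#' from the planted start to the CDS) receive per-codon Poisson reads
#' distributed over the three frames with frame-0 probability `p_frame`.
#' The region of the extension upstream of a true start receives
#' equal-frame reads at `depth / step_mult` (the density step the detector
#' scores). Extensions of non-true genes receive equal-frame reads at
#' `decoy_ext_depth` (0 by default). Uniform Poisson noise covers every
#' transcript except planted zero-coverage decoys, which receive nothing.
#' The initiating channel places a read peak at every used start.
#'
#' @param transcriptome Output of [sim_transcriptome()].
#' @param cfg The same [sim_config()].
#' @return Profile tibble (`transcript_id`, `channel`, `position`,
#'   `count`) ordered as [read_ribo_profiles()] returns it. Attribute
#'   `"expected"`: per-transcript expected totals (generator bookkeeping).
#' @export
sim_ribo_profiles <- function(transcriptome, cfg) {
  set.seed(cfg$seed + 202L)
  truth <- transcriptome$truth
  tx <- transcriptome$transcripts
  pieces <- vector("list", nrow(truth))
  expected <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    if (tr$class == "zero_cov") next
    len <- tx$length[[match(tr$transcript_id, tx$transcript_id)]]
    # per-gene expression level: mean-1 log-normal multiplier on the
    # translated depth (the decoy null depth stays fixed by design)
    expr <- if (cfg$depth_spread > 0) {
      exp(stats::rnorm(1L, -cfg$depth_spread^2 / 2, cfg$depth_spread))
    } else 1
    depth_i <- cfg$depth * expr
    elong <- list()
    cds_codons <- seq.int(tr$cds_start, tr$cds_end - 3L, by = 3L)
    elong[[1L]] <- draw_codon_reads(cds_codons, depth_i, cfg$p_frame)
    if (tr$is_true_nte) {
      nte_codons <- seq.int(tr$true_start, tr$cds_start - 3L, by = 3L)
      elong[[2L]] <- draw_codon_reads(nte_codons, depth_i, cfg$p_frame)
      if (tr$true_start > tr$ext_start) {
        up_codons <- seq.int(tr$ext_start, tr$true_start - 3L, by = 3L)
        elong[[3L]] <- draw_codon_reads(up_codons, depth_i / cfg$step_mult,
                                        1 / 3)
      }
    } else if (cfg$decoy_ext_depth > 0 && tr$cds_start > tr$ext_start) {
      ext_codons <- seq.int(tr$ext_start, tr$cds_start - 3L, by = 3L)
      elong[[2L]] <- draw_codon_reads(ext_codons, cfg$decoy_ext_depth, 1 / 3)
    }
    # background reads land within the translated span: 5' leaders outside
    # a translated extension genuinely carry near-zero footprint density
    noise_from <- if (tr$is_true_nte) tr$true_start else tr$cds_start
    noise_span <- tr$cds_end - noise_from
    noise_n <- rpois(1L, cfg$noise_rate * noise_span)
    if (noise_n > 0) {
      elong[[length(elong) + 1L]] <- list(
        position = noise_from + sample.int(noise_span, noise_n,
                                           replace = TRUE) - 1L,
        count = rep(1, noise_n)
      )
    }
    e_pos <- unlist(lapply(elong, `[[`, "position"))
    e_cnt <- unlist(lapply(elong, `[[`, "count"))

    init_pos <- c(tr$cds_start, if (tr$is_true_nte) tr$true_start)
    init_cnt <- rpois(length(init_pos), cfg$init_peak)

    pieces[[i]] <- list(
      transcript_id = tr$transcript_id,
      position = c(e_pos, init_pos),
      count = c(e_cnt, init_cnt),
      channel = rep(c("elong", "init"), c(length(e_pos), length(init_pos)))
    )
    exp_elong <- depth_i * length(cds_codons) + cfg$noise_rate * noise_span
    if (tr$is_true_nte) {
      exp_elong <- exp_elong + depth_i * (tr$cds_start - tr$true_start) / 3 +
        (depth_i / cfg$step_mult) * (tr$true_start - tr$ext_start) / 3
    } else {
      exp_elong <- exp_elong +
        cfg$decoy_ext_depth * (tr$cds_start - tr$ext_start) / 3
    }
    expected[[i]] <- tibble(transcript_id = tr$transcript_id,
                            expected_elong = exp_elong)
  }
  pieces <- pieces[!vapply(pieces, is.null, TRUE)]
  flat <- tibble(
    transcript_id = rep(vapply(pieces, `[[`, "", "transcript_id"),
                        vapply(pieces, function(p) length(p$position), 0L)),
    channel = unlist(lapply(pieces, `[[`, "channel")),
    position = unlist(lapply(pieces, `[[`, "position")),
    count = unlist(lapply(pieces, `[[`, "count"))
  )
  out <- flat[flat$count > 0, ] |>
    group_by(.data$transcript_id, .data$channel, .data$position) |>
    summarise(count = sum(.data$count), .groups = "drop")
  attr(out, "expected") <- bind_rows(expected)
  out
}

#' Simulate one codon alignment under a coding or neutral regime
#'
#' Star phylogeny: each non-reference species evolves independently from
#' the reference. Per species and codon, a Poisson(`t`) number of
#' single-nucleotide mutation events is proposed; nonsynonymous proposals
#' are accepted with probability `omega`, and proposals creating a stop
#' codon are rejected under the coding regime.
#'
#' @param ref_codons Character vector of reference codons.
#' @param n_species Number of non-reference species.
#' @param t Expected substitution proposals per codon per branch.
#' @param omega Acceptance probability of nonsynonymous proposals.
#' @param coding Reject stop-creating changes? (`TRUE` for the coding
#'   regime.)
#' @return Character matrix, `(n_species + 1)` rows (reference first,
#'   rownames `ref`, `sp01`, ...) by `length(ref_codons)` columns.
#' @export
sim_codon_alignment <- function(ref_codons, n_species, t, omega, coding) {
  bases <- c("A", "C", "G", "T")
  n_cod <- length(ref_codons)
  m <- matrix(rep(ref_codons, each = n_species + 1L), nrow = n_species + 1L)
  rownames(m) <- c("ref", sprintf("sp%02d", seq_len(n_species)))
  for (sp in seq_len(n_species) + 1L) {
    for (ci in seq_len(n_cod)) {
      cur <- m[sp, ci]
      for (ev in seq_len(rpois(1L, t))) {
        p <- sample(3L, 1L)
        b <- sample(setdiff(bases, substr(cur, p, p)), 1L)
        cand <- cur
        substr(cand, p, p) <- b
        if (coding && is_stop_codon(cand)) next
        syn <- codon_aa[[cand]] == codon_aa[[cur]] && codon_aa[[cand]] != "*"
        if (syn || runif(1) < omega) cur <- cand
      }
      m[sp, ci] <- cur
    }
  }
  m
}

#' Generate a reference-anchored MAF for extension windows
#'
#' Evolves each window's codons under its gene's regime (coding for true
#' extensions, neutral otherwise) on a star tree and lays the alignment
#' out as reference-anchored MAF blocks over the window's genomic blocks,
#' reverse-complemented on the minus strand. With `cfg$maf_split`, each
#' block is emitted as two abutting MAF blocks to exercise stitching.
#'
#' @param windows Window tibble (needs `blocks`, `win_seq`).
#' @param truth Ground-truth tibble from [sim_transcriptome()].
#' @param cfg A [sim_config()].
#' @return List: `maf` (block list for [write_maf()] /
#'   [extract_alignment_window()]), `truth_codons` (named list of the
#'   simulated codon matrices, transcript orientation).
#' @export
sim_alignments <- function(windows, truth, cfg) {
  set.seed(cfg$seed + 303L)
  maf <- list()
  truth_codons <- list()
  for (i in seq_len(nrow(windows))) {
    tx <- windows$transcript_id[[i]]
    tr <- truth[truth$transcript_id == tx, ]
    omega <- if (nrow(tr) && tr$regime[[1L]] == "coding") cfg$omega_coding else
      cfg$omega_neutral
    coding <- nrow(tr) > 0 && tr$regime[[1L]] == "coding"
    ref_cod <- codons_of(windows$win_seq[[i]], 0L, windows$win_codons[[i]])
    mat <- sim_codon_alignment(ref_cod, cfg$n_species, cfg$t_branch, omega,
                               coding)
    truth_codons[[tx]] <- mat
    chars <- matrix(unlist(strsplit(as.vector(t(apply(mat, 1L, paste,
                                                      collapse = ""))), "")),
                    nrow = nrow(mat), byrow = TRUE,
                    dimnames = list(rownames(mat), NULL))
    blocks <- windows$blocks[[i]]
    offs <- cumsum(c(0L, blocks$end - blocks$start))
    for (b in seq_len(nrow(blocks))) {
      seg <- chars[, (offs[[b]] + 1L):offs[[b + 1L]], drop = FALSE]
      if (blocks$strand[[b]] == "-") {
        seg <- matrix(complement_chars(seg), nrow = nrow(seg),
                      dimnames = dimnames(seg))[, rev(seq_len(ncol(seg))),
                                                drop = FALSE]
      }
      pieces <- if (cfg$maf_split && ncol(seg) >= 2L) {
        mid <- ncol(seg) %/% 2L
        list(list(cols = 1:mid, gstart = blocks$start[[b]]),
             list(cols = (mid + 1L):ncol(seg),
                  gstart = blocks$start[[b]] + mid))
      } else {
        list(list(cols = seq_len(ncol(seg)), gstart = blocks$start[[b]]))
      }
      for (pc in pieces) {
        texts <- apply(seg[, pc$cols, drop = FALSE], 1L, paste, collapse = "")
        width <- length(pc$cols)
        maf[[length(maf) + 1L]] <- tibble(
          src = paste0(rownames(seg), ".", blocks$chrom[[b]]),
          assembly = rownames(seg),
          chrom = blocks$chrom[[b]],
          start = c(pc$gstart, rep(0L, nrow(seg) - 1L)),
          size = width,
          strand = "+",
          src_size = c(10000000L, rep(width, nrow(seg) - 1L)),
          text = unname(texts)
        )
      }
    }
  }
  list(maf = maf, truth_codons = truth_codons)
}

#' Plant variants inside and outside extension windows
#'
#' @param windows Window tibble with `blocks`.
#' @param cfg A [sim_config()].
#' @param n_inside,n_outside Planted variant counts.
#' @return Tibble `variant_id`, `chrom`, `pos` (0-based), `class`,
#'   `inside`, `gene_id` (the targeted gene for inside variants).
#' @export
sim_variants <- function(windows, cfg, n_inside = 20L, n_outside = 20L) {
  set.seed(cfg$seed + 404L)
  classes <- c("Pathogenic", "Benign", "Uncertain_significance")
  usable <- which(vapply(windows$blocks, nrow, 0L) > 0L)
  rows <- list()
  for (k in seq_len(n_inside)) {
    wi <- sample(usable, 1L)
    blk <- windows$blocks[[wi]]
    b <- blk[sample(nrow(blk), 1L), ]
    rows[[length(rows) + 1L]] <- tibble(
      variant_id = sprintf("var_in_%03d", k),
      chrom = b$chrom,
      pos = sample(seq.int(b$start, b$end - 1L), 1L),
      class = sample(classes, 1L),
      inside = TRUE,
      gene_id = windows$gene_id[[wi]]
    )
  }
  far <- max(purrr::map_int(windows$blocks[usable],
                            ~ max(.x$end))) + 1000000L
  for (k in seq_len(n_outside)) {
    rows[[length(rows) + 1L]] <- tibble(
      variant_id = sprintf("var_out_%03d", k),
      chrom = "chr1",
      pos = far + 100L * k,
      class = sample(classes, 1L),
      inside = FALSE,
      gene_id = NA_character_
    )
  }
  bind_rows(rows)
}

#' Generate a TIS efficiency table covering the supplied contexts
#'
#' The optimal context CACCAUGG scores exactly 100; other AUG-codon
#' contexts draw from 50-100 and non-AUG contexts from 0.2-50.4.
#'
#' @param contexts Character vector of 8-mer contexts to cover.
#' @param cfg A [sim_config()] (seed source).
#' @return Tibble `context`, `score`.
#' @export
sim_tis_table <- function(contexts, cfg) {
  set.seed(cfg$seed + 505L)
  ctx <- unique(c(OPTIMAL_TIS, norm_dna(contexts)))
  is_aug <- substring(ctx, 5L, 7L) == "ATG"
  score <- ifelse(is_aug, runif(length(ctx), 50, 100),
                  runif(length(ctx), 0.2, 50.4))
  score[ctx == OPTIMAL_TIS] <- 100
  tibble(context = ctx, score = round(score, 2))
}

# ---- writers -------------------------------------------------------------

#' Write transcripts as a gencode_pc-dialect FASTA
#' @param transcripts Transcript tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transcript_fasta <- function(transcripts, path) {
  hdr <- sprintf("%s|%s|-|-|%s-201|%s|%d|UTR5:1-%d|CDS:%d-%d|UTR3:%d-%d|",
                 transcripts$transcript_id, transcripts$gene_id,
                 transcripts$gene_id, transcripts$gene_id,
                 transcripts$length, transcripts$cds_start,
                 transcripts$cds_start + 1L, transcripts$cds_end,
                 transcripts$cds_end + 1L, transcripts$length)
  ss <- Biostrings::DNAStringSet(transcripts$sequence)
  names(ss) <- hdr
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write exon and CDS features as GTF
#' @param transcripts Transcript tibble with `exons`.
#' @param path Output path.
#' @param hash Config hash stamped in a header comment.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(transcripts, path, hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(hash)) writeLines(paste0("## config_hash: ", hash), con)
  for (i in seq_len(nrow(transcripts))) {
    ex <- transcripts$exons[[i]]
    if (nrow(ex) == 0L) next
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                     transcripts$gene_id[[i]], transcripts$transcript_id[[i]])
    writeLines(sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\t%s",
                       ex$chrom, ex$start + 1L, ex$end, ex$strand, attrs), con)
  }
  invisible(path)
}

#' Write a P-site profile TSV
#' @param profiles Profile tibble.
#' @param path Output path.
#' @param hash Config hash stamped in a header comment.
#' @return `path`, invisibly.
#' @export
write_ribo_tsv <- function(profiles, path, hash = NULL) {
  con <- file(path, "w")
  if (!is.null(hash)) writeLines(paste0("# config_hash: ", hash), con)
  close(con)
  readr::write_tsv(as_tibble(profiles)[c("transcript_id", "position",
                                         "count", "channel")],
                   path, append = !is.null(hash), col_names = TRUE)
  invisible(path)
}

#' Write planted variants as VCF
#' @param variants Tibble from [sim_variants()].
#' @param path Output path.
#' @param hash Config hash stamped in the header.
#' @return `path`, invisibly.
#' @export
write_vcf_file <- function(variants, path, hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               if (!is.null(hash)) paste0("##config_hash=", hash),
               "##INFO=<ID=CLNSIG,Number=.,Type=String,Description=\"Clinical significance\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  writeLines(sprintf("%s\t%d\t%s\tA\tG\t.\t.\tCLNSIG=%s",
                     variants$chrom, variants$pos + 1L, variants$variant_id,
                     variants$class), con)
  invisible(path)
}

#' Write a TIS table TSV
#' @param tis Tibble `context`, `score`.
#' @param path Output path.
#' @param hash Config hash stamped in a header comment.
#' @return `path`, invisibly.
#' @export
write_tis_tsv <- function(tis, path, hash = NULL) {
  con <- file(path, "w")
  if (!is.null(hash)) writeLines(paste0("# config_hash: ", hash), con)
  close(con)
  readr::write_tsv(tis, path, append = !is.null(hash), col_names = TRUE)
  invisible(path)
}
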