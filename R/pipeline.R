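# End-to-end orchestration: extraction -> filters -> ribosome-profiling
# prediction/ranking -> conservation scoring -> set building -> statistics,
# with per-stage attrition accounting and a machine-readable run report.

#' Mean CDS footprint density per transcript
#'
#' @param profiles Profile tibble.
#' @param transcripts Transcript tibble.
#' @return Tibble `transcript_id`, `density` (elongating reads per codon
#'   over the annotated CDS).
#' @export
cds_coverage <- function(profiles, transcripts) {
  elong <- profiles[profiles$channel == "elong", ]
  idx <- match(elong$transcript_id, transcripts$transcript_id)
  cs <- transcripts$cds_start[idx]
  ce <- transcripts$cds_end[idx]
  sel <- !is.na(cs) & elong$position >= cs & elong$position < ce
  per_tx <- elong[sel, ] |>
    group_by(.data$transcript_id) |>
    summarise(reads = sum(.data$count), .groups = "drop")
  per_tx$density <- per_tx$reads /
    ((transcripts$cds_end - transcripts$cds_start)[
      match(per_tx$transcript_id, transcripts$transcript_id)] / 3)
  per_tx[c("transcript_id", "density")]
}

#' Pipeline run configuration
#'
#' Defaults are the pipeline's reference constants: 50-codon analysis
#' windows, a 20-codon minimum extension, rank thresholds 500
#' (conservative set) and 5000 (extended set), same-strand coding-exon
#' exclusion, and strictly-positive conservation classification.
#'
#' @param fasta,gtf,profiles,maf,tis,vcf Input paths (`profiles` may name
#'   several files). Any may be `NULL` when the corresponding arm or
#'   statistic is disabled.
#' @param out_dir Output directory (created if needed).
#' @param simulate Optional [sim_config()]; when set, all inputs are
#'   generated into `out_dir/inputs` first and the path arguments are
#'   ignored.
#' @param arms Character subset of `c("ribo", "phylo")`.
#' @param window_codons,min_ext_codons,top_n,top_n_ext,same_strand Stage
#'   parameters.
#' @param ribo,scorer,untransl Sub-configurations ([nte_config()],
#'   [scorer_config()], [untransl_config()]).
#' @param ref_assembly Reference assembly name used in the MAF.
#' @return A `run_config` list.
#' @export
run_config <- function(fasta = NULL, gtf = NULL, profiles = NULL, maf = NULL,
                       tis = NULL, vcf = NULL, out_dir = tempfile("ntescan_run_"),
                       simulate = NULL, arms = c("ribo", "phylo"),
                       window_codons = 50L, min_ext_codons = 20L,
                       top_n = 500L, top_n_ext = 5000L, same_strand = TRUE,
                       ribo = nte_config(), scorer = scorer_config(),
                       untransl = untransl_config(), ref_assembly = "ref") {
  structure(list(fasta = fasta, gtf = gtf, profiles = profiles, maf = maf,
                 tis = tis, vcf = vcf, out_dir = out_dir, simulate = simulate,
                 arms = match.arg(arms, c("ribo", "phylo"), several.ok = TRUE),
                 window_codons = window_codons, min_ext_codons = min_ext_codons,
                 top_n = top_n, top_n_ext = top_n_ext, same_strand = same_strand,
                 ribo = ribo, scorer = scorer, untransl = untransl,
                 ref_assembly = ref_assembly),
            class = "run_config")
}

stage_row <- function(stage, n_in, n_out, reasons = NULL) {
  tibble(stage = stage, n_in = n_in, n_out = n_out,
         n_dropped = n_in - n_out,
         reasons = list(reasons %||% tibble(reason = character(), n = integer())))
}

#' Run the full discovery pipeline
#'
#' Executes, per the configured arms: annotation parsing, theoretical
#' extension extraction, length and coding-exon-overlap filtering,
#' per-gene collapse, candidate enumeration, ribosome-profiling scoring
#' and ranking, alignment-window scoring and strictly-positive
#' classification, gene-set construction (including the
#' untranslated-control set) and the comparison statistics. All artifacts
#' are written under `cfg$out_dir`; any stage failure halts with the stage
#' name while already-written outputs persist.
#'
#' @param cfg A [run_config()].
#' @return List of in-memory results (`transcripts`, `extensions`,
#'   `windows`, `ranked`, `tracks`, `sets`, `stats`, `report`), invisibly
#'   usable for further analysis; the run report is also written as JSON.
#' @export
run_pipeline <- function(cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- list()
  current_stage <- "init"
  run_stage <- function(name, expr) {
    current_stage <<- name
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage %s failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  reason_table <- function(reasons) {
    if (!length(reasons)) return(tibble(reason = character(), n = integer()))
    as_tibble(as.data.frame(table(reason = reasons),
                            responseName = "n", stringsAsFactors = FALSE))
  }

  truth <- NULL
  if (!is.null(cfg$simulate)) {
    run_stage("simulate", {
      ind <- file.path(cfg$out_dir, "inputs")
      dir.create(ind, showWarnings = FALSE)
      sim <- sim_transcriptome(cfg$simulate)
      truth <- sim$truth
      cfg$fasta <- write_transcript_fasta(sim$transcripts,
                                          file.path(ind, "transcripts.fa"))
      cfg$gtf <- write_gtf(sim$transcripts, file.path(ind, "structures.gtf"),
                           hash = cfg$simulate$hash)
      prof <- sim_ribo_profiles(sim, cfg$simulate)
      cfg$profiles <- write_ribo_tsv(prof, file.path(ind, "profiles.tsv"),
                                     hash = cfg$simulate$hash)
      ext0 <- extract_extensions(sim$transcripts) |>
        clip_windows(sim$transcripts, max_codons = cfg$window_codons)
      aln <- sim_alignments(ext0, sim$truth, cfg$simulate)
      cfg$maf <- write_maf(aln$maf, file.path(ind, "alignment.maf"),
                           header_comment = paste0("config_hash: ",
                                                   cfg$simulate$hash))
      starts0 <- enumerate_candidate_starts(ext0) |>
        start_contexts(sim$transcripts)
      cfg$tis <- write_tis_tsv(sim_tis_table(starts0$context, cfg$simulate),
                               file.path(ind, "tis_table.tsv"),
                               hash = cfg$simulate$hash)
      vars <- sim_variants(ext0, cfg$simulate)
      cfg$vcf <- write_vcf_file(vars, file.path(ind, "variants.vcf"),
                                hash = cfg$simulate$hash)
      readr::write_tsv(sim$truth, file.path(ind, "ground_truth.tsv"))
    })
  }

  transcripts <- run_stage("parse", {
    tx <- parse_transcript_fasta(cfg$fasta)
    skipped <- attr(tx, "skipped")
    stages[[length(stages) + 1L]] <- stage_row(
      "parse", nrow(tx) + nrow(skipped), nrow(tx), reason_table(skipped$reason))
    if (!is.null(cfg$gtf)) tx <- attach_exons(tx, cfg$gtf)
    tx
  })

  extensions <- run_stage("extract", {
    ext <- extract_extensions(transcripts)
    dropped <- attr(ext, "dropped")
    stages[[length(stages) + 1L]] <- stage_row(
      "extract", nrow(transcripts), nrow(ext), reason_table(dropped$reason))
    ext
  })

  windows <- run_stage("filter", {
    kept <- filter_min_length(extensions, cfg$min_ext_codons)
    stages[[length(stages) + 1L]] <- stage_row(
      "min_length", nrow(extensions), nrow(kept),
      tibble(reason = "below_min_codons", n = nrow(extensions) - nrow(kept)))
    win <- clip_windows(kept, transcripts, max_codons = cfg$window_codons)
    coding_exons <- coding_exon_catalog(transcripts)
    win2 <- filter_coding_overlap(win, coding_exons,
                                  same_strand = cfg$same_strand)
    stages[[length(stages) + 1L]] <- stage_row(
      "coding_overlap", nrow(win), nrow(win2),
      tibble(reason = "coding_exon_overlap", n = nrow(win) - nrow(win2)))
    win3 <- collapse_genes(win2)
    stages[[length(stages) + 1L]] <- stage_row(
      "gene_collapse", nrow(win2), nrow(win3),
      tibble(reason = "non_representative", n = nrow(win2) - nrow(win3)))
    write_extensions_tsv(win3, file.path(cfg$out_dir, "extensions.tsv"))
    win3
  })

  ranked <- NULL
  profiles <- NULL
  sets <- list()
  if ("ribo" %in% cfg$arms) {
    ranked <- run_stage("ribo", {
      profiles <- read_ribo_profiles(cfg$profiles)
      cands <- enumerate_candidate_starts(windows)
      rk <- call_and_rank(profiles, windows, cands, transcripts,
                          config = cfg$ribo)
      stages[[length(stages) + 1L]] <- stage_row(
        "ribo_call", nrow(windows), nrow(rk),
        tibble(reason = "no_passing_candidate", n = nrow(windows) - nrow(rk)))
      readr::write_tsv(as_tibble(rk), file.path(cfg$out_dir, "predictions.tsv"))
      rk
    })
    sets$riboset <- build_riboset(ranked, cfg$top_n, label = "RiboSET")
    sets$riboset_ext <- build_riboset(ranked, cfg$top_n_ext,
                                      label = "RiboSET_ext")
  }

  tracks <- NULL
  if ("phylo" %in% cfg$arms && !is.null(cfg$maf)) {
    tracks <- run_stage("phylo", {
      maf <- read_maf(cfg$maf)
      tr <- vector("list", nrow(windows))
      for (i in seq_len(nrow(windows))) {
        if (nrow(windows$blocks[[i]]) == 0L) next
        aw <- extract_alignment_window(maf, windows$blocks[[i]],
                                       cfg$ref_assembly, windows$win_seq[[i]],
                                       windows$transcript_id[[i]])
        tr[[i]] <- builtin_coding_score(aw, cfg$scorer)
      }
      tr <- classify_positive(bind_rows(tr))
      tr$gene_id <- windows$gene_id[match(tr$transcript_id,
                                          windows$transcript_id)]
      stages[[length(stages) + 1L]] <- stage_row(
        "phylo_score", nrow(windows), nrow(tr),
        tibble(reason = "no_genomic_blocks", n = nrow(windows) - nrow(tr)))
      write_score_tracks(tr, file.path(cfg$out_dir, "score_tracks.tsv"))
      tr
    })
    sets$phyloset <- gene_set("PhyloSET", tracks$gene_id[tracks$conserved],
                              params = list(threshold = "total > 0",
                                            scorer = tracks$scorer_id[1] %||%
                                              "builtin"))
  }

  if ("ribo" %in% cfg$arms) {
    sets$untranslset <- run_stage("untranslset", {
      full_ext <- extensions
      full_ext$win_start <- full_ext$ext_start
      full_ext$win_codons <- full_ext$length_codons
      blocks <- vector("list", nrow(full_ext))
      for (i in seq_len(nrow(full_ext))) {
        j <- match(full_ext$transcript_id[[i]], transcripts$transcript_id)
        ok <- identical(transcripts$structure[[j]], "ok") &&
          full_ext$length_codons[[i]] > 0
        blocks[[i]] <- if (ok) {
          map_to_genome(transcripts$exons[[j]], full_ext$ext_start[[i]],
                        full_ext$cds_start[[i]])
        } else tibble(chrom = character(), start = integer(),
                      end = integer(), strand = character())
      }
      full_ext$blocks <- blocks
      ce <- coding_exon_catalog(transcripts)
      kept <- filter_coding_overlap(full_ext, ce, same_strand = cfg$same_strand)
      overlapping <- setdiff(full_ext$transcript_id, kept$transcript_id)
      build_untranslset(transcripts, extensions, profiles,
                        predicted = as_tibble(ranked)[c("transcript_id",
                                                        "gene_id")],
                        overlapping_ids = overlapping, cfg = cfg$untransl)
    })
  }

  stats <- run_stage("stats", {
    st <- list()
    universe <- unique(transcripts$gene_id[
      !has_flag(transcripts$flags, "cds_incomplete")])
    have <- sets[!vapply(sets, is.null, TRUE)]
    if (length(have) >= 2L) {
      st$overlap <- hypergeom_overlap(unname(have), universe)
    }
    if (!is.null(ranked) && !is.null(sets$phyloset)) {
      st$sweep <- glance(rank_sweep(ranked, sets$phyloset, step = cfg$top_n,
                                    max_rank = max(ranked$rank)))
      dens <- cds_coverage(profiles, transcripts)
      st$rank_coverage <- tryCatch(rank_vs_coverage(ranked, dens),
                                   error = function(e) NULL)
    }
    if (!is.null(cfg$tis) && !is.null(ranked)) {
      tis <- read_tis_table(cfg$tis)
      called <- start_contexts(as_tibble(ranked)[!ranked$aug_called, ],
                               transcripts)
      all_cand <- enumerate_candidate_starts(windows)
      all_cand <- start_contexts(all_cand[all_cand$codon_class ==
                                            "near_cognate", ], transcripts)
      x <- tis_score(called$context, tis)
      y <- tis_score(all_cand$context, tis)
      if (sum(!is.na(x)) > 0 && sum(!is.na(y)) > 0) {
        st$tis_ks <- compare_distributions(x[!is.na(x)], y[!is.na(y)])
      }
    }
    if (!is.null(cfg$vcf)) {
      st$variant_hits <- intersect_variants(windows, cfg$vcf)
    }
    st
  })

  if (length(sets)) {
    write_gene_sets(unname(sets[!vapply(sets, is.null, TRUE)]),
                    file.path(cfg$out_dir, "gene_sets.tsv"))
  }
  report <- make_report(stages, cfg)
  list(transcripts = transcripts, extensions = extensions, windows = windows,
       ranked = ranked, tracks = tracks, sets = sets, stats = stats,
       truth = truth, report = report)
}

coding_exon_catalog <- function(transcripts) {
  rows <- vector("list", nrow(transcripts))
  for (i in seq_len(nrow(transcripts))) {
    if (!identical(transcripts$structure[[i]], "ok")) next
    rows[[i]] <- map_to_genome(transcripts$exons[[i]],
                               transcripts$cds_start[[i]],
                               transcripts$cds_end[[i]]) |>
      mutate(catalog = "input", transcript_id = transcripts$transcript_id[[i]])
  }
  bind_rows(rows)
}

#' Assemble and validate the run report
#'
#' Asserts count conservation (`n_in = n_out + n_dropped`, and each
#' stage's drop reasons summing to `n_dropped`) and writes the report as
#' JSON (with file checksums) plus a human-readable text summary.
#'
#' @param stages List of stage tibbles (internal layout).
#' @param cfg The [run_config()] of the run.
#' @return The report list, invisibly written to
#'   `out_dir/report.json` and `out_dir/report.txt`.
#' @export
make_report <- function(stages, cfg) {
  tab <- bind_rows(stages)
  for (i in seq_len(nrow(tab))) {
    if (tab$n_in[[i]] != tab$n_out[[i]] + tab$n_dropped[[i]]) {
      stop("count conservation violated at stage ", tab$stage[[i]],
           call. = FALSE)
    }
    rsum <- sum(tab$reasons[[i]]$n)
    if (nrow(tab$reasons[[i]]) && rsum != tab$n_dropped[[i]]) {
      stop("drop reasons do not sum to the dropped count at stage ",
           tab$stage[[i]], call. = FALSE)
    }
  }
  files <- list.files(cfg$out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("report\\.(json|txt)$", files)]
  sums <- tools::md5sum(files)
  report <- list(
    tool = paste0("ntescan ", as.character(utils::packageVersion("ntescan"))),
    config = cfg[setdiff(names(cfg), c("ribo", "scorer", "untransl",
                                       "simulate"))],
    stages = lapply(seq_len(nrow(tab)), function(i) {
      list(stage = tab$stage[[i]], n_in = tab$n_in[[i]], n_out = tab$n_out[[i]],
           n_dropped = tab$n_dropped[[i]],
           reasons = as.list(setNames(tab$reasons[[i]]$n,
                                      tab$reasons[[i]]$reason)))
    }),
    checksums = as.list(setNames(unname(sums), basename(names(sums))))
  )
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  txt <- c(sprintf("%s run report", report$tool),
           sprintf("%-16s in=%-6d out=%-6d dropped=%d",
                   tab$stage, tab$n_in, tab$n_out, tab$n_dropped))
  writeLines(txt, file.path(cfg$out_dir, "report.txt"))
  invisible(report)
}
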