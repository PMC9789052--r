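# Gene-set construction (ribosome-profiling-supported, conservation-
# supported, untranslated-control) and the comparison statistics between
# the two evidence arms.

#' Construct a labelled gene set
#'
#' @param label Set label, unique within a run.
#' @param members Character vector of gene ids (de-duplicated, sorted).
#' @param params Named list of provenance parameters.
#' @return A `gene_set` object.
#' @export
gene_set <- function(label, members, params = list()) {
  structure(list(label = label,
                 members = sort(unique(as.character(members))),
                 params = params),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d genes\n", x$label, length(x$members)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.gene_set <- function(x, ...) {
  tibble(label = x$label, gene_id = x$members)
}

#' Build the ribosome-profiling-supported gene set
#'
#' Takes the predictions ranked at or above `top_n`, drops calls whose
#' start codon is AUG (the pipeline targets non-AUG proteoforms; AUG calls
#' are tagged upstream, not discarded), and collapses to the gene level.
#'
#' @param ranked Ranked call tibble from [call_and_rank()].
#' @param top_n Rank threshold (500 for the conservative set, 5000 for the
#'   extended set).
#' @param exclude_aug Drop AUG-called starts? Default `TRUE`.
#' @param label Set label.
#' @return A [gene_set()]; `params` records `top_n` and the post-filter
#'   prediction count.
#' @export
build_riboset <- function(ranked, top_n = 500L, exclude_aug = TRUE,
                          label = "RiboSET") {
  if (nrow(ranked) == 0L) {
    warning("empty ranking; returning empty set")
    return(gene_set(label, character(), params = list(top_n = top_n,
                                                      post_filter_n = 0L)))
  }
  if (top_n > max(ranked$rank)) {
    warning(sprintf("top_n = %d exceeds available ranks (%d); using all",
                    top_n, max(ranked$rank)))
  }
  sel <- ranked[ranked$rank <= top_n, , drop = FALSE]
  if (exclude_aug) sel <- sel[!sel$aug_called, , drop = FALSE]
  gene_set(label, sel$gene_id,
           params = list(top_n = top_n, post_filter_n = nrow(sel),
                         exclude_aug = exclude_aug))
}

#' Configuration for the untranslated-control set rules
#'
#' The seven rules, applied in order: (1) non-truncated CDS; (2) the
#' theoretical extension has no same-strand coding-exon overlap; (3)
#' extension length at least `min_ext_codons`; (4) neither transcript nor
#' gene appears anywhere in the predicted set; (5) fraction of covered
#' positions in the extension at most `max_ext_cov_frac`; (6) CDS in-frame
#' reads per codon at least `min_cds_density`; (7) fraction of covered
#' positions in the CDS at least `min_cds_cov_frac`.
#'
#' @param min_ext_codons Rule-3 threshold (default 20).
#' @param max_ext_cov_frac Rule-5 threshold (default 0.0005, inclusive).
#' @param min_cds_density Rule-6 threshold (default 1, inclusive).
#' @param min_cds_cov_frac Rule-7 threshold (default 0.3, inclusive).
#' @return Named list of rule parameters.
#' @export
untransl_config <- function(min_ext_codons = 20L, max_ext_cov_frac = 0.0005,
                            min_cds_density = 1, min_cds_cov_frac = 0.3) {
  list(min_ext_codons = min_ext_codons, max_ext_cov_frac = max_ext_cov_frac,
       min_cds_density = min_cds_density, min_cds_cov_frac = min_cds_cov_frac)
}

#' Build the untranslated-control gene set
#'
#' Applies the seven selection rules in order, attributing every excluded
#' transcript to the first rule it fails, then keeps one transcript per
#' gene — the one with the highest CDS coverage (ties by transcript id).
#'
#' @param transcripts Transcript tibble (flags used for rule 1).
#' @param extensions Theoretical-extension tibble (rules 2, 3, 5; a
#'   transcript with no extension record fails rule 3 at length 0).
#' @param profiles Profile tibble (rules 5-7 use the elongating channel).
#' @param predicted Tibble (or vector) of every predicted
#'   transcript/gene: columns `transcript_id`, `gene_id` (rule 4).
#' @param overlapping_ids Transcript ids whose theoretical extension
#'   overlaps a foreign coding exon (rule 2), e.g. from the `"overlaps"`
#'   attribute of [filter_coding_overlap()] run on full extensions.
#' @param cfg Rule thresholds from [untransl_config()].
#' @param label Set label.
#' @return A [gene_set()]. Attributes: `"attrition"`, a tibble
#'   (`rule`, `description`, `failed`, `remaining`); `"selected"`, the
#'   per-gene representative tibble.
#' @export
build_untranslset <- function(transcripts, extensions, profiles, predicted,
                              overlapping_ids = character(),
                              cfg = untransl_config(),
                              label = "UntranslSET") {
  ext_idx <- match(transcripts$transcript_id, extensions$transcript_id)
  ext_len <- ifelse(is.na(ext_idx), 0L, extensions$length_codons[ext_idx])
  ext_start <- ifelse(is.na(ext_idx), transcripts$cds_start,
                      extensions$ext_start[ext_idx])

  elong <- profiles[profiles$channel == "elong", ]
  elong_by <- split(elong[c("position", "count")], elong$transcript_id)
  region_stats <- function(tx, a, b) {
    e <- elong_by[[tx]]
    if (is.null(e) || a >= b) return(c(inframe = 0, covered = 0))
    sel <- e$position >= a & e$position < b
    c(inframe = sum(e$count[sel & (e$position - a) %% 3L == 0L]),
      covered = sum(sel & e$count > 0))
  }

  n <- nrow(transcripts)
  ext_cov_frac <- numeric(n)
  cds_density <- numeric(n)
  cds_cov_frac <- numeric(n)
  for (i in seq_len(n)) {
    tx <- transcripts$transcript_id[[i]]
    cs <- transcripts$cds_start[[i]]
    ce <- transcripts$cds_end[[i]]
    es <- ext_stats <- region_stats(tx, ext_start[[i]], cs)
    ext_cov_frac[[i]] <- if (cs > ext_start[[i]]) {
      ext_stats[["covered"]] / (cs - ext_start[[i]])
    } else 0
    cds <- region_stats(tx, cs, ce)
    cds_density[[i]] <- cds[["inframe"]] / ((ce - cs) / 3)
    cds_cov_frac[[i]] <- cds[["covered"]] / (ce - cs)
  }

  predicted_tx <- unique(as.character(predicted$transcript_id))
  predicted_gene <- unique(as.character(predicted$gene_id))

  rules <- list(
    list(id = 1L, desc = "non-truncated CDS",
         pass = !has_flag(transcripts$flags, "cds_incomplete")),
    list(id = 2L, desc = "no coding-exon overlap of theoretical extension",
         pass = !(transcripts$transcript_id %in% overlapping_ids)),
    list(id = 3L, desc = sprintf("extension >= %d codons", cfg$min_ext_codons),
         pass = ext_len >= cfg$min_ext_codons),
    list(id = 4L, desc = "transcript and gene absent from predicted set",
         pass = !(transcripts$transcript_id %in% predicted_tx) &
                !(transcripts$gene_id %in% predicted_gene)),
    list(id = 5L, desc = sprintf("extension covered fraction <= %g",
                                 cfg$max_ext_cov_frac),
         pass = ext_cov_frac <= cfg$max_ext_cov_frac),
    list(id = 6L, desc = sprintf("CDS in-frame reads/codon >= %g",
                                 cfg$min_cds_density),
         pass = cds_density >= cfg$min_cds_density),
    list(id = 7L, desc = sprintf("CDS covered fraction >= %g",
                                 cfg$min_cds_cov_frac),
         pass = cds_cov_frac >= cfg$min_cds_cov_frac)
  )

  alive <- rep(TRUE, n)
  attrition <- vector("list", length(rules))
  for (k in seq_along(rules)) {
    failed_now <- alive & !rules[[k]]$pass
    alive <- alive & rules[[k]]$pass
    attrition[[k]] <- tibble(rule = rules[[k]]$id,
                             description = rules[[k]]$desc,
                             failed = sum(failed_now),
                             remaining = sum(alive))
  }

  selected <- tibble(
    transcript_id = transcripts$transcript_id[alive],
    gene_id = transcripts$gene_id[alive],
    cds_density = cds_density[alive]
  ) |>
    arrange(.data$gene_id, dplyr::desc(.data$cds_density), .data$transcript_id) |>
    group_by(.data$gene_id) |>
    slice(1L) |>
    ungroup()

  out <- gene_set(label, selected$gene_id,
                  params = c(cfg, list(n_input = n, n_selected = nrow(selected))))
  attr(out, "attrition") <- bind_rows(attrition)
  attr(out, "selected") <- selected
  out
}

#' Hypergeometric overlap tests between gene sets
#'
#' For each requested pair of sets, computes the upper-tail hypergeometric
#' probability of an overlap at least as large as observed, given the gene
#' universe, and applies Benjamini-Hochberg correction across the supplied
#' family of tests.
#'
#' @param sets List of [gene_set()] objects.
#' @param universe Character vector of gene ids; every set must be a
#'   subset (violations are fatal).
#' @param pairs List of 2-element label vectors; default all unordered
#'   pairs of `sets`.
#' @return An `overlap_test` tibble: `label_a`, `label_b`, `size_a`,
#'   `size_b`, `overlap`, `universe`, `p_raw`, `p_adj`, `method`.
#' @export
hypergeom_overlap <- function(sets, universe, pairs = NULL) {
  names(sets) <- vapply(sets, `[[`, "", "label")
  universe <- unique(as.character(universe))
  for (s in sets) {
    if (length(setdiff(s$members, universe))) {
      stop("universe_violation: set '", s$label,
           "' has members outside the universe", call. = FALSE)
    }
  }
  if (is.null(pairs)) {
    labs <- names(sets)
    pairs <- list()
    if (length(labs) >= 2L) {
      for (i in seq_len(length(labs) - 1L)) for (j in (i + 1L):length(labs)) {
        pairs[[length(pairs) + 1L]] <- c(labs[[i]], labs[[j]])
      }
    }
  }
  rows <- purrr::map(pairs, function(pr) {
    a <- sets[[pr[[1L]]]]
    b <- sets[[pr[[2L]]]]
    ov <- length(intersect(a$members, b$members))
    na <- length(a$members)
    nb <- length(b$members)
    p <- if (na == 0L || nb == 0L) 1 else {
      phyper(ov - 1L, na, length(universe) - na, nb, lower.tail = FALSE)
    }
    tibble(label_a = a$label, label_b = b$label, size_a = na, size_b = nb,
           overlap = ov, universe = length(universe), p_raw = p)
  })
  out <- bind_rows(rows)
  out$p_adj <- p.adjust(out$p_raw, method = "BH")
  out$method <- "hypergeometric+BH"
  class(out) <- c("overlap_test", class(out))
  out
}

#' @exportS3Method generics::glance
glance.overlap_test <- function(x, ...) {
  tibble(n_tests = nrow(x), min_p_adj = suppressWarnings(min(x$p_adj)),
         n_significant = sum(x$p_adj < 0.05))
}

#' Overlap growth across rank thresholds
#'
#' Sweeps the prediction ranking in bins of `step` ranks and counts, per
#' bin, the newly gained members of a reference gene set, against the
#' expectation under uniform placement of the reference genes among the
#' ranked genes. The observed and expected per-bin increments are compared
#' with a two-sided Mann-Whitney test (exact for at most 30 bins per side
#' when tie-free, asymptotic otherwise; the method used is recorded).
#'
#' @param ranked Ranked call tibble from [call_and_rank()].
#' @param reference A [gene_set()] (the conservation-supported set in the
#'   two-arm design).
#' @param step Bin width in ranks, default 500.
#' @param max_rank Sweep limit; default the maximum available rank.
#' @param exclude_aug Ignore AUG-called predictions, default `TRUE`.
#' @return A `rank_sweep` object: `thresholds`, `observed`, `expected`,
#'   `statistic`, `test_p`, `method`, `overlap_total`.
#' @export
rank_sweep <- function(ranked, reference, step = 500L, max_rank = NULL,
                       exclude_aug = TRUE) {
  stopifnot(step >= 1L)
  sel <- ranked
  if (exclude_aug && "aug_called" %in% names(sel)) {
    sel <- sel[!sel$aug_called, , drop = FALSE]
  }
  gene_rank <- sel |>
    group_by(.data$gene_id) |>
    summarise(rank = min(.data$rank), .groups = "drop")
  if (is.null(max_rank)) {
    max_rank <- if (nrow(sel)) max(sel$rank) else step
  }
  n_bins <- ceiling(max_rank / step)
  thresholds <- step * seq_len(n_bins)
  in_ref <- gene_rank$gene_id %in% reference$members
  bin_of <- ceiling(gene_rank$rank / step)   # genes past max_rank fall
  bin_of[bin_of > n_bins] <- NA_integer_     # outside every bin
  observed <- vapply(seq_len(n_bins), function(b) {
    sum(in_ref & !is.na(bin_of) & bin_of == b)
  }, 0L)
  n_bin_genes <- vapply(seq_len(n_bins), function(b) {
    sum(!is.na(bin_of) & bin_of == b)
  }, 0L)
  # uniform placement of the reference genes over the whole ranking
  m <- sum(in_ref)
  expected <- if (nrow(gene_rank)) m * n_bin_genes / nrow(gene_rank) else
    rep(0, n_bins)
  exact <- n_bins <= 30L && !any(duplicated(c(observed, expected)))
  wt <- suppressWarnings(wilcox.test(observed, expected, exact = exact))
  structure(list(thresholds = thresholds,
                 observed = as.integer(observed),
                 expected = expected,
                 statistic = unname(wt$statistic),
                 test_p = wt$p.value,
                 method = if (exact) "mann-whitney-exact" else
                   "mann-whitney-asymptotic",
                 overlap_total = sum(observed)),
            class = "rank_sweep")
}

#' @export
print.rank_sweep <- function(x, ...) {
  cat(sprintf("<rank_sweep> %d bins, total overlap %d, MW p = %.4g (%s)\n",
              length(x$thresholds), x$overlap_total, x$test_p, x$method))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.rank_sweep <- function(x, ...) {
  tibble(threshold = x$thresholds, observed = x$observed,
         expected = x$expected)
}

#' @exportS3Method generics::glance
glance.rank_sweep <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$test_p, method = x$method,
         overlap_total = x$overlap_total, n_bins = length(x$thresholds))
}

#' Correlation between prediction rank and CDS footprint density
#'
#' Spearman correlation (two-sided) between log10 mean CDS footprint
#' density and the prediction rank, over genes with a known rank.
#'
#' @param ranked Ranked call tibble.
#' @param cds_density Tibble `transcript_id`, `density` (mean CDS reads
#'   per codon).
#' @return One-row tibble `rho`, `p_value`, `n`.
#' @export
rank_vs_coverage <- function(ranked, cds_density) {
  df <- inner_join(
    as_tibble(ranked)[c("transcript_id", "rank")],
    cds_density, by = "transcript_id"
  )
  df <- df[df$density > 0, , drop = FALSE]
  if (nrow(df) < 5L) stop("insufficient_n: need at least 5 paired observations",
                          call. = FALSE)
  if (length(unique(df$density)) == 1L || length(unique(df$rank)) == 1L) {
    stop("degenerate: constant ranks or coverage", call. = FALSE)
  }
  ct <- suppressWarnings(
    cor.test(log10(df$density), df$rank, method = "spearman")
  )
  tibble(rho = unname(ct$estimate), p_value = ct$p.value, n = nrow(df))
}

#' Overlap variants with extension windows
#'
#' Reads a VCF, converts the 1-based variant positions to the internal
#' 0-based convention, and reports every variant falling inside any
#' window's genomic blocks (variants are unstranded), optionally filtered
#' to a set of clinical classifications.
#'
#' @param windows Window tibble with `blocks`.
#' @param vcf_path Path to a VCF file.
#' @param classes Keep only these classification values (default all).
#' @param class_field INFO field holding the classification, default
#'   `"CLNSIG"`.
#' @return Tibble `gene_id`, `transcript_id`, `variant_id`, `class`,
#'   `chrom`, `pos` (0-based).
#' @export
intersect_variants <- function(windows, vcf_path, classes = NULL,
                               class_field = "CLNSIG") {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  cls <- vcfR::extract.info(vcf, element = class_field)
  var <- tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS) - 1L,
    variant_id = fix$ID,
    class = as.character(cls)
  )
  if (!is.null(classes)) var <- var[var$class %in% classes, , drop = FALSE]
  rows <- vector("list", nrow(windows))
  for (i in seq_len(nrow(windows))) {
    blk <- windows$blocks[[i]]
    if (nrow(blk) == 0L) next
    hit <- logical(nrow(var))
    for (b in seq_len(nrow(blk))) {
      hit <- hit | (var$chrom == blk$chrom[[b]] &
                      var$pos >= blk$start[[b]] & var$pos < blk$end[[b]])
    }
    if (any(hit)) {
      rows[[i]] <- bind_cols(
        tibble(gene_id = windows$gene_id[[i]],
               transcript_id = windows$transcript_id[[i]]),
        var[hit, , drop = FALSE]
      )
    }
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble(gene_id = character(), transcript_id = character(),
                  chrom = character(), pos = integer(),
                  variant_id = character(), class = character())
  }
  out
}

#' Write gene sets as TSV plus a JSON parameter sidecar
#'
#' @param sets List of [gene_set()] objects.
#' @param path Output TSV path; the sidecar is written next to it as
#'   `<path>.params.json`.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path) {
  long <- bind_rows(lapply(sets, tidy))
  readr::write_tsv(long, path)
  params <- lapply(sets, function(s) s$params)
  names(params) <- vapply(sets, `[[`, "", "label")
  jsonlite::write_json(params, paste0(path, ".params.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
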