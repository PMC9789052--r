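---
title: "Discovering non-AUG N-terminal extensions: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering non-AUG N-terminal extensions: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ntescan)
```

This vignette is the package's account of its science: the models behind
each stage, the assumptions they make, the parameters that matter, and
the design decisions taken where the design was genuinely open. The
README shows the surface; this document explains what is underneath.

## The two-arm design

A gene can acquire an N-terminally extended proteoform when ribosomes
initiate at a near-cognate codon upstream of, and in frame with, the
annotated AUG. Evidence for such an extension comes from two independent
directions: ribosomes caught in the act (footprint periodicity in the
extended frame) and evolution (a protein-coding substitution pattern in
the upstream region). The pipeline runs both arms over the same
substrate — the *theoretical extension* — and studies their agreement.
Neither arm is taken as ground truth for the other: the comparison
statistics (overlap, rank sweep, rank/coverage correlation) are the
product.

## Theoretical extensions and their filters

Extraction walks upstream from the annotated start in steps of three
nucleotides until the first in-frame stop, or, failing that, the 5'-most
complete in-frame codon; a sub-codon leftover at the transcript edge is
never part of a codon. The walk assumes the annotation's CDS frame is
correct and that the transcript sequence is the spliced mRNA. Codons
containing `N` never match a stop (or start) codon, which errs on the
side of longer extensions for ambiguous sequence.

Three filters shape the analysis set, all with exposed parameters:

* **window clipping** (`max_codons = 50`): the scored window is the
  3'-most 50 codons of the extension. Scoring a fixed-length window
  makes coding-evolution totals comparable across genes, at the known
  cost that a genuine extension much shorter than the window dilutes its
  signal with upstream non-coding codons;
* **minimum length** (`min_codons = 20`, boundary inclusive: a 20-codon
  extension is kept): below this, neither periodicity nor substitution
  counts carry usable information;
* **coding-exon overlap**: a window whose genomic projection shares even
  one same-strand base with another transcript's coding exon is
  excluded, because footprints and conservation there are explained by
  the other gene. The transcript's own CDS exons are exempt — every
  extension abuts its own CDS, and frame-agnostic interval logic would
  otherwise self-collide. Whether opposite-strand coding exons should
  also exclude is genuinely ambiguous; same-strand-only is the default
  and a `same_strand = FALSE` switch exists.

When several transcripts of a gene yield extensions, the gene is
represented by the transcript with the longest theoretical extension,
ties broken by smallest transcript id. Any deterministic rule would do;
this one favours the most informative substrate.

## The periodicity detector

The detector consumes P-site-assigned counts (`elong` channel) and tests
the region from a candidate start to the annotated AUG. Its null
hypothesis is that reads fall on the three frames independently with
equal probability — appropriate for untranslated upstream sequence, and
the same null the synthetic noise cohorts are drawn from.

Two statistics view the same signal at different granularity. The
read-level tail `P[Bin(N, 1/3) >= F0]` is powerful but a single heavily
piled-up position can dominate `F0`. The codon-level statistic counts
codons whose frame-0 position holds the *strict* maximum (ties never
win) and compares the count against a binomial whose success probability
is the exact trinomial strict-maximum probability at each codon's read
total (enumerated exactly for totals ≤ 30, 1/3 beyond — the tie mass is
negligible there). Using the mean per-codon win probability as a single
binomial parameter is conservative relative to the exact
Poisson-binomial tail. The codon-level view is robust to pileups
precisely because each codon contributes at most one win.

**Combining the two p-values.** The two statistics are computed from the
same frame-0 counts and are strongly positively dependent. Fisher's
product rule, which assumes independence, proved anticonservative in
calibration runs (null rejection rates slightly above nominal at the
0.05 level on 2,000-extension noise cohorts), so the default combination
is the Bonferroni-style minimum rule `min(1, 2 min(p1, p2))`, valid
under arbitrary dependence; measured null rejection then sits safely
below nominal. `nte_config(combine = "fisher")` restores the product
rule for users who want it. This is the one place the implementation
departs from its original sketch, for a measured reason.

Secondary scores are reported but do not decide calls: the density step
`sigma = (mu_down + eps)/(mu_up + eps)` with `eps = 0.1` reads/codon
(regularising empty upstream windows; `mu_up` uses at most 15 in-frame
codons upstream of the candidate, inside the extension), and the
initiation-peak score `iota` from the `init` channel. Initiation data
contributes one read position per event and is intrinsically noisy, so
`iota` is excluded from ranking by default (`use_iota = FALSE`).

Gates: at least `min_inframe_reads = 10` in-frame reads on the candidate
region and strictly non-zero coverage. Zero-read transcripts are never
called. Per transcript the candidate with smallest combined p-value wins
(ties: larger `sigma`, then 5'-most); the transcriptome-wide rank orders
calls by combined p-value, then mean density, then transcript id, so
ranking is a deterministic permutation.

## The built-in coding-evolution scorer

The scorer answers one question per species codon: do the substitutions
separating it from the reference look like protein-coding evolution?
Each differing codon is decomposed into single-nucleotide steps averaged
over all orderings of the differing positions (Nei–Gojobori path
counting; paths through stop codons are excluded, and if every path hits
a stop, all orderings are used). With `f_s(r)` the fraction of the nine
single-nucleotide neighbours of reference codon `r` that are synonymous,
a synonymous step contributes `-log(f_s + ω(1 - f_s))` and a
nonsynonymous step `log ω - log(f_s + ω(1 - f_s))` — the log-likelihood
ratio of a coding model in which nonsynonymous changes are accepted with
probability `ω` against a neutral model. Defaults: `omega_coding = 0.1`
(strong purifying selection; N-termini are often under weaker selection
than protein cores, so this is deliberately not extreme),
`stop_penalty = -10` per species codon that is an in-frame stop, and
`min_species = 3` informative rows for a usable total.

The scorer deliberately ignores phylogeny: a star topology with
pairwise-to-reference comparison, no branch lengths, no codon-model
fitting. Shared branches make related species pseudo-replicates, so
totals are not calibrated likelihoods — they are a monotone coding
signal, used only through the strictly-positive classification
(`total > 0`). Every track carries a `scorer_id`; per-codon output from
an external empirical codon model can be substituted through
`read_external_scores()`, and totals there are cross-checked against
per-codon sums at 1e-6, the per-codon sum winning on disagreement.

MAF extraction is exact rather than statistical: reference-insertion
columns are dropped, uncovered reference bases and absent species get an
explicit missing marker, minus-strand windows are reverse-complemented,
and the stitched reference row must equal the window sequence
byte-for-byte (`ref_mismatch` otherwise). Gapped or missing species
codons contribute zero — alignment absence is not evidence against
coding.

## Gene sets and statistics

RiboSET takes ranks ≤ 500 (RiboSET_ext: 5000), drops AUG-called starts
(the pipeline's subject is non-AUG initiation; AUG calls are tagged, not
deleted), and collapses to genes. The untranslated control set applies
seven rules in order, each transcript attributed to the first rule it
fails, with all thresholds boundary-inclusive: covered fraction of the
extension ≤ 0.0005, CDS in-frame reads per codon ≥ 1, covered fraction
of the CDS ≥ 0.3; one transcript per gene by highest CDS coverage.

Overlap tests use the upper-tail hypergeometric distribution over a gene
universe that defaults to all genes passing the complete-CDS gate —
config-overridable, since any universe choice is defensible and the
p-values move with it. Benjamini–Hochberg correction applies across
whatever family of tests is computed together. The rank sweep counts
newly gained reference-set genes per rank bin (width 500) against a
uniform-placement expectation over the full ranking — an explicit,
simple null; observed and expected increment vectors are compared by
two-sided Mann–Whitney, exact when there are at most 30 tie-free bins
per side, asymptotic otherwise, with the method recorded. Note the test
has power only when the sweep range is a proper subset of the ranking
(otherwise both vectors share their sum by construction).

## Start-context analyses

TIS efficiency scores are exact 8-mer lookups (4 nt upstream + start
codon + 1 nt downstream, the spelling of the optimal context
CACCAUGG = 100); absent contexts are reported missing, never imputed.
The context width follows the printed optimal context; a wider table can
be swapped in. The structure scan slides a 22-nt window at 1-nt steps
from 10 nt upstream to 100 nt downstream of a start. The built-in
energy is the negated maximum number of nested base pairs (minimum
hairpin loop 3, G·U allowed) — a pair-maximisation stand-in chosen for
exactness and testability, not a thermodynamic model; every profile
carries an `energy_model_id` so outputs from different energy functions
cannot silently mix, and real folding engines plug in via `energy_fn`.

## What the generator emulates — and what it does not

The synthetic cohorts are built to match the detector's and scorer's
model assumptions, which is exactly what makes power and calibration
analytically checkable — and what limits what passing tests prove about
real data.

Emulated: per-codon read depths (Poisson, mean `depth = 10`/codon at
reference conditions) split across frames with frame-0 probability
`p_frame = 0.8`; a density step of `step_mult = 5` at planted starts;
per-gene expression variation (mean-1 log-normal multiplier,
`depth_spread = 0.5`) driving the rank/coverage relationship;
initiation-channel peaks (`init_peak = 20` reads) at used starts;
planted decoy classes (short extensions, zero coverage, same-strand
coding-exon overlaps); star-tree codon evolution at `t_branch = 0.3`
proposals/codon/branch with `omega` 0.1 (coding) or 1 (neutral), stops
rejected under the coding regime; strong initiation contexts (G at +4
with probability 0.8) at true starts; spliced and unspliced gene
structures on both strands. Background reads land within the translated
span of a transcript — an untranslated 5' leader genuinely shows
near-zero footprint density, which is what the control set's covered-
fraction rule describes.

Not emulated: sequence-dependent ligation/amplification bias, P-site
offset uncertainty across read lengths (profiles are consumed already
P-site-assigned), reads mapping across paralogs, non-uniform codon-level
dwell times, phylogenetic correlation between species, indel evolution,
and isoform mixtures. Consequently, passing calibration here shows the
statistics are correct under their null, not that real libraries satisfy
that null; on real data the upstream QC (per-sample in-frame fraction,
emitted by `periodicity_qc()`) and the external scorer option matter.

Determinism: every generator function derives its RNG stream from
`sim_config(seed)` plus a fixed per-function offset, so any subset of
outputs is reproducible without generating the rest; emitted files carry
the config hash in a header comment where the format allows comments
(GTF, TSV, MAF, VCF — the GENCODE-style FASTA dialect does not, so its
hash travels in the ground-truth table and run report).

## Numerical choices and degenerate inputs

Coordinates are 0-based half-open everywhere internally; 1-based
conventions (GTF, FASTA headers, VCF) are converted only at I/O
boundaries. Zero-read regions give p-values of exactly 1. P-values are
floored at the smallest positive double before combination so logs stay
finite. Empty candidate lists, empty rankings and empty gene sets are
legal values with warnings, not errors; a constant coverage vector or
fewer than five pairs make the rank/coverage correlation an explicit
error (`degenerate`, `insufficient_n`) rather than an `NA`. All
tie-breaks (candidate calls, ranking, gene collapse, control-set
selection) are documented total orders, so reruns are byte-identical —
the pipeline's run report checks this with file checksums and asserts
count conservation (`in = out + dropped`, reasons summing to the drop)
at every stage.

Problem sizes in the test-suite and acceptance script — 1,000 transcripts
against the extraction oracle, 500×500 interval instances, 2,000
noise-only extensions for calibration, 500 genes with 50 planted
extensions for ranking power, 200 + 200 alignment windows for scorer
separation — were chosen as the smallest cohorts at which the binomial
standard errors of the measured rates are comfortably below the margins
being asserted.

## Known limitations

The built-in conservation scorer is not a substitute for an empirical
codon model when absolute coding likelihoods matter; it is a pluggable
monotone signal. The detector assumes P-site assignment upstream of the
package. The 50-codon window can dilute or truncate true extensions far
from that length, biasing both arms against very short and very long
extensions — a structural property of fixed-window designs, not a
parameter to tune away. And the two arms share the extraction filters,
so a transcript lost there is invisible to both kinds of evidence.
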