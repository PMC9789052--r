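# Internal sequence helpers. Everything is DNA-alphabet and 0-based
# half-open internally; conversions to/from 1-based conventions happen
# only in the I/O functions.

STOP_CODONS <- c("TAA", "TAG", "TGA")

# AUG plus the nine near-cognate codons (one mismatch from AUG), DNA spelling.
START_PALETTE <- c("ATG", "CTG", "GTG", "TTG", "ATA", "ATT", "ATC",
                   "ACG", "AGG", "AAG")

ALL_CODONS <- {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

# Amino acid per codon ("*" for stops), from the standard genetic code.
codon_aa <- local({
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc[ALL_CODONS]), ALL_CODONS)
})

is_stop_codon <- function(codon) codon %in% STOP_CODONS

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Gap ("-") and missing (".") markers pass through unchanged.
complement_chars <- function(x) {
  chartr("ACGTNacgtn", "TGCANtgcan", x)
}

# Split a sequence into consecutive codons starting at `from` (0-based).
codons_of <- function(seq, from, n_codons) {
  if (n_codons <= 0L) return(character(0))
  starts <- from + 3L * (seq_len(n_codons) - 1L)
  substring(seq, starts + 1L, starts + 3L)
}

# Normalise RNA/DNA spelling to uppercase DNA.
norm_dna <- function(x) chartr("u", "T", chartr("U", "T", toupper(x)))

assert_cols <- function(df, cols, what = deparse(substitute(df))) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

# Stable short hash of an R object (used to stamp generated files).
config_hash <- function(x) rlang::hash(x)
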