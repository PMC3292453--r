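# Internal sequence and alignment helpers shared across modules.

.datatable.aware <- TRUE

BASES <- c("A", "C", "G", "T")

#' @importFrom stats runif rpois setNames
random_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

# integer encoding A=0 C=1 G=2 T=3, N/other = NA
seq_to_int <- function(s) {
  v <- match(strsplit(toupper(s), "", fixed = TRUE)[[1]], BASES) - 1L
  v
}

int_to_seq <- function(v) {
  paste(BASES[v + 1L], collapse = "")
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Shannon entropy in bits/base over mononucleotide frequencies
shannon_entropy <- function(s) {
  v <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
  tab <- table(factor(v, levels = BASES))
  p <- tab / sum(tab)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Substitution matrix over A,C,G,T,N; N is neutral (score 0) against anything.
scoring_matrix <- function(match, mismatch) {
  letters <- c(BASES, "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(letters, letters))
  diag(m) <- match
  m["N", ] <- 0
  m[, "N"] <- 0
  m
}

# Local (Smith-Waterman) alignment of two sequences under the package's affine
# scheme. gap_open/gap_extend are the (negative) per-event penalties as stored
# in AnnotateConfig; Biostrings wants positive costs with the opening cost not
# including the first extension.
local_align <- function(pattern, subject, match = 3, mismatch = -4,
                        gap_open = -6, gap_extend = -1) {
  Biostrings::pairwiseAlignment(
    pattern = pattern, subject = subject, type = "local",
    substitutionMatrix = scoring_matrix(match, mismatch),
    gapOpening = abs(gap_open) - abs(gap_extend), gapExtension = abs(gap_extend)
  )
}

# identity = matching columns / alignment length (gap columns count against)
alignment_identity <- function(aln_a, aln_b) {
  a <- strsplit(aln_a, "", fixed = TRUE)[[1]]
  b <- strsplit(aln_b, "", fixed = TRUE)[[1]]
  sum(a == b & a != "-") / length(a)
}

# Derive a child seed from the master seed and a small offset, staying within
# 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
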