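# Low-level nucleotide string helpers shared by all stages.
# Sequences are plain upper-case character scalars over {A,C,G,T,N};
# all coordinates are 0-based half-open unless a function says otherwise.

#' Reverse complement of nucleotide strings
#'
#' Vectorised over its input; `N` complements to `N`.
#'
#' @param x character vector of sequences over `{A,C,G,T,N}`.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Number of mismatching positions between two equal-length strings.
#' @noRd
str_mismatches <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  stopifnot(length(ra) == length(rb))
  sum(ra != rb)
}

# Logical match vector between two equal-length strings.
#' @noRd
str_match_vec <- function(a, b) {
  charToRaw(a) == charToRaw(b)
}

# All k-mers of a single sequence, as (kmer, pos0) with 0-based start
# positions.  K-mers containing N are dropped: N never seeds matches.
#' @noRd
seq_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(list(kmer = character(0), pos0 = integer(0)))
  starts <- seq_len(n - k + 1L)
  km <- substring(seq, starts, starts + k - 1L)
  keep <- !grepl("N", km, fixed = TRUE)
  list(kmer = km[keep], pos0 = starts[keep] - 1L)
}

# K-mers of many sequences at once via one concatenated string with 'N'
# spacers (spacer-crossing k-mers contain N and are dropped).  Returns
# (kmer, seq_idx, pos0).
#' @noRd
multi_seq_kmers <- function(seqs, k) {
  if (length(seqs) == 0L) {
    return(list(kmer = character(0), seq_idx = integer(0), pos0 = integer(0)))
  }
  lens <- nchar(seqs)
  spacer <- strrep("N", k)
  big <- paste(seqs, collapse = spacer)
  nb <- nchar(big)
  if (nb < k) return(list(kmer = character(0), seq_idx = integer(0), pos0 = integer(0)))
  starts <- seq_len(nb - k + 1L)
  km <- substring(big, starts, starts + k - 1L)
  # map a global 1-based start to (sequence, local 0-based offset)
  seq_start <- cumsum(c(1L, head(lens, -1L) + k))
  idx <- findInterval(starts, seq_start)
  local0 <- starts - seq_start[idx]
  keep <- !grepl("N", km, fixed = TRUE) & local0 <= (lens[idx] - k)
  list(kmer = km[keep], seq_idx = idx[keep], pos0 = as.integer(local0[keep]))
}

# Validate and normalise a nucleotide sequence string.
#' @noRd
normalize_seq <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    stop(what, " must be a single character string", call. = FALSE)
  }
  s <- toupper(seq)
  if (nchar(s) < 1L) stop(what, " must have length >= 1", call. = FALSE)
  if (grepl("[^ACGTN]", s)) {
    bad <- regmatches(s, regexpr("[^ACGTN]", s))
    stop(what, " contains disallowed symbol '", bad, "'", call. = FALSE)
  }
  s
}

# Random nucleotide string (uses the current RNG state).
#' @noRd
random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
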