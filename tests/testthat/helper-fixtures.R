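# Shared fixture builders.  Everything is generated in code under fixed
# seeds; no data files.

# Deterministic error-free single-end reads tiling a genome at fixed step.
tile_reads <- function(genome_seq, read_len = 150L, step = 5L,
                       prefix = "t") {
  L <- nchar(genome_seq)
  starts <- seq(1L, L - read_len + 1L, by = step)
  readset(sprintf("%s%06d", prefix, seq_along(starts)),
          substring(genome_seq, starts, starts + read_len - 1L))
}

# Substitute a fraction of positions (never to the same base).
mutate_seq <- function(seq, rate, seed = 1L) {
  withr::with_seed(seed, {
    n <- nchar(seq)
    pos <- which(stats::runif(n) < rate)
    for (p in pos) {
      orig <- substr(seq, p, p)
      alt <- setdiff(c("A", "C", "G", "T"), orig)
      substr(seq, p, p) <- sample(alt, 1L)
    }
    seq
  })
}

# Random uppercase ACGT sequence under a local seed.
rand_seq <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = ""))
}

# Fraction of a target's 21-mers found in a query sequence.
kmer_recovery <- function(target_seq, query_seq, k = 21L) {
  tk <- unique(substring(target_seq, 1:(nchar(target_seq) - k + 1L),
                         k:nchar(target_seq)))
  qk <- unique(substring(query_seq, 1:(nchar(query_seq) - k + 1L),
                         k:nchar(query_seq)))
  mean(tk %in% qk)
}

# Count of a target's 21-mers present in the query (contamination check).
kmer_hits <- function(target_seq, query_seq, k = 21L) {
  tk <- unique(substring(target_seq, 1:(nchar(target_seq) - k + 1L),
                         k:nchar(target_seq)))
  qk <- unique(substring(query_seq, 1:(nchar(query_seq) - k + 1L),
                         k:nchar(query_seq)))
  sum(qk %in% tk)
}
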