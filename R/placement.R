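# Gapless semiglobal read placement by k-mer probes + mismatch verification.
#
# Each read is probed at a handful of k-mer positions; probes vote for a
# candidate offset on the contig (first occurrence wins for repeated
# k-mers).  A read is placed at the modal offset when at least two probes
# agree and the clipped overlap passes a mismatch-rate check.  Reads whose
# left-half and right-half probes vote for two different offsets are not
# placed but are reported with both offsets -- the polisher uses them as
# small-indel evidence.

# Modal value and vote count of a numeric vector with NAs.
#' @noRd
vec_mode <- function(v) {
  v <- v[!is.na(v)]
  if (!length(v)) return(c(NA_integer_, 0L))
  t <- table(v)
  i <- which.max(t)
  c(as.integer(names(t)[i]), as.integer(t[i]))
}

# Probe offsets for one strand: returns an n x P matrix of candidate
# 0-based start offsets (NA where the probe found no contig k-mer).
#' @noRd
probe_offsets <- function(seqs, ckmers, k, n_probes) {
  n <- length(seqs)
  lens <- nchar(seqs)
  P <- n_probes
  offs <- matrix(NA_integer_, n, P)
  # probe start positions per read (1-based), spread across the read
  for (j in seq_len(P)) {
    p <- pmax(1L, pmin(lens - k + 1L,
                       1L + floor((j - 1L) * (lens - k) / max(1L, P - 1L))))
    km <- substring(seqs, p, p + k - 1L)
    hit <- match(km, ckmers)                # 1-based contig k-mer start
    offs[, j] <- hit - p                    # 0-based read start on contig
  }
  offs
}

# Collapse probe votes row-wise: list(off, votes) with a fast path for
# rows whose non-NA probes all agree.
#' @noRd
collapse_votes <- function(offs) {
  n <- nrow(offs)
  off <- rep(NA_integer_, n)
  votes <- integer(n)
  nn <- rowSums(!is.na(offs))
  cols <- lapply(seq_len(ncol(offs)), function(j) offs[, j])
  rmin <- do.call(pmin, c(cols, list(na.rm = TRUE)))
  rmax <- do.call(pmax, c(cols, list(na.rm = TRUE)))
  agree <- nn > 0L & !is.na(rmin) & rmin == rmax
  off[agree] <- as.integer(rmin[agree])
  votes[agree] <- nn[agree]
  mixed <- which(nn > 0L & !agree)
  for (i in mixed) {
    m <- vec_mode(offs[i, ])
    off[i] <- m[1L]
    votes[i] <- m[2L]
  }
  list(off = off, votes = votes)
}

#' Place reads on a contig
#'
#' Gapless placement of every read (both strands) on the contig, with end
#' clipping.  Returns one row per read; unplaced reads have `accepted =
#' FALSE`.  For reads rejected gaplessly but with consistent left-half and
#' right-half probe offsets, `off_left`/`off_right` expose the two offsets
#' (small-indel evidence for [polish()]).
#'
#' @param ctg a [contig()] (or a plain sequence string).
#' @param rs a [readset()].
#' @param k probe k-mer size, default 21.
#' @param n_probes number of probe positions per read, default 6.
#' @param max_mismatch_rate maximum mismatch fraction over the clipped
#'   overlap, default 0.1.
#' @param min_overlap minimum clipped overlap in bp, default 30.
#' @return data frame with columns `read` (index into `rs`), `strand`
#'   (`"+"`/`"-"`), `start`, `end` (clipped, 0-based half-open), `offset`,
#'   `mismatches`, `accepted`, `off_left`, `off_right`.
#' @export
place_reads <- function(ctg, rs, k = 21L, n_probes = 6L,
                        max_mismatch_rate = 0.1, min_overlap = 30L) {
  cseq <- if (inherits(ctg, "contig")) ctg$seq else ctg
  L <- nchar(cseq)
  n <- n_reads(rs)
  if (L < k || n == 0L) {
    return(data.frame(read = integer(0), strand = character(0),
                      start = integer(0), end = integer(0), offset = integer(0),
                      mismatches = integer(0), accepted = logical(0),
                      off_left = integer(0), off_right = integer(0)))
  }
  starts <- seq_len(L - k + 1L)
  ckmers <- substring(cseq, starts, starts + k - 1L)

  fwd <- probe_offsets(rs$seqs, ckmers, k, n_probes)
  rev <- probe_offsets(readset_revcomp(rs), ckmers, k, n_probes)
  vf <- collapse_votes(fwd)
  vr <- collapse_votes(rev)

  use_rev <- vr$votes > vf$votes
  off <- ifelse(use_rev, vr$off, vf$off)
  votes <- ifelse(use_rev, vr$votes, vf$votes)
  strand <- ifelse(use_rev, "-", "+")
  seqs <- ifelse(use_rev, readset_revcomp(rs), rs$seqs)
  lens <- nchar(seqs)

  res <- data.frame(read = seq_len(n), strand = strand,
                    start = NA_integer_, end = NA_integer_, offset = off,
                    mismatches = NA_integer_, accepted = FALSE,
                    off_left = NA_integer_, off_right = NA_integer_,
                    stringsAsFactors = FALSE)

  craw <- charToRaw(cseq)
  cand <- which(votes >= 2L)
  for (i in cand) {
    s0 <- off[i]
    e0 <- s0 + lens[i]
    cs <- max(0L, s0)
    ce <- min(L, e0)
    ovl <- ce - cs
    if (ovl < min_overlap) next
    rseg <- charToRaw(substr(seqs[i], cs - s0 + 1L, ce - s0))
    mm <- sum(rseg != craw[(cs + 1L):ce])
    res$start[i] <- cs
    res$end[i] <- ce
    res$mismatches[i] <- mm
    res$accepted[i] <- mm <= ceiling(max_mismatch_rate * ovl)
  }

  # split-offset evidence for rejected reads (indel candidates)
  half <- ceiling(n_probes / 2)
  rej <- which(!res$accepted)
  for (i in rej) {
    offs <- if (use_rev[i]) rev[i, , drop = TRUE] else fwd[i, , drop = TRUE]
    ml <- vec_mode(offs[seq_len(half)])
    mr <- vec_mode(offs[(half + 1L):n_probes])
    if (ml[2L] >= 2L) res$off_left[i] <- ml[1L]
    if (mr[2L] >= 2L) res$off_right[i] <- mr[1L]
  }
  res
}

#' Accepted placements as coverage intervals
#'
#' @param placements output of [place_reads()].
#' @return data frame of `start`, `end` intervals from accepted placements,
#'   ready for [compute_depth()].
#' @export
placement_intervals <- function(placements) {
  acc <- placements[placements$accepted, c("start", "end")]
  rownames(acc) <- NULL
  acc
}
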