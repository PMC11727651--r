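# Pileup-majority polishing: substitution and small-indel correction of the
# final contig from the read pileup.  Reads are placed with the same
# gapless semiglobal machinery the rest of the pipeline uses; reads whose
# left and right halves place at two consistent but different offsets are
# the evidence for short indels.

#' Polishing parameters
#'
#' @param min_depth minimum pileup depth at a column before it may be
#'   edited (default 5).
#' @param min_majority minimum frequency of the plurality symbol among the
#'   covering reads for a correction (default 0.7; must exceed 0.5).
#' @param max_indel_len longest insertion/deletion that will be corrected
#'   (default 10); longer discrepancies are left to the trim/extension
#'   machinery.
#' @return an object of class `polish_params`.
#' @export
polish_params <- function(min_depth = 5L, min_majority = 0.7,
                          max_indel_len = 10L) {
  stopifnot(min_depth >= 1L, min_majority > 0.5, min_majority <= 1,
            max_indel_len >= 1L)
  structure(list(min_depth = as.integer(min_depth),
                 min_majority = min_majority,
                 max_indel_len = as.integer(max_indel_len)),
            class = "polish_params")
}

# Pileup base counts from accepted gapless placements: 5 x L matrix over
# A,C,G,T,N.
#' @noRd
pileup_counts <- function(cseq, rs, pl) {
  L <- nchar(cseq)
  code <- integer(256)
  code[utf8ToInt("A")] <- 1L; code[utf8ToInt("C")] <- 2L
  code[utf8ToInt("G")] <- 3L; code[utf8ToInt("T")] <- 4L
  code[utf8ToInt("N")] <- 5L
  acc <- which(pl$accepted)
  if (!length(acc)) return(matrix(0L, 5L, L))
  rc <- readset_revcomp(rs)
  pos_all <- vector("list", length(acc))
  base_all <- vector("list", length(acc))
  for (j in seq_along(acc)) {
    i <- acc[j]
    s <- if (pl$strand[i] == "-") rc[pl$read[i]] else rs$seqs[pl$read[i]]
    cs <- pl$start[i]; ce <- pl$end[i]; off <- pl$offset[i]
    seg <- substr(s, cs - off + 1L, ce - off)
    pos_all[[j]] <- cs:(ce - 1L)
    base_all[[j]] <- code[utf8ToInt(seg)]
  }
  pos <- unlist(pos_all)            # 0-based columns
  bse <- unlist(base_all)
  matrix(tabulate(bse + 5L * pos, nbins = 5L * L), nrow = 5L)
}

# Detect small-indel candidates from reads rejected by gapless placement.
# Returns votes data frame (pos0, d, bases) with one row per supporting
# read, already left-normalised via a minimal-cost breakpoint.
#' @noRd
indel_votes <- function(cseq, rs, pl, params) {
  L <- nchar(cseq)
  craw <- charToRaw(cseq)
  rc <- readset_revcomp(rs)
  cand <- which(!pl$accepted & !is.na(pl$off_left) & !is.na(pl$off_right) &
                  pl$off_left != pl$off_right)
  rows <- list()
  for (i in cand) {
    oL <- pl$off_left[i]; oR <- pl$off_right[i]
    d <- oR - oL                       # d < 0: contig lacks |d| bases
    if (abs(d) > params$max_indel_len) next
    s <- if (pl$strand[i] == "-") rc[pl$read[i]] else rs$seqs[pl$read[i]]
    n <- nchar(s)
    skip <- max(0L, -d)                # read bases absent from the contig
    # clip to contig bounds for both offset regimes
    if (oL < 0L || oR < 0L || oL + n > L + abs(d) + 1L) next
    rraw <- charToRaw(s)
    # mismatch cost of read[1..b] at offset oL (prefix) and read[b+1..n] at
    # offset oR (suffix), as cumulative vectors
    iL <- oL + seq_len(n)              # 1-based contig pos under left offset
    iR <- oR + seq_len(n)
    okL <- iL >= 1L & iL <= L
    okR <- iR >= 1L & iR <= L
    mmL <- cumsum(ifelse(okL, craw[pmin(pmax(iL, 1L), L)] != rraw, 1L))
    mmRv <- ifelse(okR, craw[pmin(pmax(iR, 1L), L)] != rraw, 1L)
    tot <- sum(mmRv)
    mmR <- c(tot, tot - cumsum(mmRv))  # mmR[b+1] = cost of read[(b+1)..n]
    # breakpoint b: left part = read[1..b], skip `skip` bases, right part
    # = read[(b+skip+1)..n]
    bs <- 0:(n - skip)
    cost <- c(0L, mmL)[bs + 1L] + mmR[bs + skip + 1L]
    b <- bs[which.min(cost)]           # leftmost minimal breakpoint
    if (min(cost) > ceiling(0.1 * n)) next
    pos0 <- oL + b                     # contig breakpoint, 0-based
    if (pos0 < 0L || pos0 > L || (d > 0L && pos0 + d > L)) next
    bases <- if (d < 0L) substr(s, b + 1L, b + skip) else ""
    rows[[length(rows) + 1L]] <- data.frame(pos0 = pos0, d = d,
                                            bases = bases,
                                            stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(pos0 = integer(0), d = integer(0),
                      bases = character(0)))
  }
  do.call(rbind, rows)
}

#' Polish a contig by pileup majority consensus
#'
#' Reads are placed on the contig; at every column with depth at least
#' `min_depth` where the plurality base differs from the contig base with
#' frequency at least `min_majority`, the contig base is corrected.  Short
#' insertions/deletions (up to `max_indel_len` bp) supported by at least
#' `min_majority` of the reads spanning the breakpoint are repaired first,
#' and reads are re-placed before the substitution pass.  All changes are
#' recorded in a single `base_correction` edit event.
#'
#' @param ctg a [contig()].
#' @param rs a [readset()].
#' @param params a [polish_params()].
#' @param iteration iteration index for the event record.
#' @return the polished [contig()]; unchanged (no event) when there is
#'   nothing to correct or no read places.
#' @export
polish <- function(ctg, rs, params = polish_params(), iteration = 0L) {
  if (n_reads(rs) == 0L) return(ctg)
  pl <- place_reads(ctg, rs)
  if (!any(pl$accepted)) return(ctg)

  seq0 <- ctg$seq

  # ---- indel pass ----
  votes <- indel_votes(seq0, rs, pl, params)
  applied_indels <- data.frame(pos0 = integer(0), d = integer(0),
                               bases = character(0))
  if (nrow(votes)) {
    grp <- paste(votes$pos0, votes$d, votes$bases, sep = "|")
    rc <- readset_revcomp(rs)
    for (g in names(sort(table(grp), decreasing = TRUE))) {
      v <- votes[grp == g, ][1L, ]
      support <- sum(grp == g)
      if (support < params$min_depth) next
      # opposition: accepted reads that align mismatch-free across the
      # breakpoint window -- impossible for every read if the indel is real,
      # so partially misplaced reads (indel near a read end) do not veto
      flank <- max(5L, abs(v$d) + 2L)
      ws <- max(0L, v$pos0 - flank)
      we <- min(nchar(seq0), v$pos0 + flank)
      span_idx <- which(pl$accepted & pl$start <= ws & pl$end >= we)
      oppose <- 0L
      for (i in span_idx) {
        s <- if (pl$strand[i] == "-") rc[pl$read[i]] else rs$seqs[pl$read[i]]
        rseg <- substr(s, ws - pl$offset[i] + 1L, we - pl$offset[i])
        if (str_mismatches(rseg, substr(seq0, ws + 1L, we)) == 0L) {
          oppose <- oppose + 1L
        }
      }
      if (support / (support + oppose) < params$min_majority) next
      applied_indels <- rbind(applied_indels, v)
    }
    if (nrow(applied_indels)) {
      # apply right-to-left so earlier positions stay valid
      applied_indels <- applied_indels[order(-applied_indels$pos0), ]
      # drop overlapping edits (keep the better-supported, i.e. first, ones)
      keep <- rep(TRUE, nrow(applied_indels))
      if (nrow(applied_indels) > 1L) {
        for (i in 2:nrow(applied_indels)) {
          prev <- applied_indels[seq_len(i - 1L), ]
          keep[i] <- all(abs(prev$pos0 - applied_indels$pos0[i]) >
                           params$max_indel_len + 1L)
        }
      }
      applied_indels <- applied_indels[keep, ]
      new_seq <- apply_corrections(seq0, list(indels = applied_indels))
      tmp <- ctg
      tmp$seq <- new_seq
      pl <- place_reads(tmp, rs)     # re-place before the substitution pass
      seq0 <- new_seq
    }
  }

  # ---- substitution pass ----
  counts <- pileup_counts(seq0, rs, pl)
  depth <- colSums(counts)
  bases <- c("A", "C", "G", "T", "N")
  top <- max.col(t(counts), ties.method = "first")
  topn <- counts[cbind(top, seq_along(depth))]
  refv <- strsplit(seq0, "")[[1]]
  edit <- which(depth >= params$min_depth &
                  bases[top] != refv &
                  bases[top] != "N" &
                  topn / pmax(depth, 1L) >= params$min_majority)
  snvs <- data.frame(pos0 = edit - 1L, from = refv[edit], to = bases[top][edit],
                     depth = depth[edit],
                     majority = round(topn[edit] / depth[edit], 4),
                     stringsAsFactors = FALSE)

  if (!nrow(snvs) && !nrow(applied_indels)) return(ctg)
  final_seq <- apply_corrections(ctg$seq,
                                 list(indels = applied_indels, snvs = snvs))
  append_event(ctg, final_seq, "base_correction", interval = NULL,
               iteration = iteration,
               detail = list(indels = applied_indels, snvs = snvs))
}
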