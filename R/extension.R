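# Edge-local extension: extract contig edges, recruit reads to them by
# shared k-mers, greedily assemble outward by suffix-prefix overlap, merge
# growth back into the contig, and -- when extension stalls -- trim both
# ends and retry with increasing trim sizes.

#' Extension parameters
#'
#' @param edge_factor edge length as a multiple of the read length
#'   (default 1.5: an edge is `round(read_length * 1.5)` bp).
#' @param trim_schedule increasing trim sizes in bp tried by
#'   [trim_and_retry()]; default `c(300, 500, 1000, 1500, 2000)`.
#' @param recruit_k k-mer size for read recruitment and overlap seeding
#'   (default 21).
#' @param min_shared_kmers k-mers a read must share with an edge to be
#'   recruited (default 3).
#' @param min_overlap minimum suffix-prefix overlap in bp (default 30).
#' @param max_mismatch_rate maximum mismatch fraction in an accepted
#'   overlap (default 0.02).
#' @param max_round_growth safety cap on bp added per side per round
#'   (default `50 * 150`); normally unreachable because recruitment is
#'   edge-local.
#' @return an object of class `extension_params`.
#' @export
extension_params <- function(edge_factor = 1.5,
                             trim_schedule = c(300L, 500L, 1000L, 1500L, 2000L),
                             recruit_k = 21L, min_shared_kmers = 3L,
                             min_overlap = 30L, max_mismatch_rate = 0.02,
                             max_round_growth = 7500L) {
  stopifnot(edge_factor > 0,
            length(trim_schedule) == 0L ||
              (all(diff(trim_schedule) > 0) && max(trim_schedule) <= 2000L),
            recruit_k >= 4L, min_shared_kmers >= 1L, min_overlap >= 1L,
            max_mismatch_rate >= 0, max_mismatch_rate < 0.5)
  structure(list(edge_factor = edge_factor,
                 trim_schedule = as.integer(trim_schedule),
                 recruit_k = as.integer(recruit_k),
                 min_shared_kmers = as.integer(min_shared_kmers),
                 min_overlap = as.integer(min_overlap),
                 max_mismatch_rate = max_mismatch_rate,
                 max_round_growth = as.integer(max_round_growth)),
            class = "extension_params")
}

#' Extract the two edge regions of a contig
#'
#' Edges are the first and last `round(read_length * edge_factor)` bases.
#' Contigs shorter than two edge lengths are split into two non-overlapping
#' halves.
#'
#' @param ctg a [contig()].
#' @param read_length representative read length.
#' @param params an [extension_params()].
#' @return list with single-row [region()] entries `left` and `right`.
#' @export
extract_edges <- function(ctg, read_length, params = extension_params()) {
  Ls <- contig_length(ctg)
  el <- as.integer(round(read_length * params$edge_factor))
  if (Ls < 2L * el) {
    half <- Ls %/% 2L
    return(list(left = region(ctg$id, 0L, max(1L, half), "edge"),
                right = region(ctg$id, max(1L, half), Ls, "edge")))
  }
  list(left = region(ctg$id, 0L, el, "edge"),
       right = region(ctg$id, Ls - el, Ls, "edge"))
}

#' Recruit reads to the contig edges
#'
#' A read is recruited when it shares at least `min_shared_kmers` k-mers
#' with either edge on either strand; the mate of a recruited read is
#' always recruited with it, regardless of the mate's own match (mates
#' provide reach beyond the edge).
#'
#' @param rs a [readset()].
#' @param edges list of `left`/`right` [region()] rows from
#'   [extract_edges()].
#' @param ctg the [contig()] the edges live on.
#' @param params an [extension_params()].
#' @return a [readset()] holding the recruited reads (possibly empty).
#' @export
recruit_reads <- function(rs, edges, ctg, params = extension_params()) {
  if (n_reads(rs) == 0L) return(rs)
  k <- params$recruit_k
  edge_seqs <- c(substr(ctg$seq, edges$left$start + 1L, edges$left$end),
                 substr(ctg$seq, edges$right$start + 1L, edges$right$end))
  ek <- unique(c(multi_seq_kmers(edge_seqs, k)$kmer,
                 multi_seq_kmers(revcomp(edge_seqs), k)$kmer))
  tab <- readset_kmer_table(rs, k)
  hit <- !is.na(match(tab$kmer, ek))
  counts <- tabulate(abs(tab$read_idx[hit]), nbins = n_reads(rs))
  idx <- which(counts >= params$min_shared_kmers)
  mates <- rs$mate[idx]
  readset_subset(rs, c(idx, mates[!is.na(mates)]))
}

# One greedy rightward extension of `seed` using recruited reads (both
# strands).  Returns list(seq, added, stopped) where `stopped` notes why
# the walk ended.
#' @noRd
greedy_extend_right <- function(seed, recruited, params) {
  k <- params$recruit_k
  min_ov <- params$min_overlap
  if (n_reads(recruited) == 0L || nchar(seed) < min_ov) {
    return(list(seq = seed, added = 0L, stopped = "no_reads"))
  }
  seqs <- c(recruited$seqs, readset_revcomp(recruited))
  ids <- c(paste0(recruited$ids, "+"), paste0(recruited$ids, "-"))
  lens <- nchar(seqs)
  usable <- lens >= min_ov
  pref <- substr(seqs, 1L, k)
  pref[grepl("N", pref, fixed = TRUE) | !usable] <- NA_character_

  S <- seed
  added <- 0L
  visited <- character(0)
  stopped <- "no_overlap"
  repeat {
    Ls <- nchar(S)
    term <- substr(S, Ls - k + 1L, Ls)
    if (term %in% visited) { stopped <- "cycle"; break }
    visited <- c(visited, term)
    # candidate reads: prefix k-mer occurs in the last max(lens) bases of S
    win <- min(Ls - k + 1L, max(lens))
    st <- (Ls - k + 1L) - win + seq_len(win)      # 1-based k-mer starts
    skm <- substring(S, st, st + k - 1L)
    hit <- match(pref, skm)                        # per read-orientation
    cand <- which(!is.na(hit))
    if (!length(cand)) break
    ov <- Ls - st[hit[cand]] + 1L                  # overlap length in bp
    ok <- ov >= min_ov & ov < lens[cand]           # need a positive overhang
    cand <- cand[ok]
    ov <- ov[ok]
    if (!length(cand)) break
    mm_ok <- logical(length(cand))
    for (j in seq_along(cand)) {
      v <- ov[j]
      mm <- str_mismatches(substr(S, Ls - v + 1L, Ls),
                           substr(seqs[cand[j]], 1L, v))
      mm_ok[j] <- mm <= floor(params$max_mismatch_rate * v)
    }
    cand <- cand[mm_ok]
    ov <- ov[mm_ok]
    if (!length(cand)) break
    vmax <- max(ov)
    top <- cand[ov == vmax]
    nxt <- substr(seqs[top], vmax + 1L, vmax + 1L)
    if (length(unique(nxt)) > 1L) { stopped <- "branch"; break }
    pick <- top[order(ids[top])][1L]               # deterministic tie-break
    overhang <- substr(seqs[pick], vmax + 1L, lens[pick])
    S <- paste0(S, overhang)
    added <- added + nchar(overhang)
    if (added >= params$max_round_growth) { stopped <- "growth_cap"; break }
  }
  list(seq = S, added = added, stopped = stopped)
}

#' Locally assemble an edge outward
#'
#' Starting from the edge sequence, repeatedly appends the overhang of the
#' read (either strand) with the longest suffix-prefix overlap of at least
#' `min_overlap` bp at mismatch rate at most `max_mismatch_rate`.
#' Extension is strictly outward, away from the contig body; ties that
#' disagree on the next base stop the walk (branch), as does revisiting a
#' terminal k-mer (cycle guard).
#'
#' @param edge_seq the edge sequence; for `direction = "left"` the edge is
#'   grown leftward (upstream of the contig).
#' @param recruited a [readset()] of recruited reads.
#' @param params an [extension_params()].
#' @param direction `"right"` (default) or `"left"`.
#' @return character vector with the extended edge sequence (the original
#'   edge is always an anchored substring of it).
#' @export
local_assemble <- function(edge_seq, recruited, params = extension_params(),
                           direction = c("right", "left")) {
  direction <- match.arg(direction)
  stopifnot(nchar(edge_seq) > 0L)
  if (direction == "left") {
    res <- greedy_extend_right(revcomp(edge_seq), recruited, params)
    return(revcomp(res$seq))
  }
  greedy_extend_right(edge_seq, recruited, params)$seq
}

#' Merge extended edges back into the contig
#'
#' Each extended edge must still contain its original edge sequence as an
#' anchored substring (suffix for the left side, prefix for the right) at
#' `>= 98%` identity, otherwise that side's growth is discarded.
#'
#' @param ctg the [contig()] the edges came from.
#' @param left_ext extended left edge (edge grown leftward), or the
#'   unchanged edge sequence.
#' @param right_ext extended right edge.
#' @param edges the [extract_edges()] result used for the round.
#' @param iteration iteration index for the event record.
#' @return list of `contig` (with an `extension` event when growth
#'   occurred) and `outcome` (fields `grew`, `left_added_bp`,
#'   `right_added_bp`, `trimmed_bp_applied`).
#' @export
merge_extension <- function(ctg, left_ext, right_ext, edges,
                            iteration = 0L) {
  left_edge <- substr(ctg$seq, edges$left$start + 1L, edges$left$end)
  right_edge <- substr(ctg$seq, edges$right$start + 1L, edges$right$end)

  anchor_ok <- function(ext, edge, side) {
    ne <- nchar(edge)
    nx <- nchar(ext)
    if (nx < ne) return(FALSE)
    anchored <- if (side == "left") substr(ext, nx - ne + 1L, nx)
                else substr(ext, 1L, ne)
    str_mismatches(anchored, edge) <= floor(0.02 * ne)
  }

  left_add <- ""
  right_add <- ""
  if (nchar(left_ext) > nchar(left_edge) && anchor_ok(left_ext, left_edge, "left")) {
    left_add <- substr(left_ext, 1L, nchar(left_ext) - nchar(left_edge))
  }
  if (nchar(right_ext) > nchar(right_edge) && anchor_ok(right_ext, right_edge, "right")) {
    right_add <- substr(right_ext, nchar(right_edge) + 1L, nchar(right_ext))
  }

  outcome <- list(grew = nchar(left_add) + nchar(right_add) > 0L,
                  left_added_bp = nchar(left_add),
                  right_added_bp = nchar(right_add),
                  trimmed_bp_applied = 0L)
  if (!outcome$grew) return(list(contig = ctg, outcome = outcome))
  new_seq <- paste0(left_add, ctg$seq, right_add)
  ctg <- append_event(ctg, new_seq, "extension", interval = NULL,
                      iteration = iteration,
                      detail = list(left = left_add, right = right_add))
  list(contig = ctg, outcome = outcome)
}

# One full extract-recruit-assemble-merge round.
#' @noRd
extension_round <- function(ctg, rs, params, iteration = 0L) {
  edges <- extract_edges(ctg, rs$read_length, params)
  recruited <- recruit_reads(rs, edges, ctg, params)
  left_edge <- substr(ctg$seq, edges$left$start + 1L, edges$left$end)
  right_edge <- substr(ctg$seq, edges$right$start + 1L, edges$right$end)
  left_ext <- local_assemble(left_edge, recruited, params, "left")
  right_ext <- local_assemble(right_edge, recruited, params, "right")
  out <- merge_extension(ctg, left_ext, right_ext, edges, iteration)
  out$n_recruited <- n_reads(recruited)
  out
}

#' Trim contig ends and retry extension
#'
#' For each trim size `t` in the schedule, removes `t` bp from both ends
#' and attempts one extract-recruit-assemble-merge round; the first `t`
#' whose merged contig is strictly longer than the pre-trim contig is
#' accepted (the growth must more than repay the `2 t` trimmed bases).  If
#' no trim succeeds the original contig is returned unchanged.
#'
#' @param ctg a [contig()].
#' @param rs a [readset()].
#' @param params an [extension_params()].
#' @param iteration iteration index for event records.
#' @return list of `contig` and `outcome` as in [merge_extension()], with
#'   `outcome$trimmed_bp_applied` set to the accepted trim (0 on failure).
#' @export
trim_and_retry <- function(ctg, rs, params = extension_params(),
                           iteration = 0L) {
  Ls <- contig_length(ctg)
  el <- as.integer(round(rs$read_length * params$edge_factor))
  fail <- list(contig = ctg,
               outcome = list(grew = FALSE, left_added_bp = 0L,
                              right_added_bp = 0L, trimmed_bp_applied = 0L))
  for (t in params$trim_schedule) {
    if (Ls <= 2L * t + 2L * el) next      # too short for this trim
    trimmed <- append_event(ctg, substr(ctg$seq, t + 1L, Ls - t), "end_trim",
                            interval = region(ctg$id, t, Ls - t, "kept"),
                            iteration = iteration,
                            detail = list(trim_bp = t))
    res <- extension_round(trimmed, rs, params, iteration)
    if (contig_length(res$contig) > Ls) {
      res$outcome$trimmed_bp_applied <- t
      res$outcome$grew <- TRUE
      return(res)
    }
  }
  fail
}
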