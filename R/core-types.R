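# Domain types: Contig, ReadSet, Region, EditEvent, IterationLog.
#
# Conventions: every interval is 0-based half-open internally; 1-based
# inclusive coordinates appear only in human-readable reports.

#' Construct a contig
#'
#' A contig is a named nucleotide sequence plus an append-only history of
#' the edits (trims, extensions, base corrections) applied to it.  Input
#' sequences are normalised to upper case and must contain only
#' `A`, `C`, `G`, `T` or `N`.
#'
#' @param id single character identifier.
#' @param seq nucleotide string of length at least 1.
#' @param history list of edit events (see [edit_event()]); usually empty.
#' @return an object of class `contig` with fields `id`, `seq`, `history`.
#' @examples
#' contig("s", "acgt")$seq  # "ACGT"
#' @export
contig <- function(id, seq, history = list()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  structure(
    list(id = id, seq = normalize_seq(seq, sprintf("contig '%s' sequence", id)),
         history = history),
    class = "contig"
  )
}

#' @export
print.contig <- function(x, ...) {
  cat(sprintf("<contig> %s: %s bp, %d recorded edit(s)\n",
              x$id, format(nchar(x$seq), big.mark = ","), length(x$history)))
  invisible(x)
}

#' Contig length in base pairs
#' @param x a `contig`.
#' @return integer length of the sequence.
#' @export
contig_length <- function(x) nchar(x$seq)

#' Construct an edit event
#'
#' One entry of a contig's provenance history.  `delta_bp` must equal the
#' signed length change the event produced.
#'
#' @param kind one of `"circular_trim"`, `"suspicious_split"`, `"end_trim"`,
#'   `"extension"`, `"base_correction"`.
#' @param interval the affected [region()] (kept region for splits/trims,
#'   removed copy for circular trims), or `NULL`.
#' @param delta_bp signed length change in bp.
#' @param iteration non-negative pipeline iteration index (0 outside the loop).
#' @param detail named list with enough information to replay the event
#'   (see [replay_history()]).
#' @return an object of class `edit_event`.
#' @export
edit_event <- function(kind, interval = NULL, delta_bp = 0L, iteration = 0L,
                       detail = list()) {
  kind <- match.arg(kind, c("circular_trim", "suspicious_split", "end_trim",
                            "extension", "base_correction"))
  stopifnot(iteration >= 0L)
  structure(
    list(kind = kind, interval = interval, delta_bp = as.integer(delta_bp),
         iteration = as.integer(iteration), detail = detail),
    class = "edit_event"
  )
}

# Append an event, asserting the delta matches the observed length change.
#' @noRd
append_event <- function(ctg, new_seq, kind, interval = NULL, iteration = 0L,
                         detail = list()) {
  ev <- edit_event(kind, interval, nchar(new_seq) - nchar(ctg$seq), iteration,
                   detail)
  ctg$seq <- new_seq
  ctg$history <- c(ctg$history, list(ev))
  ctg
}

#' Replay a contig's edit history
#'
#' Applies every recorded edit event, in order, to a starting sequence.
#' For any pipeline output, replaying the history from the original input
#' sequence reproduces the final sequence exactly.
#'
#' @param seq the original (pre-pipeline) nucleotide string.
#' @param history list of `edit_event` objects.
#' @return the reconstructed sequence string.
#' @export
replay_history <- function(seq, history) {
  for (ev in history) {
    seq <- switch(
      ev$kind,
      suspicious_split = ,
      end_trim = substr(seq, ev$interval$start + 1L, ev$interval$end),
      circular_trim = paste0(substr(seq, 1L, ev$interval$start),
                             substr(seq, ev$interval$end + 1L, nchar(seq))),
      extension = paste0(ev$detail$left, seq, ev$detail$right),
      base_correction = apply_corrections(seq, ev$detail)
    )
  }
  seq
}

# Replay helper for base_correction events: detail carries data frames
# `snvs` (pos0, from, to) and `indels` (pos0, d, bases), indels already
# ordered right-to-left as applied.
#' @noRd
apply_corrections <- function(seq, detail) {
  ind <- detail$indels
  if (!is.null(ind) && nrow(ind)) {
    for (i in seq_len(nrow(ind))) {
      p <- ind$pos0[i]
      if (ind$d[i] < 0) {            # contig was missing bases: insert them
        seq <- paste0(substr(seq, 1L, p), ind$bases[i],
                      substr(seq, p + 1L, nchar(seq)))
      } else {                       # contig had extra bases: delete them
        seq <- paste0(substr(seq, 1L, p),
                      substr(seq, p + ind$d[i] + 1L, nchar(seq)))
      }
    }
  }
  snv <- detail$snvs
  if (!is.null(snv) && nrow(snv)) {
    for (i in seq_len(nrow(snv))) {
      substr(seq, snv$pos0[i] + 1L, snv$pos0[i] + 1L) <- snv$to[i]
    }
  }
  seq
}

#' Construct a region table
#'
#' Regions are rows of a data frame with columns `contig_id`, `start`,
#' `end` (0-based half-open) and `label`.  An empty call returns the empty
#' table, used e.g. for "no suspicious regions".
#'
#' @param contig_id character vector of contig identifiers.
#' @param start,end integer vectors, `0 <= start < end`.
#' @param label character vector of labels (e.g. `"suspicious"`).
#' @return a `data.frame` of class `regions`.
#' @export
region <- function(contig_id = character(0), start = integer(0),
                   end = integer(0), label = character(0)) {
  stopifnot(all(start >= 0L), all(end > start))
  df <- data.frame(contig_id = as.character(contig_id),
                   start = as.integer(start), end = as.integer(end),
                   label = as.character(label), stringsAsFactors = FALSE)
  class(df) <- c("regions", "data.frame")
  df
}

#' @noRd
empty_regions <- function() region()

#' Construct a read set
#'
#' Reads are stored column-wise (parallel vectors) for speed.  `mate` holds,
#' for each read, the integer index of its partner (or `NA`).
#' `read_length` is the modal read length of the set, used as the
#' representative length throughout the pipeline.
#'
#' @param ids unique character identifiers.
#' @param seqs nucleotide strings.
#' @param quals optional quality strings (same lengths as `seqs`).
#' @param mate optional integer vector of partner indices.
#' @return an object of class `readset` with fields `ids`, `seqs`, `quals`,
#'   `mate`, `read_length` and an internal cache environment.
#' @export
readset <- function(ids, seqs, quals = NULL, mate = NULL) {
  stopifnot(length(ids) == length(seqs))
  if (anyDuplicated(ids)) stop("read ids must be unique", call. = FALSE)
  seqs <- unname(toupper(seqs))
  if (!is.null(quals)) quals <- unname(quals)
  ids <- unname(ids)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("read '", ids[which(bad)[1L]], "' contains disallowed symbols",
         call. = FALSE)
  }
  if (!is.null(quals) && !all(nchar(quals) == nchar(seqs))) {
    stop("quality strings must match read lengths", call. = FALSE)
  }
  if (is.null(mate)) mate <- rep(NA_integer_, length(ids))
  structure(
    list(ids = as.character(ids), seqs = seqs, quals = quals,
         mate = as.integer(mate),
         read_length = modal_length(nchar(seqs)),
         cache = new.env(parent = emptyenv())),
    class = "readset"
  )
}

#' @export
print.readset <- function(x, ...) {
  cat(sprintf("<readset> %s reads, representative length %d bp, %s paired\n",
              format(length(x$ids), big.mark = ","), x$read_length,
              format(sum(!is.na(x$mate)) / 2, big.mark = ",")))
  invisible(x)
}

#' Number of reads in a read set
#' @param x a `readset`.
#' @return integer count.
#' @export
n_reads <- function(x) length(x$ids)

# Modal value of a length vector; ties broken towards the larger length.
#' @noRd
modal_length <- function(lens) {
  if (length(lens) == 0L) return(0L)
  tab <- table(lens)
  cand <- as.integer(names(tab)[tab == max(tab)])
  max(cand)
}

# Subset a readset by integer indices, remapping mate links.
#' @noRd
readset_subset <- function(rs, idx) {
  idx <- sort(unique(idx))
  map <- integer(length(rs$ids))
  map[idx] <- seq_along(idx)
  new_mate <- rs$mate[idx]
  keep <- !is.na(new_mate) & new_mate %in% idx
  new_mate[!keep] <- NA_integer_
  new_mate[keep] <- map[new_mate[keep]]
  out <- readset(rs$ids[idx], rs$seqs[idx],
                 if (is.null(rs$quals)) NULL else rs$quals[idx],
                 new_mate)
  out$read_length <- rs$read_length   # keep the parent's representative length
  out
}

# Cached reverse complements of all reads.
#' @noRd
readset_revcomp <- function(rs) {
  if (is.null(rs$cache$revcomp)) rs$cache$revcomp <- revcomp(rs$seqs)
  rs$cache$revcomp
}

# Cached k-mer table of all reads (forward and reverse strands):
# list(kmer, read_idx) where read_idx is negative for the reverse strand.
#' @noRd
readset_kmer_table <- function(rs, k) {
  key <- paste0("kmers_", k)
  if (is.null(rs$cache[[key]])) {
    fwd <- multi_seq_kmers(rs$seqs, k)
    rev <- multi_seq_kmers(readset_revcomp(rs), k)
    rs$cache[[key]] <- list(kmer = c(fwd$kmer, rev$kmer),
                            read_idx = c(fwd$seq_idx, -rev$seq_idx))
  }
  rs$cache[[key]]
}

#' Construct an iteration log
#'
#' Ordered record of pipeline rounds.  Exactly one (terminal) round carries a
#' stop reason from `circular`, `no_growth_after_trim`, `max_iterations`,
#' `whole_contig_suspicious`.
#'
#' @param rounds data frame with columns `iteration`, `action`,
#'   `length_before`, `length_after`, `stop_reason`.
#' @return an object of class `iteration_log`.
#' @export
iteration_log <- function(rounds) {
  stopifnot(is.data.frame(rounds),
            all(c("iteration", "action", "length_before", "length_after",
                  "stop_reason") %in% names(rounds)))
  if (nrow(rounds)) {
    stopifnot(all(diff(rounds$iteration) > 0L))
    reasons <- rounds$stop_reason[!is.na(rounds$stop_reason)]
    stopifnot(length(reasons) == 1L,
              reasons %in% c("circular", "no_growth_after_trim",
                             "max_iterations", "whole_contig_suspicious"))
  }
  structure(list(rounds = rounds), class = "iteration_log")
}

#' @export
print.iteration_log <- function(x, ...) {
  r <- x$rounds
  cat(sprintf("<iteration_log> %d round(s), stop reason: %s\n", nrow(r),
              if (nrow(r)) r$stop_reason[!is.na(r$stop_reason)] else "none"))
  if (nrow(r)) print.data.frame(utils::tail(r, 10L), row.names = FALSE)
  invisible(x)
}

#' Stop reason of a pipeline run
#' @param log an `iteration_log`.
#' @return the terminal stop reason string.
#' @export
stop_reason <- function(log) {
  r <- log$rounds$stop_reason
  r[!is.na(r)][1L]
}
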