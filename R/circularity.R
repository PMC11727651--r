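# Circularity / terminal-redundancy detection and trimming.
#
# A contig that closed the circle during assembly carries the genome start
# duplicated at its 3' end.  The detector takes the terminal window
# G_a = [L_s - 2*L_r, L_s - L_r) (one read length, one read length before
# the end) and searches for it in the remainder G_b = [0, L_s - 2*L_r)
# with an exact k-mer seed (k = 21) and ungapped diagonal extension.  A hit
# qualifies when an alignment window of at least `aln_len_frac * L_r`
# columns on a seeded diagonal reaches the identity threshold; the window
# is then grown base-by-base in both directions (mismatches allowed while
# the running identity stays at or above the threshold) into the maximal
# repeat pair.  Only the forward strand is eligible for trimming; an
# inverted terminal repeat is reported as a hint but never trimmed.

#' Check a contig for circularity / terminal redundancy
#'
#' @param ctg a [contig()].
#' @param read_length representative read length `L_r` of the read set.
#' @param identity_threshold minimum identity of the repeat alignment
#'   (default 0.95).
#' @param aln_len_frac minimum alignment length as a fraction of the probe
#'   window length (default 0.95).
#' @param k seed k-mer size (default 21).
#' @return an object of class `circularity_result` with fields
#'   `is_circular`, `match_in_gb` (left copy as a [region()] row or `NULL`),
#'   `maximal_repeat` (two-row [region()] of the copies or `NULL`),
#'   `repeat_length`, `identity`, `inverted_repeat_hint` and `note`.
#' @export
check_circularity <- function(ctg, read_length,
                              identity_threshold = 0.95,
                              aln_len_frac = 0.95, k = 21L) {
  Ls <- contig_length(ctg)
  Lr <- as.integer(read_length)
  not_circ <- function(note) {
    structure(list(is_circular = FALSE, match_in_gb = NULL,
                   maximal_repeat = NULL, repeat_length = 0L,
                   identity = NA_real_, inverted_repeat_hint = FALSE,
                   note = note),
              class = "circularity_result")
  }
  if (Ls <= 3L * Lr) {
    res <- not_circ("contig shorter than 3 read lengths; circularity not assessable")
    warning("contig '", ctg$id, "' is too short (", Ls,
            " bp <= 3 * ", Lr, " bp) for the circularity check", call. = FALSE)
    return(res)
  }

  ga_start <- Ls - 2L * Lr            # 0-based
  ga <- substr(ctg$seq, ga_start + 1L, ga_start + Lr)
  gb_len <- Ls - 2L * Lr
  gb <- substr(ctg$seq, 1L, gb_len)

  gak <- seq_kmers(ga, k)
  if (!length(gak$kmer)) return(not_circ("probe window is all N"))
  starts <- seq_len(gb_len - k + 1L)
  gbk <- substring(gb, starts, starts + k - 1L)

  hit <- match(gbk, gak$kmer)
  jj <- which(!is.na(hit))
  # inverted terminal repeat hint (reported, never trimmed)
  ga_rc <- revcomp(ga)
  rck <- seq_kmers(ga_rc, k)
  itr <- length(rck$kmer) > 0L && any(!is.na(match(gbk, rck$kmer)))

  if (!length(jj)) {
    res <- not_circ("no seed match of the terminal window in the contig body")
    res$inverted_repeat_hint <- itr
    return(res)
  }

  # candidate diagonals: D = (position of the right copy) - (left copy)
  gb_pos0 <- jj - 1L
  ga_pos0 <- ga_start + gak$pos0[hit[jj]]
  diags <- sort(unique(ga_pos0 - gb_pos0), decreasing = TRUE)
  diags <- diags[diags > 0L]
  if (length(diags) > 50L) {           # tandem-repeat guard
    tabd <- table(ga_pos0 - gb_pos0)
    diags <- as.integer(names(sort(tabd, decreasing = TRUE)))[1:50]
  }

  w_min <- as.integer(ceiling(aln_len_frac * Lr))
  max_mm_min <- floor((1 - identity_threshold) * w_min)
  craw <- charToRaw(ctg$seq)

  best <- NULL
  for (D in diags) {
    span <- Ls - D                     # valid x in [0, span): compare x, x+D
    if (span < w_min) next
    m <- craw[seq_len(span)] == craw[seq_len(span) + D]
    cmm <- cumsum(!m)
    # minimum-mismatch window of length w_min
    wmm <- cmm[w_min:span] - c(0L, cmm)[1:(span - w_min + 1L)]
    if (min(wmm) > max_mm_min) next
    ws <- which(wmm == min(wmm))[1L]   # 1-based window start
    s <- ws - 1L                       # 0-based
    e <- s + w_min                     # 0-based half-open end
    mm <- wmm[ws]
    # grow both directions while running identity stays >= threshold
    repeat {
      grew <- FALSE
      if (e < span &&
          (mm + !m[e + 1L]) / (e - s + 1L) <= 1 - identity_threshold) {
        mm <- mm + !m[e + 1L]; e <- e + 1L; grew <- TRUE
      }
      if (s > 0L &&
          (mm + !m[s]) / (e - s + 1L) <= 1 - identity_threshold) {
        mm <- mm + !m[s]; s <- s - 1L; grew <- TRUE
      }
      if (!grew) break
    }
    # shed mismatching end columns (they add no evidence)
    while (e - s > w_min && !m[e]) { e <- e - 1L; mm <- mm - 1L }
    while (e - s > w_min && !m[s + 1L]) { s <- s + 1L; mm <- mm - 1L }
    len <- e - s
    # ties prefer the later (smaller-D) diagonal: rightmost match in G_b
    if (is.null(best) || len >= best$len) {
      best <- list(D = D, s = s, e = e, len = len, mm = mm)
    }
  }

  if (is.null(best)) {
    res <- not_circ("seed matches failed the identity/length thresholds")
    res$inverted_repeat_hint <- itr
    return(res)
  }

  left <- region(ctg$id, best$s, best$e, "repeat")
  right <- region(ctg$id, best$s + best$D, best$e + best$D, "repeat")
  structure(
    list(is_circular = TRUE,
         match_in_gb = left,
         maximal_repeat = rbind(left, right),
         repeat_length = best$len,
         identity = 1 - best$mm / best$len,
         inverted_repeat_hint = itr,
         note = NULL),
    class = "circularity_result"
  )
}

#' @export
print.circularity_result <- function(x, ...) {
  if (x$is_circular) {
    cat(sprintf(
      "<circularity> circular: repeat %s bp at [%d,%d) / [%d,%d), identity %.4f\n",
      format(x$repeat_length, big.mark = ","),
      x$maximal_repeat$start[1], x$maximal_repeat$end[1],
      x$maximal_repeat$start[2], x$maximal_repeat$end[2], x$identity))
  } else {
    cat("<circularity> not circular:", x$note %||% "", "\n")
  }
  if (x$inverted_repeat_hint) cat("  note: inverted terminal repeat hint (not trimmed)\n")
  invisible(x)
}

#' Trim the redundant copy of a circular contig
#'
#' Removes the downstream (rightmost) copy of the maximal repeat, keeping
#' the coordinates of the genome start stable, and records a
#' `circular_trim` edit event.
#'
#' @param ctg a [contig()].
#' @param result a `circularity_result` with `is_circular = TRUE`.
#' @param iteration pipeline iteration index for the event record.
#' @return the trimmed [contig()].
#' @export
trim_circular_redundancy <- function(ctg, result, iteration = 0L) {
  if (!isTRUE(result$is_circular)) {
    stop("trim_circular_redundancy() requires a circular result", call. = FALSE)
  }
  rep2 <- result$maximal_repeat[2L, ]
  new_seq <- paste0(substr(ctg$seq, 1L, rep2$start),
                    substr(ctg$seq, rep2$end + 1L, contig_length(ctg)))
  append_event(ctg, new_seq, "circular_trim",
               interval = region(ctg$id, rep2$start, rep2$end, "repeat_copy"),
               iteration = iteration,
               detail = list(repeat_length = result$repeat_length,
                             identity = result$identity))
}
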