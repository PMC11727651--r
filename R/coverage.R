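# Coverage audit: per-base depth, percentile-band segmentation into
# suspicious / non-suspicious regions, and the longest clean segment.

#' Coverage audit parameters
#'
#' A base is "normal" when its depth sits within the central percentile band
#' of the contig's depth distribution; maximal runs of out-of-band bases
#' longer than `min_suspicious_len` are true suspicious regions.
#'
#' @param lower_pct lower percentile bound (percent), default 15.
#' @param upper_pct upper percentile bound (percent), default 85.
#' @param min_suspicious_len minimum run length in bp; runs must be strictly
#'   longer than this to count (default 1000, read strictly: a run of exactly
#'   1000 bp is not flagged).
#' @return an object of class `audit_params`.
#' @export
audit_params <- function(lower_pct = 15, upper_pct = 85,
                         min_suspicious_len = 1000L) {
  stopifnot(lower_pct >= 0, lower_pct < upper_pct, upper_pct <= 100,
            min_suspicious_len >= 1L)
  structure(list(lower_pct = lower_pct, upper_pct = upper_pct,
                 min_suspicious_len = as.integer(min_suspicious_len)),
            class = "audit_params")
}

# Tie-aware percentile rank of each depth value: for value v,
# rank(v) = 100 * (count(depth < v) + 0.5 * count(depth == v)) / n.
# Returns the band [lower_bound, upper_bound] of depth VALUES whose rank
# falls inside [lower_pct, upper_pct].  With this definition a constant
# profile is entirely normal (rank 50), while a zero-support insert is
# below the band even when it holds more than lower_pct percent of the
# bases -- which a plain nearest-rank cut ignores because of the ties.
#' @noRd
depth_band <- function(depth, params) {
  n <- length(depth)
  tab <- table(depth)
  vals <- as.numeric(names(tab))
  cnt <- as.numeric(tab)
  below <- cumsum(cnt) - cnt
  midrank <- 100 * (below + 0.5 * cnt) / n
  lb_i <- which(midrank >= params$lower_pct)
  ub_i <- which(midrank <= params$upper_pct)
  # both always exist for lower_pct < 50 < upper_pct bands; guard anyway
  lower <- if (length(lb_i)) vals[min(lb_i)] else min(vals)
  upper <- if (length(ub_i)) vals[max(ub_i)] else max(vals)
  c(lower = lower, upper = max(lower, upper))
}

#' Compute a per-base coverage profile
#'
#' `depth[i]` counts the placements covering position `i - 1` (0-based).
#' Percentile bounds for the normal band are derived from `params` with a
#' tie-aware percentile rank (see the methods vignette).
#'
#' @param ctg a [contig()].
#' @param placements data frame with integer columns `start`, `end`
#'   (0-based half-open intervals on the contig), e.g. from [place_reads()].
#' @param params an [audit_params()].
#' @return an object of class `coverage_profile` with fields `contig_id`,
#'   `depth`, `lower_bound`, `upper_bound`.
#' @export
compute_depth <- function(ctg, placements, params = audit_params()) {
  L <- contig_length(ctg)
  if (is.null(placements) || nrow(placements) == 0L) {
    depth <- integer(L)
  } else {
    s <- placements$start
    e <- placements$end
    if (any(s < 0L) || any(e > L) || any(e <= s)) {
      stop("placement interval out of range [0, ", L, ")", call. = FALSE)
    }
    delta <- integer(L + 1L)
    add <- tabulate(s + 1L, nbins = L)
    rem <- tabulate(e + 1L, nbins = L + 1L)
    delta[seq_len(L)] <- add
    delta <- delta - rem
    depth <- cumsum(delta[seq_len(L)])
  }
  band <- depth_band(depth, params)
  structure(list(contig_id = ctg$id, depth = as.integer(depth),
                 lower_bound = band[["lower"]], upper_bound = band[["upper"]]),
            class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf("<coverage_profile> %s: %s bp, depth %s-%s (median %s), normal band [%s, %s]\n",
              x$contig_id, format(length(x$depth), big.mark = ","),
              min(x$depth), max(x$depth), stats::median(x$depth),
              x$lower_bound, x$upper_bound))
  invisible(x)
}

#' Flag true suspicious regions
#'
#' Bases with depth outside `[lower_bound, upper_bound]` are suspicious;
#' maximal runs of suspicious bases strictly longer than
#' `min_suspicious_len` are returned as true suspicious regions.  All other
#' positions are implicitly non-suspicious.
#'
#' @param profile a `coverage_profile` from [compute_depth()].
#' @param params an [audit_params()].
#' @return a [region()] table (possibly empty) with label `"suspicious"`.
#' @export
flag_suspicious <- function(profile, params = audit_params()) {
  stopifnot(length(profile$depth) > 0L)
  sus <- profile$depth < profile$lower_bound |
    profile$depth > profile$upper_bound
  r <- rle(sus)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values & r$lengths > params$min_suspicious_len
  if (!any(keep)) return(empty_regions())
  region(profile$contig_id, starts[keep], ends[keep], "suspicious")
}

#' Longest true non-suspicious region
#'
#' The longest gap between (and around) the suspicious regions; ties are
#' broken by the leftmost start.
#'
#' @param profile a `coverage_profile` (supplies the contig length and id).
#' @param suspicious a sorted, non-overlapping [region()] table.
#' @return a single-row [region()] labelled `"non_suspicious"`.
#' @export
longest_non_suspicious <- function(profile, suspicious) {
  L <- length(profile$depth)
  if (nrow(suspicious) == 0L) {
    return(region(profile$contig_id, 0L, L, "non_suspicious"))
  }
  stopifnot(all(diff(suspicious$start) > 0L),
            all(suspicious$end[-nrow(suspicious)] <= suspicious$start[-1L]))
  gs <- c(0L, suspicious$end)
  ge <- c(suspicious$start, L)
  len <- ge - gs
  if (max(len) <= 0L) {
    stop("whole contig is suspicious: no non-suspicious region to extend",
         call. = FALSE)
  }
  i <- which.max(len)   # which.max returns the first (leftmost) maximum
  region(profile$contig_id, gs[i], ge[i], "non_suspicious")
}
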