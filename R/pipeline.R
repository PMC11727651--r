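# The full refinement loop: per iteration (1) circularity check -- a
# circular contig is trimmed and the loop exits; (2) coverage audit -- reads
# are re-placed genome-wide, suspicious regions flagged, and only the
# longest non-suspicious segment is kept; (3) extension -- one edge-local
# assembly round, falling back to trim-and-retry when nothing grows.  The
# loop is capped at `max_iterations`.  After the loop the contig is checked
# for circularity once more, trimmed if needed, and polished.

#' Pipeline configuration
#'
#' Bundles the audit, extension and polish parameter sets with the loop
#' controls.
#'
#' @param audit an [audit_params()].
#' @param extension an [extension_params()].
#' @param polish a [polish_params()].
#' @param max_iterations cap on extension iterations (default 100).
#' @param circ_identity,circ_aln_frac circularity thresholds (default 0.95
#'   identity over 0.95 of the probe window).
#' @param map_max_mismatch_rate mismatch tolerance for genome-wide read
#'   placement when computing depth (default 0.1).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(audit = audit_params(),
                            extension = extension_params(),
                            polish = polish_params(),
                            max_iterations = 100L,
                            circ_identity = 0.95, circ_aln_frac = 0.95,
                            map_max_mismatch_rate = 0.1) {
  stopifnot(max_iterations >= 1L)
  structure(list(audit = audit, extension = extension, polish = polish,
                 max_iterations = as.integer(max_iterations),
                 circ_identity = circ_identity, circ_aln_frac = circ_aln_frac,
                 map_max_mismatch_rate = map_max_mismatch_rate),
            class = "pipeline_config")
}

# Build a pipeline_config from a (possibly partial) named list, e.g. read
# from a YAML file.  Unknown keys are an error.
#' @noRd
config_from_list <- function(lst) {
  take <- function(ctor, sub) {
    args <- lst[[sub]]
    if (is.null(args)) return(ctor())
    do.call(ctor, args)
  }
  known <- c("audit", "extension", "polish", "max_iterations",
             "circ_identity", "circ_aln_frac", "map_max_mismatch_rate")
  extra <- setdiff(names(lst), known)
  if (length(extra)) stop("unknown config keys: ",
                          paste(extra, collapse = ", "), call. = FALSE)
  pipeline_config(
    audit = take(audit_params, "audit"),
    extension = take(extension_params, "extension"),
    polish = take(polish_params, "polish"),
    max_iterations = lst$max_iterations %||% 100L,
    circ_identity = lst$circ_identity %||% 0.95,
    circ_aln_frac = lst$circ_aln_frac %||% 0.95,
    map_max_mismatch_rate = lst$map_max_mismatch_rate %||% 0.1
  )
}

#' Run the full refinement pipeline on one contig
#'
#' Iterates error correction (circularity check, coverage audit with
#' suspicious-region removal) and edge extension until the contig closes
#' into a circle, stops growing even after end-trimming, or the iteration
#' cap is reached; then re-checks circularity and polishes the result by
#' pileup consensus.
#'
#' @param ctg input [contig()].
#' @param rs the [readset()] the contig was assembled from.
#' @param config a [pipeline_config()].
#' @param verbose print one line per iteration.
#' @return an object of class `pipeline_result`: a list with `contig`
#'   (final, with full edit history), `regions` (suspicious regions on the
#'   final contig), `log` (an [iteration_log()]), `circularity` (the last
#'   positive or final circularity result) and `profile` (final coverage
#'   profile).
#' @export
run_pipeline <- function(ctg, rs, config = pipeline_config(),
                         verbose = FALSE) {
  stopifnot(inherits(ctg, "contig"), inherits(rs, "readset"))
  original <- ctg
  rounds <- list()
  note_round <- function(it, action, before, after, reason = NA_character_) {
    rounds[[length(rounds) + 1L]] <<-
      data.frame(iteration = it, action = action, length_before = before,
                 length_after = after, stop_reason = reason,
                 stringsAsFactors = FALSE)
  }
  circ_final <- NULL
  reason <- NULL
  it <- 0L

  repeat {
    it <- it + 1L
    if (it > config$max_iterations) {
      note_round(it, "iteration_cap", contig_length(ctg),
                 contig_length(ctg), "max_iterations")
      reason <- "max_iterations"
      break
    }
    len0 <- contig_length(ctg)

    # (1) circularity
    cres <- suppressWarnings(
      check_circularity(ctg, rs$read_length, config$circ_identity,
                        config$circ_aln_frac, config$extension$recruit_k)
    )
    if (cres$is_circular) {
      ctg <- trim_circular_redundancy(ctg, cres, iteration = it)
      circ_final <- cres
      note_round(it, "circular_trim", len0, contig_length(ctg), "circular")
      reason <- "circular"
      if (verbose) message(sprintf("[%d] circular; trimmed %d bp repeat",
                                   it, cres$repeat_length))
      break
    }

    # (2) coverage audit on the whole contig
    pl <- place_reads(ctg, rs, k = config$extension$recruit_k,
                      max_mismatch_rate = config$map_max_mismatch_rate)
    profile <- compute_depth(ctg, placement_intervals(pl), config$audit)
    sus <- flag_suspicious(profile, config$audit)
    keep <- tryCatch(longest_non_suspicious(profile, sus),
                     error = function(e) NULL)
    if (is.null(keep)) {
      note_round(it, "audit", len0, contig_length(original),
                 "whole_contig_suspicious")
      reason <- "whole_contig_suspicious"
      ctg <- original           # uncorrectable: hand back the input
      break
    }
    if (keep$start > 0L || keep$end < len0) {
      ctg <- append_event(ctg, substr(ctg$seq, keep$start + 1L, keep$end),
                          "suspicious_split",
                          interval = region(ctg$id, keep$start, keep$end,
                                            "kept_non_suspicious"),
                          iteration = it,
                          detail = list(n_suspicious = nrow(sus)))
      if (verbose) message(sprintf("[%d] kept longest clean segment [%d,%d)",
                                   it, keep$start, keep$end))
    }

    # (3) extension, with trim-and-retry fallback
    res <- extension_round(ctg, rs, config$extension, iteration = it)
    action <- "extend"
    if (!res$outcome$grew) {
      res <- trim_and_retry(ctg, rs, config$extension, iteration = it)
      action <- "trim_and_retry"
    }
    if (!res$outcome$grew) {
      note_round(it, action, len0, contig_length(ctg), "no_growth_after_trim")
      reason <- "no_growth_after_trim"
      break
    }
    ctg <- res$contig
    note_round(it, sprintf("%s(+%d/+%d%s)", action, res$outcome$left_added_bp,
                           res$outcome$right_added_bp,
                           if (res$outcome$trimmed_bp_applied > 0L)
                             paste0(", trim ", res$outcome$trimmed_bp_applied)
                           else ""),
               len0, contig_length(ctg))
    if (verbose) message(sprintf("[%d] %s: %d -> %d bp", it, action, len0,
                                 contig_length(ctg)))
  }

  # post-loop: final circularity re-check (unless the loop just trimmed)
  if (reason != "circular" && reason != "whole_contig_suspicious") {
    cres <- suppressWarnings(
      check_circularity(ctg, rs$read_length, config$circ_identity,
                        config$circ_aln_frac, config$extension$recruit_k)
    )
    circ_final <- cres
    if (cres$is_circular) {
      ctg <- trim_circular_redundancy(ctg, cres, iteration = it)
    }
  }

  # polish by pileup consensus
  if (reason != "whole_contig_suspicious") {
    ctg <- polish(ctg, rs, config$polish, iteration = it)
  }

  # final audit for the region report
  pl <- place_reads(ctg, rs, k = config$extension$recruit_k,
                    max_mismatch_rate = config$map_max_mismatch_rate)
  profile <- compute_depth(ctg, placement_intervals(pl), config$audit)
  regions <- flag_suspicious(profile, config$audit)

  log <- iteration_log(do.call(rbind, rounds))
  structure(list(contig = ctg, regions = regions, log = log,
                 circularity = circ_final, profile = profile),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("== refinement result ==\n")
  print(x$contig)
  cat(sprintf("stop reason: %s after %d round(s)\n", stop_reason(x$log),
              nrow(x$log$rounds)))
  if (!is.null(x$circularity) && x$circularity$is_circular) {
    cat(sprintf("circular: yes (trimmed %s bp redundancy)\n",
                format(x$circularity$repeat_length, big.mark = ",")))
  } else {
    cat("circular: no\n")
  }
  cat(sprintf("suspicious regions on output: %d\n", nrow(x$regions)))
  invisible(x)
}
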