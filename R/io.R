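# FASTA/FASTQ/BED/JSON reading and writing.

#' Read contigs from a FASTA file
#'
#' @param path path to a FASTA file (optionally gzipped).
#' @return list of [contig()] objects, sequences upper-cased, empty history.
#'   An empty file yields an empty list.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) stop("malformed FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) return(list())
  ids <- vapply(strsplit(names(set), "[ \t]"), `[[`, "", 1L)
  lapply(seq_along(set), function(i) contig(ids[i], as.character(set[[i]])))
}

#' Write contigs to a FASTA file
#'
#' @param contigs a [contig()] or list of contigs.
#' @param path output path.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(contigs, path, width = 70L) {
  if (inherits(contigs, "contig")) contigs <- list(contigs)
  seqs <- Biostrings::DNAStringSet(vapply(contigs, `[[`, "", "seq"))
  names(seqs) <- vapply(contigs, `[[`, "", "id")
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}

#' Read short reads from FASTQ
#'
#' With two files, records pair positionally (file1 record i mates file2
#' record i); a record-count mismatch is an error.  Colliding ids between the
#' two files get `/1` and `/2` suffixes.
#'
#' @param path FASTQ file (optionally gzipped) with 4-line records.
#' @param path2 optional second FASTQ file of mates.
#' @return a [readset()] with mate links when paired; `read_length` is the
#'   modal read length.
#' @export
read_fastq <- function(path, path2 = NULL) {
  rd <- function(p) {
    if (!file.exists(p)) stop("FASTQ file not found: ", p, call. = FALSE)
    tryCatch(
      Biostrings::readDNAStringSet(p, format = "fastq", with.qualities = TRUE),
      error = function(e) stop("malformed FASTQ '", p, "': ",
                               conditionMessage(e), call. = FALSE)
    )
  }
  s1 <- rd(path)
  if (is.null(path2)) {
    return(readset(names(s1), as.character(s1),
                   as.character(S4Vectors::mcols(s1)$qualities)))
  }
  s2 <- rd(path2)
  if (length(s1) != length(s2)) {
    stop("pairing error: ", path, " has ", length(s1), " records but ",
         path2, " has ", length(s2), call. = FALSE)
  }
  ids1 <- names(s1)
  ids2 <- names(s2)
  if (any(ids1 %in% ids2)) {
    ids1 <- paste0(ids1, "/1")
    ids2 <- paste0(ids2, "/2")
  }
  n <- length(s1)
  readset(c(ids1, ids2), c(as.character(s1), as.character(s2)),
          c(as.character(S4Vectors::mcols(s1)$qualities),
            as.character(S4Vectors::mcols(s2)$qualities)),
          mate = c(seq_len(n) + n, seq_len(n)))
}

#' Write a read set to FASTQ
#'
#' Mate pairs are interleaved into a single file in id order of appearance.
#'
#' @param rs a [readset()].
#' @param path output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(rs, path) {
  seqs <- Biostrings::DNAStringSet(rs$seqs)
  names(seqs) <- rs$ids
  quals <- if (is.null(rs$quals)) {
    Biostrings::BStringSet(strrep("I", nchar(rs$seqs)))
  } else {
    Biostrings::BStringSet(rs$quals)
  }
  Biostrings::writeXStringSet(seqs, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' Write flagged regions as BED
#'
#' BED uses 0-based half-open coordinates, matching the internal convention.
#' The file always starts with a single `track` header line.
#'
#' @param regions a [region()] table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("track name=flagged_regions", con)
  if (nrow(regions)) {
    writeLines(sprintf("%s\t%d\t%d\t%s", regions$contig_id, regions$start,
                       regions$end, regions$label), con)
  }
  invisible(path)
}

#' Dump a depth vector as TSV
#'
#' @param profile a [coverage_profile] as returned by [compute_depth()].
#' @param path output path; columns `pos` (0-based) and `depth`.
#' @return `path`, invisibly.
#' @export
write_depth_tsv <- function(profile, path) {
  utils::write.table(
    data.frame(pos = seq_along(profile$depth) - 1L, depth = profile$depth),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

# Serialise a single edit event for the JSON log.
#' @noRd
event_json <- function(ev) {
  out <- list(kind = ev$kind, delta_bp = ev$delta_bp, iteration = ev$iteration)
  if (!is.null(ev$interval)) {
    out$interval <- list(start = ev$interval$start, end = ev$interval$end,
                         label = ev$interval$label)
  }
  if (ev$kind == "base_correction") {
    out$n_snvs <- if (is.null(ev$detail$snvs)) 0L else nrow(ev$detail$snvs)
    out$n_indels <- if (is.null(ev$detail$indels)) 0L else nrow(ev$detail$indels)
    if (out$n_snvs > 0L) out$snvs <- ev$detail$snvs
    if (out$n_indels > 0L) out$indels <- ev$detail$indels
  }
  if (ev$kind == "extension") {
    out$left_added_bp <- nchar(ev$detail$left %||% "")
    out$right_added_bp <- nchar(ev$detail$right %||% "")
  }
  out
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write the final contig, flagged regions and provenance log
#'
#' Produces three files in `outdir`: `<id>.final.fasta`,
#' `<id>.regions.bed` and `<id>.log.json` (provenance schema version 1).
#'
#' @param ctg final [contig()].
#' @param regions [region()] table of flagged regions on the final contig.
#' @param log an [iteration_log()].
#' @param outdir writable output directory (created if missing).
#' @param extra optional named list merged into the JSON log (e.g. the
#'   circularity result).
#' @return named character vector of written paths (`fasta`, `bed`, `json`).
#' @export
write_outputs <- function(ctg, regions, log, outdir, extra = list()) {
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", outdir, call. = FALSE)
  }
  base <- file.path(outdir, ctg$id)
  paths <- c(fasta = paste0(base, ".final.fasta"),
             bed = paste0(base, ".regions.bed"),
             json = paste0(base, ".log.json"))
  write_fasta(ctg, paths[["fasta"]])
  write_bed(regions, paths[["bed"]])
  payload <- c(
    list(schema = 1L, contig_id = ctg$id, final_length = contig_length(ctg),
         events = lapply(ctg$history, event_json),
         rounds = if (inherits(log, "iteration_log")) log$rounds else log),
    extra
  )
  jsonlite::write_json(payload, paths[["json"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "rows")
  paths
}
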