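# Read/genome simulator: generates circular or linear viral genomes
# (optionally with terminal repeats), chimeric constructs, and Illumina-like
# single or paired short reads with substitution errors.  Everything is
# driven by a single integer seed and is fully reproducible.

#' Simulation configuration
#'
#' Defaults emulate the data regime the pipeline targets: Illumina-like
#' ~150 bp reads at ~30x depth with ~1% substitution errors, paired with a
#' 600 +/- 60 bp insert (the insert is chosen so that rescued mates chain
#' contiguously back to the recruitment edge; see the methods vignette).
#'
#' @param genome_length genome length in bp.
#' @param circular logical; circular genomes wrap the origin when reads are
#'   drawn.
#' @param terminal_repeat_len for linear genomes, the first
#'   `terminal_repeat_len` bp are copied onto the end (default 0).
#' @param read_length read length in bp (default 150).
#' @param coverage target fold coverage (default 30).
#' @param error_rate per-base substitution probability in `[0, 0.5)`
#'   (default 0.01).
#' @param paired logical; paired reads come from the two fragment ends with
#'   the inner mate reverse-complemented (default `TRUE`).
#' @param insert_mean,insert_sd fragment length distribution for paired
#'   reads (defaults 600 and 60 bp).
#' @param seed integer RNG seed; a fixed seed makes all outputs
#'   byte-identical across runs.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(genome_length = 30000L, circular = TRUE,
                       terminal_repeat_len = 0L, read_length = 150L,
                       coverage = 30, error_rate = 0.01, paired = TRUE,
                       insert_mean = 600L, insert_sd = 60L, seed = 1L) {
  stopifnot(genome_length >= 1L, read_length >= 1L, coverage > 0,
            error_rate >= 0, error_rate < 0.5, terminal_repeat_len >= 0L,
            insert_mean >= read_length, insert_sd >= 0)
  structure(list(genome_length = as.integer(genome_length),
                 circular = isTRUE(circular),
                 terminal_repeat_len = as.integer(terminal_repeat_len),
                 read_length = as.integer(read_length), coverage = coverage,
                 error_rate = error_rate, paired = isTRUE(paired),
                 insert_mean = as.integer(insert_mean),
                 insert_sd = as.numeric(insert_sd), seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a genome
#'
#' An i.i.d. uniform nucleotide sequence.  Linear genomes with
#' `terminal_repeat_len > 0` get their first `terminal_repeat_len` bases
#' copied onto the end (total length `genome_length +
#' terminal_repeat_len`), mimicking a linear phage with terminal repeats.
#'
#' @param config a [sim_config()].
#' @param id contig id for the genome (default `"genome"`).
#' @return a [contig()]; attribute `"circular"` records the topology.
#' @export
make_genome <- function(config, id = "genome") {
  g <- withr::with_seed(config$seed, random_seq(config$genome_length))
  if (!config$circular && config$terminal_repeat_len > 0L) {
    g <- paste0(g, substr(g, 1L, config$terminal_repeat_len))
  }
  out <- contig(id, g)
  attr(out, "circular") <- config$circular
  out
}

#' Build a chimeric contig
#'
#' Inserts a foreign sequence into a host contig at `position`, recording
#' the truth coordinates of the insert for downstream oracles.
#'
#' @param host host [contig()].
#' @param insert inserted [contig()] (may be empty via a 0-length slice).
#' @param position 0-based insertion point, `0 <= position <= length(host)`.
#' @return a [contig()] named `<host>|chimera`; attribute
#'   `"insert_interval"` holds the 0-based half-open insert coordinates.
#' @export
make_chimera <- function(host, insert, position) {
  Lh <- contig_length(host)
  stopifnot(position >= 0L, position <= Lh)
  ins_seq <- if (is.null(insert)) "" else insert$seq
  seq <- paste0(substr(host$seq, 1L, position), ins_seq,
                substr(host$seq, position + 1L, Lh))
  out <- contig(paste0(host$id, "|chimera"), seq)
  attr(out, "insert_interval") <- c(start = as.integer(position),
                                    end = as.integer(position + nchar(ins_seq)))
  out
}

# Inject per-base substitution errors (never to the original base).
#' @noRd
mutate_reads <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  lens <- nchar(seqs)
  total <- sum(lens)
  hit <- which(stats::runif(total) < error_rate)
  if (!length(hit)) return(seqs)
  ends <- cumsum(lens)
  ri <- findInterval(hit - 1L, ends) + 1L        # read index per error
  pos <- hit - c(0L, ends)[ri]                   # 1-based position in read
  alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
              G = c("A", "C", "T"), T = c("A", "C", "G"),
              N = c("A", "C", "G", "T"))
  pick <- stats::runif(length(hit))
  for (j in seq_along(hit)) {
    orig <- substr(seqs[ri[j]], pos[j], pos[j])
    a <- alt[[orig]]
    substr(seqs[ri[j]], pos[j], pos[j]) <- a[ceiling(pick[j] * length(a))]
  }
  seqs
}

#' Simulate short reads from a genome
#'
#' Fragments are drawn uniformly along the genome (wrapping the origin for
#' circular genomes); paired reads come from the two fragment ends with the
#' inner mate reverse-complemented, and each fragment is assigned a random
#' strand.  The number of fragments is
#' `round(coverage * genome_length / (read_length * (2 if paired else 1)))`
#' so that total sequenced bases match the target coverage.
#'
#' @param genome a [contig()] from [make_genome()] (or any contig).
#' @param config a [sim_config()]; its `seed` drives all randomness.
#' @return a [readset()] with constant `"I"` quality strings.
#' @export
simulate_reads <- function(genome, config) {
  L <- contig_length(genome)
  rl <- config$read_length
  stopifnot(L > rl)
  n_frag <- as.integer(round(config$coverage * L /
                               (rl * (if (config$paired) 2L else 1L))))
  withr::with_seed(config$seed + 1L, {
    if (config$paired) {
      frag <- pmax(rl, as.integer(round(stats::rnorm(n_frag,
                                                     config$insert_mean,
                                                     config$insert_sd))))
    } else {
      frag <- rep(rl, n_frag)
    }
    if (config$circular) {
      starts <- sample.int(L, n_frag, replace = TRUE) - 1L
      gx <- paste0(genome$seq, substr(genome$seq, 1L, max(frag)))
    } else {
      frag <- pmin(frag, L)
      starts <- vapply(frag, function(f) {
        sample.int(L - f + 1L, 1L) - 1L
      }, integer(1))
      gx <- genome$seq
    }
    flip <- stats::runif(n_frag) < 0.5
    r1 <- substring(gx, starts + 1L, starts + rl)
    if (config$paired) {
      r2 <- revcomp(substring(gx, starts + frag - rl + 1L, starts + frag))
      # random fragment strand: swap the roles of the two ends
      tmp <- r1[flip]
      r1[flip] <- r2[flip]
      r2[flip] <- tmp
      seqs <- mutate_reads(c(r1, r2), config$error_rate)
      ids <- c(sprintf("r%06d/1", seq_len(n_frag)),
               sprintf("r%06d/2", seq_len(n_frag)))
      mate <- c(seq_len(n_frag) + n_frag, seq_len(n_frag))
    } else {
      r1[flip] <- revcomp(r1[flip])
      seqs <- mutate_reads(r1, config$error_rate)
      ids <- sprintf("r%06d", seq_len(n_frag))
      mate <- NULL
    }
    rs <- readset(ids, seqs, strrep("I", nchar(seqs)), mate)
    rs$read_length <- rl
    rs
  })
}

#' Write simulator truth files
#'
#' Writes the genome FASTA, the reads FASTQ and a JSON truth file (genome
#' length, topology, terminal repeat length, insert coordinates when
#' present) for use as test oracles.
#'
#' @param genome a [contig()] (possibly a chimera from [make_chimera()]).
#' @param rs a [readset()].
#' @param outdir output directory (created if missing).
#' @return named character vector of paths (`fasta`, `fastq`, `truth`).
#' @export
write_simulation <- function(genome, rs, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  paths <- c(fasta = file.path(outdir, paste0(genome$id, ".fasta")),
             fastq = file.path(outdir, paste0(genome$id, ".reads.fastq")),
             truth = file.path(outdir, paste0(genome$id, ".truth.json")))
  write_fasta(genome, paths[["fasta"]])
  write_fastq(rs, paths[["fastq"]])
  truth <- list(id = genome$id, length = contig_length(genome),
                circular = isTRUE(attr(genome, "circular")))
  ins <- attr(genome, "insert_interval")
  if (!is.null(ins)) truth$insert_interval <- as.list(ins)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE, digits = NA)
  paths
}
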