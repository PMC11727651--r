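test_that("a fixed seed reproduces genomes and reads byte-identically", {
  cfg <- sim_config(genome_length = 8000, seed = 1)
  g1 <- make_genome(cfg)
  g2 <- make_genome(cfg)
  expect_identical(g1$seq, g2$seq)
  expect_equal(contig_length(g1), 8000L)
  r1 <- simulate_reads(g1, cfg)
  r2 <- simulate_reads(g2, cfg)
  expect_identical(r1$seqs, r2$seqs)
  # and the FASTQ on disk is byte-identical too
  f1 <- tempfile(); f2 <- tempfile()
  write_fastq(r1, f1); write_fastq(r2, f2)
  expect_identical(readLines(f1), readLines(f2))

  # different seeds diverge at ~75% of positions (iid uniform)
  g3 <- make_genome(sim_config(genome_length = 8000, seed = 2))
  d <- mean(charToRaw(g1$seq) != charToRaw(g3$seq))
  expect_gt(d, 0.70)
  expect_lt(d, 0.80)
})

test_that("linear genomes carry the requested terminal repeat", {
  cfg <- sim_config(genome_length = 8000, circular = FALSE,
                    terminal_repeat_len = 500, seed = 3)
  g <- make_genome(cfg)
  expect_equal(contig_length(g), 8500L)
  expect_identical(substr(g$seq, 1, 500), substr(g$seq, 8001, 8500))
})

test_that("read counts follow coverage * length / (read_length * mates)", {
  g <- make_genome(sim_config(genome_length = 30000, seed = 4))
  rs_se <- simulate_reads(g, sim_config(genome_length = 30000, paired = FALSE,
                                        coverage = 30, seed = 4))
  expect_equal(n_reads(rs_se), 6000L)
  rs_pe <- simulate_reads(g, sim_config(genome_length = 30000, paired = TRUE,
                                        coverage = 30, seed = 4))
  expect_equal(n_reads(rs_pe), 6000L)          # 3000 fragments x 2 mates
  expect_equal(sum(!is.na(rs_pe$mate)), 6000L)
})

test_that("error-free reads are exact substrings of the (wrapped) genome", {
  cfg <- sim_config(genome_length = 6000, circular = TRUE, error_rate = 0,
                    seed = 5)
  g <- make_genome(cfg)
  rs <- simulate_reads(g, cfg)
  doubled <- paste0(g$seq, g$seq)
  doubled_rc <- revcomp(doubled)
  ok <- vapply(rs$seqs, function(s) {
    grepl(s, doubled, fixed = TRUE) || grepl(s, doubled_rc, fixed = TRUE)
  }, logical(1))
  expect_true(all(ok))
})

test_that("mean simulated depth is within 5% of nominal", {
  for (seed in c(6, 7)) {
    cfg <- sim_config(genome_length = 12000, circular = TRUE, error_rate = 0,
                      coverage = 30, seed = seed)
    g <- make_genome(cfg)
    rs <- simulate_reads(g, cfg)
    pl <- place_reads(g, rs)
    prof <- compute_depth(g, placement_intervals(pl))
    expect_lt(abs(mean(prof$depth) - 30) / 30, 0.05)
  }
})

test_that("substitution errors appear at close to the requested rate", {
  cfg <- sim_config(genome_length = 10000, circular = FALSE,
                    error_rate = 0.01, paired = FALSE, seed = 8)
  g <- make_genome(cfg)
  rs <- simulate_reads(g, cfg)
  pl <- place_reads(g, rs)
  acc <- pl[pl$accepted & pl$end - pl$start == 150, ]
  rate <- sum(acc$mismatches) / (nrow(acc) * 150)
  expect_gt(rate, 0.008)
  expect_lt(rate, 0.012)
})

test_that("make_chimera splices the insert at the stated coordinates", {
  host <- contig("h", rand_seq(30000, 9))
  ins <- contig("i", rand_seq(8000, 10))
  chim <- make_chimera(host, ins, 15000L)
  expect_equal(contig_length(chim), 38000L)
  expect_equal(attr(chim, "insert_interval"),
               c(start = 15000L, end = 23000L))
  expect_identical(substr(chim$seq, 15001, 23000), ins$seq)
  # zero-length insert leaves the host unchanged
  empty <- make_chimera(host, NULL, 100L)
  expect_identical(empty$seq, host$seq)
})

test_that("host-only reads give a chimera a flaggable zero-depth insert", {
  cfg <- sim_config(genome_length = 20000, circular = TRUE, error_rate = 0,
                    seed = 11)
  host <- make_genome(cfg, "host")
  ins <- make_genome(sim_config(genome_length = 5000, circular = FALSE,
                                seed = 12), "ins")
  chim <- make_chimera(host, ins, 10000L)
  rs <- simulate_reads(host, cfg)
  pl <- place_reads(chim, rs)
  prof <- compute_depth(chim, placement_intervals(pl))
  # insert depth ~0, flanks ~30
  expect_lt(mean(prof$depth[10500:14500]), 1)
  expect_gt(mean(prof$depth[1:9000]), 25)
  sus <- flag_suspicious(prof)
  expect_equal(nrow(sus), 1L)
  expect_lte(abs(sus$start - 10000L), 200L)
  expect_lte(abs(sus$end - 15000L), 200L)
})

test_that("write_simulation produces FASTA, FASTQ and truth JSON", {
  cfg <- sim_config(genome_length = 2000, seed = 13)
  g <- make_genome(cfg)
  rs <- simulate_reads(g, cfg)
  out <- tempfile()
  paths <- write_simulation(g, rs, out)
  expect_true(all(file.exists(paths)))
  truth <- jsonlite::read_json(paths[["truth"]])
  expect_equal(truth$length, 2000L)
  expect_true(truth$circular)
})
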