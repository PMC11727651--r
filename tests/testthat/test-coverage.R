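# Independent oracle: per-base tie-aware percentile rank via rank(), then a
# run-length scan.  The package computes the same classification through
# value bounds derived from cumulative counts -- a different code path.
oracle_flag <- function(depth, lower_pct = 15, upper_pct = 85,
                        min_len = 1000L) {
  n <- length(depth)
  pr <- 100 * (rank(depth, ties.method = "average") - 0.5) / n
  sus <- pr < lower_pct | pr > upper_pct
  r <- rle(sus)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values & r$lengths > min_len
  data.frame(start = starts[keep], end = ends[keep])
}

profile_of <- function(depth, params = audit_params()) {
  ctg <- contig("p", strrep("A", length(depth)))
  pr <- compute_depth(ctg, NULL, params)
  pr$depth <- as.integer(depth)
  band <- viralrefine:::depth_band(pr$depth, params)
  pr$lower_bound <- band[["lower"]]
  pr$upper_bound <- band[["upper"]]
  pr
}

test_that("compute_depth counts interval pileup per base", {
  ctg <- contig("c", strrep("A", 10))
  expect_equal(compute_depth(ctg, NULL)$depth, rep(0L, 10))
  one <- data.frame(start = 0L, end = 10L)
  expect_equal(compute_depth(ctg, one)$depth, rep(1L, 10))
  ctg8 <- contig("c", strrep("A", 8))
  pls <- data.frame(start = c(0L, 2L, 4L), end = c(4L, 6L, 8L))
  expect_equal(compute_depth(ctg8, pls)$depth,
               c(1L, 1L, 2L, 2L, 2L, 2L, 1L, 1L))
  expect_error(compute_depth(ctg8, data.frame(start = 0L, end = 9L)),
               "out of range")
})

test_that("flag_suspicious applies the percentile band and strict >1000 rule", {
  # constant profile: nothing suspicious
  expect_equal(nrow(flag_suspicious(profile_of(rep(100L, 5000)))), 0L)

  # 1,500 bp zero dip in a 10 kb profile -> exactly that region
  depth <- rep(100L, 10000)
  depth[4001:5500] <- 0L
  fl <- flag_suspicious(profile_of(depth))
  expect_equal(nrow(fl), 1L)
  expect_equal(fl$start, 4000L)
  expect_equal(fl$end, 5500L)

  # 800 bp dip: a suspicious run but not longer than 1,000 -> dropped
  depth <- rep(100L, 10000)
  depth[4001:4800] <- 0L
  expect_equal(nrow(flag_suspicious(profile_of(depth))), 0L)

  # run of exactly 1,000 is excluded ("longer than", read strictly)
  depth <- rep(100L, 10000)
  depth[4001:5000] <- 0L
  expect_equal(nrow(flag_suspicious(profile_of(depth))), 0L)
  depth[4001:5001] <- 0L
  expect_equal(nrow(flag_suspicious(profile_of(depth))), 1L)
})

test_that("flag_suspicious matches the brute-force oracle on random profiles", {
  withr::with_seed(404, {
    for (trial in 1:40) {
      n <- sample(2000:50000, 1)
      base <- sample(c(5, 30, 100, 300), 1)
      depth <- stats::rpois(n, base)
      # inject 0-3 anomalous runs (dips and spikes of varied lengths)
      for (j in seq_len(sample(0:3, 1))) {
        w <- sample(200:3000, 1)
        s <- sample(n - w, 1)
        depth[s:(s + w - 1L)] <-
          if (stats::runif(1) < 0.5) stats::rpois(w, base / 20)
          else stats::rpois(w, base * 4)
      }
      fl <- flag_suspicious(profile_of(depth))
      orc <- oracle_flag(depth)
      expect_equal(nrow(fl), nrow(orc))
      expect_equal(fl$start, orc$start)
      expect_equal(fl$end, orc$end)
    }
  })
})

test_that("suspicious and non-suspicious regions tile the contig", {
  withr::with_seed(77, {
    depth <- stats::rpois(20000, 50)
    depth[3001:5500] <- 0L
    depth[12001:13700] <- 400L
  })
  prof <- profile_of(depth)
  sus <- flag_suspicious(prof)
  expect_gte(nrow(sus), 2L)
  # gaps + suspicious runs cover every position exactly once
  covered <- integer(length(depth))
  for (i in seq_len(nrow(sus))) {
    covered[(sus$start[i] + 1):(sus$end[i])] <-
      covered[(sus$start[i] + 1):(sus$end[i])] + 1L
  }
  gs <- c(0L, sus$end)
  ge <- c(sus$start, length(depth))
  for (i in seq_along(gs)) {
    if (ge[i] > gs[i]) covered[(gs[i] + 1):ge[i]] <- covered[(gs[i] + 1):ge[i]] + 1L
  }
  expect_true(all(covered == 1L))
})

test_that("widening the percentile band never adds suspicious bases", {
  withr::with_seed(88, {
    for (trial in 1:10) {
      depth <- stats::rpois(8000, sample(c(10, 60), 1))
      w <- sample(1200:2500, 1)
      s <- sample(8000 - w, 1)
      depth[s:(s + w - 1L)] <- 0L
      total_sus <- function(lp, up) {
        p <- audit_params(lp, up)
        sum(flag_suspicious(profile_of(depth, p), p)$end -
              flag_suspicious(profile_of(depth, p), p)$start)
      }
      expect_lte(total_sus(10, 90), total_sus(15, 85))
      expect_lte(total_sus(15, 85), total_sus(25, 75))
    }
  })
})

test_that("longest_non_suspicious picks the longest gap, leftmost on ties", {
  prof <- profile_of(rep(10L, 5000))
  r <- longest_non_suspicious(prof, region())
  expect_equal(c(r$start, r$end), c(0L, 5000L))

  prof10 <- profile_of(rep(10L, 10000))
  sus <- region("p", 2000L, 3600L, "suspicious")
  r <- longest_non_suspicious(prof10, sus)
  expect_equal(c(r$start, r$end), c(3600L, 10000L))
  expect_equal(r$end - r$start, 6400L)

  # tie -> leftmost
  prof9 <- profile_of(rep(10L, 9000))
  sus2 <- region(rep("p", 2), c(3000L, 6500L), c(3500L, 7000L),
                 rep("suspicious", 2))
  r2 <- longest_non_suspicious(prof9, sus2)
  expect_equal(c(r2$start, r2$end), c(0L, 3000L))

  # 1-based inclusive report arithmetic: a gap printed as 25,567..152,989
  # (1-based inclusive) is [25566, 152989) internally, length 127,423
  r3 <- region("p", 25566L, 152989L, "non_suspicious")
  expect_equal(r3$end - r3$start, 127423L)
})

test_that("a fully suspicious contig is an uncorrectable-input error", {
  prof <- profile_of(rep(10L, 2000))
  sus <- region("p", 0L, 2000L, "suspicious")
  expect_error(longest_non_suspicious(prof, sus), "whole contig")
})
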