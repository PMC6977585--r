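# Reference-baited circular assembly: baiting, circular chain filter,
# overlap splitting and circularization.

test_that("origin-wrapping reads are baited; background reads are not", {
  mito <- simulate_genome(15000, list(), circular = TRUE, seed = 101)
  sim <- simulate_reads(mito, coverage = 4, read_length = c(7000, 5000),
                        error_rate = 0, seed = 102)
  nuc <- simulate_genome(30000, list(), seed = 103)
  noise <- simulate_reads(nuc, coverage = 2, read_length = c(7000, 5000),
                          error_rate = 0, seed = 104)
  noise$reads$read_id <- paste0("nuc_", noise$reads$read_id)
  noise$reads$zmw <- paste0("nuc_", noise$reads$zmw)
  db <- suppressMessages(build_db(rbind(sim$reads, noise$reads), 4000))
  hits <- bait_reads(db, mito$sequence)
  ids <- vapply(hits, function(x) x$read_id, "")
  expect_true(all(!grepl("^nuc_", ids)))
  mito_reads <- db$reads$read_id[!grepl("^nuc_", db$reads$read_id)]
  expect_setequal(ids, mito_reads)
  # a wrapping read is found with nearly all its bases aligned
  wraps <- vapply(sim$truth, function(t)
    any(t$source_intervals$genome_end > 15000), TRUE)
  wrap_ids <- vapply(sim$truth[wraps], function(t) t$read_id, "")
  wrap_ids <- intersect(wrap_ids, mito_reads)
  expect_gt(length(wrap_ids), 0)
  h <- hits[[match(wrap_ids[1], ids)]]
  expect_lt(h$unaligned, 100)
})

test_that("the circular chain filter applies its bounds exactly", {
  cand <- data.frame(aligned = c(3500, 10000, 15000, 10000),
                     unaligned = c(100, 1200, 100, 1600))
  kept <- filter_circular_chains(cand)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$aligned, 10000)
  expect_equal(kept$unaligned, 1200)
  # monotone in max_unaligned
  k1 <- filter_circular_chains(cand, circular_chain_filter(
    max_unaligned = 1500))
  k2 <- filter_circular_chains(cand, circular_chain_filter(
    max_unaligned = 2000))
  expect_true(all(do.call(paste, k1) %in% do.call(paste, k2)))
})

test_that("overlap splitting follows the stated arithmetic", {
  s <- rand_seq(10000, seed = 105)
  out <- split_with_overlap("r", s, target_length = 4000, overlap = 1500)
  expect_equal(nrow(out), 4)
  expect_equal(nchar(out$sequence), c(4000L, 4000L, 4000L, 2500L))
  # fragments start at multiples of target - overlap
  expect_equal(out$sequence[1], substr(s, 1, 4000))
  expect_equal(out$sequence[2], substr(s, 2501, 6500))
  expect_equal(out$sequence[3], substr(s, 5001, 9000))
  expect_equal(out$sequence[4], substr(s, 7501, 10000))
  # consecutive fragments share exactly `overlap` bases
  for (i in 1:3) {
    tail_i <- substr(out$sequence[i], nchar(out$sequence[i]) - 1499,
                     nchar(out$sequence[i]))
    head_n <- substr(out$sequence[i + 1], 1, 1500)
    expect_identical(substr(s, 2500 * i + 1, 2500 * i + 1500), head_n)
    expect_true(grepl(head_n, out$sequence[i], fixed = TRUE))
  }
  # short reads pass through unchanged
  s2 <- rand_seq(3000, seed = 106)
  expect_identical(split_with_overlap("r", s2, 4000, 1500)$sequence, s2)
})

test_that("circularize trims a duplicated terminal block and rotates", {
  set.seed(107)
  S <- rand_seq(2000); Tm <- rand_seq(9000)
  res <- circularize(paste0(S, Tm, S))
  expect_true(res$circular)
  expect_equal(res$sequence, paste0(S, Tm))
  expect_equal(res$trimmed, 2000L)
  # no self-overlap: unchanged
  plain <- rand_seq(8000)
  res2 <- circularize(plain)
  expect_false(res2$circular)
  expect_identical(res2$sequence, plain)
  # rotation to an anchor
  rot <- olca:::rotate_to_anchor(res$sequence, substr(Tm, 101, 160))
  expect_equal(substr(rot, 1, 60), substr(Tm, 101, 160))
  expect_equal(nchar(rot), nchar(res$sequence))
})

test_that("a circular genome is recovered exactly from error-free reads", {
  gsize <- 15303
  mito <- simulate_genome(gsize, list(), circular = TRUE, seed = 108)
  sim <- simulate_reads(mito, coverage = 40, read_length = c(8000, 6000),
                        error_rate = 0, seed = 109)
  db <- suppressMessages(build_db(sim$reads, 4000))
  res <- suppressMessages(suppressWarnings(
    assemble_mito(db, mito$sequence)))
  expect_false(is.null(res$contig))
  expect_true(res$contig$circular)
  expect_equal(res$contig$length, gsize)
  doubled <- paste0(mito$sequence, mito$sequence)
  expect_true(grepl(res$contig$sequence, doubled, fixed = TRUE) ||
                grepl(revcomp(res$contig$sequence), doubled, fixed = TRUE))
})
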