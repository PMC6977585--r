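# Simulator: determinism, planted repeats, coverage accounting, artefact
# bookkeeping.

test_that("genome simulation plants repeats and is seed-deterministic", {
  g0 <- simulate_genome(50000, list(), seed = 7)
  expect_equal(nchar(g0$sequence), 50000)
  expect_equal(nrow(g0$repeat_intervals), 0)
  expect_identical(g0$sequence, simulate_genome(50000, list(), seed = 7)$sequence)

  g1 <- simulate_genome(100000, list(repeat_spec("fam", 2000, 10, 0.95)),
                        seed = 1)
  expect_equal(nrow(g1$repeat_intervals), 10)
  lens <- g1$repeat_intervals$end - g1$repeat_intervals$begin
  expect_true(all(lens == 2000))
  expect_true(all(g1$repeat_intervals$begin >= 0 &
                    g1$repeat_intervals$end <= 100000))
  # planted copies are close to each other (identity ~0.90 pairwise)
  c1 <- substr(g1$sequence, g1$repeat_intervals$begin[1] + 1,
               g1$repeat_intervals$end[1])
  c2 <- substr(g1$sequence, g1$repeat_intervals$begin[2] + 1,
               g1$repeat_intervals$end[2])
  expect_gt(seq_identity(c1, c2), 0.80)
})

test_that("tandem repeat specs plant adjacent copies", {
  g <- simulate_genome(30000, list(repeat_spec("tr", 300, 5, 1, tandem = TRUE)),
                       seed = 3)
  iv <- g$repeat_intervals
  expect_equal(nrow(iv), 5)
  expect_true(all(diff(iv$begin) == 300))
})

test_that("repeats exceeding the genome are rejected", {
  expect_error(simulate_genome(5000, list(repeat_spec("x", 3000, 2)), seed = 1),
               "exceed")
})

test_that("read simulation hits the requested coverage", {
  g <- simulate_genome(100000, list(), seed = 5)
  sim <- simulate_reads(g, coverage = 30, read_length = c(8000, 4000),
                        error_rate = 0, seed = 3)
  tot <- sum(nchar(sim$reads$sequence))
  expect_lt(abs(tot - 3e6) / 3e6, 0.05)
})

test_that("error-free reads are exact genome substrings and truth round-trips", {
  g <- simulate_genome(60000, list(), seed = 9)
  sim <- simulate_reads(g, coverage = 3, read_length = c(6000, 3000),
                        error_rate = 0, seed = 10)
  for (t in sim$truth[1:10]) {
    si <- t$source_intervals
    piece <- substr(g$sequence, si$genome_begin[1] + 1, si$genome_end[1])
    if (si$strand[1] == "-") piece <- revcomp(piece)
    read <- sim$reads$sequence[sim$reads$read_id == t$read_id]
    expect_identical(read, piece)
  }
})

test_that("chimera counts are binomially consistent with the rate", {
  g <- simulate_genome(150000, list(), seed = 2)
  sim <- simulate_reads(g, coverage = 25, read_length = c(4000, 2500),
                        error_rate = 0,
                        artefact_rates = c(chimera = 0.05), seed = 6)
  n <- nrow(sim$reads)
  chim <- sum(vapply(sim$truth, function(t) {
    length(t$artefacts) > 0 && t$artefacts[[1]]$kind == "chimera"
  }, TRUE))
  expect_lt(abs(chim - 0.05 * n), 3 * sqrt(n * 0.05 * 0.95) + 1)
})

test_that("fold-back reads continue with the reverse complement", {
  g <- simulate_genome(60000, list(), seed = 4)
  sim <- simulate_reads(g, coverage = 5, read_length = c(6000, 3000),
                        error_rate = 0,
                        artefact_rates = c(adapter = 1), seed = 8)
  folded <- Filter(function(t) length(t$artefacts) &&
                     t$artefacts[[1]]$kind == "adapter", sim$truth)
  expect_gt(length(folded), 0)
  t <- folded[[1]]
  p <- t$artefacts[[1]]$position
  read <- sim$reads$sequence[sim$reads$read_id == t$read_id]
  left <- substr(read, 1, p)
  right <- substr(read, p + 1, nchar(read))
  # the fold-back mirrors the end of the first segment
  mirror <- substr(revcomp(left), 1, nchar(right))
  expect_identical(right, mirror)
})

test_that("reads wrap the origin of circular genomes", {
  g <- simulate_genome(15000, list(), circular = TRUE, seed = 12)
  sim <- simulate_reads(g, coverage = 20, read_length = c(7000, 5000),
                        error_rate = 0, seed = 13)
  wraps <- vapply(sim$truth, function(t)
    any(t$source_intervals$genome_end > 15000), TRUE)
  expect_gt(sum(wraps), 0)
  t <- sim$truth[[which(wraps)[1]]]
  si <- t$source_intervals
  piece <- paste0(substr(g$sequence, si$genome_begin[1] + 1, 15000),
                  substr(g$sequence, 1, si$genome_end[1] - 15000))
  if (si$strand[1] == "-") piece <- revcomp(piece)
  read <- sim$reads$sequence[sim$reads$read_id == t$read_id]
  expect_identical(read, piece)
})

test_that("identical seeds give byte-identical read sets", {
  g <- simulate_genome(40000, list(), seed = 20)
  s1 <- simulate_reads(g, 10, c(5000, 3000), 0.1,
                       c(chimera = 0.03, low_quality = 0.03), seed = 21)
  s2 <- simulate_reads(g, 10, c(5000, 3000), 0.1,
                       c(chimera = 0.03, low_quality = 0.03), seed = 21)
  expect_identical(s1$reads, s2$reads)
})
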