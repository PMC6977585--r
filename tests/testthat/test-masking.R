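# Three-tier masking: DUST low-complexity scoring, tandem self-matching
# and coverage-based repeat detection.

test_that("dust masks a homopolymer nearly end to end", {
  m <- dust_mask(strrep("A", 200))
  expect_equal(nrow(m), 1)
  expect_lt(m[1, 1], 5)
  expect_gt(m[1, 2], 195)
})

test_that("dust agrees with the brute-force window score oracle", {
  set.seed(41)
  # mixed read: random + AT microsatellite + random
  s <- paste0(rand_seq(300), strrep("AT", 60), rand_seq(300))
  got <- dust_mask(s, window = 64, threshold = 2.0)
  want <- oracle_dust_positions(s, 64, 2.0)
  got_pos <- logical(nchar(s))
  for (r in seq_len(nrow(got))) got_pos[(got[r, 1] + 1):got[r, 2]] <- TRUE
  expect_identical(got_pos, want)
})

test_that("random sequence is not dust-masked; short reads score empty", {
  set.seed(42)
  expect_equal(nrow(dust_mask(rand_seq(1000))), 0)
  expect_equal(nrow(dust_mask(rand_seq(30), window = 64)), 0)
})

test_that("tandem masking recovers a planted tandem array within a period", {
  set.seed(43)
  unit <- "ACGTT"
  s <- paste0(rand_seq(500), strrep(unit, 100), rand_seq(400))
  m <- tandem_mask(s)
  expect_equal(nrow(m), 1)
  expect_lte(abs(m[1, 1] - 500), nchar(unit) + 8)
  expect_lte(abs(m[1, 2] - 1000), nchar(unit) + 8)
  # random read: nothing; homopolymer: period-1 mask
  expect_equal(nrow(tandem_mask(rand_seq(2000))), 0)
  hp <- tandem_mask(strrep("G", 300))
  expect_equal(nrow(hp), 1)
  expect_gt(hp[1, 2] - hp[1, 1], 250)
})

test_that("1x grouping accumulates reads to the genome size", {
  lens <- rep(1000L, 10)
  groups <- olca:::group_reads_1x(lens, 5000)
  expect_equal(length(groups), 2)
  expect_equal(lengths(groups), c(5L, 5L))
})

test_that("coverage masking applies the distinct-read threshold exactly", {
  # constructed pile: 12 partners over [2000, 3000), 1 elsewhere
  mk <- function(n, b, e, b0 = 100) {
    data.frame(a_id = 1L, b_id = seq_len(n) + 1L, comp = 0L,
               a_begin = b, a_end = e, b_begin = b0, b_end = b0 + (e - b),
               diffs = 0L)
  }
  pile <- rbind(mk(12, 2000, 3000), data.frame(
    a_id = 1L, b_id = 20L, comp = 0L, a_begin = 5000L, a_end = 5600L,
    b_begin = 0L, b_end = 600L, diffs = 0L))
  cov <- olca:::coverage_by_distinct_partner(pile, 8000)
  iv <- olca:::runs_at_least(cov, 10)
  expect_equal(iv, cbind(2000L, 3000L))
  # 9 partners stay below the threshold of 10
  cov9 <- olca:::coverage_by_distinct_partner(mk(9, 2000, 3000), 8000)
  expect_equal(nrow(olca:::runs_at_least(cov9, 10)), 0)
  # multiple alignments from one partner count once
  dup <- rbind(mk(9, 2000, 3000), mk(9, 2100, 2900))
  covd <- olca:::coverage_by_distinct_partner(dup, 8000)
  expect_equal(nrow(olca:::runs_at_least(covd, 10)), 0)
})

test_that("planted interspersed repeats are coverage-masked, unique stays", {
  # a 1x group of a 150-kb genome holds ~25 reads, so a 20-copy family
  # puts ~20 distinct partner reads over each repeat instance, clearing
  # the >=10-read threshold, while unique sequence sees ~1
  gsize <- 150000
  g <- simulate_genome(gsize, list(repeat_spec("fam", 2000, 20, 0.95)),
                       seed = 51)
  sim <- simulate_reads(g, coverage = 12, read_length = c(6000, 3000),
                        error_rate = 0.1, seed = 52)
  db <- suppressMessages(build_db(sim$reads, 3000))
  db <- suppressMessages(suppressWarnings(
    mask_reads(db, genome_size_estimate = gsize, mask_threshold = 10)))
  cov <- db$tracks$coverage
  # project read masks onto the genome through the truth coordinates
  tru <- sim$truth
  names(tru) <- vapply(tru, function(t) t$read_id, "")
  rep_true <- logical(gsize)
  for (r in seq_len(nrow(g$repeat_intervals)))
    rep_true[(g$repeat_intervals$begin[r] + 1):g$repeat_intervals$end[r]] <- TRUE
  n_rep_read <- 0; n_rep_masked <- 0; n_uni_read <- 0; n_uni_masked <- 0
  for (i in seq_len(nrow(db$reads))) {
    id <- db$reads$read_id[i]
    si <- tru[[id]]$source_intervals
    L <- db$reads$length[i]
    m <- cov[[id]]
    pos_masked <- logical(L)
    if (!is.null(m) && nrow(m))
      for (r in seq_len(nrow(m))) pos_masked[(m[r, 1] + 1):m[r, 2]] <- TRUE
    # map read positions to genome (error-free mapping is approximate
    # under indels; sample every 20th position)
    gb <- si$genome_begin[1]; ge <- si$genome_end[1]
    glen <- ge - gb
    for (p in seq(1, L, by = 20)) {
      gp <- if (si$strand[1] == "+") gb + round((p - 1) * glen / L) else
        ge - 1 - round((p - 1) * glen / L)
      gp <- min(max(gp, 0), gsize - 1)
      if (rep_true[gp + 1]) {
        n_rep_read <- n_rep_read + 1
        if (pos_masked[p]) n_rep_masked <- n_rep_masked + 1
      } else {
        n_uni_read <- n_uni_read + 1
        if (pos_masked[p]) n_uni_masked <- n_uni_masked + 1
      }
    }
  }
  expect_gt(n_rep_masked / n_rep_read, 0.8)
  expect_lt(n_uni_masked / n_uni_read, 0.05)
})
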