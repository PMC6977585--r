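# Pairwise local alignment, chaining, classification and re-alignment.

test_that("an exact shared block is found with zero diffs on both strands", {
  set.seed(61)
  blk <- rand_seq(500)
  a <- paste0(rand_seq(400), blk, rand_seq(300))
  b <- paste0(rand_seq(200), blk, rand_seq(350))
  tab <- local_align(a, b, params = align_params(min_alignment_length = 300))
  expect_equal(nrow(tab), 1)
  expect_equal(tab$comp, 0L)
  # the block is covered; trimming may overhang a few coincidental bases
  expect_lte(tab$a_begin, 400 + 4)
  expect_gte(tab$a_end, 900 - 4)
  expect_equal(tab$diffs, oracle_edit(
    substr(a, tab$a_begin + 1, tab$a_end),
    substr(b, tab$b_begin + 1, tab$b_end)))

  b2 <- paste0(rand_seq(150), revcomp(blk), rand_seq(100))
  tab2 <- local_align(a, b2, params = align_params(min_alignment_length = 300))
  expect_equal(tab2$comp, 1L)
  expect_lte(abs(tab2$b_begin - 150), 4)
})

test_that("a read aligns to its own reverse complement full length", {
  set.seed(62)
  a <- rand_seq(2000)
  tab <- local_align(a, revcomp(a), params = align_params())
  tab <- tab[tab$comp == 1, , drop = FALSE]
  expect_equal(nrow(tab), 1)
  expect_lte(tab$a_begin, 2)
  expect_gte(tab$a_end, 1998)
  expect_equal(tab$diffs, 0L)
})

test_that("reported diffs equal the dynamic-programming edit distance", {
  set.seed(63)
  for (rep in 1:25) {
    n <- sample(800:2000, 1)
    src <- rand_seq(n)
    a <- paste0(rand_seq(sample(50:300, 1)), src)
    b <- paste0(olca:::mutate_errors(src, runif(1, 0, 0.12)),
                rand_seq(sample(50:300, 1)))
    tab <- local_align(a, b, params = align_params(min_alignment_length = 400))
    expect_gt(nrow(tab), 0)
    for (r in seq_len(nrow(tab))) {
      bseq <- substr(b, tab$b_begin[r] + 1, tab$b_end[r])
      if (tab$comp[r] == 1) bseq <- revcomp(bseq)
      expect_equal(tab$diffs[r],
                   oracle_edit(substr(a, tab$a_begin[r] + 1, tab$a_end[r]),
                               bseq))
    }
  }
})

test_that("masked k-mer seeding suppresses repeat-only alignments", {
  set.seed(64)
  rep_unit <- rand_seq(800)
  a <- paste0(rand_seq(700), rep_unit, rand_seq(700))
  b <- paste0(rand_seq(400), rep_unit, rand_seq(900))
  p <- align_params(min_alignment_length = 500)
  free <- local_align(a, b, params = p)
  expect_gt(nrow(free), 0)
  masked <- local_align(a, b, mask_a = rbind(c(700, 1500)),
                        mask_b = rbind(c(400, 1200)), params = p)
  expect_equal(nrow(masked), 0)
})

test_that("unmasked overlap set is a superset of the masked one", {
  g <- simulate_genome(40000, list(), seed = 65)
  sim <- simulate_reads(g, coverage = 6, read_length = c(6000, 3000),
                        error_rate = 0, seed = 66)
  db <- suppressMessages(build_db(sim$reads, 3000))
  masks <- interval_track(setNames(
    lapply(seq_len(nrow(db$reads)), function(i) rbind(c(100L, 900L))),
    db$reads$read_id))
  db2 <- set_track(db, "m", masks)
  free <- all_vs_all(db, NULL, align_params())
  masked <- all_vs_all(db2, "m", align_params())
  key <- function(t) unique(paste(t$a_id, t$b_id, t$comp))
  expect_true(all(key(masked) %in% key(free)))
})

test_that("all-vs-all alignments are symmetric under read exchange", {
  g <- simulate_genome(30000, list(), seed = 67)
  sim <- simulate_reads(g, coverage = 5, read_length = c(6000, 3000),
                        error_rate = 0.08, seed = 68)
  db <- suppressMessages(build_db(sim$reads, 3000))
  aln <- all_vs_all(db, NULL, align_params())
  fwd <- paste(aln$a_id, aln$b_id, aln$comp, aln$a_begin, aln$a_end,
               aln$b_begin, aln$b_end, aln$diffs)
  rev_ <- paste(aln$b_id, aln$a_id, aln$comp, aln$b_begin, aln$b_end,
                aln$a_begin, aln$a_end, aln$diffs)
  expect_setequal(fwd, rev_)
})

test_that("three identical reads give full-length piles", {
  s <- rand_seq(5000, seed = 69)
  db <- suppressMessages(build_db(subread_df(c(s, s, s)), 3000))
  aln <- all_vs_all(db, NULL, align_params())
  pl <- piles(aln)
  expect_equal(length(pl), 3)
  for (p in pl) {
    expect_equal(nrow(p), 2)
    expect_true(all(p$a_end - p$a_begin == 5000))
    expect_true(all(p$diffs == 0))
  }
})

test_that("error-free overlaps >= the minimum length are all recovered", {
  g <- simulate_genome(50000, list(), seed = 70)
  sim <- simulate_reads(g, coverage = 4, read_length = c(8000, 5000),
                        error_rate = 0, seed = 71)
  db <- suppressMessages(build_db(sim$reads, 4000))
  tru <- do.call(rbind, lapply(sim$truth, function(t)
    data.frame(read_id = t$read_id, b = t$source_intervals$genome_begin[1],
               e = t$source_intervals$genome_end[1])))
  tru <- tru[match(db$reads$read_id, tru$read_id), ]
  aln <- all_vs_all(db, NULL, align_params())
  found <- unique(paste(pmin(aln$a_id, aln$b_id), pmax(aln$a_id, aln$b_id)))
  n <- nrow(db$reads)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ovl <- min(tru$e[i], tru$e[j]) - max(tru$b[i], tru$b[j])
    if (ovl >= 700) expect_true(paste(i, j) %in% found)
  }
})

test_that("chaining joins co-linear pieces and splits crossing ones", {
  base <- data.frame(a_id = 1L, b_id = 2L, comp = 0L)
  two <- rbind(cbind(base, a_begin = 0L, a_end = 1000L,
                     b_begin = 100L, b_end = 1100L, diffs = 5L),
               cbind(base, a_begin = 1200L, a_end = 2000L,
                     b_begin = 1300L, b_end = 2100L, diffs = 3L))
  ch <- chain_alignments(two, max_gap = 1500)
  expect_equal(length(ch), 1)
  expect_equal(nrow(ch[[1]]), 2)
  expect_equal(attr(ch[[1]], "aligned"), 1800L)
  crossing <- rbind(cbind(base, a_begin = 0L, a_end = 1000L,
                          b_begin = 1300L, b_end = 2300L, diffs = 0L),
                    cbind(base, a_begin = 1200L, a_end = 2000L,
                          b_begin = 100L, b_end = 900L, diffs = 0L))
  expect_equal(length(chain_alignments(crossing, max_gap = 1500)), 2)
  expect_error(chain_alignments(rbind(two, cbind(
    data.frame(a_id = 1L, b_id = 3L, comp = 0L), a_begin = 0L, a_end = 10L,
    b_begin = 0L, b_end = 10L, diffs = 0L))), "mixed")
})

test_that("best chain matches exhaustive enumeration on small instances", {
  set.seed(72)
  for (rep in 1:20) {
    m <- sample(3:7, 1)
    tab <- data.frame(
      a_id = 1L, b_id = 2L, comp = 0L,
      a_begin = sort(sample.int(8000, m)))
    tab$a_end <- tab$a_begin + sample(200:900, m, replace = TRUE)
    tab$b_begin <- tab$a_begin + sample(-800:800, m, replace = TRUE)
    tab$b_end <- tab$b_begin + (tab$a_end - tab$a_begin)
    tab$diffs <- 0L
    chains <- chain_alignments(tab, max_gap = 1500)
    best <- max(vapply(chains, function(ch)
      sum(ch$a_end - ch$a_begin + ch$b_end - ch$b_begin), 0))
    expect_equal(best, oracle_best_chain(tab, max_gap = 1500))
  }
})

test_that("chain classification separates proper, premature and improper", {
  mk <- function(ab, ae, bb, be) data.frame(
    a_id = 1L, b_id = 2L, comp = 0L, a_begin = ab, a_end = ae,
    b_begin = bb, b_end = be, diffs = 0L)
  # spans A fully
  expect_equal(classify_chain(mk(0, 8000, 100, 8100), 8000, 10000), "proper")
  # dovetail: A-right to B-left
  expect_equal(classify_chain(mk(3000, 8000, 0, 5000), 8000, 9000), "proper")
  # ends 3 kb inside both reads, endpoint masked -> premature
  rep_a <- rbind(c(4800, 6000))
  expect_equal(classify_chain(mk(0, 5000, 0, 5000), 8000, 9000,
                              repeat_a = rep_a), "premature_in_repeat")
  # same, no mask -> improper
  expect_equal(classify_chain(mk(0, 5000, 0, 5000), 8000, 9000), "improper")
})

test_that("mask-free re-alignment rescues overlaps through masked repeats", {
  set.seed(73)
  # both reads sample the same locus: unique | 4 kb repeat | unique; the
  # repeat is masked in both, extensions stop inside it, and the chain
  # cannot bridge the remaining gap
  locus <- paste0(rand_seq(4500), rand_seq(4000), rand_seq(4500))
  a <- substr(locus, 1, 10500)         # covers [0, 10500)
  b <- substr(locus, 2001, 13000)      # covers [2000, 13000)
  mask_a <- rbind(c(4500L, 8500L))     # repeat on a
  mask_b <- rbind(c(2500L, 6500L))     # same repeat on b
  p <- align_params()
  masked <- local_align(a, b, mask_a = mask_a, mask_b = mask_b, params = p)
  masked$a_id <- 1L; masked$b_id <- 2L
  chains <- list()
  for (grp in split(masked, masked$comp))
    chains <- c(chains, chain_alignments(grp, max_gap = p$max_gap))
  status <- vapply(chains, classify_chain, "", len_a = nchar(a),
                   len_b = nchar(b), repeat_a = mask_a, repeat_b = mask_b,
                   end_slack = p$end_slack)
  expect_true(any(status == "premature_in_repeat"))
  expect_false(any(status == "proper"))
  # re-run without masks: the overlap becomes one proper chain
  free <- local_align(a, b, params = p)
  free$a_id <- 1L; free$b_id <- 2L
  chains2 <- list()
  for (grp in split(free, free$comp))
    chains2 <- c(chains2, chain_alignments(grp, max_gap = p$max_gap))
  status2 <- vapply(chains2, classify_chain, "", len_a = nchar(a),
                    len_b = nchar(b), end_slack = p$end_slack)
  expect_true(any(status2 == "proper"))
  # a control pair with no true overlap beyond the repeat stays improper
  c2 <- paste0(rand_seq(2500), substr(locus, 4501, 8500), rand_seq(2500))
  free3 <- local_align(a, c2, params = p)
  if (nrow(free3)) {
    free3$a_id <- 1L; free3$b_id <- 2L
    chains3 <- list()
    for (grp in split(free3, free3$comp))
      chains3 <- c(chains3, chain_alignments(grp, max_gap = p$max_gap))
    status3 <- vapply(chains3, classify_chain, "", len_a = nchar(a),
                      len_b = nchar(c2), end_slack = p$end_slack)
    expect_false(any(status3 == "proper"))
  }
})
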