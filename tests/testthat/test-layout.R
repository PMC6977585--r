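# Layout: quality track, pile filtering, string graph, transitive
# reduction, touring, consensus and contiguity statistics.

test_that("quality track localizes divergence and flags uncovered segments", {
  # one read with a locally mutated stretch against clean partners
  set.seed(81)
  src <- rand_seq(6000)
  bad <- paste0(substr(src, 1, 2999),
                olca:::mutate_errors(substr(src, 3000, 3999), 0.25),
                substr(src, 4000, 6000))
  db <- suppressMessages(build_db(subread_df(c(bad, src, src, src)), 3000))
  aln <- all_vs_all(db, NULL, align_params(segment_diffs = TRUE))
  pile1 <- piles(aln)[["1"]]
  qt <- quality_track(pile1, db$reads$length[1], segment = 100)
  mid <- qt[32:38]          # inside the mutated stretch
  flank <- qt[c(5:25, 45:58)]
  expect_true(all(is.finite(mid)))
  expect_gt(min(mid, na.rm = TRUE), 3 * max(max(flank, na.rm = TRUE), 0.01))
  # a read with no alignments is all sentinel
  qt0 <- quality_track(NULL, 5000, segment = 100)
  expect_true(all(is.na(qt0)))
  # identical partners: covered segments away from the planted stretch
  # have zero divergence
  pile2 <- piles(aln)[["3"]]
  qt2 <- quality_track(pile2, db$reads$length[3], segment = 100)
  flank2 <- qt2[c(5:25, 45:58)]
  expect_true(all(flank2[!is.na(flank2)] == 0))
})

test_that("filter_piles emits dovetails, records containments, drops repeat-only", {
  g <- simulate_genome(40000, list(), seed = 82)
  sim <- simulate_reads(g, coverage = 10, read_length = c(6000, 3000),
                        error_rate = 0, seed = 83)
  db <- suppressMessages(build_db(sim$reads, 3000))
  aln <- all_vs_all(db, NULL, align_params())
  fp <- filter_piles(aln, db, NULL)
  expect_gt(nrow(fp$edges), 0)
  expect_gt(length(fp$contained), 0)
  # no edge touches a contained read
  expect_false(any(fp$edges$a_id %in% fp$contained |
                     fp$edges$b_id %in% fp$contained))
  # an alignment wholly inside repeat intervals on both reads is dropped
  rt <- interval_track(setNames(
    lapply(db$reads$length, function(L) rbind(c(0L, L))),
    db$reads$read_id))
  fp2 <- filter_piles(aln, db, rt)
  expect_equal(nrow(fp2$edges), 0)
})

test_that("transitive reduction removes implied edges, keeps reachability", {
  # A->B (5 kb), B->C (5 kb), A->C (10 kb) collapses to the two short edges
  g3 <- data.frame(from = c(1L, 2L, 1L), to = c(2L, 3L, 3L),
                   length = c(5000L, 5000L, 10050L),
                   overlap = c(4000L, 4000L, 2000L), diffs = 0L)
  red <- transitive_reduction(g3, fuzz = 200)
  expect_equal(nrow(red), 2)
  expect_false(any(red$from == 1 & red$to == 3))
  # no transitive triples -> unchanged
  g2 <- g3[1:2, ]
  expect_equal(nrow(transitive_reduction(g2, 200)), 2)
})

test_that("reduction preserves reachability on random consistent graphs", {
  for (seed in 1:40) {
    g <- random_overlap_graph(sample(4:12, 1), seed)
    if (is.null(g)) next
    red <- transitive_reduction(g, fuzz = 200)
    expect_true(nrow(red) <= nrow(g))
    R0 <- oracle_reachable(g)
    R1 <- oracle_reachable(red)
    expect_identical(rownames(R0), rownames(R1))
    expect_identical(R0, R1)
  }
})

test_that("touring walks linear chains, flags cycles, takes the long branch", {
  db <- structure(list(reads = data.frame(
    id = 1:6, read_id = paste0("r", 1:6), zmw = paste0("r", 1:6),
    length = rep(1000L, 6), sequence = replicate(6, rand_seq(1000))),
    tracks = list()), class = "read_db")
  line <- data.frame(from = c(1:4, -5:-2), to = c(2:5, -4:-1),
                     length = 500L, overlap = 500L, diffs = 0L)
  p <- tour(line, db)
  main <- Filter(function(x) length(x$reads) > 1, p)
  expect_equal(length(main), 1)
  expect_equal(abs(main[[1]]$reads), 1:5)
  expect_false(main[[1]]$circular)
  # simple cycle
  cyc <- data.frame(from = c(1:4, -1, -4:-2), to = c(2:4, 1, -4, -3:-1),
                    length = 500L, overlap = 500L, diffs = 0L)
  pc <- tour(cyc, db)
  mainc <- Filter(function(x) length(x$reads) > 1, pc)
  expect_true(any(vapply(mainc, function(x) x$circular, TRUE)))
  # junction: 1 -> {2 (overlap 800), 6 (overlap 300)}; richer branch wins
  jn <- data.frame(from = c(1L, 1L, 2L, -2L, -6L, -3L),
                   to = c(2L, 6L, 3L, -1L, -1L, -2L),
                   length = 500L, overlap = c(800L, 300L, 700L, 800L, 300L,
                                              700L), diffs = 0L)
  pj <- tour(jn, db)
  first <- pj[[which.max(vapply(pj, function(x) length(x$reads), 0L))]]
  expect_true(all(c(1, 2, 3) %in% abs(first$reads)))
  expect_false(6 %in% abs(first$reads))
})

test_that("consensus reproduces the truth exactly from error-free reads", {
  g <- simulate_genome(30000, list(), seed = 84)
  sim <- simulate_reads(g, coverage = 10, read_length = c(6000, 3000),
                        error_rate = 0, seed = 85)
  db <- suppressMessages(build_db(sim$reads, 3000))
  aln <- all_vs_all(db, NULL, align_params())
  asm <- assemble(db, aln, NULL)
  expect_equal(nrow(asm$contigs), 1)
  s <- asm$contigs$sequence[1]
  expect_true(s == g$sequence || s == revcomp(g$sequence))
  # single-read path: consensus is the read itself
  one <- consensus(list(reads = 1L, circular = FALSE), db,
                   asm$graph[0, , drop = FALSE],
                   polish_reads = db$reads$sequence[1])
  expect_equal(one$sequence, db$reads$sequence[1])
})

test_that("N(x) statistics match the sort-and-accumulate definition", {
  st <- assembly_stats(c(10, 7, 5, 3))
  expect_equal(st$n50, 7)
  expect_equal(unname(st$n_curve["0"]), 10)
  expect_equal(unname(st$n_curve["100"]), 3)
  expect_true(all(diff(st$n_curve) <= 0))
  one <- assembly_stats(12345)
  expect_true(all(one$n_curve == 12345))
  zero <- assembly_stats(integer())
  expect_equal(zero$n50, 0)
  # random length sets against an independent accumulation
  set.seed(86)
  for (rep in 1:50) {
    lens <- sample.int(5000, sample(1:30, 1))
    st <- assembly_stats(lens)
    expect_true(all(diff(st$n_curve) <= 0))
    sorted <- sort(lens, decreasing = TRUE)
    cum <- cumsum(sorted)
    expect_equal(st$n50, sorted[which(cum >= sum(lens) * 0.5)[1]])
  }
})
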