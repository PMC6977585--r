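# Artefact detection from piles, the spanning-chain chimera rule, and
# patch application.

test_that("a simulated chimeric read gets exactly one break near the junction", {
  g <- simulate_genome(80000, list(), seed = 91)
  sim <- simulate_reads(g, coverage = 25, read_length = c(6000, 3500),
                        error_rate = 0, seed = 92)
  db <- suppressMessages(build_db(sim$reads, 3500))
  # plant one chimeric read: two distant loci joined bluntly
  left <- substr(g$sequence, 10001, 13000)
  right <- substr(g$sequence, 60001, 63000)
  chim <- paste0(left, right)
  db2 <- suppressMessages(build_db(rbind(
    data.frame(read_id = "chim", zmw = "chim", subread_index = 1L,
               sequence = chim),
    db$reads[, c("read_id", "zmw", "sequence")] |>
      transform(subread_index = 1L)), 3000))
  aln <- all_vs_all(db2, NULL, align_params())
  chim_id <- which(db2$reads$read_id == "chim")
  ev <- detect_artefacts(piles(aln)[[as.character(chim_id)]], db2)
  br <- ev[ev$kind == "chimera_break", ]
  expect_equal(nrow(br), 1)
  expect_lt(abs(br$begin - 3000), 100 + 1)
  # clean reads: no artefact calls
  clean_id <- chim_id + 1
  ev0 <- detect_artefacts(piles(aln)[[as.character(clean_id)]], db2)
  expect_equal(nrow(ev0), 0)
})

test_that("a fold-back read gets an adapter break at the fold", {
  g <- simulate_genome(60000, list(), seed = 93)
  sim <- simulate_reads(g, coverage = 25, read_length = c(6000, 3500),
                        error_rate = 0, seed = 94)
  db <- suppressMessages(build_db(sim$reads, 3500))
  piece <- substr(g$sequence, 20001, 23500)
  fold <- paste0(piece, revcomp(piece))
  db2 <- suppressMessages(build_db(rbind(
    data.frame(read_id = "fold", zmw = "fold", subread_index = 1L,
               sequence = fold),
    db$reads[, c("read_id", "zmw", "sequence")] |>
      transform(subread_index = 1L)), 3000))
  aln <- all_vs_all(db2, NULL, align_params())
  fold_id <- which(db2$reads$read_id == "fold")
  ev <- detect_artefacts(piles(aln)[[as.character(fold_id)]], db2)
  br <- ev[ev$kind == "adapter_break", ]
  expect_equal(nrow(br), 1)
  expect_lt(abs(br$begin - 3500), 150)
})

test_that("the spanning-chain rule applies the repeat-length and count bounds", {
  mk_chain <- function(ab, ae, status = "proper") {
    ch <- data.frame(a_id = 1L, b_id = 2L, comp = 0L, a_begin = ab,
                     a_end = ae, b_begin = 0L, b_end = ae - ab, diffs = 0L)
    attr(ch, "status") <- status
    ch
  }
  L <- 20000L
  rep5 <- rbind(c(8000L, 13000L))       # 5-kb repeat interval
  spanning <- function(n) replicate(n, mk_chain(7000L, 14000L),
                                    simplify = FALSE)
  expect_equal(apply_chimera_repeat_rule("r", spanning(2), rep5, L), "exclude")
  expect_equal(apply_chimera_repeat_rule("r", spanning(3), rep5, L), "keep")
  # chains must really span with flanks: touching chains do not count
  touching <- replicate(3, mk_chain(8000L, 13000L), simplify = FALSE)
  expect_equal(apply_chimera_repeat_rule("r", touching, rep5, L), "exclude")
  # improper chains never certify
  bad <- replicate(3, mk_chain(7000L, 14000L, "improper"), simplify = FALSE)
  expect_equal(apply_chimera_repeat_rule("r", bad, rep5, L), "exclude")
  # a 9-kb repeat exceeds the 8-kb re-analysis bound: rule not applied
  rep9 <- rbind(c(5000L, 14000L))
  expect_equal(apply_chimera_repeat_rule("r", list(), rep9, L), "keep")
  # monotone: adding a spanning chain never flips keep -> exclude
  for (n in 3:6)
    expect_equal(apply_chimera_repeat_rule("r", spanning(n), rep5, L), "keep")
})

test_that("patch application splits, replaces and renames", {
  s <- rand_seq(20000, seed = 95)
  ev <- data.frame(read_id = "r", kind = "chimera_break",
                   begin = 12000L, end = 12000L, replacement = NA_character_)
  out <- apply_patches("r", s, ev, min_length = 4000)
  expect_equal(out$read_id, c("r.part1", "r.part2"))
  expect_equal(nchar(out$sequence), c(12000L, 8000L))
  expect_equal(paste0(out$sequence[1], out$sequence[2]), s)
  # no events: identity
  out2 <- apply_patches("r", s, NULL)
  expect_identical(out2$sequence, s)
  expect_identical(out2$read_id, "r")
  # replacement changes length by the replacement difference
  ev3 <- data.frame(read_id = "r", kind = "low_quality_patch",
                    begin = 5000L, end = 6000L,
                    replacement = rand_seq(980))
  out3 <- apply_patches("r", s, ev3, min_length = 4000)
  expect_equal(nchar(out3$sequence), 20000L - 20L)
  # short fragments are discarded
  ev4 <- data.frame(read_id = "r", kind = "chimera_break",
                    begin = 2000L, end = 2000L, replacement = NA_character_)
  out4 <- apply_patches("r", s, ev4, min_length = 4000)
  expect_equal(nchar(out4$sequence), 18000L)
  # overlapping events are rejected
  ev5 <- rbind(ev3, data.frame(read_id = "r", kind = "low_quality_patch",
                               begin = 5500L, end = 6500L,
                               replacement = rand_seq(1000)))
  expect_error(apply_patches("r", s, ev5), "overlap")
})

test_that("splitting conserves sequence: output is substrings of the input", {
  s <- rand_seq(15000, seed = 96)
  ev <- data.frame(read_id = "r", kind = c("chimera_break", "adapter_break"),
                   begin = c(5000L, 10000L), end = c(5000L, 10000L),
                   replacement = NA_character_)
  out <- apply_patches("r", s, ev, min_length = 1000)
  expect_equal(nrow(out), 3)
  for (fr in out$sequence) expect_true(grepl(fr, s, fixed = TRUE))
  expect_lte(sum(nchar(out$sequence)), nchar(s))
})
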