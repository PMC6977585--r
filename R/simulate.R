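# Synthetic data: genomes with planted repeat families and noisy long
# reads with injected artefacts, each carrying machine-readable ground
# truth. The generator stands in for real single-molecule data so that
# every pipeline stage can be tested against known answers.

#' Describe a repeat family to plant in a simulated genome
#'
#' @param family_id label for the family.
#' @param unit_length repeat unit length in bases.
#' @param copies number of copies to plant.
#' @param identity expected sequence identity of each copy to the family
#'   consensus, in `[0, 1]`; copies are mutated from the consensus at a
#'   per-base substitution rate of `1 - identity`.
#' @param tandem if `TRUE` the copies are planted head-to-tail at a single
#'   locus; otherwise they are scattered at random non-overlapping
#'   positions.
#' @return a `repeat_spec` object.
#' @export
repeat_spec <- function(family_id, unit_length, copies,
                        identity = 0.95, tandem = FALSE) {
  stopifnot(unit_length >= 1, copies >= 1, identity >= 0, identity <= 1)
  structure(list(family_id = as.character(family_id),
                 unit_length = as.integer(unit_length),
                 copies = as.integer(copies),
                 identity = identity, tandem = isTRUE(tandem)),
            class = "repeat_spec")
}

#' Simulate a genome with planted repeat families
#'
#' Background sequence is uniform random; each repeat family gets a random
#' consensus unit and `copies` mutated copies, planted tandemly or
#' scattered without overlap. Every planted copy is recorded in
#' `repeat_intervals` as ground truth.
#'
#' @param length genome length in bases.
#' @param repeats list of [repeat_spec()] objects.
#' @param circular logical; circular genomes allow reads to wrap the
#'   origin in [simulate_reads()].
#' @param seed integer seed; identical seeds give identical genomes.
#' @return a `genome_truth` list with `sequence`, `circular` and
#'   `repeat_intervals` (data.frame family_id/begin/end, half-open 0-based).
#' @export
simulate_genome <- function(length, repeats = list(), circular = FALSE,
                            seed = 1L) {
  stopifnot(length >= 1)
  if (inherits(repeats, "repeat_spec")) repeats <- list(repeats)
  total_rep <- sum(vapply(repeats, function(r) r$unit_length * r$copies, 0))
  if (total_rep >= length)
    stop("planted repeats (", total_rep,
         " bases) exceed the genome length (", length, ")")
  with_seed(seed, {
    seq <- random_seq(length)
    iv <- list()
    occupied <- matrix(integer(), 0, 2)
    for (r in repeats) {
      unit <- random_seq(r$unit_length)
      copies <- vapply(seq_len(r$copies), function(i) {
        mutate_substitutions(unit, 1 - r$identity)
      }, "")
      if (r$tandem) {
        block <- paste(copies, collapse = "")
        pos <- place_block(nchar(block), length, occupied)
        occupied <- rbind(occupied, c(pos, pos + nchar(block)))
        substr(seq, pos + 1, pos + nchar(block)) <- block
        at <- pos
        for (cp in copies) {
          iv[[length(iv) + 1]] <- data.frame(
            family_id = r$family_id, begin = at, end = at + nchar(cp))
          at <- at + nchar(cp)
        }
      } else {
        for (cp in copies) {
          pos <- place_block(nchar(cp), length, occupied)
          occupied <- rbind(occupied, c(pos, pos + nchar(cp)))
          substr(seq, pos + 1, pos + nchar(cp)) <- cp
          iv[[length(iv) + 1]] <- data.frame(
            family_id = r$family_id, begin = pos, end = pos + nchar(cp))
        }
      }
    }
    repeat_intervals <- if (length(iv)) do.call(rbind, iv) else
      data.frame(family_id = character(), begin = integer(), end = integer())
    structure(list(sequence = seq, circular = isTRUE(circular),
                   repeat_intervals = repeat_intervals),
              class = "genome_truth")
  })
}

# random non-overlapping placement by rejection sampling
place_block <- function(blen, glen, occupied) {
  for (try in 1:2000) {
    pos <- sample.int(glen - blen + 1L, 1L) - 1L
    if (nrow(occupied) == 0 ||
        all(pos + blen <= occupied[, 1] | pos >= occupied[, 2]))
      return(pos)
  }
  stop("could not place a repeat copy without overlap; genome too crowded")
}

# substitution-only mutation (used for repeat copy divergence)
mutate_substitutions <- function(seq, rate) {
  if (rate <= 0) return(seq)
  s <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(s)) < rate)
  if (length(hit)) {
    alt <- c("A", "C", "G", "T")
    s[hit] <- vapply(s[hit], function(b) sample(setdiff(alt, b), 1), "")
  }
  paste(s, collapse = "")
}

# apply sequencing errors to a sequence; composition is the
# insertion/deletion/substitution split of the total error rate.
# Returns the mutated sequence.
mutate_errors <- function(seq, rate, composition = c(0.55, 0.25, 0.20)) {
  if (rate <= 0 || nchar(seq) == 0) return(seq)
  s <- strsplit(seq, "")[[1]]
  n <- length(s)
  p <- rate * composition / sum(composition)
  ev <- sample.int(4L, n, replace = TRUE,
                   prob = c(p[1], p[2], p[3], 1 - sum(p)))
  alt <- c("A", "C", "G", "T")
  out <- s
  sub_i <- which(ev == 3L)
  if (length(sub_i))
    out[sub_i] <- vapply(out[sub_i], function(b) sample(setdiff(alt, b), 1), "")
  ins_i <- which(ev == 1L)
  if (length(ins_i))
    out[ins_i] <- paste0(sample(alt, length(ins_i), replace = TRUE), out[ins_i])
  del_i <- which(ev == 2L)
  if (length(del_i)) out[del_i] <- ""
  paste(out, collapse = "")
}

# extract genome interval with optional wrap for circular genomes
genome_substr <- function(genome, begin, end) {
  G <- nchar(genome$sequence)
  if (end <= G) return(substr0(genome$sequence, begin, end))
  if (!genome$circular) stop("interval beyond linear genome end")
  paste0(substr0(genome$sequence, begin, G),
         substr0(genome$sequence, 0, end - G))
}

#' Simulate noisy long reads with injected artefacts
#'
#' Reads are sampled from both strands until the requested coverage in
#' bases is reached. Lengths follow a log-normal fitted to
#' `read_length = c(mean, min)` with hard truncation at the minimum.
#' Errors are indel-dominated (default 55\% insertion / 25\% deletion /
#' 20\% substitution). Optionally, reads carry one of four artefacts:
#' a chimeric junction joining an unrelated locus (blunt, no shared
#' sequence), a missed-adapter fold-back (the read continues with the
#' reverse complement of the preceding segment), a polymerase strand
#' jump (continues on the opposite strand at a nearby position), or a
#' long low-quality segment with at least 3x the baseline error rate.
#' Each simulated molecule gets one ZMW identity; with probability equal
#' to the adapter rate a ZMW emits a second, shorter subread so that
#' longest-subread selection is exercised. For circular genomes reads may
#' wrap the origin. Every artefact is recorded in the returned truth.
#'
#' @param genome a `genome_truth` from [simulate_genome()].
#' @param coverage fold coverage in bases.
#' @param read_length numeric pair `c(mean, min)` in bases.
#' @param error_rate total per-base error rate in `[0, 0.3]`.
#' @param artefact_rates named numeric vector with any of `chimera`,
#'   `adapter`, `strand_jump`, `low_quality` (per-read probabilities).
#' @param seed integer seed.
#' @param error_composition insertion/deletion/substitution split.
#' @return list with `reads` (data.frame read_id/zmw/subread_index/
#'   sequence) and `truth` (list of per-read truth records with
#'   `source_intervals` and `artefacts`).
#' @export
simulate_reads <- function(genome, coverage, read_length = c(8000, 4000),
                           error_rate = 0.1,
                           artefact_rates = c(chimera = 0, adapter = 0,
                                              strand_jump = 0,
                                              low_quality = 0),
                           seed = 1L,
                           error_composition = c(0.55, 0.25, 0.20)) {
  stopifnot(coverage > 0, error_rate >= 0, error_rate <= 0.3)
  G <- nchar(genome$sequence)
  rates <- c(chimera = 0, adapter = 0, strand_jump = 0, low_quality = 0)
  rates[names(artefact_rates)] <- artefact_rates
  target <- coverage * G
  with_seed(seed, {
    reads <- list(); truth <- list()
    total <- 0; zmw <- 0
    while (total < target) {
      zmw <- zmw + 1
      L <- min(draw_read_lengths(1, read_length[1], read_length[2]), G)
      kind <- sample(c(names(rates), "none"), 1,
                     prob = c(rates, max(0, 1 - sum(rates))))
      rec <- make_read(genome, L, kind, error_rate, error_composition)
      id <- sprintf("sim/%d/0_%d", zmw, nchar(rec$sequence))
      reads[[length(reads) + 1]] <- data.frame(
        read_id = id, zmw = as.character(zmw), subread_index = 1L,
        sequence = rec$sequence)
      rec$read_id <- id
      truth[[length(truth) + 1]] <- rec[c("read_id", "source_intervals",
                                          "artefacts")]
      total <- total + nchar(rec$sequence)
      # a second, shorter subread from the same ZMW (detected adapter)
      if (runif(1) < rates[["adapter"]]) {
        L2 <- max(read_length[2] %/% 2L, as.integer(nchar(rec$sequence) * 0.5))
        rec2 <- make_read(genome, L2, "none", error_rate, error_composition)
        id2 <- sprintf("sim/%d/%d_%d", zmw, nchar(rec$sequence) + 50L,
                       nchar(rec$sequence) + 50L + nchar(rec2$sequence))
        reads[[length(reads) + 1]] <- data.frame(
          read_id = id2, zmw = as.character(zmw), subread_index = 2L,
          sequence = rec2$sequence)
        rec2$read_id <- id2
        truth[[length(truth) + 1]] <- rec2[c("read_id", "source_intervals",
                                             "artefacts")]
      }
    }
    list(reads = do.call(rbind, reads), truth = truth)
  })
}

# sample one read of target length L with an optional artefact
make_read <- function(genome, L, kind, error_rate, composition) {
  G <- nchar(genome$sequence)
  L <- min(L, G)
  segs <- list() # each: list(begin, end, strand) genome coordinates
  if (kind == "chimera" && L >= 2000) {
    l1 <- as.integer(L * runif(1, 0.3, 0.7)); l2 <- L - l1
    segs[[1]] <- sample_segment(genome, l1)
    s2 <- sample_segment(genome, l2)
    for (try in 1:50) { # unrelated locus: force distance from the first
      d <- abs(s2$begin - segs[[1]]$begin)
      if (genome$circular) d <- min(d, G - d)
      if (d > 1.5 * L) break
      s2 <- sample_segment(genome, l2)
    }
    segs[[2]] <- s2
  } else if (kind == "adapter" && L >= 2000) {
    l1 <- as.integer(L * runif(1, 0.4, 0.6))
    s1 <- sample_segment(genome, l1)
    l1 <- s1$end - s1$begin  # clipping at genome edges may shorten it
    segs[[1]] <- s1
    # fold-back: reverse complement of the tail of the first segment
    l2 <- min(L - l1, l1)
    if (s1$strand == "+") {
      segs[[2]] <- list(begin = s1$end - l2, end = s1$end, strand = "-")
    } else {
      segs[[2]] <- list(begin = s1$begin, end = s1$begin + l2, strand = "+")
    }
  } else if (kind == "strand_jump" && L >= 2000) {
    l1 <- as.integer(L * runif(1, 0.3, 0.7)); l2 <- L - l1
    s1 <- sample_segment(genome, l1)
    segs[[1]] <- s1
    jump <- as.integer(runif(1, 200, 2000))
    b2 <- max(0, min(G - l2, s1$end + jump))
    segs[[2]] <- list(begin = b2, end = b2 + l2,
                      strand = if (s1$strand == "+") "-" else "+")
  } else {
    segs[[1]] <- sample_segment(genome, L)
  }
  pieces <- character(length(segs)); junctions <- integer(0)
  lowq <- NULL
  at <- 0L
  for (i in seq_along(segs)) {
    s <- segs[[i]]
    raw <- genome_substr(genome, s$begin, s$end)
    if (s$strand == "-") raw <- revcomp(raw)
    piece <- mutate_errors(raw, error_rate, composition)
    pieces[i] <- piece
    at <- at + nchar(piece)
    if (i < length(segs)) junctions <- c(junctions, at)
  }
  seqread <- paste(pieces, collapse = "")
  if (kind == "low_quality" && nchar(seqread) > 3000) {
    n <- nchar(seqread)
    w <- as.integer(runif(1, 800, 2000))
    b <- as.integer(runif(1, 500, max(501, n - w - 500)))
    bad_rate <- min(0.45, max(3 * error_rate, 0.25))
    extra <- (bad_rate - error_rate) / max(1e-9, 1 - error_rate)
    bad <- mutate_errors(substr0(seqread, b, b + w), extra, composition)
    seqread <- paste0(substr0(seqread, 0, b), bad,
                      substr0(seqread, b + w, n))
    lowq <- c(b, b + nchar(bad))
  }
  artefacts <- list()
  kinds <- c(chimera = "chimera", adapter = "adapter",
             strand_jump = "strand_jump")
  if (kind %in% names(kinds) && length(junctions))
    artefacts[[1]] <- list(kind = kind, position = junctions[1])
  if (!is.null(lowq))
    artefacts[[length(artefacts) + 1]] <- list(kind = "low_quality",
                                               interval = lowq)
  list(sequence = seqread,
       source_intervals = data.frame(
         genome_begin = vapply(segs, function(s) s$begin, 0),
         genome_end = vapply(segs, function(s) s$end, 0),
         strand = vapply(segs, function(s) s$strand, "")),
       artefacts = artefacts)
}

# sample a genome segment of length l (clipped at linear genome edges so
# that terminal bases stay reachable; wrapping allowed when circular)
sample_segment <- function(genome, l) {
  G <- nchar(genome$sequence)
  l <- min(l, G)
  strand <- sample(c("+", "-"), 1)
  if (genome$circular) {
    b <- sample.int(G, 1) - 1L
    list(begin = b, end = b + l, strand = strand)
  } else {
    b <- sample.int(G + l - 1L, 1) - l  # in [-(l-1), G-1]
    e <- min(G, b + l); b <- max(0L, b)
    list(begin = b, end = e, strand = strand)
  }
}

#' Write simulated reads and truth to disk
#'
#' Reads go to FASTA (headers `sim/<zmw>/<start>_<end>`), the genome to
#' FASTA, and truth to JSON.
#' @param sim result of [simulate_reads()].
#' @param genome the `genome_truth` used.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(setNames(sim$reads$sequence, sim$reads$read_id),
              file.path(dir, "reads.fasta"))
  write_fasta(setNames(genome$sequence, "genome"),
              file.path(dir, "genome.fasta"))
  jsonlite::write_json(
    list(circular = genome$circular,
         repeat_intervals = genome$repeat_intervals,
         reads = sim$truth),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
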