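# Three-tier repeat masking of reads before alignment seeding:
# low-complexity (DUST-style triplet scoring), tandem repeats
# (self-alignment at bounded period) and interspersed repeats detected
# from read coverage within 1x read groups.

#' Low-complexity (DUST-style) masking of one read
#'
#' Scores each window by the triplet-composition statistic
#' `sum_t c_t (c_t - 1) / 2` divided by the number of triplets in the
#' window; windows exceeding `threshold` are masked and merged.
#'
#' @param sequence nucleotide string.
#' @param window window size in bases (default 64).
#' @param threshold per-triplet score threshold (default 2.0).
#' @return two-column matrix of half-open masked intervals.
#' @export
dust_mask <- function(sequence, window = 64, threshold = 2.0) {
  stopifnot(window >= 3, threshold > 0)
  if (nchar(sequence) < window)
    return(matrix(integer(), 0, 2, dimnames = list(NULL, c("begin", "end"))))
  normalize_intervals(cpp_dust_intervals(sequence, as.integer(window),
                                         threshold))
}

#' Tandem-repeat masking of one read
#'
#' Masks regions where the read matches itself at a positive offset of at
#' most `max_period`: exact k-mer self-matches within the period bound
#' are merged (gap allowance `max_gap`) and intervals shorter than
#' `min_span` are discarded.
#'
#' @param sequence nucleotide string.
#' @param max_period largest tandem period considered (default 500).
#' @param min_span minimum masked span (default 100).
#' @param k k-mer length of the self-matching (default 8).
#' @param max_gap merge gap in bases (default 50).
#' @return two-column matrix of half-open masked intervals.
#' @export
tandem_mask <- function(sequence, max_period = 500, min_span = 100,
                        k = 8, max_gap = 50) {
  stopifnot(max_period >= 1)
  if (nchar(sequence) < k)
    return(matrix(integer(), 0, 2, dimnames = list(NULL, c("begin", "end"))))
  normalize_intervals(cpp_tandem_intervals(sequence, as.integer(k),
                                           as.integer(max_period),
                                           as.integer(max_gap),
                                           as.integer(min_span)))
}

# apply dust+tandem to every read of a db -> interval_track
dust_tandem_tracks <- function(db, dust_window = 64, dust_threshold = 2.0,
                               tandem_period = 500, tandem_span = 100) {
  ids <- db$reads$read_id
  dust <- list(); tand <- list()
  for (i in seq_along(ids)) {
    s <- db$reads$sequence[i]
    d <- dust_mask(s, dust_window, dust_threshold)
    t <- tandem_mask(s, tandem_period, tandem_span)
    if (nrow(d)) dust[[ids[i]]] <- d
    if (nrow(t)) tand[[ids[i]]] <- t
  }
  list(dust = interval_track(dust), tandem = interval_track(tand))
}

#' Coverage-based interspersed-repeat masking
#'
#' Reads are partitioned greedily, in database order, into groups whose
#' total length is about one genome equivalent (1x read coverage). Within
#' each group all reads are aligned against all others; every position of
#' a read where at least `mask_threshold` distinct other reads align is
#' masked (multiple alignments from one partner count once). The
#' resulting mask is the union over groups.
#'
#' @param db a `read_db`.
#' @param genome_size_estimate expected genome size in bases (defines the
#'   1x group size).
#' @param mask_threshold minimum number of distinct covering reads
#'   (default 10).
#' @param seed_mask optional `interval_track` (e.g. dust+tandem union)
#'   suppressing alignment seeding within groups.
#' @param params [align_params()].
#' @return an `interval_track` of repeat intervals per read.
#' @export
coverage_repeat_mask <- function(db, genome_size_estimate,
                                 mask_threshold = 10, seed_mask = NULL,
                                 params = align_params()) {
  stopifnot(genome_size_estimate > 0, mask_threshold >= 1)
  if (nrow(db$reads) == 0) stop("empty read database")
  total <- sum(db$reads$length)
  if (genome_size_estimate > total)
    warning("genome size estimate exceeds total read length; one group")
  groups <- group_reads_1x(db$reads$length, genome_size_estimate)
  out <- list()
  for (g in groups) {
    sub <- db$reads[g, , drop = FALSE]
    gdb <- structure(list(reads = transform(sub, id = seq_along(g)),
                          tracks = list()), class = "read_db")
    gmask <- NULL
    if (!is.null(seed_mask)) {
      keep <- intersect(names(seed_mask), sub$read_id)
      gmask <- interval_track(seed_mask[keep])
    }
    aln <- all_vs_all(gdb, gmask, params)
    if (nrow(aln) == 0) next
    for (p in piles(aln)) {
      a <- p$a_id[1]
      L <- sub$length[a]
      cov <- coverage_by_distinct_partner(p, L)
      iv <- runs_at_least(cov, mask_threshold)
      if (nrow(iv)) {
        id <- sub$read_id[a]
        out[[id]] <- rbind(out[[id]], iv)
      }
    }
  }
  interval_track(out, db_lengths(db))
}

# greedy 1x grouping in database order
group_reads_1x <- function(lengths, genome_size) {
  groups <- list(); cur <- integer(); acc <- 0
  for (i in seq_along(lengths)) {
    cur <- c(cur, i); acc <- acc + lengths[i]
    if (acc >= genome_size) {
      groups[[length(groups) + 1]] <- cur
      cur <- integer(); acc <- 0
    }
  }
  if (length(cur)) {
    if (length(groups) && acc < genome_size / 2) {
      groups[[length(groups)]] <- c(groups[[length(groups)]], cur)
    } else groups[[length(groups) + 1]] <- cur
  }
  groups
}

# per-base count of distinct B-reads covering A
coverage_by_distinct_partner <- function(pile, len_a) {
  cov <- integer(len_a)
  for (b in unique(pile$b_id)) {
    sub <- pile[pile$b_id == b, , drop = FALSE]
    iv <- normalize_intervals(cbind(sub$a_begin, sub$a_end))
    for (r in seq_len(nrow(iv)))
      cov[(iv[r, 1] + 1):iv[r, 2]] <- cov[(iv[r, 1] + 1):iv[r, 2]] + 1L
  }
  cov
}

# maximal runs where cov >= threshold, as half-open intervals
runs_at_least <- function(cov, threshold) {
  hit <- cov >= threshold
  if (!any(hit)) return(matrix(integer(), 0, 2))
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  begins <- ends - r$lengths
  cbind(begins[r$values], ends[r$values])
}

#' Three-tier repeat masking of a read database
#'
#' Runs dust, tandem and coverage masking and attaches four tracks to the
#' database: `dust`, `tandem`, `coverage` and their union `repeat`.
#'
#' @param db a `read_db`.
#' @param genome_size_estimate expected genome size in bases.
#' @param mask_threshold coverage mask threshold (default 10).
#' @param params [align_params()].
#' @param dust_window,dust_threshold,tandem_period,tandem_span tier
#'   parameters.
#' @return the `read_db` with mask tracks attached.
#' @export
mask_reads <- function(db, genome_size_estimate, mask_threshold = 10,
                       params = align_params(), dust_window = 64,
                       dust_threshold = 2.0, tandem_period = 500,
                       tandem_span = 100) {
  dt <- dust_tandem_tracks(db, dust_window, dust_threshold,
                           tandem_period, tandem_span)
  lens <- db_lengths(db)
  seed_mask <- merge_track(dt$dust, dt$tandem, lens)
  cov <- coverage_repeat_mask(db, genome_size_estimate, mask_threshold,
                              seed_mask, params)
  db <- set_track(db, "dust", dt$dust)
  db <- set_track(db, "tandem", dt$tandem)
  db <- set_track(db, "coverage", cov)
  db <- set_track(db, "repeat", merge_track(seed_mask, cov, lens))
  db
}
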