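# Pairwise local alignment of reads: k-mer seeding outside masked
# intervals, diagonal-band clustering, banded extension, identity
# trimming, chaining into alignment chains, proper-chain classification
# and mask-free re-alignment of chains that end prematurely in repeats.

#' Alignment parameters
#'
#' @param k seed k-mer length.
#' @param band_width diagonal band width in bases used to cluster seeds;
#'   the banded extension uses a quarter of this as its half-band.
#' @param min_seeds minimum seeds in a diagonal band before extension.
#' @param max_divergence maximum divergence of a reported alignment
#'   (identity is `1 - diffs / max(span_a, span_b)`).
#' @param min_alignment_length minimum reported alignment span.
#' @param end_slack tolerance in bases for "reaches the read end" in
#'   chain classification and dovetail detection.
#' @param max_gap maximum per-read gap between consecutive chain members.
#' @param max_seed_gap maximum seed-to-seed gap inside one extension.
#' @param max_kmer_occ seeds from k-mers occurring more often than this
#'   are skipped.
#' @param mask_extension_limit masked bases an alignment extension may
#'   cross before it stops; short low-complexity or tandem masks are
#'   crossed, long coverage-masked repeats end the alignment (chains and
#'   mask-free re-alignment take over there).
#' @param segment_width width in bases of quality-track segments.
#' @param segment_diffs record per-segment diff counts with each
#'   alignment (needed for the quality track).
#' @return a named list of parameters.
#' @export
align_params <- function(k = 14, band_width = 256, min_seeds = 3,
                         max_divergence = 0.30, min_alignment_length = 600,
                         end_slack = 25, max_gap = 1500,
                         max_seed_gap = 1500, max_kmer_occ = 500,
                         mask_extension_limit = 500,
                         segment_width = 100, segment_diffs = FALSE) {
  stopifnot(k >= 8, k <= 28, band_width >= 16, max_divergence > 0,
            max_divergence < 1)
  list(k = as.integer(k), band_width = as.integer(band_width),
       diag_band = as.integer(band_width), min_seeds = as.integer(min_seeds),
       max_divergence = max_divergence,
       min_alignment_length = as.integer(min_alignment_length),
       end_slack = as.integer(end_slack), max_gap = as.integer(max_gap),
       max_seed_gap = as.integer(max_seed_gap),
       max_kmer_occ = as.integer(max_kmer_occ),
       mask_extension_limit = as.integer(mask_extension_limit),
       segment_width = as.integer(segment_width),
       segment_diffs = isTRUE(segment_diffs))
}

empty_alignments <- function() {
  data.frame(a_id = integer(), b_id = integer(), comp = integer(),
             a_begin = integer(), a_end = integer(),
             b_begin = integer(), b_end = integer(), diffs = integer())
}

#' Local alignment of two sequences
#'
#' Seeds are exact k-mer matches whose start lies outside the masked
#' intervals of both sequences (both strands of `b` are tried); seed
#' clusters are extended by banded edit-distance alignment and trimmed
#' to maximal segments with identity at least `1 - max_divergence`.
#' Reported `diffs` is the exact edit distance of the reported segment;
#' `b` coordinates are always on the forward strand of `b`, with
#' `comp = 1` marking complement-orientation alignments.
#'
#' @param a,b nucleotide strings.
#' @param mask_a,mask_b optional two-column matrices of half-open masked
#'   intervals (k-mer seeding is suppressed there).
#' @param params [align_params()].
#' @return data.frame of alignments (`a_id` = 1, `b_id` = 2). With
#'   `params$segment_diffs`, attribute `seg` carries per-segment diff
#'   buckets.
#' @export
local_align <- function(a, b, mask_a = NULL, mask_b = NULL,
                        params = align_params()) {
  stopifnot(params$k <= nchar(a), params$k <= nchar(b))
  empty <- matrix(integer(), 0, 2)
  r <- cpp_align_pair(a, b,
                      if (is.null(mask_a)) empty else as_cpp_mask(mask_a),
                      if (is.null(mask_b)) empty else as_cpp_mask(mask_b),
                      params)
  tab <- r$tab
  tab <- data.frame(a_id = rep(1L, nrow(tab)), b_id = rep(2L, nrow(tab)),
                    tab)
  if (params$segment_diffs) {
    tab$seg <- I(as.list(r$seg_a))
    tab$seg0 <- if (nrow(tab)) r$seg0_a else integer()
  }
  tab
}

as_cpp_mask <- function(m) {
  m <- normalize_intervals(m)
  storage.mode(m) <- "integer"
  m
}

#' All-vs-all alignment of a read database
#'
#' Every unordered read pair is attempted once through a global seed
#' index; the result contains the alignment and its mirrored counterpart
#' (A and B exchanged), so that one pile per A-read can be formed by
#' splitting on `a_id`.
#'
#' @param db a `read_db`.
#' @param mask optional `interval_track` suppressing k-mer seeding.
#' @param params [align_params()].
#' @return data.frame of alignments with columns `a_id`, `b_id`, `comp`,
#'   `a_begin`, `a_end`, `b_begin`, `b_end`, `diffs`; attribute `seg`
#'   (per-A-read segment diff buckets) when `params$segment_diffs`.
#' @export
all_vs_all <- function(db, mask = NULL, params = align_params()) {
  if (nrow(db$reads) < 2) return(empty_alignments())
  masks <- db_track_by_index(db, mask)
  masks <- lapply(masks, function(m) if (is.null(m)) NULL else as_cpp_mask(m))
  r <- cpp_all_vs_all(db$reads$sequence, masks, params)
  tab <- r$tab
  if (params$segment_diffs && nrow(tab)) {
    tab$seg <- I(as.list(r$seg_a))
    tab$seg0 <- r$seg0_a
    mirrored <- mirror_alignments(tab)
    mirrored$seg <- I(as.list(r$seg_b))
    mirrored$seg0 <- r$seg0_b
  } else {
    mirrored <- mirror_alignments(tab)
  }
  out <- rbind(tab, mirrored)
  out <- out[order(out$a_id, out$b_id, out$a_begin, out$b_begin,
                   out$comp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# unmasked alignment of one pair, both table directions, seg columns kept
pair_alignments_both <- function(i, j, seqs, params) {
  empty <- matrix(integer(), 0, 2)
  r <- cpp_align_pair(seqs[i], seqs[j], empty, empty, params)
  tab <- r$tab
  if (nrow(tab) == 0) return(NULL)
  fwd <- data.frame(a_id = rep(as.integer(i), nrow(tab)),
                    b_id = rep(as.integer(j), nrow(tab)), tab)
  bwd <- mirror_alignments(fwd)
  if (params$segment_diffs) {
    fwd$seg <- I(as.list(r$seg_a)); fwd$seg0 <- r$seg0_a
    bwd$seg <- I(as.list(r$seg_b)); bwd$seg0 <- r$seg0_b
  }
  rbind(fwd, bwd)
}

# exchange A and B roles; coordinates stay forward-strand half-open
mirror_alignments <- function(tab) {
  if (nrow(tab) == 0) return(tab)
  data.frame(a_id = tab$b_id, b_id = tab$a_id, comp = tab$comp,
             a_begin = tab$b_begin, a_end = tab$b_end,
             b_begin = tab$a_begin, b_end = tab$a_end, diffs = tab$diffs)
}

#' Split an alignment table into piles
#'
#' A pile holds all alignments sharing a fixed A-read.
#' @param alignments alignment data.frame from [all_vs_all()].
#' @return named list of data.frames keyed by `a_id`.
#' @export
piles <- function(alignments) {
  split(alignments, alignments$a_id)
}

#' Chain co-linear alignments of one read pair
#'
#' Builds maximum-coverage co-linear chains: members are strictly
#' increasing in both reads' coordinates with per-read gaps at most
#' `max_gap`; each alignment belongs to at most one chain. Ties are
#' broken by total aligned bases, then fewer diffs, then coordinates.
#'
#' @param alignments alignments of a single `(a_id, b_id, comp)` triple.
#' @param max_gap maximum per-read gap between consecutive members.
#' @param overlap_tol small coordinate overlap tolerated between
#'   consecutive members (alignment ends are ragged).
#' @return list of chains; each chain is a data.frame of its members in
#'   order, with attributes `span_a`, `span_b`, `aligned`, `diffs`.
#' @export
chain_alignments <- function(alignments, max_gap = 1500, overlap_tol = 50) {
  if (nrow(alignments) == 0) return(list())
  if (length(unique(alignments$a_id)) != 1 ||
      length(unique(alignments$b_id)) != 1 ||
      length(unique(alignments$comp)) != 1)
    stop("chain_alignments: mixed read pairs/orientations")
  comp <- alignments$comp[1] == 1
  if (nrow(alignments) == 1) { # fast path: a chain of one
    ch <- alignments
    rownames(ch) <- NULL
    attr(ch, "aligned") <- ch$a_end - ch$a_begin
    attr(ch, "diffs") <- ch$diffs
    return(list(ch))
  }
  tab <- alignments[order(alignments$a_begin, alignments$a_end), , drop = FALSE]
  # orientation-aware B progression: for complement alignments, advancing
  # along A means *decreasing* forward-strand B coordinates
  n <- nrow(tab)
  remaining <- rep(TRUE, n)
  chains <- list()
  while (any(remaining)) {
    idx <- which(remaining)
    sub <- tab[idx, , drop = FALSE]
    m <- nrow(sub)
    score <- sub$a_end - sub$a_begin + sub$b_end - sub$b_begin
    best <- score; dtot <- sub$diffs; prev <- rep(NA_integer_, m)
    for (j in seq_len(m)) {
      for (i in seq_len(j - 1)) {
        ok_a <- sub$a_begin[j] >= sub$a_end[i] - overlap_tol &&
          sub$a_begin[j] - sub$a_end[i] <= max_gap &&
          sub$a_end[j] > sub$a_end[i]
        if (!ok_a) next
        if (!comp) {
          ok_b <- sub$b_begin[j] >= sub$b_end[i] - overlap_tol &&
            sub$b_begin[j] - sub$b_end[i] <= max_gap &&
            sub$b_end[j] > sub$b_end[i]
        } else {
          ok_b <- sub$b_end[j] <= sub$b_begin[i] + overlap_tol &&
            sub$b_begin[i] - sub$b_end[j] <= max_gap &&
            sub$b_begin[j] < sub$b_begin[i]
        }
        if (!ok_b) next
        cand <- best[i] + score[j]
        cd <- dtot[i] + sub$diffs[j]
        if (cand > best[j] || (cand == best[j] && cd < dtot[j])) {
          best[j] <- cand; dtot[j] <- cd; prev[j] <- i
        }
      }
    }
    top <- which(best == max(best))
    top <- top[order(dtot[top], sub$a_begin[top])][1]
    members <- integer()
    at <- top
    while (!is.na(at)) { members <- c(at, members); at <- prev[at] }
    ch <- sub[members, , drop = FALSE]
    rownames(ch) <- NULL
    attr(ch, "aligned") <- sum(ch$a_end - ch$a_begin)
    attr(ch, "diffs") <- sum(ch$diffs)
    chains[[length(chains) + 1]] <- ch
    remaining[idx[members]] <- FALSE
  }
  # deterministic order: by chain start
  chains[order(vapply(chains, function(ch) ch$a_begin[1], 0),
               vapply(chains, function(ch) ch$b_begin[1], 0))]
}

# chain span helpers (A coordinates; B forward-strand coordinates)
chain_a_range <- function(ch) c(min(ch$a_begin), max(ch$a_end))
chain_b_range <- function(ch) c(min(ch$b_begin), max(ch$b_end))

#' Classify an alignment chain
#'
#' A chain is `proper` when each of its two ends reaches (within
#' `end_slack`) an end of read A or of read B; `premature_in_repeat`
#' when an interior chain end lies inside a repeat interval of the
#' corresponding read; otherwise `improper`.
#'
#' @param chain a chain from [chain_alignments()].
#' @param len_a,len_b read lengths.
#' @param repeat_a,repeat_b repeat interval matrices for the two reads
#'   (may be `NULL`).
#' @param end_slack tolerance in bases.
#' @return one of `"proper"`, `"premature_in_repeat"`, `"improper"`.
#' @export
classify_chain <- function(chain, len_a, len_b, repeat_a = NULL,
                           repeat_b = NULL, end_slack = 25) {
  stopifnot(nrow(chain) >= 1)
  comp <- chain$comp[1] == 1
  ar <- chain_a_range(chain); br <- chain_b_range(chain)
  # left end of the chain along A pairs with B's start (normal) or
  # B's end (complement)
  left_ok <- ar[1] <= end_slack ||
    (if (!comp) br[1] <= end_slack else br[2] >= len_b - end_slack)
  right_ok <- ar[2] >= len_a - end_slack ||
    (if (!comp) br[2] >= len_b - end_slack else br[1] <= end_slack)
  if (left_ok && right_ok) return("proper")
  in_rep <- function(ok, a_pos, b_pos) {
    if (ok) return(FALSE)
    # alignment ends are ragged; an end within end_slack of a repeat
    # interval counts as ending in it
    near <- function(m, p) {
      !is.null(m) && nrow(m) > 0 &&
        any(m[, 1] - end_slack <= p & p < m[, 2] + end_slack)
    }
    near(repeat_a, a_pos) || near(repeat_b, b_pos)
  }
  left_rep <- in_rep(left_ok, ar[1], if (!comp) br[1] else br[2] - 1L)
  right_rep <- in_rep(right_ok, ar[2] - 1L, if (!comp) br[2] - 1L else br[1])
  if ((left_ok || left_rep) && (right_ok || right_rep))
    return("premature_in_repeat")
  "improper"
}

#' Build classified chains for every (pair, orientation) of a pile
#' @param pile alignments sharing one A-read.
#' @param db the `read_db` the ids refer to.
#' @param repeat_track repeat `interval_track` (by read_id) or `NULL`.
#' @param params [align_params()].
#' @return list of chains, each with attributes `status`, `b_id`.
#' @export
pile_chains <- function(pile, db, repeat_track = NULL,
                        params = align_params()) {
  if (nrow(pile) == 0) return(list())
  rt <- if (is.null(repeat_track)) NULL else repeat_track
  lens <- db$reads$length
  ids <- db$reads$read_id
  get_rep <- function(i) {
    if (is.null(rt)) return(NULL)
    rt[[ids[i]]]
  }
  out <- list()
  for (grp in split(pile, list(pile$b_id, pile$comp), drop = TRUE)) {
    chs <- chain_alignments(grp, max_gap = params$max_gap)
    for (ch in chs) {
      a <- ch$a_id[1]; b <- ch$b_id[1]
      attr(ch, "status") <- classify_chain(
        ch, lens[a], lens[b], get_rep(a), get_rep(b),
        end_slack = params$end_slack)
      attr(ch, "b_id") <- b
      out[[length(out) + 1]] <- ch
    }
  }
  out
}

#' Re-align read pairs whose chains end prematurely in repeats
#'
#' For every read pair with at least one `premature_in_repeat` chain,
#' local alignment is recomputed without any mask and the pair's
#' alignments are replaced by the result.
#'
#' @param alignments full alignment table (both directions present).
#' @param premature_pairs two-column matrix/data.frame of (a_id, b_id)
#'   pairs to re-align (unordered; duplicates ignored).
#' @param db the `read_db`.
#' @param params [align_params()].
#' @return the updated alignment table.
#' @export
realign_unmasked <- function(alignments, premature_pairs, db,
                             params = align_params()) {
  if (is.null(premature_pairs) || nrow(premature_pairs) == 0)
    return(alignments)
  pp <- unique(data.frame(a = pmin(premature_pairs[, 1], premature_pairs[, 2]),
                          b = pmax(premature_pairs[, 1], premature_pairs[, 2])))
  keep <- !(pmin(alignments$a_id, alignments$b_id) * 1e9 +
              pmax(alignments$a_id, alignments$b_id)) %in%
    (pp$a * 1e9 + pp$b)
  out <- alignments[keep, , drop = FALSE]
  seqs <- db$reads$sequence
  news <- list(out)
  for (r in seq_len(nrow(pp))) {
    both <- pair_alignments_both(pp$a[r], pp$b[r], seqs, params)
    if (!is.null(both)) news[[length(news) + 1]] <- both
  }
  res <- do.call(rbind, news)
  res <- res[order(res$a_id, res$b_id, res$a_begin, res$b_begin, res$comp), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}
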