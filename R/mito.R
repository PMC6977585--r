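# Reference-baited circular genome assembly (mitogenome mode): read
# extraction against a circular reference, circular chain filtering,
# overlap-aware read splitting, assembly through the general pipeline,
# and circularization by self-mapping and trimming.

#' Circular chain filter parameters
#'
#' Bounds on the proper circular alignment chains used to select
#' mitochondrial reads: total aligned read length within
#' `[min_chain, max_chain]` and at most `max_unaligned` unaligned read
#' bases (tails plus internal gaps).
#'
#' @param min_chain minimum aligned read bases (default 4000).
#' @param max_chain maximum aligned read bases (default 14000).
#' @param max_unaligned maximum unaligned read bases (default 1500).
#' @return named list.
#' @export
circular_chain_filter <- function(min_chain = 4000, max_chain = 14000,
                                  max_unaligned = 1500) {
  stopifnot(min_chain > 0, min_chain <= max_chain, max_unaligned >= 0)
  list(min_chain = as.integer(min_chain), max_chain = as.integer(max_chain),
       max_unaligned = as.integer(max_unaligned))
}

#' Bait reads against a circular reference
#'
#' The reference is doubled so that alignment chains may wrap the
#' origin; chain coordinates on the reference are reported modulo the
#' reference length. Each read with at least one alignment chain to the
#' reference is returned with its chains.
#'
#' @param db a `read_db`.
#' @param reference reference nucleotide string (treated as circular).
#' @param aparams [align_params()].
#' @return list of records: `id` (read index), `read_id`, `chains`
#'   (list of chain data.frames in doubled-reference A-coordinates),
#'   `aligned` / `unaligned` read bases of the best chain.
#' @export
bait_reads <- function(db, reference, aparams = align_params()) {
  if (nrow(db$reads) == 0) return(list())
  ref2 <- paste0(reference, reference)
  L <- nchar(reference)
  out <- list()
  for (i in seq_len(nrow(db$reads))) {
    tab <- local_align(ref2, db$reads$sequence[i], params = aparams)
    if (nrow(tab) == 0) next
    tab$a_id <- 1L; tab$b_id <- 2L
    # chains over the doubled reference; wrapping chains appear as plain
    # co-linear chains crossing position L
    chains <- list()
    for (grp in split(tab, tab$comp)) {
      chains <- c(chains, chain_alignments(grp, max_gap = aparams$max_gap))
    }
    if (!length(chains)) next
    rl <- db$reads$length[i]
    per <- lapply(chains, function(ch) {
      iv <- normalize_intervals(cbind(ch$b_begin, ch$b_end))
      aligned <- sum(iv[, 2] - iv[, 1])
      list(chain = ch, aligned = aligned, unaligned = rl - aligned)
    })
    best <- per[[order(-vapply(per, function(x) x$aligned, 0))[1]]]
    out[[length(out) + 1]] <- list(
      id = i, read_id = db$reads$read_id[i],
      chains = lapply(per, function(x) x$chain),
      aligned = best$aligned, unaligned = best$unaligned)
  }
  out
}

#' Filter baited reads for proper circular alignment chains
#'
#' A read is kept when one of its chains has total aligned read length
#' within `[min_chain, max_chain]` and unaligned read bases (tails plus
#' internal gaps) at most `max_unaligned`.
#'
#' @param candidates output of [bait_reads()], or a data.frame with
#'   `aligned` and `unaligned` columns for direct testing.
#' @param params [circular_chain_filter()].
#' @return the accepted subset of `candidates`.
#' @export
filter_circular_chains <- function(candidates,
                                   params = circular_chain_filter()) {
  ok <- function(aligned, unaligned) {
    aligned >= params$min_chain && aligned <= params$max_chain &&
      unaligned <= params$max_unaligned
  }
  if (is.data.frame(candidates)) {
    keep <- mapply(ok, candidates$aligned, candidates$unaligned)
    return(candidates[keep, , drop = FALSE])
  }
  Filter(function(x) ok(x$aligned, x$unaligned), candidates)
}

#' Split a read into overlapping fragments
#'
#' Fragments start at multiples of `target_length - overlap`; every
#' fragment has length `target_length` except the last, which extends to
#' the read end and is merged into the previous fragment when shorter
#' than `overlap`. Consecutive fragments share exactly `overlap` bases.
#'
#' @param read_id,sequence the read.
#' @param target_length fragment length in bases.
#' @param overlap shared bases between consecutive fragments
#'   (default 1500).
#' @return data.frame with `read_id` and `sequence`.
#' @export
split_with_overlap <- function(read_id, sequence, target_length,
                               overlap = 1500) {
  stopifnot(overlap < target_length)
  L <- nchar(sequence)
  if (L <= target_length)
    return(data.frame(read_id = read_id, sequence = sequence))
  step <- target_length - overlap
  starts <- seq(0L, L - 1L, by = step)
  starts <- starts[starts < L]
  iv <- cbind(starts, pmin(L, starts + target_length))
  # drop start points at or beyond the read end after clipping
  iv <- iv[iv[, 1] < iv[, 2], , drop = FALSE]
  # a last fragment shorter than the overlap adds nothing: merge it
  n <- nrow(iv)
  while (n > 1 && iv[n, 2] - iv[n, 1] < overlap) {
    iv[n - 1, 2] <- iv[n, 2]
    iv <- iv[-n, , drop = FALSE]
    n <- nrow(iv)
  }
  # remove fragments fully contained in the previous one
  keep <- c(TRUE, iv[-1, 2] > iv[-nrow(iv), 2])
  iv <- iv[keep, , drop = FALSE]
  data.frame(
    read_id = paste0(read_id, ".split", seq_len(nrow(iv))),
    sequence = vapply(seq_len(nrow(iv)),
                      function(r) substr0(sequence, iv[r, 1], iv[r, 2]), ""))
}

#' Circularize a linear contig by self-mapping and trimming
#'
#' If a suffix of the contig aligns to a prefix with identity at least
#' `min_identity` over at least `min_overlap` bases, the suffix copy is
#' trimmed off and the contig flagged circular. With several conflicting
#' self-overlaps the longest is used (with a warning).
#'
#' @param sequence contig nucleotide string.
#' @param min_overlap minimum self-overlap in bases (default 500).
#' @param min_identity minimum identity of the self-overlap
#'   (default 0.95).
#' @param anchor optional sequence; when given and found, the circular
#'   contig is rotated to start at its match.
#' @param aparams [align_params()].
#' @return list: `sequence`, `circular`, `trimmed` (bases removed).
#' @export
circularize <- function(sequence, min_overlap = 500, min_identity = 0.95,
                        anchor = NULL, aparams = align_params()) {
  L <- nchar(sequence)
  ap <- aparams
  ap$min_alignment_length <- as.integer(min_overlap)
  ap$max_divergence <- min(ap$max_divergence, 1 - min_identity + 0.05)
  tab <- local_align(sequence, sequence, params = ap)
  slack <- ap$end_slack
  cand <- tab[tab$comp == 0 & tab$a_begin > tab$b_begin &
                tab$a_end >= L - slack & tab$b_begin <= slack, , drop = FALSE]
  if (nrow(cand)) {
    ident <- 1 - cand$diffs / pmax(cand$a_end - cand$a_begin,
                                   cand$b_end - cand$b_begin)
    cand <- cand[ident >= min_identity &
                   pmax(cand$a_end - cand$a_begin,
                        cand$b_end - cand$b_begin) >= min_overlap, ,
                 drop = FALSE]
  }
  if (nrow(cand) == 0) {
    return(list(sequence = sequence, circular = FALSE, trimmed = 0L))
  }
  if (nrow(cand) > 1) {
    warning("multiple self-overlaps; keeping the longest")
    cand <- cand[order(-(cand$a_end - cand$a_begin)), , drop = FALSE]
  }
  # the circular period: position a_begin re-reads position b_begin
  cut <- cand$a_begin[1] - cand$b_begin[1]
  out <- substr0(sequence, 0, cut)
  if (!is.null(anchor)) out <- rotate_to_anchor(out, anchor)
  list(sequence = out, circular = TRUE, trimmed = L - cut)
}

# rotate a circular sequence so that it starts at the anchor match
rotate_to_anchor <- function(sequence, anchor) {
  hit <- regexpr(anchor, paste0(sequence, sequence), fixed = TRUE)
  if (hit < 0) return(sequence)
  p <- (as.integer(hit) - 1L) %% nchar(sequence)
  paste0(substr0(sequence, p, nchar(sequence)), substr0(sequence, 0, p))
}

#' Reference-baited circular genome assembly
#'
#' Extracts reads matching a circular reference, filters them for proper
#' circular chains, patches them, splits them into overlapping
#' fragments, assembles, and circularizes the resulting contig.
#'
#' @param db a `read_db` of all reads.
#' @param reference circular reference nucleotide string.
#' @param filter [circular_chain_filter()].
#' @param target_length split fragment length; default half the
#'   reference length.
#' @param split_overlap shared bases between fragments (default 1500).
#' @param aparams [align_params()].
#' @param pparams [patch_params()].
#' @param lparams [layout_params()].
#' @return list: `contig` (sequence/circular/length), `n_baited`,
#'   `n_kept`, `assembly` (the underlying [assemble()] result).
#' @export
assemble_mito <- function(db, reference,
                          filter = circular_chain_filter(),
                          target_length = NULL, split_overlap = 1500,
                          aparams = align_params(),
                          pparams = patch_params(),
                          lparams = layout_params()) {
  if (is.null(target_length))
    target_length <- max(split_overlap * 2L,
                         as.integer(nchar(reference) / 2))
  baited <- bait_reads(db, reference, aparams)
  kept <- filter_circular_chains(baited, filter)
  if (length(kept) == 0) {
    return(list(contig = NULL, n_baited = length(baited), n_kept = 0L,
                assembly = NULL))
  }
  ids <- vapply(kept, function(x) x$id, 0)
  sub <- db$reads[ids, , drop = FALSE]
  mdb <- build_db(data.frame(read_id = sub$read_id, zmw = sub$read_id,
                             sequence = sub$sequence),
                  min_length = min(filter$min_chain, pparams$min_length))
  # patch the baited reads before splitting
  aln <- all_vs_all(mdb, NULL, aparams)
  pr <- patch_reads(mdb, aln, NULL,
                    within_list(pparams, min_length = 1000L), aparams)
  pdb <- pr$db
  # split with overlap so the circular contig consists of >1 read
  pieces <- do.call(rbind, lapply(seq_len(nrow(pdb$reads)), function(i) {
    split_with_overlap(pdb$reads$read_id[i], pdb$reads$sequence[i],
                       target_length, split_overlap)
  }))
  sdb <- build_db(data.frame(read_id = pieces$read_id, zmw = pieces$read_id,
                             sequence = pieces$sequence),
                  min_length = min(1000L, target_length %/% 2L))
  saln <- all_vs_all(sdb, NULL, aparams)
  asm <- assemble(sdb, saln, NULL, NULL, lparams, aparams)
  if (nrow(asm$contigs) == 0) {
    return(list(contig = NULL, n_baited = length(baited),
                n_kept = length(kept), assembly = asm))
  }
  main <- asm$contigs[order(-asm$contigs$length), ][1, ]
  circ <- circularize(main$sequence, aparams = aparams)
  if (!circ$circular && isTRUE(main$circular)) circ$circular <- TRUE
  list(contig = list(sequence = circ$sequence, circular = circ$circular,
                     length = nchar(circ$sequence)),
       n_baited = length(baited), n_kept = length(kept), assembly = asm)
}

# shallow list update helper
within_list <- function(x, ...) {
  up <- list(...)
  x[names(up)] <- up
  x
}
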