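# Read patching: detection and correction of read artefacts from
# alignment piles — chimeric junctions, missed-adapter fold-backs,
# polymerase strand jumps and long low-quality segments — plus the
# spanning-chain rule that excludes reads whose repeat regions cannot be
# certified contiguous by enough proper chains.

#' Patching parameters
#'
#' @param span_slack half-width in bases of the window an alignment must
#'   cover to count as spanning a position.
#' @param min_flank_support minimum alignments ending on each side of a
#'   candidate break.
#' @param min_patch_length minimum length of a low-quality patch.
#' @param min_length fragments shorter than this are discarded after
#'   splitting.
#' @param max_repeat_length repeat intervals longer than this are not
#'   re-analysed by the spanning-chain rule (default 8000).
#' @param min_spanning_chains proper chains required to span a repeat
#'   interval (default 3).
#' @param span_flank bases a spanning chain must extend beyond the repeat
#'   interval on each side (default 500).
#' @return named list.
#' @export
patch_params <- function(span_slack = 100, min_flank_support = 3,
                         min_patch_length = 400, min_length = 4000,
                         max_repeat_length = 8000, min_spanning_chains = 3,
                         span_flank = 500) {
  stopifnot(max_repeat_length > 0, min_spanning_chains > 0)
  list(span_slack = as.integer(span_slack),
       min_flank_support = as.integer(min_flank_support),
       min_patch_length = as.integer(min_patch_length),
       min_length = as.integer(min_length),
       max_repeat_length = as.integer(max_repeat_length),
       min_spanning_chains = as.integer(min_spanning_chains),
       span_flank = as.integer(span_flank))
}

#' Detect read artefacts from one alignment pile
#'
#' A chimera break is called at interior positions that no alignment
#' spans (window `span_slack` on both sides, clipped at read ends) while
#' at least `min_flank_support` alignments end on each side. If several
#' partner reads align in opposite orientations on the two sides the
#' break is reclassified: coinciding forward-strand partner intervals are
#' the fold-back signature of a missed adapter; otherwise a strand jump.
#' Low-quality segments are interior intervals of length at least
#' `min_patch_length` that no alignment spans but at least
#' `min_flank_support` partner chains bridge with an internal gap; the
#' replacement is taken from the best-supported partner, polished by the
#' other bridging partners.
#'
#' @param pile alignments sharing one A-read (from [piles()]).
#' @param db the `read_db`.
#' @param repeat_track repeat `interval_track` (breaks inside repeats are
#'   left to the spanning-chain rule) or `NULL`.
#' @param params [patch_params()].
#' @param align_params [align_params()] (chain construction).
#' @return data.frame of patch events: `read_id`, `kind`, `begin`, `end`,
#'   `replacement` (NA except for `low_quality_patch`).
#' @export
detect_artefacts <- function(pile, db, repeat_track = NULL,
                             params = patch_params(),
                             align_params = olca::align_params()) {
  empty <- data.frame(read_id = character(), kind = character(),
                      begin = integer(), end = integer(),
                      replacement = character())
  if (is.null(pile) || nrow(pile) == 0) return(empty)
  a <- pile$a_id[1]
  L <- db$reads$length[a]
  id <- db$reads$read_id[a]
  slack <- params$span_slack
  rep_iv <- if (is.null(repeat_track)) NULL else repeat_track[[id]]

  # spanning count per position (event-based, at breakpoint resolution)
  spans <- function(p) {
    lo <- max(0L, p - slack); hi <- min(L, p + slack)
    sum(pile$a_begin <= lo & pile$a_end >= hi)
  }
  # candidate breakpoints: scan zero-span runs via alignment end events
  cov <- integer(L)
  for (r in seq_len(nrow(pile))) {
    lo <- pile$a_begin[r] + slack; hi <- pile$a_end[r] - slack
    if (hi > lo) {
      lo2 <- if (pile$a_begin[r] <= 0) 1L else lo + 1L
      hi2 <- if (pile$a_end[r] >= L) L else hi
      if (hi2 >= lo2) cov[lo2:hi2] <- cov[lo2:hi2] + 1L
    }
  }
  # interior zero-span runs
  zero <- runs_at_least(-cov, 0)  # cov == 0 runs
  zero <- zero[zero[, 1] > 0 & zero[, 2] < L, , drop = FALSE]

  chains <- pile_chains(pile, db, repeat_track, align_params)
  events <- list()

  for (z in seq_len(nrow(zero))) {
    b <- zero[z, 1]; e <- zero[z, 2]
    mid <- as.integer((b + e) / 2)
    if (e - b > 4 * slack + params$min_patch_length) next # handled as low-q
    if (!is.null(rep_iv) && intervals_overlap_bases(rep_iv, b, e) > 0) next
    left <- sum(pile$a_end >= b - slack & pile$a_end <= e + slack)
    right <- sum(pile$a_begin >= b - slack & pile$a_begin <= e + slack)
    if (left < params$min_flank_support || right < params$min_flank_support)
      next
    # orientation signature: partners with chains ending left and
    # (opposite orientation) starting right of the break
    lft <- pile[pile$a_end >= b - slack & pile$a_end <= e + slack, ]
    rgt <- pile[pile$a_begin >= b - slack & pile$a_begin <= e + slack, ]
    common <- intersect(lft$b_id, rgt$b_id)
    fold <- 0L; jump <- 0L
    for (bb in common) {
      lo_ <- lft[lft$b_id == bb, ]; ro_ <- rgt[rgt$b_id == bb, ]
      for (i1 in seq_len(nrow(lo_))) for (i2 in seq_len(nrow(ro_))) {
        if (lo_$comp[i1] == ro_$comp[i2]) next
        ovl <- min(lo_$b_end[i1], ro_$b_end[i2]) -
          max(lo_$b_begin[i1], ro_$b_begin[i2])
        shorter <- min(lo_$b_end[i1] - lo_$b_begin[i1],
                       ro_$b_end[i2] - ro_$b_begin[i2])
        if (ovl > 0.5 * shorter) fold <- fold + 1L else jump <- jump + 1L
      }
    }
    kind <- if (fold >= 2) "adapter_break"
            else if (jump >= 2) "strand_jump_break"
            else "chimera_break"
    events[[length(events) + 1]] <- data.frame(
      read_id = id, kind = kind, begin = mid, end = mid,
      replacement = NA_character_)
  }

  # low-quality segments: bridged by partner chains with an internal gap
  gaps <- list()
  for (ch in chains) {
    if (nrow(ch) < 2) next
    for (i in seq_len(nrow(ch) - 1)) {
      gb <- ch$a_end[i]; ge <- ch$a_begin[i + 1]
      if (ge - gb >= params$min_patch_length)
        gaps[[length(gaps) + 1]] <- list(b = gb, e = ge, ch = ch, i = i)
    }
  }
  if (length(gaps) >= params$min_flank_support) {
    used <- rep(FALSE, length(gaps))
    for (gi in seq_along(gaps)) {
      if (used[gi]) next
      g <- gaps[[gi]]
      support <- which(vapply(gaps, function(h) {
        min(h$e, g$e) - max(h$b, g$b) > 0.5 * (g$e - g$b)
      }, TRUE))
      if (length(support) < params$min_flank_support) next
      used[support] <- TRUE
      # the common low-quality core
      core_b <- max(vapply(gaps[support], function(h) h$b, 0))
      core_e <- min(vapply(gaps[support], function(h) h$e, 0))
      if (core_e - core_b < params$min_patch_length) next
      if (max(cov[(core_b + 1):core_e]) > 0) next  # actually spanned
      repl <- best_gap_replacement(gaps[support], db, core_b, core_e)
      if (is.null(repl)) next
      events[[length(events) + 1]] <- data.frame(
        read_id = id, kind = "low_quality_patch",
        begin = core_b, end = core_e, replacement = repl)
    }
  }
  if (!length(events)) return(empty)
  ev <- do.call(rbind, events)
  ev <- ev[order(ev$begin, ev$end), , drop = FALSE]
  # drop overlapping events (priority: adapter > strand jump > chimera >
  # low quality; then input order)
  pri <- match(ev$kind, c("adapter_break", "strand_jump_break",
                          "chimera_break", "low_quality_patch"))
  keep <- rep(TRUE, nrow(ev))
  for (i in seq_len(nrow(ev))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(ev))) {
      if (i == j || !keep[j]) next
      if (ev$begin[j] <= ev$end[i] + 50 && ev$end[j] >= ev$begin[i] - 50) {
        if (pri[j] > pri[i] || (pri[j] == pri[i] && j > i)) keep[j] <- FALSE
      }
    }
  }
  ev <- ev[keep, , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

# replacement sequence for a low-quality gap: the bridging partner chain
# with the smallest divergence donates its segment between the two chain
# members; the other bridging partners polish it by majority.
best_gap_replacement <- function(gaps, db, core_b, core_e) {
  seg_of <- function(g) {
    ch <- g$ch; i <- g$i
    comp <- ch$comp[1] == 1
    b_id <- ch$b_id[1]
    bseq <- db$reads$sequence[b_id]
    if (!comp) {
      gb <- ch$b_end[i]; ge <- ch$b_begin[i + 1]
    } else {
      gb <- ch$b_end[i + 1]; ge <- ch$b_begin[i]
    }
    if (ge <= gb) return(NULL)
    # trim the donor segment to the core interval proportionally
    lead <- core_b - g$b; trail <- g$e - core_e
    s <- substr0(bseq, gb, ge)
    if (comp) s <- revcomp(s)
    n <- nchar(s)
    b2 <- min(n, max(0, lead)); e2 <- max(b2, n - max(0, trail))
    if (e2 - b2 < 1) return(NULL)
    substr0(s, b2, e2)
  }
  div <- vapply(gaps, function(g) {
    attr(g$ch, "diffs") / max(1, attr(g$ch, "aligned"))
  }, 0)
  segs <- lapply(gaps[order(div)], seg_of)
  segs <- Filter(Negate(is.null), segs)
  if (!length(segs)) return(NULL)
  if (length(segs) >= 3) {
    polished <- cpp_polish(segs[[1]], unlist(segs[-1]),
                           align_params(min_alignment_length = 50,
                                        min_seeds = 2))
    polished$seq
  } else segs[[1]]
}

#' Spanning-chain rule for chimeric junctions hidden in repeats
#'
#' For every repeat interval on the read not longer than
#' `max_repeat_length`, counts the proper chains whose A-span covers the
#' interval with at least `span_flank` bases on each side (clipped at
#' read ends). If any such interval is spanned by fewer than
#' `min_spanning_chains` chains the read is excluded.
#'
#' @param read_id read identifier (for reporting).
#' @param chains this read's classified A-chains ([pile_chains()]).
#' @param repeat_intervals two-column matrix of repeat intervals on the
#'   read.
#' @param read_length read length.
#' @param params [patch_params()].
#' @return `"keep"` or `"exclude"`.
#' @export
apply_chimera_repeat_rule <- function(read_id, chains, repeat_intervals,
                                      read_length,
                                      params = patch_params()) {
  if (is.null(repeat_intervals) || nrow(repeat_intervals) == 0)
    return("keep")
  proper <- Filter(function(ch) identical(attr(ch, "status"), "proper"),
                   chains)
  for (r in seq_len(nrow(repeat_intervals))) {
    ib <- repeat_intervals[r, 1]; ie <- repeat_intervals[r, 2]
    if (ie - ib > params$max_repeat_length) next
    need_b <- max(0L, ib - params$span_flank)
    need_e <- min(read_length, ie + params$span_flank)
    n_span <- sum(vapply(proper, function(ch) {
      ar <- chain_a_range(ch)
      ar[1] <= need_b && ar[2] >= need_e
    }, TRUE))
    if (n_span < params$min_spanning_chains) return("exclude")
  }
  "keep"
}

#' Apply patch events to a read
#'
#' Breaks split the read into fragments; `low_quality_patch` intervals
#' are replaced by their replacement sequence. Fragments shorter than
#' `min_length` are discarded. Emitted reads are renamed
#' `<read_id>.part<i>` when the read is split.
#'
#' @param read_id,sequence the read.
#' @param events data.frame from [detect_artefacts()] (this read's rows).
#' @param min_length minimum emitted fragment length.
#' @return data.frame with `read_id` and `sequence` (possibly 0 rows).
#' @export
apply_patches <- function(read_id, sequence, events, min_length = 4000) {
  L <- nchar(sequence)
  if (is.null(events) || nrow(events) == 0) {
    return(data.frame(read_id = read_id, sequence = sequence))
  }
  ev <- events[order(events$begin, events$end), , drop = FALSE]
  if (any(ev$begin < 0 | ev$end > L | ev$begin > ev$end))
    stop("patch event out of read bounds for ", read_id)
  if (nrow(ev) > 1 && any(ev$begin[-1] < ev$end[-nrow(ev)]))
    stop("overlapping patch events for ", read_id)
  # build the patched sequence piece-wise, breaking at break events
  frags <- character(); cur <- ""
  at <- 0L
  for (i in seq_len(nrow(ev))) {
    cur <- paste0(cur, substr0(sequence, at, ev$begin[i]))
    if (ev$kind[i] == "low_quality_patch") {
      cur <- paste0(cur, ev$replacement[i])
    } else {
      frags <- c(frags, cur); cur <- ""
    }
    at <- ev$end[i]
  }
  cur <- paste0(cur, substr0(sequence, at, L))
  frags <- c(frags, cur)
  frags <- frags[nchar(frags) >= min_length]
  if (length(frags) == 0)
    return(data.frame(read_id = character(), sequence = character()))
  nm <- if (length(frags) == 1 && nrow(ev[ev$kind != "low_quality_patch", ,
                                          drop = FALSE]) == 0) read_id
        else paste0(read_id, ".part", seq_along(frags))
  data.frame(read_id = nm, sequence = frags)
}

#' Patch a whole read database
#'
#' Runs [detect_artefacts()] on every pile, applies the events, rebuilds
#' the database from the patched reads (keeping ZMW identities), and
#' optionally applies the spanning-chain chimera rule afterwards (on
#' chains recomputed from patched-read alignments by the caller).
#'
#' @param db a `read_db`.
#' @param alignments alignment table over `db` from [all_vs_all()].
#' @param repeat_track repeat `interval_track` or `NULL`.
#' @param params [patch_params()].
#' @param align_params [align_params()].
#' @return list: `db` (patched `read_db`), `events` (all patch events).
#' @export
patch_reads <- function(db, alignments, repeat_track = NULL,
                        params = patch_params(),
                        align_params = olca::align_params()) {
  pl <- piles(alignments)
  all_events <- list()
  out <- list()
  for (i in seq_len(nrow(db$reads))) {
    p <- pl[[as.character(i)]]
    ev <- detect_artefacts(p, db, repeat_track, params, align_params)
    if (nrow(ev)) all_events[[length(all_events) + 1]] <- ev
    out[[i]] <- apply_patches(db$reads$read_id[i], db$reads$sequence[i],
                              ev, params$min_length)
    if (nrow(out[[i]])) out[[i]]$zmw <- db$reads$zmw[i]
  }
  patched <- do.call(rbind, out)
  events <- if (length(all_events)) do.call(rbind, all_events) else
    data.frame(read_id = character(), kind = character(),
               begin = integer(), end = integer(),
               replacement = character())
  # patched fragments of one ZMW are distinct reads; keep them all by
  # giving each fragment its own ZMW label
  patched$zmw <- paste0(patched$zmw, "#", stats::ave(
    seq_len(nrow(patched)), patched$zmw, FUN = seq_along))
  newdb <- build_db(patched, min_length = params$min_length)
  list(db = newdb, events = events)
}

#' Write patch events as a tab-separated report
#' @param events data.frame from [patch_reads()].
#' @param path output file.
#' @export
write_patch_report <- function(events, path) {
  utils::write.table(events[, c("read_id", "kind", "begin", "end")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
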