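# Assembly phase: quality track, pile filtering to dovetail edges,
# string-graph construction with transitive reduction, touring to
# primary contigs, column-majority consensus and contiguity statistics.

#' Layout parameters
#'
#' @param end_slack dovetail/containment end tolerance in bases.
#' @param fuzz length tolerance when removing transitively implied edges.
#' @param segment_width quality-track segment width in bases.
#' @param min_quality_cov partners required before a segment's divergence
#'   is estimated (below it the segment holds the sentinel `NA`).
#' @return named list.
#' @export
layout_params <- function(end_slack = 25, fuzz = 200, segment_width = 100,
                          min_quality_cov = 2) {
  list(end_slack = as.integer(end_slack), fuzz = as.integer(fuzz),
       segment_width = as.integer(segment_width),
       min_quality_cov = as.integer(min_quality_cov))
}

#' Quality track of one read from its pile
#'
#' Per fixed-width segment of the read, the mean alignment divergence
#' over partners covering the segment; `NA` (sentinel) where fewer than
#' `min_cov` partners cover it. Requires alignments computed with
#' `segment_diffs = TRUE` so that divergence is localized.
#'
#' @param pile alignments of one A-read carrying `seg`/`seg0` columns.
#' @param read_length length of the A-read.
#' @param segment segment width in bases.
#' @param min_cov sentinel threshold (default 2).
#' @return numeric vector of per-segment divergences (NA = sentinel).
#' @export
quality_track <- function(pile, read_length, segment = 100, min_cov = 2) {
  nseg <- ceiling(read_length / segment)
  dsum <- numeric(nseg); dcov <- integer(nseg)
  if (!is.null(pile) && nrow(pile) > 0) {
    stopifnot(!is.null(pile$seg))
    for (r in seq_len(nrow(pile))) {
      sg <- pile$seg[[r]]
      if (!length(sg)) next
      first <- pile$seg0[r] + 1L          # 1-based segment index
      last <- min(nseg, first + length(sg) - 1L)
      if (last < first) next
      take <- seq_len(last - first + 1L)
      # per-segment divergence of this alignment: diffs per aligned base
      b0 <- pmax(pile$a_begin[r], (first + take - 2L) * segment)
      b1 <- pmin(pile$a_end[r], (first + take - 1L) * segment)
      w <- pmax(1L, b1 - b0)
      dsum[first:last] <- dsum[first:last] + sg[take] / w
      dcov[first:last] <- dcov[first:last] + as.integer(b1 > b0)
    }
  }
  out <- ifelse(dcov >= min_cov, dsum / pmax(1L, dcov), NA_real_)
  out
}

#' Quality tracks for every read of a database
#' @param db a `read_db`.
#' @param alignments alignment table with `seg`/`seg0` columns.
#' @param segment segment width in bases.
#' @param min_cov sentinel threshold.
#' @return named list of per-read divergence vectors (NA = sentinel).
#' @export
quality_tracks <- function(db, alignments, segment = 100, min_cov = 2) {
  pl <- piles(alignments)
  out <- lapply(seq_len(nrow(db$reads)), function(i) {
    quality_track(pl[[as.character(i)]], db$reads$length[i], segment,
                  min_cov)
  })
  names(out) <- db$reads$read_id
  out
}

#' Filter overlap piles into dovetail edges and containments
#'
#' Keeps only proper dovetail chains; drops alignments lying entirely
#' within repeat intervals on both reads; records contained reads (fully
#' covered by a partner within `end_slack`) separately.
#'
#' @param alignments alignment table over patched reads.
#' @param db the patched `read_db`.
#' @param repeat_track repeat `interval_track` or `NULL`.
#' @param quality optional list of per-read quality tracks
#'   ([quality_tracks()]); carried for inspection — the filtering
#'   decisions themselves rest on chain classification and the repeat
#'   track, because patching has already removed low-quality segments.
#' @param params [layout_params()].
#' @param aparams [align_params()].
#' @return list: `edges` (data.frame of dovetail overlaps: a_id, b_id,
#'   comp, a_end_side, overlap length, diffs and coordinates),
#'   `contained` (integer ids), `chains` (the proper chains used).
#' @export
filter_piles <- function(alignments, db, repeat_track = NULL,
                         quality = NULL,
                         params = layout_params(),
                         aparams = align_params()) {
  slack <- params$end_slack
  lens <- db$reads$length
  ids <- db$reads$read_id
  # drop repeat-only alignments
  if (!is.null(repeat_track) && nrow(alignments)) {
    drop <- logical(nrow(alignments))
    for (r in seq_len(nrow(alignments))) {
      ra <- repeat_track[[ids[alignments$a_id[r]]]]
      rb <- repeat_track[[ids[alignments$b_id[r]]]]
      ina <- intervals_overlap_bases(ra, alignments$a_begin[r],
                                     alignments$a_end[r]) >=
        (alignments$a_end[r] - alignments$a_begin[r])
      inb <- intervals_overlap_bases(rb, alignments$b_begin[r],
                                     alignments$b_end[r]) >=
        (alignments$b_end[r] - alignments$b_begin[r])
      drop[r] <- ina && inb
    }
    alignments <- alignments[!drop, , drop = FALSE]
  }
  contained <- logical(nrow(db$reads))
  edges <- list(); kept_chains <- list()
  for (p in piles(alignments)) {
    a <- p$a_id[1]
    chs <- pile_chains(p, db, repeat_track, aparams)
    for (ch in chs) {
      if (!identical(attr(ch, "status"), "proper")) next
      b <- ch$b_id[1]
      ar <- chain_a_range(ch); br <- chain_b_range(ch)
      a_left <- ar[1] <= slack; a_right <- ar[2] >= lens[a] - slack
      b_left <- br[1] <= slack; b_right <- br[2] >= lens[b] - slack
      if (a_left && a_right) { contained[a] <- TRUE; next }
      if (b_left && b_right) next # partner contained; recorded in its pile
      kept_chains[[length(kept_chains) + 1]] <- ch
      # dovetail: which end of A does the overlap leave?
      side_a <- if (a_right) "right" else "left"
      edges[[length(edges) + 1]] <- data.frame(
        a_id = a, b_id = b, comp = ch$comp[1],
        a_side = side_a,
        a_begin = ar[1], a_end = ar[2], b_begin = br[1], b_end = br[2],
        overlap = attr(ch, "aligned"), diffs = attr(ch, "diffs"))
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(a_id = integer(), b_id = integer(), comp = integer(),
               a_side = character(), a_begin = integer(), a_end = integer(),
               b_begin = integer(), b_end = integer(), overlap = integer(),
               diffs = integer())
  # edges from or to contained reads are not graph edges
  if (nrow(edges)) {
    keep <- !(contained[edges$a_id] | contained[edges$b_id])
    edges <- edges[keep, , drop = FALSE]
  }
  rownames(edges) <- NULL
  list(edges = edges, contained = which(contained), chains = kept_chains)
}

# ---------------------------------------------------------- string graph

# Directed string graph on read orientations: node `+r` is read r read
# left-to-right, `-r` reversed. A dovetail overlap leaving A's right end
# induces A(+) -> B(+/-) and the symmetric B' -> A' edge. Edge length is
# the overhang (bases of the target read beyond the overlap).
#' Build the directed string graph from dovetail edges
#' @param edges data.frame from [filter_piles()].
#' @param db the patched `read_db`.
#' @return data.frame of directed edges: `from`, `to` (signed read ids),
#'   `length` (overhang), `overlap`, `diffs`.
#' @export
string_graph <- function(edges, db) {
  lens <- db$reads$length
  out <- list()
  for (r in seq_len(nrow(edges))) {
    a <- edges$a_id[r]; b <- edges$b_id[r]
    comp <- edges$comp[r] == 1
    right <- edges$a_side[r] == "right"
    ovl_a <- edges$a_end[r] - edges$a_begin[r]
    ovl_b <- edges$b_end[r] - edges$b_begin[r]
    # orientation of B in the walk continuing out of A's right end:
    # normal overlap at A-right meets B-left (B forward); complement
    # overlap at A-right meets B-right (B reversed); symmetric at A-left
    from <- if (right) +a else -a
    to <- if (right == !comp) +b else -b
    out[[length(out) + 1]] <- data.frame(
      from = from, to = to, length = lens[b] - ovl_b,
      overlap = edges$overlap[r], diffs = edges$diffs[r])
    # reverse-complement twin: -to -> -from, overhang on the A side
    out[[length(out) + 1]] <- data.frame(
      from = -to, to = -from, length = lens[a] - ovl_a,
      overlap = edges$overlap[r], diffs = edges$diffs[r])
  }
  g <- if (length(out)) do.call(rbind, out) else
    data.frame(from = integer(), to = integer(), length = integer(),
               overlap = integer(), diffs = integer())
  if (nrow(g)) {
    bad <- g$length < 0
    if (any(bad)) {
      warning(sum(bad), " inconsistent overlap edges dropped")
      g <- g[!bad, , drop = FALSE]
    }
    g <- g[order(g$from, g$to, -g$overlap, g$length), , drop = FALSE]
    g <- g[!duplicated(paste(g$from, g$to)), , drop = FALSE]
    rownames(g) <- NULL
  }
  g
}

#' Transitive reduction of a string graph
#'
#' Removes every edge whose overlap is implied by a two-edge path with
#' consistent lengths (within `fuzz`); pairwise reachability between
#' read orientations is preserved.
#'
#' @param graph data.frame from [string_graph()].
#' @param fuzz length tolerance in bases (default 200).
#' @return the reduced edge data.frame.
#' @export
transitive_reduction <- function(graph, fuzz = 200) {
  if (nrow(graph) < 3) return(graph)
  g <- graph[order(graph$from, graph$length), , drop = FALSE]
  adj <- split(seq_len(nrow(g)), g$from)
  drop <- logical(nrow(g))
  for (v in names(adj)) {
    out_e <- adj[[v]]
    if (length(out_e) < 2) next
    # Myers-style marking: for each neighbour w (shortest first), check
    # whether a longer edge v->x is implied by w->x
    lens_v <- g$length[out_e]
    targets <- g$to[out_e]
    for (ei in seq_along(out_e)) {
      w <- targets[ei]
      lw <- lens_v[ei]
      if (drop[out_e[ei]]) next
      mid <- adj[[as.character(w)]]
      if (is.null(mid)) next
      for (mj in mid) {
        x <- g$to[mj]
        lx <- lw + g$length[mj]
        hit <- which(targets == x & abs(lens_v - lx) <= fuzz &
                       seq_along(out_e) != ei)
        if (length(hit)) drop[out_e[hit]] <- TRUE
      }
    }
  }
  out <- g[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tour the reduced graph into primary contig paths
#'
#' Maximal unbranched paths are traversed from tips and junctions; at a
#' branch the extension with the most aligned bases (then fewer diffs,
#' then smaller read index) wins and the others start new paths. A path
#' returning to its start is flagged circular. Each read is used at most
#' once.
#'
#' @param graph reduced edge data.frame.
#' @param db the patched `read_db`.
#' @return list of paths; each a list with `reads` (signed ids) and
#'   `circular` flag.
#' @export
tour <- function(graph, db) {
  n <- nrow(db$reads)
  if (n == 0) return(list())
  used <- logical(n)
  paths <- list()
  nodes <- if (nrow(graph)) sort(unique(c(graph$from, graph$to))) else integer()
  pick_next <- function(v) {
    cand <- graph[graph$from == v, , drop = FALSE]
    cand <- cand[!used[abs(cand$to)], , drop = FALSE]
    if (nrow(cand) == 0) return(NULL)
    cand[order(-cand$overlap, cand$diffs, abs(cand$to)), ][1, ]
  }
  # walk from every unused node, preferring true tips (no predecessor)
  if (length(nodes)) {
    has_pred <- function(v) any(graph$from == -v)
    ord <- nodes[order(vapply(nodes, has_pred, TRUE), abs(nodes),
                       -sign(nodes))]
    for (v in ord) {
      if (used[abs(v)]) next
      path <- c(v); used[abs(v)] <- TRUE
      circular <- FALSE
      at <- v
      repeat {
        nx <- pick_next(at)
        if (is.null(nx)) {
          # does the walk close a cycle back to the start?
          closing <- graph[graph$from == at & graph$to == path[1], ,
                           drop = FALSE]
          if (nrow(closing) && length(path) > 2) circular <- TRUE
          break
        }
        path <- c(path, nx$to)
        used[abs(nx$to)] <- TRUE
        at <- nx$to
      }
      # extend backwards from the start (unless circular)
      if (!circular) {
        at <- -path[1]
        back <- integer()
        repeat {
          nx <- pick_next(at)
          if (is.null(nx)) break
          back <- c(back, nx$to)
          used[abs(nx$to)] <- TRUE
          at <- nx$to
        }
        if (length(back)) path <- c(-rev(back), path)
      }
      paths[[length(paths) + 1]] <- list(reads = path, circular = circular)
    }
  }
  # singleton reads (no graph presence) become single-read paths
  for (r in which(!used)) {
    paths[[length(paths) + 1]] <- list(reads = r, circular = FALSE)
    used[r] <- TRUE
  }
  paths
}

#' Consensus sequence of a toured path
#'
#' The backbone concatenates the path's reads (oriented), trimmed at the
#' edge overlaps; every database read is then aligned to the backbone and
#' each column corrected to the majority base (including deletions and
#' between-column insertions). Deterministic.
#'
#' @param path one path from [tour()].
#' @param db the patched `read_db`.
#' @param graph the reduced edge data.frame (for overlap trims).
#' @param polish_reads character vector of reads to polish with (default:
#'   all database reads).
#' @param aparams [align_params()].
#' @return list: `sequence`, `circular`, `path`.
#' @export
consensus <- function(path, db, graph, polish_reads = db$reads$sequence,
                      aparams = align_params()) {
  stopifnot(length(path$reads) >= 1)
  seqs <- db$reads$sequence
  lens <- db$reads$length
  oriented <- function(v) {
    s <- seqs[abs(v)]
    if (v < 0) revcomp(s) else s
  }
  backbone <- oriented(path$reads[1])
  if (length(path$reads) > 1) {
    for (i in 2:length(path$reads)) {
      v_prev <- path$reads[i - 1]; v <- path$reads[i]
      e <- graph[graph$from == v_prev & graph$to == v, , drop = FALSE]
      overhang <- if (nrow(e)) e$length[1] else lens[abs(v)]
      s <- oriented(v)
      if (overhang > 0)
        backbone <- paste0(backbone,
                           substr0(s, nchar(s) - overhang, nchar(s)))
    }
  }
  polished <- cpp_polish(backbone, polish_reads, aparams)
  list(sequence = polished$seq, circular = isTRUE(path$circular),
       path = path$reads)
}

#' Contiguity statistics and the N(x) curve
#'
#' `n_curve(x)` is the length of the smallest contig needed, taking
#' contigs longest first, to reach x percent of the total assembly
#' length; N50 is the curve at x = 50.
#'
#' @param lengths integer vector of contig lengths.
#' @return list: `contig_count`, `total_length`, `n50`, `n_curve`
#'   (named numeric vector over x = 0..100).
#' @export
assembly_stats <- function(lengths) {
  lengths <- sort(as.numeric(lengths), decreasing = TRUE)
  xs <- 0:100
  if (length(lengths) == 0 || sum(lengths) == 0) {
    return(list(contig_count = 0L, total_length = 0,
                n50 = 0, n_curve = setNames(rep(0, 101), xs)))
  }
  total <- sum(lengths)
  cum <- cumsum(lengths)
  curve <- vapply(xs, function(x) {
    if (x == 0) return(lengths[1])
    lengths[which(cum >= total * x / 100)[1]]
  }, 0)
  list(contig_count = length(lengths), total_length = total,
       n50 = curve[51], n_curve = setNames(curve, xs))
}

#' Assemble a patched read database into contigs
#'
#' Runs pile filtering, string-graph construction, transitive reduction,
#' touring and consensus.
#'
#' @param db patched `read_db`.
#' @param alignments alignment table over `db`.
#' @param repeat_track repeat `interval_track` or `NULL`.
#' @param quality optional per-read quality tracks ([quality_tracks()]).
#' @param params [layout_params()].
#' @param aparams [align_params()].
#' @param min_contig_reads paths with fewer reads than this and no
#'   alignment support are dropped from the output (singletons default
#'   to dropped when they are contained elsewhere).
#' @return list: `contigs` (data.frame contig_id, length, circular,
#'   n_reads, sequence), `graph` (reduced edges), `stats`.
#' @export
assemble <- function(db, alignments, repeat_track = NULL, quality = NULL,
                     params = layout_params(), aparams = align_params(),
                     min_contig_reads = 2) {
  fp <- filter_piles(alignments, db, repeat_track, quality, params, aparams)
  g <- string_graph(fp$edges, db)
  g <- transitive_reduction(g, params$fuzz)
  pths <- tour(g, db)
  # singleton paths are reported only when nothing was assembled at all:
  # at usable coverage an unplaced read is contained, repeat-only or junk
  multi <- Filter(function(p) length(p$reads) >= min_contig_reads, pths)
  if (length(multi)) pths <- multi
  contigs <- list()
  for (p in pths) {
    cs <- consensus(p, db, g, aparams = aparams)
    contigs[[length(contigs) + 1]] <- data.frame(
      contig_id = sprintf("contig_%d", length(contigs) + 1),
      length = nchar(cs$sequence), circular = cs$circular,
      n_reads = length(p$reads), sequence = cs$sequence)
  }
  contigs <- if (length(contigs)) do.call(rbind, contigs) else
    data.frame(contig_id = character(), length = integer(),
               circular = logical(), n_reads = integer(),
               sequence = character())
  list(contigs = contigs, graph = g, reduced_graph = g,
       filtered = fp, stats = assembly_stats(contigs$length))
}
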