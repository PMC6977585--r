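# Shared fixture builders. Everything is generated in code under fixed
# seeds; no stored data files.

rand_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a subread table straight from sequences
subread_df <- function(seqs, ids = sprintf("read%02d", seq_along(seqs)),
                       zmw = ids) {
  data.frame(read_id = ids, zmw = zmw,
             subread_index = 1L, sequence = seqs,
             stringsAsFactors = FALSE)
}

# brute-force Levenshtein via base R (the independent oracle)
oracle_edit <- function(a, b) as.integer(utils::adist(a, b))

# brute-force DUST score of every window; returns masked positions
oracle_dust_positions <- function(seq, window, threshold) {
  s <- strsplit(seq, "")[[1]]
  n <- length(s)
  masked <- logical(n)
  if (n < window) return(masked)
  for (w0 in 0:(n - window)) {
    tri <- sapply(1:(window - 2), function(i) {
      paste(s[w0 + i + 0:2], collapse = "")
    })
    tri <- tri[!grepl("N", tri)]
    cnt <- table(tri)
    score <- sum(cnt * (cnt - 1) / 2) / length(tri)
    if (score > threshold) masked[(w0 + 1):(w0 + window)] <- TRUE
  }
  masked
}

# exhaustive maximum-coverage co-linear chain over <= 10 alignments
oracle_best_chain <- function(tab, max_gap = 1500, overlap_tol = 50) {
  comp <- tab$comp[1] == 1
  n <- nrow(tab)
  best <- 0
  ok_pair <- function(i, j) {
    ok_a <- tab$a_begin[j] >= tab$a_end[i] - overlap_tol &&
      tab$a_begin[j] - tab$a_end[i] <= max_gap && tab$a_end[j] > tab$a_end[i]
    if (!ok_a) return(FALSE)
    if (!comp) {
      tab$b_begin[j] >= tab$b_end[i] - overlap_tol &&
        tab$b_begin[j] - tab$b_end[i] <= max_gap &&
        tab$b_end[j] > tab$b_end[i]
    } else {
      tab$b_end[j] <= tab$b_begin[i] + overlap_tol &&
        tab$b_begin[i] - tab$b_end[j] <= max_gap &&
        tab$b_begin[j] < tab$b_begin[i]
    }
  }
  for (size in 1:n) {
    for (sub in utils::combn(n, size, simplify = FALSE)) {
      o <- sub[order(tab$a_begin[sub])]
      valid <- TRUE
      if (length(o) > 1)
        for (t in 1:(length(o) - 1))
          if (!ok_pair(o[t], o[t + 1])) { valid <- FALSE; break }
      if (valid) {
        sc <- sum(tab$a_end[o] - tab$a_begin[o] +
                    tab$b_end[o] - tab$b_begin[o])
        if (sc > best) best <- sc
      }
    }
  }
  best
}

# brute-force reachability closure of a signed-node edge list
oracle_reachable <- function(graph) {
  nodes <- sort(unique(c(graph$from, graph$to)))
  idx <- function(v) match(v, nodes)
  n <- length(nodes)
  R <- matrix(FALSE, n, n)
  for (r in seq_len(nrow(graph))) R[idx(graph$from[r]), idx(graph$to[r])] <- TRUE
  for (k in seq_len(n)) for (i in seq_len(n)) if (R[i, k])
    R[i, ] <- R[i, ] | R[k, ]
  dimnames(R) <- list(nodes, nodes)
  R
}

# random consistent overlap graph: reads placed on a line, edges from
# true dovetail overlaps
random_overlap_graph <- function(n_reads, seed) {
  set.seed(seed)
  starts <- sort(sample.int(5000, n_reads))
  lens <- sample(800:2500, n_reads, replace = TRUE)
  ends <- starts + lens
  edges <- list()
  for (i in seq_len(n_reads - 1)) {
    for (j in (i + 1):n_reads) {
      ovl <- min(ends[i], ends[j]) - max(starts[i], starts[j])
      contained <- (starts[j] >= starts[i] && ends[j] <= ends[i]) ||
        (starts[i] >= starts[j] && ends[i] <= ends[j])
      if (ovl > 50 && !contained) {
        # i left of j: edge +i -> +j and twin -j -> -i
        edges[[length(edges) + 1]] <- data.frame(
          from = i, to = j, length = ends[j] - ends[i],
          overlap = ovl, diffs = 0L)
        edges[[length(edges) + 1]] <- data.frame(
          from = -j, to = -i, length = starts[j] - starts[i],
          overlap = ovl, diffs = 0L)
      }
    }
  }
  if (!length(edges)) return(NULL)
  do.call(rbind, edges)
}

# map a contig back to the truth genome and test for chimeric structure:
# the contig must align to the (doubled, both-strand) truth in one piece
contig_is_chimeric <- function(contig, genome_seq, aparams = align_params()) {
  targets <- c(genome_seq, revcomp(genome_seq))
  for (tg in targets) {
    tab <- local_align(tg, contig, params = aparams)
    tab <- tab[tab$comp == 0, , drop = FALSE]
    if (nrow(tab) == 0) next
    cov <- sum(tab$b_end - tab$b_begin)
    span_ok <- any((tab$b_end - tab$b_begin) > 0.9 * nchar(contig))
    if (span_ok) return(FALSE)
    # piecewise co-linear cover also counts as non-chimeric
    tab <- tab[order(tab$b_begin), , drop = FALSE]
    if (nrow(tab) >= 2) {
      colinear <- all(diff(tab$a_begin) > 0) &&
        cov > 0.9 * nchar(contig) &&
        all(abs((tab$a_begin[-1] - tab$a_end[-nrow(tab)]) -
                  (tab$b_begin[-1] - tab$b_end[-nrow(tab)])) < 2000)
      if (colinear) return(FALSE)
    }
  }
  TRUE
}
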