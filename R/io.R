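# Standard-format writers: PAF for alignments, GFA 1 for the assembly
# graph. BED and FASTA writers live next to their data types.

#' Write alignments as PAF
#'
#' Standard 12 columns; diffs go in the `NM:i:` tag and only the
#' non-mirrored direction (`a_id < b_id`) is emitted.
#'
#' @param alignments alignment table.
#' @param db the `read_db` the ids refer to.
#' @param path output file.
#' @export
write_paf <- function(alignments, db, path) {
  tab <- alignments[alignments$a_id < alignments$b_id, , drop = FALSE]
  ids <- db$reads$read_id
  lens <- db$reads$length
  if (nrow(tab) == 0) {
    file.create(path)
    return(invisible(path))
  }
  span <- pmax(tab$a_end - tab$a_begin, tab$b_end - tab$b_begin)
  lines <- sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t255\tNM:i:%d",
                   ids[tab$a_id], lens[tab$a_id], tab$a_begin, tab$a_end,
                   ifelse(tab$comp == 1, "-", "+"),
                   ids[tab$b_id], lens[tab$b_id], tab$b_begin, tab$b_end,
                   span - tab$diffs, span, tab$diffs)
  writeLines(lines, path)
  invisible(path)
}

#' Write the assembly graph as GFA 1
#'
#' S lines carry the reads used in the graph, L lines the dovetail
#' overlaps (overlap as a CIGAR match length); contig paths are emitted
#' as P lines.
#'
#' @param graph reduced edge data.frame from [assemble()].
#' @param db the patched `read_db`.
#' @param contigs contig data.frame (optional, adds P lines).
#' @param path output file.
#' @export
write_gfa <- function(graph, db, contigs = NULL, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("H\tVN:Z:1.0", con)
  ids <- db$reads$read_id
  used <- if (!is.null(graph) && nrow(graph))
    sort(unique(abs(c(graph$from, graph$to)))) else integer()
  for (i in used) {
    writeLines(sprintf("S\t%s\t%s\tLN:i:%d", ids[i],
                       db$reads$sequence[i], db$reads$length[i]), con)
  }
  if (!is.null(graph) && nrow(graph)) {
    for (r in seq_len(nrow(graph))) {
      f <- graph$from[r]; t <- graph$to[r]
      ovl <- max(0L, db$reads$length[abs(t)] - graph$length[r])
      writeLines(sprintf("L\t%s\t%s\t%s\t%s\t%dM",
                         ids[abs(f)], if (f > 0) "+" else "-",
                         ids[abs(t)], if (t > 0) "+" else "-", ovl), con)
    }
  }
  if (!is.null(contigs) && nrow(contigs)) {
    for (r in seq_len(nrow(contigs))) {
      writeLines(sprintf("P\t%s\t*\t*", contigs$contig_id[r]), con)
    }
  }
  invisible(path)
}
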