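# Read database set-up: FASTA/FASTQ parsing, ZMW grouping,
# longest-subread selection and the minimum-length filter.

#' Read sequences from FASTA or FASTQ
#'
#' Qualities in FASTQ input are ignored. Headers in PacBio style
#' (`movie/zmw/start_end`) are parsed into ZMW identities; any other
#' header is treated as a singleton ZMW.
#'
#' @param path input file; format guessed from the first character.
#' @return data.frame with `read_id`, `zmw`, `subread_index`, `sequence`.
#' @export
read_seqs <- function(path) {
  first <- readChar(path, 1)
  fmt <- if (identical(first, "@")) "fastq" else "fasta"
  ss <- Biostrings::readDNAStringSet(path, format = fmt)
  ids <- sub("\\s.*$", "", names(ss))
  subreads(ids, as.character(ss))
}

# build the subread table from ids + sequences
subreads <- function(ids, sequences) {
  m <- regmatches(ids, regexec("^(.+)/(\\d+)/(\\d+)_(\\d+)$", ids))
  zmw <- character(length(ids)); idx <- integer(length(ids))
  for (i in seq_along(ids)) {
    if (length(m[[i]]) == 5) {
      zmw[i] <- paste0(m[[i]][2], "/", m[[i]][3])
      idx[i] <- 1L
    } else {
      zmw[i] <- ids[i]
      idx[i] <- 1L
    }
  }
  # subread index: order of appearance within a ZMW
  idx <- stats::ave(seq_along(ids), zmw, FUN = seq_along)
  data.frame(read_id = ids, zmw = zmw, subread_index = as.integer(idx),
             sequence = toupper(sequences), stringsAsFactors = FALSE)
}

#' Build the read database
#'
#' For each ZMW only the longest subread is considered; reads shorter
#' than `min_length` are then dropped. Stable integer indices are
#' assigned in input order.
#'
#' @param subreads data.frame with `read_id`, `zmw`, `sequence` (and
#'   optionally `subread_index`), e.g. from [read_seqs()] or
#'   [simulate_reads()].
#' @param min_length minimum read length in bases (default 4000).
#' @return a `read_db` object: data.frame `reads` (id, read_id, zmw,
#'   length, sequence) plus a `tracks` environment for interval tracks.
#' @export
build_db <- function(subreads, min_length = 4000) {
  if (is.null(subreads) || nrow(subreads) == 0) {
    return(new_read_db(data.frame(read_id = character(), zmw = character(),
                                  sequence = character())))
  }
  if (anyDuplicated(subreads$read_id))
    stop("duplicate read_id in input: ",
         subreads$read_id[duplicated(subreads$read_id)][1])
  bad <- grepl("[^ACGTN]", subreads$sequence)
  if (any(bad)) stop("sequence alphabet must be A/C/G/T/N (read ",
                     subreads$read_id[bad][1], ")")
  len <- nchar(subreads$sequence)
  keep <- rep(FALSE, nrow(subreads))
  for (z in split(seq_len(nrow(subreads)), subreads$zmw)) {
    keep[z[which.max(len[z])]] <- TRUE
  }
  sel <- subreads[keep & len >= min_length, , drop = FALSE]
  sel <- sel[order(match(sel$read_id, subreads$read_id)), , drop = FALSE]
  db <- new_read_db(sel)
  message(sprintf("read_db: %d reads, %.0f bases (from %d subreads)",
                  nrow(db$reads), sum(db$reads$length), nrow(subreads)))
  db
}

new_read_db <- function(sel) {
  reads <- data.frame(id = seq_len(nrow(sel)),
                      read_id = sel$read_id,
                      zmw = if ("zmw" %in% names(sel)) sel$zmw else sel$read_id,
                      length = nchar(sel$sequence),
                      sequence = sel$sequence,
                      stringsAsFactors = FALSE)
  rownames(reads) <- NULL
  structure(list(reads = reads, tracks = list()), class = "read_db")
}

#' @export
print.read_db <- function(x, ...) {
  cat("read_db:", nrow(x$reads), "reads,", sum(x$reads$length), "bases; tracks:",
      if (length(x$tracks)) paste(names(x$tracks), collapse = ", ") else "none",
      "\n")
  invisible(x)
}

# named lengths helper
db_lengths <- function(db) setNames(db$reads$length, db$reads$read_id)

# fetch a track as per-id (integer index) list of matrices; absent -> empty
db_track_by_index <- function(db, track) {
  if (is.character(track)) track <- db$tracks[[track]]
  out <- vector("list", nrow(db$reads))
  if (!is.null(track)) {
    hit <- match(names(track), db$reads$read_id)
    for (i in seq_along(track)) if (!is.na(hit[i])) out[[hit[i]]] <- track[[i]]
  }
  out
}

#' Attach an interval track to a read database
#' @param db a `read_db`.
#' @param name track name (e.g. `"dust"`, `"repeat"`).
#' @param track an `interval_track`.
#' @return the modified `read_db`.
#' @export
set_track <- function(db, name, track) {
  db$tracks[[name]] <- track
  db
}

#' Write sequences as FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @param width line width.
#' @export
write_fasta <- function(seqs, path, width = 80) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}
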