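# Per-read interval tracks: the carrier for every mask, patch and quality
# annotation. A track is a named list (one element per read id) of
# two-column integer matrices holding sorted, merged, half-open 0-based
# intervals. Normalization goes through IRanges.

#' Create an interval track
#'
#' @param intervals named list; each element a two-column matrix (or
#'   data.frame) of 0-based half-open `(begin, end)` intervals for one
#'   read. Intervals are sorted and overlapping/adjacent ones merged.
#' @param read_lengths optional named integer vector used to validate
#'   interval bounds.
#' @return an object of class `interval_track`.
#' @export
interval_track <- function(intervals = list(), read_lengths = NULL) {
  out <- lapply(names(intervals), function(id) {
    m <- intervals[[id]]
    m <- normalize_intervals(m)
    if (!is.null(read_lengths) && id %in% names(read_lengths)) {
      L <- read_lengths[[id]]
      if (nrow(m) && (min(m[, 1]) < 0 || max(m[, 2]) > L))
        stop("interval out of read bounds for read ", id)
    }
    m
  })
  names(out) <- names(intervals)
  structure(out, class = "interval_track")
}

#' @export
print.interval_track <- function(x, ...) {
  n <- sum(vapply(x, nrow, 0L))
  cat("interval_track:", length(x), "reads,", n, "intervals,",
      sum(vapply(x, function(m) sum(m[, 2] - m[, 1]), 0)), "bases\n")
  invisible(x)
}

# sort + merge overlapping/adjacent half-open intervals
normalize_intervals <- function(m) {
  m <- as.matrix(m)
  if (is.null(dim(m)) || nrow(m) == 0)
    return(matrix(integer(), 0, 2, dimnames = list(NULL, c("begin", "end"))))
  storage.mode(m) <- "integer"
  if (any(m[, 1] >= m[, 2])) stop("empty or inverted interval")
  if (any(m[, 1] < 0)) stop("negative interval begin")
  ir <- IRanges::reduce(IRanges::IRanges(start = m[, 1] + 1L, end = m[, 2]))
  cbind(begin = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

#' Union of two interval tracks
#'
#' Per-read interval union, normalized (sorted, merged). Reads present in
#' only one track keep their intervals.
#'
#' @param track_a,track_b `interval_track` objects over the same read set.
#' @param read_lengths optional named lengths; out-of-bounds intervals are
#'   rejected.
#' @return an `interval_track`.
#' @export
merge_track <- function(track_a, track_b, read_lengths = NULL) {
  ids <- union(names(track_a), names(track_b))
  out <- lapply(ids, function(id) {
    rbind(if (id %in% names(track_a)) track_a[[id]],
          if (id %in% names(track_b)) track_b[[id]])
  })
  names(out) <- ids
  interval_track(out, read_lengths)
}

# total masked bases per read (named vector)
track_bases <- function(track) {
  vapply(track, function(m) sum(m[, 2] - m[, 1]), 0)
}

# does any interval of `m` contain position p (half-open)?
point_in_intervals <- function(m, p) {
  if (is.null(m) || nrow(m) == 0) return(FALSE)
  any(m[, 1] <= p & p < m[, 2])
}

# intersect intervals of `m` with [b, e); returns total overlapping bases
intervals_overlap_bases <- function(m, b, e) {
  if (is.null(m) || nrow(m) == 0) return(0L)
  sum(pmax(0L, pmin(m[, 2], e) - pmax(m[, 1], b)))
}

#' Write an interval track as BED
#'
#' Read names go in the chromosome column; coordinates are 0-based
#' half-open, matching BED.
#' @param track an `interval_track`.
#' @param path output file.
#' @param name optional feature name written in column 4.
#' @export
write_track_bed <- function(track, path, name = "mask") {
  rows <- lapply(names(track), function(id) {
    m <- track[[id]]
    if (nrow(m) == 0) return(NULL)
    data.frame(chrom = id, start = m[, 1], end = m[, 2], name = name)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- data.frame(chrom = character(), start = integer(),
                                    end = integer(), name = character())
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file into an interval track
#' @param path BED file with read names in column 1.
#' @return an `interval_track`.
#' @export
read_track_bed <- function(path) {
  if (!file.exists(path) || file.size(path) == 0) return(interval_track())
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  df <- stats::setNames(df[, 1:3], c("chrom", "start", "end"))
  sp <- split(df[, 2:3], df$chrom)
  interval_track(lapply(sp, as.matrix))
}
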