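#' Coverage track container
#'
#' A `coverage_track` holds per-chromosome base-resolution signal as a
#' run-length-encoded [S4Vectors::RleList], together with a strand label
#' and the total signal of the track (the sum of value x span over the
#' source intervals), which downstream functions use for per-million
#' library scaling. Positions beyond the last encoded run are zero signal;
#' positions beyond a known chromosome length (when `seqlengths` is
#' supplied) are off-genome and treated as missing in metaplots.
#'
#' @param cov an [S4Vectors::RleList] (or coercible list of `Rle`) of
#'   non-negative per-base signal, one element per chromosome.
#' @param strand one of `"+"`, `"-"`, `"*"` (unstranded).
#' @param seqlengths optional named integer vector of chromosome lengths.
#' @return an object of class `coverage_track` with elements `cov`,
#'   `strand`, `total_signal`, `seqlengths`.
#' @examples
#' tr <- coverage_track(list(chr1 = S4Vectors::Rle(c(0, 2, 2, 0))), "+")
#' tr$total_signal
#' @export
coverage_track <- function(cov, strand = c("*", "+", "-"), seqlengths = NULL) {
  strand <- match.arg(strand)
  if (!is(cov, "RleList")) cov <- methods::as(cov, "RleList")
  vals <- unlist(lapply(cov, runValue), use.names = FALSE)
  .assert(length(vals) == 0 || all(vals >= 0),
          "coverage values must be non-negative")
  total <- sum(vapply(cov, function(r) sum(as.numeric(runValue(r)) * runLength(r)),
                      numeric(1)))
  structure(
    list(cov = cov, strand = strand, total_signal = total,
         seqlengths = seqlengths),
    class = "coverage_track"
  )
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> strand=%s  chromosomes=%d  total_signal=%g\n",
              x$strand, length(x$cov), x$total_signal))
  invisible(x)
}

#' Is an object a coverage track?
#' @param x object to test.
#' @return logical scalar.
#' @export
is_coverage_track <- function(x) inherits(x, "coverage_track")

# Sum of signal over each window, clipping windows that run off the
# encoded region (off-chromosome-start positions contribute nothing;
# a warning is raised when clipping occurs).
#' @noRd
.window_sums <- function(track, windows) {
  .assert(is_coverage_track(track), "`track` must be a coverage_track")
  .assert(all(width(windows) > 0), "zero-length window")
  out <- numeric(length(windows))
  clipped <- FALSE
  chroms <- as.character(seqnames(windows))
  for (ch in unique(chroms)) {
    idx <- which(chroms == ch)
    if (!ch %in% names(track$cov)) {
      clipped <- TRUE
      next
    }
    r <- track$cov[[ch]]
    len <- length(r)
    s <- pmax(start(windows)[idx], 1L)
    e <- pmin(end(windows)[idx], len)
    if (any(start(windows)[idx] < 1L)) clipped <- TRUE
    ok <- s <= e
    if (any(ok)) {
      v <- Views(r, start = s[ok], end = e[ok])
      out[idx[ok]] <- viewSums(v)
    }
  }
  if (clipped) warning("one or more windows extended past the covered region; clipped")
  out
}

#' Mean signal density over genomic windows
#'
#' Density is signal per base pair per million units of total library
#' signal: `(sum over window / window width) * 1e6 / library_total`.
#'
#' @param track a [coverage_track].
#' @param windows a [GenomicRanges::GRanges] of windows.
#' @param library_total total library signal used for per-million scaling;
#'   defaults to the track's own `total_signal`. For a stranded pair of
#'   tracks pass the summed total of both strands.
#' @return numeric vector of densities, one per window.
#' @examples
#' tr <- coverage_track(list(chr1 = S4Vectors::Rle(rep(2, 100))), "*")
#' w <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))
#' window_density(tr, w, library_total = 1e6)  # 2.0
#' @export
window_density <- function(track, windows, library_total = NULL) {
  if (is.null(library_total)) library_total <- track$total_signal
  .assert(is.numeric(library_total) && library_total > 0,
          "`library_total` must be > 0")
  sums <- .window_sums(track, windows)
  (sums / width(windows)) * (1e6 / library_total)
}
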