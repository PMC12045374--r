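#' TSS anchor points for a gene annotation
#'
#' @param genes gene `GRanges` with `gene_id`.
#' @return width-1 `GRanges` at each TSS, keeping gene strand and ids.
#' @export
tss_anchors <- function(genes) {
  tss <- gene_tss(genes)
  out <- GRanges(seqnames(genes), IRanges(tss, tss), strand = strand(genes))
  mcols(out)$name <- genes$gene_id
  out
}

# Per-base values of one window on an Rle, padding with NA off the
# chromosome (position < 1 or beyond a known seqlength) and with 0
# beyond the encoded runs but inside the chromosome.
#' @noRd
.window_values <- function(rle, s, e, seqlen) {
  w <- e - s + 1L
  vals <- rep(NA_real_, w)
  hi <- if (is.na(seqlen)) e else min(e, seqlen)
  lo <- max(s, 1L)
  if (lo > hi) return(vals)
  inside <- rep(0, hi - lo + 1L)
  rl <- length(rle)
  if (lo <= rl) {
    seg_hi <- min(hi, rl)
    inside[seq_len(seg_hi - lo + 1L)] <-
      as.numeric(S4Vectors::window(rle, lo, seg_hi))
  }
  vals[(lo - s + 1L):(hi - s + 1L)] <- inside
  vals
}

#' Signal matrix around anchor points
#'
#' Builds a rows x bins matrix of mean per-base signal in windows
#' `[-upstream, +downstream)` around each anchor, oriented 5' to 3':
#' rows for minus-strand anchors are flipped so column 1 is always the
#' upstream-most bin. Signal is library-normalized to per-bp-per-million
#' by default. Window parts off the chromosome edge are missing values
#' (`NA`), excluded from downstream column means.
#'
#' @param track a [coverage_track].
#' @param anchors width-1 `GRanges` of anchor positions (strand used for
#'   orientation; `*` treated as `+`). See [tss_anchors()].
#' @param upstream,downstream window extent in bp (default 100 / 2000).
#' @param bin bin width in bp; must divide `upstream + downstream`
#'   (default 10).
#' @param normalize multiply by `1e6 / total_signal` (default `TRUE`).
#' @return object of class `meta_matrix`: list with `values` (matrix),
#'   `row_ids`, `offsets` (bin start offsets relative to the anchor, bp),
#'   `bin`, `upstream`, `downstream`.
#' @export
matrix_at_anchors <- function(track, anchors, upstream = 100L,
                              downstream = 2000L, bin = 10L,
                              normalize = TRUE) {
  .assert(is_coverage_track(track), "`track` must be a coverage_track")
  .assert(length(anchors) > 0, "no anchors supplied")
  .assert(all(width(anchors) == 1L), "`anchors` must be width-1 positions")
  span <- upstream + downstream
  .assert(span > 0 && span %% bin == 0,
          "(upstream + downstream) must be a positive multiple of `bin`")
  chroms <- as.character(seqnames(anchors))
  .assert(any(chroms %in% names(track$cov)),
          "no anchors on chromosomes present in the track")
  pos <- start(anchors)
  minus <- as.character(strand(anchors)) == "-"
  M <- matrix(NA_real_, nrow = length(anchors), ncol = span)
  for (i in seq_along(anchors)) {
    ch <- chroms[i]
    if (!ch %in% names(track$cov)) next
    seqlen <- if (!is.null(track$seqlengths) && ch %in% names(track$seqlengths))
      track$seqlengths[[ch]] else NA_integer_
    if (!minus[i]) {
      v <- .window_values(track$cov[[ch]], pos[i] - upstream,
                          pos[i] + downstream - 1L, seqlen)
    } else {
      v <- rev(.window_values(track$cov[[ch]], pos[i] - downstream + 1L,
                              pos[i] + upstream, seqlen))
    }
    M[i, ] <- v
  }
  if (normalize) {
    .assert(track$total_signal > 0, "cannot normalize a zero-signal track")
    M <- M * (1e6 / track$total_signal)
  }
  nbins <- span %/% bin
  B <- matrix(NA_real_, nrow = nrow(M), ncol = nbins)
  for (j in seq_len(nbins)) {
    cols <- ((j - 1L) * bin + 1L):(j * bin)
    # partial edge bins average their in-genome bases; fully off-genome
    # bins stay missing
    bj <- rowMeans(M[, cols, drop = FALSE], na.rm = TRUE)
    bj[is.nan(bj)] <- NA_real_
    B[, j] <- bj
  }
  ids <- if (!is.null(anchors$name)) as.character(anchors$name)
         else sprintf("anchor_%d", seq_along(anchors))
  structure(list(values = B, row_ids = ids,
                 offsets = seq(-upstream, downstream - 1L, by = bin),
                 bin = bin, upstream = upstream, downstream = downstream),
            class = "meta_matrix")
}

#' @export
print.meta_matrix <- function(x, ...) {
  cat(sprintf("<meta_matrix> %d rows x %d bins (bin = %d bp, window %+d..%+d)\n",
              nrow(x$values), ncol(x$values), x$bin, -x$upstream, x$downstream))
  invisible(x)
}

#' Average profile of a metaplot matrix with a bootstrap band
#'
#' Column means ignore missing values; the confidence band comes from
#' resampling matrix rows with replacement under a fixed seed.
#'
#' @param m a [matrix_at_anchors()] result.
#' @param B number of bootstrap resamples (default 1000).
#' @param conf confidence level of the band (default 0.95).
#' @param seed RNG seed for the bootstrap (default 1).
#' @return data.frame with columns `offset`, `mean`, `lower`, `upper`.
#' @export
meta_profile <- function(m, B = 1000L, conf = 0.95, seed = 1L) {
  .assert(inherits(m, "meta_matrix"), "`m` must be a meta_matrix")
  .assert(nrow(m$values) > 0, "empty matrix")
  mu <- colMeans(m$values, na.rm = TRUE)
  n <- nrow(m$values)
  if (n == 1L || B < 2L) {
    lower <- upper <- mu
  } else {
    qs <- .with_seed(seed, {
      boot <- matrix(NA_real_, nrow = B, ncol = ncol(m$values))
      for (b in seq_len(B)) {
        idx <- sample.int(n, n, replace = TRUE)
        boot[b, ] <- colMeans(m$values[idx, , drop = FALSE], na.rm = TRUE)
      }
      apply(boot, 2, stats::quantile,
            probs = c((1 - conf) / 2, 1 - (1 - conf) / 2), na.rm = TRUE)
    })
    lower <- qs[1, ]; upper <- qs[2, ]
  }
  data.frame(offset = m$offsets, mean = mu, lower = lower, upper = upper)
}

#' Signal matrix centered on peak midpoints
#'
#' Unstranded symmetric window `[-flank, +flank)` around each peak
#' midpoint; otherwise identical to [matrix_at_anchors()].
#'
#' @param track a [coverage_track].
#' @param peaks non-empty peak `GRanges`.
#' @param flank half-window in bp (default 2000).
#' @param bin bin width in bp (default 10).
#' @param normalize library-normalize (default `TRUE`).
#' @return a `meta_matrix`.
#' @export
centered_matrix <- function(track, peaks, flank = 2000L, bin = 10L,
                            normalize = TRUE) {
  .assert(length(peaks) > 0, "empty peak set")
  mid <- floor((start(peaks) + end(peaks)) / 2)
  anchors <- GRanges(seqnames(peaks), IRanges(mid, mid), strand = "*")
  mcols(anchors)$name <- if (!is.null(peaks$name)) peaks$name
    else sprintf("peak_%d", seq_along(peaks))
  matrix_at_anchors(track, anchors, upstream = flank, downstream = flank,
                    bin = bin, normalize = normalize)
}

#' Write a metaplot matrix (and profile) as TSV
#'
#' @param m a `meta_matrix`.
#' @param path output TSV path (row ids in the first column, one column
#'   per bin labelled by its start offset).
#' @param sort_rows if `TRUE`, rows sorted by decreasing total signal,
#'   the usual heatmap ordering.
#' @return invisibly, `path`.
#' @export
write_meta_matrix <- function(m, path, sort_rows = FALSE) {
  vals <- m$values
  ids <- m$row_ids
  if (sort_rows) {
    o <- order(rowSums(vals, na.rm = TRUE), decreasing = TRUE)
    vals <- vals[o, , drop = FALSE]; ids <- ids[o]
  }
  df <- data.frame(row_id = ids, vals, check.names = FALSE)
  colnames(df) <- c("row_id", sprintf("%d", m$offsets))
  .write_tsv(df, path)
}

#' Plot a metaplot profile
#'
#' Line plot of the mean profile with its bootstrap band. Requires
#' ggplot2.
#'
#' @param profile a [meta_profile()] data.frame (optionally with a
#'   `group` column to draw several profiles).
#' @return a ggplot object.
#' @export
plot_meta_profile <- function(profile) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  p <- ggplot2::ggplot(profile, ggplot2::aes(x = offset, y = mean))
  if ("group" %in% names(profile)) {
    p <- p +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = lower, ymax = upper,
                                        fill = group), alpha = 0.2) +
      ggplot2::geom_line(ggplot2::aes(color = group))
  } else {
    p <- p +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = lower, ymax = upper),
                           alpha = 0.2) +
      ggplot2::geom_line()
  }
  p + ggplot2::labs(x = "offset from anchor (bp)",
                    y = "signal (per bp per million)")
}
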