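# Brute-force oracles and small fixture builders. The oracles are
# deliberately naive (per-base masks, pooled-point suprema, exhaustive
# enumeration) and share no code with the implementation they check.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

gr1 <- function(starts, ends, strand = "*", chrom = "chr1", ...) {
  g <- GRanges(chrom, IRanges(starts, ends), strand = strand)
  extra <- list(...)
  for (nm in names(extra)) mcols(g)[[nm]] <- extra[[nm]]
  g
}

# coverage_track from a plain numeric vector of per-base signal
track_from_vector <- function(v, strand = "*", chrom = "chr1", seqlen = NULL) {
  cov <- setNames(list(S4Vectors::Rle(v)), chrom)
  coverage_track(cov, strand,
                 seqlengths = if (is.null(seqlen)) NULL else setNames(seqlen, chrom))
}

# per-base boolean mask (length L) -> GRanges of maximal runs
mask_to_granges <- function(mask, chrom = "chr1") {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  if (!any(keep)) return(GRanges())
  GRanges(chrom, IRanges(starts[keep], ends[keep]))
}

granges_to_mask <- function(gr, L) {
  mask <- logical(L)
  for (i in seq_along(gr)) mask[start(gr)[i]:min(end(gr)[i], L)] <- TRUE
  mask
}

# Per-base occupancy oracle for any_bp consensus with union extent:
# bases covered by >= min_sets reduced sets seed the region, then any
# peak touching the region donates its bases, to a fixpoint.
oracle_consensus <- function(sets, min_sets, fdr_max, L) {
  filt <- lapply(sets, function(s) if (!is.null(s$fdr)) s[s$fdr <= fdr_max] else s)
  occ <- integer(L)
  for (s in filt) occ <- occ + granges_to_mask(reduce(granges(s)), L)
  mask <- occ >= min_sets
  pool <- do.call(c, lapply(filt, granges))
  repeat {
    changed <- FALSE
    for (i in seq_along(pool)) {
      idx <- start(pool)[i]:min(end(pool)[i], L)
      if (any(mask[idx]) && !all(mask[idx])) {
        mask[idx] <- TRUE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  mask_to_granges(mask)
}

oracle_intersect_strict <- function(a, b, L) {
  mask_to_granges(granges_to_mask(reduce(granges(a)), L) &
                  granges_to_mask(reduce(granges(b)), L))
}

# K-S D as the supremum of |ECDF_a - ECDF_b| over the pooled points
oracle_ks_D <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(t) mean(a <= t) - mean(b <= t), numeric(1))))
}

# Exhaustive hypergeometric upper tail: enumerate all C(N, n) draws
oracle_hyper_p <- function(N, m, n, k_obs) {
  draws <- utils::combn(N, n)
  mean(colSums(draws <= m) >= k_obs)  # members 1..m are the set
}

# random peak sets on a small chromosome
random_peak_sets <- function(n_sets, max_peaks = 10L, L = 1000L, with_fdr = TRUE) {
  lapply(seq_len(n_sets), function(i) {
    n <- sample.int(max_peaks, 1)
    s <- sample.int(L - 30L, n, replace = TRUE)
    w <- sample(5:30, n, replace = TRUE)
    g <- GRanges("chr1", IRanges(s, pmin(s + w, L)))
    if (with_fdr) mcols(g)$fdr <- runif(n)
    g
  })
}

toy_genes <- function() {
  gr1(c(1000, 6000, 12000), c(3000, 9000, 16000), strand = c("+", "-", "+"),
      gene_id = c("gA", "gB", "gC"))
}
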