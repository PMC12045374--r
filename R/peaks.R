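# Regions of an integer RleList at or above a threshold, as GRanges.
#' @noRd
.rle_regions <- function(rlelist, lower) {
  grl <- lapply(names(rlelist), function(ch) {
    ir <- ranges(slice(rlelist[[ch]], lower = lower, rangesOnly = TRUE))
    if (length(ir) == 0) return(GRanges())
    GRanges(ch, ir)
  })
  out <- suppressWarnings(do.call(c, grl))
  if (is.null(out)) GRanges() else out
}

# Common-width coverage across peak sets (each set reduced first so one
# set contributes at most 1 per base).
#' @noRd
.occupancy <- function(sets) {
  all_gr <- suppressWarnings(do.call(c, lapply(sets, granges)))
  lv <- unique(as.character(seqnames(all_gr)))
  if (length(lv) == 0) return(methods::as(list(), "RleList"))
  wid <- vapply(lv, function(ch) max(end(all_gr[seqnames(all_gr) == ch])),
                numeric(1))
  covs <- lapply(sets, function(s) {
    s <- reduce(granges(s), ignore.strand = TRUE)
    seqlevels(s) <- lv
    coverage(s, width = as.list(wid))
  })
  Reduce(`+`, covs)
}

# Attach min-FDR of overlapping source peaks to each consensus region.
#' @noRd
.inherit_fdr <- function(regions, pool) {
  fdr <- rep(NA_real_, length(regions))
  if (length(pool) && !is.null(pool$fdr)) {
    hits <- findOverlaps(regions, pool, ignore.strand = TRUE)
    if (length(hits)) {
      agg <- tapply(pool$fdr[subjectHits(hits)], queryHits(hits), min)
      fdr[as.integer(names(agg))] <- as.numeric(agg)
    }
  }
  mcols(regions)$fdr <- fdr
  regions
}

# Union-find over pooled peaks linked by reciprocal-fraction overlap.
#' @noRd
.reciprocal_components <- function(pool, f) {
  hits <- findOverlaps(pool, pool, ignore.strand = TRUE)
  q <- queryHits(hits); s <- subjectHits(hits)
  keep <- q < s
  q <- q[keep]; s <- s[keep]
  if (length(q)) {
    ow <- width(pintersect(pool[q], pool[s], ignore.strand = TRUE))
    rec <- ow >= f * width(pool[q]) & ow >= f * width(pool[s])
    q <- q[rec]; s <- s[rec]
  }
  parent <- seq_along(pool)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_along(q)) {
    a <- find(q[k]); b <- find(s[k])
    if (a != b) parent[a] <- b
  }
  vapply(seq_along(pool), find, integer(1))
}

#' Consensus peaks across replicate peak sets
#'
#' Peaks failing the FDR filter are dropped, then regions supported by at
#' least `min_sets` of the input sets under the overlap rule are merged
#' into consensus peaks. With `overlap_rule = "any_bp"` support is
#' per-base occupancy; the consensus peak takes the union extent of all
#' contributing peaks (transitively, so chained overlaps merge) and
#' inherits the minimum FDR among them. With `"reciprocal"`, peaks are
#' linked when their overlap covers at least fraction `reciprocal` of
#' both, and components touching `>= min_sets` distinct sets are emitted.
#'
#' @param peak_sets non-empty list of peak `GRanges` (each with an `fdr`
#'   metadata column; sets without one pass the filter untouched).
#' @param min_sets minimum number of supporting input sets (default: all
#'   of them).
#' @param fdr_max FDR filter threshold in (0, 1] (default 0.05).
#' @param overlap_rule `"any_bp"` (default) or `"reciprocal"`.
#' @param reciprocal overlap fraction for the reciprocal rule
#'   (default 0.5).
#' @return `GRanges` of non-overlapping consensus peaks with an `fdr`
#'   column; provenance (inputs, rule) in `S4Vectors::metadata()`.
#' @export
consensus_peaks <- function(peak_sets, min_sets = length(peak_sets),
                            fdr_max = 0.05,
                            overlap_rule = c("any_bp", "reciprocal"),
                            reciprocal = 0.5) {
  overlap_rule <- match.arg(overlap_rule)
  .assert(is.list(peak_sets) && length(peak_sets) > 0,
          "`peak_sets` must be a non-empty list")
  .assert(min_sets >= 1 && min_sets <= length(peak_sets),
          "`min_sets` must be between 1 and the number of sets")
  .assert(fdr_max > 0 && fdr_max <= 1, "`fdr_max` must be in (0, 1]")
  filtered <- lapply(peak_sets, function(s) {
    if (!is.null(s$fdr)) s[s$fdr <= fdr_max] else s
  })
  pool <- suppressWarnings(do.call(c, lapply(filtered, function(s) {
    g <- granges(s)
    mcols(g)$fdr <- if (is.null(s$fdr)) rep(NA_real_, length(g)) else s$fdr
    g
  })))
  set_of <- rep(seq_along(filtered), vapply(filtered, length, integer(1)))
  empty <- GRanges()
  mcols(empty)$fdr <- numeric(0)
  if (length(pool) == 0) {
    out <- empty
  } else if (overlap_rule == "any_bp") {
    occ <- .occupancy(filtered)
    core <- .rle_regions(occ, min_sets)
    if (length(core) == 0) {
      out <- empty
    } else {
      # union extent: grow to include every pooled peak touching the
      # consensus region, to a fixpoint (chained overlaps merge).
      out <- reduce(core, ignore.strand = TRUE)
      repeat {
        sel <- overlapsAny(pool, out, ignore.strand = TRUE)
        grown <- reduce(c(granges(out), granges(pool[sel])), ignore.strand = TRUE)
        if (identical(as.data.frame(grown), as.data.frame(out))) break
        out <- grown
      }
      out <- .inherit_fdr(out, pool)
    }
  } else {
    comp <- .reciprocal_components(pool, reciprocal)
    keep_comp <- names(which(tapply(set_of, comp, function(x) length(unique(x))) >= min_sets))
    sel <- comp %in% as.integer(keep_comp)
    out <- if (any(sel)) {
      regions <- reduce(granges(pool[sel]), ignore.strand = TRUE)
      .inherit_fdr(regions, pool)
    } else empty
  }
  strand(out) <- "*"
  metadata(out) <- list(provenance = list(
    n_input_sets = length(peak_sets),
    input_sizes = vapply(peak_sets, length, integer(1)),
    min_sets = min_sets, fdr_max = fdr_max,
    overlap_rule = overlap_rule,
    reciprocal = if (overlap_rule == "reciprocal") reciprocal else NULL))
  out
}

#' Intersect two consensus peak sets across assays
#'
#' With `extent = "strict"` (default) the result is the strict
#' per-base intersection of the two merged sets, so it can never exceed
#' either parent. With `extent = "union"` each mutually supported region
#' is emitted with the union extent of the overlapping parent peaks.
#'
#' @param a,b peak `GRanges` (internally merged; [consensus_peaks()]
#'   output).
#' @param extent `"strict"` or `"union"`.
#' @return `GRanges` with inherited minimum `fdr` per region.
#' @export
intersect_assays <- function(a, b, extent = c("strict", "union")) {
  extent <- match.arg(extent)
  ra <- reduce(granges(a), ignore.strand = TRUE)
  rb <- reduce(granges(b), ignore.strand = TRUE)
  pool <- suppressWarnings(c(
    {g <- granges(a)
     mcols(g)$fdr <- if (is.null(a$fdr)) rep(NA_real_, length(g)) else a$fdr; g},
    {g <- granges(b)
     mcols(g)$fdr <- if (is.null(b$fdr)) rep(NA_real_, length(g)) else b$fdr; g}))
  if (extent == "strict") {
    out <- GenomicRanges::intersect(ra, rb, ignore.strand = TRUE)
  } else {
    hits <- findOverlaps(ra, rb, ignore.strand = TRUE)
    out <- if (length(hits) == 0) GRanges() else
      reduce(c(ra[queryHits(hits)], rb[subjectHits(hits)]), ignore.strand = TRUE)
  }
  if (length(out) == 0) {
    mcols(out)$fdr <- numeric(0)
  } else {
    out <- .inherit_fdr(out, pool)
  }
  metadata(out) <- list(provenance = list(op = "intersect_assays", extent = extent))
  out
}

#' Annotate peaks to genomic features and nearest genes
#'
#' Each peak is assigned one feature class with precedence
#' promoter > exon > intron > distal_intergenic: any overlap with a
#' promoter window (TSS +/- `promoter_window`) wins regardless of other
#' overlaps. The nearest gene is chosen by distance from the peak
#' midpoint to the TSS; `distance_to_tss` is signed positive downstream
#' of the TSS in the gene's orientation. When no exon models are given,
#' each gene is treated as a single exon spanning its body, so genic
#' non-promoter peaks class as "exon".
#'
#' @param peaks peak `GRanges`.
#' @param genes gene `GRanges` with `gene_id`.
#' @param promoter_window half-width in bp of the promoter window around
#'   each TSS (default 2000).
#' @param exons optional `GRanges` of exons (with or without gene ids).
#' @return data.frame with columns `chrom`, `start`, `end`,
#'   `feature_class`, `nearest_gene_id`, `distance_to_tss`.
#' @export
annotate_peaks <- function(peaks, genes, promoter_window = 2000L, exons = NULL) {
  .assert(promoter_window > 0, "`promoter_window` must be > 0")
  .assert(!is.null(genes$gene_id), "`genes` must carry gene_id")
  tss <- gene_tss(genes)
  chr <- as.character(seqnames(genes))
  prom <- GRanges(chr, IRanges(pmax(tss - promoter_window, 1L),
                               tss + promoter_window))
  if (is.null(exons)) exons <- granges(genes)
  is_prom <- overlapsAny(peaks, prom, ignore.strand = TRUE)
  is_exon <- overlapsAny(peaks, exons, ignore.strand = TRUE)
  is_genic <- overlapsAny(peaks, genes, ignore.strand = TRUE)
  cls <- ifelse(is_prom, "promoter",
         ifelse(is_exon, "exon",
         ifelse(is_genic, "intron", "distal_intergenic")))
  mid <- floor((start(peaks) + end(peaks)) / 2)
  mid_gr <- GRanges(seqnames(peaks), IRanges(mid, mid))
  tss_gr <- GRanges(chr, IRanges(tss, tss))
  near <- GenomicRanges::nearest(mid_gr, tss_gr, ignore.strand = TRUE)
  minus <- as.character(strand(genes)) == "-"
  dist <- ifelse(is.na(near), NA_integer_,
                 ifelse(minus[near], tss[near] - mid, mid - tss[near]))
  data.frame(
    chrom = as.character(seqnames(peaks)),
    start = start(peaks), end = end(peaks),
    feature_class = factor(cls, levels = c("promoter", "exon", "intron",
                                           "distal_intergenic")),
    nearest_gene_id = ifelse(is.na(near), NA_character_, genes$gene_id[near]),
    distance_to_tss = dist,
    stringsAsFactors = FALSE
  )
}

#' Cross-assay correlation of per-peak signal fold changes
#'
#' For each assay, the per-peak log2 fold change is
#' `log2((treat_density + pc) / (ctrl_density + pc))` with densities
#' library-normalized per track; the result is the Spearman rank
#' correlation of the two per-peak fold-change vectors.
#'
#' @param peaks peak `GRanges` (at least 3 peaks).
#' @param assay_a,assay_b each `list(ctrl = , treat = )` of
#'   [coverage_track] objects (unstranded combined signal).
#' @param pseudocount density pseudocount (default 0.1).
#' @return list with `rho` (Spearman coefficient), `log2fc_a`, `log2fc_b`.
#' @export
signal_fold_change_correlation <- function(peaks, assay_a, assay_b,
                                           pseudocount = 0.1) {
  .assert(length(peaks) >= 3, "need at least 3 peaks for a rank correlation")
  fc <- function(assay) {
    .assert(is.list(assay) && all(c("ctrl", "treat") %in% names(assay)),
            "each assay must be list(ctrl=, treat=)")
    dc <- window_density(assay$ctrl, peaks)
    dt <- window_density(assay$treat, peaks)
    log2((dt + pseudocount) / (dc + pseudocount))
  }
  a <- fc(assay_a); b <- fc(assay_b)
  list(rho = stats::cor(a, b, method = "spearman"), log2fc_a = a, log2fc_b = b)
}
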