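#' Build promoter and gene-body quantification windows
#'
#' The pausing release ratio compares signal density in the gene body to
#' density at the promoter region. Windows follow the pausing-index
#' convention of the GRO-seq literature: promoter = `[TSS - promoter_up,
#' TSS + promoter_down)` in gene orientation, body = `[TSS + body_gap,
#' TES]` (or a fixed extent clipped at the TES). Genes too short to leave
#' a non-empty body are omitted, not truncated; their ids are returned in
#' `omitted`.
#'
#' @param genes `GRanges` with `gene_id` (see [read_annotation()]).
#'   Unstranded genes are oriented as `+`.
#' @param promoter_up bases upstream of the TSS in the promoter window
#'   (default 50).
#' @param promoter_down bases downstream of the TSS (default 300).
#' @param body_gap offset from TSS to body start (default 300, so the
#'   body abuts the promoter window).
#' @param body_extent `Inf` for body-to-TES (default), or a fixed body
#'   length in bp, clipped at the TES.
#' @return an object of class `pausing_windows`: a list with `GRanges`
#'   elements `promoter` and `body` (parallel, `gene_id` and gene strand
#'   on both) and a character vector `omitted`.
#' @examples
#' g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10000, 20000),
#'                             strand = "+", gene_id = "g1")
#' w <- build_windows(g)
#' w$promoter  # chr1:9950-10299
#' @export
build_windows <- function(genes, promoter_up = 50L, promoter_down = 300L,
                          body_gap = 300L, body_extent = Inf) {
  .assert(promoter_up >= 0 && promoter_down >= 0, "promoter bounds must be >= 0")
  .assert(promoter_up + promoter_down > 0, "promoter window must be non-empty")
  .assert(body_gap >= 0, "`body_gap` must be >= 0")
  .assert(is.infinite(body_extent) || body_extent > 0,
          "`body_extent` must be positive or Inf")
  .assert(!is.null(genes$gene_id), "`genes` must carry a gene_id column")
  tss <- gene_tss(genes)
  tes <- gene_tes(genes)
  minus <- as.character(strand(genes)) == "-"

  # promoter, oriented: [TSS - up, TSS + down) expressed in 1-based
  # closed coordinates on the reference.
  p_start <- ifelse(minus, tss - promoter_down + 1L, tss - promoter_up)
  p_end   <- ifelse(minus, tss + promoter_up,        tss + promoter_down - 1L)
  p_start <- pmax(p_start, 1L)

  # body: starts body_gap downstream of the TSS, runs to the TES (or a
  # fixed extent clipped there).
  b_start <- ifelse(minus, tes, tss + body_gap)
  b_end   <- ifelse(minus, tss - body_gap, tes)
  if (is.finite(body_extent)) {
    b_end   <- ifelse(minus, b_end, pmin(b_end, tss + body_gap + body_extent - 1L))
    b_start <- ifelse(minus, pmax(b_start, tss - body_gap - body_extent + 1L), b_start)
  }
  keep <- b_end >= b_start & b_start >= 1L
  omitted <- genes$gene_id[!keep]
  if (length(omitted))
    message(sprintf("build_windows: omitted %d gene(s) with empty body window: %s%s",
                    length(omitted), paste(utils::head(omitted, 5), collapse = ", "),
                    if (length(omitted) > 5) ", ..." else ""))
  ok <- which(keep)
  chr <- as.character(seqnames(genes))[ok]
  str <- strand(genes)[ok]
  promoter <- GRanges(chr, IRanges(p_start[ok], p_end[ok]), strand = str,
                      gene_id = genes$gene_id[ok])
  body <- GRanges(chr, IRanges(b_start[ok], b_end[ok]), strand = str,
                  gene_id = genes$gene_id[ok])
  structure(list(promoter = promoter, body = body, omitted = omitted),
            class = "pausing_windows")
}

#' @export
print.pausing_windows <- function(x, ...) {
  cat(sprintf("<pausing_windows> %d genes (%d omitted: empty body)\n",
              length(x$promoter), length(x$omitted)))
  invisible(x)
}

#' Pausing release ratio
#'
#' `PRR = (body_density + pseudocount) / (promoter_density + pseudocount)`.
#' A high PRR means polymerase has been released into the body; a low PRR
#' means promoter-proximal accumulation (pausing). The pseudocount guards
#' silent promoters; with `pseudocount = 0` the raw ratio is returned
#' (possibly `Inf`/`NaN` for zero densities).
#'
#' @param promoter_density,body_density non-negative densities (any
#'   common unit; PRR is scale-invariant up to the pseudocount).
#' @param pseudocount non-negative density added to both terms
#'   (default 0.1).
#' @return numeric vector of PRR values.
#' @examples
#' compute_prr(10, 10)            # ~1
#' compute_prr(0.5714, 0.05, 0)   # 0.0875
#' @export
compute_prr <- function(promoter_density, body_density, pseudocount = 0.1) {
  .assert(all(promoter_density >= 0) && all(body_density >= 0),
          "densities must be non-negative")
  .assert(length(pseudocount) == 1 && pseudocount >= 0,
          "`pseudocount` must be a single value >= 0")
  (body_density + pseudocount) / (promoter_density + pseudocount)
}

#' Classify genes by log2 PRR fold change
#'
#' Genes with `log2_prr_fc > threshold` are "GroupI_paused" (pausing
#' released most strongly on treatment), genes with `|log2_prr_fc| <=
#' threshold` are "GroupII_other", and genes below `-threshold` are
#' "Decreased". Genes flagged inactive (`active = FALSE`) are "Excluded"
#' before classification. The default threshold 0.585 is log2(1.5).
#' Boundary equality is assigned to GroupII_other.
#'
#' @param log2_prr_fc numeric vector of log2 PRR fold changes.
#' @param threshold positive classification threshold (default 0.585).
#' @param active logical vector (recycled); `FALSE` excludes a gene.
#' @return factor with levels `GroupI_paused`, `GroupII_other`,
#'   `Decreased`, `Excluded`.
#' @export
classify_genes <- function(log2_prr_fc, threshold = 0.585, active = TRUE) {
  .assert(threshold > 0, "`threshold` must be > 0")
  active <- rep_len(active, length(log2_prr_fc))
  lab <- ifelse(!active, "Excluded",
         ifelse(log2_prr_fc > threshold, "GroupI_paused",
         ifelse(log2_prr_fc < -threshold, "Decreased", "GroupII_other")))
  factor(lab, levels = c("GroupI_paused", "GroupII_other", "Decreased", "Excluded"))
}

# Resolve a coverage argument: either one unstranded track or
# list(plus=, minus=). Returns list(plus, minus, total).
#' @noRd
.resolve_tracks <- function(x, what) {
  if (is_coverage_track(x)) {
    return(list(plus = x, minus = x, total = x$total_signal, stranded = FALSE))
  }
  .assert(is.list(x) && all(c("plus", "minus") %in% names(x)) &&
            is_coverage_track(x$plus) && is_coverage_track(x$minus),
          sprintf("`%s` must be a coverage_track or list(plus=, minus=)", what))
  list(plus = x$plus, minus = x$minus,
       total = x$plus$total_signal + x$minus$total_signal, stranded = TRUE)
}

# Strand-matched window sums: sense-strand signal for stranded data,
# combined signal for unstranded.
#' @noRd
.stranded_density <- function(tracks, windows) {
  minus <- as.character(strand(windows)) == "-"
  d <- numeric(length(windows))
  if (any(!minus))
    d[!minus] <- window_density(tracks$plus, windows[!minus],
                                library_total = tracks$total)
  if (any(minus))
    d[minus] <- window_density(tracks$minus, windows[minus],
                               library_total = tracks$total)
  d
}

#' Per-gene PRR table for two conditions
#'
#' Computes promoter and body densities (signal per bp per million total
#' library signal; sense strand only for stranded input) in control and
#' treatment, the PRR in each condition, the log2 PRR fold change
#' (treatment over control by default), applies the promoter-activity
#' filter, and classifies each gene.
#'
#' @param windows a [build_windows()] result.
#' @param ctrl,treat coverage for each condition: a single unstranded
#'   [coverage_track] or `list(plus = , minus = )` of stranded tracks.
#' @param pseudocount PRR pseudocount in density units (default 0.1).
#' @param log2_threshold classification threshold (default 0.585 =
#'   log2 1.5).
#' @param min_activity_quantile genes whose control promoter density is
#'   below this quantile of all genes are Excluded (default 0.25; 0
#'   disables the filter).
#' @param flip_fc if `TRUE`, the fold change is control over treatment.
#' @return data.frame with columns `gene_id`, `promoter_density_ctrl`,
#'   `body_density_ctrl`, `promoter_density_treat`, `body_density_treat`,
#'   `prr_ctrl`, `prr_treat`, `log2_prr_fc`, `group`.
#' @export
prr_table <- function(windows, ctrl, treat, pseudocount = 0.1,
                      log2_threshold = 0.585, min_activity_quantile = 0.25,
                      flip_fc = FALSE) {
  .assert(inherits(windows, "pausing_windows"),
          "`windows` must come from build_windows()")
  .assert(min_activity_quantile >= 0 && min_activity_quantile < 1,
          "`min_activity_quantile` must be in [0, 1)")
  tc <- .resolve_tracks(ctrl, "ctrl")
  tt <- .resolve_tracks(treat, "treat")
  pc <- .stranded_density(tc, windows$promoter)
  bc <- .stranded_density(tc, windows$body)
  pt <- .stranded_density(tt, windows$promoter)
  bt <- .stranded_density(tt, windows$body)
  prr_c <- compute_prr(pc, bc, pseudocount)
  prr_t <- compute_prr(pt, bt, pseudocount)
  l2fc <- log2(prr_t / prr_c)
  if (flip_fc) l2fc <- -l2fc
  active <- if (min_activity_quantile > 0) {
    pc >= stats::quantile(pc, min_activity_quantile, names = FALSE)
  } else rep(TRUE, length(pc))
  data.frame(
    gene_id = windows$promoter$gene_id,
    promoter_density_ctrl = pc, body_density_ctrl = bc,
    promoter_density_treat = pt, body_density_treat = bt,
    prr_ctrl = prr_c, prr_treat = prr_t, log2_prr_fc = l2fc,
    group = classify_genes(l2fc, log2_threshold, active),
    stringsAsFactors = FALSE
  )
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' The statistic D is the supremum over the pooled sample points of the
#' absolute difference of the two empirical distribution functions; the
#' p-value is the asymptotic two-sided K-S tail with effective sample
#' size `n_a * n_b / (n_a + n_b)`.
#'
#' @param a,b non-empty numeric vectors.
#' @return list of class `ks_comparison` with `statistic` (D), `p_value`,
#'   `n_a`, `n_b`.
#' @export
ks_two_sample <- function(a, b) {
  .assert(is.numeric(a) && length(a) > 0, "sample `a` is empty")
  .assert(is.numeric(b) && length(b) > 0, "sample `b` is empty")
  ks <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  structure(list(statistic = unname(ks$statistic), p_value = ks$p.value,
                 n_a = length(a), n_b = length(b)),
            class = "ks_comparison")
}

#' @export
print.ks_comparison <- function(x, ...) {
  cat(sprintf("Two-sample K-S: D = %.4g, p = %.4g (n = %d, %d)\n",
              x$statistic, x$p_value, x$n_a, x$n_b))
  invisible(x)
}

#' Empirical cumulative distribution table
#'
#' Right-continuous step function as (value, cumulative fraction) pairs
#' at the distinct sample values; the final fraction is 1.
#'
#' @param sample non-empty numeric vector.
#' @return data.frame with columns `value`, `fraction`.
#' @examples
#' ecdf_table(c(1, 1, 2))  # (1, 2/3), (2, 1)
#' @export
ecdf_table <- function(sample) {
  .assert(is.numeric(sample) && length(sample) > 0, "`sample` is empty")
  v <- sort(unique(sample))
  data.frame(value = v,
             fraction = cumsum(tabulate(match(sort(sample), v))) / length(sample))
}
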