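#' Configuration for the synthetic nascent-transcription generator
#'
#' The generator emulates a GRO-seq style experiment with a controllable
#' pause-release effect: genes carry a promoter-proximal signal peak
#' whose height relative to the gene-body density encodes pausing, and a
#' "knockout" condition shifts signal from promoter to body for a chosen
#' gene subset. Per-base counts are Poisson; the treatment effect is
#' applied symmetrically (promoter rate divided by `sqrt(release_fold)`,
#' body rate multiplied by it) so total gene signal is approximately
#' conserved and only the promoter/body ratio moves.
#'
#' @param n_genes number of genes (default 2000).
#' @param chrom chromosome name (default `"chrS"`).
#' @param chrom_length chromosome length in bp; `NULL` (default) sizes
#'   the chromosome to fit the genes with spacing.
#' @param fraction_paused fraction of genes whose pausing is released on
#'   treatment (default 0.3).
#' @param fraction_gained fraction gaining pausing on treatment
#'   (default 0.05).
#' @param promoter_enrichment control promoter rate / body rate fold
#'   (default 10).
#' @param paused_extra_enrichment additional control promoter-enrichment
#'   fold for `paused_released` genes (default 2): the genes that respond
#'   to pause release are the highly paused ones, so their control
#'   promoters carry more signal.
#' @param release_fold expected PRR fold change for released genes
#'   (default 3).
#' @param body_rate_meanlog,body_rate_sdlog log-normal parameters of the
#'   per-gene control body rate, signal per bp (defaults give mean
#'   ~0.57/bp).
#' @param background_rate intergenic/antisense Poisson rate per bp per
#'   strand (default 0.01).
#' @param promoter_len length of the promoter signal region downstream
#'   of the TSS, bp (default 300).
#' @param gene_length_min,gene_length_max gene lengths drawn log-uniform
#'   in this range, bp (defaults 2000 / 20000).
#' @param spacing_min,spacing_max intergenic gaps drawn uniform in this
#'   range, bp (defaults 1000 / 3000).
#' @param replicates number of replicate peak sets (default 3).
#' @param decoy_fraction decoy peaks per replicate as a fraction of
#'   genes (default 0.2).
#' @param jitter replicate peak boundary jitter, bp each side
#'   (default 20).
#' @param overdispersion optional gamma shape for a per-gene rate
#'   multiplier (`NULL`, the default, is pure Poisson).
#' @param seed root RNG seed; all generator stages derive sub-streams
#'   from it (default 1).
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(n_genes = 2000L, chrom = "chrS",
                             chrom_length = NULL,
                             fraction_paused = 0.3, fraction_gained = 0.05,
                             promoter_enrichment = 10,
                             paused_extra_enrichment = 2,
                             release_fold = 3,
                             body_rate_meanlog = log(0.5),
                             body_rate_sdlog = 0.5,
                             background_rate = 0.01, promoter_len = 300L,
                             gene_length_min = 2000L, gene_length_max = 20000L,
                             spacing_min = 1000L, spacing_max = 3000L,
                             replicates = 3L, decoy_fraction = 0.2,
                             jitter = 20L, overdispersion = NULL,
                             seed = 1L) {
  cfg <- as.list(environment())
  .assert(n_genes >= 1, "`n_genes` must be >= 1")
  .assert(fraction_paused >= 0 && fraction_paused <= 1 &&
            fraction_gained >= 0 && fraction_gained <= 1 &&
            fraction_paused + fraction_gained <= 1,
          "class fractions must lie in [0,1] and sum to <= 1")
  .assert(promoter_enrichment > 0 && release_fold > 0 &&
            paused_extra_enrichment > 0, "folds must be > 0")
  .assert(background_rate >= 0, "`background_rate` must be >= 0")
  .assert(gene_length_min > promoter_len,
          "genes must be longer than the promoter region")
  .assert(replicates >= 1, "`replicates` must be >= 1")
  structure(cfg, class = "generator_config")
}

#' Generate a synthetic genome annotation with per-gene truth
#'
#' Places non-overlapping genes with random strands and log-uniform
#' lengths along one chromosome, assigns each a true class
#' (`paused_released`, `pause_gained`, `unchanged`) and the generative
#' promoter/body Poisson rates in both conditions. Deterministic under
#' the config seed.
#'
#' @param config a [generator_config()].
#' @return list with `genes` (`GRanges` with `gene_id`, seqlengths set)
#'   and `truth` (data.frame: `gene_id`, `true_class`, the four rates,
#'   `seed`).
#' @export
generate_genome <- function(config) {
  .assert(inherits(config, "generator_config"), "`config` must be a generator_config")
  .with_seed(.substream(config$seed, 1L), {
    n <- config$n_genes
    lens <- round(exp(runif(n, log(config$gene_length_min),
                            log(config$gene_length_max))))
    gaps <- round(runif(n, config$spacing_min, config$spacing_max))
    starts <- cumsum(gaps) + cumsum(c(0, utils::head(lens, -1)))
    ends <- starts + lens - 1
    needed <- ends[n] + config$spacing_max
    L <- if (is.null(config$chrom_length)) needed else config$chrom_length
    if (ends[n] > L)
      stop(sprintf("genes do not fit: need %d bp, chrom_length is %d", needed, L),
           call. = FALSE)
    strands <- sample(c("+", "-"), n, replace = TRUE)
    classes <- sample(c("paused_released", "pause_gained", "unchanged"), n,
                      replace = TRUE,
                      prob = c(config$fraction_paused, config$fraction_gained,
                               1 - config$fraction_paused - config$fraction_gained))
    body_c <- rlnorm(n, config$body_rate_meanlog, config$body_rate_sdlog)
    prom_c <- body_c * config$promoter_enrichment *
      ifelse(classes == "paused_released", config$paused_extra_enrichment, 1)
    sf <- sqrt(config$release_fold)
    prom_t <- ifelse(classes == "paused_released", prom_c / sf,
              ifelse(classes == "pause_gained", prom_c * sf, prom_c))
    body_t <- ifelse(classes == "paused_released", body_c * sf,
              ifelse(classes == "pause_gained", body_c / sf, body_c))
    # rescale so each gene's expected total signal is conserved across
    # conditions: only the promoter/body ratio moves, not expression.
    pl <- config$promoter_len
    mass_c <- prom_c * pl + body_c * (lens - pl)
    mass_t <- prom_t * pl + body_t * (lens - pl)
    sc <- mass_c / mass_t
    prom_t <- prom_t * sc
    body_t <- body_t * sc
    ids <- sprintf("gene_%04d", seq_len(n))
    genes <- GRanges(config$chrom, IRanges(starts, ends), strand = strands,
                     gene_id = ids)
    seqlengths(genes) <- stats::setNames(L, config$chrom)
    truth <- data.frame(gene_id = ids, true_class = classes,
                        promoter_rate_ctrl = prom_c, body_rate_ctrl = body_c,
                        promoter_rate_treat = prom_t, body_rate_treat = body_t,
                        seed = config$seed, stringsAsFactors = FALSE)
    list(genes = genes, truth = truth)
  })
}

# Draw Poisson per-base counts for a set of constant-rate regions by
# total-count thinning: per region, N ~ Poisson(rate * len) reads at
# uniform positions is exactly iid Poisson per base. One pass, one
# tabulate over the chromosome.
#' @noRd
.poisson_regions <- function(from, to, rate, L) {
  len <- to - from + 1
  keep <- len > 0 & rate > 0
  from <- from[keep]; len <- len[keep]; rate <- rate[keep]
  if (!length(from)) return(integer(L))
  n <- rpois(length(from), rate * len)
  total <- sum(n)
  if (total == 0) return(integer(L))
  idx <- rep.int(seq_along(from), n)
  pos <- from[idx] + floor(runif(total) * len[idx])
  tabulate(pos, L)
}

#' Simulate stranded coverage for one condition
#'
#' Per-base counts are Poisson with the truth-table rates: the promoter
#' region (first `promoter_len` bases downstream of the TSS) at the
#' promoter rate and the rest of the gene at the body rate, on the
#' gene's sense strand, plus a uniform background on both strands.
#'
#' @param genes,truth a [generate_genome()] result's components.
#' @param config the [generator_config()] used to generate them.
#' @param condition `"ctrl"` or `"treat"`.
#' @return `list(plus = , minus = )` of [coverage_track] objects with
#'   chromosome length recorded.
#' @export
simulate_coverage <- function(genes, truth, config,
                              condition = c("ctrl", "treat")) {
  condition <- match.arg(condition)
  .assert(identical(genes$gene_id, truth$gene_id),
          "`truth` is not parallel to `genes`")
  L <- seqlengths(genes)[[config$chrom]]
  .assert(is.finite(L) && L > 0, "genes must carry a chromosome length")
  .with_seed(.substream(config$seed, if (condition == "ctrl") 2L else 3L), {
    prom_rate <- if (condition == "ctrl") truth$promoter_rate_ctrl
                 else truth$promoter_rate_treat
    body_rate <- if (condition == "ctrl") truth$body_rate_ctrl
                 else truth$body_rate_treat
    if (!is.null(config$overdispersion)) {
      mult <- rgamma(length(prom_rate), shape = config$overdispersion,
                     rate = config$overdispersion)
      prom_rate <- prom_rate * mult
      body_rate <- body_rate * mult
    }
    tss <- gene_tss(genes)
    minus <- as.character(strand(genes)) == "-"
    s <- start(genes); e <- end(genes)
    pl <- config$promoter_len
    # constant-rate regions per strand: background + promoter + body
    reg <- function(is_minus) {
      i <- which(minus == is_minus)
      if (is_minus) {
        list(from = c(1L, tss[i] - pl + 1L, s[i]),
             to = c(L, tss[i], tss[i] - pl),
             rate = c(config$background_rate, prom_rate[i], body_rate[i]))
      } else {
        list(from = c(1L, tss[i], tss[i] + pl),
             to = c(L, tss[i] + pl - 1L, e[i]),
             rate = c(config$background_rate, prom_rate[i], body_rate[i]))
      }
    }
    rp <- reg(FALSE); rm_ <- reg(TRUE)
    cplus <- .poisson_regions(rp$from, rp$to, rp$rate, L)
    cminus <- .poisson_regions(rm_$from, rm_$to, rm_$rate, L)
    sl <- stats::setNames(L, config$chrom)
    mk <- function(counts, strand_lab) {
      cov <- methods::as(stats::setNames(list(Rle(counts)), config$chrom),
                         "RleList")
      coverage_track(cov, strand_lab, seqlengths = sl)
    }
    list(plus = mk(cplus, "+"), minus = mk(cminus, "-"))
  })
}

#' Simulate replicate peak calls over promoters
#'
#' Each replicate carries one true peak per gene promoter (TSS - 100 to
#' TSS + `promoter_len` + 100 in gene orientation) with boundaries
#' jittered independently per replicate and a low FDR (< 0.01), plus
#' decoy peaks at random positions with FDR uniform in [0.05, 1].
#'
#' @param genes,truth a [generate_genome()] result's components.
#' @param config the [generator_config()].
#' @param decoys include decoy peaks (default `TRUE`).
#' @return list of `replicates` peak `GRanges` (metadata columns `name`,
#'   `score`, `fdr`).
#' @export
simulate_peaks <- function(genes, truth, config, decoys = TRUE) {
  L <- seqlengths(genes)[[config$chrom]]
  tss <- gene_tss(genes)
  minus <- as.character(strand(genes)) == "-"
  lo <- ifelse(minus, tss - config$promoter_len - 100L, tss - 100L)
  hi <- ifelse(minus, tss + 100L, tss + config$promoter_len + 100L)
  n <- length(genes)
  lapply(seq_len(config$replicates), function(r) {
    .with_seed(.substream(config$seed, 100L + r), {
      js <- round(runif(n, -config$jitter, config$jitter))
      je <- round(runif(n, -config$jitter, config$jitter))
      gs <- pmax(lo + js, 1L)
      ge <- pmin(hi + je, L)
      fdr <- runif(n, 1e-6, 0.009)
      nm <- sprintf("%s_rep%d", genes$gene_id, r)
      if (decoys && config$decoy_fraction > 0) {
        nd <- max(1L, round(config$decoy_fraction * n))
        ds <- sample.int(L - 200L, nd)
        gs <- c(gs, ds); ge <- c(ge, ds + 199L)
        fdr <- c(fdr, runif(nd, 0.05, 1))
        nm <- c(nm, sprintf("decoy_%d_rep%d", seq_len(nd), r))
      }
      gr <- GRanges(config$chrom, IRanges(gs, ge))
      mcols(gr)$name <- nm
      mcols(gr)$score <- round(-10 * log10(pmax(fdr, 1e-10)))
      mcols(gr)$fdr <- fdr
      GenomicRanges::sort(gr, ignore.strand = TRUE)
    })
  })
}

#' Generate and write a complete synthetic dataset
#'
#' Writes the annotation (GTF), stranded coverage (bedGraph per strand
#' and condition), replicate peak calls (narrowPeak), the truth table
#' (TSV) and a provenance sidecar into a directory.
#'
#' @param config a [generator_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with `paths` (named list of output paths)
#'   and the in-memory `genes` and `truth` objects.
#' @export
generate_dataset <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gen <- generate_genome(config)
  ctrl <- simulate_coverage(gen$genes, gen$truth, config, "ctrl")
  treat <- simulate_coverage(gen$genes, gen$truth, config, "treat")
  reps <- simulate_peaks(gen$genes, gen$truth, config)
  paths <- list(
    annotation = file.path(dir, "genes.gtf"),
    truth = file.path(dir, "truth.tsv"),
    ctrl_plus = file.path(dir, "ctrl_plus.bedGraph"),
    ctrl_minus = file.path(dir, "ctrl_minus.bedGraph"),
    treat_plus = file.path(dir, "treat_plus.bedGraph"),
    treat_minus = file.path(dir, "treat_minus.bedGraph"),
    peaks = file.path(dir, sprintf("peaks_rep%d.narrowPeak",
                                   seq_len(config$replicates)))
  )
  write_annotation(gen$genes, paths$annotation)
  .write_tsv(gen$truth, paths$truth)
  write_coverage(ctrl$plus, paths$ctrl_plus)
  write_coverage(ctrl$minus, paths$ctrl_minus)
  write_coverage(treat$plus, paths$treat_plus)
  write_coverage(treat$minus, paths$treat_minus)
  for (r in seq_along(reps)) write_peaks(reps[[r]], paths$peaks[r])
  write_provenance(paths$truth, inputs = list(),
                   params = config[setdiff(names(config), "chrom_length")],
                   seed = config$seed)
  invisible(list(paths = paths, genes = gen$genes, truth = gen$truth))
}
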