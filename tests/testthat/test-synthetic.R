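# Small configuration used across synthetic-data tests: quick to
# simulate, same structure as the full-scale defaults.
small_config <- function(seed = 123, ...) {
  generator_config(n_genes = 40, gene_length_min = 2000, gene_length_max = 6000,
                   seed = seed, ...)
}

test_that("generation is deterministic under the seed and genes never overlap", {
  cfg <- small_config()
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(g1$truth, g2$truth)
  expect_equal(start(g1$genes), start(g2$genes))
  expect_equal(length(GenomicRanges::reduce(g1$genes, ignore.strand = TRUE)),
               length(g1$genes))
  g3 <- generate_genome(small_config(seed = 124))
  expect_false(identical(g1$truth$body_rate_ctrl, g3$truth$body_rate_ctrl))
  # gene lengths within the configured range
  expect_true(all(width(g1$genes) >= 2000 & width(g1$genes) <= 6000))
})

test_that("class labels follow the configured fractions", {
  none <- generate_genome(small_config(fraction_paused = 0, fraction_gained = 0))
  expect_true(all(none$truth$true_class == "unchanged"))
  cfg <- generator_config(n_genes = 100, fraction_paused = 0.3, seed = 7)
  gen <- generate_genome(cfg)
  n_paused <- sum(gen$truth$true_class == "paused_released")
  # a Binomial(100, 0.3) draw, reproducible under the seed
  expect_equal(n_paused, sum(generate_genome(cfg)$truth$true_class ==
                               "paused_released"))
  expect_true(n_paused >= 15 && n_paused <= 45)
})

test_that("truth rates satisfy the release-fold invariant", {
  gen <- generate_genome(small_config(release_fold = 3))
  tr <- gen$truth
  rel <- tr$true_class == "paused_released"
  unch <- tr$true_class == "unchanged"
  expect_true(all(
    (tr$body_rate_treat / tr$promoter_rate_treat)[rel] >
      1.5 * (tr$body_rate_ctrl / tr$promoter_rate_ctrl)[rel]))
  expect_equal(tr$promoter_rate_treat[unch], tr$promoter_rate_ctrl[unch])
  expect_equal(tr$body_rate_treat[unch], tr$body_rate_ctrl[unch])
  # expected PRR fold change equals release_fold exactly
  fc <- (tr$body_rate_treat / tr$promoter_rate_treat)[rel] /
    (tr$body_rate_ctrl / tr$promoter_rate_ctrl)[rel]
  expect_equal(fc, rep(3, sum(rel)))
})

test_that("genes that do not fit the chromosome are rejected", {
  expect_error(generate_genome(small_config(chrom_length = 10000)),
               "do not fit")
})

test_that("simulated coverage is strand-correct Poisson with conserved totals", {
  cfg <- small_config(background_rate = 0)
  gen <- generate_genome(cfg)
  ctrl <- simulate_coverage(gen$genes, gen$truth, cfg, "ctrl")
  expect_identical(ctrl$plus$strand, "+")
  # signal only within plus-strand genes on the plus track
  plus_genes <- gen$genes[strand(gen$genes) == "+"]
  outside <- GenomicRanges::gaps(GenomicRanges::reduce(plus_genes,
                                                       ignore.strand = TRUE))
  outside <- outside[strand(outside) == "*"]
  expect_equal(sum(pausekit::window_density(ctrl$plus, outside) *
                     width(outside)), 0)
  # total signal close to the expected mass on each strand
  pl <- cfg$promoter_len
  mass <- with(gen$truth, promoter_rate_ctrl * pl +
                 body_rate_ctrl * (width(gen$genes) - pl))
  for (s in c("+", "-")) {
    sel <- as.character(strand(gen$genes)) == s
    tot <- if (s == "+") ctrl$plus$total_signal else ctrl$minus$total_signal
    expect_lt(abs(tot - sum(mass[sel])) / sum(mass[sel]), 0.05)
  }
  # treatment conserves each condition's library size in expectation
  treat <- simulate_coverage(gen$genes, gen$truth, cfg, "treat")
  tot_c <- ctrl$plus$total_signal + ctrl$minus$total_signal
  tot_t <- treat$plus$total_signal + treat$minus$total_signal
  expect_lt(abs(tot_t - tot_c) / tot_c, 0.05)
})

test_that("measured PRR matches the analytic expectation over repeat simulations", {
  # one gene, promoter rate 5/bp over 350 bp, body rate 0.5/bp over 2 kb:
  # expected PRR = 0.5 / 5 = 0.1
  cfg <- generator_config(n_genes = 1, gene_length_min = 2350,
                          gene_length_max = 2351, promoter_len = 350,
                          promoter_enrichment = 10, fraction_paused = 0,
                          fraction_gained = 0, background_rate = 0,
                          body_rate_meanlog = log(0.5), body_rate_sdlog = 0,
                          seed = 55)
  prrs <- vapply(1:50, function(i) {
    cfg$seed <- 55 + i
    gen <- generate_genome(cfg)
    cov <- simulate_coverage(gen$genes, gen$truth, cfg, "ctrl")
    w <- build_windows(gen$genes, promoter_up = 0, promoter_down = 350,
                       body_gap = 350)
    tab <- prr_table(w, cov, cov, pseudocount = 0, min_activity_quantile = 0)
    tab$prr_ctrl
  }, numeric(1))
  se <- sd(prrs) / sqrt(length(prrs))
  expect_lt(abs(mean(prrs) - 0.1), 3 * se + 1e-9)
})

test_that("neutral settings give null expectations", {
  # promoter_enrichment = 1: expected PRR ~ 1 for every gene
  cfg <- small_config(promoter_enrichment = 1, fraction_paused = 0,
                      fraction_gained = 0, background_rate = 0)
  gen <- generate_genome(cfg)
  cov <- simulate_coverage(gen$genes, gen$truth, cfg, "ctrl")
  w <- build_windows(gen$genes, promoter_up = 0, promoter_down = 300)
  tab <- prr_table(w, cov, cov, pseudocount = 0, min_activity_quantile = 0)
  expect_lt(abs(mean(tab$prr_ctrl) - 1), 3 * sd(tab$prr_ctrl) / sqrt(nrow(tab)))
  # release_fold = 1: expected log2 PRR fold change 0
  cfg2 <- small_config(release_fold = 1, background_rate = 0)
  gen2 <- generate_genome(cfg2)
  ctrl2 <- simulate_coverage(gen2$genes, gen2$truth, cfg2, "ctrl")
  treat2 <- simulate_coverage(gen2$genes, gen2$truth, cfg2, "treat")
  tab2 <- prr_table(build_windows(gen2$genes, promoter_up = 0), ctrl2, treat2,
                    pseudocount = 0, min_activity_quantile = 0)
  expect_lt(abs(mean(tab2$log2_prr_fc)),
            3 * sd(tab2$log2_prr_fc) / sqrt(nrow(tab2)))
})

test_that("replicate peaks recover promoters through consensus", {
  cfg <- small_config(jitter = 20)
  gen <- generate_genome(cfg)
  reps <- simulate_peaks(gen$genes, gen$truth, cfg, decoys = FALSE)
  expect_length(reps, cfg$replicates)
  cons <- consensus_peaks(reps, min_sets = 3, fdr_max = 0.05)
  # one consensus peak per promoter, extent within the jitter of truth
  expect_length(cons, length(gen$genes))
  tss <- gene_tss(gen$genes)
  minus <- as.character(strand(gen$genes)) == "-"
  lo <- sort(ifelse(minus, tss - cfg$promoter_len - 100, tss - 100))
  expect_true(all(abs(start(cons) - lo) <= cfg$jitter))
  # with decoys, the FDR filter removes them all
  reps_d <- simulate_peaks(gen$genes, gen$truth, cfg, decoys = TRUE)
  filt <- reps_d[[1]][reps_d[[1]]$fdr <= 0.05]
  expect_false(any(grepl("decoy", filt$name)))
  expect_true(any(grepl("decoy", reps_d[[1]]$name)))
})

test_that("a generated dataset round-trips through the standard formats", {
  dir <- withr::local_tempdir()
  cfg <- generator_config(n_genes = 8, gene_length_min = 2000,
                          gene_length_max = 4000, replicates = 2, seed = 9)
  out <- generate_dataset(cfg, dir)
  genes <- read_annotation(out$paths$annotation, "gtf")
  expect_equal(genes$gene_id, out$genes$gene_id)
  expect_equal(start(genes), start(out$genes))
  truth <- read.delim(out$paths$truth)
  expect_equal(truth$gene_id, out$truth$gene_id)
  tr <- read_coverage(out$paths$ctrl_plus, "bedgraph", "+")
  direct <- simulate_coverage(out$genes, out$truth, cfg, "ctrl")
  expect_equal(tr$total_signal, direct$plus$total_signal)
  pk <- read_peaks(out$paths$peaks[1], "narrowpeak")
  expect_gt(length(pk), 8)                    # true peaks + decoys
  expect_true(file.exists(paste0(out$paths$truth, ".prov.json")))
})
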