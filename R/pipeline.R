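#' Default run configuration
#'
#' Builds the nested configuration list consumed by
#' [run_pausing_analysis()]; any element can be overridden. The same
#' structure round-trips through YAML ([read_run_config()]).
#'
#' @param annotation path to the gene annotation (GTF).
#' @param coverage nested list
#'   `list(ctrl = list(plus=, minus=), treat = list(plus=, minus=))` of
#'   bedGraph paths (use a single `unstranded =` entry per condition for
#'   unstranded data).
#' @param peaks optional named list, one element per assay, each a
#'   character vector of replicate narrowPeak paths.
#' @param gene_sets optional GMT path for over-representation analysis.
#' @param seed integer seed for all stochastic steps (bootstrap bands).
#' @param ... overrides for the parameter blocks `pausing`,
#'   `peaks_params`, `metaplot`, `ora`.
#' @return a named list (class `run_config`).
#' @export
run_config <- function(annotation, coverage, peaks = NULL, gene_sets = NULL,
                       seed = 1L, ...) {
  cfg <- list(
    annotation = annotation,
    coverage = coverage,
    peaks = peaks,
    gene_sets = gene_sets,
    pausing = list(promoter_up = 50L, promoter_down = 300L, body_gap = 300L,
                   pseudocount = 0.1, log2_threshold = 0.585,
                   min_activity_quantile = 0.25, flip_fc = FALSE),
    peaks_params = list(fdr_max = 0.05, min_sets = NULL,
                        overlap_rule = "any_bp", promoter_window = 2000L,
                        intersect_extent = "strict"),
    metaplot = list(upstream = 100L, downstream = 2000L, bin = 10L,
                    bootstrap = 200L),
    ora = list(alpha = 0.05),
    seed = seed
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], dots[[nm]])
    else cfg[[nm]] <- dots[[nm]]
  }
  structure(cfg, class = c("run_config", "list"))
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with the [run_config()] structure.
#' @return a `run_config` list.
#' @export
read_run_config <- function(path) {
  .assert(file.exists(path), sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  .assert(!is.null(raw$annotation) && !is.null(raw$coverage),
          "config must name `annotation` and `coverage`")
  do.call(run_config, c(
    list(annotation = raw$annotation, coverage = raw$coverage,
         peaks = raw$peaks, gene_sets = raw$gene_sets,
         seed = if (is.null(raw$seed)) 1L else raw$seed),
    raw[intersect(names(raw), c("pausing", "peaks_params", "metaplot", "ora"))]
  ))
}

#' Validate a run configuration
#'
#' Checks file existence, parameter ranges, strand-file pairing and
#' metaplot window divisibility. Problems are returned as data, not
#' thrown.
#'
#' @param config a [run_config()] list.
#' @return character vector of problems; empty when the config is valid.
#' @export
validate_run_config <- function(config) {
  probs <- character(0)
  add <- function(msg) probs <<- c(probs, msg)
  if (is.null(config$annotation)) add("missing annotation path")
  else if (!file.exists(config$annotation))
    add(sprintf("annotation file not found: %s", config$annotation))
  cov <- config$coverage
  if (is.null(cov$ctrl) || is.null(cov$treat)) {
    add("coverage must have ctrl and treat entries")
  } else {
    for (cond in c("ctrl", "treat")) {
      cc <- cov[[cond]]
      stranded <- all(c("plus", "minus") %in% names(cc))
      if (!stranded && !"unstranded" %in% names(cc))
        add(sprintf("coverage$%s must give plus+minus or unstranded paths", cond))
      for (p in unlist(cc))
        if (!file.exists(p)) add(sprintf("coverage file not found: %s", p))
    }
  }
  for (p in unlist(config$peaks))
    if (!file.exists(p)) add(sprintf("peak file not found: %s", p))
  if (!is.null(config$gene_sets) && !file.exists(config$gene_sets))
    add(sprintf("gene-set file not found: %s", config$gene_sets))
  pp <- config$peaks_params
  if (!is.null(pp$fdr_max) && (pp$fdr_max <= 0 || pp$fdr_max > 1))
    add(sprintf("peaks_params$fdr_max out of (0,1]: %s", pp$fdr_max))
  pz <- config$pausing
  for (nm in c("promoter_up", "promoter_down", "body_gap"))
    if (!is.null(pz[[nm]]) && pz[[nm]] < 0)
      add(sprintf("pausing$%s must be >= 0", nm))
  if (!is.null(pz$pseudocount) && pz$pseudocount < 0)
    add("pausing$pseudocount must be >= 0")
  if (!is.null(pz$min_activity_quantile) &&
      (pz$min_activity_quantile < 0 || pz$min_activity_quantile >= 1))
    add("pausing$min_activity_quantile must be in [0,1)")
  mp <- config$metaplot
  if (!is.null(mp$bin)) {
    span <- mp$upstream + mp$downstream
    if (span %% mp$bin != 0)
      add(sprintf("metaplot window %d not divisible by bin %d", span, mp$bin))
  }
  probs
}

#' @noRd
.read_condition_tracks <- function(cc) {
  if ("unstranded" %in% names(cc)) {
    read_coverage(cc$unstranded, "bedgraph", "*")
  } else {
    list(plus = read_coverage(cc$plus, "bedgraph", "+"),
         minus = read_coverage(cc$minus, "bedgraph", "-"))
  }
}

#' Run the pausing analysis pipeline end to end
#'
#' Stages, in order: per-assay consensus peaks, cross-assay
#' intersection, peak annotation, pausing windows, densities, PRR,
#' classification, ECDF/K-S report, TSS metaplot profiles per group, and
#' over-representation analysis (when gene sets are supplied). When peak
#' files are given, the gene universe is restricted to genes whose
#' promoter window overlaps the cross-assay consensus, mirroring the
#' multi-assay gene selection of nascent-transcription studies. All
#' outputs are TSV with provenance sidecars and a run manifest with
#' output digests; a rerun with the same config and inputs is
#' byte-identical.
#'
#' @param config a [run_config()] (or path-compatible list).
#' @param out_dir output directory, created if needed.
#' @return invisibly, a list with the main results: `prr` (data.frame),
#'   `ks` (data.frame), `consensus` (`GRanges` or `NULL`), `annotation`
#'   (data.frame or `NULL`), `profiles` (data.frame), `ora` (data.frame
#'   or `NULL`), `manifest` (list).
#' @export
run_pausing_analysis <- function(config, out_dir) {
  probs <- validate_run_config(config)
  if (length(probs))
    stop(paste(c("invalid run config:", probs), collapse = "\n  "), call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    message(sprintf("[pausekit] stage: %s", name))
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  outputs <- character(0)
  emit <- function(df, file) {
    path <- file.path(out_dir, file)
    .write_tsv(df, path)
    outputs <<- c(outputs, path)
    path
  }

  genes <- stage("read_annotation", read_annotation(config$annotation, "gtf"))
  ctrl <- stage("read_coverage", .read_condition_tracks(config$coverage$ctrl))
  treat <- stage("read_coverage", .read_condition_tracks(config$coverage$treat))

  cons <- NULL; annot <- NULL
  pp <- config$peaks_params
  if (!is.null(config$peaks) && length(config$peaks)) {
    per_assay <- stage("consensus", lapply(config$peaks, function(paths) {
      sets <- lapply(paths, read_peaks, format = "narrowpeak")
      ms <- if (is.null(pp$min_sets)) length(sets) else min(pp$min_sets, length(sets))
      consensus_peaks(sets, min_sets = ms, fdr_max = pp$fdr_max,
                      overlap_rule = pp$overlap_rule)
    }))
    cons <- stage("intersect", Reduce(function(a, b)
      intersect_assays(a, b, extent = pp$intersect_extent), per_assay))
    annot <- stage("annotate", annotate_peaks(cons, genes,
                                              promoter_window = pp$promoter_window))
    emit(annot, "peak_annotation.tsv")
    emit(data.frame(chrom = as.character(seqnames(cons)),
                    start = start(cons) - 1L, end = end(cons),
                    fdr = cons$fdr), "consensus_peaks.tsv")
    # restrict the gene universe to genes supported by the consensus
    tss <- gene_tss(genes)
    promw <- GRanges(as.character(seqnames(genes)),
                     IRanges(pmax(tss - pp$promoter_window, 1L),
                             tss + pp$promoter_window))
    keep <- overlapsAny(promw, cons, ignore.strand = TRUE)
    genes <- genes[keep]
    .assert(length(genes) > 0, "no genes overlap the consensus peak set")
  }

  pz <- config$pausing
  windows <- stage("windows", build_windows(
    genes, promoter_up = pz$promoter_up, promoter_down = pz$promoter_down,
    body_gap = pz$body_gap))
  prr <- stage("prr", prr_table(
    windows, ctrl, treat, pseudocount = pz$pseudocount,
    log2_threshold = pz$log2_threshold,
    min_activity_quantile = pz$min_activity_quantile,
    flip_fc = isTRUE(pz$flip_fc)))
  emit(prr, "prr.tsv")
  counts <- as.data.frame(table(group = prr$group), stringsAsFactors = FALSE)
  names(counts) <- c("group", "n_genes")
  emit(counts, "group_counts.tsv")

  classified <- prr[prr$group != "Excluded", , drop = FALSE]
  ks_rows <- stage("ecdf_ks", {
    groups <- list(all = classified,
                   GroupI_paused = classified[classified$group == "GroupI_paused", ],
                   GroupII_other = classified[classified$group == "GroupII_other", ])
    rows <- lapply(names(groups), function(nm) {
      g <- groups[[nm]]
      if (nrow(g) < 2) return(NULL)
      ec <- ecdf_table(g$prr_ctrl); et <- ecdf_table(g$prr_treat)
      emit(rbind(data.frame(condition = "ctrl", ec),
                 data.frame(condition = "treat", et)),
           sprintf("ecdf_prr_%s.tsv", nm))
      ks <- ks_two_sample(g$prr_treat, g$prr_ctrl)
      data.frame(comparison = sprintf("prr_treat_vs_ctrl_%s", nm),
                 ks_D = ks$statistic, p_value = ks$p_value,
                 n_a = ks$n_a, n_b = ks$n_b)
    })
    do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  })
  emit(ks_rows, "ks_report.tsv")

  mp <- config$metaplot
  profiles <- stage("metaplot", {
    rows <- list()
    for (grp in c("GroupI_paused", "GroupII_other")) {
      ids <- classified$gene_id[classified$group == grp]
      if (length(ids) < 2) next
      sub <- genes[genes$gene_id %in% ids]
      anchors <- tss_anchors(sub)
      for (cond in c("ctrl", "treat")) {
        trk <- if (cond == "ctrl") ctrl else treat
        tc <- .resolve_tracks(trk, cond)
        # sense-strand metaplot: plus-strand anchors from the plus track
        mplus <- if (any(strand(anchors) != "-"))
          matrix_at_anchors(tc$plus, anchors[strand(anchors) != "-"],
                            mp$upstream, mp$downstream, mp$bin) else NULL
        mminus <- if (any(strand(anchors) == "-"))
          matrix_at_anchors(tc$minus, anchors[strand(anchors) == "-"],
                            mp$upstream, mp$downstream, mp$bin) else NULL
        m <- if (is.null(mplus)) mminus else if (is.null(mminus)) mplus else {
          mplus$values <- rbind(mplus$values, mminus$values)
          mplus$row_ids <- c(mplus$row_ids, mminus$row_ids)
          mplus
        }
        mm_path <- file.path(out_dir, sprintf("metamatrix_%s_%s.tsv", grp, cond))
        write_meta_matrix(m, mm_path, sort_rows = TRUE)
        outputs <<- c(outputs, mm_path)
        prof <- meta_profile(m, B = mp$bootstrap,
                             seed = .substream(config$seed, 7L))
        prof$group <- grp; prof$condition <- cond
        rows[[sprintf("%s_%s", grp, cond)]] <- prof
      }
    }
    do.call(rbind, rows)
  })
  if (!is.null(profiles)) {
    rownames(profiles) <- NULL
    emit(profiles, "meta_profiles.tsv")
  }

  ora <- NULL
  if (!is.null(config$gene_sets)) {
    ora <- stage("ora", {
      sets <- read_gene_sets(config$gene_sets)
      universe <- classified$gene_id
      rows <- lapply(c("GroupI_paused", "GroupII_other"), function(grp) {
        q <- classified$gene_id[classified$group == grp]
        if (length(q) == 0) return(NULL)
        cbind(query = grp, hypergeom_ora(q, sets, universe))
      })
      do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    })
    rownames(ora) <- NULL
    emit(ora, "ora.tsv")
  }

  manifest <- list(
    package = "pausekit",
    inputs = list(annotation = config$annotation,
                  coverage = config$coverage, peaks = config$peaks,
                  gene_sets = config$gene_sets),
    params = config[c("pausing", "peaks_params", "metaplot", "ora")],
    seed = config$seed,
    outputs = as.list(stats::setNames(unname(tools::md5sum(outputs)),
                                      basename(outputs)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  for (p in outputs)
    write_provenance(p, inputs = manifest$inputs, params = manifest$params,
                     seed = config$seed)
  invisible(list(prr = prr, ks = ks_rows, consensus = cons, annotation = annot,
                 profiles = profiles, ora = ora, manifest = manifest))
}
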