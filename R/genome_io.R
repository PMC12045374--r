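#' Read a gene annotation (GTF or BED12)
#'
#' Parses gene models into a [GenomicRanges::GRanges] with a `gene_id`
#' metadata column. GTF input uses rows with feature type `"gene"` (or,
#' when none are present, the per-`gene_id` span over all rows); BED12
#' uses the `name` column as the gene id. Coordinate dialects (GTF
#' 1-based closed, BED 0-based half-open) are converted by rtracklayer.
#'
#' @param path input file path.
#' @param format `"gtf"` or `"bed12"`.
#' @return `GRanges` of genes with `mcols(x)$gene_id`.
#' @seealso [gene_tss()], [gene_tes()], [write_annotation()]
#' @export
read_annotation <- function(path, format = c("gtf", "bed12")) {
  format <- match.arg(format)
  .assert(file.exists(path), sprintf("annotation file not found: %s", path))
  gr <- tryCatch(
    rtracklayer::import(path, format = if (format == "gtf") "gtf" else "bed"),
    error = function(e) stop(sprintf("failed to parse %s as %s: %s",
                                     path, format, conditionMessage(e)),
                             call. = FALSE)
  )
  if (format == "gtf") {
    .assert(!is.null(gr$gene_id), "GTF records lack the required gene_id attribute")
    if (!is.null(gr$type) && any(gr$type == "gene")) {
      gr <- gr[gr$type == "gene"]
    } else {
      spl <- split(gr, gr$gene_id)
      rng <- unlist(range(spl))
      gr <- GRanges(seqnames(rng), ranges(rng),
                    strand = strand(rng), gene_id = names(rng))
    }
    genes <- granges(gr)
    mcols(genes)$gene_id <- as.character(gr$gene_id)
  } else {
    .assert(!is.null(gr$name), "BED12 records lack a name column for gene ids")
    genes <- granges(gr)
    mcols(genes)$gene_id <- as.character(gr$name)
  }
  .assert(all(!is.na(genes$gene_id) & nzchar(genes$gene_id)),
          "missing/empty gene_id in annotation")
  dup <- unique(genes$gene_id[duplicated(genes$gene_id)])
  if (length(dup))
    stop(sprintf("duplicate gene_id in annotation: %s",
                 paste(utils::head(dup, 5), collapse = ", ")), call. = FALSE)
  genes
}

#' Strand-aware transcription start / end sites
#'
#' The TSS is a gene's 5' end (`start` on `+`/unstranded genes, `end` on
#' `-` genes); the TES is the 3' end. Positions are 1-based reference
#' coordinates of the terminal base.
#'
#' @param genes `GRanges` of genes (as from [read_annotation()]).
#' @return integer vector of positions, one per gene.
#' @export
gene_tss <- function(genes) {
  minus <- as.character(strand(genes)) == "-"
  ifelse(minus, end(genes), start(genes))
}

#' @rdname gene_tss
#' @export
gene_tes <- function(genes) {
  minus <- as.character(strand(genes)) == "-"
  ifelse(minus, start(genes), end(genes))
}

#' Write a gene annotation as GTF
#'
#' @param genes `GRanges` with `gene_id` metadata column.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_annotation <- function(genes, path) {
  .assert(!is.null(genes$gene_id), "`genes` must carry a gene_id column")
  lines <- sprintf('%s\tpausekit\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s";',
                   as.character(seqnames(genes)), start(genes), end(genes),
                   as.character(strand(genes)), genes$gene_id)
  writeLines(lines, path)
  invisible(path)
}

#' Read a coverage track (bedGraph or bigWig)
#'
#' bedGraph intervals must be non-overlapping per chromosome and carry
#' non-negative values; the track is stored run-length encoded at base
#' resolution with exact values, and `total_signal` is the sum of
#' value x span over all intervals.
#'
#' @param path input file path.
#' @param format `"bedgraph"` or `"bigwig"`.
#' @param strand strand label for the track: `"+"`, `"-"`, or `"*"`.
#' @return a [coverage_track].
#' @export
read_coverage <- function(path, format = c("bedgraph", "bigwig"),
                          strand = c("*", "+", "-")) {
  format <- match.arg(format)
  strand <- match.arg(strand)
  .assert(file.exists(path), sprintf("coverage file not found: %s", path))
  if (format == "bedgraph" && file.size(path) == 0) {
    return(coverage_track(methods::as(list(), "RleList"), strand))
  }
  gr <- rtracklayer::import(path,
                            format = if (format == "bedgraph") "bedGraph" else "bigWig")
  .assert(all(gr$score >= 0), "negative coverage values in track")
  red <- reduce(gr, ignore.strand = TRUE)
  if (sum(as.numeric(width(red))) < sum(as.numeric(width(gr))))
    stop("overlapping intervals in coverage input (bedGraph contract violated)",
         call. = FALSE)
  sl <- seqlengths(gr)
  if (all(is.na(sl))) sl <- NULL
  cov <- coverage(gr, weight = gr$score)
  coverage_track(cov, strand, seqlengths = sl)
}

#' Write a coverage track as bedGraph
#'
#' Zero-signal runs are omitted, the usual sparse bedGraph form; reading
#' the file back reproduces the track's values exactly.
#'
#' @param track a [coverage_track].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_coverage <- function(track, path) {
  .assert(is_coverage_track(track), "`track` must be a coverage_track")
  gr <- methods::as(track$cov, "GRanges")
  gr <- gr[gr$score != 0]
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read peak calls (narrowPeak or BED6+)
#'
#' Per-peak false-discovery-rate values are taken from `fdr_column`
#' (1-based file column index) and stored on the linear scale. narrowPeak
#' q-values are -log10 scaled by convention; declare the scale explicitly
#' with `fdr_scale`. Linear-scale values outside `[0, 1]` are rejected
#' (the usual symptom of an undeclared -log10 column).
#'
#' @param path input file path.
#' @param format `"narrowpeak"` or `"bed6plus"`.
#' @param fdr_column 1-based column index holding the FDR/q-value
#'   (default 9, the narrowPeak qValue column).
#' @param fdr_scale `"neglog10"` or `"linear"`; default `"neglog10"` for
#'   narrowPeak, `"linear"` for bed6plus.
#' @return `GRanges` sorted by (chrom, start) with metadata columns
#'   `name`, `score`, `fdr`.
#' @export
read_peaks <- function(path, format = c("narrowpeak", "bed6plus"),
                       fdr_column = 9L,
                       fdr_scale = if (match.arg(format) == "narrowpeak")
                         "neglog10" else "linear") {
  format <- match.arg(format)
  fdr_scale <- match.arg(fdr_scale, c("neglog10", "linear"))
  .assert(file.exists(path), sprintf("peak file not found: %s", path))
  df <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE, comment.char = "#"),
    error = function(e) stop(sprintf("failed to parse peaks %s: %s",
                                     path, conditionMessage(e)), call. = FALSE)
  )
  need <- if (format == "narrowpeak") 10L else max(6L, fdr_column)
  .assert(ncol(df) >= need,
          sprintf("peak file has %d columns; %d required", ncol(df), need))
  .assert(fdr_column >= 4L && fdr_column <= ncol(df),
          sprintf("fdr_column %d out of range", fdr_column))
  raw <- df[[fdr_column]]
  .assert(is.numeric(raw) && all(is.finite(raw)),
          "FDR column is not numeric/finite")
  fdr <- if (fdr_scale == "neglog10") 10^(-raw) else raw
  if (any(fdr < 0 | fdr > 1))
    stop("FDR values outside [0,1] on the linear scale; was a -log10 column left undeclared?",
         call. = FALSE)
  gr <- GRanges(df[[1]], IRanges(df[[2]] + 1L, df[[3]]),
                strand = if (ncol(df) >= 6 && all(df[[6]] %in% c("+", "-", ".")))
                  sub("^\\.$", "*", df[[6]]) else "*")
  mcols(gr)$name <- as.character(df[[4]])
  mcols(gr)$score <- if (ncol(df) >= 5) as.numeric(df[[5]]) else 0
  mcols(gr)$fdr <- fdr
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Write peaks as narrowPeak
#'
#' The `fdr` column is emitted as a -log10 q-value (narrowPeak column 9).
#'
#' @param peaks `GRanges` with `fdr` (and optionally `name`, `score`)
#'   metadata columns.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_peaks <- function(peaks, path) {
  .assert(!is.null(peaks$fdr), "`peaks` must carry an fdr column")
  nm <- if (is.null(peaks$name)) sprintf("peak_%d", seq_along(peaks)) else peaks$name
  sc <- if (is.null(peaks$score)) rep(0, length(peaks)) else peaks$score
  st <- as.character(strand(peaks))
  st[st == "*"] <- "."
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s\t%s\t%s\t%s\t-1",
                   as.character(seqnames(peaks)), start(peaks) - 1L, end(peaks),
                   nm, format(sc, trim = TRUE, scientific = FALSE), st,
                   format(sc, trim = TRUE, scientific = FALSE), "-1",
                   format(-log10(pmax(peaks$fdr, 1e-300)), trim = TRUE, digits = 17))
  writeLines(lines, path)
  invisible(path)
}
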