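#' Read gene sets from a GMT file
#'
#' @param path GMT file path (set name, description, then member ids,
#'   tab-separated).
#' @return named list of character vectors of gene ids.
#' @export
read_gene_sets <- function(path) {
  .assert(file.exists(path), sprintf("gene-set file not found: %s", path))
  fgsea::gmtPathways(path)
}

#' Hypergeometric over-representation analysis
#'
#' Tests each gene set for over-representation in a query list: the
#' p-value is the upper-tail hypergeometric probability of drawing at
#' least the observed overlap when `query_size` genes are drawn without
#' replacement from a universe containing `set_size` set members.
#' Sets are intersected with the universe before testing; p-values are
#' Benjamini-Hochberg adjusted across all tested sets.
#'
#' @param query character vector of gene ids; must be a subset of
#'   `universe`.
#' @param sets named list of gene-id vectors (see [read_gene_sets()]).
#' @param universe character vector of background gene ids.
#' @param min_set_size sets with fewer in-universe members are skipped
#'   (default 1).
#' @return data.frame sorted by `adjusted_p` (ties by set name) with
#'   columns `set_name`, `overlap`, `set_size`, `query_size`,
#'   `universe_size`, `p_value`, `adjusted_p`.
#' @examples
#' hypergeom_ora(c("g1", "g2"), list(s = paste0("g", 1:5)), paste0("g", 1:10))
#' @export
hypergeom_ora <- function(query, sets, universe, min_set_size = 1L) {
  universe <- unique(as.character(universe))
  query <- unique(as.character(query))
  .assert(length(universe) > 0, "empty universe")
  .assert(length(query) > 0, "empty query")
  .assert(all(query %in% universe), "query contains genes outside the universe")
  .assert(is.list(sets) && length(sets) > 0 && !is.null(names(sets)),
          "`sets` must be a non-empty named list")
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(unique(as.character(sets[[nm]])), universe)
    m <- length(s)
    if (m < min_set_size) return(NULL)
    k <- length(intersect(query, s))
    p <- stats::phyper(k - 1, m, N - m, n, lower.tail = FALSE)
    data.frame(set_name = nm, overlap = k, set_size = m, query_size = n,
               universe_size = N, p_value = p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  .assert(length(rows) > 0, "no gene set passed min_set_size")
  out <- do.call(rbind, rows)
  out$adjusted_p <- stats::p.adjust(out$p_value, method = "BH")
  out[order(out$adjusted_p, out$p_value, out$set_name), , drop = FALSE]
}
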