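utils::globalVariables(c("offset", "lower", "upper", "group"))

#' @noRd
.assert <- function(cond, msg, call. = FALSE) {
  if (!isTRUE(cond)) stop(msg, call. = call.)
}

# Run expr under a temporary RNG seed, restoring the caller's RNG state.
#' @noRd
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Deterministic sub-stream seed derivation; keeps results independent
# across stages while everything flows from one root seed.
#' @noRd
.substream <- function(seed, stream) {
  as.integer((as.numeric(seed) * 2654435.0 + 97 * stream) %% 2147483647)
}

#' Write a provenance sidecar JSON next to an output file
#'
#' Records input paths, parameters and the seed used to produce an output,
#' so any result file can be traced back to its run.
#'
#' @param path path of the output file the sidecar describes; the sidecar
#'   is written to `paste0(path, ".prov.json")`.
#' @param inputs named list/character of input paths.
#' @param params named list of parameters.
#' @param seed integer seed (or `NULL`).
#' @return invisibly, the sidecar path.
#' @export
write_provenance <- function(path, inputs = list(), params = list(), seed = NULL) {
  side <- paste0(path, ".prov.json")
  jsonlite::write_json(
    list(output = basename(path), inputs = inputs, params = params, seed = seed),
    side, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
  )
  invisible(side)
}

# Deterministic TSV writer used for all tabular outputs.
#' @noRd
.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
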