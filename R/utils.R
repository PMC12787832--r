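# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @keywords internal
#' @noRd
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# Derive a reproducible sub-seed for a named pipeline stage from the run seed.
# Keeps every stage's RNG stream independent of the others while remaining a
# pure function of (seed, stage). Result stays inside 32-bit integer range.
derive_seed <- function(seed, stage) {
  offsets <- c(design = 11L, truth = 23L, transcript = 37L, protein = 53L,
               metabolite = 71L, network = 97L, vip = 113L, gsea = 131L,
               perm = 151L, misc = 173L)
  off <- offsets[[stage]] %||% 199L
  as.integer((as.numeric(seed) * 1000L + off) %% 2147483647)
}

# Canonicalize an undirected edge table: from < to lexicographically,
# rows sorted. Used by both node- and module-level networks so that
# deterministic runs write byte-identical artifacts.
canonical_edges <- function(from, to, extra = NULL) {
  swap <- from > to
  tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
  out <- data.frame(from = from, to = to, stringsAsFactors = FALSE)
  if (!is.null(extra)) out <- cbind(out, extra)
  out <- out[order(out$from, out$to), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a data frame as TSV
#'
#' Plain tab-separated output with a header row, no quoting and no row
#' names; `NA` is written as an empty cell so downstream readers see a
#' missing value. All pipeline artifacts go through this writer so that
#' identical inputs produce byte-identical files.
#'
#' @param x data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "")
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' @param path input file path.
#' @return data frame; empty cells become `NA`.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    na.strings = "", check.names = FALSE,
                    stringsAsFactors = FALSE)
}
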