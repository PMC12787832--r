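#' Gene-set (pathway) collections and the GMT format
#'
#' A `gene_sets` object is a named list of pathway records, each a list
#' with a `description` string and a non-empty character vector `members`.
#' This is the in-memory form of the standard GMT file
#' (`set_id<TAB>description<TAB>member1<TAB>member2...`), the format used
#' for KEGG pathway annotations throughout the package.
#'
#' @param sets named list; each element a list with `description` and
#'   `members`, or simply a character vector of members.
#' @return a `gene_sets` object.
#' @export
gene_sets <- function(sets) {
  assert_that(length(names(sets)) == length(sets) && !anyDuplicated(names(sets)),
              "set ids must be unique and named")
  sets <- lapply(sets, function(s) {
    if (is.character(s)) s <- list(description = "", members = s)
    assert_that(length(s$members) > 0, "member sets must be non-empty")
    list(description = s$description %||% "",
         members = unique(as.character(s$members)))
  })
  structure(sets, class = "gene_sets")
}

#' @export
print.gene_sets <- function(x, ...) {
  sizes <- vapply(x, function(s) length(s$members), integer(1))
  cat(sprintf("<gene_sets> %d sets, member counts %d-%d (median %.0f)\n",
              length(x), min(sizes), max(sizes), stats::median(sizes)))
  invisible(x)
}

#' Membership list of a gene-set collection
#' @param sets a [gene_sets()] object.
#' @return named list of member character vectors.
#' @export
set_members <- function(sets) lapply(unclass(sets), `[[`, "members")

#' Read / write GMT files
#'
#' @param path file path.
#' @param sets a [gene_sets()] object.
#' @return `read_gmt` returns a `gene_sets`; `write_gmt` returns `path`
#'   invisibly.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1), 1L)
  sets <- lapply(parts, function(p) {
    assert_that(length(p) >= 3, "GMT lines need id, description, >=1 member")
    list(description = p[[2]], members = p[-(1:2)])
  })
  names(sets) <- ids
  gene_sets(sets)
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(id) {
    s <- sets[[id]]
    paste(c(id, s$description, s$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# Invert a gene_sets collection into feature -> pathway ids.
membership_of <- function(sets) {
  mem <- set_members(sets)
  feat <- unlist(mem, use.names = FALSE)
  path <- rep(names(mem), lengths(mem))
  split(path, feat)
}
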