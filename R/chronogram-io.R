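#' Parse a Newick chronogram
#'
#' Reads a rooted tree with branch lengths in units of absolute time
#' (conventionally Ma) from a Newick string and validates it as a
#' chronogram: unique non-empty tip labels, a branch length on every
#' non-root edge, and no negative branch lengths. Polytomies are
#' preserved as given; no resolution is attempted.
#'
#' Parsing itself is delegated to [ape::read.tree()]; the returned object
#' is a standard `"phylo"` tree (additionally classed `"chronogram"`)
#' and can be used with any ape function.
#'
#' @param text Newick string (single tree, terminated by `;`).
#' @return An object of class `c("chronogram", "phylo")`.
#' @seealso [read_chronogram()] to read from a file, [check_ultrametric()],
#'   [crown_age()].
#' @examples
#' tr <- parse_chronogram("((A:1,B:1):1,C:2);")
#' crown_age(tr, c("A", "B"))
#' @export
parse_chronogram <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  .check_newick_syntax(text)
  tr <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("Newick parse error: ", conditionMessage(e), call. = FALSE)
  )
  if (is.null(tr)) stop("Newick parse error: no tree could be read", call. = FALSE)
  if (inherits(tr, "multiPhylo")) tr <- tr[[1L]]
  .validate_chronogram(tr)
  class(tr) <- c("chronogram", "phylo")
  tr
}

#' Read a Newick chronogram from a file
#'
#' @param file path to a Newick file containing one tree.
#' @return An object of class `c("chronogram", "phylo")`.
#' @export
read_chronogram <- function(file) {
  parse_chronogram(paste(readLines(file, warn = FALSE), collapse = ""))
}

#' Write a chronogram to Newick
#'
#' @param tree a `"phylo"` tree.
#' @param file path to write to; if `NULL`, the Newick string is returned.
#' @return The Newick string, invisibly when writing to a file.
#' @export
write_chronogram <- function(tree, file = NULL) {
  txt <- ape::write.tree(tree, digits = 12)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

## Cheap structural scan so malformed input fails with the offending
## character position rather than an opaque downstream error.
.check_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("Newick parse error: unmatched ')' at position ", i, call. = FALSE)
    }
  }
  if (depth > 0L)
    stop("Newick parse error: ", depth, " unclosed '(' (string ends at position ",
         length(chars), " without ';')", call. = FALSE)
  if (!grepl(";", text, fixed = TRUE))
    stop("Newick parse error: missing terminating ';' at position ",
         length(chars) + 1L, call. = FALSE)
  invisible(TRUE)
}

.validate_chronogram <- function(tr) {
  if (is.null(tr$tip.label) || length(tr$tip.label) < 2L)
    stop("chronogram must have at least 2 tips", call. = FALSE)
  if (anyNA(tr$tip.label) || any(!nzchar(tr$tip.label)))
    stop("all tip labels must be non-empty", call. = FALSE)
  dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
  if (length(dup))
    stop("duplicate tip labels: ", paste(dup, collapse = ", "), call. = FALSE)
  if (is.null(tr$edge.length))
    stop("chronogram has no branch lengths", call. = FALSE)
  if (anyNA(tr$edge.length))
    stop("missing branch length on ", sum(is.na(tr$edge.length)), " edge(s)",
         call. = FALSE)
  if (any(tr$edge.length < 0))
    stop("negative branch lengths are not allowed in a chronogram", call. = FALSE)
  invisible(tr)
}

## root-to-tip path lengths, in input branch-length units
.tip_depths <- function(tree) {
  d <- ape::node.depth.edgelength(tree)
  d[seq_len(ape::Ntip(tree))]
}

#' Check a tree for ultrametricity
#'
#' A chronogram produced by dating software is ultrametric up to rounding
#' of printed branch lengths. The check compares every root-to-tip path
#' length against the mean over tips: pass iff
#' `max |depth - mean| / mean <= rel_tol`.
#'
#' @param tree a `"phylo"` tree with branch lengths.
#' @param rel_tol relative tolerance; the default `1e-6` accommodates
#'   branch lengths printed with 6+ significant digits.
#' @return A list of class `"ultrametric_report"`: `pass` (logical),
#'   `max_rel_dev`, `mean_depth`, `rel_tol`.
#' @export
check_ultrametric <- function(tree, rel_tol = 1e-6) {
  stopifnot(inherits(tree, "phylo"), rel_tol >= 0)
  depths <- .tip_depths(tree)
  m <- mean(depths)
  dev <- if (m > 0) max(abs(depths - m)) / m else 0
  structure(
    list(pass = dev <= rel_tol, max_rel_dev = dev, mean_depth = m,
         rel_tol = rel_tol),
    class = "ultrametric_report"
  )
}

#' @export
print.ultrametric_report <- function(x, ...) {
  cat(sprintf(
    "ultrametricity: %s (max relative deviation %.3g, tolerance %.3g, mean depth %.6g)\n",
    if (x$pass) "PASS" else "FAIL", x$max_rel_dev, x$rel_tol, x$mean_depth))
  invisible(x)
}

#' Crown age of a clade defined by a tip set
#'
#' The crown age is the time before present of the most recent common
#' ancestor (MRCA) of the given tips. The present is taken as the mean
#' tip depth, so ages remain well defined on trees that are ultrametric
#' only up to `rel_tol`. The MRCA is defined set-theoretically and works
#' on polytomies.
#'
#' @param tree a `"phylo"` tree passing [check_ultrametric()].
#' @param tips character vector (length >= 2) of tip labels whose MRCA
#'   defines the clade.
#' @param rel_tol ultrametricity tolerance forwarded to
#'   [check_ultrametric()].
#' @return Crown age in the tree's branch-length units (Ma for a
#'   chronogram).
#' @export
crown_age <- function(tree, tips, rel_tol = 1e-6) {
  stopifnot(inherits(tree, "phylo"))
  tips <- unique(as.character(tips))
  if (length(tips) < 2L)
    stop("a clade selector needs at least 2 distinct tips", call. = FALSE)
  missing <- setdiff(tips, tree$tip.label)
  if (length(missing))
    stop("tip labels not in tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  rep <- check_ultrametric(tree, rel_tol)
  if (!rep$pass)
    stop(sprintf(
      "tree is not ultrametric at rel_tol %g (max relative deviation %.3g)",
      rel_tol, rep$max_rel_dev), call. = FALSE)
  node <- ape::getMRCA(tree, tips)
  all_depths <- ape::node.depth.edgelength(tree)
  rep$mean_depth - all_depths[node]
}

#' Read clade selectors from a delimited file
#'
#' One clade per row: a name and a comma-separated list of tip labels
#' whose MRCA defines the clade.
#'
#' @param file tab-delimited file with columns `name` and `tips`.
#' @return A data frame with columns `name` (character) and `tips`
#'   (list of character vectors).
#' @export
read_clade_selectors <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("name", "tips")
  if (!all(need %in% names(df)))
    stop("selector file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  tips <- lapply(strsplit(df$tips, ","), trimws)
  bad <- vapply(tips, length, 1L) < 2L
  if (any(bad))
    stop("selector rows with < 2 tips: ",
         paste(df$name[bad], collapse = ", "), call. = FALSE)
  data.frame(name = df$name, tips = I(tips), stringsAsFactors = FALSE)
}

#' Crown ages for a set of clade selectors
#'
#' Convenience wrapper applying [crown_age()] over a selector table, the
#' bridge from a tree + selectors to the clade table consumed by
#' [rate_table()] and [test_exceptional()] (richness must still be
#' supplied by the user: sampled tips undercount real clades).
#'
#' @param tree a `"phylo"` chronogram.
#' @param selectors data frame as returned by [read_clade_selectors()].
#' @param rel_tol ultrametricity tolerance.
#' @return data frame with columns `name`, `age_mean`.
#' @export
crown_ages <- function(tree, selectors, rel_tol = 1e-6) {
  data.frame(
    name = selectors$name,
    age_mean = vapply(selectors$tips, function(tp) crown_age(tree, tp, rel_tol), 0),
    stringsAsFactors = FALSE
  )
}
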