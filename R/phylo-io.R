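#' Parse a Newick chronogram
#'
#' Reads a rooted, strictly bifurcating, ultrametric tree with branch lengths
#' in time units (Ma). Node ages are measured backward from the present, so
#' all tips sit at age 0 and the root age equals the tree height. Trees that
#' are non-binary, missing branch lengths, or whose tips are not contemporary
#' (within tolerance) are rejected.
#'
#' @param text A Newick string.
#' @param tol_rel Relative ultrametricity tolerance: tips must be within
#'   `tol_rel * root_age` of age 0 (default `1e-6`).
#' @return An [ape::phylo] object (validated).
#' @examples
#' tr <- parse_newick("((a:1,b:1):1,c:2);")
#' root_age(tr)  # 2
#' @export
parse_newick <- function(text, tol_rel = 1e-6) {
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr)) stop("malformed Newick string")
  validate_chronogram(tr, tol_rel = tol_rel)
  tr
}

#' Write a tree to Newick
#'
#' @param tree A `phylo` object.
#' @param file Optional path; if `NULL` the Newick string is returned.
#' @param digits Number of significant digits for branch lengths.
#' @return The Newick string, invisibly when written to file.
#' @export
write_newick <- function(tree, file = NULL, digits = 15) {
  txt <- ape::write.tree(tree, digits = digits)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Validate a time-scaled bifurcating tree
#'
#' Checks that the tree is rooted and binary, that every non-root edge has a
#' nonnegative branch length, and that all tip ages are 0 within
#' `tol_rel * root_age` (ultrametricity).
#'
#' @inheritParams parse_newick
#' @param tree A `phylo` object.
#' @return The tree, invisibly; errors describe the first violated invariant.
#' @export
validate_chronogram <- function(tree, tol_rel = 1e-6) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (is.null(tree$edge.length) || length(tree$edge.length) != nrow(tree$edge))
    stop("missing branch length on a non-root edge")
  if (anyNA(tree$edge.length)) stop("missing branch length on a non-root edge")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (!ape::is.binary(tree)) stop("non-binary node: every internal node must have exactly 2 children")
  ages <- node_ages(tree)
  ra <- max(ages)
  tol <- tol_rel * max(ra, .Machine$double.eps)
  tip_ages <- ages[seq_len(ape::Ntip(tree))]
  if (any(abs(tip_ages) > tol))
    stop(sprintf("not ultrametric: tip ages differ by up to %.3g (tolerance %.3g)",
                 max(abs(tip_ages)), tol))
  invisible(tree)
}

#' Node ages of a chronogram
#'
#' Ages are in the tree's branch-length units (Ma), measured backward from
#' the present: tips at 0, root at the tree height. A branch's length equals
#' the parent age minus the child age.
#'
#' @param tree A `phylo` object with branch lengths.
#' @return Numeric vector of ages indexed by node number (tips first, then
#'   internal nodes, ape convention).
#' @export
node_ages <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  max(depth) - depth
}

#' Root age of a chronogram
#' @param tree A `phylo` object.
#' @return Root age in branch-length units (Ma).
#' @export
root_age <- function(tree) max(ape::node.depth.edgelength(tree))

#' Read a tip-to-area assignment table
#'
#' Expects two tab-separated columns, taxon label and range string over the
#' area alphabet (e.g. `"A"`, or `"AB"` for a widespread tip). A header line
#' `taxon<TAB>areas` is allowed and skipped.
#'
#' @param path Path to a TSV file, or a literal TSV string containing a tab.
#' @param aset The `area_set` whose alphabet the ranges must use.
#' @return Named character vector of range labels (class `tip_areas`).
#' @export
read_tip_areas <- function(path, aset = default_area_set()) {
  if (length(path) == 1L && !grepl("[\t\n]", path) && file.exists(path)) {
    lines <- readLines(path)
  } else {
    lines <- strsplit(paste(path, collapse = "\n"), "\n")[[1]]
  }
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && grepl("^taxon\t", lines[1], ignore.case = TRUE))
    lines <- lines[-1]
  if (!length(lines)) stop("empty tip-area table")
  parts <- strsplit(lines, "\t")
  if (any(lengths(parts) < 2L)) stop("each row needs two tab-separated columns")
  taxa <- vapply(parts, `[[`, character(1), 1L)
  ranges <- trimws(vapply(parts, `[[`, character(1), 2L))
  if (anyDuplicated(taxa)) stop("duplicate tip: ", taxa[duplicated(taxa)][1])
  range_mask(ranges, aset)  # errors on unknown letters
  tip_areas(setNames(ranges, taxa), aset)
}

#' Construct a tip-area table from a named vector
#' @param x Named character vector, tip label -> range string.
#' @param aset An `area_set`.
#' @return A `tip_areas` object.
#' @export
tip_areas <- function(x, aset = default_area_set()) {
  if (is.null(names(x)) || any(!nzchar(names(x)))) stop("tip areas must be named by taxon")
  range_mask(unname(x), aset)
  structure(as.character(x), names = names(x), aset = aset, class = "tip_areas")
}

#' Check a tip-area table against a tree
#'
#' @param tree A `phylo` object.
#' @param tips A `tip_areas` table.
#' @return Invisibly `TRUE`; errors name missing or unknown tips.
#' @export
validate_tip_areas <- function(tree, tips) {
  miss <- setdiff(tree$tip.label, names(tips))
  if (length(miss)) stop("tip missing from area table: ", paste(miss, collapse = ", "))
  extra <- setdiff(names(tips), tree$tip.label)
  if (length(extra)) stop("area table names unknown tip: ", paste(extra, collapse = ", "))
  invisible(TRUE)
}

#' Write a tip-area table to TSV
#' @param tips A `tip_areas` object.
#' @param file Output path.
#' @export
write_tip_areas <- function(tips, file) {
  writeLines(c("taxon\tareas", paste(names(tips), unname(tips), sep = "\t")), file)
  invisible(file)
}

#' Read an MCMC trace
#'
#' Parses a tab-separated log with a header row that names a log-likelihood
#' column (`lnL`, case-insensitive; `Lh` and `likelihood` are also accepted).
#' The first `burn_in` samples are flagged as discarded but retained in the
#' object.
#'
#' @param path Path to a TSV file, or a literal TSV string containing a tab.
#' @param burn_in Number of leading samples to discard (default 0).
#' @return An `mcmc_trace`: data frame of the numeric columns with attributes
#'   `burn_in` and `lnl_col`.
#' @export
read_trace <- function(path, burn_in = 0L) {
  if (length(path) == 1L && !grepl("[\t\n]", path) && file.exists(path)) {
    df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  } else {
    df <- read.table(text = path, header = TRUE, sep = "\t", check.names = FALSE)
  }
  mcmc_trace(df, burn_in = burn_in)
}

#' Construct an MCMC trace object
#' @param df Data frame of samples (one row per recorded sample).
#' @param burn_in Count of leading samples flagged as burn-in.
#' @return An `mcmc_trace`.
#' @export
mcmc_trace <- function(df, burn_in = 0L) {
  lnl_col <- grep("^(lnl|lnlik|loglik|likelihood|lh)$", names(df),
                  ignore.case = TRUE, value = TRUE)
  if (!length(lnl_col)) stop("no lnL column in trace header")
  lnl_col <- lnl_col[1]
  if (!is.numeric(df[[lnl_col]]) || anyNA(df[[lnl_col]]) || any(!is.finite(df[[lnl_col]])))
    stop("lnL column must be finite numeric")
  burn_in <- as.integer(burn_in)
  if (burn_in < 0L) stop("burn_in must be nonnegative")
  if (burn_in >= nrow(df)) stop("burn_in (", burn_in, ") leaves no usable samples of ", nrow(df))
  if (nrow(df) - burn_in < 2L) stop("need at least 2 post-burn-in samples")
  structure(df, burn_in = burn_in, lnl_col = lnl_col,
            class = c("mcmc_trace", "data.frame"))
}

#' Post-burn-in log-likelihood samples of a trace
#' @param trace An `mcmc_trace`.
#' @return Numeric vector of lnL values after burn-in.
#' @export
trace_lnl <- function(trace) {
  stopifnot(inherits(trace, "mcmc_trace"))
  x <- trace[[attr(trace, "lnl_col")]]
  b <- attr(trace, "burn_in")
  x[seq.int(b + 1L, length(x))]
}

#' Write an MCMC trace to TSV
#' @param trace An `mcmc_trace` or data frame.
#' @param file Output path.
#' @export
write_trace <- function(trace, file) {
  write.table(as.data.frame(trace), file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}
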