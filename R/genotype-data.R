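#' Construct a genotype matrix
#'
#' An n-sites x m-cells matrix of observed (or true) genotypes with an
#' explicit missing-data mask. Binary mode codes absence/presence of a
#' mutation as 0/1; ternary mode codes homozygous reference, heterozygous
#' and homozygous non-reference genotypes as 0/1/2. Missing entries are
#' stored as `NA`.
#'
#' @param values Integer matrix, sites in rows, cells in columns; `NA` marks
#'   missing entries.
#' @param mode `"binary"` or `"ternary"`.
#' @param site_ids,cell_ids Optional row/column identifiers; defaults are
#'   generated.
#' @return An object of class `genotype_matrix` with elements `values`,
#'   `mode`, `site_ids`, `cell_ids`.
#' @export
genotype_matrix <- function(values, mode = c("ternary", "binary"),
                            site_ids = NULL, cell_ids = NULL) {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  n <- nrow(values); m <- ncol(values)
  if (n < 1L || m < 2L) stop("need at least 1 site and 2 cells")
  alphabet <- mode_states(mode)
  bad <- which(!is.na(values) & !(values %in% alphabet), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("entry (%d, %d) = %s outside the %s alphabet",
                 bad[1, 1], bad[1, 2], values[bad[1, 1], bad[1, 2]], mode))
  if (is.null(site_ids)) site_ids <- rownames(values)
  if (is.null(site_ids)) site_ids <- paste0("site", seq_len(n))
  if (is.null(cell_ids)) cell_ids <- colnames(values)
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(m))
  if (anyDuplicated(cell_ids)) stop("cell_ids must be unique")
  if (length(site_ids) != n || length(cell_ids) != m) stop("id lengths do not match matrix")
  dimnames(values) <- list(site_ids, cell_ids)
  structure(list(values = values, mode = mode,
                 site_ids = as.character(site_ids),
                 cell_ids = as.character(cell_ids)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d sites x %d cells (%s), %.1f%% missing\n",
              nrow(x$values), ncol(x$values), x$mode,
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$values)

#' Missing-data mask of a genotype matrix
#' @param g A [genotype_matrix()].
#' @return Logical matrix, `TRUE` where the entry is missing.
#' @export
missing_mask <- function(g) is.na(g$values)

#' Read a genotype matrix from delimited text
#'
#' Expects rows = sites and columns = cells, a header row of cell names and
#' a first column of site ids. Entries must belong to the mode's alphabet
#' or equal `missing_token`.
#'
#' @param path File path (tab-delimited by default).
#' @param mode `"binary"` or `"ternary"`.
#' @param missing_token Token encoding missing data (default `"X"`; inputs
#'   from some pipelines use `"3"`).
#' @param sep Field separator.
#' @return A [genotype_matrix()].
#' @export
read_genotype_matrix <- function(path, mode = c("ternary", "binary"),
                                 missing_token = "X", sep = "\t") {
  mode <- match.arg(mode)
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   colClasses = "character", row.names = 1L)
  vals <- as.matrix(df)
  alphabet <- as.character(mode_states(mode))
  ok <- matrix(vals %in% c(alphabet, missing_token), nrow(vals), ncol(vals))
  bad <- which(!ok, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("entry (row %d, column %d) = '%s' is neither a %s genotype nor '%s'",
                 bad[1, 1], bad[1, 2], vals[bad[1, 1], bad[1, 2]], mode, missing_token))
  vals[vals == missing_token] <- NA
  storage.mode(vals) <- "integer"
  genotype_matrix(vals, mode = mode,
                  site_ids = rownames(df), cell_ids = colnames(df))
}

#' Write a genotype matrix to delimited text
#'
#' @param g A [genotype_matrix()].
#' @param path Output file path.
#' @inheritParams read_genotype_matrix
#' @return `path`, invisibly.
#' @export
write_genotype_matrix <- function(g, path, missing_token = "X", sep = "\t") {
  vals <- g$values
  out <- matrix(as.character(vals), nrow(vals), ncol(vals))
  out[is.na(vals)] <- missing_token
  dimnames(out) <- dimnames(vals)
  df <- data.frame(site_id = rownames(out), out, check.names = FALSE)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Binarize a ternary genotype matrix
#'
#' Heterozygous (1) and homozygous non-reference (2) genotypes both become
#' 1 (mutation present); 0 stays 0; missing stays missing.
#'
#' @param g A ternary [genotype_matrix()].
#' @return A binary [genotype_matrix()].
#' @export
binarize <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (g$mode != "ternary") stop("binarize expects a ternary matrix; input is already binary")
  vals <- g$values
  vals[!is.na(vals) & vals == 2L] <- 1L
  genotype_matrix(vals, mode = "binary", site_ids = g$site_ids, cell_ids = g$cell_ids)
}

#' Four-gamete test for infinite-sites violations
#'
#' A pair of sites (rows) violates the four-gamete condition when, among the
#' cells where both sites are observed, all four genotype combinations
#' (0,0), (0,1), (1,0), (1,1) occur. Any violating pair rules out a perfect
#' phylogeny, i.e. the data cannot have arisen under the infinite-sites
#' assumption without error. Missing entries are handled pairwise-complete:
#' a cell contributes to a pair only if both entries are observed.
#'
#' @param g A binary [genotype_matrix()] (binarize ternary data first).
#' @return A list with `violating_pairs` (count), `total_pairs`
#'   (`n * (n - 1) / 2`), and `violating_pair_list` (data frame with columns
#'   `site_i`, `site_j`).
#' @export
four_gamete_test <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (g$mode != "binary")
    stop("four_gamete_test expects a binary matrix; call binarize() first")
  v <- g$values
  n <- nrow(v)
  ones <- !is.na(v) & v == 1L
  zeros <- !is.na(v) & v == 0L
  storage.mode(ones) <- "double"; storage.mode(zeros) <- "double"
  # counts of co-observed genotype combinations for every site pair
  c11 <- tcrossprod(ones)
  c00 <- tcrossprod(zeros)
  c01 <- tcrossprod(zeros, ones)  # (i=0, j=1)
  c10 <- tcrossprod(ones, zeros)
  viol <- c11 > 0 & c00 > 0 & c01 > 0 & c10 > 0
  viol[lower.tri(viol, diag = TRUE)] <- FALSE
  idx <- which(viol, arr.ind = TRUE)
  list(violating_pairs = nrow(idx),
       total_pairs = n * (n - 1L) / 2L,
       violating_pair_list = data.frame(site_i = g$site_ids[idx[, 1]],
                                        site_j = g$site_ids[idx[, 2]],
                                        stringsAsFactors = FALSE))
}

#' Write a four-gamete report
#'
#' Tab-separated listing of violating site pairs plus a trailing summary
#' line `# violating/total`.
#'
#' @param fg Result of [four_gamete_test()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_four_gamete_report <- function(fg, path) {
  write.table(fg$violating_pair_list, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("# %d/%d\n", fg$violating_pairs, fg$total_pairs),
      file = path, append = TRUE)
  invisible(path)
}
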