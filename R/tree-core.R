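#' @importFrom ape read.tree
NULL

# children edge indices per node, as a list indexed by node number
.child_edges <- function(tree) {
  n_nodes <- length(tree$tip.label) + tree$Nnode
  out <- vector("list", n_nodes)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]
    out[[p]] <- c(out[[p]], e)
  }
  out
}

.root_node <- function(tree) length(tree$tip.label) + 1L

# tip indices descending from every node (postorder accumulation);
# works for multifurcating trees too
.tip_descendants <- function(tree) {
  ntip <- length(tree$tip.label)
  n_nodes <- ntip + tree$Nnode
  kids <- .child_edges(tree)
  desc <- vector("list", n_nodes)
  for (i in seq_len(ntip)) desc[[i]] <- i
  # process internal nodes children-first: ape post-order via depths
  ord <- integer(0)
  stack <- .root_node(tree)
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    ord <- c(ord, v)
    ch <- tree$edge[kids[[v]], 2]
    stack <- c(stack, ch[ch > ntip])
  }
  for (v in rev(ord)) desc[[v]] <- sort(unlist(desc[tree$edge[kids[[v]], 2]]))
  desc
}

#' Validate a rooted (binary) cell phylogeny
#'
#' Checks the structural invariants used throughout the package: an `ape`
#' `phylo` object that is rooted, has unique non-empty tip labels, and
#' non-negative finite branch lengths. With `binary = TRUE` every internal
#' node must have exactly two children.
#'
#' @param tree An [ape::read.tree()]-style `phylo` object.
#' @param binary Require strictly bifurcating internal nodes.
#' @return `tree`, invisibly; errors describe the violated invariant.
#' @export
validate_phylo <- function(tree, binary = TRUE) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  lab <- tree$tip.label
  if (any(!nzchar(lab))) stop("empty tip labels")
  if (anyDuplicated(lab)) stop("duplicate tip labels: ",
                               paste(unique(lab[duplicated(lab)]), collapse = ", "))
  deg <- tabulate(tree$edge[, 1], nbins = length(lab) + tree$Nnode)
  internal <- deg[(length(lab) + 1L):(length(lab) + tree$Nnode)]
  if (binary && any(internal != 2L))
    stop("non-binary internal node (", sum(internal != 2L), " node(s) with != 2 children)")
  if (!is.null(tree$edge.length)) {
    if (any(!is.finite(tree$edge.length))) stop("non-finite branch length")
    if (any(tree$edge.length < 0)) stop("negative branch length")
  }
  invisible(tree)
}

#' Parse a Newick string into a rooted phylogeny
#'
#' Thin validating layer over [ape::read.tree()]: checks parenthesis
#' balance, requires a terminal `";"`, rejects duplicate leaf labels and
#' (in strict mode) non-binary internal nodes. Missing branch lengths
#' default to 0.
#'
#' @param text A Newick string.
#' @param strict_binary Reject multifurcations (default `TRUE`; set `FALSE`
#'   for lineage-tree projections and metric-only input).
#' @return A `phylo` object.
#' @export
#' @examples
#' tr <- parse_newick("((A:0.1,B:0.2):0.3,C:0.4);")
parse_newick <- function(text, strict_binary = TRUE) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  depth <- 0L
  chars <- strsplit(text, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("unbalanced parentheses: unexpected ')' at position ", i)
    }
  }
  if (depth != 0L) stop("unbalanced parentheses: ", depth, " unclosed '('")
  if (!endsWith(text, ";")) stop("Newick string must end with ';'")
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop("could not parse Newick string")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (is.null(tree$edge.length)) tree$edge.length <- numeric(nrow(tree$edge))
  tree$edge.length[is.na(tree$edge.length)] <- 0
  validate_phylo(tree, binary = strict_binary)
  tree
}

#' Write a phylogeny as a canonical Newick string
#'
#' Deterministic output: at every internal node children are ordered by
#' their lexicographically smallest descendant leaf label; branch lengths
#' are printed with `precision` significant digits and are never omitted
#' (zero lengths print as `0.0`).
#'
#' @param tree A `phylo` object.
#' @param precision Significant digits for branch lengths.
#' @return A Newick string.
#' @export
write_newick <- function(tree, precision = 6L) {
  validate_phylo(tree, binary = FALSE)
  ntip <- length(tree$tip.label)
  kids <- .child_edges(tree)
  el <- tree$edge.length
  if (is.null(el)) el <- numeric(nrow(tree$edge))
  fmt <- function(x) {
    if (x == 0) return("0.0")
    format(signif(x, precision), scientific = FALSE, trim = TRUE)
  }
  rec <- function(node) {
    if (node <= ntip)
      return(list(str = tree$tip.label[node], min = tree$tip.label[node]))
    parts <- lapply(kids[[node]], function(e) {
      sub <- rec(tree$edge[e, 2])
      list(str = paste0(sub$str, ":", fmt(el[e])), min = sub$min)
    })
    ord <- order(vapply(parts, `[[`, "", "min"))
    list(str = paste0("(", paste(vapply(parts[ord], `[[`, "", "str"), collapse = ","), ")"),
         min = min(vapply(parts, `[[`, "", "min")))
  }
  paste0(rec(.root_node(tree))$str, ";")
}

#' Non-trivial bipartition encoding of a tree
#'
#' The set of leaf-set splits induced by the edges of the tree viewed as
#' unrooted: the two edges incident to the root induce the same split and
#' are counted once, and trivial splits (one block a single leaf) are
#' excluded. Each bipartition is represented canonically by the block
#' containing the alphabetically first leaf, with labels sorted and joined
#' by `"|"`.
#'
#' @param tree A `phylo` object (binary or not).
#' @return Character vector (a set) of canonical split keys; empty for
#'   trees with fewer than 4 leaves.
#' @export
bipartition_encoding <- function(tree) {
  validate_phylo(tree, binary = FALSE)
  labs <- tree$tip.label
  ntip <- length(labs)
  if (ntip < 4L) return(character(0))
  anchor <- labs[order(labs)][1]
  desc <- .tip_descendants(tree)
  keys <- character(0)
  for (e in seq_len(nrow(tree$edge))) {
    block <- desc[[tree$edge[e, 2]]]
    sz <- length(block)
    if (sz <= 1L || sz >= ntip - 1L) next  # trivial
    side <- labs[block]
    if (!(anchor %in% side)) side <- setdiff(labs, side)
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  sort(unique(keys))
}

#' Bipartition-based tree-distance metrics
#'
#' False-negative distance: fraction of the true tree's non-trivial
#' bipartitions absent from the inferred tree; false-positive distance:
#' fraction of the inferred tree's bipartitions absent from the true tree;
#' Robinson-Foulds distance: their average. For two binary trees on the
#' same leaves the three coincide. When an encoding is empty (fewer than 4
#' leaves) the corresponding normalized distance is defined as 0.
#'
#' @param t_true,t_inferred `phylo` objects on identical leaf sets (the
#'   inferred tree may be multifurcating, e.g. a projected lineage tree).
#' @return List with elements `fn`, `fp`, `rf`, each in \[0, 1\].
#' @export
tree_distances <- function(t_true, t_inferred) {
  lt <- t_true$tip.label; li <- t_inferred$tip.label
  if (!setequal(lt, li))
    stop("leaf sets differ: ",
         paste(c(setdiff(lt, li), setdiff(li, lt)), collapse = ", "))
  ct <- bipartition_encoding(t_true)
  ci <- bipartition_encoding(t_inferred)
  fn <- if (length(ct) == 0L) 0 else length(setdiff(ct, ci)) / length(ct)
  fp <- if (length(ci) == 0L) 0 else length(setdiff(ci, ct)) / length(ci)
  list(fn = fn, fp = fp, rf = (fn + fp) / 2)
}

#' Leaf-to-leaf path distance matrix
#'
#' Entry (i, j) is the sum of branch lengths on the unique path connecting
#' cells i and j in the tree; the input distance for clonal clustering.
#'
#' @param tree A `phylo` object with branch lengths.
#' @return An m x m symmetric matrix with zero diagonal, rows/columns
#'   named and ordered as `tree$tip.label`.
#' @export
path_distance_matrix <- function(tree) {
  validate_phylo(tree, binary = FALSE)
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label]
}

#' Project a cell-lineage tree onto a leaf phylogeny
#'
#' Lineage trees (e.g. from clonal-tree methods) place observed cells at
#' internal nodes. For bipartition-based comparison against a cell
#' phylogeny, every internal cell is projected to a pendant leaf attached
#' to its node by a zero-length branch; a projected cell is genotypically
#' identical to the ancestral node it labels. The result may be
#' multifurcating, which [tree_distances()] accepts.
#'
#' @param edges Data frame with columns `parent` and `child` (cell labels)
#'   and optionally `length` (defaults to 1 per edge).
#' @return A `phylo` object whose leaves are exactly the labelled nodes of
#'   the lineage.
#' @export
lineage_to_phylogeny <- function(edges) {
  stopifnot(is.data.frame(edges), all(c("parent", "child") %in% names(edges)))
  parent <- as.character(edges$parent)
  child <- as.character(edges$child)
  len <- if ("length" %in% names(edges)) as.numeric(edges$length) else rep(1, length(parent))
  if (anyDuplicated(child)) stop("duplicate child labels: ",
                                 paste(unique(child[duplicated(child)]), collapse = ", "))
  roots <- setdiff(parent, child)
  if (length(unique(roots)) != 1L) stop("lineage must have exactly one root")
  root <- roots[1]
  rec <- function(node) {
    idx <- which(parent == node)
    if (length(idx) == 0L) return(node)
    subs <- vapply(idx, function(i) paste0(rec(child[i]), ":", format(len[i])), "")
    # the internal cell itself becomes a zero-length pendant leaf
    paste0("(", paste(c(subs, paste0(node, ":0")), collapse = ","), ")")
  }
  body <- rec(root)
  if (!startsWith(body, "(")) stop("degenerate lineage with a single node")
  parse_newick(paste0(body, ";"), strict_binary = FALSE)
}

#' Number of rooted binary tree topologies
#'
#' The count of distinct labelled rooted bifurcating topologies on `m`
#' leaves, `(2m - 3)! / (2^(m - 2) (m - 2)!)`, i.e. the double factorial
#' `(2m - 3)!!`. Computed exactly in arbitrary precision: the result is a
#' numeric when exactly representable as a double, otherwise a decimal
#' character string.
#'
#' @param m Number of leaves, `>= 2`.
#' @return Numeric (exact) or character string of digits.
#' @export
#' @examples
#' topology_count(4)  # 15
topology_count <- function(m) {
  stopifnot(length(m) == 1L, m == as.integer(m))
  if (m < 2) stop("m must be at least 2")
  # big-integer product of odd numbers 1, 3, ..., 2m-3 in base 1e6
  digits <- 1  # little-endian base-1e6 limbs
  odds <- seq(1L, 2L * m - 3L, by = 2L)
  for (f in odds) {
    digits <- digits * f
    carry <- 0
    for (i in seq_along(digits)) {
      tot <- digits[i] + carry
      digits[i] <- tot %% 1e6
      carry <- tot %/% 1e6
    }
    while (carry > 0) {
      digits <- c(digits, carry %% 1e6)
      carry <- carry %/% 1e6
    }
  }
  str <- paste0(c(format(rev(digits)[1], scientific = FALSE),
                  sprintf("%06.0f", rev(digits)[-1])), collapse = "")
  num <- suppressWarnings(as.numeric(str))
  if (!is.na(num) && num < 2^53) num else str
}
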