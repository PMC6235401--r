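#' Parse a rooted Newick tree
#'
#' Reads a single rooted Newick expression into an [ape::phylo] object and
#' validates it for use in linkage-state reconstruction: tip names must be
#' unique and non-empty, branch lengths (when present) finite and
#' non-negative, and the expression must describe exactly one rooted tree.
#' Internal node labels (clade names such as `"montium"`) are preserved.
#'
#' Branch lengths are interpreted as millions of years (Myr) throughout the
#' package; trees without branch lengths support event counting but not rate
#' estimation (see [validate_dataset()]).
#'
#' @param text A Newick string terminated by `";"`, or a length-one path is
#'   not accepted here — use [read_tree_file()] for files.
#' @return A `phylo` object.
#' @seealso [write_newick()], [read_tree_file()]
#' @examples
#' tr <- parse_newick("(mel,(vir,((aca,nan),(imm,(afr,(bog,dav))))));")
#' ape::Ntip(tr)
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) {
    abort("empty Newick string")
  }
  if (!grepl(";\\s*$", text)) {
    abort("Newick string must be terminated by ';'")
  }
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close) {
    abort(sprintf(
      "unbalanced parentheses in Newick string (%d '(' vs %d ')')",
      n_open, n_close
    ))
  }
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) abort(paste0("Newick parse error: ", conditionMessage(e)))
  )
  if (is.null(tree) || inherits(tree, "multiPhylo")) {
    abort("expected exactly one Newick tree")
  }
  validate_phylo(tree)
  tree
}

#' Read a tree from a Newick file
#'
#' @param path Path to a file containing one rooted Newick tree.
#' @return A `phylo` object, validated as in [parse_newick()].
#' @export
read_tree_file <- function(path) {
  if (!file.exists(path)) abort(sprintf("tree file not found: '%s'", path))
  parse_newick(paste(readLines(path, warn = FALSE), collapse = ""))
}

#' Serialize a tree to Newick
#'
#' Inverse of [parse_newick()] on canonical-form trees: topology, tip and
#' internal labels, and branch lengths round-trip.
#'
#' @param tree A `phylo` object.
#' @param path Optional path; when given the string is also written to disk.
#' @return The Newick string, invisibly when `path` is given.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

# structural checks shared by all tree entry points
validate_phylo <- function(tree) {
  tips <- tree$tip.label
  if (any(!nzchar(tips))) abort("tree has empty tip names")
  dup <- unique(tips[duplicated(tips)])
  if (length(dup) > 0) {
    abort(sprintf("duplicate tip names in tree: %s", paste(dup, collapse = ", ")))
  }
  if (!is.null(tree$edge.length)) {
    bad <- !is.finite(tree$edge.length) | tree$edge.length < 0
    if (any(bad)) {
      abort(sprintf(
        "invalid branch lengths (negative or non-finite) on %d edge(s)",
        sum(bad)
      ))
    }
  }
  invisible(tree)
}

#' Does a tree carry branch lengths?
#' @param tree A `phylo` object.
#' @return `TRUE` if every edge has a finite branch length.
#' @export
has_branch_lengths <- function(tree) {
  !is.null(tree$edge.length) && all(is.finite(tree$edge.length))
}

# deterministic node identifiers: tips by name, internal nodes by label when
# present, otherwise "node_<k>" in ape numbering
node_ids <- function(tree) {
  n_tip <- ape::Ntip(tree)
  n_node <- tree$Nnode
  internal <- paste0("node_", seq_len(n_node) + n_tip)
  if (!is.null(tree$node.label)) {
    lab <- tree$node.label
    keep <- !is.na(lab) & nzchar(lab)
    internal[keep] <- lab[keep]
  }
  c(tree$tip.label, internal)
}

# postorder edge traversal with deterministic child order: ape's reorder
# gives a valid postorder; determinism of reconstructions is enforced at the
# state-choice step, not the traversal order
postorder_edges <- function(tree) {
  reorder(tree, "postorder")$edge
}

#' Find the most recent common ancestor of a set of tips
#'
#' Clades may be addressed either by internal node labels or as the MRCA of
#' a tip set; this helper supports the latter.
#'
#' @param tree A `phylo` object.
#' @param tips Character vector of tip names (length >= 1).
#' @return The ape node number of the MRCA (the tip itself for length 1).
#' @export
mrca_node <- function(tree, tips) {
  stopifnot(length(tips) >= 1)
  missing <- setdiff(tips, tree$tip.label)
  if (length(missing) > 0) {
    abort(sprintf("tips not in tree: %s", paste(missing, collapse = ", ")))
  }
  if (length(tips) == 1L) {
    return(match(tips, tree$tip.label))
  }
  ape::getMRCA(tree, tips)
}

# tip numbers of the clade rooted at `node` (ape numbering)
clade_tips <- function(tree, node) {
  n_tip <- ape::Ntip(tree)
  if (node <= n_tip) {
    return(node)
  }
  desc <- ape::extract.clade(tree, node)$tip.label
  match(desc, tree$tip.label)
}
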