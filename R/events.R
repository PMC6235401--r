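#' Classify state changes into independent evolutionary events
#'
#' Pools the per-gene change lists of a set of reconstructions (all on the
#' same tree) and merges them into independent events, branch by branch:
#'
#' * **incorporation** — on a branch where the `Y -> AX` changes comprise at
#'   least `inc_fraction` of the genes reconstructed as Y-linked in the
#'   parent node, and at least `min_genes` genes, all those changes are one
#'   whole-Y incorporation event (the entire chromosome moved, not the
#'   genes one by one).
#' * **transfer** — remaining `Y -> AX` changes are individual gene
#'   movements, except that genes listed in one declared adjacency `groups`
#'   entry that change on the same branch merge into a single transfer
#'   (physically adjacent genes move together; adjacency is external
#'   synteny evidence supplied by the user, never inferred).
#' * **genomic_loss** — `Y -> absent` changes, one event per gene.
#' * **gain** — `AX -> Y` changes (possible only outside Dollo mode), one
#'   event per gene.
#'
#' Every change belongs to exactly one event, so summing `n_genes` per
#' branch recovers the raw change count.
#'
#' @param reconstructions A list of `y_reconstruction` objects sharing one
#'   tree (as from [reconstruct_genes()]).
#' @param groups Optional list of character vectors; each vector is a set
#'   of physically adjacent genes that may move as a unit.
#' @param min_genes Minimum number of genes for an incorporation call
#'   (default 3).
#' @param inc_fraction Fraction (in `(0, 1]`) of parent-node Y-linked genes
#'   that must change on a branch for an incorporation call; 1.0 means
#'   "all", 0.9 a "nearly all" sensitivity setting.
#' @return A tibble of events: `event_id`, `parent`, `child`,
#'   `parent_label`, `child_label`, `type`, `genes` (list-column),
#'   `n_genes`.
#' @examples
#' fx <- load_fixture("fig2_ory")
#' recs <- reconstruct_genes(fx$tree, fx$matrix)
#' classify_events(recs)
#' @export
classify_events <- function(reconstructions, groups = NULL, min_genes = 3,
                            inc_fraction = 1.0) {
  if (inherits(reconstructions, "y_reconstruction")) {
    reconstructions <- list(reconstructions)
  }
  stopifnot(length(reconstructions) > 0)
  if (!(inc_fraction > 0 && inc_fraction <= 1)) {
    abort("inc_fraction must be in (0, 1]")
  }
  if (!is.null(groups)) {
    stopifnot(is.list(groups))
    flat <- unlist(groups)
    if (anyDuplicated(flat)) abort("a gene appears in more than one adjacency group")
  }

  changes <- purrr::map_dfr(reconstructions, function(r) {
    if (nrow(r$changes) == 0) return(NULL)
    mutate(r$changes, gene = r$gene)
  })
  empty <- tibble(
    event_id = integer(), parent = integer(), child = integer(),
    parent_label = character(), child_label = character(),
    type = character(), genes = list(), n_genes = integer()
  )
  if (nrow(changes) == 0) return(empty)

  # genes reconstructed Y at each node, pooled over the gene set analysed
  parent_y_count <- function(node) {
    sum(vapply(
      reconstructions,
      function(r) r$node_state[[node]] == "Y", logical(1)
    ))
  }

  events <- list()
  for (br in split(changes, changes$child)) {
    p <- br$parent[1]; ch <- br$child[1]
    pl <- br$parent_label[1]; cl <- br$child_label[1]
    yax <- br$gene[br$from == "Y" & br$to == "AX"]
    n_parent_y <- parent_y_count(p)
    if (length(yax) >= min_genes && n_parent_y > 0 &&
        length(yax) >= inc_fraction * n_parent_y) {
      events[[length(events) + 1]] <- tibble(
        parent = p, child = ch, parent_label = pl, child_label = cl,
        type = "incorporation", genes = list(sort(yax))
      )
      yax <- character()
    }
    if (length(yax) > 0) {
      taken <- character()
      for (grp in groups %||% list()) {
        hit <- sort(intersect(grp, yax))
        if (length(hit) >= 2) {
          events[[length(events) + 1]] <- tibble(
            parent = p, child = ch, parent_label = pl, child_label = cl,
            type = "transfer", genes = list(hit)
          )
          taken <- c(taken, hit)
        }
      }
      for (g in sort(setdiff(yax, taken))) {
        events[[length(events) + 1]] <- tibble(
          parent = p, child = ch, parent_label = pl, child_label = cl,
          type = "transfer", genes = list(g)
        )
      }
    }
    for (g in sort(br$gene[br$from == "Y" & br$to == "absent"])) {
      events[[length(events) + 1]] <- tibble(
        parent = p, child = ch, parent_label = pl, child_label = cl,
        type = "genomic_loss", genes = list(g)
      )
    }
    for (g in sort(br$gene[br$to == "Y" & br$from != "Y"])) {
      events[[length(events) + 1]] <- tibble(
        parent = p, child = ch, parent_label = pl, child_label = cl,
        type = "gain", genes = list(g)
      )
    }
    # AX -> absent changes (loss of an autosomal copy) are genomic losses too
    for (g in sort(br$gene[br$from == "AX" & br$to == "absent"])) {
      events[[length(events) + 1]] <- tibble(
        parent = p, child = ch, parent_label = pl, child_label = cl,
        type = "genomic_loss", genes = list(g)
      )
    }
  }

  out <- bind_rows(events) %>%
    arrange(child, type, purrr::map_chr(genes, 1)) %>%
    mutate(event_id = dplyr::row_number(), n_genes = lengths(genes)) %>%
    select(event_id, parent, child, parent_label, child_label, type, genes, n_genes)
  out
}

#' 2x2 contingency table of gene counts
#'
#' Rows are gene classes (ancestrally Y-linked, control), columns are
#' "moved to the Y" / "not moved to the Y" — i.e. whether the gene shows
#' Y-linkage in at least one species of the focal clade.
#'
#' @param a,b,c,d Non-negative integer counts: `a` = ancestral-Y genes with
#'   Y-linkage somewhere in the clade, `b` = without; `c`, `d` analogous
#'   for control genes.
#' @return A `contingency_2x2` object.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    abort("contingency counts must be non-negative integers")
  }
  if (sum(counts) == 0) abort("contingency table is empty")
  structure(
    as.list(setNames(as.integer(counts), names(counts))),
    class = "contingency_2x2"
  )
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
    dimnames = list(
      c("ancestral_Y", "control"),
      c("moved_to_Y", "not_moved")
    ))
  cat("<contingency_2x2>\n")
  print(m)
  invisible(x)
}

#' @export
as.matrix.contingency_2x2 <- function(x, ...) {
  matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
    dimnames = list(
      c("ancestral_Y", "control"),
      c("moved_to_Y", "not_moved")
    ))
}

#' Build the gene "re-acquisition" table for a focal clade
#'
#' For each gene, asks whether it is Y-linked (`M`) in at least one species
#' of the supplied matrix (typically restricted to a focal clade such as
#' the *montium* subgroup). Ancestrally Y-linked genes re-appearing on the
#' Y versus control genes never acquired by the Y is the signature of the
#' duplicated-Y model, as opposed to a generally elevated gain rate.
#'
#' @param matrix A `linkage_matrix` restricted to the focal clade (a
#'   clade-summary matrix with one row also works).
#' @param labels A [gene_class_labels()] object; label sets must be
#'   disjoint and contained in the matrix genes.
#' @return A [contingency_2x2()]: rows ancestral-Y / control, columns
#'   moved-to-Y / not.
#' @examples
#' fx <- load_fixture("montium_partial")
#' reacquisition_table(fx$summary, fx$labels)
#' @export
reacquisition_table <- function(matrix, labels) {
  stopifnot(inherits(matrix, "linkage_matrix"), inherits(labels, "gene_class_labels"))
  if (nrow(matrix) < 1) abort("focal clade has no species")
  if (length(labels$ancestral_Y) == 0 && length(labels$control) == 0) {
    abort("gene class labels are empty")
  }
  missing <- setdiff(c(labels$ancestral_Y, labels$control), linkage_genes(matrix))
  if (length(missing) > 0) {
    abort(sprintf("labelled genes not in matrix: %s", paste(missing, collapse = ", ")))
  }
  has_m <- function(g) any(matrix[[g]] == "M", na.rm = TRUE)
  a <- sum(vapply(labels$ancestral_Y, has_m, logical(1)))
  c_ <- sum(vapply(labels$control, has_m, logical(1)))
  contingency_2x2(
    a, length(labels$ancestral_Y) - a,
    c_, length(labels$control) - c_
  )
}
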