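#' Parsimony reconstruction of ancestral linkage states for one gene
#'
#' Minimum-cost (Sankoff) ancestral-state assignment over the states `Y`,
#' `AX`, `absent` under a [cost_model()]. The minimum cost is the global
#' optimum over all internal assignments; among co-optimal assignments one
#' is chosen deterministically by delayed transformation: at each node the
#' parent's state is preferred when tied (changes are pushed toward the
#' tips), remaining ties broken in the fixed state order `Y`, `AX`,
#' `absent`.
#'
#' Tip constraints come from the observation model: `M` maps to `Y`, `MF`
#' to `AX`, clade-confirmed `F` to `absent`, and `NA` tips (or tips absent
#' from the data) are free variables in the minimisation, equivalent to
#' pruning them.
#'
#' @param tree A rooted `phylo` object.
#' @param tip_states Named character vector over (a subset of) tip names
#'   with values in `"Y"`, `"AX"`, `"absent"`, or `NA` (free).
#' @param cost A [cost_model()].
#' @param gene Gene name carried through to the result (default `"gene"`).
#' @return A `y_reconstruction`: list with `gene`, `min_cost`, `node_state`
#'   (character vector indexed by ape node number, named with node ids),
#'   `changes` (tibble: `parent`, `child`, `parent_label`, `child_label`,
#'   `from`, `to`, `cost`), and the `cost_model` used.
#' @examples
#' fx <- load_fixture("fig2_ory")
#' st <- linkage_to_tip_states(fx$matrix, "ORY")
#' rec <- sankoff_reconstruct(fx$tree, st, cost_model("dollo", root_state = "Y"))
#' rec$min_cost
#' @export
sankoff_reconstruct <- function(tree, tip_states, cost, gene = "gene") {
  stopifnot(inherits(tree, "phylo"), inherits(cost, "cost_model"))
  n_tip <- ape::Ntip(tree)
  n_nodes <- n_tip + tree$Nnode
  allowed <- tip_allowed_matrix(tree, tip_states)
  if (all(rowSums(allowed[seq_len(n_tip), , drop = FALSE]) == 3L)) {
    abort(sprintf("gene '%s' uninformative: all tips NA", gene))
  }

  mat <- cost$mat
  # down-pass: S[node, s] = min cost of the subtree rooted at node given
  # node is in state s
  S <- matrix(0, n_nodes, 3)
  S[seq_len(n_tip), ][!allowed[seq_len(n_tip), ]] <- Inf
  po <- postorder_edges(tree)
  for (i in seq_len(nrow(po))) {
    p <- po[i, 1]; ch <- po[i, 2]
    sc <- S[ch, ]
    S[p, ] <- S[p, ] + pmin(mat[, 1] + sc[1], mat[, 2] + sc[2], mat[, 3] + sc[3])
  }

  root <- n_tip + 1L
  root_allowed <- rep(TRUE, 3)
  if (cost$root_state != "free") {
    root_allowed <- .ANC_STATES == cost$root_state
  }
  root_costs <- ifelse(root_allowed, S[root, ], Inf)
  min_cost <- min(root_costs)
  if (!is.finite(min_cost)) {
    abort(sprintf(
      "gene '%s': no feasible ancestral assignment under this cost model (root '%s'); data would require a forbidden change",
      gene, cost$root_state
    ))
  }

  # up-pass with delayed transformation: prefer the parent's state on ties
  state_idx <- integer(n_nodes)
  state_idx[root] <- which(root_costs <= min_cost + 1e-9)[1]
  pre <- po[rev(seq_len(nrow(po))), , drop = FALSE]
  for (i in seq_len(nrow(pre))) {
    p <- pre[i, 1]; ch <- pre[i, 2]
    ps <- state_idx[p]
    tot <- mat[ps, ] + S[ch, ]
    best <- min(tot)
    cand <- which(tot <= best + 1e-9)
    state_idx[ch] <- if (ps %in% cand) ps else cand[1]
  }

  ids <- node_ids(tree)
  node_state <- setNames(.ANC_STATES[state_idx], ids)
  ed <- tree$edge
  from <- .ANC_STATES[state_idx[ed[, 1]]]
  to <- .ANC_STATES[state_idx[ed[, 2]]]
  chg <- which(from != to)
  chg_from <- from[chg]
  chg_to <- to[chg]
  changes <- tibble(
    parent = ed[chg, 1], child = ed[chg, 2],
    parent_label = ids[ed[chg, 1]], child_label = ids[ed[chg, 2]],
    from = chg_from, to = chg_to,
    cost = mat[cbind(match(chg_from, .ANC_STATES), match(chg_to, .ANC_STATES))]
  )
  changes <- arrange(changes, child)
  stopifnot(abs(sum(changes$cost) - min_cost) < 1e-6)

  structure(
    list(
      gene = gene, min_cost = unname(min_cost), node_state = node_state,
      changes = changes, cost_model = cost, tree = tree
    ),
    class = "y_reconstruction"
  )
}

#' @export
print.y_reconstruction <- function(x, ...) {
  cat(sprintf(
    "<y_reconstruction> gene=%s mode=%s min_cost=%g changes=%d\n",
    x$gene, x$cost_model$mode, x$min_cost, nrow(x$changes)
  ))
  if (nrow(x$changes) > 0) print(x$changes)
  invisible(x)
}

# allowed-state indicator matrix for every node; internal nodes fully free
tip_allowed_matrix <- function(tree, tip_states) {
  n_tip <- ape::Ntip(tree)
  n_nodes <- n_tip + tree$Nnode
  allowed <- matrix(TRUE, n_nodes, 3, dimnames = list(NULL, .ANC_STATES))
  if (length(tip_states) > 0) {
    unknown <- setdiff(names(tip_states), tree$tip.label)
    if (length(unknown) > 0) {
      abort(sprintf("tip states given for non-tips: %s", paste(unknown, collapse = ", ")))
    }
    bad <- !is.na(tip_states) & !tip_states %in% .ANC_STATES
    if (any(bad)) {
      abort(sprintf(
        "invalid ancestral tip state(s): %s (expected Y/AX/absent/NA)",
        paste(unique(tip_states[bad]), collapse = ", ")
      ))
    }
    for (tip in names(tip_states)) {
      s <- tip_states[[tip]]
      if (!is.na(s)) {
        allowed[match(tip, tree$tip.label), ] <- .ANC_STATES == s
      }
    }
  }
  allowed
}

#' Map one gene column of a linkage matrix to ancestral tip states
#'
#' Observation codes map as `M -> Y` and `MF -> AX`. An `F` (PCR failed in
#' both sexes) is only treated as a genomic absence when corroborated —
#' by default when the gene shows `F` in at least `f_min_species` species,
#' or when the gene is listed in `confirmed_absent`; otherwise `F` is
#' conservatively treated as `NA` (assay failure).
#'
#' @param matrix A `linkage_matrix`.
#' @param gene Gene column name.
#' @param f_min_species Minimum number of `F` species for `F` to count as
#'   `absent` (default 2).
#' @param confirmed_absent Character vector of genes whose `F` calls are
#'   externally confirmed genomic losses.
#' @return Named character vector of tip states (`Y`/`AX`/`absent`/`NA`).
#' @export
linkage_to_tip_states <- function(matrix, gene, f_min_species = 2,
                                  confirmed_absent = character()) {
  stopifnot(inherits(matrix, "linkage_matrix"))
  if (!gene %in% linkage_genes(matrix)) {
    abort(sprintf("gene '%s' not in linkage matrix", gene))
  }
  obs <- matrix[[gene]]
  n_f <- sum(obs == "F", na.rm = TRUE)
  f_is_absent <- gene %in% confirmed_absent || n_f >= f_min_species
  out <- dplyr::case_when(
    is.na(obs) ~ NA_character_,
    obs == "M" ~ "Y",
    obs == "MF" ~ "AX",
    obs == "F" & f_is_absent ~ "absent",
    TRUE ~ NA_character_
  )
  setNames(out, matrix$species)
}

#' Reconstruct every gene of a linkage matrix
#'
#' @inheritParams sankoff_reconstruct
#' @inheritParams linkage_to_tip_states
#' @param matrix A `linkage_matrix`; species must be tips of `tree`.
#' @param genes Genes to reconstruct (default: all columns with at least
#'   one non-`NA` state).
#' @return Named list of `y_reconstruction` objects.
#' @export
reconstruct_genes <- function(tree, matrix, cost = cost_model("dollo", root_state = "Y"),
                              genes = NULL, f_min_species = 2,
                              confirmed_absent = character()) {
  rep_ok <- validate_dataset(tree, matrix)
  if (!is_valid(rep_ok)) {
    abort(paste0("invalid dataset: ", paste(rep_ok$errors, collapse = "; ")))
  }
  if (is.null(genes)) {
    genes <- linkage_genes(matrix)
    genes <- genes[vapply(genes, function(g) any(!is.na(matrix[[g]])), logical(1))]
  }
  out <- lapply(genes, function(g) {
    sankoff_reconstruct(
      tree,
      linkage_to_tip_states(matrix, g,
        f_min_species = f_min_species,
        confirmed_absent = confirmed_absent
      ),
      cost, gene = g
    )
  })
  setNames(out, genes)
}

#' Exhaustive minimum-cost oracle
#'
#' Enumerates every assignment of states to internal nodes (and to free
#' tips) and returns the minimum total cost. Exponential in tree size, so
#' it refuses trees with more than 14 tips; intended as an independent
#' check of [sankoff_reconstruct()].
#'
#' @inheritParams sankoff_reconstruct
#' @return The exhaustive minimum cost (may be `Inf` when the data are
#'   infeasible under the cost model).
#' @export
brute_force_min_cost <- function(tree, tip_states, cost) {
  stopifnot(inherits(tree, "phylo"), inherits(cost, "cost_model"))
  n_tip <- ape::Ntip(tree)
  if (n_tip > 14) abort("brute force refused: more than 14 tips")
  n_nodes <- n_tip + tree$Nnode
  allowed <- tip_allowed_matrix(tree, tip_states)
  root <- n_tip + 1L
  if (cost$root_state != "free") {
    allowed[root, ] <- allowed[root, ] & (.ANC_STATES == cost$root_state)
  }

  # a fully-free tip always matches its parent at zero cost (the diagonal
  # is 0), so it can be dropped from the enumeration exactly
  free_tip <- rep(FALSE, n_nodes)
  free_tip[seq_len(n_tip)] <- rowSums(allowed[seq_len(n_tip), , drop = FALSE]) == 3L
  choice_sets <- lapply(seq_len(n_nodes), function(i) {
    if (free_tip[i]) 1L else which(allowed[i, ])
  })
  sizes <- lengths(choice_sets)
  n_comb <- prod(sizes)
  if (n_comb > 3^13) abort("brute force refused: assignment space too large")

  # mixed-radix enumeration of all state assignments, one column per node
  idx <- seq_len(n_comb) - 1L
  assign_mat <- matrix(0L, n_comb, n_nodes)
  radix <- 1
  for (j in seq_len(n_nodes)) {
    digit <- (idx %/% radix) %% sizes[j]
    assign_mat[, j] <- choice_sets[[j]][digit + 1L]
    radix <- radix * sizes[j]
  }

  total <- numeric(n_comb)
  ed <- tree$edge
  for (e in seq_len(nrow(ed))) {
    if (free_tip[ed[e, 2]]) next
    total <- total + cost$mat[cbind(assign_mat[, ed[e, 1]], assign_mat[, ed[e, 2]])]
  }
  min(total)
}
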