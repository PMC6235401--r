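#' Simulation configuration for the duplicated-Y model
#'
#' Bundles the per-gene and per-lineage rates of the forward model. All
#' rates are per Myr. Genes start at the root either on the Y (`"Y"`) or
#' autosomal/X (`"AX"`). The duplicated-Y mechanism: an incorporation event
#' duplicates every currently Y-only gene (the free Y survives alongside
#' the new autosomal/X copy); each redundant gene then resolves
#' independently at rate `rho_resolution`, keeping the Y copy with
#' probability `pi_keep_Y` and the autosomal/X copy otherwise. Random
#' one-per-gene resolution is what makes formerly Y-linked genes appear to
#' "re-acquire" Y-linkage in some descendants while related species lose it
#' entirely.
#'
#' @param genes Character vector of gene names, or a data frame with
#'   columns `gene` and `initial` (`"Y"`/`"AX"`); a bare character vector
#'   starts every gene on the Y.
#' @param lambda_transfer Y-to-autosome/X movement rate per Y-only gene.
#' @param lambda_genomic_loss Genomic loss rate per Y-only gene.
#' @param lambda_gain Gain rate per AX-only gene (default 0; gains are
#'   biased in PCR surveys and are off by default).
#' @param mu_incorporation Whole-Y incorporation rate per lineage (fires
#'   only while at least one gene is Y-only).
#' @param rho_resolution Resolution rate per redundant gene.
#' @param pi_keep_Y Probability a resolution keeps the Y copy.
#' @param pcr_fail_prob Per-cell probability that the assay fails and the
#'   observation is masked to `NA` (distinct from genomic `F`).
#' @param seed Integer seed; mandatory, so every simulated dataset is
#'   reproducible.
#' @param forced_events Optional tibble of deterministic events with
#'   columns `child` (node id or label identifying the branch above that
#'   node), `time` (Myr from the start of the branch) and `type`
#'   (`"incorporation"`, or `"transfer"`/`"genomic_loss"`/`"gain"` with a
#'   `gene` column). Used to build fixed scenarios (e.g. one incorporation
#'   on a named clade stem).
#' @return A `sim_config` list.
#' @export
sim_config <- function(genes,
                       lambda_transfer = 0.001,
                       lambda_genomic_loss = 0.0001,
                       lambda_gain = 0,
                       mu_incorporation = 0,
                       rho_resolution = 0,
                       pi_keep_Y = 0.5,
                       pcr_fail_prob = 0,
                       seed,
                       forced_events = NULL) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    abort("sim_config requires an explicit integer seed")
  }
  if (is.character(genes)) {
    genes <- tibble(gene = genes, initial = "Y")
  }
  genes <- as_tibble(genes)
  stopifnot(all(c("gene", "initial") %in% names(genes)))
  if (anyDuplicated(genes$gene)) abort("duplicate gene names in config")
  if (!all(genes$initial %in% c("Y", "AX"))) {
    abort("initial gene locations must be 'Y' or 'AX'")
  }
  rates <- c(lambda_transfer, lambda_genomic_loss, lambda_gain,
             mu_incorporation, rho_resolution)
  if (any(rates < 0) || any(is.na(rates))) abort("rates must be >= 0")
  if (!(pi_keep_Y >= 0 && pi_keep_Y <= 1)) abort("pi_keep_Y must be in [0, 1]")
  if (!(pcr_fail_prob >= 0 && pcr_fail_prob < 1)) {
    abort("pcr_fail_prob must be in [0, 1)")
  }
  if (!is.null(forced_events)) {
    forced_events <- as_tibble(forced_events)
    stopifnot(all(c("child", "time", "type") %in% names(forced_events)))
  }
  structure(
    list(
      genes = genes,
      lambda_transfer = lambda_transfer,
      lambda_genomic_loss = lambda_genomic_loss,
      lambda_gain = lambda_gain,
      mu_incorporation = mu_incorporation,
      rho_resolution = rho_resolution,
      pi_keep_Y = pi_keep_Y,
      pcr_fail_prob = pcr_fail_prob,
      seed = as.integer(seed),
      forced_events = forced_events
    ),
    class = "sim_config"
  )
}

#' Simulate a pure-birth (Yule) tree
#'
#' Starts from the root split (two lineages at time 0); while fewer than
#' `n_tips` lineages exist, waits an exponential time with rate
#' `k * birth_rate` (`k` = current lineage count) and splits a uniformly
#' chosen lineage. After the `n_tips`-th lineage appears the tree is
#' extended by a final `Exp(n_tips * birth_rate)` overhang, so the expected
#' crown age is `sum(1 / (k * birth_rate))` for `k = 2 .. n_tips`. Branch
#' lengths are in Myr. Tips are labelled `s1 .. sn`.
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth_rate Speciation rate per lineage per Myr (> 0).
#' @param seed Optional integer seed; when `NULL` the current RNG stream
#'   is used (so callers managing their own seed get reproducibility).
#' @return A `phylo` object.
#' @examples
#' tr <- simulate_tree(8, 0.1, seed = 1)
#' ape::Ntip(tr)
#' @export
simulate_tree <- function(n_tips, birth_rate, seed = NULL) {
  if (n_tips < 2 || n_tips != round(n_tips)) abort("n_tips must be an integer >= 2")
  if (birth_rate <= 0) abort("birth_rate must be > 0")
  if (!is.null(seed)) set.seed(as.integer(seed))

  n_internal <- n_tips - 1L
  n_nodes <- n_tips + n_internal
  parent <- integer(0); child <- integer(0); elen <- numeric(0)

  # active lineages: parent internal node (final numbering) + start time
  next_internal <- n_tips + 1L
  act_parent <- c(next_internal, next_internal)
  act_start <- c(0, 0)
  next_internal <- next_internal + 1L
  t <- 0
  k <- 2L
  next_tip <- 1L
  while (k < n_tips) {
    t <- t + rexp(1, k * birth_rate)
    i <- sample.int(k, 1L)
    # the chosen lineage becomes an internal node
    parent <- c(parent, act_parent[i])
    child <- c(child, next_internal)
    elen <- c(elen, t - act_start[i])
    act_parent[i] <- next_internal
    act_start[i] <- t
    act_parent <- c(act_parent, next_internal)
    act_start <- c(act_start, t)
    next_internal <- next_internal + 1L
    k <- k + 1L
  }
  t_end <- t + rexp(1, n_tips * birth_rate)
  for (i in seq_len(k)) {
    parent <- c(parent, act_parent[i])
    child <- c(child, next_tip)
    elen <- c(elen, t_end - act_start[i])
    next_tip <- next_tip + 1L
  }

  tree <- structure(
    list(
      edge = cbind(parent, child, deparse.level = 0),
      edge.length = elen,
      tip.label = paste0("s", seq_len(n_tips)),
      Nnode = n_internal
    ),
    class = "phylo", order = "cladewise"
  )
  tree <- reorder(ape::read.tree(text = ape::write.tree(tree)), "cladewise")
  validate_phylo(tree)
  tree
}

#' Forward-simulate Y-linked gene content down a tree
#'
#' Continuous-time (Gillespie) simulation in pre-order over branches:
#' per-gene transfers, genomic losses and (optionally) gains are Poisson
#' processes on Y-only / AX-only genes; whole-Y incorporation is a
#' lineage-level Poisson process that duplicates every Y-only gene; each
#' redundant gene resolves independently at `rho_resolution`, keeping the
#' Y copy with probability `pi_keep_Y`. Random-number consumption order is
#' fixed (pre-order branches, genes in input order), so a seed fully
#' determines the outcome.
#'
#' @param tree A `phylo` with branch lengths (Myr).
#' @param config A [sim_config()].
#' @return A list: `truth` (a `genotype_matrix`: logical species x gene
#'   matrices `has_Y`, `has_AX`) and `events` (tibble: `parent`, `child`,
#'   `child_label`, `time`, `type`, `gene`, `forced`).
#' @export
simulate_gene_content <- function(tree, config) {
  stopifnot(inherits(tree, "phylo"), inherits(config, "sim_config"))
  if (!has_branch_lengths(tree)) abort("simulation requires branch lengths")
  set.seed(config$seed)
  simulate_gene_content_impl(tree, config)
}

# same machinery without touching the seed; used internally when the
# caller manages the RNG stream
simulate_gene_content_impl <- function(tree, config) {
  genes <- config$genes$gene
  G <- length(genes)
  n_tip <- ape::Ntip(tree)
  n_nodes <- n_tip + tree$Nnode
  ids <- node_ids(tree)

  forced <- config$forced_events
  if (!is.null(forced)) {
    chn <- forced$child
    num <- suppressWarnings(as.integer(chn))
    resolved <- ifelse(is.na(num), match(chn, ids), num)
    if (any(is.na(resolved))) {
      abort(sprintf(
        "forced_events: unknown branch child node(s): %s",
        paste(chn[is.na(resolved)], collapse = ", ")
      ))
    }
    forced$child <- resolved
  }

  has_Y <- matrix(FALSE, n_nodes, G, dimnames = list(NULL, genes))
  has_AX <- matrix(FALSE, n_nodes, G, dimnames = list(NULL, genes))
  root <- n_tip + 1L
  has_Y[root, ] <- config$genes$initial == "Y"
  has_AX[root, ] <- config$genes$initial == "AX"

  pre_tree <- reorder(tree, "cladewise")   # pre-order traversal
  ed <- pre_tree$edge
  lens <- pre_tree$edge.length
  log_rows <- list()

  apply_event <- function(state, type, gene_idx) {
    switch(type,
      transfer = { state$Y[gene_idx] <- FALSE; state$AX[gene_idx] <- TRUE },
      genomic_loss = { state$Y[gene_idx] <- FALSE },
      gain = { state$AX[gene_idx] <- FALSE; state$Y[gene_idx] <- TRUE },
      incorporation = {
        y_only <- state$Y & !state$AX
        state$AX[y_only] <- TRUE
      },
      resolution = {
        if (runif(1) < config$pi_keep_Y) state$AX[gene_idx] <- FALSE
        else state$Y[gene_idx] <- FALSE
      },
      abort(sprintf("unknown event type '%s'", type))
    )
    state
  }

  for (e in seq_along(lens)) {
    p <- ed[e, 1]; ch <- ed[e, 2]; len <- lens[e]
    state <- list(Y = has_Y[p, ], AX = has_AX[p, ])

    fq <- if (is.null(forced)) NULL else forced[forced$child == ch, , drop = FALSE]
    fq <- if (!is.null(fq) && nrow(fq) > 0) fq[order(fq$time), , drop = FALSE] else NULL
    f_i <- 1L
    t_now <- 0
    repeat {
      y_only <- which(state$Y & !state$AX)
      ax_only <- which(state$AX & !state$Y)
      redundant <- which(state$Y & state$AX)
      r_transfer <- config$lambda_transfer * length(y_only)
      r_loss <- config$lambda_genomic_loss * length(y_only)
      r_gain <- config$lambda_gain * length(ax_only)
      r_inc <- if (length(y_only) > 0) config$mu_incorporation else 0
      r_res <- config$rho_resolution * length(redundant)
      total <- r_transfer + r_loss + r_gain + r_inc + r_res

      t_next <- if (total > 0) t_now + rexp(1, total) else Inf
      t_forced <- if (!is.null(fq) && f_i <= nrow(fq)) fq$time[f_i] else Inf

      if (t_forced <= t_next && t_forced <= len) {
        type <- fq$type[f_i]
        gene_idx <- if ("gene" %in% names(fq) && !is.na(fq$gene[f_i])) {
          match(fq$gene[f_i], genes)
        } else NA_integer_
        affected <- if (type == "incorporation") genes[state$Y & !state$AX] else genes[gene_idx]
        state <- apply_event(state, type, gene_idx)
        log_rows[[length(log_rows) + 1]] <- tibble(
          parent = p, child = ch, child_label = ids[ch],
          time = t_forced, type = type,
          gene = list(affected), forced = TRUE
        )
        t_now <- t_forced
        f_i <- f_i + 1L
        next
      }
      if (t_next > len) break
      t_now <- t_next
      u <- runif(1) * total
      pick <- function(pool, offset, per_rate) {
        pos <- ceiling((u - offset) / per_rate)
        pool[min(length(pool), max(1L, pos))]
      }
      if (u < r_transfer) {
        type <- "transfer"
        gi <- pick(y_only, 0, config$lambda_transfer)
      } else if (u < r_transfer + r_loss) {
        type <- "genomic_loss"
        gi <- pick(y_only, r_transfer, config$lambda_genomic_loss)
      } else if (u < r_transfer + r_loss + r_gain) {
        type <- "gain"
        gi <- pick(ax_only, r_transfer + r_loss, config$lambda_gain)
      } else if (u < r_transfer + r_loss + r_gain + r_inc) {
        type <- "incorporation"
        gi <- NA_integer_
      } else {
        type <- "resolution"
        gi <- pick(redundant, r_transfer + r_loss + r_gain + r_inc,
                   config$rho_resolution)
      }
      affected <- if (type == "incorporation") genes[state$Y & !state$AX] else genes[gi]
      state <- apply_event(state, type, gi)
      log_rows[[length(log_rows) + 1]] <- tibble(
        parent = p, child = ch, child_label = ids[ch],
        time = t_now, type = type, gene = list(affected), forced = FALSE
      )
    }
    has_Y[ch, ] <- state$Y
    has_AX[ch, ] <- state$AX
  }

  events <- if (length(log_rows) > 0) bind_rows(log_rows) else tibble(
    parent = integer(), child = integer(), child_label = character(),
    time = numeric(), type = character(), gene = list(), forced = logical()
  )
  truth <- structure(
    list(
      has_Y = has_Y[seq_len(n_tip), , drop = FALSE],
      has_AX = has_AX[seq_len(n_tip), , drop = FALSE],
      species = tree$tip.label,
      genes = genes
    ),
    class = "genotype_matrix"
  )
  rownames(truth$has_Y) <- rownames(truth$has_AX) <- tree$tip.label
  list(truth = truth, events = events)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<genotype_matrix> %d species x %d genes (truth before observation)\n",
    length(x$species), length(x$genes)
  ))
  invisible(x)
}

#' Observe a simulated genotype through the PCR assay
#'
#' The male/female PCR design sees: `M` when a species has only the Y copy,
#' `MF` when it has an autosomal/X copy (a surviving redundant Y copy is
#' invisible behind it — which is why "re-acquired" Y-linkage surfaces
#' only after the autosomal copy is lost), `F` when no copy remains.
#' Independently, each cell is masked to `NA` with probability
#' `pcr_fail_prob` (assay failure, distinct from genomic `F`).
#'
#' @param truth A `genotype_matrix` from [simulate_gene_content()].
#' @param pcr_fail_prob Per-cell masking probability in `[0, 1)`.
#' @param seed Optional integer seed for the masking draws.
#' @return A [linkage_matrix()].
#' @export
observe_pcr <- function(truth, pcr_fail_prob = 0, seed = NULL) {
  stopifnot(inherits(truth, "genotype_matrix"))
  if (!(pcr_fail_prob >= 0 && pcr_fail_prob < 1)) {
    abort("pcr_fail_prob must be in [0, 1)")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  state <- ifelse(truth$has_AX, "MF", ifelse(truth$has_Y, "M", "F"))
  if (pcr_fail_prob > 0) {
    mask <- matrix(
      runif(length(state)) < pcr_fail_prob,
      nrow = nrow(state)
    )
    state[mask] <- NA_character_
  }
  df <- as_tibble(as.data.frame(state, stringsAsFactors = FALSE))
  names(df) <- truth$genes
  df <- dplyr::bind_cols(tibble(species = truth$species), df)
  linkage_matrix(df)
}
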