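#' Run the full gene-movement analysis
#'
#' End-to-end orchestration: validate the dataset, reconstruct every
#' informative gene by parsimony, classify changes into independent
#' events, and — when branch lengths are present — estimate the per-gene
#' loss rate (transfers + genomic losses per gene-Myr at risk) and the
#' whole-Y incorporation rate (incorporations per Myr of tree). When gene
#' class labels are given, the re-acquisition table and its two-tailed
#' Fisher exact test are included.
#'
#' @param tree A `phylo`, or a path to a Newick file.
#' @param matrix A `linkage_matrix`, or a path to a TSV/CSV matrix.
#' @param labels Optional [gene_class_labels()] (or path to a labels TSV).
#' @param groups Optional list of adjacency groups (character vectors of
#'   gene names), see [classify_events()].
#' @param mode,root_state Cost model settings, see [cost_model()].
#' @param min_genes,inc_fraction Incorporation call settings.
#' @param f_min_species,confirmed_absent `F`-to-absent policy, see
#'   [linkage_to_tip_states()].
#' @param event_branch Exposure convention, see [exposure()].
#' @param conf Confidence level for rate CIs.
#' @param reacq_matrix Optional `linkage_matrix` to use for the
#'   re-acquisition table instead of `matrix` (e.g. a clade-summary
#'   matrix).
#' @return A `y_analysis` object: list with `summary`, `reconstructions`,
#'   `events`, `loss_rate`, `incorporation_rate`, `reacquisition`,
#'   `validation`, `provenance`.
#' @examples
#' fx <- load_fixture("fig2_ory")
#' an <- infer_gene_movements(fx$tree, fx$matrix)
#' an$events
#' @export
infer_gene_movements <- function(tree, matrix, labels = NULL, groups = NULL,
                                 mode = "dollo", root_state = "Y",
                                 min_genes = 3, inc_fraction = 1.0,
                                 f_min_species = 2,
                                 confirmed_absent = character(),
                                 event_branch = "full",
                                 conf = 0.95,
                                 reacq_matrix = NULL) {
  if (is.character(tree)) tree <- read_tree_file(tree)
  if (is.character(matrix)) matrix <- read_linkage_matrix(matrix)
  if (is.character(labels)) labels <- read_gene_labels(labels)

  report <- validate_dataset(tree, matrix)
  if (!is_valid(report)) {
    abort(paste0("invalid dataset: ", paste(report$errors, collapse = "; ")))
  }

  cm <- cost_model(mode, root_state = root_state)
  recs <- reconstruct_genes(
    tree, matrix, cost = cm,
    f_min_species = f_min_species, confirmed_absent = confirmed_absent
  )
  events <- classify_events(
    recs, groups = groups, min_genes = min_genes, inc_fraction = inc_fraction
  )

  long <- linkage_long(matrix)
  summary <- list(
    n_species = nrow(matrix),
    n_genes = length(linkage_genes(matrix)),
    n_genes_informative = length(recs),
    na_fraction = mean(is.na(long$state)),
    n_events = nrow(events),
    n_events_by_type = as.list(table(events$type))
  )

  loss_rate <- NULL
  inc_rate <- NULL
  if (has_branch_lengths(tree)) {
    expo <- exposure(tree, recs, event_branch = event_branch)
    n_loss <- sum(events$type %in% c("transfer", "genomic_loss"))
    loss_rate <- poisson_rate_ci(n_loss, expo$total, conf = conf)
    loss_rate$per_gene_exposure <- expo$per_gene
    inc_rate <- incorporation_rate(
      sum(events$type == "incorporation"),
      sum(tree$edge.length), conf = conf
    )
  }

  reacq <- NULL
  if (!is.null(labels)) {
    tab <- reacquisition_table(reacq_matrix %||% matrix, labels)
    reacq <- list(table = tab, fisher = fisher_exact_2x2(tab))
  }

  structure(
    list(
      summary = summary,
      reconstructions = recs,
      events = events,
      loss_rate = loss_rate,
      incorporation_rate = inc_rate,
      reacquisition = reacq,
      validation = report,
      provenance = list(
        package = "ycontent",
        version = as.character(utils::packageVersion("ycontent")),
        schema = "y_analysis/1",
        options = list(
          mode = mode, root_state = root_state, min_genes = min_genes,
          inc_fraction = inc_fraction, f_min_species = f_min_species,
          event_branch = event_branch, conf = conf
        )
      )
    ),
    class = "y_analysis"
  )
}

#' @export
print.y_analysis <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<y_analysis> %d species x %d genes (%d informative), NA fraction %.2f\n",
    s$n_species, s$n_genes, s$n_genes_informative, s$na_fraction
  ))
  cat(sprintf("  %d independent event(s):\n", s$n_events))
  for (ty in names(s$n_events_by_type)) {
    cat(sprintf("    %s: %d\n", ty, s$n_events_by_type[[ty]]))
  }
  if (!is.null(x$loss_rate)) {
    cat(sprintf(
      "  loss rate %.6f /gene/Myr, %g%% CI (%.6f, %.6f)\n",
      x$loss_rate$rate, 100 * x$loss_rate$conf,
      x$loss_rate$ci_low, x$loss_rate$ci_high
    ))
  }
  if (!is.null(x$reacquisition)) {
    cat(sprintf(
      "  re-acquisition Fisher p = %.4g\n", x$reacquisition$fisher$p_value
    ))
  }
  invisible(x)
}

#' Write a machine-readable analysis report
#'
#' Serialises a `y_analysis` to JSON (schema `y_analysis/1`): dataset
#' summary, event list, per-node reconstructions, rate estimates and test
#' results, plus a provenance block. Also writable: the event list and
#' reconstruction dump as TSV.
#'
#' @param analysis A `y_analysis`.
#' @param path Output JSON path.
#' @param events_tsv,reconstructions_tsv Optional TSV output paths.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(analysis, path, events_tsv = NULL,
                              reconstructions_tsv = NULL) {
  stopifnot(inherits(analysis, "y_analysis"))
  ev <- analysis$events
  ev$genes <- vapply(ev$genes, paste, character(1), collapse = ",")
  rec_tbl <- purrr::map_dfr(analysis$reconstructions, tidy_reconstruction)
  out <- list(
    schema = analysis$provenance$schema,
    summary = analysis$summary,
    events = ev,
    reconstructions = rec_tbl,
    loss_rate = rate_json(analysis$loss_rate),
    incorporation_rate = rate_json(analysis$incorporation_rate),
    reacquisition = if (!is.null(analysis$reacquisition)) {
      list(
        table = as.matrix(analysis$reacquisition$table),
        p = analysis$reacquisition$fisher$p_value,
        method = analysis$reacquisition$fisher$method
      )
    },
    provenance = analysis$provenance
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(events_tsv)) readr::write_tsv(ev, events_tsv)
  if (!is.null(reconstructions_tsv)) readr::write_tsv(rec_tbl, reconstructions_tsv)
  invisible(path)
}

rate_json <- function(est) {
  if (is.null(est)) return(NULL)
  list(
    n = est$n_events, exposure = est$exposure, rate = est$rate,
    ci = c(est$ci_low, est$ci_high), conf = est$conf, method = est$method
  )
}

tidy_reconstruction <- function(r) {
  tibble(
    gene = r$gene,
    node = seq_along(r$node_state),
    node_label = names(r$node_state),
    state = unname(r$node_state)
  )
}

#' Simulate a dataset and write it to disk
#'
#' Runs [simulate_tree()] (unless a tree is supplied) and
#' [simulate_gene_content()] / [observe_pcr()], writing `tree.nwk`,
#' `linkage.tsv`, `truth_events.tsv` and `config.json` (the full
#' configuration echo, seed included) into `dir`. Identical configurations
#' and seeds produce byte-identical outputs.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @param tree Optional user tree (`phylo`); when `NULL` a Yule tree with
#'   `n_tips` and `birth_rate` is simulated from the config seed.
#' @param n_tips,birth_rate Yule parameters used when `tree` is `NULL`.
#' @return Invisibly, a list with the simulated `tree`, `truth`, `events`,
#'   `matrix` and the output paths.
#' @export
simulate_dataset <- function(config, dir, tree = NULL, n_tips = 20,
                             birth_rate = 0.1) {
  stopifnot(inherits(config, "sim_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(config$seed)
  if (is.null(tree)) tree <- simulate_tree(n_tips, birth_rate)
  sim <- simulate_gene_content_impl(tree, config)
  mat <- observe_pcr(sim$truth, config$pcr_fail_prob)

  paths <- list(
    tree = file.path(dir, "tree.nwk"),
    linkage = file.path(dir, "linkage.tsv"),
    events = file.path(dir, "truth_events.tsv"),
    config = file.path(dir, "config.json")
  )
  write_newick(tree, paths$tree)
  write_linkage_matrix(mat, paths$linkage)
  ev <- sim$events
  ev$gene <- vapply(ev$gene, paste, character(1), collapse = ",")
  readr::write_tsv(ev, paths$events)
  cfg <- config
  cfg$genes <- as.data.frame(cfg$genes)
  jsonlite::write_json(
    unclass(cfg), paths$config, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(list(
    tree = tree, truth = sim$truth, events = sim$events,
    matrix = mat, paths = paths
  ))
}
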