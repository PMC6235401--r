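#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a rate estimate
#'
#' @param x A `y_rate_estimate`.
#' @param ... Unused.
#' @return One-row tibble: `estimate`, `conf.low`, `conf.high`, `n_events`,
#'   `exposure`, `conf.level`, `method`.
#' @export
tidy.y_rate_estimate <- function(x, ...) {
  tibble(
    estimate = x$rate,
    conf.low = x$ci_low,
    conf.high = x$ci_high,
    n_events = x$n_events,
    exposure = x$exposure,
    conf.level = x$conf,
    method = x$method
  )
}

#' @rdname tidy.y_rate_estimate
#' @export
glance.y_rate_estimate <- function(x, ...) tidy(x, ...)

#' Tidy an exact test result
#'
#' @param x A `y_test_result`.
#' @param ... Unused.
#' @return One-row tibble: `p.value`, `statistic`, `statistic.name`,
#'   `method`.
#' @export
tidy.y_test_result <- function(x, ...) {
  tibble(
    p.value = x$p_value,
    statistic = x$statistic,
    statistic.name = x$statistic_name,
    method = x$method
  )
}

#' Tidy a parsimony reconstruction
#'
#' @param x A `y_reconstruction`.
#' @param ... Unused.
#' @return Tibble of per-node states: `gene`, `node`, `node_label`,
#'   `state`.
#' @export
tidy.y_reconstruction <- function(x, ...) tidy_reconstruction(x)

#' @rdname tidy.y_reconstruction
#' @export
glance.y_reconstruction <- function(x, ...) {
  tibble(
    gene = x$gene,
    min_cost = x$min_cost,
    n_changes = nrow(x$changes),
    mode = x$cost_model$mode,
    root_state = x$cost_model$root_state
  )
}

#' Tidy an analysis: the independent-event table
#'
#' @param x A `y_analysis`.
#' @param ... Unused.
#' @return The event tibble with `genes` flattened to a comma-separated
#'   column.
#' @export
tidy.y_analysis <- function(x, ...) {
  ev <- x$events
  ev$genes <- vapply(ev$genes, paste, character(1), collapse = ",")
  ev
}

#' @rdname tidy.y_analysis
#' @export
glance.y_analysis <- function(x, ...) {
  s <- x$summary
  tibble(
    n_species = s$n_species,
    n_genes = s$n_genes,
    n_events = s$n_events,
    n_transfers = sum(x$events$type == "transfer"),
    n_genomic_losses = sum(x$events$type == "genomic_loss"),
    n_incorporations = sum(x$events$type == "incorporation"),
    loss_rate = if (is.null(x$loss_rate)) NA_real_ else x$loss_rate$rate,
    reacquisition_p = if (is.null(x$reacquisition)) NA_real_ else
      x$reacquisition$fisher$p_value
  )
}

#' Per-replicate results of a recovery experiment
#'
#' @param x A `y_recovery`.
#' @param ... Unused.
#' @return The per-replicate tibble.
#' @export
tidy.y_recovery <- function(x, ...) x$replicates

#' @rdname tidy.y_recovery
#' @export
glance.y_recovery <- function(x, ...) {
  r <- x$replicates
  ident <- r[r$identifiable, , drop = FALSE]
  tibble(
    n_reps = nrow(r),
    coverage = mean(r$covered),
    mean_rate_error = mean(r$rate - x$lambda_transfer),
    identifiable_fraction = mean(r$identifiable),
    exact_match_identifiable = if (nrow(ident) > 0) mean(ident$exact_match) else NA_real_,
    inc_sensitivity = if (sum(r$n_true_inc) > 0) {
      sum(r$inc_recovered) / sum(r$n_true_inc)
    } else NA_real_,
    inc_precision = if (sum(r$n_inferred_inc) > 0) {
      sum(r$inc_recovered) / sum(r$n_inferred_inc)
    } else NA_real_
  )
}
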