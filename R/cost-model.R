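#' Transition cost model for linkage-state parsimony
#'
#' Ancestral linkage states are `Y` (gene on the Y chromosome), `AX`
#' (autosomal or X-linked) and `absent` (lost from the genome). The cost
#' model fixes the price of each change along a branch and the allowed root
#' state:
#'
#' * `mode = "dollo"` (default): Y-linkage can only be lost. Gains
#'   (`AX -> Y`, resurrection from `absent`) are forbidden (infinite cost);
#'   losses cost 1. This encodes the minimum-change argument that a gene
#'   ancestrally on the Y moved off it, rather than being repeatedly gained.
#' * `mode = "fitch"`: all changes cost 1 (symmetric, for sensitivity
#'   analysis).
#' * `mode = "sankoff"`: user-supplied costs, including `Inf` to forbid a
#'   change.
#'
#' Changes out of `absent` are always forbidden except under `fitch`;
#' `AX -> absent` defaults to the `Y -> absent` loss cost.
#'
#' @param mode `"dollo"`, `"fitch"` or `"sankoff"`.
#' @param cost_y_to_ax Cost of a Y-to-autosome/X movement.
#' @param cost_ax_to_y Cost of a gain of Y-linkage.
#' @param cost_y_to_absent Cost of a genomic loss.
#' @param cost_ax_to_absent Cost of losing an autosomal/X copy
#'   (defaults to `cost_y_to_absent`).
#' @param root_state Constraint on the root: `"Y"`, `"AX"` or `"free"`.
#' @return A `cost_model` with the 3x3 cost matrix in `$mat`.
#' @examples
#' cost_model("dollo", root_state = "Y")$mat
#' @export
cost_model <- function(mode = c("dollo", "fitch", "sankoff"),
                       cost_y_to_ax = 1,
                       cost_ax_to_y = if (mode == "fitch") 1 else Inf,
                       cost_y_to_absent = 1,
                       cost_ax_to_absent = cost_y_to_absent,
                       root_state = c("Y", "AX", "free")) {
  mode <- arg_match(mode)
  root_state <- arg_match(root_state)
  if (mode == "fitch") {
    mat <- matrix(1, 3, 3, dimnames = list(.ANC_STATES, .ANC_STATES))
    diag(mat) <- 0
  } else {
    resurrect <- if (mode == "dollo") Inf else Inf  # absent is terminal
    mat <- matrix(
      c(
        0,                cost_y_to_ax,  cost_y_to_absent,
        cost_ax_to_y,     0,             cost_ax_to_absent,
        resurrect,        resurrect,     0
      ),
      nrow = 3, byrow = TRUE, dimnames = list(.ANC_STATES, .ANC_STATES)
    )
    if (mode == "dollo") {
      mat["AX", "Y"] <- Inf
    }
  }
  bad <- mat < 0 | (is.na(mat))
  if (any(bad)) abort("cost model entries must be non-negative (Inf allowed)")
  structure(
    list(mode = mode, mat = mat, root_state = root_state),
    class = "cost_model"
  )
}

#' @export
print.cost_model <- function(x, ...) {
  cat(sprintf("<cost_model> mode=%s root=%s\n", x$mode, x$root_state))
  print(x$mat)
  invisible(x)
}
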