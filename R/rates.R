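#' Gene-Myr exposure on a tree
#'
#' Total evolutionary time during which genes were at risk of leaving the
#' Y: for each gene, the sum of branch lengths (Myr) over branches whose
#' parent node is reconstructed `Y`. The branch on which a loss occurs is
#' included in full by default — the gene was at risk until the (unknown)
#' event time within the branch; `event_branch = "half"` is a sensitivity
#' setting that counts such branches at half length.
#'
#' @param tree A `phylo` with branch lengths in Myr.
#' @param reconstructions A list of `y_reconstruction` objects on `tree`.
#' @param event_branch `"full"` (default) or `"half"`.
#' @return A list with `total` (gene-Myr) and `per_gene` (tibble: `gene`,
#'   `exposure`).
#' @examples
#' tr <- parse_newick("((a:3,b:3):4,c:7);")
#' rec <- sankoff_reconstruct(tr, c(a = "Y", b = "Y", c = "Y"),
#'   cost_model("dollo", root_state = "Y"), gene = "g1")
#' exposure(tr, list(rec))$total
#' @export
exposure <- function(tree, reconstructions, event_branch = c("full", "half")) {
  event_branch <- arg_match(event_branch)
  if (inherits(reconstructions, "y_reconstruction")) {
    reconstructions <- list(reconstructions)
  }
  if (!has_branch_lengths(tree)) {
    abort(paste0(
      "tree has no branch lengths: exposure is undefined. ",
      "Unit-length substitution supports event counting only, not rates."
    ))
  }
  ed <- tree$edge
  len <- tree$edge.length
  per_gene <- purrr::map_dfr(reconstructions, function(r) {
    st <- r$node_state
    at_risk <- st[ed[, 1]] == "Y"
    w <- as.numeric(at_risk)
    if (event_branch == "half") {
      w[at_risk & st[ed[, 2]] != "Y"] <- 0.5
    }
    tibble(gene = r$gene, exposure = sum(w * len))
  })
  list(total = sum(per_gene$exposure), per_gene = per_gene)
}

#' Exact (Garwood) Poisson rate estimate with confidence interval
#'
#' Point rate `n / T` with the exact chi-square-quantile interval: lower
#' bound `qchisq(alpha/2, 2n) / (2T)` (0 when `n = 0`), upper bound
#' `qchisq(1 - alpha/2, 2n + 2) / (2T)`.
#'
#' @param n Number of events (non-negative integer).
#' @param T_exposure Exposure (gene-Myr for per-gene loss rates, Myr for
#'   incorporation rates); must be positive.
#' @param conf Confidence level (default 0.95).
#' @return A `y_rate_estimate`: `n_events`, `exposure`, `rate`, `ci_low`,
#'   `ci_high`, `conf`, `method`.
#' @examples
#' poisson_rate_ci(13, 13198)
#' @export
poisson_rate_ci <- function(n, T_exposure, conf = 0.95) {
  if (length(n) != 1 || is.na(n) || n < 0 || n != round(n)) {
    abort("n must be a single non-negative integer")
  }
  if (length(T_exposure) != 1 || is.na(T_exposure) || T_exposure <= 0) {
    abort("exposure must be a single positive number")
  }
  if (!(conf > 0 && conf < 1)) abort("conf must be in (0, 1)")
  alpha <- 1 - conf
  ci_low <- if (n == 0) 0 else qchisq(alpha / 2, 2 * n) / (2 * T_exposure)
  ci_high <- qchisq(1 - alpha / 2, 2 * n + 2) / (2 * T_exposure)
  structure(
    list(
      n_events = as.integer(n), exposure = T_exposure,
      rate = n / T_exposure, ci_low = ci_low, ci_high = ci_high,
      conf = conf, method = "garwood"
    ),
    class = "y_rate_estimate"
  )
}

#' @export
print.y_rate_estimate <- function(x, ...) {
  cat(sprintf(
    "<y_rate_estimate> %d events / %g exposure\n  rate %.6f, %g%% CI (%.6f, %.6f) [%s]\n",
    x$n_events, x$exposure, x$rate, 100 * x$conf, x$ci_low, x$ci_high, x$method
  ))
  invisible(x)
}

#' Whole-Y incorporation rate
#'
#' Incorporations are lineage-level events, so the exposure is tree time in
#' Myr (total branch length of the surveyed phylogeny), not gene-Myr.
#' Delegates to [poisson_rate_ci()].
#'
#' @param n_inc Number of independent incorporation events.
#' @param total_Myr Total tree length in Myr.
#' @inheritParams poisson_rate_ci
#' @return A `y_rate_estimate`.
#' @export
incorporation_rate <- function(n_inc, total_Myr, conf = 0.95) {
  est <- poisson_rate_ci(n_inc, total_Myr, conf = conf)
  est$method <- "garwood (incorporations per Myr)"
  est
}

#' Exact test for the ratio of two Poisson means
#'
#' Conditional on the total count `n1 + n2`, `n1` is binomial with success
#' probability `T1 / (T1 + T2)` under the null hypothesis of equal rates.
#' The two-sided p-value sums the probabilities of all outcomes no more
#' likely than the observed one (minimum-likelihood convention;
#' `two_sided = "doubling"` doubles the smaller tail instead). p is clamped
#' to \[0, 1\].
#'
#' @param n1,n2 Event counts (non-negative integers, `n1 + n2 >= 1`).
#' @param T1,T2 Exposures (positive).
#' @param two_sided `"minlik"` (default) or `"doubling"`.
#' @return A `y_test_result` with `p_value`, `method`, `statistic` (the
#'   observed rate ratio).
#' @examples
#' poisson_ratio_test(13, 13198, 2, 1949.3)
#' @export
poisson_ratio_test <- function(n1, T1, n2, T2,
                               two_sided = c("minlik", "doubling")) {
  two_sided <- arg_match(two_sided)
  for (v in list(n1, n2)) {
    if (length(v) != 1 || is.na(v) || v < 0 || v != round(v)) {
      abort("event counts must be single non-negative integers")
    }
  }
  if (n1 + n2 < 1) abort("need at least one event in total")
  if (any(c(T1, T2) <= 0) || any(is.na(c(T1, T2)))) {
    abort("exposures must be positive")
  }
  N <- n1 + n2
  p0 <- T1 / (T1 + T2)
  probs <- dbinom(0:N, N, p0)
  obs <- probs[n1 + 1]
  p <- switch(two_sided,
    minlik = sum(probs[probs <= obs * (1 + 1e-7)]),
    doubling = 2 * min(sum(probs[0:N >= n1]), sum(probs[0:N <= n1]))
  )
  rate1 <- n1 / T1
  rate2 <- n2 / T2
  structure(
    list(
      p_value = min(1, p),
      method = sprintf("exact ratio of two Poisson means (conditional binomial, %s)", two_sided),
      statistic = if (rate2 > 0) rate1 / rate2 else Inf,
      statistic_name = "rate_ratio",
      detail = list(n1 = n1, T1 = T1, n2 = n2, T2 = T2)
    ),
    class = "y_test_result"
  )
}

#' Two-tailed Fisher exact test on a 2x2 table
#'
#' Conditions on both margins; the two-sided p-value is the sum of
#' hypergeometric point probabilities of all tables no more likely than
#' the observed one (minimum-likelihood convention, the standard two-tailed
#' Fisher test).
#'
#' @param table A [contingency_2x2()] (or a 2x2 matrix).
#' @return A `y_test_result` with `p_value`, `method`, `statistic` (the
#'   sample odds ratio).
#' @examples
#' fisher_exact_2x2(contingency_2x2(9, 2, 0, 4))
#' @export
fisher_exact_2x2 <- function(table) {
  if (is.matrix(table)) {
    stopifnot(all(dim(table) == c(2, 2)))
    table <- contingency_2x2(table[1, 1], table[1, 2], table[2, 1], table[2, 2])
  }
  stopifnot(inherits(table, "contingency_2x2"))
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  r1 <- a + b; c1 <- a + c; N <- a + b + c + d
  if (r1 == 0 || c1 == 0 || r1 == N || c1 == N) {
    p <- 1  # degenerate margin: only one table possible
    obs <- 1
  } else {
    lo <- max(0, c1 - (N - r1))
    hi <- min(r1, c1)
    probs <- dhyper(lo:hi, r1, N - r1, c1)
    obs <- dhyper(a, r1, N - r1, c1)
    p <- min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
  }
  or <- (a * d) / (b * c)
  structure(
    list(
      p_value = p,
      method = "two-tailed Fisher exact test (minimum-likelihood)",
      statistic = or,
      statistic_name = "odds_ratio",
      detail = list(table = as.matrix(table))
    ),
    class = "y_test_result"
  )
}

#' @export
print.y_test_result <- function(x, ...) {
  cat(sprintf(
    "<y_test_result> p = %.6g (%s = %.4g)\n  method: %s\n",
    x$p_value, x$statistic_name, x$statistic, x$method
  ))
  invisible(x)
}
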