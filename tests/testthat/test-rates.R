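dollo_y <- cost_model("dollo", root_state = "Y")

test_that("exposure sums branch lengths while the gene is on the Y", {
  cherry <- parse_newick("(a:3,b:3);")
  rec <- sankoff_reconstruct(cherry, c(a = "Y", b = "Y"), dollo_y, gene = "g1")
  expect_equal(exposure(cherry, list(rec))$total, 6)

  # cherry with a 4-Myr stem and a 7-Myr outgroup branch
  tr <- parse_newick("((a:3,b:3):4,o:7);")
  st_all <- c(a = "Y", b = "Y", o = "Y")
  rec_all <- sankoff_reconstruct(tr, st_all, dollo_y, gene = "g1")
  rec_all2 <- sankoff_reconstruct(tr, st_all, dollo_y, gene = "g2")
  expect_equal(exposure(tr, list(rec_all))$total, 17)
  # two genes double the exposure
  expect_equal(exposure(tr, list(rec_all, rec_all2))$total, 34)
})

test_that("the branch carrying a loss counts in full (at risk until event)", {
  tr <- parse_newick("((a:3,b:3):4,o:7);")
  rec <- sankoff_reconstruct(tr, c(a = "AX", b = "Y", o = "Y"), dollo_y)
  # all four branches have parent state Y, including the a branch with the event
  expect_equal(exposure(tr, list(rec))$total, 17)
  # half-branch sensitivity counts the event branch at half length
  expect_equal(exposure(tr, list(rec), event_branch = "half")$total, 15.5)
})

test_that("exposure requires branch lengths", {
  fx <- load_fixture("fig2_ory")
  rec <- reconstruct_genes(fx$tree, fx$matrix)
  expect_error(exposure(fx$tree, rec), "branch lengths")
})

test_that("Garwood intervals reproduce published bounds", {
  est <- poisson_rate_ci(13, 13198)
  expect_equal(est$rate, 13 / 13198)
  expect_equal(est$ci_low, 0.000525, tolerance = 0.005)
  expect_equal(est$ci_high, 0.001685, tolerance = 0.005)

  est2 <- poisson_rate_ci(2, 1949.3)
  expect_equal(est2$ci_low, 0.000124, tolerance = 0.005)
  expect_equal(est2$ci_high, 0.003707, tolerance = 0.005)

  est0 <- poisson_rate_ci(0, 100)
  expect_equal(est0$ci_low, 0)
  expect_equal(est0$ci_high, qchisq(0.975, 2) / 200)
  expect_equal(est0$ci_high, 0.036889, tolerance = 1e-4)
})

test_that("Garwood interval scales as 1/T and brackets the point rate", {
  for (n in c(0, 1, 5, 20)) {
    a <- poisson_rate_ci(n, 50)
    b <- poisson_rate_ci(n, 100)
    expect_equal(a$ci_low, 2 * b$ci_low)
    expect_equal(a$ci_high, 2 * b$ci_high)
    expect_lte(a$ci_low, a$rate)
    expect_gte(a$ci_high, a$rate)
  }
  expect_error(poisson_rate_ci(3, 0), "positive")
  expect_error(poisson_rate_ci(-1, 10), "non-negative")
})

test_that("Garwood coverage is at least nominal (simulation)", {
  set.seed(99)
  for (mean_count in c(2, 9)) {
    n_sim <- 4000
    counts <- stats::rpois(n_sim, mean_count)
    covered <- vapply(counts, function(k) {
      est <- poisson_rate_ci(k, 1)
      est$ci_low <= mean_count && mean_count <= est$ci_high
    }, logical(1))
    # exact interval is conservative; allow Monte-Carlo error below 0.95
    mc <- 3 * sqrt(0.95 * 0.05 / n_sim)
    expect_gte(mean(covered), 0.95 - mc)
  }
})

test_that("Poisson ratio test matches hand-derived binomial sums", {
  # symmetric case: observed at the mode of Binomial(10, 1/2)
  expect_equal(poisson_ratio_test(5, 100, 5, 100)$p_value, 1)
  # extreme split: only k=0 and k=10 are as unlikely as observed
  expect_equal(poisson_ratio_test(10, 100, 0, 100)$p_value, 2 / 1024)
  # published comparison: the two loss-rate estimates do not differ
  expect_gt(poisson_ratio_test(13, 13198, 2, 1949.3)$p_value, 0.5)
})

test_that("Poisson ratio test is symmetric and agrees with binom.test", {
  set.seed(55)
  for (i in 1:25) {
    n1 <- sample(0:12, 1); n2 <- sample(0:12, 1)
    if (n1 + n2 == 0) n1 <- 1
    T1 <- runif(1, 10, 500); T2 <- runif(1, 10, 500)
    p_ab <- poisson_ratio_test(n1, T1, n2, T2)$p_value
    p_ba <- poisson_ratio_test(n2, T2, n1, T1)$p_value
    expect_equal(p_ab, p_ba, tolerance = 1e-12)
    # stats::binom.test uses the same minimum-likelihood convention
    expect_equal(
      p_ab,
      stats::binom.test(n1, n1 + n2, T1 / (T1 + T2))$p.value,
      tolerance = 1e-9,
      info = paste("case", i)
    )
  }
  expect_error(poisson_ratio_test(0, 10, 0, 10), "at least one event")
  expect_error(poisson_ratio_test(1, -1, 0, 10), "positive")
})

test_that("Fisher exact test reproduces published and enumerable cases", {
  expect_equal(
    fisher_exact_2x2(contingency_2x2(9, 2, 0, 4))$p_value,
    55 / 5005,
    tolerance = 1e-12
  )
  expect_equal(round(fisher_exact_2x2(contingency_2x2(9, 2, 0, 4))$p_value, 3), 0.011)
  expect_equal(fisher_exact_2x2(contingency_2x2(5, 5, 5, 5))$p_value, 1)
  # margins (2,2;2,2): three tables, observed the most extreme corner
  expect_equal(fisher_exact_2x2(contingency_2x2(2, 0, 0, 2))$p_value, 1 / 3,
    tolerance = 1e-12)
})

test_that("Fisher test is invariant under row/column swaps and transpose", {
  set.seed(66)
  for (i in 1:30) {
    x <- sample(0:8, 4, replace = TRUE)
    if (sum(x) == 0) x[1] <- 1
    p <- function(a, b, c, d) fisher_exact_2x2(contingency_2x2(a, b, c, d))$p_value
    p0 <- p(x[1], x[2], x[3], x[4])
    expect_equal(p0, p(x[3], x[4], x[1], x[2]), tolerance = 1e-12) # row swap
    expect_equal(p0, p(x[2], x[1], x[4], x[3]), tolerance = 1e-12) # col swap
    expect_equal(p0, p(x[1], x[3], x[2], x[4]), tolerance = 1e-12) # transpose
  }
})

test_that("Fisher p equals full margin-constrained enumeration (oracle)", {
  enum_p <- function(a, b, c, d) {
    r1 <- a + b; c1 <- a + c; N <- a + b + c + d
    tabs <- max(0, c1 - (N - r1)):min(r1, c1)
    probs <- vapply(tabs, function(aa) {
      choose(r1, aa) * choose(N - r1, c1 - aa) / choose(N, c1)
    }, numeric(1))
    obs <- probs[match(a, tabs)]
    sum(probs[probs <= obs * (1 + 1e-7)])
  }
  set.seed(67)
  for (i in 1:60) {
    x <- sample(0:8, 4, replace = TRUE)  # totals <= 32
    if (sum(x) == 0 || (x[1] + x[2]) == 0 || (x[1] + x[3]) == 0) x <- x + 1
    p_pkg <- fisher_exact_2x2(contingency_2x2(x[1], x[2], x[3], x[4]))$p_value
    expect_equal(p_pkg, enum_p(x[1], x[2], x[3], x[4]), tolerance = 1e-10,
      info = paste(x, collapse = ","))
    # independent implementation in stats::fisher.test (same convention)
    if ((x[2] + x[4]) > 0 && (x[3] + x[4]) > 0) {
      m <- matrix(x, 2, 2, byrow = TRUE)
      expect_equal(p_pkg, stats::fisher.test(m)$p.value, tolerance = 1e-9)
    }
  }
})

test_that("incorporation_rate delegates to the Garwood machinery", {
  est <- incorporation_rate(2, 6529)
  expect_equal(est$rate, 2 / 6529)
  expect_equal(est$ci_low, qchisq(0.025, 4) / (2 * 6529))
  est0 <- incorporation_rate(0, 1000)
  expect_equal(est0$rate, 0)
  expect_equal(est0$ci_low, 0)
  expect_equal(incorporation_rate(1, 1)$rate, 1)
})

test_that("tidy/glance methods return well-formed tibbles", {
  td <- tidy(poisson_rate_ci(13, 13198))
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("estimate", "conf.low", "conf.high", "n_events",
    "exposure", "conf.level", "method"))
  tt <- tidy(fisher_exact_2x2(contingency_2x2(9, 2, 0, 4)))
  expect_equal(tt$p.value, 55 / 5005, tolerance = 1e-12)
})
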