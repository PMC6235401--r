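test_that("simulate_tree is reproducible and validates parameters", {
  t1 <- simulate_tree(6, 0.5, seed = 3)
  t2 <- simulate_tree(6, 0.5, seed = 3)
  expect_identical(write_newick(t1), write_newick(t2))
  expect_equal(ape::Ntip(simulate_tree(2, 1.0, seed = 1)), 2L)
  expect_error(simulate_tree(1, 1.0, seed = 1), "n_tips")
  expect_error(simulate_tree(5, 0, seed = 1), "birth_rate")
})

test_that("simulate_tree depth matches the Yule expectation", {
  # crown age expectation with the Exp(n*lambda) overhang:
  # sum_{k=2..n} 1/(k*lambda)
  n <- 50; lambda <- 0.1; reps <- 200
  expected <- sum(1 / ((2:n) * lambda))
  set.seed(12)
  depths <- replicate(reps, {
    tr <- simulate_tree(n, lambda)
    max(ape::node.depth.edgelength(tr))
  })
  # var of crown age = sum (1/(k lambda))^2
  se <- sqrt(sum(1 / ((2:n) * lambda)^2) / reps)
  expect_lt(abs(mean(depths) - expected), 4 * se)
})

test_that("sim_config validates rates, probabilities and the mandatory seed", {
  expect_error(sim_config(c("g1"), lambda_transfer = -1, seed = 1), ">= 0")
  expect_error(sim_config(c("g1"), pi_keep_Y = 2, seed = 1), "pi_keep_Y")
  expect_error(sim_config(c("g1"), pcr_fail_prob = 1, seed = 1), "pcr_fail_prob")
  expect_error(sim_config(c("g1")), "seed")
  cfg <- sim_config(c("g1", "g2"), seed = 9)
  expect_equal(cfg$genes$initial, c("Y", "Y"))
})

test_that("zero rates propagate the root state unchanged with empty log", {
  tr <- balanced8()
  cfg <- sim_config(
    data.frame(gene = c("y1", "y2", "x1"), initial = c("Y", "Y", "AX")),
    lambda_transfer = 0, lambda_genomic_loss = 0, seed = 4
  )
  sim <- simulate_gene_content(tr, cfg)
  expect_equal(nrow(sim$events), 0L)
  m <- observe_pcr(sim$truth)
  expect_true(all(m$y1 == "M" & m$y2 == "M" & m$x1 == "MF"))
})

test_that("identical config and seed give identical truth and log", {
  tr <- balanced8()
  cfg <- sim_config(paste0("g", 1:4),
    lambda_transfer = 0.05, lambda_genomic_loss = 0.01,
    mu_incorporation = 0.02, rho_resolution = 0.5, seed = 11
  )
  s1 <- simulate_gene_content(tr, cfg)
  s2 <- simulate_gene_content(tr, cfg)
  expect_identical(s1, s2)
})

test_that("state machine soundness: no resurrection, resolutions only when redundant", {
  set.seed(21)
  tr <- simulate_tree(20, 0.2)
  cfg <- sim_config(paste0("g", 1:5),
    lambda_transfer = 0.05, lambda_genomic_loss = 0.05,
    mu_incorporation = 0.05, rho_resolution = 0.3, pi_keep_Y = 0.5,
    seed = 31
  )
  sim <- simulate_gene_content(tr, cfg)
  # a species lacking both copies can only arise via genomic loss or a
  # resolution that dropped the last copy; it can never show M or MF
  m <- observe_pcr(sim$truth)
  gone <- !sim$truth$has_Y & !sim$truth$has_AX
  expect_true(all(as.matrix(m[, -1])[gone] == "F"))
  # resolution events only recorded where both copies existed: resolved
  # genes must have been duplicated by an earlier incorporation
  if (any(sim$events$type == "resolution")) {
    expect_true(any(sim$events$type == "incorporation"))
  }
})

test_that("transfer counts match the Poisson mean over replicates", {
  # lambda * G * L expected events; empirical mean within 3 SE
  tr <- balanced8() # total length 14 Myr
  L <- sum(tr$edge.length)
  G <- 3; lambda <- 0.02; reps <- 1000
  counts <- integer(reps)
  for (r in seq_len(reps)) {
    cfg <- sim_config(paste0("g", 1:G),
      lambda_transfer = lambda, lambda_genomic_loss = 0, seed = 1000 + r
    )
    counts[r] <- nrow(simulate_gene_content(tr, cfg)$events)
  }
  expected <- lambda * G * L
  se <- sqrt(expected / reps) # Poisson variance
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("observation model: Y-only is M, redundant is MF, absent is F", {
  truth <- structure(
    list(
      has_Y = matrix(c(TRUE, TRUE, FALSE), 1, dimnames = list("sp", NULL)),
      has_AX = matrix(c(FALSE, TRUE, FALSE), 1, dimnames = list("sp", NULL)),
      species = "sp",
      genes = c("y_only", "redundant", "gone")
    ),
    class = "genotype_matrix"
  )
  m <- observe_pcr(truth)
  expect_equal(m$y_only, "M")
  expect_equal(m$redundant, "MF") # the Y copy is invisible behind the A/X copy
  expect_equal(m$gone, "F")
})

test_that("NA masking frequency matches pcr_fail_prob", {
  set.seed(8)
  tr <- simulate_tree(40, 0.2)
  cfg <- sim_config(paste0("g", 1:10), lambda_transfer = 0,
    lambda_genomic_loss = 0, pcr_fail_prob = 0.06, seed = 81)
  sim <- simulate_gene_content(tr, cfg)
  m <- observe_pcr(sim$truth, pcr_fail_prob = 0.06, seed = 82)
  n_cells <- 40 * 10
  frac <- mean(is.na(as.matrix(m[, -1])))
  se <- sqrt(0.06 * 0.94 / n_cells)
  expect_lt(abs(frac - 0.06), 4 * se)
})

test_that("forced incorporation with instant resolution makes an all-MF clade", {
  tr <- balanced8()
  stem <- mrca_node(tr, c("a", "b", "c", "d"))
  cfg <- sim_config(paste0("g", 1:6),
    lambda_transfer = 0, lambda_genomic_loss = 0,
    rho_resolution = 1e4, pi_keep_Y = 0, seed = 5,
    forced_events = tibble::tibble(child = stem, time = 0.5, type = "incorporation")
  )
  sim <- simulate_gene_content(tr, cfg)
  m <- observe_pcr(sim$truth)
  in_clade <- m$species %in% c("a", "b", "c", "d")
  expect_true(all(as.matrix(m[in_clade, -1]) == "MF"))
  expect_true(all(as.matrix(m[!in_clade, -1]) == "M"))
  expect_true(any(sim$events$type == "incorporation" & sim$events$forced))
})

test_that("with pi_keep_Y > 0 only ancestrally-Y genes ever show M", {
  set.seed(14)
  for (s in 1:5) {
    tr <- simulate_tree(25, 0.2)
    cfg <- sim_config(
      data.frame(
        gene = c(paste0("y", 1:6), paste0("ctrl", 1:3)),
        initial = c(rep("Y", 6), rep("AX", 3))
      ),
      lambda_transfer = 0.002, lambda_genomic_loss = 0.0005,
      mu_incorporation = 0.01, rho_resolution = 0.2, pi_keep_Y = 0.5,
      seed = 140 + s
    )
    sim <- simulate_gene_content(tr, cfg)
    m <- observe_pcr(sim$truth)
    ctrl <- as.matrix(m[, paste0("ctrl", 1:3)])
    expect_false(any(ctrl == "M", na.rm = TRUE), info = paste("seed", 140 + s))
  }
})
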