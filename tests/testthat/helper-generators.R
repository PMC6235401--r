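# random-instance generators shared by the property tests

random_tree <- function(n_tips, lengths = TRUE) {
  tr <- ape::rtree(n_tips, br = if (lengths) stats::runif else NULL)
  tr$tip.label <- paste0("t", seq_len(n_tips))
  tr$node.label <- NULL
  tr
}

random_tip_states <- function(tree, p_na = 0.1, states = c("Y", "AX", "absent")) {
  n <- ape::Ntip(tree)
  st <- sample(states, n, replace = TRUE)
  st[stats::runif(n) < p_na] <- NA_character_
  # keep the instance informative: at least one constrained tip
  if (all(is.na(st))) st[1] <- sample(states, 1)
  stats::setNames(st, tree$tip.label)
}

random_cost_model <- function() {
  mode <- sample(c("fitch", "dollo", "sankoff"), 1)
  root <- sample(c("Y", "AX", "free"), 1)
  if (mode == "sankoff") {
    cost_model("sankoff",
      cost_y_to_ax = sample(c(1, 2, 0.5, Inf), 1),
      cost_ax_to_y = sample(c(1, 3, Inf), 1),
      cost_y_to_absent = sample(c(1, 2, Inf), 1),
      root_state = root
    )
  } else {
    cost_model(mode, root_state = root)
  }
}

# simple fixed 8-tip balanced tree used across simulator tests
balanced8 <- function() {
  parse_newick("(((a:1,b:1):1,(c:1,d:1):1):1,((e:1,f:1):1,(g:1,h:1):1):1);")
}
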