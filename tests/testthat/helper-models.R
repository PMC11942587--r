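# shared toy models and a random-tree generator for property tests

# one chance node: p = 0.25 -> (1000, 0.6), else -> (200, 0.8)
two_branch_tree <- function() {
  decision_tree(list(
    A = chance_node("outcome",
      branch(0.25, terminal_node("bad", cost = 1000, effect = 0.6)),
      branch(complement(), terminal_node("good", cost = 200, effect = 0.8)))
  ))
}

empty_params <- function() parameter_set(list())

# random valid tree over `n_params` probability-free constants; depth and
# branching bounded; a complement branch is used with probability 1/2
random_tree <- function(depth = 4, max_branch = 4) {
  build <- function(d) {
    if (d == 0 || stats::runif(1) < 0.3)
      return(terminal_node(paste0("t", sample.int(1e6, 1)),
                           cost = stats::runif(1, 0, 5000),
                           effect = stats::runif(1, 0, 1)))
    k <- sample(2:max_branch, 1)
    probs <- stats::rgamma(k, 1)
    probs <- probs / sum(probs)
    use_comp <- stats::runif(1) < 0.5
    branches <- lapply(seq_len(k), function(i) {
      pr <- if (use_comp && i == k) complement() else probs[i]
      branch(pr, build(d - 1))
    })
    chance_node(paste0("c", sample.int(1e6, 1)), branches)
  }
  decision_tree(list(S = build(depth)))
}

picc_fixture_path <- function() {
  system.file("extdata", "picc_agba_vs_standard.json", package = "ceatree")
}

# scale every terminal cost payoff by k (constants and multiplier vectors)
scale_tree_costs <- function(tree, k) {
  scale_node <- function(node) {
    if (node$type == "terminal") {
      node$cost <- node$cost * k
      return(node)
    }
    node$branches <- lapply(node$branches, function(b) {
      b$node <- scale_node(b$node)
      b
    })
    node
  }
  tree$strategies <- lapply(tree$strategies, scale_node)
  tree
}
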