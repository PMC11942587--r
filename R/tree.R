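#' Decision-tree construction
#'
#' A decision tree compares named strategies (the root decision). Under
#' each strategy hangs an out-tree of chance nodes and terminal nodes.
#' Chance-node branch probabilities are expressions over parameters: a
#' single parameter reference, a product of references (a character
#' vector), a numeric constant, or [complement()] for the one residual
#' branch `1 - sum(siblings)`. Terminal payoffs are a cost expression
#' (a named numeric vector of multipliers over cost parameters, or a
#' numeric constant) and an effect expression (a utility parameter name
#' or a numeric constant).
#'
#' @param strategies named list of root nodes, one per strategy.
#' @return an object of class `cea_decision_tree`.
#' @export
#' @examples
#' tree <- decision_tree(list(
#'   A = chance_node("outcome",
#'     branch(0.25, terminal_node("bad", cost = 1000, effect = 0.6)),
#'     branch(complement(), terminal_node("good", cost = 200, effect = 0.8))
#'   )
#' ))
#' rollback(tree, parameter_set(list()))
decision_tree <- function(strategies) {
  if (is.null(names(strategies)) || any(!nzchar(names(strategies))))
    abort_ceatree("strategies must be a named list", "ceatree_schema_error")
  if (anyDuplicated(names(strategies)))
    abort_ceatree("duplicate strategy names", "ceatree_schema_error")
  structure(list(strategies = strategies), class = "cea_decision_tree")
}

#' @rdname decision_tree
#' @param name node label, used in path listings and error messages.
#' @param ... for `chance_node()`, the branches (created with [branch()]).
#' @export
chance_node <- function(name, ...) {
  branches <- list(...)
  if (length(branches) == 1 && is.list(branches[[1]]) &&
      is.null(branches[[1]]$prob)) branches <- branches[[1]]
  structure(list(type = "chance", name = name, branches = branches),
            class = "cea_node")
}

#' @rdname decision_tree
#' @param prob branch-probability expression (see Details).
#' @param node child node.
#' @export
branch <- function(prob, node) list(prob = prob, node = node)

#' @rdname decision_tree
#' @param cost terminal cost expression.
#' @param effect terminal effect expression.
#' @export
terminal_node <- function(name, cost, effect) {
  structure(list(type = "terminal", name = name, cost = cost, effect = effect),
            class = "cea_node")
}

#' @rdname decision_tree
#' @export
complement <- function() "complement"

is_complement <- function(prob) {
  is.character(prob) && length(prob) == 1 && identical(prob, "complement")
}

# ---- expression resolution -------------------------------------------------

# product of parameter references (or a constant); errors list missing refs
resolve_prob <- function(prob, values, node_name, collect) {
  if (is.numeric(prob)) return(prod(prob))
  missing <- setdiff(prob, names(values))
  if (length(missing)) {
    collect(sprintf("node '%s': unresolved parameter reference(s): %s",
                    node_name, paste(missing, collapse = ", ")))
    return(NA_real_)
  }
  prod(values[prob])
}

resolve_cost <- function(cost, values, node_name, collect) {
  if (is.numeric(cost) && is.null(names(cost))) return(sum(cost))
  if (is.character(cost)) cost <- stats::setNames(rep(1, length(cost)), cost)
  missing <- setdiff(names(cost), names(values))
  if (length(missing)) {
    collect(sprintf("terminal '%s': unresolved cost parameter(s): %s",
                    node_name, paste(missing, collapse = ", ")))
    return(NA_real_)
  }
  sum(cost * values[names(cost)])
}

resolve_effect <- function(effect, values, node_name, collect) {
  if (is.numeric(effect)) return(effect)
  if (!effect %in% names(values)) {
    collect(sprintf("terminal '%s': unresolved effect parameter '%s'",
                    node_name, effect))
    return(NA_real_)
  }
  unname(values[effect])
}

# branch probabilities of a chance node, complement filled in last
branch_probs <- function(node, values, collect) {
  probs <- vapply(node$branches, function(b) {
    if (is_complement(b$prob)) NA_real_
    else resolve_prob(b$prob, values, node$name, collect)
  }, numeric(1))
  comp <- vapply(node$branches, function(b) is_complement(b$prob), logical(1))
  if (sum(comp) > 1) {
    collect(sprintf("node '%s': more than one complement branch", node$name))
    return(probs)
  }
  if (any(comp)) probs[comp] <- 1 - sum(probs[!comp])
  probs
}

# ---- validation ------------------------------------------------------------

#' Validate a decision tree against a parameter set
#'
#' Walks every strategy and returns all violations found under the base
#' values of `params`: unresolved parameter references, branch
#' probabilities outside `[0, 1]`, chance nodes whose resolved branch
#' probabilities do not sum to 1 within `1e-9` (the message carries the
#' node id and the offending sum), more than one complement branch at a
#' node, and malformed nodes. An empty report means the tree is valid.
#'
#' @param tree a `cea_decision_tree`.
#' @param params a `cea_parameter_set` (or named numeric assignment).
#' @return character vector of violations; `character(0)` if valid.
#' @export
validate_tree <- function(tree, params) {
  values <- as_assignment(params)
  out <- character(0)
  collect <- function(msg) out <<- c(out, msg)
  if ("complement" %in% names(values))
    collect("'complement' is reserved and cannot be a parameter name")
  if (inherits(params, "cea_parameter_set"))
    out <- c(out, validate_parameters(params))
  for (s in names(tree$strategies))
    walk_validate(tree$strategies[[s]], values, s, collect)
  out
}

walk_validate <- function(node, values, strategy, collect) {
  if (!inherits(node, "cea_node") || !node$type %in% c("chance", "terminal")) {
    collect(sprintf("strategy '%s': malformed node", strategy))
    return(invisible())
  }
  if (node$type == "terminal") {
    resolve_cost(node$cost, values, node$name, collect)
    resolve_effect(node$effect, values, node$name, collect)
    return(invisible())
  }
  if (length(node$branches) < 2)
    collect(sprintf("node '%s': chance node needs >= 2 branches", node$name))
  probs <- branch_probs(node, values, collect)
  if (!anyNA(probs)) {
    bad <- probs < -1e-12 | probs > 1 + 1e-12
    if (any(bad))
      collect(sprintf("node '%s': branch probability outside [0, 1]: %s",
                      node$name,
                      paste(sprintf("%.6g", probs[bad]), collapse = ", ")))
    s <- sum(probs)
    if (abs(s - 1) > 1e-9)
      collect(sprintf("node '%s': branch probabilities sum to %.10g, not 1",
                      node$name, s))
  }
  for (b in node$branches) walk_validate(b$node, values, strategy, collect)
  invisible()
}

as_assignment <- function(params) {
  if (inherits(params, "cea_parameter_set")) base_values(params)
  else if (is.numeric(params) && !is.null(names(params))) params
  else abort_ceatree("params must be a cea_parameter_set or named numeric",
                     "ceatree_type_error")
}

# ---- evaluation ------------------------------------------------------------

#' Expected-value rollback of a decision tree
#'
#' Evaluates each strategy from the leaves up: the expected cost and
#' expected effect at a chance node are the branch-probability-weighted
#' sums of its children, and a terminal contributes its payoffs. The
#' result is deterministic given the tree and the parameter assignment.
#'
#' @param tree a `cea_decision_tree`.
#' @param params a `cea_parameter_set` (evaluated at base values) or a
#'   named numeric parameter assignment (e.g. one PSA draw).
#' @param check validate first and refuse to evaluate an invalid tree
#'   (default `TRUE`; turned off internally in PSA loops where the
#'   sampling scheme guarantees validity).
#' @return a tibble with one row per strategy: `strategy`,
#'   `expected_cost`, `expected_effect`.
#' @export
#' @examples
#' tree <- decision_tree(list(
#'   A = chance_node("outcome",
#'     branch(0.25, terminal_node("bad", cost = 1000, effect = 0.6)),
#'     branch(complement(), terminal_node("good", cost = 200, effect = 0.8))
#'   )
#' ))
#' rollback(tree, parameter_set(list())) # cost 400, effect 0.75
rollback <- function(tree, params, check = TRUE) {
  values <- as_assignment(params)
  if (check) {
    report <- validate_tree(tree, params)
    if (length(report))
      abort_ceatree(c("tree validation failed:", report),
                    "ceatree_validation_error")
  }
  res <- lapply(names(tree$strategies), function(s) {
    ev <- node_ev(tree$strategies[[s]], values)
    tibble::tibble(strategy = s, expected_cost = ev[1], expected_effect = ev[2])
  })
  dplyr::bind_rows(res)
}

node_ev <- function(node, values) {
  collect <- function(msg) abort_ceatree(msg, "ceatree_validation_error")
  if (node$type == "terminal")
    return(c(resolve_cost(node$cost, values, node$name, collect),
             resolve_effect(node$effect, values, node$name, collect)))
  probs <- branch_probs(node, values, collect)
  ev <- c(0, 0)
  for (i in seq_along(node$branches))
    ev <- ev + probs[i] * node_ev(node$branches[[i]]$node, values)
  ev
}

#' Enumerate root-to-leaf paths of a decision tree
#'
#' Lists every path per strategy with its probability (the product of
#' branch probabilities along it) and terminal payoffs. Serves as an
#' independent check on [rollback()]: per strategy the path probabilities
#' sum to 1 and the probability-weighted payoff sums equal the rollback
#' expectations.
#'
#' @inheritParams rollback
#' @return a tibble: `strategy`, `path` (node labels joined by `" > "`),
#'   `probability`, `cost`, `effect`.
#' @export
enumerate_paths <- function(tree, params, check = TRUE) {
  values <- as_assignment(params)
  if (check) {
    report <- validate_tree(tree, params)
    if (length(report))
      abort_ceatree(c("tree validation failed:", report),
                    "ceatree_validation_error")
  }
  res <- lapply(names(tree$strategies), function(s) {
    rows <- node_paths(tree$strategies[[s]], values, character(0), 1)
    dplyr::bind_rows(rows) |> dplyr::mutate(strategy = s, .before = 1)
  })
  dplyr::bind_rows(res)
}

node_paths <- function(node, values, trail, prob) {
  collect <- function(msg) abort_ceatree(msg, "ceatree_validation_error")
  trail <- c(trail, node$name)
  if (node$type == "terminal")
    return(list(tibble::tibble(
      path = paste(trail, collapse = " > "),
      probability = prob,
      cost = resolve_cost(node$cost, values, node$name, collect),
      effect = resolve_effect(node$effect, values, node$name, collect)
    )))
  probs <- branch_probs(node, values, collect)
  unlist(lapply(seq_along(node$branches), function(i) {
    node_paths(node$branches[[i]]$node, values, trail, prob * probs[i])
  }), recursive = FALSE)
}

#' @export
print.cea_decision_tree <- function(x, ...) {
  cat(sprintf("<cea_decision_tree> %d strategies: %s\n",
              length(x$strategies),
              paste(names(x$strategies), collapse = ", ")))
  for (s in names(x$strategies)) print_node(x$strategies[[s]], paste0(s, ": "))
  invisible(x)
}

print_node <- function(node, indent) {
  if (node$type == "terminal") {
    cat(indent, "[", node$name, "]\n", sep = "")
  } else {
    cat(indent, node$name, "\n", sep = "")
    for (b in node$branches)
      print_node(b$node, paste0("  ", gsub(".", " ", indent)))
  }
}
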