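#' Sample parameter vectors for probabilistic sensitivity analysis
#'
#' Draws `n` joint parameter vectors from the declared uncertainty
#' distributions. Parameters with distribution `none` are held at their
#' base value. Members of a `dirichlet` group (multinomial branch sets)
#' are drawn jointly from a Dirichlet with their `alpha` values as the
#' concentration vector, so sampled branch probabilities always lie on
#' the simplex. A single RNG stream is consumed in parameter declaration
#' order, making draws reproducible by seed independent of tree shape.
#'
#' @param params a `cea_parameter_set`.
#' @param n number of draws.
#' @param seed integer seed (`NULL` to use the current RNG state).
#' @return an `n` by `length(params)` numeric matrix, columns named.
#' @export
sample_parameters <- function(params, n, seed = NULL) {
  stopifnot(n >= 1)
  bad <- validate_parameters(params)
  if (length(bad))
    abort_ceatree(c("invalid parameter specification:", bad),
                  "ceatree_validation_error")
  nm <- names(params)
  with_seed(seed, {
    draws <- matrix(NA_real_, nrow = n, ncol = length(params),
                    dimnames = list(NULL, nm))
    done_groups <- character(0)
    for (j in seq_along(params)) {
      p <- params[[j]]
      d <- p$distribution
      draws[, j] <- switch(
        d$type,
        none = rep(p$base, n),
        beta = stats::rbeta(n, d$shape1, d$shape2),
        gamma = stats::rgamma(n, shape = d$shape, scale = d$scale),
        lognormal = stats::rlnorm(n, d$meanlog, d$sdlog),
        uniform = stats::runif(n, d$min, d$max),
        dirichlet = {
          if (d$group %in% done_groups) {
            draws[, j] # already filled when the first member was reached
          } else {
            members <- which(vapply(params, function(q)
              identical(q$distribution$type, "dirichlet") &&
                identical(q$distribution$group, d$group), logical(1)))
            alpha <- vapply(params[members], function(q)
              q$distribution$alpha, numeric(1))
            g <- vapply(alpha, function(a) stats::rgamma(n, shape = a),
                        numeric(n))
            g <- matrix(g, nrow = n)
            draws[, members] <- g / rowSums(g)
            done_groups <- c(done_groups, d$group)
            draws[, j]
          }
        }
      )
    }
    draws
  })
}

# ---- vectorised tree evaluation over a draw matrix -------------------------

# returns list(cost = n-vector, effect = n-vector); `bad` is an environment
# accumulating rows whose explicit branch probabilities leave the simplex
node_ev_mat <- function(node, V, bad) {
  n <- nrow(V)
  if (node$type == "terminal") {
    cost <- node$cost
    if (is.character(cost)) cost <- stats::setNames(rep(1, length(cost)), cost)
    cvec <- if (is.numeric(cost) && is.null(names(cost))) rep(sum(cost), n)
            else as.vector(V[, names(cost), drop = FALSE] %*% cost)
    evec <- if (is.numeric(node$effect)) rep(node$effect, n)
            else V[, node$effect]
    return(list(cost = cvec, effect = evec))
  }
  probs <- vector("list", length(node$branches))
  comp <- vapply(node$branches, function(b) is_complement(b$prob), logical(1))
  for (i in which(!comp)) {
    pr <- node$branches[[i]]$prob
    probs[[i]] <- if (is.numeric(pr)) rep(prod(pr), n)
                  else apply(V[, pr, drop = FALSE], 1, prod)
  }
  explicit_sum <- Reduce(`+`, probs[!comp], rep(0, n))
  if (any(comp)) {
    probs[[which(comp)]] <- 1 - explicit_sum
  } else if (any(abs(explicit_sum - 1) > 1e-9)) {
    bad$rows <- union(bad$rows, which(abs(explicit_sum - 1) > 1e-9))
  }
  cost <- rep(0, n)
  effect <- rep(0, n)
  for (i in seq_along(node$branches)) {
    child <- node_ev_mat(node$branches[[i]]$node, V, bad)
    cost <- cost + probs[[i]] * child$cost
    effect <- effect + probs[[i]] * child$effect
  }
  list(cost = cost, effect = effect)
}

#' Run a probabilistic sensitivity analysis
#'
#' Samples `n` parameter vectors with [sample_parameters()] and evaluates
#' the tree on each, producing a Monte Carlo cloud of (cost, effect)
#' pairs per strategy. With every distribution degenerate (`none`), each
#' iteration reproduces the base case exactly. Iterations whose
#' explicitly specified branch probabilities do not sum to 1 (possible
#' only when a user samples complement-free branch sets independently
#' instead of via a dirichlet group) are counted and excluded.
#'
#' @param tree a `cea_decision_tree`.
#' @param params a `cea_parameter_set`.
#' @param n iterations (the bundled model's analysis uses 10,000).
#' @param seed integer seed.
#' @return an object of class `cea_psa`: list with `outcomes` (tibble
#'   `iteration`, `strategy`, `cost`, `effect`), `draws` (the sampled
#'   parameter matrix, retained for audit), `n`, `seed`, `n_excluded`.
#' @export
run_psa <- function(tree, params, n = 10000, seed = NULL) {
  report <- validate_tree(tree, params)
  if (length(report))
    abort_ceatree(c("tree validation failed:", report),
                  "ceatree_validation_error")
  V <- sample_parameters(params, n, seed)
  bad <- new.env()
  bad$rows <- integer(0)
  per_strategy <- lapply(names(tree$strategies), function(s) {
    ev <- node_ev_mat(tree$strategies[[s]], V, bad)
    tibble::tibble(iteration = seq_len(n), strategy = s,
                   cost = ev$cost, effect = ev$effect)
  })
  outcomes <- dplyr::bind_rows(per_strategy)
  if (length(bad$rows)) {
    warning(sprintf(
      "%d PSA iteration(s) produced branch probabilities off the simplex and were excluded",
      length(bad$rows)))
    outcomes <- outcomes[!outcomes$iteration %in% bad$rows, ]
    V <- V[-bad$rows, , drop = FALSE]
  }
  structure(
    list(outcomes = outcomes, draws = V, n = n, seed = seed,
         n_excluded = length(bad$rows)),
    class = "cea_psa"
  )
}

#' @export
print.cea_psa <- function(x, ...) {
  cat(sprintf("<cea_psa> %d iterations x %d strategies (seed %s)\n",
              x$n, length(unique(x$outcomes$strategy)),
              x$seed %||% "none"))
  print(psa_summary(x), ...)
  invisible(x)
}

#' Summarise a PSA cloud
#'
#' @param psa a `cea_psa` object.
#' @return tibble per strategy: mean cost/effect, Monte Carlo standard
#'   errors, and 95% prediction intervals.
#' @export
psa_summary <- function(psa) {
  psa$outcomes |>
    dplyr::group_by(.data$strategy) |>
    dplyr::summarise(
      mean_cost = mean(.data$cost),
      mcse_cost = stats::sd(.data$cost) / sqrt(dplyr::n()),
      cost_lo = stats::quantile(.data$cost, 0.025, names = FALSE),
      cost_hi = stats::quantile(.data$cost, 0.975, names = FALSE),
      mean_effect = mean(.data$effect),
      mcse_effect = stats::sd(.data$effect) / sqrt(dplyr::n()),
      effect_lo = stats::quantile(.data$effect, 0.025, names = FALSE),
      effect_hi = stats::quantile(.data$effect, 0.975, names = FALSE)
    )
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the probability that each strategy
#' has the strictly highest net monetary benefit across PSA iterations;
#' ties are split equally among the tied strategies, so at every lambda
#' the probabilities sum to 1.
#'
#' @param psa a `cea_psa` object with at least two strategies.
#' @param lambdas numeric grid of willingness-to-pay values (RMB/QALY).
#' @return tibble: `lambda`, `strategy`, `probability`.
#' @export
ceac <- function(psa, lambdas) {
  if (!length(lambdas)) abort_ceatree("empty lambda grid", "ceatree_input_error")
  strategies <- unique(psa$outcomes$strategy)
  if (length(strategies) < 2)
    abort_ceatree("CEAC needs >= 2 strategies", "ceatree_input_error")
  iters <- sort(unique(psa$outcomes$iteration))
  cost <- matrix(psa$outcomes$cost, nrow = length(iters))
  effect <- matrix(psa$outcomes$effect, nrow = length(iters))
  res <- lapply(lambdas, function(l) {
    benefit <- l * effect - cost
    top <- apply(benefit, 1, max)
    win <- benefit >= top - 1e-12 * pmax(1, abs(top)) # ties within rounding
    share <- win / rowSums(win)
    tibble::tibble(lambda = l, strategy = strategies,
                   probability = colMeans(share))
  })
  dplyr::bind_rows(res)
}

#' Empirical prediction interval from a PSA cloud
#'
#' Central interval from the empirical quantiles (linear interpolation,
#' type 7) of a per-strategy quantity across iterations.
#'
#' @param psa a `cea_psa` object.
#' @param quantity one of `"cost"`, `"effect"`, `"nmb"`.
#' @param level coverage level in (0, 1), default 0.95.
#' @param lambda willingness-to-pay, required for `quantity = "nmb"`.
#' @return tibble per strategy: `lower`, `upper`.
#' @export
prediction_interval <- function(psa, quantity = c("cost", "effect", "nmb"),
                                level = 0.95, lambda = NULL) {
  quantity <- match.arg(quantity)
  if (level <= 0 || level >= 1)
    abort_ceatree("level must be in (0, 1)", "ceatree_input_error")
  x <- psa$outcomes
  x$value <- switch(quantity,
    cost = x$cost,
    effect = x$effect,
    nmb = {
      if (is.null(lambda))
        abort_ceatree("lambda required for nmb intervals", "ceatree_input_error")
      lambda * x$effect - x$cost
    })
  probs <- c((1 - level) / 2, (1 + level) / 2)
  x |>
    dplyr::group_by(.data$strategy) |>
    dplyr::summarise(
      quantity = quantity, level = level,
      lower = stats::quantile(.data$value, probs[1], names = FALSE),
      upper = stats::quantile(.data$value, probs[2], names = FALSE)
    )
}
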