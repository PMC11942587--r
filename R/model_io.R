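#' Write a model to a JSON model file
#'
#' Serialises a `cea_model` (tree, parameters, willingness-to-pay,
#' exchange rate, metadata) to the package's JSON model-file schema
#' (`ceatree-model/1`). [read_model()] on the written file reproduces a
#' semantically equal model.
#'
#' @param model a `cea_model` (e.g. from [build_picc_model()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  doc <- list(
    schema = "ceatree-model/1",
    metadata = model$metadata,
    exchange_rate = model$exchange_rate,
    wtp = model$wtp,
    parameters = lapply(unname(unclass(model$params)), function(p) {
      out <- list(name = p$name, kind = p$kind, base = p$base,
                  distribution = p$distribution)
      if (!is.null(p$owsa_range)) out$owsa_range <- p$owsa_range
      if (!is.null(p$note)) out$note <- p$note
      out
    }),
    strategies = lapply(names(model$tree$strategies), function(s) {
      list(name = s, root = serialize_node(model$tree$strategies[[s]]))
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

serialize_node <- function(node) {
  if (node$type == "terminal") {
    cost <- node$cost
    cost_json <- if (is.numeric(cost) && is.null(names(cost))) sum(cost)
                 else as.list(cost)
    list(type = "terminal", name = node$name, cost = cost_json,
         effect = node$effect)
  } else {
    list(type = "chance", name = node$name,
         branches = lapply(node$branches, function(b) {
           pr <- b$prob
           # character vectors of length > 1 must stay arrays in JSON
           pr_json <- if (is.character(pr) && length(pr) > 1) as.list(pr)
                      else pr
           list(prob = pr_json, node = serialize_node(b$node))
         }))
  }
}

#' Read and validate a JSON model file
#'
#' Parses a `ceatree-model/1` document into a `cea_model` and validates
#' it end to end, collecting *all* schema violations and tree/parameter
#' invariant violations rather than failing on the first. Unknown fields
#' produce warnings (forward compatibility); structural and type
#' violations are errors carrying the JSON path of the offending entry.
#'
#' @param path model file path.
#' @return a validated `cea_model`.
#' @export
#' @examples
#' model <- read_model(picc_model_file())
#' rollback(model$tree, model$params)
read_model <- function(path) {
  if (!file.exists(path))
    abort_ceatree(sprintf("model file not found: %s", path),
                  "ceatree_schema_error")
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    abort_ceatree(sprintf("cannot parse '%s': %s",
                                          path, conditionMessage(e)),
                                  "ceatree_schema_error"))
  errs <- character(0)
  note <- function(msg) errs <<- c(errs, msg)

  known <- c("schema", "metadata", "exchange_rate", "wtp", "parameters",
             "strategies")
  extra <- setdiff(names(doc), known)
  if (length(extra))
    warning(sprintf("ignoring unknown top-level field(s): %s",
                    paste(extra, collapse = ", ")))
  for (req in c("parameters", "strategies"))
    if (is.null(doc[[req]])) note(sprintf("$.%s: missing", req))
  if (length(errs))
    abort_ceatree(c("model file violations:", errs), "ceatree_schema_error")

  params <- lapply(seq_along(doc$parameters), function(i) {
    p <- doc$parameters[[i]]
    at <- sprintf("$.parameters[%d]", i)
    if (is.null(p$name) || !is.character(p$name)) {
      note(sprintf("%s.name: missing or not a string", at))
      return(NULL)
    }
    if (is.null(p$kind) || !p$kind %in% c("probability", "cost", "utility")) {
      note(sprintf("%s.kind: must be probability|cost|utility", at))
      return(NULL)
    }
    if (is.null(p$base) || !is.numeric(p$base)) {
      note(sprintf("%s.base: missing or not a number", at))
      return(NULL)
    }
    rng <- if (!is.null(p$owsa_range)) unlist(p$owsa_range)
    parameter_spec(p$name, p$kind, p$base,
                   distribution = p$distribution,
                   owsa_range = rng, note = p$note)
  })
  params <- params[!vapply(params, is.null, logical(1))]

  strategies <- list()
  for (i in seq_along(doc$strategies)) {
    s <- doc$strategies[[i]]
    at <- sprintf("$.strategies[%d]", i)
    if (is.null(s$name) || is.null(s$root)) {
      note(sprintf("%s: needs name and root", at))
      next
    }
    strategies[[s$name]] <- parse_node(s$root, paste0(at, ".root"), note)
  }
  if (length(errs))
    abort_ceatree(c("model file violations:", errs), "ceatree_schema_error")

  model <- structure(
    list(tree = decision_tree(strategies),
         params = parameter_set(params),
         wtp = doc$wtp %||% list(lambda = NA_real_),
         exchange_rate = doc$exchange_rate %||% list(rmb_per_100_usd = 678.03),
         metadata = doc$metadata %||% list()),
    class = "cea_model")
  if (!is.null(model$wtp$lambda) && !is.na(model$wtp$lambda) &&
      model$wtp$lambda <= 0)
    note("$.wtp.lambda: must be > 0")
  if (model$exchange_rate$rmb_per_100_usd <= 0)
    note("$.exchange_rate.rmb_per_100_usd: must be > 0")
  errs <- c(errs, validate_tree(model$tree, model$params))
  if (length(errs))
    abort_ceatree(c("model file violations:", errs),
                  "ceatree_validation_error")
  model
}

parse_node <- function(x, at, note) {
  if (is.null(x$type) || !x$type %in% c("chance", "terminal")) {
    note(sprintf("%s.type: must be chance|terminal", at))
    return(terminal_node("invalid", 0, 0))
  }
  nm <- x$name %||% "unnamed"
  if (x$type == "terminal") {
    cost <- x$cost
    if (is.list(cost)) cost <- unlist(cost)
    if (is.null(cost) || !is.numeric(cost)) {
      note(sprintf("%s.cost: must be a number or {parameter: multiplier}", at))
      cost <- 0
    }
    effect <- x$effect
    if (is.null(effect) || !(is.numeric(effect) || is.character(effect))) {
      note(sprintf("%s.effect: must be a number or a parameter name", at))
      effect <- 0
    }
    return(terminal_node(nm, cost, effect))
  }
  branches <- lapply(seq_along(x$branches), function(i) {
    b <- x$branches[[i]]
    bat <- sprintf("%s.branches[%d]", at, i)
    pr <- b$prob
    if (is.list(pr)) pr <- unlist(pr)
    if (is.null(pr) || !(is.numeric(pr) || is.character(pr))) {
      note(sprintf("%s.prob: must be a number, parameter name(s), or 'complement'",
                   bat))
      pr <- 0
    }
    branch(pr, parse_node(b$node, paste0(bat, ".node"), note))
  })
  chance_node(nm, branches)
}

#' @export
print.cea_model <- function(x, ...) {
  cat(sprintf("<cea_model> %s\n", x$metadata$title %||% "unnamed model"))
  cat(sprintf("  strategies: %s\n",
              paste(names(x$tree$strategies), collapse = ", ")))
  cat(sprintf("  parameters: %d; WTP lambda: %s RMB/QALY\n",
              length(x$params), format(x$wtp$lambda)))
  invisible(x)
}

#' Run the full analysis of a model end to end
#'
#' Base-case rollback and incremental analysis, a willingness-to-pay
#' sweep, a tornado table, a probabilistic sensitivity analysis with
#' CEAC and prediction intervals, and — when a cohort config is supplied
#' — a synthetic cohort with bias-corrected bootstrap intervals for
#' every cost component. All randomness derives from `seed`; two runs
#' with the same inputs and seed produce identical results (and, via
#' [write_report()], byte-identical files apart from the manifest
#' timestamp).
#'
#' @param model a `cea_model`.
#' @param psa_iterations Monte Carlo iterations (default 10,000).
#' @param bootstrap_B bootstrap resamples (default 10,000).
#' @param seed integer seed.
#' @param cohort_config optional `cea_cohort_config` for the
#'   patient-level arm of the analysis.
#' @param lambdas willingness-to-pay grid for the sweep and CEAC
#'   (default 0 to 2 x the model threshold in 41 steps).
#' @return a list of class `cea_results` with elements `base_case`,
#'   `incremental`, `wtp_sweep`, `tornado`, `psa`, `psa_summary`,
#'   `ceac`, `prediction_intervals`, `cohort`, `cost_cis`, `manifest`.
#' @export
run_cea_analysis <- function(model, psa_iterations = 10000,
                             bootstrap_B = 10000, seed = 1,
                             cohort_config = NULL, lambdas = NULL) {
  lambda <- model$wtp$lambda
  if (is.null(lambdas)) lambdas <- seq(0, 2 * lambda, length.out = 41)
  base_case <- rollback(model$tree, model$params)
  inc <- incremental(base_case[1, ], base_case[2, ], lambda)
  sweep <- wtp_sweep(base_case, lambdas)
  torn <- tornado(model$tree, model$params, lambda = lambda)
  psa <- run_psa(model$tree, model$params, n = psa_iterations, seed = seed)
  curves <- ceac(psa, lambdas)
  pis <- dplyr::bind_rows(
    prediction_interval(psa, "cost"),
    prediction_interval(psa, "effect"),
    prediction_interval(psa, "nmb", lambda = lambda))
  cohort <- NULL
  cis <- NULL
  if (!is.null(cohort_config)) {
    cohort <- generate_cohort(cohort_config, seed = seed + 1)
    cis <- cost_component_cis(cohort, B = bootstrap_B, seed = seed + 2)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("ceatree")),
    seed = seed,
    psa_iterations = psa_iterations,
    psa_excluded = psa$n_excluded,
    bootstrap_B = bootstrap_B,
    lambda = lambda,
    lambda_grid = range(lambdas),
    defaults_used = list(
      cost_cv = 0.3,
      owsa_probability_range = "Wilson interval when counts exist, else +/-50% clamped to [0,1]",
      owsa_cost_range = "+/-25%",
      distribution_families = "beta for count probabilities, dirichlet for branch sets, gamma for costs, utilities fixed"
    )
  )
  structure(list(base_case = base_case, incremental = inc,
                 wtp_sweep = sweep, tornado = torn,
                 psa = psa, psa_summary = psa_summary(psa), ceac = curves,
                 prediction_intervals = pis,
                 cohort = cohort, cost_cis = cis,
                 model = model, manifest = manifest),
            class = "cea_results")
}

#' Write analysis results to disk
#'
#' Writes CSV/JSON result files and a human-readable markdown summary:
#' `base_case.csv` (RMB and USD side by side), `incremental.json` (the
#' computed increments and ICER-or-status *and*, for models that carry
#' one, the verbatim `paper_reported` annotation block from the model
#' metadata), `wtp_sweep.csv`, `tornado.csv`, `psa_cloud.csv`,
#' `ceac.csv`, `psa_summary.json`, `cohort.csv`, `cost_cis.csv`,
#' `summary.md`, and `run_manifest.json`. Apart from the timestamp in
#' the manifest, repeated runs with the same seed produce byte-identical
#' files.
#'
#' @param results a `cea_results` from [run_cea_analysis()].
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_report <- function(results, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  model <- results$model
  rate <- model$exchange_rate$rmb_per_100_usd
  wr <- function(df, name)
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)

  bc <- results$base_case
  bc_out <- tibble::tibble(
    strategy = bc$strategy,
    expected_cost_rmb = round_half_away(bc$expected_cost),
    expected_cost_usd = rmb_to_usd(bc$expected_cost, rate),
    expected_effect_qaly = round_half_away(bc$expected_effect, 4))
  wr(bc_out, "base_case.csv")
  jsonlite::write_json(bc_out, file.path(dir, "base_case.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  inc <- results$incremental
  inc_doc <- list(
    computed = list(
      intervention = inc$intervention, comparator = inc$comparator,
      delta_cost_rmb = round_half_away(inc$delta_cost),
      delta_cost_usd = rmb_to_usd(inc$delta_cost, rate),
      delta_effect_qaly = round_half_away(inc$delta_effect, 4),
      icer_rmb_per_qaly = if (is.na(inc$icer)) NULL
                          else round_half_away(inc$icer),
      status = inc$status,
      inmb_rmb = round_half_away(inc$inmb),
      cost_effective_at_lambda = inc$cost_effective,
      lambda_rmb_per_qaly = model$wtp$lambda,
      lambda_usd_per_qaly = rmb_to_usd(model$wtp$lambda, rate)))
  if (!is.null(model$metadata$paper_reported))
    inc_doc$paper_reported <- model$metadata$paper_reported
  jsonlite::write_json(inc_doc, file.path(dir, "incremental.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  wr(results$wtp_sweep, "wtp_sweep.csv")
  wr(results$tornado, "tornado.csv")
  wr(results$psa$outcomes, "psa_cloud.csv")
  wr(results$ceac, "ceac.csv")
  jsonlite::write_json(results$psa_summary, file.path(dir, "psa_summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  wr(results$prediction_intervals, "prediction_intervals.csv")
  if (!is.null(results$cohort)) wr(results$cohort, "cohort.csv")
  if (!is.null(results$cost_cis)) wr(results$cost_cis, "cost_cis.csv")

  manifest <- results$manifest
  manifest$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  writeLines(summary_md(results, rate), file.path(dir, "summary.md"))
  invisible(dir)
}

summary_md <- function(results, rate) {
  bc <- results$base_case
  inc <- results$incremental
  model <- results$model
  lines <- c(
    sprintf("# %s", model$metadata$title %||% "Cost-effectiveness analysis"),
    "",
    "## Base case",
    "",
    "| Strategy | Cost (RMB) | Cost (USD) | Effect (QALY) |",
    "|---|---|---|---|",
    sprintf("| %s | %.2f | %.2f | %.4f |", bc$strategy,
            round_half_away(bc$expected_cost),
            rmb_to_usd(bc$expected_cost, rate),
            bc$expected_effect),
    "",
    "## Incremental analysis (computed)",
    "",
    sprintf("- %s vs %s", inc$intervention, inc$comparator),
    sprintf("- Delta cost: %.2f RMB (%.2f USD)",
            round_half_away(inc$delta_cost), rmb_to_usd(inc$delta_cost, rate)),
    sprintf("- Delta effect: %.4f QALY", inc$delta_effect),
    if (inc$status == "icer")
      sprintf("- ICER: %.2f RMB/QALY", round_half_away(inc$icer))
    else
      sprintf("- ICER: not reported (status: %s; negative ratios are suppressed)",
              inc$status),
    sprintf("- Incremental NMB at lambda = %s RMB/QALY: %.2f RMB -> %s",
            format(model$wtp$lambda), round_half_away(inc$inmb),
            if (inc$cost_effective) "cost-effective" else "not cost-effective"))
  pr <- model$metadata$paper_reported
  if (!is.null(pr)) {
    lines <- c(lines, "",
      "## Source-analysis figures (verbatim annotation)", "",
      pr$note %||% character(0), "",
      sprintf("- Reported mean costs (RMB): %s",
              paste(sprintf("%s %.2f", names(unlist(pr$mean_cost_rmb)),
                            unlist(pr$mean_cost_rmb)), collapse = ", ")),
      sprintf("- Reported QALYs: %s",
              paste(sprintf("%s %.2f", names(unlist(pr$qaly)),
                            unlist(pr$qaly)), collapse = ", ")),
      sprintf("- Reported incremental cost: %.2f RMB (%.2f USD as printed)",
              pr$incremental_cost_rmb, pr$incremental_cost_usd),
      sprintf("- Reported ICER: %.2f RMB/QALY (%.2f USD as printed)",
              pr$icer_rmb_per_qaly, pr$icer_usd_per_qaly))
  }
  ps <- results$psa_summary
  lines <- c(lines, "", "## Probabilistic sensitivity analysis", "",
    sprintf("- %d iterations (seed %s), %d excluded",
            results$psa$n, format(results$psa$seed), results$psa$n_excluded),
    sprintf("- %s: mean cost %.2f (95%% PI %.2f-%.2f), mean effect %.4f (95%% PI %.4f-%.4f)",
            ps$strategy, ps$mean_cost, ps$cost_lo, ps$cost_hi,
            ps$mean_effect, ps$effect_lo, ps$effect_hi))
  if (!is.null(results$cost_cis)) {
    tot <- results$cost_cis[results$cost_cis$category == "total", ]
    lines <- c(lines, "", "## Bootstrap cost intervals (per-patient totals)", "",
      sprintf("- %s: %.2f RMB, 95%% BC interval [%.2f, %.2f] (B = %d)",
              tot$arm, tot$estimate, tot$lower, tot$upper, tot$B))
  }
  lines
}
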