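#' Fit reverse causal reasoning to a differential-expression data set
#'
#' Runs the full inference: collapse the causal knowledge graph, map
#' measurements to trinary node states, derive one mechanism hypothesis
#' network (HYP) per controller with enough measured downstream RNAs,
#' assign each HYP a direction by majority vote of its changed downstream
#' nodes, and score every HYP with a hypergeometric richness p-value and an
#' ambiguity-corrected binomial concordance p-value.
#'
#' @param edges Raw causal edge table (data frame with `source`,
#'   `relation`, `target`), a path to an edge TSV, or an already collapsed
#'   `causal_graph`.
#' @param de Differential-expression table (data frame with `id`,
#'   `fold_change`, `adj_p`, `avg_abundance`) or a path to one.
#' @param mapping Measurement-to-node table (data frame with
#'   `measurement_id`, `node_id`) or a path to one.
#' @param fc_threshold,p_threshold,abundance_threshold Significance
#'   criteria for a state change: |fold change| >= 1.3, adjusted
#'   p <= 0.05, average abundance >= 32 by default.
#' @param min_possible Minimum measured downstream RNAs for a controller to
#'   be evaluated (default 4).
#' @param alpha Joint richness/concordance significance threshold
#'   (default 0.1).
#' @param fc_scale `"linear"` or `"log2"` fold changes when `de` is a path.
#' @return An object of class `rcr`: a list with the collapsed `graph`,
#'   the `states` vector, the `hyps` set, the `population` (N, m), the
#'   full `scores` table, the `significant` subset, the thresholds used,
#'   and the matched `call`.
#' @examples
#' spec <- fixture_spec(planted = list(list(controller = "act(SYN:C1)",
#'                                          direction = 1, penetrance = 0.9)))
#' fx <- generate_fixture_graph(spec)
#' de <- simulate_de_table(fx, spec)
#' fit <- rcr(fx$edges, de, fx$mapping)
#' summary(fit)
#' @export
rcr <- function(edges, de, mapping,
                fc_threshold = 1.3, p_threshold = 0.05,
                abundance_threshold = 32, min_possible = 4, alpha = 0.1,
                fc_scale = c("linear", "log2")) {
  fc_scale <- match.arg(fc_scale)
  graph <- if (inherits(edges, "causal_graph")) edges
           else if (is.character(edges)) read_causal_graph(edges)
           else collapse_edges(edges)
  if (is.character(de)) de <- read_de_table(de, fc_scale = fc_scale)
  if (is.character(mapping)) mapping <- read_mapping(mapping)

  states <- map_to_nodes(de, mapping, graph, fc_min = fc_threshold,
                         p_max = p_threshold, abund_min = abundance_threshold)
  hyps <- generate_hyps(graph, names(states), min_possible = min_possible)
  if (length(hyps) == 0L) {
    stop("no HYPs could be generated: no controller has >= ", min_possible,
         " measured downstream RNA nodes (check the graph/mapping overlap)",
         call. = FALSE)
  }
  pop <- compute_population(hyps, states)
  if (pop$m == 0L) {
    warning("no state changes in the population; all p-values are 1",
            call. = FALSE)
  }
  scores <- score_hyps(hyps, states, pop)
  fit <- list(
    graph = graph, states = states, hyps = hyps, population = pop,
    scores = scores, significant = filter_significant(scores, alpha),
    thresholds = list(fc = fc_threshold, p = p_threshold,
                      abundance = abundance_threshold,
                      min_possible = min_possible, alpha = alpha),
    call = match.call()
  )
  class(fit) <- "rcr"
  fit
}

#' @export
print.rcr <- function(x, ...) {
  cat("Reverse causal reasoning fit\n")
  cat("  population N =", x$population$N, ", state changes m =",
      x$population$m, "\n")
  cat("  HYPs evaluated:", nrow(x$scores),
      "; significant at alpha =", x$thresholds$alpha, ":",
      nrow(x$significant), "\n")
  invisible(x)
}

#' @export
summary.rcr <- function(object, ...) {
  out <- list(
    N = object$population$N, m = object$population$m,
    n_hyps = nrow(object$scores), n_significant = nrow(object$significant),
    thresholds = object$thresholds,
    top = utils::head(format_scores(object$scores), 10L)
  )
  class(out) <- "summary.rcr"
  out
}

#' @export
print.summary.rcr <- function(x, ...) {
  cat("Reverse causal reasoning summary\n")
  cat("  population N =", x$N, "; state changes m =", x$m, "\n")
  cat("  HYPs evaluated:", x$n_hyps, "; significant (richness and ",
      "concordance <= ", x$thresholds$alpha, "): ", x$n_significant,
      "\n\n", sep = "")
  cat("Top mechanisms by concordance:\n")
  print(x$top, row.names = FALSE)
  invisible(x)
}

#' Plot p-values against HYP size
#'
#' Diagnostic scatter of log10 richness and concordance p-values versus
#' HYP size (`possible`); both statistics are intrinsically biased towards
#' significance for larger HYPs.
#'
#' @param x An `rcr` fit.
#' @param which `"concordance"`, `"richness"`, or both.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.rcr <- function(x, which = c("concordance", "richness"), ...) {
  which <- match.arg(which, several.ok = TRUE)
  old <- graphics::par(mfrow = c(1, length(which)))
  on.exit(graphics::par(old))
  for (w in which) {
    graphics::plot(x$scores$possible, log10(x$scores[[w]]),
                   xlab = "possible (downstream measured RNAs)",
                   ylab = paste0("log10 ", w, " p-value"), ...)
    graphics::abline(h = log10(x$thresholds$alpha), lty = 2)
  }
  invisible(x)
}

#' Simulate matched random score tables from a fit
#'
#' Draws `nsim` matched random state sets (same population, same numbers
#' of increased and decreased nodes as the fitted data) and rescores the
#' fit's HYP set on each — the null ensemble used for threshold
#' calibration and size-bias diagnostics.
#'
#' @param object An `rcr` fit.
#' @param nsim Number of random data sets.
#' @param seed Master seed.
#' @param ... Unused.
#' @return Stacked null score table with an `iteration` column.
#' @export
simulate.rcr <- function(object, nsim = 1000, seed = 1, ...) {
  score_random_sets(object$hyps, object$population, object$states,
                    iterations = nsim, seed = seed)
}

#' Run the full pipeline and write result files
#'
#' Thin orchestration over [rcr()]: fits the model from the three input
#' files, writes the formatted score table, a run summary JSON (population
#' constants, HYP counts, the resolved configuration and seed), and
#' optionally the randomization threshold sweep.
#'
#' @param edges,de,mapping Input file paths (see [rcr()]).
#' @param out_dir Output directory, created if needed.
#' @param randomizations Number of matched random data sets for the sweep;
#'   0 skips the sweep.
#' @param sweep_thresholds Thresholds for [threshold_sweep()].
#' @param seed Master seed for all randomization.
#' @param ... Further arguments to [rcr()] (thresholds, `fc_scale`, ...).
#' @return The `rcr` fit, invisibly; files `results.tsv`, `summary.json`
#'   and (if requested) `sweep.tsv` appear in `out_dir`.
#' @export
rcr_run <- function(edges, de, mapping, out_dir,
                    randomizations = 0,
                    sweep_thresholds = c(0.2, 0.15, 0.1, 0.05, 0.01, 0.005),
                    seed = 1, ...) {
  fit <- rcr(edges, de, mapping, ...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  format_scores(fit$scores, file.path(out_dir, "results.tsv"))
  smry <- list(
    population_N = fit$population$N,
    state_changes_m = fit$population$m,
    hyps_evaluated = nrow(fit$scores),
    hyps_significant = nrow(fit$significant),
    thresholds = fit$thresholds,
    randomizations = randomizations,
    seed = seed,
    version = as.character(utils::packageVersion("rcr"))
  )
  jsonlite::write_json(smry, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (randomizations > 0) {
    sweep <- threshold_sweep(fit$hyps, fit$population, fit$states,
                             iterations = randomizations,
                             thresholds = sweep_thresholds, seed = seed)
    utils::write.table(sweep, file.path(out_dir, "sweep.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  message("population N=", fit$population$N, " m=", fit$population$m,
          "; HYPs evaluated=", nrow(fit$scores),
          " significant=", nrow(fit$significant))
  invisible(fit)
}
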