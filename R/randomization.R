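#' Draw one matched random state set
#'
#' Samples `n_up + n_down` distinct nodes uniformly without replacement
#' from the population and assigns +1 to `n_up` of them and -1 to `n_down`;
#' all other population nodes get state 0. This preserves the marginal
#' counts of significantly increased and decreased RNAs of the real data
#' set while permuting which nodes carry them — the matched-random null
#' used for threshold calibration.
#'
#' @param pop Population list from [compute_population()].
#' @param n_up,n_down Numbers of increased / decreased nodes to plant.
#' @return Named integer state vector over all population nodes.
#' @export
sample_random_states <- function(pop, n_up, n_down) {
  total <- n_up + n_down
  if (total > pop$N) {
    stop("n_up + n_down exceeds the population size", call. = FALSE)
  }
  states <- stats::setNames(integer(pop$N), pop$nodes)
  changed <- sample(pop$nodes, total)
  if (n_up > 0) states[changed[seq_len(n_up)]] <- 1L
  if (n_down > 0) states[changed[n_up + seq_len(n_down)]] <- -1L
  states
}

# Per-iteration seeds derived once from the master seed, so iteration i is
# reproducible in isolation (and a shorter run is a prefix of a longer one).
.iteration_seeds <- function(seed, iterations) {
  set.seed(seed)
  as.integer(floor(stats::runif(iterations, 1, .Machine$integer.max)))
}

#' Score HYPs over matched random data sets
#'
#' Repeatedly draws matched random state sets (same population, same
#' numbers of increased and decreased nodes as the real data), scores the
#' fixed HYP set on each, and returns all null scores. The HYP set and
#' population are held constant across iterations; only the identity of
#' the changed nodes is randomised.
#'
#' @param hyps A `hyp_set`.
#' @param pop Population from [compute_population()] for the same HYPs.
#' @param real_states Named integer state vector of the real data set
#'   (defines the matched `n_up`, `n_down`).
#' @param iterations Number of random data sets (default 1000).
#' @param seed Master seed; each iteration gets its own derived stream.
#' @return Data frame of stacked score tables with an `iteration` column.
#' @export
score_random_sets <- function(hyps, pop, real_states, iterations = 1000,
                              seed = 1) {
  stopifnot(iterations >= 1)
  st <- real_states[match(pop$nodes, names(real_states))]
  st[is.na(st)] <- 0L
  n_up <- sum(st == 1L)
  n_down <- sum(st == -1L)
  seeds <- .iteration_seeds(seed, iterations)
  out <- vector("list", iterations)
  for (i in seq_len(iterations)) {
    set.seed(seeds[i])
    rs <- sample_random_states(pop, n_up, n_down)
    sc <- score_hyps(hyps, rs, pop)
    sc$iteration <- i
    out[[i]] <- sc
  }
  do.call(rbind, out)
}

#' Significance-threshold sweep against matched random data
#'
#' For each candidate p-value threshold, counts the HYPs passing the joint
#' richness-and-concordance filter in the real data and the median such
#' count over matched random data sets; their ratio estimates the
#' false-positive fraction at that threshold.
#'
#' @inheritParams score_random_sets
#' @param thresholds Candidate p-value cutoffs.
#' @return Data frame with columns `threshold`, `random_median`,
#'   `real_count`, `ratio` (random/real as a fraction; `NA` when the real
#'   count is 0) and `ratio_pct` (whole-percent rendering).
#' @export
threshold_sweep <- function(hyps, pop, real_states, iterations = 1000,
                            thresholds = c(0.2, 0.15, 0.1, 0.05, 0.01, 0.005),
                            seed = 1) {
  stopifnot(all(thresholds > 0 & thresholds < 1))
  real_scores <- score_hyps(hyps, real_states, pop)
  null_scores <- score_random_sets(hyps, pop, real_states,
                                   iterations = iterations, seed = seed)
  res <- lapply(thresholds, function(a) {
    real_n <- nrow(filter_significant(real_scores, a))
    per_iter <- tapply(
      null_scores$richness <= a & null_scores$concordance <= a,
      null_scores$iteration, sum
    )
    med <- stats::median(as.numeric(per_iter))
    data.frame(threshold = a, random_median = med, real_count = real_n,
               ratio = if (real_n > 0) med / real_n else NA_real_)
  })
  res <- do.call(rbind, res)
  res <- res[order(-res$threshold), , drop = FALSE]
  res$ratio_pct <- ifelse(is.na(res$ratio), "N/A",
                          paste0(round(100 * res$ratio), "%"))
  rownames(res) <- NULL
  res
}

#' Size-bias diagnostics for the evaluation statistics
#'
#' Both p-values are biased in favour of HYPs with more downstream nodes.
#' This reports the Pearson correlation between log10 p-value and HYP size
#' (`possible`) over null scores, overall and restricted to HYPs with at
#' least `min_observed` changed nodes — the restriction under which
#' concordance is critically evaluated in practice.
#'
#' @param scored Stacked score table (e.g. from [score_random_sets()]).
#' @param min_observed Restriction threshold (default 4).
#' @return Data frame with one row per (statistic, subset) combination:
#'   `statistic`, `subset`, `n`, `correlation` (`NA` when a p-value or size
#'   column is constant).
#' @export
size_bias_report <- function(scored, min_observed = 4) {
  if (nrow(scored) < 3L) {
    stop("need at least 3 scored HYPs for a correlation", call. = FALSE)
  }
  if (length(unique(scored$possible)) < 2L) {
    stop("need at least 2 distinct HYP sizes", call. = FALSE)
  }
  one <- function(df, stat, label) {
    lp <- log10(df[[stat]])
    r <- if (stats::sd(lp) == 0 || stats::sd(df$possible) == 0) NA_real_
         else stats::cor(lp, df$possible)
    data.frame(statistic = stat, subset = label, n = nrow(df),
               correlation = r, stringsAsFactors = FALSE)
  }
  restricted <- scored[scored$observed >= min_observed, , drop = FALSE]
  out <- rbind(
    one(scored, "richness", "all"),
    one(scored, "concordance", "all"),
    if (nrow(restricted) >= 3L)
      one(restricted, "richness", paste0("observed>=", min_observed)),
    if (nrow(restricted) >= 3L)
      one(restricted, "concordance", paste0("observed>=", min_observed))
  )
  rownames(out) <- NULL
  out
}

#' LOESS size-adjusted concordance
#'
#' Fits a LOESS curve to log10 concordance versus HYP size over null
#' (matched-random) scores and subtracts the fitted trend from each real
#' HYP's log10 concordance. The adjusted value is returned alongside — never
#' replacing — the raw concordance: it is a diagnostic re-ranking aid, and
#' the raw p-value remains the reported statistic.
#'
#' @param scored_random Null score table used to fit the trend.
#' @param scored_real Score table to adjust.
#' @param span,degree LOESS parameters (defaults 0.75, 2; fit in log10
#'   space).
#' @return `scored_real` with extra columns `log_concordance`,
#'   `loess_fit`, `adj_log_concordance` (raw minus fit).
#' @export
loess_adjust_concordance <- function(scored_random, scored_real,
                                     span = 0.75, degree = 2) {
  if (length(unique(scored_random$possible)) < 2L) {
    stop("degenerate predictor: random scores span a single HYP size",
         call. = FALSE)
  }
  fit_df <- data.frame(possible = scored_random$possible,
                       lconc = log10(scored_random$concordance))
  fit <- stats::loess(lconc ~ possible, data = fit_df, span = span,
                      degree = degree,
                      control = stats::loess.control(surface = "direct"))
  out <- scored_real
  out$log_concordance <- log10(out$concordance)
  out$loess_fit <- stats::predict(fit,
                                  newdata = data.frame(possible = out$possible))
  out$adj_log_concordance <- out$log_concordance - out$loess_fit
  out
}
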