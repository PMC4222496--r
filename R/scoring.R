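# log(sum(exp(lx))) without leaving log space; lx may be -Inf.
.logsumexp <- function(lx) {
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}

#' Infer the direction of a mechanism hypothesis
#'
#' Each significantly changed downstream node implies a state for the
#' upstream controller: a node with state s connected by an edge of sign e
#' implies upstream direction s * e (an increase seen through a decreases
#' edge supports a decreased controller). Nodes on ambiguous edges imply no
#' direction and are counted as *ambiguous*. The HYP direction is the
#' majority implied direction; nodes agreeing with it are *correct*, nodes
#' opposing it *contra*, and *observed* = correct + contra + ambiguous. A
#' tie (or no unambiguous evidence) gives direction `0` ("none"), with
#' `correct` set to the tied (larger) count.
#'
#' @param hyp One HYP from [generate_hyps()].
#' @param states Named integer state vector; nodes missing from it count as
#'   unchanged.
#' @return List with `direction` (+1, -1, or 0), `correct`, `contra`,
#'   `ambiguous`, `observed`.
#' @export
assign_direction <- function(hyp, states) {
  s <- states[match(names(hyp$downstream), names(states))]
  s[is.na(s)] <- 0L
  changed <- s != 0L
  edge <- hyp$downstream
  ambiguous <- sum(changed & is.na(edge))
  implied <- s[changed & !is.na(edge)] * edge[changed & !is.na(edge)]
  up <- sum(implied == 1L)
  down <- sum(implied == -1L)
  if (up > down) {
    direction <- 1L; correct <- up; contra <- down
  } else if (down > up) {
    direction <- -1L; correct <- down; contra <- up
  } else {
    direction <- 0L; correct <- up; contra <- down
  }
  list(direction = direction, correct = correct, contra = contra,
       ambiguous = ambiguous, observed = correct + contra + ambiguous)
}

#' Concordance p-value (directional consistency)
#'
#' Upper binomial tail for the number of significantly changed downstream
#' nodes consistent with the assigned direction. Nodes on ambiguous edges
#' are excluded from the trials, so with k = `correct` and the number of
#' effective trials t = correct + contra, the p-value is
#' \deqn{\sum_{j=k}^{t} \binom{t}{j} p^j (1-p)^{t-j}}
#' computed in log space so that extreme tails (e.g. 9.2e-16 for 69 of 74)
#' do not underflow. With no trials (t = 0) the p-value is 1. Under the
#' null each changed node predicts the direction correctly with
#' probability p = 0.5.
#'
#' @param correct,contra,ambiguous Non-negative counts.
#' @param p Per-trial success probability (default 0.5).
#' @return The concordance p-value in (0, 1].
#' @export
concordance_pvalue <- function(correct, contra, ambiguous = 0, p = 0.5) {
  stopifnot(correct >= 0, contra >= 0, ambiguous >= 0, p > 0, p < 1)
  t <- correct + contra
  if (t == 0) return(1)
  j <- correct:t
  exp(.logsumexp(lchoose(t, j) + j * log(p) + (t - j) * log1p(-p)))
}

#' Richness p-value (enrichment of state changes)
#'
#' Upper hypergeometric tail for the number of significantly changed nodes
#' among a HYP's downstream nodes, against the population of all downstream
#' nodes of all HYPs. With k = `observed` changed of n = `possible`
#' downstream nodes, drawn from a population of N nodes of which m carry a
#' state change,
#' \deqn{\sum_{j=k}^{\min(n,m)} \binom{m}{j}\binom{N-m}{n-j} / \binom{N}{n}}
#' computed in log space. k = 0 gives 1 by convention.
#'
#' @param observed Number of changed downstream nodes (k); ambiguous-edge
#'   nodes included.
#' @param possible Number of downstream nodes (n).
#' @param N Population size.
#' @param m Number of state changes in the population.
#' @return The richness p-value in (0, 1].
#' @export
richness_pvalue <- function(observed, possible, N, m) {
  if (possible > N || m > N) {
    stop("possible and m cannot exceed the population size N", call. = FALSE)
  }
  stopifnot(observed >= 0, observed <= possible, observed <= m || observed == 0)
  if (observed == 0) return(1)
  j <- observed:min(possible, m)
  exp(.logsumexp(lchoose(m, j) + lchoose(N - m, possible - j) -
                   lchoose(N, possible)))
}

#' Score every HYP against the mapped states
#'
#' Assigns a direction to each HYP and computes its richness and
#' concordance p-values against the shared population constants.
#'
#' @param hyps A `hyp_set`.
#' @param states Named integer state vector.
#' @param pop Population list from [compute_population()], computed from the
#'   same `hyps`.
#' @return Data frame sorted by concordance then richness, with columns
#'   `mechanism`, `direction`, `correct`, `richness`, `concordance`,
#'   `ambiguous`, `contra`, `possible`, `observed` (the layout of the
#'   reported score tables; p-values kept at full precision).
#' @export
score_hyps <- function(hyps, states, pop) {
  stopifnot(inherits(hyps, "hyp_set"))
  rows <- lapply(unname(hyps), function(h) {
    d <- assign_direction(h, states)
    data.frame(
      mechanism = h$upstream,
      direction = d$direction,
      correct = d$correct,
      richness = richness_pvalue(d$observed, h$possible, pop$N, pop$m),
      concordance = concordance_pvalue(d$correct, d$contra, d$ambiguous),
      ambiguous = d$ambiguous,
      contra = d$contra,
      possible = h$possible,
      observed = d$observed,
      stringsAsFactors = FALSE
    )
  })
  scored <- do.call(rbind, rows)
  scored <- scored[order(scored$concordance, scored$richness,
                         scored$mechanism), , drop = FALSE]
  rownames(scored) <- NULL
  scored
}

#' Filter HYPs on the joint significance threshold
#'
#' Keeps mechanisms whose richness AND concordance p-values are both at or
#' below `alpha`. The default 0.1 is the permissive threshold calibrated
#' against matched random data sets, trading a <10% false-positive rate for
#' a low false-negative rate.
#'
#' @param scored Score table from [score_hyps()] (only `richness` and
#'   `concordance` columns are required).
#' @param alpha Significance threshold in (0, 1).
#' @return The significant subset of `scored`.
#' @export
filter_significant <- function(scored, alpha = 0.1) {
  stopifnot(alpha > 0, alpha < 1)
  scored[scored$richness <= alpha & scored$concordance <= alpha, ,
         drop = FALSE]
}

#' Format a score table for reporting
#'
#' Renders p-values in two-significant-figure scientific notation and
#' writes the table as TSV if a path is given.
#'
#' @param scored Score table from [score_hyps()].
#' @param path Optional output TSV path.
#' @return The formatted data frame, invisibly if written to `path`.
#' @export
format_scores <- function(scored, path = NULL) {
  # two significant figures, rounding halves up (table convention:
  # 0.0625 renders as 6.3E-02, not banker's-rounded 6.2E-02)
  sci2 <- function(x) {
    e <- floor(log10(x))
    mant <- floor(x / 10^e * 10 + 0.5) / 10
    bump <- mant >= 10
    mant[bump] <- 1
    e[bump] <- e[bump] + 1
    sprintf("%.1fE%+03d", mant, e)
  }
  out <- scored
  out$richness <- sci2(scored$richness)
  out$concordance <- sci2(scored$concordance)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(out))
  }
  out
}
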