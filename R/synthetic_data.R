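#' Specify a synthetic RCR fixture
#'
#' Describes a synthetic causal graph with RNA-abundance leaves plus a
#' matched differential-expression experiment with planted active
#' mechanisms. Controllers are named `act(SYN:C<i>)` and RNAs `r(SYN:G<j>)`;
#' each controller regulates a random subset of RNAs. Downstream nodes are
#' conditionally independent given the controller state, mirroring the
#' naive-Bayes-like assumption under which the evaluation statistics are
#' derived. The defaults describe a moderately sized knowledge base (20
#' controllers over 500 RNAs, out-degree 10-30, 30% repressing edges, 5%
#' conflicting-evidence edges) with a quiet background (2% of unrelated
#' RNAs differentially expressed).
#'
#' @param n_controllers Number of upstream controller nodes.
#' @param n_rna Number of RNA abundance nodes.
#' @param out_degree Length-2 integer vector: (min, max) downstream edges
#'   per controller.
#' @param sign_mix Probability an edge is a decrease (-1).
#' @param ambiguous_frac Probability a controller-RNA link carries both an
#'   increases and a decreases statement (ambiguous after collapsing).
#' @param planted List of planted active mechanisms, each
#'   `list(controller=, direction=, penetrance=)`: the controller's
#'   non-ambiguous downstream RNAs become differentially expressed with
#'   probability `penetrance`, in the direction implied by
#'   `direction * edge_sign`.
#' @param background_rate Probability an RNA not regulated by a planted
#'   controller is differentially expressed (sign uniform).
#' @param duplicate_probe_frac Fraction of RNAs measured by a second probe
#'   set (for multi-probe aggregation tests).
#' @param seed Integer seed; all fixture randomness derives from it.
#' @return An object of class `fixture_spec` (a validated list).
#' @export
fixture_spec <- function(n_controllers = 20, n_rna = 500,
                         out_degree = c(10, 30), sign_mix = 0.3,
                         ambiguous_frac = 0.05, planted = list(),
                         background_rate = 0.02,
                         duplicate_probe_frac = 0, seed = 1) {
  stopifnot(n_controllers >= 1, n_rna >= 1,
            length(out_degree) == 2, out_degree[1] <= out_degree[2],
            out_degree[1] >= 1,
            sign_mix >= 0, sign_mix <= 1,
            ambiguous_frac >= 0, ambiguous_frac <= 1,
            background_rate >= 0, background_rate <= 1,
            duplicate_probe_frac >= 0, duplicate_probe_frac <= 1)
  if (out_degree[2] > n_rna) {
    stop("max out-degree exceeds the number of RNA nodes", call. = FALSE)
  }
  for (p in planted) {
    stopifnot(is.list(p),
              all(c("controller", "direction", "penetrance") %in% names(p)),
              p$direction %in% c(-1L, 1L),
              p$penetrance >= 0, p$penetrance <= 1)
  }
  spec <- list(n_controllers = n_controllers, n_rna = n_rna,
               out_degree = as.integer(out_degree), sign_mix = sign_mix,
               ambiguous_frac = ambiguous_frac, planted = planted,
               background_rate = background_rate,
               duplicate_probe_frac = duplicate_probe_frac,
               seed = as.integer(seed))
  class(spec) <- "fixture_spec"
  spec
}

#' Generate the synthetic causal graph and probe mapping
#'
#' @param spec A [fixture_spec()].
#' @return List with `graph` (a `causal_graph`), `edges` (raw edge table,
#'   TSV-ready), and `mapping` (probe-to-node table; probe ids `P<j>`, one
#'   per RNA plus optional duplicates `P<j>b`). Deterministic per seed.
#' @export
generate_fixture_graph <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  controllers <- sprintf("act(SYN:C%d)", seq_len(spec$n_controllers))
  rnas <- sprintf("r(SYN:G%d)", seq_len(spec$n_rna))
  rows <- list()
  for (ctrl in controllers) {
    d <- spec$out_degree[1] +
      sample.int(spec$out_degree[2] - spec$out_degree[1] + 1L, 1L) - 1L
    targets <- sample(rnas, d)
    sgn <- ifelse(stats::runif(d) < spec$sign_mix, -1L, 1L)
    amb <- stats::runif(d) < spec$ambiguous_frac
    rel <- ifelse(sgn == 1L, "increases", "decreases")
    rows[[length(rows) + 1L]] <- data.frame(
      source = ctrl, relation = rel, target = targets,
      stringsAsFactors = FALSE)
    if (any(amb)) {
      rows[[length(rows) + 1L]] <- data.frame(
        source = ctrl,
        relation = ifelse(sgn[amb] == 1L, "decreases", "increases"),
        target = targets[amb], stringsAsFactors = FALSE)
    }
  }
  edges <- do.call(rbind, rows)
  graph <- collapse_edges(edges)
  # probes only for RNAs present in the knowledge graph: a probed RNA with
  # no causal edge could never join a HYP or the population
  in_graph <- which(rnas %in% graph$nodes$node)
  mapping <- data.frame(measurement_id = sprintf("P%d", in_graph),
                        node_id = rnas[in_graph], stringsAsFactors = FALSE)
  if (spec$duplicate_probe_frac > 0) {
    dup <- in_graph[stats::runif(length(in_graph)) < spec$duplicate_probe_frac]
    if (length(dup)) {
      mapping <- rbind(mapping, data.frame(
        measurement_id = sprintf("P%db", dup),
        node_id = rnas[dup], stringsAsFactors = FALSE))
    }
  }
  list(graph = graph, edges = edges, mapping = mapping)
}

# Draw DE-table rows for a vector of trinary states: changed rows clear all
# three significance criteria, unchanged rows miss at least one.
.draw_de_rows <- function(ids, states) {
  n <- length(ids)
  changed <- states != 0L
  fc <- numeric(n)
  adj_p <- numeric(n)
  abund <- stats::runif(n, 50, 5000)
  fc[changed] <- states[changed] * stats::runif(sum(changed), 1.5, 4)
  adj_p[changed] <- stats::runif(sum(changed), 1e-6, 0.04)
  # unchanged: sub-threshold fold change and non-significant p
  fc[!changed] <- sample(c(-1L, 1L), sum(!changed), replace = TRUE) *
    stats::runif(sum(!changed), 1.0, 1.2)
  adj_p[!changed] <- stats::runif(sum(!changed), 0.1, 1)
  data.frame(id = ids, fold_change = fc, adj_p = adj_p,
             avg_abundance = abund, stringsAsFactors = FALSE)
}

#' Simulate a differential-expression table with planted mechanisms
#'
#' For every planted (controller, direction, penetrance), each of the
#' controller's non-ambiguous downstream RNAs becomes differentially
#' expressed with probability `penetrance`, with sign
#' `direction * edge_sign`; RNAs downstream of ambiguous edges, and all
#' RNAs not regulated by a planted controller, change with probability
#' `background_rate` in a uniform direction. Changed rows satisfy all
#' three significance criteria (|fc| uniform in [1.5, 4], adjusted p in
#' [1e-6, 0.04], abundance in [50, 5000]); unchanged rows fail the fold
#' change and p-value criteria. The measurement randomness is seeded from
#' `spec$seed` (offset from the graph stream) so the bundle is
#' deterministic per seed.
#'
#' @param fixture_graph Result of [generate_fixture_graph()].
#' @param spec The same [fixture_spec()].
#' @return A DE data frame (`id`, `fold_change`, `adj_p`, `avg_abundance`)
#'   with one row per probe in the mapping.
#' @export
simulate_de_table <- function(fixture_graph, spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  graph <- fixture_graph$graph
  mapping <- fixture_graph$mapping
  set.seed(spec$seed + 1L)
  # the measured universe is every probed RNA, incl. those absent from the
  # graph (a measurement need not be in the knowledge base)
  rnas <- unique(mapping$node_id)
  states <- stats::setNames(integer(length(rnas)), rnas)
  planted_targets <- character()
  for (p in spec$planted) {
    if (!(p$controller %in% graph$edges$source)) {
      stop("planted controller not in graph: ", p$controller, call. = FALSE)
    }
    ed <- graph$edges[graph$edges$source == p$controller &
                        !is.na(graph$edges$sign), , drop = FALSE]
    hit <- stats::runif(nrow(ed)) < p$penetrance
    states[ed$target[hit]] <- p$direction * ed$sign[hit]
    planted_targets <- c(planted_targets, ed$target)
  }
  bg <- setdiff(rnas, planted_targets)
  flip <- bg[stats::runif(length(bg)) < spec$background_rate]
  states[flip] <- sample(c(-1L, 1L), length(flip), replace = TRUE)
  node_states <- states[match(mapping$node_id, names(states))]
  .draw_de_rows(mapping$measurement_id, node_states)
}

#' Write a complete fixture bundle to disk
#'
#' Emits the three TSVs the pipeline consumes: `edges.tsv`, `mapping.tsv`,
#' `de.tsv`.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return Named list of the three file paths, invisibly.
#' @export
write_fixture <- function(spec, dir) {
  fx <- generate_fixture_graph(spec)
  de <- simulate_de_table(fx, spec)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(edges = file.path(dir, "edges.tsv"),
                mapping = file.path(dir, "mapping.tsv"),
                de = file.path(dir, "de.tsv"))
  utils::write.table(fx$edges, paths$edges, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(fx$mapping, paths$mapping, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(de, paths$de, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
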