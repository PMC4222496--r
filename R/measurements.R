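#' Read a differential-expression results table
#'
#' Reads a tab-delimited table of differential-expression statistics as
#' produced by an upstream microarray/RNA-seq pipeline (e.g. limma). Required
#' columns: `id` (measurement/probe-set identifier), `fold_change`, `adj_p`
#' (multiplicity-adjusted p-value), `avg_abundance` (average normalised
#' expression). Fold changes may be supplied as signed linear ratios
#' (convention |fc| >= 1, negative = down-regulated) or as log2 fold changes,
#' which are converted to signed linear via `sign(x) * 2^|x|`.
#'
#' @param path Path to the TSV file.
#' @param fc_scale `"linear"` (default) or `"log2"`.
#' @return A data frame with columns `id`, `fold_change` (signed linear),
#'   `adj_p`, `avg_abundance`.
#' @export
read_de_table <- function(path, fc_scale = c("linear", "log2")) {
  fc_scale <- match.arg(fc_scale)
  if (!file.exists(path)) stop("DE table not found: ", path, call. = FALSE)
  de <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("id", "fold_change", "adj_p", "avg_abundance")
  missing_cols <- setdiff(need, names(de))
  if (length(missing_cols)) {
    stop("DE table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("fold_change", "adj_p", "avg_abundance")) {
    v <- de[[col]]
    if (!is.numeric(v)) {
      num <- suppressWarnings(as.numeric(v))
      if (anyNA(num) & !anyNA(v)) {
        stop("DE table column '", col, "' non-numeric at data row ",
             which(is.na(num))[1L], call. = FALSE)
      }
      v <- num
    }
    if (anyNA(v)) {
      stop("DE table column '", col, "' missing/non-numeric at data row ",
           which(is.na(v))[1L], call. = FALSE)
    }
    de[[col]] <- v
  }
  de$id <- as.character(de$id)
  if (fc_scale == "log2") {
    de$fold_change <- sign(de$fold_change) * 2^abs(de$fold_change)
  }
  de[need]
}

#' Read a measurement-to-node mapping table
#'
#' @param path TSV with columns `measurement_id`, `node_id`; `#` comments
#'   skipped. The mapping may be many-to-one (several probe sets per RNA
#'   node). Cross-namespace or cross-species identity must already be
#'   resolved here; node ids are matched to the graph byte-for-byte.
#' @return Data frame with character columns `measurement_id`, `node_id`.
#' @export
read_mapping <- function(path) {
  if (!file.exists(path)) stop("mapping file not found: ", path, call. = FALSE)
  mp <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("measurement_id", "node_id")
  if (!all(need %in% names(mp))) {
    stop("mapping table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  mp$measurement_id <- as.character(mp$measurement_id)
  mp$node_id <- as.character(mp$node_id)
  mp[need]
}

#' Call the trinary differential state of measurements
#'
#' A measurement is called significantly increased (+1) when its fold change
#' is at least `fc_min`, its adjusted p-value at most `p_max`, and its
#' average abundance at least `abund_min`; significantly decreased (-1)
#' symmetrically for fold change <= -`fc_min`; otherwise no significant
#' change (0). Defaults are the standard significance criteria
#' |fc| >= 1.3, BH-adjusted p <= 0.05, average abundance >= 32.
#'
#' @param fold_change Signed linear fold change(s).
#' @param adj_p Adjusted p-value(s).
#' @param avg_abundance Average abundance(s).
#' @param fc_min,p_max,abund_min Positive thresholds.
#' @return Integer vector of states in \{-1, 0, +1\}.
#' @export
call_state <- function(fold_change, adj_p, avg_abundance,
                       fc_min = 1.3, p_max = 0.05, abund_min = 32) {
  stopifnot(fc_min > 0, p_max > 0, abund_min > 0)
  ok <- adj_p <= p_max & avg_abundance >= abund_min
  ifelse(ok & fold_change >= fc_min, 1L,
         ifelse(ok & fold_change <= -fc_min, -1L, 0L))
}

#' Map measurement states onto graph nodes
#'
#' Aggregates per-measurement trinary calls to per-node states through the
#' measurement-to-node mapping. A node mapped by several probe sets is
#' called changed if at least one probe set meets the significance criteria.
#' If probe sets for one node call opposite directions, the call with the
#' smallest adjusted p-value wins; ties on adjusted p go to the larger
#' absolute fold change; a still-unresolved conflict yields state 0 with a
#' warning. Measurements without a mapping, and mappings pointing at node
#' ids absent from the graph (or not measurable RNA), are dropped with a
#' warning.
#'
#' @param de DE data frame as from [read_de_table()].
#' @param mapping Mapping data frame as from [read_mapping()].
#' @param graph A [collapse_edges()] `causal_graph`.
#' @param fc_min,p_max,abund_min State-call thresholds, see [call_state()].
#' @return Named integer vector: state in \{-1, 0, +1\} for every mapped,
#'   measured RNA node (the measured node set).
#' @export
map_to_nodes <- function(de, mapping, graph,
                         fc_min = 1.3, p_max = 0.05, abund_min = 32) {
  stopifnot(inherits(graph, "causal_graph"))
  unmapped <- setdiff(de$id, mapping$measurement_id)
  if (length(unmapped)) {
    message(length(unmapped), " measurement(s) without node mapping dropped")
  }
  m <- merge(de, mapping, by.x = "id", by.y = "measurement_id")
  known_rna <- rna_nodes(graph)
  off_graph <- !(m$node_id %in% known_rna)
  if (any(off_graph)) {
    warning(length(unique(m$node_id[off_graph])),
            " mapped node id(s) absent from the graph's measurable RNA ",
            "nodes; dropped", call. = FALSE)
    m <- m[!off_graph, , drop = FALSE]
  }
  if (nrow(m) == 0L) {
    return(stats::setNames(integer(0), character(0)))
  }
  m$state <- call_state(m$fold_change, m$adj_p, m$avg_abundance,
                        fc_min = fc_min, p_max = p_max, abund_min = abund_min)
  states <- vapply(split(m, m$node_id), function(g) {
    s <- g$state
    if (all(s == 0L)) return(0L)
    g <- g[s != 0L, , drop = FALSE]
    if (length(unique(g$state)) == 1L) return(g$state[1L])
    # conflicting directions: strongest evidence wins
    g <- g[g$adj_p == min(g$adj_p), , drop = FALSE]
    g <- g[abs(g$fold_change) == max(abs(g$fold_change)), , drop = FALSE]
    if (length(unique(g$state)) > 1L) {
      warning("unresolvable conflicting probe-set directions for node '",
              g$node_id[1L], "'; state set to 0", call. = FALSE)
      return(0L)
    }
    g$state[1L]
  }, integer(1))
  states[sort(names(states))]
}
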