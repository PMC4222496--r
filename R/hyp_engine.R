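#' Derive mechanism hypothesis networks (HYPs) from the graph
#'
#' Every graph node with at least `min_possible` distinct immediate
#' (path-length-1) collapsed edges onto *measured* RNA abundance nodes
#' becomes the upstream controller of one HYP; the HYP's downstream map
#' copies the collapsed edge signs (+1, -1, or `NA` = ambiguous). HYP
#' generation depends only on graph topology and on which RNA nodes were
#' measured — never on the differential states — so the same HYP set serves
#' the real data and all matched random data sets. Upstream nodes may
#' themselves be RNA nodes; a controller's own state never contributes to
#' its HYP.
#'
#' @param graph A `causal_graph`.
#' @param measured Character vector of measured RNA node ids (typically
#'   `names(map_to_nodes(...))`).
#' @param min_possible Minimum number of measured downstream nodes for a
#'   controller to be evaluated (default 4).
#' @return An object of class `hyp_set`: a named list (sorted by upstream
#'   id) of HYPs, each a list with `upstream`, `downstream` (named integer
#'   vector of edge signs, `NA` = ambiguous) and `possible`.
#' @export
generate_hyps <- function(graph, measured, min_possible = 4) {
  stopifnot(inherits(graph, "causal_graph"), min_possible >= 1)
  ed <- graph$edges
  keep <- ed$target %in% intersect(measured, rna_nodes(graph))
  ed <- ed[keep, , drop = FALSE]
  hyps <- lapply(split(ed, ed$source), function(g) {
    if (nrow(g) < min_possible) return(NULL)
    downstream <- stats::setNames(g$sign, g$target)
    downstream <- downstream[sort(names(downstream))]
    list(upstream = g$source[1L], downstream = downstream,
         possible = length(downstream))
  })
  hyps <- hyps[!vapply(hyps, is.null, logical(1))]
  hyps <- hyps[sort(names(hyps))]
  class(hyps) <- "hyp_set"
  hyps
}

#' @export
print.hyp_set <- function(x, ...) {
  sizes <- vapply(x, `[[`, 0L, "possible")
  cat("HYP set: ", length(x), " mechanism hypothesis network(s)",
      if (length(x)) paste0("; possible (downstream measured RNAs) ",
                            min(sizes), "-", max(sizes)),
      "\n", sep = "")
  invisible(x)
}

#' Compute the population shared by all richness tests
#'
#' The population is the union of the downstream node sets over all
#' generated HYPs: N is its size, m the number of its members with a
#' significant (nonzero) state. N and m are constants shared by every HYP's
#' richness calculation for a given data set.
#'
#' @param hyps A `hyp_set`.
#' @param states Named integer state vector (nodes absent from `states`
#'   count as unchanged).
#' @return List with `nodes` (sorted character vector), `N`, and `m`.
#' @export
compute_population <- function(hyps, states) {
  if (length(hyps) == 0L) {
    stop("no HYPs: population undefined", call. = FALSE)
  }
  nodes <- sort(unique(unlist(lapply(hyps, function(h) names(h$downstream)),
                              use.names = FALSE)))
  st <- states[match(nodes, names(states))]
  st[is.na(st)] <- 0L
  list(nodes = nodes, N = length(nodes), m = sum(st != 0L))
}

#' Write a HYP set to a TSV audit file
#'
#' @param hyps A `hyp_set`.
#' @param path Output path; columns `upstream`, `downstream`, `sign`
#'   (ambiguous edges written as `ambiguous`).
#' @return `path`, invisibly.
#' @export
write_hyps <- function(hyps, path) {
  rows <- do.call(rbind, lapply(unname(hyps), function(h) {
    data.frame(upstream = h$upstream, downstream = names(h$downstream),
               sign = ifelse(is.na(h$downstream), "ambiguous",
                             as.character(h$downstream)),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
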