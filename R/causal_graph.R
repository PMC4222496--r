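# Relation vocabulary. Long forms are the canonical TSV values; short forms
# are the operator spellings accepted by parse_bel_statement().
.relations <- c(
  increases = 1L, directlyIncreases = 1L,
  decreases = -1L, directlyDecreases = -1L
)
.short_relations <- c(
  "->" = "increases", "=>" = "directlyIncreases",
  "-|" = "decreases", "=|" = "directlyDecreases"
)

#' Read a causal edge table
#'
#' Reads a tab-delimited table of causal statements, one edge per row, with
#' columns `source`, `relation`, `target`. The relation must be one of
#' `increases`, `directlyIncreases`, `decreases`, `directlyDecreases`.
#' A header row is optional and is detected by the literal column names;
#' lines starting with `#` are skipped. Node identifiers are opaque,
#' case-sensitive strings (typically BEL terms such as `p(HGNC:TNF)` or
#' `r(MGI:Igfbp1)`) and are preserved byte-for-byte.
#'
#' @param path Path to a UTF-8, tab-delimited edge file.
#' @return A data frame with character columns `source`, `relation`,
#'   `target`, one row per raw edge.
#' @seealso [collapse_edges()] to build a [causal_graph] from the raw edges,
#'   [parse_bel_statement()] for one-line BEL input.
#' @export
read_causal_edges <- function(path) {
  if (!file.exists(path)) {
    stop("edge file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(data.frame(source = character(), relation = character(),
                      target = character(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  first <- fields[[1L]]
  has_header <- length(first) >= 3L &&
    identical(tolower(trimws(first[1:3])), c("source", "relation", "target"))
  if (has_header) {
    fields <- fields[-1L]
    line_no <- line_no[-1L]
  }
  if (length(fields) == 0L) {
    return(data.frame(source = character(), relation = character(),
                      target = character(), stringsAsFactors = FALSE))
  }
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("edge file line ", line_no[which(nf < 3L)[1L]],
         ": expected 3 tab-separated columns (source, relation, target), got ",
         nf[which(nf < 3L)[1L]], call. = FALSE)
  }
  src <- vapply(fields, `[[`, "", 1L)
  rel <- trimws(vapply(fields, `[[`, "", 2L))
  tgt <- vapply(fields, `[[`, "", 3L)
  bad <- !(rel %in% names(.relations))
  if (any(bad)) {
    i <- which(bad)[1L]
    stop("edge file line ", line_no[i], ": unknown relation '", rel[i],
         "'; allowed: ", paste(names(.relations), collapse = ", "),
         call. = FALSE)
  }
  data.frame(source = src, relation = rel, target = tgt,
             stringsAsFactors = FALSE)
}

# Split a BEL statement into whitespace-separated tokens, respecting
# parenthesis depth and double-quoted strings (BEL values may contain
# spaces inside quotes, e.g. bp(GO:"response to oxidative stress")).
.bel_tokens <- function(line) {
  chars <- strsplit(line, "", fixed = TRUE)[[1L]]
  depth <- 0L
  in_quote <- FALSE
  tokens <- character()
  starts <- integer()
  buf <- character()
  buf_start <- NA_integer_
  flush <- function() {
    if (length(buf)) {
      tokens[[length(tokens) + 1L]] <<- paste(buf, collapse = "")
      starts[[length(starts) + 1L]] <<- buf_start
      buf <<- character()
      buf_start <<- NA_integer_
    }
  }
  for (i in seq_along(chars)) {
    ch <- chars[[i]]
    if (ch == '"') in_quote <- !in_quote
    if (!in_quote) {
      if (ch == "(") depth <- depth + 1L
      if (ch == ")") {
        depth <- depth - 1L
        if (depth < 0L) {
          stop("unbalanced ')' at position ", i, " in BEL statement: ", line,
               call. = FALSE)
        }
      }
      if (grepl("^\\s$", ch) && depth == 0L) {
        flush()
        next
      }
    }
    if (is.na(buf_start)) buf_start <- i
    buf[[length(buf) + 1L]] <- ch
  }
  flush()
  if (in_quote) {
    stop("unterminated quote in BEL statement: ", line, call. = FALSE)
  }
  if (depth != 0L) {
    stop("unbalanced '(' in BEL statement: ", line, call. = FALSE)
  }
  list(tokens = tokens, starts = starts)
}

#' Parse a one-line BEL causal statement
#'
#' Parses a minimal `SUBJECT RELATION OBJECT` statement where each term is a
#' balanced-parenthesis BEL term (kept as an opaque string, nesting intact)
#' and the relation is one of the four causal relations in long form
#' (`increases`, `directlyIncreases`, `decreases`, `directlyDecreases`) or
#' the corresponding short forms (`->`, `=>`, `-|`, `=|`).
#'
#' @param line A single BEL statement, e.g.
#'   `"p(HGNC:TNF) increases r(HGNC:VCAM1)"`.
#' @return A one-row data frame with columns `source`, `relation`, `target`;
#'   short-form relations are normalised to their long form.
#' @export
parse_bel_statement <- function(line) {
  stopifnot(is.character(line), length(line) == 1L)
  tk <- .bel_tokens(line)
  if (length(tk$tokens) != 3L) {
    stop("BEL statement must be 'TERM RELATION TERM' (got ",
         length(tk$tokens), " top-level tokens): ", line, call. = FALSE)
  }
  rel <- tk$tokens[[2L]]
  if (rel %in% names(.short_relations)) rel <- .short_relations[[rel]]
  if (!(rel %in% names(.relations))) {
    stop("unknown relation '", tk$tokens[[2L]], "' at position ",
         tk$starts[[2L]], "; allowed: ",
         paste(c(names(.relations), names(.short_relations)), collapse = ", "),
         call. = FALSE)
  }
  data.frame(source = tk$tokens[[1L]], relation = rel,
             target = tk$tokens[[3L]], stringsAsFactors = FALSE)
}

#' Read a file of one-line BEL statements
#'
#' @param path Path to a text file with one BEL causal statement per line;
#'   blank lines and `#` comments are skipped.
#' @return A data frame of raw edges, as [read_causal_edges()].
#' @export
read_bel_statements <- function(path) {
  if (!file.exists(path)) stop("BEL file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(data.frame(source = character(), relation = character(),
                      target = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(lines, parse_bel_statement))
}

#' Collapse raw causal edges into a causal graph
#'
#' Collapses the raw edge list into at most one signed edge per
#' (source, target) pair: `increases`/`directlyIncreases` map to +1,
#' `decreases`/`directlyDecreases` to -1, and a pair supported by both sign
#' classes becomes an *ambiguous* edge (the knowledge base contains
#' conflicting evidence). Duplicate same-sign edges are deduplicated and
#' self-edges are dropped with a warning. Collapsing is idempotent and does
#' not depend on the input order.
#'
#' @param edges A data frame of raw edges (`source`, `relation`, `target`),
#'   as returned by [read_causal_edges()] or [read_bel_statements()].
#' @param rna_prefixes Character vector of term prefixes marking a node as a
#'   measurable RNA abundance; a node is measurable RNA iff its identifier
#'   starts with one of these followed by `(`.
#' @return An object of class `causal_graph`: a list with
#'   \describe{
#'     \item{edges}{data frame `source`, `target`, `sign` (+1, -1, or
#'       `NA` for ambiguous), one row per collapsed pair, sorted.}
#'     \item{nodes}{data frame `node`, `is_rna`.}
#'   }
#' @export
collapse_edges <- function(edges, rna_prefixes = c("r", "rnaAbundance")) {
  stopifnot(is.data.frame(edges),
            all(c("source", "relation", "target") %in% names(edges)))
  bad <- !(edges$relation %in% names(.relations))
  if (any(bad)) {
    stop("unknown relation '", edges$relation[which(bad)[1L]],
         "'; allowed: ", paste(names(.relations), collapse = ", "),
         call. = FALSE)
  }
  self <- edges$source == edges$target
  if (any(self)) {
    warning(sum(self), " self-edge(s) dropped (a node cannot be its own ",
            "downstream)", call. = FALSE)
    edges <- edges[!self, , drop = FALSE]
  }
  if (nrow(edges)) {
    sign_class <- unname(.relations[edges$relation])
    key <- paste(edges$source, edges$target, sep = "\r")
    pos <- tapply(sign_class == 1L, key, any)
    neg <- tapply(sign_class == -1L, key, any)
    keys <- sort(names(pos))
    pos <- pos[keys]; neg <- neg[keys]
    sgn <- ifelse(pos & neg, NA_integer_, ifelse(pos, 1L, -1L))
    parts <- strsplit(keys, "\r", fixed = TRUE)
    collapsed <- data.frame(
      source = vapply(parts, `[[`, "", 1L),
      target = vapply(parts, `[[`, "", 2L),
      sign = as.integer(sgn),
      stringsAsFactors = FALSE
    )
  } else {
    collapsed <- data.frame(source = character(), target = character(),
                            sign = integer(), stringsAsFactors = FALSE)
  }
  node_ids <- sort(unique(c(collapsed$source, collapsed$target)))
  rna_re <- paste0("^(", paste(sub("\\($", "", rna_prefixes), collapse = "|"),
                   ")\\(")
  graph <- list(
    edges = collapsed,
    nodes = data.frame(node = node_ids,
                       is_rna = grepl(rna_re, node_ids),
                       stringsAsFactors = FALSE)
  )
  class(graph) <- "causal_graph"
  graph
}

#' Load and collapse a causal graph in one step
#'
#' @param path Edge TSV (or BEL statement file when `format = "bel"`).
#' @param format `"tsv"` or `"bel"`.
#' @inheritParams collapse_edges
#' @return A `causal_graph` object.
#' @export
read_causal_graph <- function(path, format = c("tsv", "bel"),
                              rna_prefixes = c("r", "rnaAbundance")) {
  format <- match.arg(format)
  raw <- switch(format,
    tsv = read_causal_edges(path),
    bel = read_bel_statements(path)
  )
  collapse_edges(raw, rna_prefixes = rna_prefixes)
}

#' @export
print.causal_graph <- function(x, ...) {
  n_amb <- sum(is.na(x$edges$sign))
  cat("Causal graph: ", nrow(x$nodes), " nodes (",
      sum(x$nodes$is_rna), " measurable RNA), ",
      nrow(x$edges), " collapsed edges (",
      sum(x$edges$sign == 1L, na.rm = TRUE), " +, ",
      sum(x$edges$sign == -1L, na.rm = TRUE), " -, ",
      n_amb, " ambiguous)\n", sep = "")
  invisible(x)
}

# Internal: measurable RNA node ids of a graph.
rna_nodes <- function(graph) graph$nodes$node[graph$nodes$is_rna]
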