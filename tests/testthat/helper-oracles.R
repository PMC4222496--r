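# Independent brute-force oracles for the two tail statistics. These never
# share code with the package implementation: the binomial oracle enumerates
# all 2^t equally likely direction sequences, the hypergeometric oracle
# enumerates all size-n subsets of an N-item urn.

oracle_binom_tail <- function(k, t) {
  if (t == 0) return(1)
  outcomes <- expand.grid(rep(list(c(0L, 1L)), t))
  mean(rowSums(outcomes) >= k)
}

oracle_hyper_tail <- function(k, n, N, m) {
  if (k == 0) return(1)
  marked <- seq_len(m)
  subsets <- utils::combn(N, n)
  mean(colSums(matrix(subsets %in% marked, nrow = n)) >= k)
}

# Small helper: collapsed graph from a compact edge description.
edge_df <- function(...) {
  rows <- list(...)
  data.frame(
    source = vapply(rows, `[[`, "", 1L),
    relation = vapply(rows, `[[`, "", 2L),
    target = vapply(rows, `[[`, "", 3L),
    stringsAsFactors = FALSE
  )
}

# The worked six-downstream example: controller U with downstream RNAs
# r(A)..r(F); A, D, F support increased U (D through a decreases edge and a
# decreased state), B opposes it, C sits on conflicting evidence, E is
# unchanged.
fig_hyp_fixture <- function() {
  graph <- collapse_edges(edge_df(
    list("U", "increases", "r(A)"),
    list("U", "increases", "r(B)"),
    list("U", "increases", "r(C)"),
    list("U", "decreases", "r(C)"),
    list("U", "decreases", "r(D)"),
    list("U", "increases", "r(E)"),
    list("U", "increases", "r(F)")
  ))
  states <- c("r(A)" = 1L, "r(B)" = -1L, "r(C)" = 1L, "r(D)" = -1L,
              "r(E)" = 0L, "r(F)" = 1L)
  list(graph = graph, states = states,
       hyps = generate_hyps(graph, names(states)))
}

planted_spec <- function(seed, direction = 1L, penetrance = 0.8,
                         background = 0.02) {
  fixture_spec(
    planted = list(list(controller = "act(SYN:C1)", direction = direction,
                        penetrance = penetrance)),
    background_rate = background, seed = seed
  )
}
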