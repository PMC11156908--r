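# Toy networks built in code for oracle comparisons.

# linear chain with one reversible step: S.ext -> A -> B -> C -> sink
toy_chain <- function() {
  parse_network(data.frame(
    id = c("src", "v1", "v2", "out"),
    equation = c("S.ext (a) + S.ext (b) -> A (ab)", "A (ab) -> B (ab)",
                 "B (ab) -> C (ab)", "C ->"),
    reversible = c(FALSE, FALSE, TRUE, FALSE)))
}

toy_chain_fluxes <- function(v = 1, exch = 0.5) {
  data.frame(id = c("src", "v1", "v2", "out"), net = rep(v, 4),
             exch = c(0, 0, exch, 0))
}

toy_chain_pools <- c(A = 2, B = 3, C = 5)

# condensation/cleavage toy: two C3 pools condense to a C6
toy_condense <- function() {
  parse_network(data.frame(
    id = c("srcA", "srcB", "cond", "cleave", "outC", "outD"),
    equation = c(
      "S.ext (a) + S.ext (b) + S.ext (c) -> A (abc)",
      "U.ext (a) + U.ext (b) + U.ext (c) -> B (abc)",
      "A (abc) + B (def) -> C (abcdef)",
      "C (abcdef) -> D (fed) + A (abc)",
      "C ->", "D ->"),
    reversible = FALSE))
}

toy_condense_fluxes <- function() {
  # steady state: A: 2 - 3 + 1 = 0; B: 3 - 3 = 0; C: 3 - 1 - 2 = 0; D: 1 - 1
  data.frame(id = c("srcA", "srcB", "cond", "cleave", "outC", "outD"),
             net = c(2, 3, 3, 1, 2, 1), exch = 0)
}

toy_condense_pools <- c(A = 1.5, B = 2, C = 4, D = 1)

# symmetric-metabolite toy: a C5 pool built from a fast precursor (X,
# small pool) and a slow one (Y, large pool) is decarboxylated to a
# symmetric C4 (succinate-like Q), then hydrated to M. Without 50/50
# scrambling, Q positions 1-2 (X-derived) would enrich faster than 3-4
# (Y-derived).
toy_symmetric <- function() {
  parse_network(data.frame(
    id = c("src1", "src2", "mk", "dec", "outC", "hyd", "outM"),
    equation = c("S.ext (a) -> X (a)", "S.ext (a) -> Y (a)",
                 "X (a) + X (b) + X (c) + Y (d) + Y (e) -> P (abcde)",
                 "P (abcde) -> Q (bcde) + C1 (a)", "C1 ->",
                 "Q (abcd) -> M (abcd)", "M ->"),
    reversible = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE)),
    symmetric = "Q")
}

toy_symmetric_fluxes <- function() {
  data.frame(id = c("src1", "src2", "mk", "dec", "outC", "hyd", "outM"),
             net = c(3, 2, 1, 1, 1, 1, 1), exch = c(0, 0, 0, 0, 0, 0.8, 0))
}

toy_symmetric_pools <- c(X = 0.3, Y = 8, P = 1, Q = 1.5, M = 2.5, C1 = 0.5)

expect_mid_equal <- function(a, b, tol = 1e-6) {
  expect_equal(names(a$mids), names(b$mids))
  for (m in names(a$mids))
    expect_lt(max(abs(a$mids[[m]] - b$mids[[m]])), tol)
}

# cache expensive fits shared between test files within one run
.fit_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (is.null(.fit_cache[[key]])) .fit_cache[[key]] <- force(expr)
  .fit_cache[[key]]
}
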