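# Small in-code fixtures shared across tests.

# A tiny two-class descriptor table with known structure:
#  GOOD  - well separated between classes
#  DULL  - identical distributions
#  COPY  - exact duplicate of GOOD (PCC 1)
#  KEYD  - missing-value pattern differing strongly between classes
tiny_table <- function(n_per_class = 20, seed = 42) {
  set.seed(seed)
  act <- c(rep(TRUE, n_per_class), rep(FALSE, n_per_class))
  good <- ifelse(act, rnorm(2 * n_per_class, 5, 0.5),
                 rnorm(2 * n_per_class, 0, 0.5))
  dull <- rnorm(2 * n_per_class)
  keyd <- rnorm(2 * n_per_class)
  keyd[act & runif(2 * n_per_class) < 0.9] <- NA
  keyd[!act & runif(2 * n_per_class) < 0.1] <- NA
  V <- cbind(GOOD = good, DULL = dull, COPY = good, KEYD = keyd)
  rownames(V) <- sprintf("c%02d", seq_len(2 * n_per_class))
  list(table = descriptor_table(V, dimension_tag = "2D"),
       labels = factor(ifelse(act, "active", "inactive"),
                       levels = c("inactive", "active")))
}

# valid SMILES with distinct structures, for adapter tests
demo_smiles <- c(ethanol = "CCO", benzene = "c1ccccc1",
                 caffeine = "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
                 aspirin = "CC(=O)Oc1ccccc1C(=O)O")

expect_metric_equal <- function(report, field, value, tol = 1e-12) {
  expect_equal(as.numeric(report[[field]]), value, tolerance = tol)
}
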