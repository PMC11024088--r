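# Builds a selection object directly so codec tests don't depend on the
# feature_selection module internals.
manual_selection <- function(descriptors, keys = character()) {
  structure(list(
    continuous = lapply(descriptors, function(d)
      structure(list(descriptor_name = d, midse = 0.5),
                class = "bbb_feature_score")) |> stats::setNames(descriptors),
    structural_keys = data.frame(descriptor = keys,
                                 freq_active = rep(0.1, length(keys)),
                                 freq_inactive = rep(0.5, length(keys)),
                                 discrepancy = rep(0.4, length(keys))),
    set_tag = "2D", params = list()),
    class = "bbb_feature_selection")
}

schema_from_values <- function(values, bits, keys = character(),
                               key_values = NULL) {
  V <- do.call(cbind, values)
  if (!is.null(key_values)) V <- cbind(V, do.call(cbind, key_values))
  rownames(V) <- sprintf("t%d", seq_len(nrow(V)))
  tab <- descriptor_table(V, dimension_tag = "2D")
  fit_schema(tab, manual_selection(names(values), keys), bits = bits)
}

test_that("boundaries follow bound_i = val_min + i * val_range / bits", {
  sc <- schema_from_values(list(D = c(0, 8)), bits = 8)
  expect_equal(sc$encodings$D$boundaries, c(0, 1, 2, 3, 4, 5, 6, 7))
  sc4 <- schema_from_values(list(D = c(0, 1)), bits = 4)
  expect_equal(sc4$encodings$D$boundaries, c(0, 0.25, 0.5, 0.75))
  # constant descriptor: all boundaries collapse, flagged degenerate
  scc <- schema_from_values(list(D = c(3, 3, 3)), bits = 4)
  expect_true(scc$encodings$D$degenerate)
  expect_equal(scc$encodings$D$boundaries, rep(3, 4))
})

test_that("assign_bin implements the stated bin rule", {
  sc <- schema_from_values(list(D = c(0, 1)), bits = 4)
  enc <- sc$encodings$D  # boundaries 0, .25, .5, .75
  expect_equal(assign_bin(-5, enc), 0)      # below training minimum
  expect_equal(assign_bin(0, enc), 0)       # <= first boundary
  expect_equal(assign_bin(0.6, enc), 3)     # 0.5 < v <= 0.75
  expect_equal(assign_bin(0.25, enc), 1)    # boundary itself -> lower bin
  expect_equal(assign_bin(0.76, enc), 4)    # above last boundary: top bin
  expect_equal(assign_bin(99, enc), 4)
  expect_true(is.na(assign_bin(NA, enc)))
})

test_that("encode produces thermometer fields, key prefix and flags", {
  sc <- schema_from_values(list(A = c(0, 1), B = c(0, 8)), bits = 4,
                           keys = "K", key_values = list(K = c(1, NA)))
  expect_equal(sc$total_length, 1 + 2 * 4)
  fp <- encode(c(A = 0.6, B = 9, K = 1), sc, "probe")
  #               key  A: bin 3      B: bin 4
  expect_equal(fp$bits, c(1, 1, 1, 1, 0, 1, 1, 1, 1))
  # missing key -> prefix 0; missing continuous -> zero field + flag
  fp2 <- encode(c(A = NA, B = 0, K = NA), sc)
  expect_equal(fp2$bits, c(0, 0, 0, 0, 0, 0, 0, 0, 0))
  expect_equal(fp2$missing_descriptors, "A")
  # all values at the training minima -> all descriptor fields zero
  fp3 <- encode(c(A = 0, B = 0, K = 5), sc)
  expect_equal(sum(fp3$bits), 1)  # only the key prefix
})

test_that("1-bit encoding sets the bit at or above the training median", {
  sc <- schema_from_values(list(D = c(1, 2, 3, 4)), bits = 1)
  expect_equal(sc$encodings$D$median, 2.5)  # even count: mean of central pair
  expect_equal(encode(c(D = 2.5), sc)$bits, 1)  # equal to median -> 1
  expect_equal(encode(c(D = 2.49), sc)$bits, 0)
  expect_equal(encode(c(D = 99), sc)$bits, 1)
})

test_that("the published composition gives 11 + 49 x 8 = 403 bits", {
  set.seed(2)
  vals <- stats::setNames(replicate(49, rnorm(10), simplify = FALSE),
                          sprintf("D%02d", 1:49))
  keyv <- stats::setNames(replicate(11, c(rnorm(9), NA), simplify = FALSE),
                          sprintf("K%02d", 1:11))
  sc <- schema_from_values(vals, bits = 8, keys = names(keyv),
                           key_values = keyv)
  expect_equal(sc$total_length, 403)
  fp <- encode(unlist(lapply(c(vals, keyv), `[`, 1)), sc)
  expect_length(fp$bits, 403)
})

test_that("thermometer fields are monotone in the encoded value", {
  set.seed(33)
  for (draw in 1:200) {
    bits <- sample(c(1, 4, 8), 1)
    train <- rnorm(sample(3:30, 1), sd = runif(1, 0.1, 5))
    sc <- schema_from_values(list(D = train), bits = bits)
    v <- sort(rnorm(50, sd = 10))
    pops <- vapply(v, function(x) sum(encode(c(D = x), sc)$bits), 0)
    expect_true(all(diff(pops) >= 0))
    expect_true(all(pops >= 0 & pops <= bits))
  }
})

test_that("boundaries fitted on train are reused unchanged for test data", {
  train <- c(2, 4, 6)
  sc <- schema_from_values(list(D = train), bits = 4)
  # out-of-range test values map to bin 0 or bin bits, never refit
  expect_equal(sum(encode(c(D = -100), sc)$bits), 0)
  expect_equal(sum(encode(c(D = 100), sc)$bits), 4)
  expect_identical(sc$encodings$D$boundaries, 2 + (0:3) * 1)
})

test_that("schema JSON round-trip yields bit-identical fingerprints", {
  set.seed(9)
  vals <- list(A = rnorm(20), B = runif(20, -5, 5), C = rexp(20))
  keyv <- list(K1 = c(rnorm(15), rep(NA, 5)), K2 = c(NA, rnorm(19)))
  for (bits in c(1, 4, 8)) {
    sc <- schema_from_values(vals, bits = bits, keys = names(keyv),
                             key_values = keyv)
    f <- tempfile(fileext = ".json")
    write_schema(sc, f)
    sc2 <- read_schema(f)
    expect_equal(sc2$total_length, sc$total_length)
    probes <- replicate(20, {
      x <- c(A = rnorm(1), B = rnorm(1, sd = 10), C = rexp(1),
             K1 = sample(c(1, NA), 1), K2 = rnorm(1))
      identical(encode(x, sc)$bits, encode(x, sc2)$bits)
    })
    expect_true(all(probes))
  }
})

test_that("encode_table encodes rows consistently with encode", {
  tt <- tiny_table()
  sel <- suppressWarnings(  # KEYD is deliberately too sparse to score
    select_features(tt$table, tt$labels, min_per_class = 3))
  sc <- fit_schema(tt$table, sel, bits = 8)
  M <- encode_table(tt$table, sc)
  expect_equal(ncol(M), sc$total_length)
  expect_equal(rownames(M), tt$table$compound_ids)
  i <- 7
  expect_equal(unname(M[i, ]), encode(tt$table$values[i, ], sc)$bits)
})

test_that("fit_schema validates inputs", {
  tab <- descriptor_table(matrix(rnorm(10), 5, dimnames =
                                   list(paste0("c", 1:5), c("A", "B"))))
  expect_error(fit_schema(tab, manual_selection(c("A", "MISSING"))), "absent")
  expect_error(fit_schema(tab, manual_selection("A"), bits = 3), "bits")
})

test_that("morgan adapter is deterministic, radius-sensitive and strict", {
  m1 <- morgan_fingerprints(rep(demo_smiles[["caffeine"]], 2), 2, 512)
  expect_identical(m1[1, ], m1[2, ])
  r0 <- morgan_fingerprints(demo_smiles[["caffeine"]], 0, 512)
  r2 <- morgan_fingerprints(demo_smiles[["caffeine"]], 2, 512)
  expect_false(identical(r0, r2))
  expect_error(morgan_fingerprints("not_a_smiles", 2, 512), "invalid")
})
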