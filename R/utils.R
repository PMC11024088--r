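# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_input <- function(...) stop(..., call. = FALSE)

#' @keywords internal
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort_input(msg)
  invisible(TRUE)
}

# Canonical binary label representation: factor with levels inactive < active.
# Accepts 0/1, logicals, "active"/"inactive" strings or an existing factor.
as_bbb_label <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  if (is.logical(x)) x <- ifelse(x, "active", "inactive")
  if (is.numeric(x)) {
    assert_that(all(x %in% c(0, 1)), "numeric labels must be 0/1")
    x <- ifelse(x == 1, "active", "inactive")
  }
  x <- tolower(as.character(x))
  ok <- x %in% c("active", "inactive")
  assert_that(all(ok | is.na(x)), "labels must be 'active'/'inactive' (or 0/1)")
  factor(x, levels = c("inactive", "active"))
}

is_active <- function(labels) as_bbb_label(labels) == "active"

# Deterministic per-stage seed fan-out from one global seed.  Knuth-style
# multiplicative mix, kept below 2^31 so it is a valid R integer seed.
derive_seed <- function(seed, stage) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((abs(as.numeric(seed)) * 48271 + h * 16807) %% 2147483647)
}

# Moore-Penrose pseudo-inverse via SVD (tolerance relative to largest
# singular value), optionally ridge-regularised beforehand.
pseudo_inverse <- function(S, ridge = 0, tol = 1e-10) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S))
  if (ridge > 0) S <- S + diag(ridge, nrow(S))
  sv <- svd(S)
  keep <- sv$d > tol * max(sv$d, 0)
  if (!any(keep)) return(matrix(0, nrow(S), ncol(S)))
  sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
}

# A single-purpose JSON writer so every module serialises numbers the same
# way (17 significant digits: doubles survive a read_json round-trip
# bit-identically), scalars unboxed.
write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}
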