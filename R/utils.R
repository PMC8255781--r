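#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Derive a reproducible child seed from a master seed and string keys
#'
#' Each (subject, session) recording in a study gets its own RNG stream,
#' derived deterministically from the study's master seed and the record's
#' identifying keys, so that adding or reordering records never perturbs the
#' signals of the others.
#'
#' @param master Single integer master seed.
#' @param ... Character or numeric keys identifying the stream.
#' @return An integer in [0, 2^31 - 2], usable with [set.seed()].
#' @export
derive_seed <- function(master, ...) {
  keys <- paste(vapply(list(...), as.character, character(1)), collapse = "\r")
  h <- as.double(master) %% 2147483647
  for (code in utf8ToInt(keys)) {
    h <- (h * 131 + code) %% 2147483647
  }
  as.integer(h)
}

# Moore-Penrose pseudoinverse via SVD (tolerance relative to largest
# singular value). Kept internal so the statistics code does not depend on
# MASS, which the test suite uses as the independent oracle route.
pinv <- function(m, tol = 1e-10) {
  s <- svd(m)
  keep <- s$d > tol * max(s$d, 0)
  if (!any(keep)) return(matrix(0, ncol(m), nrow(m)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

mat_rank <- function(m, tol = 1e-10) {
  if (all(m == 0)) return(0L)
  d <- svd(m, nu = 0, nv = 0)$d
  sum(d > tol * max(d))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
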