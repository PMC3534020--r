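#' @keywords internal
"_PACKAGE"

utils::globalVariables(c("fpr", "tpr", "model"))

# Angle arithmetic ------------------------------------------------------------

#' Wrap angles to the interval [-pi, pi)
#'
#' All harmonic-phase arithmetic in this package is performed on wrapped
#' differences; no global phase unwrapping is ever attempted.
#'
#' @param x numeric vector of angles (radians).
#' @return angles wrapped to `[-pi, pi)`.
#' @export
wrap_pi <- function(x) {
  ((x + pi) %% (2 * pi)) - pi
}

#' Wrap angles to the interval [0, 2*pi)
#' @param x numeric vector of angles (radians).
#' @return angles wrapped to `[0, 2*pi)`.
#' @export
wrap_2pi <- function(x) {
  x %% (2 * pi)
}

# Cubic smoothstep and its derivative; used for all smooth spatial transitions
# (regional contractility borders, tissue edges, activation shoulder).
smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

smoothstep_deriv <- function(u) {
  inside <- u > 0 & u < 1
  out <- numeric(length(u))
  out[inside] <- 6 * u[inside] * (1 - u[inside])
  out
}

# Seeding ---------------------------------------------------------------------

# Deterministic fan-out of one global seed into per-stage streams.  Stage names
# are hashed additively; results stay well below 2^31.
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, !is.na(seed))
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((as.numeric(seed) * 10007 + h) %% 2147483629)
}

# Evaluate `expr` under a given seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) {
    stop("a seed is required (reproducibility contract)", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Binary erosion of a 2D logical mask by n pixels (4-neighbourhood).
erode_mask2 <- function(mask, n = 1) {
  m <- mask
  for (i in seq_len(n)) {
    shr <- m
    shr[-1, ] <- shr[-1, ] & m[-nrow(m), ]
    shr[-nrow(m), ] <- shr[-nrow(m), ] & m[-1, ]
    shr[, -1] <- shr[, -1] & m[, -ncol(m)]
    shr[, -ncol(m)] <- shr[, -ncol(m)] & m[, -1]
    shr[1, ] <- FALSE; shr[nrow(m), ] <- FALSE
    shr[, 1] <- FALSE; shr[, ncol(m)] <- FALSE
    m <- shr
  }
  m
}

# Small linear algebra helpers ------------------------------------------------

# Vectorised inverse of n stacked 3x3 matrices given as an n x 9 matrix in
# column-major order (m11,m21,m31,m12,...).  Returns list(inv = n x 9, det = n).
inv3x3 <- function(m) {
  a <- m[, 1]; d <- m[, 4]; g <- m[, 7]
  b <- m[, 2]; e <- m[, 5]; h <- m[, 8]
  c <- m[, 3]; f <- m[, 6]; i <- m[, 9]
  A <- e * i - f * h
  B <- -(d * i - f * g)
  C <- d * h - e * g
  det <- a * A + b * B + c * C
  inv <- cbind(
    A / det, -(b * i - c * h) / det, (b * f - c * e) / det,
    B / det, (a * i - c * g) / det, -(a * f - c * d) / det,
    C / det, -(a * h - b * g) / det, (a * e - b * d) / det
  )
  list(inv = inv, det = det)
}

# Multiply stacked 3x3 matrices (n x 9, column-major) by stacked 3-vectors.
mat3_vec <- function(m, v) {
  cbind(
    m[, 1] * v[, 1] + m[, 4] * v[, 2] + m[, 7] * v[, 3],
    m[, 2] * v[, 1] + m[, 5] * v[, 2] + m[, 8] * v[, 3],
    m[, 3] * v[, 1] + m[, 6] * v[, 2] + m[, 9] * v[, 3]
  )
}

# Stacked matrix product C = A %*% B for n x 9 stacks.
mat3_mat <- function(a, b) {
  out <- matrix(0, nrow(a), 9)
  for (j in 1:3) {
    for (i in 1:3) {
      acc <- 0
      for (k in 1:3) {
        acc <- acc + a[, i + (k - 1) * 3] * b[, k + (j - 1) * 3]
      }
      out[, i + (j - 1) * 3] <- acc
    }
  }
  out
}

# t(A) %*% A for stacked matrices.
mat3_crossprod <- function(a) {
  out <- matrix(0, nrow(a), 9)
  for (j in 1:3) {
    for (i in 1:3) {
      acc <- 0
      for (k in 1:3) {
        acc <- acc + a[, k + (i - 1) * 3] * a[, k + (j - 1) * 3]
      }
      out[, i + (j - 1) * 3] <- acc
    }
  }
  out
}
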