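#' @useDynLib cartimech, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats lm coef predict rnorm runif setNames approx sd
#' @importFrom graphics hist
#' @importFrom utils write.csv head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Normalize rows of a matrix of vectors
#' @noRd
row_normalize <- function(m) {
  n <- sqrt(rowSums(m^2))
  m / n
}

## Batch symmetric 3x3 eigenvalues (Voigt rows xx,yy,zz,xy,yz,xz), descending.
## Closed-form (Cardano) solution; robust for the well-conditioned strain/stress
## tensors this package produces. Cross-checked against base eigen() in tests.
eig3_sym <- function(v) {
  if (is.null(dim(v))) v <- matrix(v, nrow = 1)
  a11 <- v[, 1]; a22 <- v[, 2]; a33 <- v[, 3]
  a12 <- v[, 4]; a23 <- v[, 5]; a13 <- v[, 6]
  q <- (a11 + a22 + a33) / 3
  b11 <- a11 - q; b22 <- a22 - q; b33 <- a33 - q
  p2 <- b11^2 + b22^2 + b33^2 + 2 * (a12^2 + a23^2 + a13^2)
  p <- sqrt(p2 / 6)
  detB <- b11 * (b22 * b33 - a23^2) - a12 * (a12 * b33 - a23 * a13) +
    a13 * (a12 * a23 - b22 * a13)
  r <- ifelse(p > 0, detB / (2 * p^3), 0)
  r <- pmin(1, pmax(-1, r))
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  cbind(e1, e2, e3)
}

## symmetric part of batch 3x3 gradients g (dim 3,3,EQ) -> Voigt with plain
## (tensor) shear components
sym_voigt <- function(g) {
  eq <- dim(g)[3]
  m <- matrix(g, nrow = 9)
  cbind(m[1, ], m[5, ], m[9, ],
        (m[2, ] + m[4, ]) / 2,
        (m[6, ] + m[8, ]) / 2,
        (m[3, ] + m[7, ]) / 2)
}

## Hencky (logarithmic) strain tensors from displacement gradients.
## g: array (3,3,EQ). Returns Voigt matrix (EQ x 6), tensor shear components.
hencky_voigt <- function(g) {
  m <- matrix(g, nrow = 9)
  eq <- ncol(m)
  ## F = I + g, C = F^T F
  f <- m
  f[c(1, 5, 9), ] <- f[c(1, 5, 9), ] + 1
  F11 <- f[1, ]; F21 <- f[2, ]; F31 <- f[3, ]
  F12 <- f[4, ]; F22 <- f[5, ]; F32 <- f[6, ]
  F13 <- f[7, ]; F23 <- f[8, ]; F33 <- f[9, ]
  C11 <- F11^2 + F21^2 + F31^2
  C22 <- F12^2 + F22^2 + F32^2
  C33 <- F13^2 + F23^2 + F33^2
  C12 <- F11 * F12 + F21 * F22 + F31 * F32
  C23 <- F12 * F13 + F22 * F23 + F32 * F33
  C13 <- F11 * F13 + F21 * F23 + F31 * F33
  cv <- cbind(C11, C22, C33, C12, C23, C13)
  ## spectral log: E = 1/2 sum log(lam_i) n_i n_i^T, per point (loop; output-only)
  out <- matrix(0, nrow = eq, ncol = 6)
  for (k in seq_len(eq)) {
    Cm <- matrix(c(cv[k, 1], cv[k, 4], cv[k, 6],
                   cv[k, 4], cv[k, 2], cv[k, 5],
                   cv[k, 6], cv[k, 5], cv[k, 3]), 3, 3)
    es <- eigen(Cm, symmetric = TRUE)
    lam <- pmax(es$values, 1e-12)
    Em <- es$vectors %*% diag(0.5 * log(lam)) %*% t(es$vectors)
    out[k, ] <- c(Em[1, 1], Em[2, 2], Em[3, 3], Em[1, 2], Em[2, 3], Em[1, 3])
  }
  out
}

## polynomial rolling hash of a serialized R object (provenance fingerprint)
object_hash <- function(x) {
  raw <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (b in raw) h <- (h * 257 + b + 1) %% 2147483647
  sprintf("%08x", as.integer(h))
}

## deterministic sub-seed derivation, kept below 2^31
derive_seed <- function(seed, tag) {
  s <- (as.numeric(seed) * 48271 + sum(utf8ToInt(tag)) * 7919) %% 2147483629
  as.integer(s) + 1L
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    stopf("%s must be a finite numeric scalar", name)
  ok_lo <- if (strict_lower) x > lower else x >= lower
  ok_hi <- if (strict_upper) x < upper else x <= upper
  if (!ok_lo || !ok_hi)
    stopf("%s = %g outside allowed range %s%g, %g%s", name, x,
          if (strict_lower) "(" else "[", lower, upper,
          if (strict_upper) ")" else "]")
  invisible(x)
}
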