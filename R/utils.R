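#' @useDynLib lactokin, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm median sd cor prop.test qnorm setNames
#' @importFrom utils write.table
#' @importFrom graphics hist
NULL

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic substream seed from a master seed and a stream name.
# Kept strictly below 2^31 so it is a valid R integer seed.
derive_seed <- function(master, name) {
  h <- 0
  for (ch in utf8ToInt(as.character(name))) h <- (h * 131 + ch) %% 2147483629
  as.integer((as.numeric(master) * 48271 + h) %% 2147483629 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Rationalize a numeric vector to small integers (continued fractions),
# used to present conserved-moiety vectors in integer form when possible.
integerize <- function(x, max_den = 1000L, tol = 1e-8) {
  rat <- function(z) {
    if (abs(z) < tol) return(c(0L, 1L))
    num <- den <- 0
    p0 <- 0; q0 <- 1; p1 <- 1; q1 <- 0; zz <- z
    for (i in 1:30) {
      a <- floor(zz)
      p <- a * p1 + p0; q <- a * q1 + q0
      if (q > max_den) break
      num <- p; den <- q
      if (abs(z - p / q) < tol * max(1, abs(z))) break
      if (abs(zz - a) < 1e-14) break
      zz <- 1 / (zz - a)
      p0 <- p1; q0 <- q1; p1 <- p; q1 <- q
    }
    c(num, den)
  }
  m <- vapply(x, rat, numeric(2))
  dens <- m[2, ]
  l <- Reduce(function(a, b) a * b / gcd2(a, b), unique(dens))
  v <- x * l
  if (max(abs(v - round(v))) < 1e-6 * max(1, max(abs(v)))) {
    v <- round(v)
    g <- Reduce(gcd2, abs(v[v != 0]))
    if (length(g) && g > 0) v <- v / g
    if (sum(v) < 0) v <- -v
    v
  } else x
}

gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 1e-9) { t <- b; b <- a %% b; a <- t }
  a
}

# Reduced row echelon form with partial pivoting; returns the echelon matrix
# and pivot column indices. Used for exact-structure left null spaces of
# small integer stoichiometries.
rref <- function(A, tol = 1e-10) {
  A <- as.matrix(A)
  n <- nrow(A); m <- ncol(A)
  piv <- integer(0)
  r <- 1L
  for (j in seq_len(m)) {
    if (r > n) break
    i <- which.max(abs(A[r:n, j])) + r - 1L
    if (abs(A[i, j]) < tol) next
    if (i != r) A[c(i, r), ] <- A[c(r, i), ]
    A[r, ] <- A[r, ] / A[r, j]
    for (k in seq_len(n)) {
      if (k != r && abs(A[k, j]) > tol) A[k, ] <- A[k, ] - A[k, j] * A[r, ]
    }
    piv <- c(piv, j)
    r <- r + 1L
  }
  list(R = A, pivots = piv)
}

binom_se <- function(p, n) sqrt(pmax(p * (1 - p), 0) / pmax(n, 1))
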