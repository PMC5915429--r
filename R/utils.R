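# internal helpers

# Run expr with a private RNG stream; the caller's .Random.seed is untouched.
with_local_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  eval.parent(substitute(expr))
}

vnorm <- function(x) sqrt(sum(x^2))

# row-wise Euclidean distances between two point matrices (n x 3, m x 3)
cross_dist <- function(a, b) {
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# minimum distance from each point in p (n x 3) to a polyline (m x 3)
dist_to_polyline <- function(p, line) {
  if (nrow(line) == 1L) return(cross_dist(p, line)[, 1])
  dmin <- rep(Inf, nrow(p))
  for (s in seq_len(nrow(line) - 1L)) {
    a <- line[s, ]
    ab <- line[s + 1L, ] - a
    len2 <- sum(ab^2)
    pa <- sweep(p, 2, a)
    t <- if (len2 > 0) pmin(1, pmax(0, as.vector(pa %*% ab) / len2)) else 0
    proj <- sweep(outer(t, ab), 2, a, "+")
    dmin <- pmin(dmin, sqrt(rowSums((p - proj)^2)))
  }
  dmin
}

zscore <- function(x) {
  n <- length(x)
  s <- sqrt(sum((x - mean(x))^2) / n)  # population SD
  if (n < 2L || s == 0) return(rep(0, n))
  (x - mean(x)) / s
}
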