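# Independent brute-force oracles used to check the native graph statistics.
# They enumerate simple paths / node pairs exhaustively and share no code with
# the implementations in R/.

# all simple paths from s, keeping for every target the shortest ones
oracle_shortest_paths <- function(A, s) {
  n <- nrow(A)
  best <- rep(Inf, n)
  paths <- replicate(n, list(), simplify = FALSE)
  cur <- integer(n); cur[1] <- s
  onpath <- logical(n); onpath[s] <- TRUE
  dfs <- function(v, depth) {
    for (w in which(A[v, ] == 1L)) {
      if (onpath[w]) next
      len <- depth
      if (len < best[w]) { best[w] <<- len; paths[[w]] <<- list() }
      if (len == best[w]) paths[[w]][[length(paths[[w]]) + 1]] <<- c(cur[1:depth], w)
      onpath[w] <<- TRUE; cur[depth + 1] <<- w
      dfs(w, depth + 1)
      onpath[w] <<- FALSE
    }
  }
  dfs(s, 1)
  best[s] <- 0
  list(dist = best, paths = paths)
}

oracle_betweenness <- function(A, standardized = TRUE) {
  n <- nrow(A)
  bc <- numeric(n)
  for (s in seq_len(n)) {
    sp <- oracle_shortest_paths(A, s)
    for (t in seq_len(n)) {
      if (t == s || is.infinite(sp$dist[t])) next
      plist <- sp$paths[[t]]
      sigma <- length(plist)
      through <- numeric(n)
      for (p in plist) {
        interior <- p[-c(1, length(p))]
        through[interior] <- through[interior] + 1
      }
      bc <- bc + through / sigma
    }
  }
  if (standardized) bc / ((n - 1) * (n - 2)) else bc
}

# closeness by exhaustive path enumeration, penalized-unreachable convention
oracle_closeness <- function(A, direction = "out") {
  n <- nrow(A)
  M <- if (direction == "out") A else t(A)
  vapply(seq_len(n), function(s) {
    d <- oracle_shortest_paths(M, s)$dist[-s]
    r <- sum(is.finite(d))
    if (r == 0) return(0)
    (n - 1) / (sum(d[is.finite(d)]) + n * (n - 1 - r))
  }, numeric(1))
}

oracle_clustering <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(v) {
    nb <- setdiff(which(A[v, ] == 1L | A[, v] == 1L), v)
    k <- length(nb)
    if (k < 2) return(0)
    arcs <- 0L
    for (i in nb) for (j in nb) if (i != j && A[i, j] == 1L) arcs <- arcs + 1L
    arcs / (k * (k - 1))
  }, numeric(1))
}

oracle_dyad_census <- function(A) {
  n <- nrow(A)
  m <- a <- nl <- 0L
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    k <- A[i, j] + A[j, i]
    if (k == 2) m <- m + 1L else if (k == 1) a <- a + 1L else nl <- nl + 1L
  }
  list(mutual = m, asymmetric = a, null_pairs = nl)
}
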