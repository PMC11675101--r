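# Independent brute-force oracles and small fixture builders. Everything
# here is deliberately naive and separate from the package implementation.

# all set partitions of n elements as restricted-growth label vectors
enum_partitions <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in enum_partitions(n - 1)) {
    for (k in seq_len(max(p) + 1L)) {
      out[[length(out) + 1L]] <- c(p, k)
    }
  }
  out
}

brute_max_modularity <- function(w) {
  qs <- vapply(enum_partitions(nrow(w)),
               function(p) modularity_score(w, p), numeric(1))
  max(qs)
}

# Floyd-Warshall all-pairs shortest paths on a length matrix (Inf = absent)
floyd_warshall <- function(lm) {
  n <- nrow(lm)
  D <- lm
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

# exhaustive simple-path enumeration betweenness (ordered-pair normalized)
brute_betweenness <- function(lm, tol = 1e-9) {
  n <- nrow(lm)
  paths_between <- function(h, j) {
    found <- list()
    walk <- function(path, len) {
      last <- path[length(path)]
      if (last == j) {
        found[[length(found) + 1L]] <<- list(path = path, len = len)
        return()
      }
      for (nxt in seq_len(n)) {
        if (nxt %in% path || !is.finite(lm[last, nxt])) next
        walk(c(path, nxt), len + lm[last, nxt])
      }
    }
    walk(h, 0)
    found
  }
  b <- numeric(n)
  for (h in seq_len(n)) {
    for (j in seq_len(n)) {
      if (h == j) next
      ps <- paths_between(h, j)
      if (!length(ps)) next
      lens <- vapply(ps, `[[`, numeric(1), "len")
      short <- which(lens <= min(lens) + tol)
      for (i in seq_len(n)) {
        if (i == h || i == j) next
        through <- sum(vapply(ps[short], function(p) i %in% p$path, logical(1)))
        b[i] <- b[i] + through / length(short)
      }
    }
  }
  b / ((n - 1) * (n - 2))
}

# BH step-up adjusted p values straight from the definition
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  sorted <- p[o] * m / seq_len(m)
  # enforce monotonicity from the largest down
  for (k in rev(seq_len(m))) {
    adj[k] <- if (k == m) sorted[k] else min(sorted[k], adj[k + 1])
  }
  res <- numeric(m)
  res[o] <- adj
  pmin(res, 1)
}

# union-find connectivity oracle on a binary adjacency matrix
uf_connected <- function(A) {
  n <- nrow(A)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (A[i, j] > 0) parent[find(i)] <- find(j)
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1)))) == 1
}

# triangle-count clustering from the definition
brute_clustering <- function(A) {
  n <- nrow(A)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    t_i <- 0
    for (a in seq_along(nb)) {
      for (b in seq_along(nb)) {
        if (a < b && A[nb[a], nb[b]] > 0) t_i <- t_i + 1
      }
    }
    ci[i] <- 2 * t_i / (k * (k - 1))
  }
  ci
}

# hop-distance characteristic path length by repeated matrix squaring-free BFS
bfs_path_length <- function(A) {
  n <- nrow(A)
  total <- 0
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- unique(unlist(lapply(frontier, function(v) which(A[v, ] > 0))))
      nxt <- nxt[dist[nxt] == Inf]
      dist[nxt] <- d
      frontier <- nxt
    }
    total <- total + sum(dist[-s])
  }
  total / (n * (n - 1))
}

random_symmetric_graph <- function(n, p = 0.4, weighted = TRUE) {
  m <- matrix(0, n, n)
  w <- if (weighted) runif(n * (n - 1) / 2, 0.1, 1) else 1
  m[upper.tri(m)] <- rbinom(n * (n - 1) / 2, 1, p) * w
  m <- m + t(m)
  rownames(m) <- colnames(m) <- paste0("n", seq_len(n))
  m
}

ring_lattice <- function(n, k = 2) {
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (d in seq_len(k)) {
      j <- ((i - 1 + d) %% n) + 1
      A[i, j] <- A[j, i] <- 1
    }
  }
  rownames(A) <- colnames(A) <- paste0("n", seq_len(n))
  A
}

toy_roiset <- function(n_par = 2, n_pm = 3) {
  roiset(
    name = c(paste0("P", seq_len(n_par)), paste0("M", seq_len(n_pm))),
    lobe = c(rep("parietal", n_par), rep("premotor", n_pm))
  )
}

# small cohort used by several end-to-end tests (kept cheap)
small_spec <- function(seed = 1L, ...) {
  synthetic_spec(n_subjects = 8, seed = seed, ...)
}
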