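# Independent brute-force graph oracles for small graphs (<= ~15 nodes).
# Deliberately naive: plain-R BFS, triangle counting, and exhaustive
# shortest-path enumeration — no igraph anywhere in this file.

oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (s in seq_len(n)) {
    frontier <- s
    depth <- 0
    visited <- logical(n)
    visited[s] <- TRUE
    while (length(frontier)) {
      depth <- depth + 1
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(adj[v, ] != 0)) {
          if (!visited[w]) {
            visited[w] <- TRUE
            d[s, w] <- depth
            nxt <- c(nxt, w)
          }
        }
      }
      frontier <- nxt
    }
  }
  d
}

oracle_local_clustering <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(v) {
    nb <- which(adj[v, ] != 0)
    k <- length(nb)
    if (k < 2) return(0)
    links <- 0
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        if (adj[nb[a], nb[b]] != 0) links <- links + 1
      }
    }
    2 * links / (k * (k - 1))
  }, numeric(1))
}

# enumerate every shortest path between two nodes as vertex sequences
oracle_shortest_paths <- function(adj, d, s, t) {
  if (!is.finite(d[s, t])) return(list())
  if (s == t) return(list(s))
  extend <- function(path) {
    v <- path[length(path)]
    if (v == t) return(list(path))
    out <- list()
    for (w in which(adj[v, ] != 0)) {
      # w lies on a shortest s-t path through v
      if (d[s, w] == d[s, v] + 1 && d[s, w] + d[w, t] == d[s, t]) {
        out <- c(out, extend(c(path, w)))
      }
    }
    out
  }
  extend(s)
}

oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- oracle_distances(adj)
  bc <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      paths <- oracle_shortest_paths(adj, d, s, t)
      np <- length(paths)
      if (np == 0) next
      for (p in paths) {
        interior <- p[-c(1, length(p))]
        bc[interior] <- bc[interior] + 1 / np
      }
    }
  }
  bc
}

oracle_global_metrics <- function(adj) {
  n <- nrow(adj)
  d <- oracle_distances(adj)
  offd <- d[row(d) != col(d)]
  finite <- is.finite(offd)
  inv <- 1 / d
  diag(inv) <- 0
  neg <- rowSums(inv) / (n - 1)
  neloc <- vapply(seq_len(n), function(v) {
    nb <- which(adj[v, ] != 0)
    if (length(nb) < 2) return(0)
    sub <- adj[nb, nb, drop = FALSE]
    ds <- oracle_distances(sub)
    invs <- 1 / ds
    diag(invs) <- 0
    k <- length(nb)
    sum(invs) / (k * (k - 1))
  }, numeric(1))
  list(Cp = mean(oracle_local_clustering(adj)),
       Lp = if (any(finite)) mean(offd[finite]) else 0,
       Eg = mean(neg), Eloc = mean(neloc),
       Dc = rowSums(adj != 0), NEg = neg, NEloc = neloc)
}

# random undirected simple graph as adjacency matrix
random_adjacency <- function(n, p, seed) {
  withr::with_seed(seed, {
    adj <- matrix(0, n, n)
    up <- which(upper.tri(adj))
    adj[up] <- as.numeric(stats::runif(length(up)) < p)
    adj + t(adj)
  })
}
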