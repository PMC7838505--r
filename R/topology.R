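# Graph topology over the sparsity range.
#
# An FC matrix is binarized at each sparsity level (fraction of strongest
# edges retained), the standard global and nodal metrics are computed, the
# small-world indices gamma/lambda/sigma are referenced to degree-preserving
# (Maslov-Sneppen) null networks, and every metric curve is integrated over
# the sparsity grid (trapezoid) to remove the dependence on any single
# threshold. Shortest-path machinery is igraph's; independent brute-force
# oracles live in the test suite.

#' Binarize an FC matrix at a target sparsity
#'
#' Keeps the `E = round(sparsity * N(N-1)/2)` edges with the largest Fisher-Z
#' values (signed, strongest positive first — the usual sparsity-thresholding
#' convention; negative edges enter only when E exceeds the number of positive
#' edges). Ties are broken deterministically by (i, j) lexicographic order;
#' rounding is half-away-from-zero for bit-exact reproducibility.
#'
#' @param fc symmetric weight matrix (Fisher-Z FC).
#' @param sparsity fraction of possible edges to retain, in (0, 1).
#' @return 0/1 adjacency matrix with zero diagonal and attribute `sparsity`.
#' @export
binarize_at_sparsity <- function(fc, sparsity) {
  stopifnot(sparsity > 0, sparsity < 1)
  n <- nrow(fc)
  ei <- edge_index(n)
  m <- nrow(ei)
  E <- round_half_away(sparsity * m)
  if (E < 1) stop("sparsity ", sparsity, " yields zero edges for N = ", n)
  w <- fc[ei]
  keep <- ei[order(-w, ei[, 1L], ei[, 2L])[seq_len(E)], , drop = FALSE]
  adj <- matrix(0, n, n)
  adj[keep] <- 1
  adj[keep[, c(2L, 1L)]] <- 1
  attr(adj, "sparsity") <- sparsity
  adj
}

# Single pass over one binary graph: everything the global and nodal metric
# surfaces need, sharing one all-pairs BFS.
graph_metrics <- function(adj) {
  n <- nrow(adj)
  g <- igraph::graph_from_adjacency_matrix(adj != 0, mode = "undirected",
                                           diag = FALSE)
  deg <- igraph::degree(g)
  cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  cc[is.nan(cc)] <- 0  # degree-1 vertices
  d <- igraph::distances(g)
  inv <- 1 / d          # 1/Inf = 0 for unreachable pairs
  diag(inv) <- 0
  ne_g <- rowSums(inv) / (n - 1)
  offd <- d[row(d) != col(d)]
  finite <- is.finite(offd)
  lp <- if (any(finite)) mean(offd[finite]) else 0
  neloc <- vapply(seq_len(n), function(v) {
    nb <- which(adj[v, ] != 0)
    if (length(nb) < 2L) return(0)
    subgraph_efficiency(adj[nb, nb, drop = FALSE])
  }, numeric(1))
  bc <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  list(Cp = mean(cc), Lp = lp, Eg = mean(ne_g), Eloc = mean(neloc),
       Dc = deg, Bc = bc, NEg = ne_g, NEloc = neloc,
       disconnected = any(!finite))
}

subgraph_efficiency <- function(a) {
  k <- nrow(a)
  if (k < 2L) return(0)
  g <- igraph::graph_from_adjacency_matrix(a != 0, mode = "undirected",
                                           diag = FALSE)
  d <- igraph::distances(g)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (k * (k - 1))
}

#' Global graph metrics
#'
#' Clustering coefficient `Cp` (mean over nodes of 2*triangles/(k(k-1)), zero
#' for degree < 2), characteristic path length `Lp` (mean shortest path over
#' connected ordered pairs; unreachable pairs are excluded and flagged),
#' global efficiency `Eg` (mean of 1/d over all ordered pairs, 1/Inf = 0) and
#' local efficiency `Eloc` (mean over nodes of the global efficiency of each
#' node's neighbor-induced subgraph).
#'
#' @param adj 0/1 adjacency matrix.
#' @return list with `Cp`, `Lp`, `Eg`, `Eloc` and logical `disconnected`.
#' @export
global_metrics <- function(adj) {
  gm <- graph_metrics(adj)
  gm[c("Cp", "Lp", "Eg", "Eloc", "disconnected")]
}

#' Nodal graph metrics
#'
#' Degree centrality `Dc`, unnormalized shortest-path betweenness `Bc`
#' (Brandes), nodal global efficiency `NEg_i = mean_{j != i} 1/d_ij`, and
#' nodal local efficiency `NEloc` (efficiency of the neighbor-induced
#' subgraph; zero for degree < 2).
#'
#' @param adj 0/1 adjacency matrix.
#' @return list of numeric vectors `Bc`, `Dc`, `NEg`, `NEloc`.
#' @export
nodal_metrics <- function(adj) {
  gm <- graph_metrics(adj)
  gm[c("Bc", "Dc", "NEg", "NEloc")]
}

#' Degree-preserving random rewiring (Maslov-Sneppen)
#'
#' Double-edge swaps that keep the degree sequence exactly and never create
#' self-loops or multi-edges (swap proposals that would are skipped).
#' Reproducible given the seed.
#'
#' @param adj 0/1 adjacency matrix.
#' @param n_swaps number of attempted swaps (default 10 per edge).
#' @param seed integer seed.
#' @return rewired 0/1 adjacency matrix.
#' @export
degree_preserving_null <- function(adj, n_swaps = NULL, seed = 1L) {
  E <- sum(adj != 0) / 2
  n_swaps <- n_swaps %||% max(1L, round(10 * E))
  if (n_swaps == 0) return(adj)
  g <- igraph::graph_from_adjacency_matrix(adj != 0, mode = "undirected",
                                           diag = FALSE)
  g2 <- withr::with_seed(as.integer(seed),
                         igraph::rewire(g, igraph::keeping_degseq(niter = n_swaps)))
  out <- igraph::as_adjacency_matrix(g2, sparse = FALSE)
  dimnames(out) <- NULL
  attr(out, "sparsity") <- attr(adj, "sparsity")
  out
}

#' Small-world indices against degree-preserving nulls
#'
#' `gamma = Cp / <Cp_null>`, `lambda = Lp / <Lp_null>`, `sigma = gamma /
#' lambda`, with `< >` the mean over `n_null` rewired null networks. When the
#' null clustering mean is zero the index is undefined and returned as `NaN`
#' (flagged; [compute_topology_profile()] imputes such points from the rest of
#' the curve).
#'
#' @param adj 0/1 adjacency matrix.
#' @param n_null number of null networks (>= 1).
#' @param seed integer seed.
#' @param n_swaps swaps per null network (default 10 per edge).
#' @return list with `gamma`, `lambda`, `sigma`.
#' @export
small_world_indices <- function(adj, n_null = 20, seed = 1L, n_swaps = NULL) {
  stopifnot(n_null >= 1)
  gm <- graph_metrics(adj)
  cp0 <- numeric(n_null)
  lp0 <- numeric(n_null)
  for (b in seq_len(n_null)) {
    nb <- degree_preserving_null(adj, n_swaps = n_swaps,
                                 seed = derive_seed(seed, sprintf("null_%03d", b)))
    nm <- null_cp_lp(nb)
    cp0[b] <- nm$Cp
    lp0[b] <- nm$Lp
  }
  gamma <- if (mean(cp0) == 0) NaN else gm$Cp / mean(cp0)
  lambda <- if (mean(lp0) == 0) NaN else gm$Lp / mean(lp0)
  list(gamma = gamma, lambda = lambda, sigma = gamma / lambda)
}

# cheap Cp/Lp only, for null networks
null_cp_lp <- function(adj) {
  g <- igraph::graph_from_adjacency_matrix(adj != 0, mode = "undirected",
                                           diag = FALSE)
  cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  cc[is.nan(cc)] <- 0
  d <- igraph::distances(g)
  offd <- d[row(d) != col(d)]
  finite <- is.finite(offd)
  list(Cp = mean(cc), Lp = if (any(finite)) mean(offd[finite]) else 0)
}

#' Integrate a metric curve over the sparsity grid
#'
#' Trapezoidal integral of metric values against sparsity (exact for linear
#' curves). Non-finite values are rejected with the offending sparsity level
#' named; impute or reject upstream.
#'
#' @param values metric value per sparsity.
#' @param sparsities strictly increasing sparsity grid (>= 2 points).
#' @return scalar area under the curve.
#' @export
auc_over_sparsity <- function(values, sparsities = seq(0.01, 0.34, by = 0.01)) {
  stopifnot(length(values) == length(sparsities), length(values) >= 2,
            all(diff(sparsities) > 0))
  bad <- !is.finite(values)
  if (any(bad))
    stop("non-finite metric value at sparsity ",
         paste(sparsities[bad], collapse = ", "))
  pracma::trapz(sparsities, values)
}

#' Sparsity-integrated topology profile of one FC matrix
#'
#' For each sparsity in the grid: binarize, compute the global metrics, the
#' small-world indices against `n_null` degree-preserving nulls, and the four
#' nodal metrics; then integrate every metric curve over the grid. Yields the
#' 7 global values (`aGamma`, `aLambda`, `aSigma`, `aCp`, `aLp`, `aEg`,
#' `aEloc`) and `4 * N` nodal values (`aBc_<node>`, `aDc_<node>`,
#' `aNEg_<node>`, `aNEloc_<node>`) — 499 numbers for a 123-node network.
#'
#' Undefined small-world points (null clustering zero, typical at the lowest
#' sparsities) are imputed by linear interpolation over the grid with
#' nearest-finite extension at the ends; an entirely non-finite curve is an
#' error.
#'
#' @param fc symmetric Fisher-Z FC matrix.
#' @param sparsities sparsity grid (default 0.01..0.34, step 0.01).
#' @param n_null null networks per sparsity for gamma/lambda/sigma.
#' @param seed integer seed (nulls are the only stochastic component).
#' @param keep_curves also return the raw metric curves.
#' @return list with `global` (named length-7 vector), `nodal` (named length
#'   `4N` vector), `disconnected` (logical per sparsity), `subject_id`, and
#'   optionally `curves`.
#' @export
compute_topology_profile <- function(fc, sparsities = seq(0.01, 0.34, by = 0.01),
                                     n_null = 20, seed = 1L,
                                     keep_curves = FALSE) {
  n <- nrow(fc)
  S <- length(sparsities)
  glob <- matrix(NA_real_, 7L, S,
                 dimnames = list(c("Gamma", "Lambda", "Sigma", "Cp", "Lp",
                                   "Eg", "Eloc"), NULL))
  nodal <- array(NA_real_, c(4L, n, S),
                 dimnames = list(c("Bc", "Dc", "NEg", "NEloc"), NULL, NULL))
  disconnected <- logical(S)
  for (s in seq_len(S)) {
    adj <- binarize_at_sparsity(fc, sparsities[s])
    gm <- graph_metrics(adj)
    sw <- small_world_indices(adj, n_null = n_null,
                              seed = derive_seed(seed, sprintf("sparsity_%02d", s)))
    glob[, s] <- c(sw$gamma, sw$lambda, sw$sigma, gm$Cp, gm$Lp, gm$Eg, gm$Eloc)
    nodal[1L, , s] <- gm$Bc
    nodal[2L, , s] <- gm$Dc
    nodal[3L, , s] <- gm$NEg
    nodal[4L, , s] <- gm$NEloc
    disconnected[s] <- gm$disconnected
  }
  for (k in 1:3) {  # gamma/lambda/sigma may carry flagged NaN points
    if (anyNA(glob[k, ]) || any(!is.finite(glob[k, ]))) {
      v <- glob[k, ]
      v[!is.finite(v)] <- NA_real_
      if (all(is.na(v)))
        stop("small-world curve ", rownames(glob)[k],
             " is non-finite at every sparsity")
      glob[k, ] <- zoo::na.approx(v, x = sparsities, na.rm = FALSE, rule = 2)
    }
  }
  global_auc <- apply(glob, 1L, auc_over_sparsity, sparsities = sparsities)
  names(global_auc) <- c("aGamma", "aLambda", "aSigma", "aCp", "aLp",
                         "aEg", "aEloc")
  nodal_auc <- numeric(0)
  for (k in 1:4) {
    a <- apply(nodal[k, , , drop = TRUE], 1L, auc_over_sparsity,
               sparsities = sparsities)
    names(a) <- paste0("a", dimnames(nodal)[[1L]][k], "_", seq_len(n))
    nodal_auc <- c(nodal_auc, a)
  }
  out <- list(global = global_auc, nodal = nodal_auc,
              disconnected = disconnected,
              subject_id = attr(fc, "subject_id"))
  if (keep_curves) out$curves <- list(global = glob, nodal = nodal)
  out
}

#' Topology feature table for a cohort
#'
#' Computes the sparsity-integrated profile for every subject and stacks the
#' `7 + 4N` values into a subjects x features matrix (columns `aGamma` ...
#' `aNEloc_<N>`).
#'
#' @param cohort a `cohort` object.
#' @param clean apply [clean_timeseries()] before the FC matrix.
#' @param sparsities,n_null,seed passed to [compute_topology_profile()];
#'   each subject gets a seed derived from `seed` and its id.
#' @return numeric matrix with rownames = subject ids.
#' @export
cohort_topology_features <- function(cohort, clean = TRUE,
                                     sparsities = seq(0.01, 0.34, by = 0.01),
                                     n_null = 20, seed = 1L) {
  tr <- cohort$spec$tr_seconds
  rows <- lapply(cohort$subjects, function(sub) {
    ts <- sub$timeseries
    if (clean) ts <- clean_timeseries(ts, tr)
    fc <- pearson_fc(ts, subject_id = sub$id)
    pr <- compute_topology_profile(fc, sparsities = sparsities, n_null = n_null,
                                   seed = derive_seed(seed, sub$id))
    c(pr$global, pr$nodal)
  })
  X <- do.call(rbind, rows)
  rownames(X) <- vapply(cohort$subjects, `[[`, "", "id")
  X
}
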