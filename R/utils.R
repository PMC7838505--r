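# shared internal helpers

# half-away-from-zero rounding; base round() is banker's rounding and would make
# sparsity edge counts platform/representation sensitive
round_half_away <- function(x) trunc(x + 0.5 * sign(x))

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage-specific seed from a master seed
#'
#' Deterministic hash of (seed, stage label) so that pipeline stages and
#' repetitions each get an independent, reproducible RNG stream. Result is
#' always a valid 32-bit integer seed.
#'
#' @param seed master integer seed.
#' @param stage character label of the stage or repetition.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage),
            length(stage) == 1L)
  ch <- utf8ToInt(stage)
  h <- sum(ch * ((seq_along(ch) - 1L) %% 31L + 1L)) * 7919
  as.integer((abs(seed) %% 2147483629 * 48271 + h) %% 2147483629)
}

# canonical row-major upper-triangle edge order: (1,2), (1,3), ..., (1,N),
# (2,3), ... — the fixed feature order used by every module
edge_index <- function(n_nodes) {
  stopifnot(n_nodes >= 2)
  i <- rep.int(seq_len(n_nodes - 1L), times = (n_nodes - 1L):1L)
  j <- unlist(lapply(seq_len(n_nodes - 1L), function(a) (a + 1L):n_nodes),
              use.names = FALSE)
  cbind(i = i, j = j)
}

edge_feature_ids <- function(n_nodes, prefix = "FC") {
  ei <- edge_index(n_nodes)
  paste0(prefix, "_", ei[, 1L], "_", ei[, 2L])
}

min_eigenvalue <- function(m) {
  min(eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values)
}
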