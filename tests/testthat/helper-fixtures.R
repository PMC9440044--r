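# Small hand-built fixtures used across test files.

# AND motif as a bare network: seeds a = 1, b = 2, output u = 3.
and_net <- function(phi_u = 0.6) {
  threshold_network(n = 3, edges = rbind(c(1, 3), c(2, 3)),
                    thresholds = c(0.5, 0.5, phi_u), seeds = c(1, 2))
}

# Star of depth 1: every non-seed node adjacent to a chosen subset of the
# seeds; function assignment is then exact and order-free.
bipartite_net <- function(k, attach, thresholds, antagonist = NULL) {
  n <- k + length(attach)
  edges <- do.call(rbind, lapply(seq_along(attach), function(i) {
    if (length(attach[[i]]) == 0) return(NULL)
    cbind(attach[[i]], k + i)
  }))
  if (is.null(edges)) edges <- matrix(integer(0), ncol = 2)
  if (is.null(antagonist)) antagonist <- rep(FALSE, n)
  threshold_network(n = n, edges = edges,
                    thresholds = c(rep(0.5, k), thresholds),
                    seeds = seq_len(k), antagonist = antagonist)
}

all_patterns <- function(k) {
  lapply(0:(2^k - 1), function(x) as.integer(bitwAnd(bitwShiftR(x, (k - 1):0), 1L)))
}
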