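#' Construct a random threshold network
#'
#' Builds an Erdos-Renyi-Gilbert graph with `n` nodes in which each of the
#' `n(n-1)/2` unordered pairs is an edge independently with probability
#' `p = z/(n-1)` (clamped to 1, so `z >= n-1` gives the complete graph).
#' Every node receives a threshold drawn uniformly from the open interval
#' (0, 1); `k` distinct seed (input) nodes are chosen uniformly at random,
#' and `round(theta * (n - k))` of the remaining nodes are flagged
#' antagonistic (inhibitory).  Seed nodes are never antagonistic: they are
#' externally clamped inputs, so their own update rule is never applied.
#'
#' A single master seed expands deterministically into independent streams
#' for topology, thresholds, seed-node choice and antagonist choice, so a
#' network is fully reproducible from `(n, z, k, theta, rng_seed)`.
#'
#' @param n Number of nodes.
#' @param z Target mean degree; edge probability is `z/(n-1)`.
#' @param k Number of seed (input) nodes, `1 <= k <= n`.
#' @param theta Fraction of non-seed nodes given the antagonistic
#'   (inhibitory) labelling rule, in `[0, 1]`.
#' @param rng_seed Integer master seed.
#' @return An object of class `threshold_network`: a list with elements
#'   `n`, `edges` (two-column integer matrix, 1-based, each row an
#'   unordered pair), `thresholds`, `antagonist` (logical), `seeds`
#'   (ordered integer vector of the input nodes), `k`, `z`, `p`,
#'   `theta`, `rng_seed`.
#' @examples
#' net <- generate_network(n = 100, z = 4, k = 2, theta = 0, rng_seed = 1)
#' mean(igraph::degree(as_igraph(net)))
#' @export
generate_network <- function(n, z, k = 2L, theta = 0, rng_seed = 1L) {
  n <- as.integer(n); k <- as.integer(k)
  if (k < 1L || k > n) stop("need 1 <= k <= n, got k = ", k, ", n = ", n)
  if (theta < 0 || theta > 1) stop("theta must lie in [0, 1], got ", theta)
  if (z < 0) stop("mean degree z must be nonnegative")
  p <- if (n > 1L) min(1, z / (n - 1)) else 0
  s <- derive_seeds(rng_seed, c("topology", "thresholds", "seeds",
                                "antagonists", "order"))

  set.seed(s[["topology"]])
  g <- igraph::sample_gnp(n, p)
  edges <- igraph::as_edgelist(g, names = FALSE)
  storage.mode(edges) <- "integer"
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]

  set.seed(s[["thresholds"]])
  phi <- runif(n)
  while (any(bad <- phi <= 0 | phi >= 1)) phi[bad] <- runif(sum(bad))

  set.seed(s[["seeds"]])
  seeds <- sample.int(n, k)

  antagonist <- rep(FALSE, n)
  n_ant <- round(theta * (n - k))
  if (n_ant > 0) {
    set.seed(s[["antagonists"]])
    non_seed <- setdiff(seq_len(n), seeds)
    antagonist[sample(non_seed, n_ant)] <- TRUE
  }

  structure(
    list(n = n, edges = edges, thresholds = phi, antagonist = antagonist,
         seeds = seeds, k = k, z = z, p = p, theta = theta,
         rng_seed = as.integer(rng_seed), order_seed = s[["order"]]),
    class = "threshold_network")
}

#' Assemble a threshold network from explicit parts
#'
#' Low-level constructor used for hand-built fragments (logic motifs, test
#' fixtures) and by [read_edgelist()].  Validates the network invariants:
#' no self-loops or duplicate edges, thresholds in `[0, 1]`, distinct
#' in-range seed nodes.
#'
#' @param n Node count.
#' @param edges Two-column matrix of 1-based node pairs (may have 0 rows).
#' @param thresholds Numeric vector of length `n` in `[0, 1]`.
#' @param seeds Integer vector of distinct seed node indices.
#' @param antagonist Logical vector of length `n` (default all `FALSE`).
#' @param z,rng_seed Optional metadata carried along (mean-degree target
#'   and master seed); purely informational here.
#' @return A `threshold_network`.
#' @export
threshold_network <- function(n, edges, thresholds, seeds,
                              antagonist = rep(FALSE, n),
                              z = NA_real_, rng_seed = NA_integer_) {
  n <- as.integer(n)
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) > 0) {
    edges <- t(apply(edges, 1, sort))
    if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
    if (anyDuplicated(paste(edges[, 1], edges[, 2]))) {
      stop("duplicate edges are not allowed")
    }
    if (any(edges < 1L) || any(edges > n)) stop("edge endpoint out of range")
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  }
  if (length(thresholds) != n) stop("need one threshold per node")
  if (any(thresholds < 0 | thresholds > 1)) {
    stop("thresholds must lie in [0, 1]")
  }
  seeds <- as.integer(seeds)
  if (anyDuplicated(seeds) || any(seeds < 1L) || any(seeds > n)) {
    stop("seed nodes must be distinct indices in 1..n")
  }
  antagonist <- as.logical(antagonist)
  if (length(antagonist) != n) stop("need one antagonist flag per node")
  structure(
    list(n = n, edges = edges, thresholds = as.numeric(thresholds),
         antagonist = antagonist, seeds = seeds, k = length(seeds),
         z = z, p = if (n > 1) nrow(edges) / (n * (n - 1) / 2) else 0,
         theta = if (n > length(seeds)) mean(antagonist[-seeds]) else 0,
         rng_seed = rng_seed,
         order_seed = 1L),
    class = "threshold_network")
}

#' @export
print.threshold_network <- function(x, ...) {
  cat(sprintf(
    "<threshold_network> %d nodes, %d edges (target z = %s), k = %d seeds\n",
    x$n, nrow(x$edges), format(x$z), x$k))
  cat(sprintf("  antagonist fraction theta = %.3f; seeds: %s\n",
              x$theta, paste(x$seeds, collapse = ", ")))
  invisible(x)
}

#' Convert a threshold network to an igraph graph
#'
#' @param net A `threshold_network`.
#' @return An undirected `igraph` graph on `net$n` vertices.
#' @export
as_igraph <- function(net) {
  g <- igraph::make_empty_graph(net$n, directed = FALSE)
  if (nrow(net$edges)) g <- igraph::add_edges(g, t(net$edges))
  g
}

#' Largest connected component of a network
#'
#' Returns the node set of the largest connected component.  Ties are
#' broken deterministically: the component containing the smallest node
#' index wins.
#'
#' @param net A `threshold_network`.
#' @return Sorted integer vector of node indices (1-based).
#' @export
giant_component <- function(net) {
  comp <- igraph::components(as_igraph(net))
  big <- which(comp$csize == max(comp$csize))
  if (length(big) > 1L) {
    first_member <- vapply(big, function(cc) min(which(comp$membership == cc)),
                           integer(1))
    big <- big[which.min(first_member)]
  }
  sort(which(comp$membership == big))
}

#' Theoretical giant-component fraction
#'
#' Solves the mean-field self-consistency relation `v = 1 - exp(-z v)` for
#' the fraction `v` of nodes in the giant connected component of an
#' Erdos-Renyi graph with mean degree `z`.  Below the critical mean degree
#' `z_c = 1` the only root in `[0, 1]` is `v = 0`; above it the nonzero
#' root is located by bisection on `(1e-12, 1]` (the trivial root `v = 0`
#' is always present and must be excluded).
#'
#' @param z Mean degree (vectorised), `z >= 0`.
#' @return Fraction(s) in `[0, 1]`, with residual
#'   `|v - (1 - exp(-z v))| < 1e-10`.
#' @examples
#' gcc_fraction_theoretical(c(0.5, 1, 4))
#' @export
gcc_fraction_theoretical <- function(z) {
  if (any(z < 0)) stop("mean degree z must be nonnegative")
  vapply(z, function(zi) {
    if (zi <= 1) return(0)
    f <- function(v) v - 1 + exp(-zi * v)
    lo <- 1e-12; hi <- 1
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) <= 0) lo <- mid else hi <- mid
      if (hi - lo < 1e-15) break
    }
    (lo + hi) / 2
  }, numeric(1))
}

#' Expected clustering coefficient of the random graph
#'
#' For an Erdos-Renyi graph the clustering coefficient equals the edge
#' probability, `C_clus ~ p = z/(n-1)`; the graph stays locally tree-like
#' well above the percolation threshold whenever `z << n`.
#'
#' @param n Node count (`n >= 2`).
#' @param z Mean degree.
#' @return The estimate `min(1, z/(n-1))`.
#' @examples
#' clustering_estimate(10000, 10)  # ~ 1/1000
#' @export
clustering_estimate <- function(n, z) {
  if (n < 2) stop("need n >= 2")
  pmin(1, z / (n - 1))
}

#' Write / read a threshold network as plain text
#'
#' The edge list is one `"u v"` pair per line (0-based indices);
#' thresholds, antagonist flags, seed nodes and metadata go to a YAML
#' sidecar file (default: `<path>.meta.yaml`).  A written network reads
#' back identically.
#'
#' @param net A `threshold_network`.
#' @param path Edge-list file path.
#' @param sidecar Sidecar file path.
#' @return `write_edgelist`: `path`, invisibly.  `read_edgelist`: a
#'   `threshold_network`.
#' @export
write_edgelist <- function(net, path, sidecar = paste0(path, ".meta.yaml")) {
  writeLines(sprintf("%d %d", net$edges[, 1] - 1L, net$edges[, 2] - 1L), path)
  meta <- list(n = net$n, k = net$k, z = net$z, theta = net$theta,
               rng_seed = net$rng_seed,
               seed_nodes = as.integer(net$seeds - 1L),
               thresholds = net$thresholds,
               antagonist_flags = as.integer(net$antagonist))
  yaml::write_yaml(meta, sidecar, precision = 15L)
  invisible(path)
}

#' @rdname write_edgelist
#' @export
read_edgelist <- function(path, sidecar = paste0(path, ".meta.yaml")) {
  if (!file.exists(sidecar)) stop("sidecar file not found: ", sidecar)
  meta <- yaml::read_yaml(sidecar)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines)) {
    parts <- strsplit(trimws(lines), "\\s+")
    bad <- which(vapply(parts, length, integer(1)) != 2L |
                   vapply(parts, function(p) anyNA(suppressWarnings(
                     as.integer(p))), logical(1)))
    if (length(bad)) {
      stop("malformed edge line ", bad[1], ": '", lines[bad[1]], "'")
    }
    edges <- do.call(rbind, lapply(parts, as.integer)) + 1L
    loops <- which(edges[, 1] == edges[, 2])
    if (length(loops)) stop("self-loop at line ", loops[1])
  } else {
    edges <- matrix(integer(0), ncol = 2)
  }
  net <- threshold_network(
    n = meta$n, edges = edges, thresholds = meta$thresholds,
    seeds = as.integer(meta$seed_nodes) + 1L,
    antagonist = as.logical(meta$antagonist_flags),
    z = if (is.null(meta$z)) NA_real_ else meta$z,
    rng_seed = if (is.null(meta$rng_seed)) NA_integer_ else
      as.integer(meta$rng_seed))
  net
}
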