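# Canonical minimal fragments realising every k = 2 Boolean function.
# Node 1 = seed a, node 2 = seed b; the output node is always last.
# Thresholds are fixed mid-interval representatives of the open intervals
# that realise each function, so the catalog is deterministic.  "Paths" of
# the idealised motifs are realised as direct edges: the distinction only
# matters for occurrence probabilities, which are carried by the
# gcc_nodes exponent, not by fragment geometry.
motif_catalog_spec <- function() {
  E <- function(...) {
    v <- c(...)
    if (is.null(v)) matrix(integer(0), ncol = 2)
    else matrix(v, ncol = 2, byrow = TRUE)
  }
  list(
    # -- pure LTM: monotone increasing functions --------------------------
    `0` = list(n = 3, edges = E(), phi = c(.5, .5, .5), antag = integer(0),
               paths = 0L, gcc_nodes = NA_integer_),
    `1` = list(n = 3, edges = E(1, 3, 2, 3), phi = c(.5, .5, .75),
               antag = integer(0), paths = 2L, gcc_nodes = 3L),   # AND
    `3` = list(n = 3, edges = E(1, 3), phi = c(.5, .5, .75),
               antag = integer(0), paths = 1L, gcc_nodes = 2L),   # a
    `5` = list(n = 3, edges = E(2, 3), phi = c(.5, .5, .75),
               antag = integer(0), paths = 1L, gcc_nodes = 2L),   # b
    `7` = list(n = 3, edges = E(1, 3, 2, 3), phi = c(.5, .5, .25),
               antag = integer(0), paths = 2L, gcc_nodes = 3L),   # OR
    # -- single-antagonist negations of the above -------------------------
    `8` = list(n = 3, edges = E(1, 3, 2, 3), phi = c(.5, .5, .25),
               antag = 3L, paths = 2L, gcc_nodes = 3L),           # NOR
    `10` = list(n = 3, edges = E(2, 3), phi = c(.5, .5, .75),
                antag = 3L, paths = 1L, gcc_nodes = 2L),          # not b
    `12` = list(n = 3, edges = E(1, 3), phi = c(.5, .5, .75),
                antag = 3L, paths = 1L, gcc_nodes = 2L),          # not a
    `14` = list(n = 3, edges = E(1, 3, 2, 3), phi = c(.5, .5, .75),
                antag = 3L, paths = 2L, gcc_nodes = 3L),          # NAND
    `15` = list(n = 3, edges = E(), phi = c(.5, .5, .5), antag = 3L,
                paths = 0L, gcc_nodes = NA_integer_),             # const 1
    # -- mixed fragments for the non-monotone functions -------------------
    # f2 = a AND (not b): node 3 negates b, node 4 conjoins.
    `2` = list(n = 4, edges = E(2, 3, 3, 4, 1, 4),
               phi = c(.5, .5, .5, .75), antag = 3L,
               paths = 3L, gcc_nodes = 4L),
    # f4 = (not a) AND b: mirror image of f2.
    `4` = list(n = 4, edges = E(1, 3, 3, 4, 2, 4),
               phi = c(.5, .5, .5, .75), antag = 3L,
               paths = 3L, gcc_nodes = 4L),
    # f6 = XOR = OR(a,b) AND NAND(a,b): 5 nodes joined by 6 paths, all of
    # which must lie in the giant component, hence exponent 5 rather than
    # the complexity-based C + 1 = 3.
    `6` = list(n = 5, edges = E(1, 3, 2, 3, 1, 4, 2, 4, 3, 5, 4, 5),
               phi = c(.5, .5, .3, .5, .75), antag = 4L,
               paths = 6L, gcc_nodes = 5L),
    # f13 = (not a) OR b; f11 = a OR (not b): negate one input, then OR.
    `13` = list(n = 4, edges = E(1, 3, 3, 4, 2, 4),
                phi = c(.5, .5, .5, .5), antag = 3L,
                paths = 3L, gcc_nodes = 4L),
    `11` = list(n = 4, edges = E(2, 3, 3, 4, 1, 4),
                phi = c(.5, .5, .5, .5), antag = 3L,
                paths = 3L, gcc_nodes = 4L),
    # f9 = XNOR = NOR(a,b) OR AND(a,b).
    `9` = list(n = 5, edges = E(1, 3, 2, 3, 1, 4, 2, 4, 3, 5, 4, 5),
               phi = c(.5, .5, 1 / 3, .6, .5), antag = 3L,
               paths = 6L, gcc_nodes = 5L)
  )
}

motif_gcc_nodes <- function(id) {
  spec <- motif_catalog_spec()[[as.character(id)]]
  if (is.null(spec)) return(NA_integer_)
  spec$gcc_nodes
}

#' Giant-component exponent of a motif
#'
#' The number of distinct nodes whose joint giant-component membership
#' governs the occurrence probability of the minimal motif for a
#' two-input function, i.e. the exponent of the giant-component fraction
#' in [motif_probability()].  `NA` for the constant functions, whose
#' probability is governed by path absence instead.
#'
#' @param function_id Integer id in `0:15`.
#' @return Integer exponent, or `NA` for ids 0 and 15.
#' @export
motif_exponent <- function(function_id) {
  motif_gcc_nodes(function_id)
}

#' Build the minimal logic motif for a two-input function
#'
#' Returns the canonical minimal sub-network (logical automaton) whose
#' output node computes the requested Boolean function of the two seed
#' nodes.  Monotone increasing functions (`0, 1, 3, 5, 7`) need only
#' excitatory nodes; their negations (`8, 10, 12, 14, 15`) antagonise the
#' output node; the remaining non-monotone functions mix both rules, the
#' XOR / XNOR pair requiring 5 nodes joined by 6 paths.
#'
#' @param function_id Integer id in `0:15`.
#' @return An object of class `motif`: list with `target_id`,
#'   `fragment` (a `threshold_network` with seeds a = 1, b = 2),
#'   `output_node`, `required_paths`, `required_gcc_nodes`.
#' @examples
#' m <- build_motif(6)            # XOR
#' verify_motif(m)
#' @export
build_motif <- function(function_id) {
  spec <- motif_catalog_spec()[[as.character(function_id)]]
  if (is.null(spec)) stop("no catalogued motif for function id ", function_id)
  antag <- rep(FALSE, spec$n)
  antag[spec$antag] <- TRUE
  frag <- threshold_network(n = spec$n, edges = spec$edges,
                            thresholds = spec$phi, seeds = c(1L, 2L),
                            antagonist = antag)
  structure(list(target_id = as.integer(function_id), fragment = frag,
                 output_node = spec$n, required_paths = spec$paths,
                 required_gcc_nodes = spec$gcc_nodes),
            class = "motif")
}

#' @export
print.motif <- function(x, ...) {
  cat(sprintf(
    "<motif> f%d: %d nodes, %d edges, %d required path(s), output node %d\n",
    x$target_id, x$fragment$n, nrow(x$fragment$edges), x$required_paths,
    x$output_node))
  invisible(x)
}

# All fixed points reachable under any asynchronous schedule, by DFS over
# the choice of which currently-eligible node fires next.  Sweep schedules
# are a subset of these interleavings and share the same termination
# condition (no eligible node left), so if every reachable fixed point
# agrees, every update order yields the same output.
reachable_outputs <- function(net, pattern, output_node) {
  labels <- rep(FALSE, net$n)
  labels[net$seeds] <- as.logical(pattern)
  non_seed <- setdiff(seq_len(net$n), net$seeds)
  seen <- new.env(parent = emptyenv())
  outs <- logical(0)
  recurse <- function(labels) {
    key <- paste(as.integer(labels), collapse = "")
    if (!is.null(seen[[key]])) return(invisible(NULL))
    seen[[key]] <- TRUE
    eligible <- non_seed[!labels[non_seed] &
                           vapply(non_seed, function(u) {
                             if (labels[u]) FALSE else fires(u, labels, net)
                           }, logical(1))]
    if (length(eligible) == 0) {
      outs[[length(outs) + 1]] <<- labels[output_node]
      return(invisible(NULL))
    }
    for (u in eligible) {
      nl <- labels
      nl[u] <- TRUE
      recurse(nl)
    }
  }
  recurse(labels)
  unique(outs)
}

#' Verify a motif against its target truth table
#'
#' Exhaustively checks that the fragment's output node computes the
#' target function for every input pattern and under *every* update
#' order: all asynchronous interleavings are enumerated by depth-first
#' search over which eligible node fires next (feasible for the small
#' catalogued fragments).
#'
#' @param m A `motif`, or a list with elements `fragment`, `output_node`,
#'   `target_id`.
#' @return `TRUE` iff every reachable fixed point matches the target
#'   table on all `2^k` patterns.
#' @export
verify_motif <- function(m) {
  k <- m$fragment$k
  target <- function_table(m$target_id, k)
  for (x in 0:(2^k - 1)) {
    pattern <- as.logical(bitwAnd(bitwShiftR(x, (k - 1):0), 1L))
    outs <- reachable_outputs(m$fragment, pattern, m$output_node)
    if (length(outs) != 1 || outs != target[x + 1]) return(FALSE)
  }
  TRUE
}

#' Path-probability prediction from a motif
#'
#' The chance a random node ends up computing function `f` scales with
#' the chance that the motif's required nodes are jointly connected.  In
#' a large sparse graph the probability of a path between two random
#' nodes approaches `v^2` (both in the giant component), and joint
#' connection of `m` specific nodes approaches `v^m`; the constant
#' functions instead require *absence* of paths from both seeds,
#' `(1 - v^2)^2`.
#'
#' @param function_id Integer id in `0:15`.
#' @param z Mean degree.
#' @param n Node count; only the large-`n` limit is used, the argument is
#'   accepted for interface symmetry.
#' @return Unnormalised probability.
#' @examples
#' motif_probability(1, z = 4)   # AND: v^3
#' motif_probability(6, z = 4)   # XOR: v^5
#' @export
motif_probability <- function(function_id, z, n = Inf) {
  if (z < 0) stop("mean degree z must be nonnegative")
  v <- gcc_fraction_theoretical(z)
  m <- motif_gcc_nodes(function_id)
  if (is.na(m)) (1 - v^2)^2 else v^m
}

#' Export the motif catalog as edge-list files
#'
#' Writes every catalogued `k = 2` motif fragment as an edge-list plus
#' YAML sidecar (same dialect as [write_edgelist()]) into a directory,
#' one pair of files per function id.
#'
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of function ids written.
#' @export
write_motif_catalog <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- as.integer(names(motif_catalog_spec()))
  for (id in ids) {
    m <- build_motif(id)
    write_edgelist(m$fragment, file.path(dir, sprintf("motif_f%02d.edges", id)))
  }
  invisible(sort(ids))
}
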