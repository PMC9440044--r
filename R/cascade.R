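#' Firing rule for one node
#'
#' Decides whether an unlabelled non-seed node `u` becomes labelled given
#' the current label state.  An ordinary (excitatory) node fires when its
#' fraction of labelled neighbours reaches its threshold,
#' `L(u)/deg(u) >= phi_u`; an antagonistic (inhibitory) node obeys the
#' negated rule and fires when the fraction is strictly below its
#' threshold, `L(u)/deg(u) < phi_u`.  An isolated node has its fraction
#' defined as 0, so an isolated excitatory node never fires (thresholds
#' are drawn from the open interval) and an isolated antagonist always
#' does.
#'
#' @param u Node index (1-based); must not be a seed node.
#' @param state A `label_state` (see [run_cascade()]) or a logical label
#'   vector of length `net$n`.
#' @param net A `threshold_network`.
#' @return `TRUE` if `u` would become labelled when examined now.
#' @export
fires <- function(u, state, net) {
  labels <- if (inherits(state, "label_state")) state$labels else state
  if (u %in% net$seeds) stop("seed nodes are clamped and never examined")
  nbrs <- c(net$edges[net$edges[, 1] == u, 2],
            net$edges[net$edges[, 2] == u, 1])
  frac <- if (length(nbrs) == 0) 0 else mean(labels[nbrs])
  if (net$antagonist[u]) frac < net$thresholds[u]
  else frac >= net$thresholds[u]
}

#' Run one computational cascade to its fixed point
#'
#' All non-seed nodes start unlabelled; the seed nodes are clamped to
#' `seed_pattern` for the whole run.  The dynamics repeatedly sweep over
#' the currently unlabelled non-seed nodes in a fresh uniformly random
#' permutation, applying the firing rule ([fires()]) asynchronously: a
#' node that fires is labelled immediately and stays labelled.  The run
#' terminates when a full sweep labels no node, which takes at most `n`
#' sweeps since every earlier sweep labels at least one node.
#'
#' For a pure LTM (no antagonists) the rule is monotone, so the fixed
#' point does not depend on the update order; with antagonists present it
#' may, and the schedule is reproducible from `order_seed`.
#'
#' @param net A `threshold_network`.
#' @param seed_pattern Logical (or 0/1) vector of length `net$k`, aligned
#'   with `net$seeds`.
#' @param order_seed Integer seed for the update-schedule stream; defaults
#'   to the stream derived from the network's master seed.
#' @param trace If `TRUE`, record the `(sweep, node)` labelling events.
#' @return An object of class `label_state`: list with `labels` (logical
#'   length `n`), `seed_pattern`, `sweeps`, and (if requested) `trace`, a
#'   data frame of labelling events in order.
#' @examples
#' net <- generate_network(50, z = 4, k = 2, rng_seed = 7)
#' st <- run_cascade(net, c(1, 1))
#' sum(st$labels)
#' @export
run_cascade <- function(net, seed_pattern, order_seed = NULL, trace = FALSE) {
  seed_pattern <- as.logical(seed_pattern)
  if (length(seed_pattern) != net$k) {
    stop("seed_pattern must have length k = ", net$k)
  }
  if (is.null(order_seed)) order_seed <- net$order_seed
  res <- cascade_run_cpp(net$n, net$edges - 1L, net$thresholds,
                         net$antagonist, net$seeds - 1L, seed_pattern,
                         as.double(order_seed), trace)
  out <- list(labels = res$labels, seed_pattern = seed_pattern,
              sweeps = res$sweeps)
  if (trace) {
    out$trace <- data.frame(sweep = res$trace_sweep,
                            node = res$trace_node + 1L)
  }
  structure(out, class = "label_state")
}

#' @export
print.label_state <- function(x, ...) {
  cat(sprintf("<label_state> %d/%d labelled after %d sweep(s); pattern (%s)\n",
              sum(x$labels), length(x$labels), x$sweeps,
              paste(as.integer(x$seed_pattern), collapse = ",")))
  invisible(x)
}

#' Write a cascade activation trace as text
#'
#' Debug helper: serialises the `(sweep, node)` labelling events of a
#' traced run as tab-separated text.
#'
#' @param state A `label_state` produced with `trace = TRUE`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trace <- function(state, path) {
  if (is.null(state$trace)) stop("state has no trace; rerun with trace = TRUE")
  write.table(state$trace, path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}
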