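#' Boolean functions as canonically numbered truth tables
#'
#' A Boolean function on `k` inputs is stored as its truth table over the
#' `2^k` input patterns in ascending integer order, where the first seed
#' node is the most significant bit of the pattern.  The canonical id is
#' the table read most-significant row first:
#' `id = sum_x table[x] * 2^(2^k - 1 - x)`.  Under this convention, for
#' `k = 2`: AND = 1, XOR = 6, OR = 7, NAND = 14.
#'
#' @param id Integer in `[0, 2^(2^k))`, or `NULL` if `table` is given.
#' @param k Number of inputs.
#' @param table Logical (or 0/1) vector of length `2^k`; alternative to
#'   `id`.
#' @return An object of class `bool_function` with elements `k`, `id`,
#'   `table` (logical, length `2^k`).
#' @examples
#' bool_function(6, k = 2)$table          # XOR: F T T F
#' bool_function(table = c(0, 0, 0, 1))$id  # AND -> 1
#' @export
bool_function <- function(id = NULL, k = 2L, table = NULL) {
  if (is.null(id) == is.null(table)) {
    stop("give exactly one of 'id' or 'table'")
  }
  if (is.null(id)) {
    table <- as.logical(table)
    k <- as.integer(round(log2(length(table))))
    if (2^k != length(table)) stop("table length must be a power of two")
    id <- function_id(table)
  } else {
    k <- as.integer(k)
    if (id < 0 || id >= 2^(2^k)) stop("id out of range for k = ", k)
    table <- function_table(id, k)
  }
  structure(list(k = k, id = as.integer(id), table = table),
            class = "bool_function")
}

#' @export
print.bool_function <- function(x, ...) {
  cat(sprintf("<bool_function> k = %d, id = %d, table = %s\n", x$k, x$id,
              paste(as.integer(x$table), collapse = "")))
  invisible(x)
}

#' @rdname bool_function
#' @export
function_id <- function(table) {
  table <- as.logical(table)
  m <- length(table)
  as.integer(sum(table * 2^(m - seq_len(m))))
}

#' @rdname bool_function
#' @export
function_table <- function(id, k) {
  m <- 2^k
  as.logical(bitwAnd(bitwShiftR(as.integer(id), m - seq_len(m)), 1L))
}

as_bf <- function(f, k = 2L) {
  if (inherits(f, "bool_function")) f else bool_function(f, k = k)
}

#' Is a Boolean function monotone increasing?
#'
#' `TRUE` iff flipping any input from 0 to 1 never flips the output from
#' 1 to 0 (`x <= y` bitwise implies `table[x] <= table[y]`).  A pure LTM
#' cascade can only assign monotone increasing functions with a 0 on the
#' all-unlabelled pattern.
#'
#' @param f A `bool_function`, or an integer id (with `k`).
#' @param k Input count used when `f` is an id.
#' @return Logical scalar.
#' @export
is_monotone <- function(f, k = 2L) {
  f <- as_bf(f, k)
  tab <- f$table
  for (x in 0:(2^f$k - 1)) {
    for (i in 0:(f$k - 1)) {
      if (bitwAnd(x, bitwShiftL(1L, i)) == 0L) {
        y <- bitwOr(x, bitwShiftL(1L, i))
        if (tab[x + 1] > tab[y + 1]) return(FALSE)
      }
    }
  }
  TRUE
}

#' Decision-tree complexity via Hamming-cube axis symmetries
#'
#' Computes `C = D - R`, where `D = k` is the input dimension and `R`
#' counts the axes along which the function's Hamming-cube representation
#' is constant, i.e. inputs the output does not depend on.  `C` is the
#' number of relevant inputs; for a monotone function it equals the number
#' of seed-to-node paths the minimal realising sub-network needs.
#'
#' @inheritParams is_monotone
#' @return Integer in `[0, k]`; 0 iff the function is constant.
#' @examples
#' complexity(bool_function(6, 2))  # XOR depends on both inputs -> 2
#' complexity(bool_function(5, 2))  # projection onto second input -> 1
#' @export
complexity <- function(f, k = 2L) {
  f <- as_bf(f, k)
  tab <- f$table
  r <- 0L
  for (i in 0:(f$k - 1)) {
    x <- 0:(2^f$k - 1)
    flipped <- bitwXor(x, bitwShiftL(1L, i))
    if (all(tab[x + 1] == tab[flipped + 1])) r <- r + 1L
  }
  f$k - r
}

#' Enumerate all monotone increasing Boolean functions
#'
#' Exhaustive scan over all `2^(2^k)` truth tables, feasible for
#' `k <= 4` (65536 candidates; the monotone counts 3, 6, 20, 168 for
#' `k = 1..4` are the first Dedekind numbers plus constants).
#'
#' @param k Input count, at most 4.
#' @return List of `bool_function` objects in ascending id order.
#' @export
enumerate_monotone <- function(k) {
  if (k > 4) stop("exhaustive enumeration supported only for k <= 4")
  m <- 2^k
  ids <- 0:(2^m - 1)
  tabs <- outer(ids, m - seq_len(m), function(i, s) bitwAnd(bitwShiftR(i, s), 1L))
  ok <- rep(TRUE, length(ids))
  for (x in 0:(m - 1)) {
    for (i in 0:(k - 1)) {
      if (bitwAnd(x, bitwShiftL(1L, i)) == 0L) {
        y <- bitwOr(x, bitwShiftL(1L, i))
        ok <- ok & (tabs[, x + 1] <= tabs[, y + 1])
      }
    }
  }
  lapply(ids[ok], bool_function, k = k)
}

#' Function ids a pure LTM cascade can assign
#'
#' The monotone increasing functions whose table is 0 on the all-zero
#' pattern: with no labelled seed nothing ever fires in a pure LTM, so
#' the constant-1 function is excluded.  For `k = 2` this is
#' `{0, 1, 3, 5, 7}`.
#'
#' @param k Input count, at most 4.
#' @return Integer vector of ids.
#' @export
ltm_computable_ids <- function(k) {
  ids <- vapply(enumerate_monotone(k), `[[`, integer(1), "id")
  tab0 <- vapply(ids, function(i) function_table(i, k)[1], logical(1))
  ids[!tab0]
}

#' Complexity-based prediction of a function's frequency
#'
#' In a locally tree-like random graph above the percolation threshold, a
#' node computing function `f` needs `C(f)` seed-to-node paths, hence
#' `C(f) + 1` specific nodes jointly inside the giant component; the
#' occurrence probability therefore scales as `v^(C(f)+1)` with `v` the
#' giant-component fraction at mean degree `z`.  Returned unnormalised.
#'
#' @inheritParams is_monotone
#' @param z Mean degree.
#' @return `v^(C(f)+1)`, which is 0 for `z <= 1`.
#' @export
predicted_probability <- function(f, z, k = 2L) {
  f <- as_bf(f, k)
  v <- gcc_fraction_theoretical(z)
  v^(complexity(f) + 1)
}

#' Identify the Boolean function computed at every node
#'
#' Freezes the network (edges, thresholds, antagonist flags) and runs one
#' cascade per input pattern: for each of the `2^k` patterns all non-seed
#' nodes are reset to unlabelled, the seeds are clamped to the pattern,
#' and the cascade runs to its fixed point.  A node's function table is
#' its final label across patterns, reported as the canonical integer id.
#' Each pattern uses an independent update-schedule stream, so with
#' antagonists present the assignment is one reproducible sample of the
#' order-dependent dynamics.
#'
#' @param net A `threshold_network`.
#' @param order_seed Integer seed for the schedule streams; defaults to
#'   the stream derived from the network's master seed.
#' @return Integer vector of length `net$n` with the function id per
#'   node; seed nodes are `NA`.
#' @examples
#' net <- generate_network(200, z = 4, k = 2, rng_seed = 3)
#' table(extract_functions(net))
#' @export
extract_functions <- function(net, order_seed = NULL) {
  if (is.null(order_seed)) order_seed <- net$order_seed
  extract_functions_cpp(net$n, net$edges - 1L, net$thresholds,
                        net$antagonist, net$seeds - 1L, net$k,
                        as.double(order_seed))
}

#' Complexity-prediction table for a set of functions
#'
#' One row per function id: decision-tree complexity `C`, the predicted
#' exponent `C + 1`, the unnormalised predicted probability `v^(C+1)` at
#' mean degree `z` together with its logarithm (computed stably even when
#' `v` is within machine precision of 1), and the minimal-motif exponent
#' where a catalogued `k = 2` motif exists.
#'
#' @param ids Integer function ids.
#' @param k Input count.
#' @param z Mean degree.
#' @return Data frame with columns `fn_id`, `complexity`, `exponent`,
#'   `predicted`, `log_predicted`, `motif_exponent`.
#' @export
prediction_table <- function(ids, k = 2L, z = 4) {
  cc <- vapply(ids, function(i) complexity(i, k), integer(1))
  v <- gcc_fraction_theoretical(z)
  logv <- if (v == 0) -Inf else log1p(-exp(-z * v))
  me <- if (k == 2L) {
    vapply(ids, function(i) {
      e <- motif_gcc_nodes(i)
      if (is.na(e)) NA_real_ else e
    }, numeric(1))
  } else rep(NA_real_, length(ids))
  data.frame(fn_id = as.integer(ids), complexity = cc,
             exponent = cc + 1L,
             predicted = exp((cc + 1) * logv),
             log_predicted = (cc + 1) * logv,
             motif_exponent = me)
}
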