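#' Ensemble census of the Boolean functions computed by cascades
#'
#' Generates `realizations` independent threshold networks (each from its
#' own seed derived deterministically from `master_seed`), identifies the
#' function computed at every non-seed node with [extract_functions()],
#' and tallies node counts per function id.  Within each realization the
#' counts sum to `n - k`: every non-seed node computes exactly one
#' function.
#'
#' Per-realization seeds are derived up front, so results are
#' bit-identical regardless of execution order.
#'
#' @param n Nodes per network.
#' @param k Number of seed (input) nodes.
#' @param z Target mean degree.
#' @param theta Antagonist fraction.
#' @param realizations Number of independent networks.
#' @param master_seed Integer master seed for the whole ensemble.
#' @return An object of class `function_census`: list with `config` (the
#'   call parameters) and `counts`, a data frame with columns
#'   `realization`, `fn_id`, `count` (ids absent from a realization have
#'   no row; they count as zero).
#' @examples
#' cen <- function_census(n = 200, z = 4, realizations = 5, master_seed = 1)
#' rank_ordering(cen)
#' @export
function_census <- function(n, k = 2L, z = 4, theta = 0, realizations = 10L,
                            master_seed = 1L) {
  if (realizations < 1) stop("need at least one realization")
  seeds <- derive_seeds(master_seed, paste0("r", seq_len(realizations)))
  rows <- vector("list", realizations)
  for (r in seq_len(realizations)) {
    net <- generate_network(n, z, k, theta, rng_seed = seeds[r])
    ids <- extract_functions(net)
    tab <- table(ids[!is.na(ids)])
    rows[[r]] <- data.frame(realization = r,
                            fn_id = as.integer(names(tab)),
                            count = as.integer(tab))
  }
  structure(list(
    config = list(n = as.integer(n), k = as.integer(k), z = z,
                  theta = theta, realizations = as.integer(realizations),
                  master_seed = as.integer(master_seed)),
    counts = do.call(rbind, rows)), class = "function_census")
}

#' @export
print.function_census <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<function_census> n = %d, k = %d, z = %s, theta = %.3f, %d realization(s)\n",
    cfg$n, cfg$k, format(cfg$z), cfg$theta, cfg$realizations))
  cat(sprintf("  %d distinct function id(s) observed\n",
              length(unique(x$counts$fn_id))))
  invisible(x)
}

# Default analysis exclusions: the zero function can occur off the giant
# component in any model; the constant-1 function likewise once
# antagonists are present.
default_exclusions <- function(census) {
  k <- census$config$k
  if (census$config$theta > 0) c(0L, 2L^(2L^k) - 1L) else 0L
}

#' Rank-ordered mean function frequencies
#'
#' Mean and standard deviation (across realizations, counting absences as
#' zero) of the per-realization node count of each function id, sorted by
#' descending mean; ties break toward the smaller id.  The zero function
#' is always excluded; the constant-1 function is additionally excluded
#' when the census contains antagonists, since both can occur outside the
#' giant component.
#'
#' @param census A `function_census`.
#' @param exclude Integer ids to drop (default as described above).
#' @return Data frame with columns `rank`, `fn_id`, `mean_freq`,
#'   `sd_freq`.
#' @export
rank_ordering <- function(census, exclude = default_exclusions(census)) {
  cts <- census$counts
  cts <- cts[!(cts$fn_id %in% exclude), , drop = FALSE]
  R <- census$config$realizations
  if (nrow(cts) == 0) {
    return(data.frame(rank = integer(0), fn_id = integer(0),
                      mean_freq = numeric(0), sd_freq = numeric(0)))
  }
  ids <- sort(unique(cts$fn_id))
  mean_freq <- vapply(ids, function(i) {
    sum(cts$count[cts$fn_id == i]) / R
  }, numeric(1))
  sd_freq <- vapply(ids, function(i) {
    x <- cts$count[cts$fn_id == i]
    x <- c(x, rep(0L, R - length(x)))
    if (R > 1) sd(x) else 0
  }, numeric(1))
  ord <- order(-mean_freq, ids)
  data.frame(rank = seq_along(ids), fn_id = ids[ord],
             mean_freq = mean_freq[ord], sd_freq = sd_freq[ord])
}

#' Correlation between observed frequencies and complexity predictions
#'
#' Pearson correlation between the mean observed frequency of each
#' (included) function and its complexity-based predicted probability
#' `v^(C(f)+1)` at the census mean degree.  Pearson correlation is
#' invariant under positive affine maps, so the raw unnormalised
#' predictions are used.  At large mean degree `v` is within machine
#' precision of 1 and the predictions collapse numerically; the
#' correlation is then evaluated against the first-order expansion
#' `(C+1) log v`, which agrees with the exact value to within the same
#' precision.
#'
#' @param census A `function_census`.
#' @param exclude Integer ids to drop before correlating.
#' @param align `"id"` pairs each function's frequency with its own
#'   prediction.  `"rank"` correlates the rank-ordering curve with the
#'   descending-sorted prediction curve — the two overlaid traces of a
#'   rank-ordering plot — measuring how well the predicted frequency
#'   profile matches the observed decay irrespective of which function
#'   occupies which rank.
#' @return List with `r` (Pearson correlation, or `NA` when either
#'   vector is constant), `n_functions`, `align`, and `table`
#'   (per-function frequencies and predictions).
#' @export
prediction_correlation <- function(census,
                                   exclude = default_exclusions(census),
                                   align = c("id", "rank")) {
  align <- match.arg(align)
  ranked <- rank_ordering(census, exclude = exclude)
  if (nrow(ranked) < 3) {
    stop("need at least 3 functions after exclusion, have ", nrow(ranked))
  }
  pred <- prediction_table(ranked$fn_id, k = census$config$k,
                           z = census$config$z)
  tab <- cbind(ranked, pred[, c("complexity", "exponent", "predicted",
                                "log_predicted")])
  freq <- tab$mean_freq
  p_raw <- tab$predicted
  p_log <- tab$log_predicted
  if (align == "rank") {
    freq <- sort(freq, decreasing = TRUE)
    p_raw <- sort(p_raw, decreasing = TRUE)
    p_log <- sort(p_log, decreasing = TRUE)
  }
  r <- if (sd(freq) == 0 || sd(p_log) == 0) {
    warning("correlation undefined: constant vector")
    NA_real_
  } else if (sd(p_raw) / mean(p_raw) > 1e-9) {
    cor(freq, p_raw)
  } else {
    # v so close to 1 that v^(C+1) is constant in doubles; use the exact
    # first-order equivalent (same Pearson r up to O((log v)^2)).
    cor(freq, p_log)
  }
  list(r = r, n_functions = nrow(tab), align = align, table = tab)
}

#' Exponential fit to the rank-ordering curve
#'
#' Ordinary least squares of `log(mean frequency)` against rank index;
#' an exponentially decaying rank-ordering appears as a straight line.
#' Entries with zero mean frequency are dropped before taking logs.
#'
#' @param ranked Output of [rank_ordering()].
#' @return List with `decay_rate` (positive for decreasing frequency),
#'   `r_squared`, `n_used`, and the fitted `lm` object.
#' @export
exponential_rank_fit <- function(ranked) {
  keep <- ranked$mean_freq > 0
  d <- ranked[keep, , drop = FALSE]
  d$rank <- seq_len(nrow(d))
  if (nrow(d) < 3) stop("need at least 3 positive-frequency entries")
  fit <- lm(log(mean_freq) ~ rank, data = d)
  list(decay_rate = -unname(coef(fit)[2]),
       r_squared = summary(fit)$r.squared,
       n_used = nrow(d), fit = fit)
}

#' Mean unique-function count over a connectivity / antagonism grid
#'
#' For every `(z, theta)` cell, generates an ensemble and records the
#' mean (over realizations) number of distinct function ids appearing in
#' a realization.  The zero function is always excluded; the constant-1
#' function is additionally excluded in cells with antagonists
#' (`theta > 0`), since both arise outside the giant component.
#'
#' @param z_list Mean degrees.
#' @param theta_list Antagonist fractions.
#' @param n Nodes per network.
#' @param k Seed count.
#' @param realizations Realizations per cell.
#' @param master_seed Master seed; each cell derives its own stream.
#' @return Data frame with columns `z`, `theta`, `mean_unique`,
#'   `sd_unique`.
#' @export
unique_function_surface <- function(z_list, theta_list, n = 10000L, k = 2L,
                                    realizations = 50L, master_seed = 1L) {
  grid <- expand.grid(z = z_list, theta = theta_list,
                      KEEP.OUT.ATTRS = FALSE)
  cell_seeds <- derive_seeds(master_seed, paste0("cell", seq_len(nrow(grid))))
  res <- lapply(seq_len(nrow(grid)), function(i) {
    cen <- function_census(n = n, k = k, z = grid$z[i],
                           theta = grid$theta[i],
                           realizations = realizations,
                           master_seed = cell_seeds[i])
    excl <- default_exclusions(cen)
    uniq <- vapply(seq_len(realizations), function(r) {
      ids <- cen$counts$fn_id[cen$counts$realization == r]
      length(setdiff(ids, excl))
    }, numeric(1))
    data.frame(z = grid$z[i], theta = grid$theta[i],
               mean_unique = mean(uniq),
               sd_unique = if (realizations > 1) sd(uniq) else 0)
  })
  do.call(rbind, res)
}

#' Antagonist fraction maximising functional diversity
#'
#' Averages the unique-function surface over a range of mean degrees and
#' returns the grid value of `theta` with the highest mean unique-function
#' count; ties break toward smaller `theta`.
#'
#' @param surface Output of [unique_function_surface()].
#' @param z_range Length-2 numeric, inclusive range of `z` to average
#'   over (default: all).
#' @return The maximising `theta` (scalar).
#' @export
argmax_theta <- function(surface, z_range = range(surface$z)) {
  s <- surface[surface$z >= z_range[1] & surface$z <= z_range[2], ,
               drop = FALSE]
  if (nrow(s) == 0) stop("surface has no cells in the given z range")
  thetas <- sort(unique(s$theta))
  means <- vapply(thetas, function(th) mean(s$mean_unique[s$theta == th]),
                  numeric(1))
  thetas[which.max(means)]
}
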