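#' Capacitance estimate from a uniform-release run
#'
#' For trajectories released uniformly on a sphere or hemisphere of radius
#' `release_radius` enclosing the absorbing geometry, the capture probability
#' is `C / release_radius`, so `C_hat = release_radius * (captured / M)`.
#' The relative error scale is the binomial coefficient of variation.
#'
#' @param records a `capture_records` data frame.
#' @param release_radius radius of the release surface.
#' @return list with `C_hat`, `p_hat`, `CV` and `M`.
#' @export
capacitance_estimate <- function(records, release_radius) {
  M <- nrow(records)
  n_cap <- sum(records$outcome == "captured")
  if (n_cap == 0) stop("no captures: cannot estimate the capacitance")
  p_hat <- n_cap / M
  list(C_hat = release_radius * p_hat, p_hat = p_hat,
       CV = coefficient_of_variation(p_hat, M), M = M)
}

#' Bootstrap spread of a record statistic
#'
#' Resamples the capture records with replacement `B` times and recomputes
#' `statistic` on each replicate; the spread is the standard deviation across
#' replicates.  Replicates use seeded substreams so the result is
#' reproducible.
#'
#' @param records a `capture_records` data frame.
#' @param statistic function of a records data frame returning a scalar.
#' @param B number of replications (default 100).
#' @param seed RNG seed for the resampling.
#' @return list with `estimate` (statistic on the full data), `spread`
#'   (standard deviation across replicates) and `replicates`.
#' @export
bootstrap_error <- function(records, statistic, B = 100, seed = 1) {
  stopifnot(B >= 2)
  est <- statistic(records)
  M <- nrow(records)
  reps <- numeric(B)
  for (b in seq_len(B)) {
    set.seed(seed + b)
    idx <- sample.int(M, M, replace = TRUE)
    reps[b] <- statistic(records[idx, , drop = FALSE])
  }
  list(estimate = est, spread = stats::sd(reps), replicates = reps)
}

#' Log-binned arrival-time histogram
#'
#' Bins capture times into edges equally spaced in `log10(t)` spanning the
#' observed range, with per-group counts and, when a theory CDF is supplied,
#' the expected count per bin computed from CDF differences
#' (`M * [F(hi) - F(lo)]`), matching the way the asymptotic overlay is drawn
#' on logarithmic arrival histograms.
#'
#' @param records a `capture_records` data frame.
#' @param n_bins number of bins (default 60).
#' @param groups optional named list mapping group labels to absorber-id
#'   vectors; default is one group per observed absorber id.
#' @param cdf optional vectorized function `F(t)` giving the cumulative
#'   capture fraction used for expected counts.
#' @return object of class `binned_arrivals`: list with `edges`, `counts`
#'   (bins x groups matrix) and optionally `expected`.
#' @export
log_histogram <- function(records, n_bins = 60, groups = NULL, cdf = NULL) {
  cap <- records[records$outcome == "captured", , drop = FALSE]
  if (nrow(cap) == 0) stop("no captured records to bin")
  lt <- log10(cap$time)
  rng <- range(lt)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  edges <- 10^seq(rng[1], rng[2], length.out = n_bins + 1)
  edges[1] <- edges[1] * (1 - 1e-12)
  edges[n_bins + 1] <- edges[n_bins + 1] * (1 + 1e-12)
  if (is.null(groups)) {
    ids <- sort(unique(cap$absorber_id))
    groups <- setNames(as.list(ids), as.character(ids))
  }
  counts <- sapply(groups, function(ids) {
    tv <- cap$time[cap$absorber_id %in% ids]
    if (length(tv) == 0) return(integer(n_bins))
    tabulate(findInterval(tv, edges, rightmost.closed = TRUE), nbins = n_bins)
  })
  counts <- matrix(counts, nrow = n_bins,
                   dimnames = list(NULL, names(groups)))
  out <- list(edges = edges, counts = counts, n_captured = nrow(cap))
  if (!is.null(cdf)) {
    out$expected <- nrow(records) * diff(cdf(edges))
  }
  structure(out, class = "binned_arrivals")
}

#' Empirical cumulative capture fraction
#'
#' The right-continuous step function `m_k(t)/M`: the fraction of all
#' released particles captured by group k by time t.  Its terminal value
#' converges to the splitting probability of the group.
#'
#' @param records a `capture_records` data frame.
#' @param group absorber ids forming the group; `NULL` means all captures.
#' @return function of `t` (vectorized); attribute `terminal` holds the final
#'   fraction.
#' @export
empirical_cdf <- function(records, group = NULL) {
  M <- nrow(records)
  cap <- records[records$outcome == "captured", , drop = FALSE]
  if (!is.null(group)) cap <- cap[cap$absorber_id %in% group, , drop = FALSE]
  tt <- sort(cap$time)
  f <- function(t) findInterval(t, tt) / M
  attr(f, "terminal") <- length(tt) / M
  f
}

#' Normalized differential flux between two receptor groups
#'
#' The ratiometric directional signal
#' \eqn{\Xi(t) = (J_{top} - J_{bottom}) / (J_{top} + J_{bottom})} evaluated
#' bin-wise from capture counts on common time-bin edges; bins with no
#' arrivals in either group are returned as `NA` (undefined, not zero).
#'
#' @param records_top,records_bottom `capture_records` restricted to each
#'   receptor (or full record sets with `top_ids` / `bottom_ids`).
#' @param edges increasing vector of bin edges.
#' @return list with `edges`, `mid`, `xi` (per-bin values in `[-1, 1]` or
#'   NA), and the per-bin counts `n_top`, `n_bottom`.
#' @export
differential_flux_ratio <- function(records_top, records_bottom, edges) {
  count_bins <- function(rec) {
    tv <- rec$time[rec$outcome == "captured"]
    tabulate(findInterval(tv, edges, rightmost.closed = TRUE),
             nbins = length(edges) - 1)
  }
  nt <- count_bins(records_top)
  nb <- count_bins(records_bottom)
  tot <- nt + nb
  xi <- ifelse(tot > 0, (nt - nb) / tot, NA_real_)
  list(edges = edges, mid = sqrt(edges[-1] * edges[-length(edges)]),
       xi = xi, n_top = nt, n_bottom = nb)
}
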