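#' Per-neuron firing rates
#'
#' @param spikes spike tibble with a `neuron` column (e.g. from an
#'   `izh_sim` or [read_spikes()]).
#' @param ids logical neuron ids of the population (silent neurons are
#'   included with rate 0).
#' @param T_s observation time (s).
#' @return tibble `neuron, n_spikes, rate` (spks/s).
#' @export
firing_rates <- function(spikes, ids, T_s) {
  stopifnot(T_s > 0)
  counts <- tabulate(match(spikes$neuron, ids), nbins = length(ids))
  tibble::tibble(neuron = as.integer(ids), n_spikes = counts,
                 rate = counts / T_s)
}

#' Coefficient of variation of inter-spike intervals
#'
#' CV = sd(ISI) / mean(ISI) per neuron; neurons with fewer than `min_spikes`
#' spikes (fewer than two intervals) are excluded and their count reported
#' on the `"n_excluded"` attribute.
#'
#' @param spikes spike tibble with `neuron` and `t_ms` columns.
#' @param ids neuron ids to evaluate.
#' @param min_spikes minimum spike count for inclusion.
#' @return tibble `neuron, n_spikes, cv` for included neurons.
#' @export
cv_isi <- function(spikes, ids, min_spikes = 3L) {
  sp <- spikes[spikes$neuron %in% ids, ]
  by_neuron <- split(sp$t_ms, sp$neuron)
  res <- purrr::map_dfr(by_neuron, function(t) {
    if (length(t) < min_spikes) {
      return(tibble::tibble(n_spikes = length(t), cv = NA_real_))
    }
    isi <- diff(sort(t))
    tibble::tibble(n_spikes = length(t), cv = stats::sd(isi) / mean(isi))
  }, .id = "neuron")
  res$neuron <- as.integer(res$neuron)
  n_candidates <- length(ids)
  out <- res[!is.na(res$cv), ]
  attr(out, "n_excluded") <- n_candidates - nrow(out)
  out
}

#' Pairwise Pearson correlation of binned spike trains
#'
#' Spike trains are binned (2 ms by default) over `[0, T_s)`; the Pearson
#' coefficient is computed for sampled within-population pairs. Trains with
#' zero variance across bins are excluded. All pairs are used when their
#' number does not exceed `max_pairs`, otherwise `max_pairs` distinct pairs
#' are drawn at random.
#'
#' @param spikes spike tibble with `neuron` and `t_ms` columns.
#' @param ids population neuron ids.
#' @param T_s observation time (s).
#' @param bin_s bin width (s).
#' @param max_pairs pair-sampling cap.
#' @param seed RNG seed for pair sampling.
#' @return tibble `i, j, cc`; excluded-train count on attribute
#'   `"n_excluded"`.
#' @export
pearson_cc <- function(spikes, ids, T_s, bin_s = 0.002, max_pairs = 20000L,
                       seed = 1L) {
  n_bins <- as.integer(round(T_s / bin_s))
  stopifnot(n_bins >= 1)
  sp <- spikes[spikes$neuron %in% ids, ]
  bin <- pmin(floor((sp$t_ms / 1000) / bin_s), n_bins - 1L) + 1L
  row <- match(sp$neuron, ids)
  counts <- matrix(tabulate((bin - 1L) * length(ids) + row,
                            nbins = length(ids) * n_bins),
                   nrow = length(ids))
  v <- apply(counts, 1, stats::var)
  keep <- which(v > 0)
  n_excluded <- length(ids) - length(keep)
  if (length(keep) < 2) {
    out <- tibble::tibble(i = integer(), j = integer(), cc = numeric())
    attr(out, "n_excluded") <- n_excluded
    return(out)
  }
  z <- counts[keep, , drop = FALSE]
  z <- (z - rowMeans(z)) / apply(z, 1, stats::sd)
  n_all <- choose(length(keep), 2)
  if (n_all <= max_pairs) {
    pr <- utils::combn(seq_along(keep), 2)
    ii <- pr[1, ]; jj <- pr[2, ]
  } else {
    set.seed(seed)
    # draw distinct unordered pairs by linear index
    lin <- sample.int(n_all, max_pairs)
    jj <- ceiling((1 + sqrt(1 + 8 * lin)) / 2)
    ii <- lin - (jj - 1) * (jj - 2) / 2
    ii <- as.integer(ii); jj <- as.integer(jj)
  }
  cc <- rowSums(z[ii, , drop = FALSE] * z[jj, , drop = FALSE]) / (n_bins - 1)
  out <- tibble::tibble(i = as.integer(ids[keep[ii]]),
                        j = as.integer(ids[keep[jj]]), cc = cc)
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Histogram and smoothed density of a measure sample
#'
#' Bin width follows the Freedman-Diaconis rule,
#' `2 * IQR(x) * n^(-1/3)`; the smoothed density is a Gaussian-kernel
#' estimate (bandwidth rule configurable, Silverman's `"nrd0"` by default)
#' renormalized to integrate to exactly one. Degenerate all-equal samples
#' are reported as a point mass without a density estimate.
#'
#' @param samples numeric vector (at least 2 values for a distribution).
#' @param bw kernel bandwidth rule or value, passed to [stats::density()].
#' @return a `measure_distribution` list: `bin_width`, `histogram` (tibble
#'   `left, right, mid, count, density`), `density` (tibble `x, y`), or a
#'   point mass (`type = "point_mass"`, `value`).
#' @export
measure_distribution <- function(samples, bw = "nrd0") {
  stopifnot(length(samples) >= 2)
  if (length(unique(samples)) == 1) {
    return(structure(list(type = "point_mass", value = samples[1],
                          n = length(samples)),
                     class = "measure_distribution"))
  }
  n <- length(samples)
  width <- 2 * stats::IQR(samples) * n^(-1 / 3)
  if (width <= 0) { # IQR can vanish with heavy ties; fall back to the range
    width <- diff(range(samples)) / ceiling(sqrt(n))
  }
  lo <- min(samples); hi <- max(samples)
  breaks <- seq(lo, hi + width, by = width)
  h <- graphics::hist(samples, breaks = breaks, plot = FALSE,
                      right = FALSE, include.lowest = TRUE)
  d <- stats::density(samples, bw = bw, kernel = "gaussian")
  area <- sum(diff(d$x) * (head(d$y, -1) + tail(d$y, -1)) / 2)
  structure(
    list(type = "distribution", n = n, bin_width = width,
         histogram = tibble::tibble(left = head(h$breaks, -1),
                                    right = tail(h$breaks, -1),
                                    mid = h$mids, count = h$counts,
                                    density = h$density),
         density = tibble::tibble(x = d$x, y = d$y / area)),
    class = "measure_distribution")
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Computed on the raw measure samples (never on smoothed densities):
#' `D = sup |ECDF_a - ECDF_b|` with the asymptotic p-value.
#'
#' @param samples_a,samples_b numeric vectors.
#' @return list with `D` and `p_value`.
#' @examples
#' ks_compare(runif(100), runif(100))
#' @export
ks_compare <- function(samples_a, samples_b) {
  if (length(samples_a) == 0 || length(samples_b) == 0)
    stop("ks_compare: both samples must be non-empty")
  kt <- suppressWarnings(stats::ks.test(samples_a, samples_b,
                                        exact = FALSE))
  list(D = unname(kt$statistic), p_value = unname(kt$p.value))
}

#' Statistical-equivalence comparison of two runs
#'
#' The full validation pipeline: per-population firing rates, CVs of
#' inter-spike intervals and pairwise Pearson correlations for two spike
#' data sets of the same network, each pair of raw measure samples compared
#' with a two-sample Kolmogorov-Smirnov statistic.
#'
#' @param spikes_a,spikes_b spike tibbles (`neuron`, `t_ms`).
#' @param exc_ids,inh_ids population memberships.
#' @param T_s observation time (s).
#' @param bin_s CC bin width (s).
#' @param max_pairs CC pair-sampling cap per population.
#' @return tibble `measure, population, n_a, n_b, D, p_value`.
#' @export
compare_runs <- function(spikes_a, spikes_b, exc_ids, inh_ids, T_s,
                         bin_s = 0.002, max_pairs = 20000L) {
  pops <- list(EXC = exc_ids, INH = inh_ids)
  purrr::map_dfr(names(pops), function(pop) {
    ids <- pops[[pop]]
    fr_a <- firing_rates(spikes_a, ids, T_s)$rate
    fr_b <- firing_rates(spikes_b, ids, T_s)$rate
    cv_a <- cv_isi(spikes_a, ids)$cv
    cv_b <- cv_isi(spikes_b, ids)$cv
    cc_a <- pearson_cc(spikes_a, ids, T_s, bin_s, max_pairs)$cc
    cc_b <- pearson_cc(spikes_b, ids, T_s, bin_s, max_pairs)$cc
    one <- function(measure, a, b) {
      if (length(a) == 0 || length(b) == 0) {
        return(tibble::tibble(measure = measure, population = pop,
                              n_a = length(a), n_b = length(b),
                              D = NA_real_, p_value = NA_real_))
      }
      ks <- ks_compare(a, b)
      tibble::tibble(measure = measure, population = pop,
                     n_a = length(a), n_b = length(b),
                     D = ks$D, p_value = ks$p_value)
    }
    dplyr::bind_rows(one("FR", fr_a, fr_b), one("CV", cv_a, cv_b),
                     one("CC", cc_a, cc_b))
  })
}
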