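#' Contingency table of network states against propagation types
#'
#' @param states label vector (network states), one per event.
#' @param types label vector (propagation types), same length.
#' @return integer matrix of counts, states in rows, types in columns.
#' @export
contingency <- function(states, types) {
  if (length(states) != length(types)) stop("label vectors differ in length")
  tab <- table(state = states, type = types)
  matrix(as.integer(tab), nrow(tab), ncol(tab),
         dimnames = dimnames(tab))
}

#' Pearson chi-squared test of independence
#'
#' Expected counts from the marginal products; df = (r-1)(c-1) after
#' dropping any all-zero row or column (with a warning). A 3-state by
#' 3-type table therefore has df = 4. Expected counts under 5 trigger a
#' warning, not an error; no continuity correction (that applies to 2x2
#' tables only).
#'
#' @param tab a contingency matrix from [contingency()].
#' @return list: `chi2`, `df`, `p_value`, `expected`.
#' @export
chi_squared <- function(tab) {
  tab <- as.matrix(tab)
  zr <- rowSums(tab) == 0; zc <- colSums(tab) == 0
  if (any(zr) || any(zc)) {
    warning("dropping ", sum(zr), " zero row(s) and ", sum(zc),
            " zero column(s) before the chi-squared test")
    tab <- tab[!zr, !zc, drop = FALSE]
  }
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("need at least 2 rows and 2 columns with positive marginals")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  if (any(ht$expected < 5))
    warning("expected count below 5; chi-squared approximation may be poor")
  list(chi2 = unname(ht$statistic), df = as.integer(unname(ht$parameter)),
       p_value = unname(ht$p.value), expected = ht$expected)
}

#' Cramér's V association strength
#'
#' `V = sqrt(chi2 / (n (min(r, c) - 1)))`, ranging 0 (independence) to 1
#' (perfect association), invariant under row/column relabelling.
#'
#' @param chi2 Pearson chi-squared statistic.
#' @param n total number of events.
#' @param r,c numbers of row and column levels.
#' @return scalar V in \[0, 1\].
#' @export
cramers_v <- function(chi2, n, r, c) {
  stopifnot(n > 0, min(r, c) >= 2)
  v <- sqrt(chi2 / (n * (min(r, c) - 1)))
  min(v, 1)
}

#' Repeated clustering-and-association runs
#'
#' k-means classifications are seed-dependent, so the association between
#' network states and propagation types is assessed over many re-clustered
#' runs: per run, k-means (seed `base_seed + run`) on the projected delay
#' features yields type labels, which are tested against the fixed network
#' states (chi-squared, Cramér's V). Each run also draws a chance-level
#' V from the label-permutation null — the network states randomly
#' permuted (seeded), the standard chance model for association at fixed
#' marginals — and the real-vs-null V samples are compared with a
#' two-sample Wilcoxon rank-sum test (alternative: real V greater).
#'
#' A run whose clustering degenerates (empty cluster) is re-seeded; the
#' count is reported.
#'
#' @param projected `[n_events x d]` projected delay features.
#' @param states fixed network-state labels, one per event.
#' @param k number of wave types (default 3).
#' @param runs number of repetitions (default 1000; scale up to mirror
#'   exhaustive analyses).
#' @param base_seed integer; run r uses seed `base_seed + r`.
#' @param n_init k-means restarts per run (default 1: each run is one
#'   seeding, which is the point of repeating).
#' @return An object of class `repeated_association`: `runs`,
#'   `chi2_samples`, `p_samples`, `v_samples`, `null_v_samples`,
#'   `null_p_samples`, `rank_sum_p`, `reseeded`.
#' @export
repeated_association <- function(projected, states, k = 3L, runs = 1000L,
                                 base_seed = 1L, n_init = 1L) {
  stopifnot(runs >= 1L)
  projected <- as.matrix(projected)
  n <- nrow(projected)
  stopifnot(length(states) == n)
  chi2s <- ps <- vs <- nvs <- nps <- numeric(runs)
  reseeded <- 0L
  for (r in seq_len(runs)) {
    seed <- base_seed + r
    cl <- NULL
    while (is.null(cl)) {
      cl <- tryCatch(kmeans_cluster(projected, k, seed = seed,
                                    n_init = n_init),
                     error = function(e) NULL)
      if (is.null(cl)) { seed <- seed + runs + 7L; reseeded <- reseeded + 1L }
    }
    types <- cl$labels
    ht <- suppressWarnings(chi_squared(contingency(states, types)))
    chi2s[r] <- ht$chi2; ps[r] <- ht$p_value
    vs[r] <- cramers_v(ht$chi2, n, length(unique(states)),
                       length(unique(types)))
    perm <- with_seed(substream(base_seed, "misc") + r, sample(states))
    hn <- suppressWarnings(chi_squared(contingency(perm, types)))
    nps[r] <- hn$p_value
    nvs[r] <- cramers_v(hn$chi2, n, length(unique(perm)),
                        length(unique(types)))
  }
  rsp <- if (runs >= 2L)
    suppressWarnings(stats::wilcox.test(vs, nvs,
                                        alternative = "greater")$p.value)
  else NA_real_
  structure(list(runs = runs, chi2_samples = chi2s, p_samples = ps,
                 v_samples = vs, null_v_samples = nvs,
                 null_p_samples = nps, rank_sum_p = rsp,
                 reseeded = reseeded),
            class = "repeated_association")
}

#' @export
print.repeated_association <- function(x, ...) {
  cat(sprintf(
    "repeated_association: %d runs, median V = %.3f (null %.3f), rank-sum p = %.3g\n",
    x$runs, stats::median(x$v_samples), stats::median(x$null_v_samples),
    x$rank_sum_p))
  invisible(x)
}
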