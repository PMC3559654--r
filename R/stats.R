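#' Summary statistics for a sample
#'
#' Sample mean, sample standard deviation (n-1 denominator, matching the
#' convention of the published tables), and quartiles by linear
#' interpolation.
#'
#' @param values numeric vector, length >= 1.
#' @return an object of class `summary_stats`: list with `n`, `mean`, `sd`
#'   (`NA` for n = 1), `median`, `q1`, `q3`.
#' @export
summarize_values <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0 || all(is.na(values)))
    stop("empty sample", call. = FALSE)
  values <- values[!is.na(values)]
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  structure(list(n = length(values), mean = mean(values),
                 sd = if (length(values) >= 2) sd(values) else NA_real_,
                 median = q[2], q1 = q[1], q3 = q[3]),
            class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("n = %d, mean +/- SD = %.4g +/- %.4g, IQR [%.4g, %.4g], median %.4g\n",
              x$n, x$mean, x$sd, x$q1, x$q3, x$median))
  invisible(x)
}

#' One value per affected participant
#'
#' Collapses per-leg values to one value per clubfoot participant for group
#' comparisons: bilateral participants contribute the mean of their two
#' (both affected) legs, unilateral participants contribute their affected
#' leg's value. Controls are excluded.
#'
#' @param values_df data frame with columns `participant`, `group`
#'   (control / unilateral / bilateral), `side_status` and `value`.
#' @return named numeric vector, one entry per clubfoot participant.
#' @export
per_participant_affected_average <- function(values_df) {
  needed <- c("participant", "group", "side_status", "value")
  stopifnot(all(needed %in% names(values_df)))
  ctev <- values_df[values_df$group %in% c("unilateral", "bilateral"), ]
  out <- numeric(0)
  for (id in unique(ctev$participant)) {
    rows <- ctev[ctev$participant == id, ]
    if (rows$group[1] == "unilateral") {
      aff <- rows$value[rows$side_status == "affected"]
      if (length(aff) != 1L)
        stop("incomplete record: participant ", id,
             " lacks exactly one affected-leg value", call. = FALSE)
      out[id] <- aff
    } else {
      if (nrow(rows) != 2L)
        stop("incomplete record: bilateral participant ", id,
             " needs both legs", call. = FALSE)
      out[id] <- mean(rows$value)
    }
  }
  out
}

# Max absolute distance between the two empirical CDFs, evaluated at every
# distinct pooled value (handles ties). Returns D plus the integer
# numerator max|i*m - j*n| used by the exact engine.
ks_statistic <- function(x, y) {
  n <- length(x); m <- length(y)
  u <- sort(unique(c(x, y)))
  i <- vapply(u, function(v) sum(x <= v), numeric(1))
  j <- vapply(u, function(v) sum(y <= v), numeric(1))
  dnum <- max(abs(i * m - j * n))
  list(D = dnum / (n * m), dnum = dnum)
}

# Exact two-sided p-value P(D* >= D) under the permutation null, by
# dynamic-programming lattice-path counting over all C(n+m, n) label
# assignments. Ties are handled by counting at tie-group boundaries only,
# weighting each path segment by the number of within-group label
# arrangements (binomial coefficients), which equals averaging over all
# tie-breaking orders.
ks_exact_pvalue <- function(x, y) {
  n <- length(x); m <- length(y)
  ks <- ks_statistic(x, y)
  if (ks$dnum == 0) return(list(D = 0, p = 1))
  pooled <- c(x, y)
  g <- as.integer(table(pooled))     # tie-group sizes in sorted value order
  total <- choose(n + m, n)
  # weights[a+1] = weighted count of label assignments with `a` x-labels
  # among the pooled values seen so far, all boundary deviations < observed
  weights <- c(1, rep(0, n))
  cum <- 0L
  for (t in seq_along(g)) {
    gt <- g[t]
    new_w <- rep(0, n + 1)
    for (a in which(weights > 0) - 1L) {
      w <- weights[a + 1]
      y_used <- cum - a
      for (k in 0:min(gt, n - a)) {
        if (gt - k > m - y_used) next   # not enough y slots remain
        new_w[a + k + 1] <- new_w[a + k + 1] + w * choose(gt, k)
      }
    }
    cum <- cum + gt
    # prune paths whose boundary deviation reaches the observed one
    # (the final boundary always has zero deviation, so this is safe there)
    a_all <- 0:n
    dev <- abs(a_all * m - (cum - a_all) * n)
    new_w[dev >= ks$dnum - 1e-9] <- 0
    weights <- new_w
  }
  surviving <- weights[n + 1]
  list(D = ks$D, p = max(0, min(1, 1 - surviving / total)))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Computes the maximal distance D between the two empirical cumulative
#' distributions (evaluated at every distinct pooled value, so ties are
#' handled consistently) and a two-sided p-value. The exact method counts
#' lattice paths over all `choose(n+m, n)` label assignments by dynamic
#' programming, averaging over tie-breaking orders; the permutation method
#' approximates the same null with seeded resampling; the asymptotic method
#' uses the Kolmogorov series at effective sample size `nm/(n+m)`.
#'
#' Well suited to the small, unequally dispersed samples typical of paired
#' contralateral imaging studies.
#'
#' @param x,y numeric samples (each n >= 1).
#' @param method `"auto"` (exact when `n + m <= exact_limit`, else
#'   permutation), `"exact"`, `"permutation"` or `"asymptotic"`.
#' @param exact_limit largest pooled size for the exact engine (default 30).
#' @param n_perm permutation count for the permutation method.
#' @param seed seed for the permutation method.
#' @return an object of class `ks_result`: list with `D`, `p_value`,
#'   `method`, `n`, `m`.
#' @examples
#' ks_two_sample(c(1, 2, 3), c(4, 5, 6))  # fully separated: D = 1
#' @export
ks_two_sample <- function(x, y,
                          method = c("auto", "exact", "permutation",
                                     "asymptotic"),
                          exact_limit = 30L, n_perm = 1e5, seed = 1L) {
  method <- match.arg(method)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1 || length(y) < 1)
    stop("empty sample", call. = FALSE)
  n <- length(x); m <- length(y)
  if (method == "auto")
    method <- if (n + m <= exact_limit) "exact" else "permutation"
  if (method == "exact" && n + m > exact_limit)
    stop("exact method limited to n + m <= ", exact_limit,
         "; use permutation", call. = FALSE)

  if (method == "exact") {
    res <- ks_exact_pvalue(x, y)
    D <- res$D; p <- res$p
  } else if (method == "permutation") {
    obs <- ks_statistic(x, y)
    D <- obs$D
    pooled <- c(x, y)
    exceed <- with_stream(seed, "ks_perm", {
      sum(vapply(seq_len(n_perm), function(i) {
        idx <- sample.int(n + m, n)
        ks_statistic(pooled[idx], pooled[-idx])$dnum >= obs$dnum
      }, logical(1)))
    })
    p <- (exceed + 1) / (n_perm + 1)
  } else {
    D <- ks_statistic(x, y)$D
    ne <- n * m / (n + m)
    lambda <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * D
    k <- 1:100
    p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
    p <- max(min(p, 1), .Machine$double.xmin)
  }
  structure(list(D = D, p_value = p, method = method, n = n, m = m),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("Two-sample KS: D = %.4g, p = %.4g (%s, n = %d, m = %d)\n",
              x$D, x$p_value, x$method, x$n, x$m))
  invisible(x)
}

#' Fractional error of the mean across operators
#'
#' Inter-operator reproducibility of a measurement: the cross-operator
#' sample standard deviation as a percentage of the cross-operator mean
#' (a coefficient of variation).
#'
#' @param values one measurement value per trained operator (n >= 2, all
#'   > 0).
#' @return FEM in percent.
#' @examples
#' fem(c(100, 102, 98))  # 2
#' @export
fem <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2)
    stop("insufficient replicates: FEM needs >= 2 operator values",
         call. = FALSE)
  if (any(values <= 0))
    stop("operator values must be > 0", call. = FALSE)
  100 * sd(values) / mean(values)
}
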