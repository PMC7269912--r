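#' Hartigan's dip statistic
#'
#' The dip of a sample is the maximum distance between its empirical CDF and
#' the closest unimodal CDF (convex up to the mode, concave after it, with an
#' atom at the mode allowed).  Computed exactly via greatest-convex-minorant
#' / least-concave-majorant constructions over all mode placements.  The dip
#' lies in [0, 0.25]; it is 0 for a point mass and approaches 0.25 for an
#' even mixture of two distant point masses.
#'
#' @param x Numeric sample.
#' @return The dip statistic.
#' @export
dip_statistic <- function(x) {
  x <- as.numeric(x)
  if (anyNA(x)) stop("NA in sample")
  .dip_cpp(x)
}

#' Brute-force dip reference
#'
#' An independent quadratic-time computation of the dip used to validate
#' \code{\link{dip_statistic}}: convex-minorant and concave-majorant values
#' are obtained by exhaustive chord enumeration rather than incremental hull
#' construction.  Intended for testing at small n.
#'
#' @param x Numeric sample.
#' @return The dip statistic.
#' @export
dip_statistic_bruteforce <- function(x) {
  xs <- sort(as.numeric(x))
  n <- length(xs)
  z <- unique(xs)
  K <- length(z)
  if (K == 1L) return(0)
  cnt <- as.integer(table(match(xs, z)))
  top <- cumsum(cnt) / n
  bot <- c(0, top[-K])
  # H[s, t]: greatest convex minorant of points (z, bot) over prefix 1..t,
  # evaluated at z_s (s <= t), as the min over all chords (i <= s <= j <= t)
  chord_min <- matrix(Inf, K, K)   # [s, j]: min over i <= s of chord_(i,j)(z_s)
  for (j in seq_len(K)) for (i in seq_len(j)) {
    s <- i:j
    v <- if (i == j) bot[i] else
      bot[i] + (bot[j] - bot[i]) * (z[s] - z[i]) / (z[j] - z[i])
    chord_min[s, j] <- pmin(chord_min[s, j], v)
  }
  H <- matrix(Inf, K, K)           # [s, t]
  for (s in seq_len(K)) H[s, s:K] <- cummin(chord_min[s, s:K])
  chord_max <- matrix(-Inf, K, K)  # [s, i]: max over j >= s of chord_(i,j)(z_s)
  for (i in seq_len(K)) for (j in i:K) {
    s <- i:j
    v <- if (i == j) top[i] else
      top[i] + (top[j] - top[i]) * (z[s] - z[i]) / (z[j] - z[i])
    chord_max[s, i] <- pmax(chord_max[s, i], v)
  }
  L <- matrix(-Inf, K, K)          # [s, t]: majorant of suffix t..K at z_s
  for (s in seq_len(K)) L[s, 1:s] <- rev(cummax(rev(chord_max[s, 1:s])))
  A <- vapply(seq_len(K), function(t) max(top[1:t] - H[1:t, t]), numeric(1))
  Ap <- vapply(seq_len(K), function(t)
    if (t == 1L) 0 else max(0, top[1:(t - 1L)] - H[1:(t - 1L), t]),
    numeric(1))
  B <- vapply(seq_len(K), function(t) max(L[t:K, t] - bot[t:K]), numeric(1))
  Bp <- vapply(seq_len(K), function(t)
    if (t == K) 0 else max(0, L[(t + 1L):K, t] - bot[(t + 1L):K]),
    numeric(1))
  best <- min(B[1L], A[K])
  if (K > 1L) for (t in seq_len(K - 1L))
    best <- min(best, max(A[t], B[t + 1L],
                          A[t] + B[t + 1L] - (top[t + 1L] - bot[t])))
  for (t in seq_len(K))
    best <- min(best, max(Ap[t], Bp[t], Ap[t] + Bp[t] - (top[t] - bot[t])))
  best / 2
}

#' Bootstrap null table for the dip test
#'
#' Dip statistics of \code{n_boot} uniform samples of size n; reusable across
#' tests of equal sample size.
#'
#' @param n Sample size.
#' @param n_boot Number of bootstrap samples.
#' @param seed Integer seed.
#' @return Numeric vector of null dip values.
#' @export
dip_null_table <- function(n, n_boot = 1e4, seed = 1L) {
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  vapply(seq_len(n_boot), function(i) .dip_cpp(stats::runif(n)), numeric(1))
}

#' Dip test of unimodality
#'
#' Tests the null of unimodality against multimodality using the dip
#' statistic with a bootstrap null of uniform samples of equal size (the
#' standard calibration for this statistic).
#'
#' @param x Numeric sample (n >= 4).
#' @param n_boot Bootstrap replicates (default 1e4).
#' @param seed Integer seed for the bootstrap.
#' @param null_table Optional precomputed \code{\link{dip_null_table}} for
#'   \code{length(x)}; overrides \code{n_boot}/\code{seed}.
#' @return List of class \code{dip_result}: \code{statistic}, \code{p}
#'   (fraction of null dips >= observed, with the +1 correction), \code{n},
#'   \code{n_boot}.
#' @export
dip_test <- function(x, n_boot = 1e4, seed = 1L, null_table = NULL) {
  x <- as.numeric(x)
  if (length(x) < 4L) stop("dip test needs at least 4 values")
  D <- dip_statistic(x)
  if (is.null(null_table)) null_table <- dip_null_table(length(x), n_boot, seed)
  p <- (sum(null_table >= D) + 1) / (length(null_table) + 1)
  structure(list(statistic = D, p = p, n = length(x),
                 n_boot = length(null_table)),
            class = "dip_result")
}

#' @export
print.dip_result <- function(x, ...) {
  cat(sprintf("dip test: D = %.4f, n = %d, bootstrap p = %.4g (%d reps)\n",
              x$statistic, x$n, x$p, x$n_boot))
  invisible(x)
}
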