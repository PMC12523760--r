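# Exact and approximate Mann-Whitney U test.
#
# For samples of at most `exact_max` per group without ties, the two-sided
# p-value is computed from the exact null distribution of U (all
# choose(n1+n2, n1) equally likely group assignments), via the standard
# counting recursion c(m, n, u) = c(m-1, n, u-n) + c(m, n-1, u). With larger
# samples or ties, a normal approximation with midrank tie correction and
# continuity correction is used. The branch taken is recorded.

# cache of exact U null distributions, keyed by "n1,n2"
.u_null_cache <- new.env(parent = emptyenv())

# exact null counts of U = 0..n1*n2 for group sizes n1, n2 (no ties),
# by the counting recursion N(m, n, u) = N(m-1, n, u-n) + N(m, n-1, u)
u_null_counts <- function(n1, n2) {
  key <- paste(n1, n2, sep = ",")
  hit <- get0(key, envir = .u_null_cache)
  if (!is.null(hit)) return(hit)
  maxu <- n1 * n2
  g <- matrix(0, n2 + 1, maxu + 1)  # g[n+1, u+1] = N(m, n, u), current m
  g[, 1] <- 1                       # m = 0: only u = 0 reachable
  for (m in seq_len(n1)) {
    gn <- matrix(0, n2 + 1, maxu + 1)
    gn[1, 1] <- 1                   # n = 0: only u = 0
    for (n in seq_len(n2)) {
      for (u in 0:maxu) {
        v <- gn[n, u + 1]                       # N(m, n-1, u)
        if (u - n >= 0) v <- v + g[n + 1, u - n + 1]  # N(m-1, n, u-n)
        gn[n + 1, u + 1] <- v
      }
    }
    g <- gn
  }
  out <- g[n2 + 1, ]
  assign(key, out, envir = .u_null_cache)
  out
}

#' Mann-Whitney U test (exact for small untied samples)
#'
#' Computes the U statistic for `x` with midranks for ties. The two-sided
#' p-value is exact (full enumeration of the U null distribution) when both
#' groups have at most `exact_max` observations and there are no ties
#' across the pooled sample; otherwise the normal approximation with tie
#' and continuity corrections is used. The two-sided exact p-value is
#' `P(|U - n1 n2 / 2| >= |u_obs - n1 n2 / 2|)` under the null.
#'
#' @param x,y numeric samples (each non-empty)
#' @param exact_max largest per-group size for the exact branch (default 8)
#' @return list with `U` (statistic for `x`), `p` (two-sided), and
#'   `method` (`"exact"` or `"normal"`)
#' @export
mann_whitney_u <- function(x, y, exact_max = 8) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) abort("both groups must be non-empty")
  pooled <- c(x, y)
  r <- rank(pooled)  # midranks
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(pooled))
  if (length(unique(pooled)) == 1) {
    return(list(U = n1 * n2 / 2, p = 1, method = "degenerate"))
  }
  if (!ties && n1 <= exact_max && n2 <= exact_max) {
    counts <- u_null_counts(n1, n2)
    total <- sum(counts)
    dev <- abs(0:(n1 * n2) - n1 * n2 / 2)
    p <- sum(counts[dev >= abs(U - n1 * n2 / 2) - 1e-9]) / total
    return(list(U = U, p = min(1, p), method = "exact"))
  }
  # normal approximation with tie correction
  N <- n1 + n2
  tie_tab <- table(pooled)
  tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) return(list(U = U, p = 1, method = "normal"))
  z <- (U - n1 * n2 / 2)
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)  # continuity correction
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(U = U, p = p, method = "normal")
}

#' Significance stars for a p-value
#'
#' `**` for p < 0.01, `*` for p < 0.05, empty string otherwise.
#'
#' @param p numeric vector of p-values
#' @return character vector of star markers
#' @export
significance_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}
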