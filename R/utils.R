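# Internal helpers shared across modules.

# stop() with sprintf formatting
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Clamp numeric vector to [lo, hi]
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Coerce an EBImage result back to a plain matrix
as_matrix <- function(x) {
  m <- EBImage::imageData(x)
  dim(m) <- dim(m)[1:2]
  m
}

# Draw from a von Mises distribution (Best & Fisher rejection sampler).
# kappa = 0 degenerates to the uniform circular distribution.
rvonmises <- function(n, mu = 0, kappa = 0) {
  if (kappa < 1e-8) {
    return(runif(n, -pi, pi) + mu)
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u1 <- runif(1); u2 <- runif(1); u3 <- runif(1)
      z <- cos(pi * u1)
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
        out[i] <- sign(u3 - 0.5) * acos(f)
        break
      }
    }
  }
  out + mu
}

# Geodesic length of a pixel path (rows, cols): unit steps count 1,
# diagonal steps sqrt(2).
path_length_px <- function(rows, cols) {
  if (length(rows) < 2) return(0)
  dr <- abs(diff(rows))
  dc <- abs(diff(cols))
  sum(ifelse(dr + dc == 2, sqrt(2), pmax(dr, dc)))
}

# Number of direction changes along a pixel path (for the corner-count
# chain-length correction)
path_corners <- function(rows, cols) {
  if (length(rows) < 3) return(0L)
  code <- diff(rows) * 3 + diff(cols)
  sum(code[-1] != code[-length(code)])
}

# Principal-axis orientation of a point cloud in image coordinates,
# returned in degrees within [0, 180). x = column, y = -row so that angles
# are measured counter-clockwise from the +x axis as drawn on screen.
principal_orientation_deg <- function(rows, cols) {
  if (length(rows) < 2) return(NA_real_)
  x <- cols - mean(cols)
  y <- -(rows - mean(rows))
  cxx <- mean(x * x); cyy <- mean(y * y); cxy <- mean(x * y)
  if (cxx + cyy < 1e-12) return(NA_real_)
  ang <- 0.5 * atan2(2 * cxy, cxx - cyy)
  deg <- (ang * 180 / pi) %% 180
  deg
}

# Distribution descriptors used throughout the trait catalog. Undefined
# values (too few observations, zero spread) are NA, never silent zeros.
# Kurtosis is the raw standardized fourth moment m4/m2^2 (>= 1 when defined)
# so that it stays non-negative like the rest of the catalog.
describe_values <- function(v) {
  v <- v[is.finite(v)]
  n <- length(v)
  if (n == 0) {
    return(c(mean = NA_real_, median = NA_real_, sd = NA_real_,
             skewness = NA_real_, kurtosis = NA_real_,
             p10 = NA_real_, p90 = NA_real_))
  }
  qs <- stats::quantile(v, c(0.1, 0.9), names = FALSE, type = 7)
  s <- if (n >= 2) stats::sd(v) else NA_real_
  m2 <- mean((v - mean(v))^2)
  if (n >= 2 && m2 > 1e-24) {
    skw <- e1071::skewness(v, type = 1)
    krt <- e1071::kurtosis(v, type = 1) + 3  # raw m4/m2^2
  } else {
    skw <- NA_real_   # zero spread or single value: shape undefined
    krt <- NA_real_
  }
  c(mean = mean(v), median = stats::median(v), sd = s,
    skewness = skw, kurtosis = krt, p10 = qs[1], p90 = qs[2])
}
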