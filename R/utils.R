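## Internal numeric helpers shared across modules.

## Centered moving average with odd window; edges use the available part of
## the window (shrinking kernel), so a window of 1 is the identity.
moving_average <- function(x, window) {
  if (window <= 1L) return(x)
  k <- rep(1, window)
  num <- stats::filter(x, k, sides = 2)
  den <- stats::filter(rep(1, length(x)), k, sides = 2)
  edge <- is.na(num)
  if (any(edge)) {
    half <- (window - 1L) %/% 2L
    n <- length(x)
    cx <- c(0, cumsum(x))
    lo <- pmax(seq_len(n) - half, 1L); hi <- pmin(seq_len(n) + half, n)
    out <- (cx[hi + 1L] - cx[lo]) / (hi - lo + 1L)
    out[!edge] <- num[!edge] / den[!edge]
    return(as.numeric(out))
  }
  as.numeric(num / den)
}

## Columnwise moving average of a matrix (stats::filter handles matrices).
moving_average_mat <- function(mat, window) {
  if (window <= 1L) return(mat)
  out <- apply(mat, 2L, moving_average, window = window)
  matrix(out, nrow = nrow(mat))
}

## Rolling low-quantile baseline, evaluated on a coarse grid and linearly
## interpolated between grid points; windows are clipped at the signal edges.
rolling_quantile <- function(x, window, prob, grid_step = NULL) {
  n <- length(x)
  half <- max(1L, (as.integer(window) - 1L) %/% 2L)
  if (is.null(grid_step)) grid_step <- max(1L, half %/% 4L)
  centers <- unique(c(seq(1L, n, by = grid_step), n))
  qs <- vapply(centers, function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    stats::quantile(x[lo:hi], probs = prob, names = FALSE, type = 1L)
  }, numeric(1))
  if (length(centers) == 1L) return(rep(qs, n))
  stats::approx(centers, qs, xout = seq_len(n), rule = 2L)$y
}

## Robust noise scale: 1.4826 * median absolute deviation about the median.
mad_noise <- function(x) {
  m <- stats::median(x)
  1.4826 * stats::median(abs(x - m))
}

## Cosine similarity of two non-negative vectors; 0 when either has norm 0.
cosine_sim <- function(a, b) {
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

## Local maxima of a vector: strictly above the left neighbour and at least
## the right neighbour (plateaus keep their left edge). Ends excluded.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1L)
  which(x[i] > x[i - 1L] & x[i] >= x[i + 1L]) + 1L
}

## Run-scoped RNG: evaluate expr under a fixed seed without disturbing the
## caller's RNG stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Gaussian elution profile (amplitude form: value 1 at the apex).
gauss_profile <- function(t, mu, sigma) exp(-((t - mu)^2) / (2 * sigma^2))

## Named-numeric spectrum utilities: names are integer m/z, values relative
## intensities. Rescale so the base peak is exactly 1000.
rescale_1000 <- function(spec) {
  spec <- spec[spec > 0]
  if (!length(spec)) return(spec)
  spec * (1000 / max(spec))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
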