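#' Highest posterior density interval
#'
#' Shortest interval containing `prob` of the draws, computed on the sorted
#' sample (the usual empirical HPDI).
#'
#' @param x numeric vector of posterior draws.
#' @param prob interval mass, default 0.95.
#' @return named numeric vector `c(lower, upper)`.
#' @export
hpdi <- function(x, prob = 0.95) {
  stopifnot(is.numeric(x), length(x) > 1, prob > 0, prob < 1)
  x <- sort(x[is.finite(x)])
  n <- length(x)
  k <- max(1L, ceiling(prob * n))
  if (k >= n) return(c(lower = x[1], upper = x[n]))
  widths <- x[(k + 1):n] - x[1:(n - k)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + k])
}

#' Derive a per-stage RNG seed from a master seed
#'
#' All stochastic stages draw their seed deterministically from one master
#' seed so that a pipeline run is reproducible end to end while stages stay
#' independently re-runnable.
#'
#' @param seed master seed (small integer).
#' @param stream integer stream index (>= 1).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
seed_stream <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(stream))
  m <- 2147483647 # 2^31 - 1 (Mersenne prime, Lehmer modulus)
  s <- (abs(seed) %% m) + 1
  for (i in seq_len(3 + (stream %% 7))) s <- (s * 48271) %% m
  as.integer(((s + stream * 2654435) %% (m - 1)) + 1)
}

# internal: %||%
`%||%` <- function(a, b) if (is.null(a)) b else a

# internal: stop unless all names present in a data.frame
.need_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

# internal: adjusted R^2 (Ezekiel)
.adj_r2 <- function(r2, n, m) 1 - (1 - r2) * (n - 1) / (n - m - 1)
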