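# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Display a calendar age in ka
#'
#' Calendar ages are carried everywhere in years cal BP (before AD 1950).
#' `ka` is a display-only unit: cal BP / 1000 rounded to 0.1.
#'
#' @param calbp Numeric vector of calendar ages in years cal BP.
#' @return Numeric vector in ka, rounded to one decimal.
#' @export
#' @examples
#' as_ka(8493) # 8.5
as_ka <- function(calbp) round(calbp / 1000, 1)

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# Generators must be pure functions of (config, seed); this keeps them from
# disturbing an enclosing simulation.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Shortest interval containing `level` mass of a posterior sample
# (sample-based HPD, one interval; draws assumed unimodal enough).
hpd_from_draws <- function(draws, level = 0.95) {
  x <- sort(draws)
  n <- length(x)
  k <- max(1L, ceiling(level * n))
  if (k >= n) return(c(lower = x[1L], upper = x[n]))
  width <- x[(k + 1L):n] - x[1:(n - k)]
  i <- which.min(width)
  c(lower = x[i], upper = x[i + k])
}

# Split R-hat (Gelman-Rubin with halved chains) for a draws matrix
# (iterations x chains).  Returns NA for fewer than 4 split halves' worth.
split_rhat <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  if (n < 4L) return(NA_real_)
  half <- floor(n / 2)
  sub <- cbind(mat[seq_len(half), , drop = FALSE],
               mat[(n - half + 1L):n, , drop = FALSE])
  m <- ncol(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, stats::var)
  w <- mean(vars)
  b <- half * stats::var(means)
  if (w == 0) return(1)
  sqrt(((half - 1) / half * w + b / half) / w)
}

# Effective sample size via the initial positive sequence of autocovariances,
# computed per chain and summed.
ess_draws <- function(mat) {
  mat <- as.matrix(mat)
  per_chain <- function(x) {
    n <- length(x)
    if (stats::var(x) == 0) return(n)
    ac <- stats::acf(x, lag.max = min(n - 1L, 200L), plot = FALSE)$acf[, 1, 1]
    s <- 0
    for (k in seq(2L, length(ac), by = 2L)) {
      if (k + 1L > length(ac)) break
      pair <- ac[k] + ac[k + 1L]
      if (pair < 0) break
      s <- s + pair
    }
    n / (1 + 2 * s)
  }
  sum(apply(mat, 2, per_chain))
}

stop_bc <- function(msg, class) {
  stop(structure(class = c(class, "baychron_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}
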