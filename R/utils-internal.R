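# Internal numerical helpers shared across modules. None exported.

#' Evaluate an expression under a temporary RNG state
#'
#' Seeds the generator, runs `expr`, and restores the caller's RNG state so
#' that library code never perturbs user-level reproducibility.
#' @noRd
with_seed <- function(seed, expr, normal_kind = "default") {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed %% .Machine$integer.max),
             normal.kind = normal_kind)
  }
  force(expr)
}

# Mirror ("reflect") index vector for padding a length-n axis by r samples on
# each side: ... 3 2 | 1 2 3 ... n | n-1 n-2 ...  Requires r <= n - 1.
reflect_idx <- function(n, r) {
  if (r <= 0L) return(seq_len(n))
  stopifnot(r <= n - 1L)
  c(seq(r + 1L, 2L), seq_len(n), seq(n - 1L, n - r))
}

# Discrete 1-D Gaussian kernel, normalized to sum 1.
gauss_kernel1d <- function(sigma, radius = ceiling(3 * sigma)) {
  x <- seq(-radius, radius)
  w <- exp(-x^2 / (2 * sigma^2))
  w / sum(w)
}

# 1-D convolution of every column of a matrix with kernel k (odd length),
# reflect padding. Returns a matrix of the same shape.
conv_cols <- function(x, k) {
  r <- (length(k) - 1L) %/% 2L
  if (r == 0L) return(x * k)
  xp <- x[reflect_idx(nrow(x), r), , drop = FALSE]
  out <- matrix(0, nrow(x), ncol(x))
  for (i in seq_along(k)) {
    out <- out + k[i] * xp[i:(i + nrow(x) - 1L), , drop = FALSE]
  }
  out
}

# Separable 2-D convolution with outer(k, k), reflect padding.
conv_sep2d <- function(x, k) {
  t(conv_cols(t(conv_cols(x, k)), k))
}

# Gaussian blur of a 2-D matrix (reflect padding).
gauss_blur2d <- function(x, sigma, radius = ceiling(3 * sigma)) {
  conv_sep2d(x, gauss_kernel1d(sigma, radius))
}

# Central-difference partial derivatives of a matrix (reflect edges).
# Returns list(dr, dc): derivative along rows (vertical) and columns.
grad2d <- function(x) {
  n <- nrow(x); m <- ncol(x)
  up <- x[c(1L, seq_len(n - 1L)), , drop = FALSE]
  dn <- x[c(seq(2L, n), n), , drop = FALSE]
  lf <- x[, c(1L, seq_len(m - 1L)), drop = FALSE]
  rt <- x[, c(seq(2L, m), m), drop = FALSE]
  list(dr = (dn - up) / 2, dc = (rt - lf) / 2)
}

# Binary dilation of a logical matrix by a disc of radius r (pixels).
binary_dilate <- function(mask, r) {
  stopifnot(is.logical(mask), r >= 0)
  if (r == 0) return(mask)
  n <- nrow(mask); m <- ncol(mask)
  out <- matrix(FALSE, n, m)
  ri <- floor(r)
  for (dr in -ri:ri) {
    for (dc in -ri:ri) {
      if (dr * dr + dc * dc > r * r) next
      rs <- pmin(pmax(seq_len(n) - dr, 1L), n)
      cs <- pmin(pmax(seq_len(m) - dc, 1L), m)
      # clamp to the border: shifting out of frame contributes nothing new
      src <- mask[rs, cs, drop = FALSE]
      if (dr != 0) {
        keep_r <- seq_len(n) - dr >= 1L & seq_len(n) - dr <= n
        src[!keep_r, ] <- FALSE
      }
      if (dc != 0) {
        keep_c <- seq_len(m) - dc >= 1L & seq_len(m) - dc <= m
        src[, !keep_c] <- FALSE
      }
      out <- out | src
    }
  }
  out
}

# Binary erosion via dilation of the complement.
binary_erode <- function(mask, r) {
  !binary_dilate(!mask, r)
}

# Steady-state initial conditions for a direct-form-II-transposed IIR filter
# (the classic lfilter_zi construction), so that filtering a constant signal
# produces that constant from the first sample.
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  b <- b / a[1]; a <- a / a[1]
  if (n == 1L) return(numeric(0))
  comp <- matrix(0, n - 1L, n - 1L)  # companion matrix of a
  comp[1L, ] <- -a[-1L]
  if (n > 2L) comp[cbind(2:(n - 1L), 1:(n - 2L))] <- 1
  IminusA <- diag(n - 1L) - t(comp)
  B <- b[-1L] - a[-1L] * b[1L]
  solve(IminusA, B)
}

# Filter every row of X (series along columns) with the IIR (b, a) using
# direct form II transposed; the per-row initial state is outer(x_first,
# zi). The time recursion runs in compiled code.
iir_filter_rows <- function(b, a, X, zi) {
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  b <- b / a[1]; a <- a / a[1]
  .iir_df2t_rows(b, a, X, zi)
}

# Zero-phase (forward-backward) filtering of every row of X, with
# mirror-reflection end padding. Mirror (rather than odd 2*x0 - x)
# padding keeps the pad at the signal's own level, so the reverse pass
# re-enters the data without a step transient even when the series ends
# mid-oscillation; the pad is generous because narrow-band designs have
# poles near the unit circle whose transients outlive the classic
# 3*(n-1) pad.
filtfilt_rows <- function(b, a, X) {
  nt <- ncol(X)
  p <- 15L * (max(length(a), length(b)) - 1L)
  p <- min(p, nt - 1L)
  zi <- lfilter_zi(b, a)
  left  <- X[, seq(p + 1L, 2L), drop = FALSE]
  right <- X[, seq(nt - 1L, nt - p), drop = FALSE]
  Xp <- cbind(left, X, right)
  Y <- iir_filter_rows(b, a, Xp, zi)
  Y <- Y[, rev(seq_len(ncol(Y))), drop = FALSE]
  Y <- iir_filter_rows(b, a, Y, zi)
  Y <- Y[, rev(seq_len(ncol(Y))), drop = FALSE]
  Y[, (p + 1L):(p + nt), drop = FALSE]
}

# Sum of values in every size x size window of a matrix, via an integral
# image. Returns matrix of dim (n - size + 1) x (m - size + 1).
window_sums <- function(x, size) {
  n <- nrow(x); m <- ncol(x)
  stopifnot(size >= 1L, size <= n, size <= m)
  ii <- matrix(0, n + 1L, m + 1L)
  ii[-1L, -1L] <- t(apply(apply(x, 2L, cumsum), 1L, cumsum))
  r <- seq_len(n - size + 1L); cc <- seq_len(m - size + 1L)
  ii[r + size, cc + size, drop = FALSE] - ii[r, cc + size, drop = FALSE] -
    ii[r + size, cc, drop = FALSE] + ii[r, cc, drop = FALSE]
}

# Otsu's threshold: maximizes between-class variance of a bimodal sample.
otsu_threshold <- function(x, nbins = 256L) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1L])
  h <- tabulate(pmin(pmax(findInterval(
    x, seq(rng[1L], rng[2L], length.out = nbins + 1L),
    rightmost.closed = TRUE), 1L), nbins), nbins)
  w <- h / sum(h)
  mids <- seq(rng[1L], rng[2L], length.out = nbins + 1L)[-1L] -
    diff(rng) / (2 * nbins)
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[nbins]
  bcv <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  bcv[!is.finite(bcv)] <- 0
  mids[which.max(bcv)]
}

# ISODATA (Ridler-Calvard) threshold: iterate to the midpoint of the two
# class means, starting from Otsu. For a two-level image with linear
# partial-volume edges this converges to the half-coverage intensity,
# i.e. the geometric vessel boundary.
isodata_threshold <- function(x, tol = 1e-8, max_iter = 100L) {
  thr <- otsu_threshold(x)
  for (i in seq_len(max_iter)) {
    lo <- x[x < thr]; hi <- x[x >= thr]
    if (length(lo) == 0L || length(hi) == 0L) break
    new_thr <- (mean(lo) + mean(hi)) / 2
    if (abs(new_thr - thr) < tol) break
    thr <- new_thr
  }
  thr
}

# Population standard deviation (divisor n).
pop_sd <- function(x) {
  x <- as.numeric(x)
  sqrt(mean((x - mean(x))^2))
}
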