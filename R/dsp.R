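# IIR filter design and zero-phase filtering.
#
# No DSP package ships with the analysis stack, so the small amount of
# classical filter design the pipeline needs (Chebyshev type II high-pass for
# drift removal, Butterworth low-pass for anti-alias decimation) is built here
# from the analog prototypes via the bilinear transform. Filters are kept as
# transfer-function (b, a) pairs; all user-facing filtering is forward-backward
# (zero phase) so evoked-potential latencies are preserved.

cplx_poly <- function(roots) {
  # monic polynomial coefficients (descending powers) from complex roots
  p <- 1 + 0i
  for (r in roots) p <- c(p, 0i) - c(0i, p * r)
  p
}

#' Design a digital Chebyshev type II filter
#'
#' @param n filter order.
#' @param rs stopband attenuation in dB (down from peak passband gain).
#' @param w cutoff (stopband edge) as a fraction of the Nyquist frequency,
#'   in (0, 1).
#' @param type `"high"` or `"low"`.
#' @return list with numerator `b` and denominator `a` coefficients.
#' @export
cheby2_design <- function(n, rs, w, type = c("high", "low")) {
  type <- match.arg(type)
  stopifnot(n >= 1, rs > 0, w > 0, w < 1)
  eps <- 1 / sqrt(10^(rs / 10) - 1)
  mu <- asinh(1 / eps) / n
  k <- seq_len(n)
  theta <- pi * (2 * k - 1) / (2 * n)
  # Chebyshev I poles; type II poles are their reciprocals
  p1 <- complex(real = -sinh(mu) * sin(theta), imaginary = cosh(mu) * cos(theta))
  p <- 1 / p1
  # zeros on the imaginary axis (skip theta = pi/2 where cos = 0, odd n)
  ct <- cos(theta)
  z <- complex(imaginary = 1 / ct[abs(ct) > 1e-12])
  g <- Re(prod(-p) / prod(-z))  # unity DC gain for the low-pass prototype
  zpk_to_digital(z, p, g, w, type)
}

#' Design a digital Butterworth filter
#'
#' @inheritParams cheby2_design
#' @return list with `b` and `a`.
#' @export
butter_design <- function(n, w, type = c("low", "high")) {
  type <- match.arg(type)
  stopifnot(n >= 1, w > 0, w < 1)
  k <- seq_len(n)
  p <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  z <- complex(0)
  g <- Re(prod(-p))
  zpk_to_digital(z, p, g, w, type)
}

zpk_to_digital <- function(z, p, g, w, type) {
  fs2 <- 4                         # 2 * fs with fs = 2 (normalized design)
  warped <- fs2 * tan(pi * w / 2)  # prewarped analog cutoff
  if (type == "high") {            # low-pass prototype -> high-pass
    g <- g * Re(prod(-z) / prod(-p))
    z2 <- warped / z
    p2 <- warped / p
    # prototype zeros at infinity map to s = 0
    z2 <- c(z2, rep(0 + 0i, length(p) - length(z)))
  } else {                         # low-pass scaling
    degree <- length(p) - length(z)
    z2 <- z * warped
    p2 <- p * warped
    g <- g * warped^degree
  }
  # bilinear transform s -> 2fs (z-1)/(z+1)
  degree <- length(p2) - length(z2)
  zd <- (fs2 + z2) / (fs2 - z2)
  pd <- (fs2 + p2) / (fs2 - p2)
  zd <- c(zd, rep(-1 + 0i, degree))
  gd <- g * Re(prod(fs2 - z2) / prod(fs2 - p2))
  b <- Re(cplx_poly(zd)) * gd
  a <- Re(cplx_poly(pd))
  list(b = b, a = a)
}

#' Evaluate the frequency response of a digital filter
#'
#' @param flt list with `b`, `a` as returned by the design functions.
#' @param f frequencies in Hz.
#' @param fs sampling rate in Hz.
#' @return complex response H at each frequency.
#' @export
freq_response <- function(flt, f, fs) {
  w <- 2 * pi * f / fs
  ew <- exp(-1i * w)
  num <- vapply(ew, function(e) sum(flt$b * e^(seq_along(flt$b) - 1)), complex(1))
  den <- vapply(ew, function(e) sum(flt$a * e^(seq_along(flt$a) - 1)), complex(1))
  num / den
}

lfilter_zi <- function(b, a) {
  # steady-state DF2T state for unit step input (scipy lfilter_zi construction)
  n <- max(length(a), length(b))
  a0 <- a[1]
  a <- c(a, rep(0, n - length(a))) / a0
  b <- c(b, rep(0, n - length(b))) / a0
  if (n == 1) return(numeric(0))
  # A = transpose of the companion matrix of a (monic)
  A <- matrix(0, n - 1, n - 1)
  A[, 1] <- -a[2:n]
  if (n > 2) A[cbind(1:(n - 2), 2:(n - 1))] <- 1
  B <- b[2:n] - a[2:n] * b[1]
  solve(diag(n - 1) - A, B)
}

lfilter_mat <- function(b, a, x, zi = NULL) {
  # direct-form II transposed filtering down the rows of a matrix
  # (columns are independent channels/trials); x: n_samples x n_chan
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  b <- b / a[1]; a <- a / a[1]
  nt <- nrow(x); nc <- ncol(x)
  y <- matrix(0, nt, nc)
  z <- if (is.null(zi)) matrix(0, n - 1, nc) else zi
  for (t in seq_len(nt)) {
    xt <- x[t, ]
    yt <- b[1] * xt + z[1, ]
    if (n > 2) {
      z[1:(n - 2), ] <- b[2:(n - 1)] * rep(xt, each = n - 2) +
        z[2:(n - 1), , drop = FALSE] -
        a[2:(n - 1)] * rep(yt, each = n - 2)
    }
    z[n - 1, ] <- b[n] * xt - a[n] * yt
    y[t, ] <- yt
  }
  y
}

#' Zero-phase (forward-backward) IIR filtering
#'
#' Applies the filter twice, forward then backward, with odd-symmetric edge
#' extension and steady-state initial conditions, so the net phase response is
#' zero and the amplitude response is applied squared.
#'
#' @param flt list with `b`, `a`.
#' @param x numeric vector or a samples-by-channels matrix.
#' @return filtered data, same shape as `x`.
#' @export
filtfilt <- function(flt, x) {
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, ncol = 1) else x
  b <- flt$b; a <- flt$a
  ntaps <- max(length(a), length(b))
  padlen <- min(nrow(xm) - 1L, 3L * (ntaps - 1L) * 10L)
  zi <- lfilter_zi(b, a)
  ext <- rbind(
    2 * xm[rep(1L, padlen), , drop = FALSE] - xm[(padlen + 1L):2L, , drop = FALSE],
    xm,
    2 * xm[rep(nrow(xm), padlen), , drop = FALSE] -
      xm[(nrow(xm) - 1L):(nrow(xm) - padlen), , drop = FALSE]
  )
  y <- lfilter_mat(b, a, ext, zi = zi %o% ext[1, ])
  y <- y[nrow(y):1L, , drop = FALSE]
  y <- lfilter_mat(b, a, y, zi = zi %o% y[1, ])
  y <- y[nrow(y):1L, , drop = FALSE]
  out <- y[(padlen + 1L):(padlen + nrow(xm)), , drop = FALSE]
  if (vec) drop(out) else out
}

#' Analytic signal via the FFT Hilbert transform
#'
#' @param x real-valued numeric vector.
#' @return complex analytic signal; `Arg()` of it is the instantaneous phase.
#' @export
hilbert_analytic <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}
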