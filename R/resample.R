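# Polyphase rational resampling with a Kaiser-windowed sinc anti-aliasing
# low-pass. Acquisition-rate traces (typically 1000 Hz) are converted to the
# analysis rates (PPG 64 Hz, EDA 4 Hz); 64/1000 is a non-integer ratio, so
# naive decimation would alias pulse harmonics.

# Best rational approximation L/M of x by continued fractions.
.rational_approx <- function(x, tol = 1e-9, max_den = 1e6) {
  stopifnot(x > 0)
  h1 <- 1; h0 <- 0; k1 <- 0; k0 <- 1
  b <- x
  repeat {
    a <- floor(b)
    h2 <- a * h1 + h0; k2 <- a * k1 + k0
    if (k2 > max_den) break
    h0 <- h1; h1 <- h2; k0 <- k1; k1 <- k2
    if (abs(h1 / k1 - x) <= tol * x) break
    frac <- b - a
    if (frac < 1e-15) break
    b <- 1 / frac
  }
  if (abs(h1 / k1 - x) > tol * x) {
    stop(sprintf(
      "resample_trace: rate ratio %g has no rational approximation with denominator <= %g",
      x, max_den), call. = FALSE)
  }
  c(num = h1, den = k1)
}

.kaiser_window <- function(n, beta = 5.0) {
  i <- seq_len(n) - 1
  arg <- beta * sqrt(pmax(0, 1 - (2 * i / (n - 1) - 1)^2))
  besselI(arg, 0) / besselI(beta, 0)
}

# Windowed-sinc low-pass, cutoff fc in cycles/sample, odd length.
.fir_lowpass <- function(ntaps, fc, beta = 5.0) {
  d <- (ntaps - 1) / 2
  t <- (seq_len(ntaps) - 1) - d
  h <- ifelse(t == 0, 2 * fc, sin(2 * pi * fc * t) / (pi * t))
  h * .kaiser_window(ntaps, beta)
}

.mod_inverse <- function(a, m) {
  if (m == 1L) return(0L)
  a <- a %% m
  t0 <- 0L; t1 <- 1L; r0 <- m; r1 <- a
  while (r1 != 0L) {
    q <- r0 %/% r1
    tmp <- t0 - q * t1; t0 <- t1; t1 <- tmp
    tmp <- r0 - q * r1; r0 <- r1; r1 <- tmp
  }
  if (r0 != 1L) stop("no modular inverse (L and M not coprime)")
  t0 %% m
}

# Core polyphase resampler: x at implicit rate 1, upsample by L, anti-alias,
# downsample by M; edge samples are replicated so a constant signal stays
# exactly constant. Output length round(length(x) * L / M).
.resample_poly <- function(x, L, M) {
  n_in <- length(x)
  n_out <- round(n_in * L / M)
  half <- 10L * max(L, M)
  ntaps <- 2L * half + 1L
  fc <- 1 / (2 * max(L, M))
  h <- .fir_lowpass(ntaps, fc)
  # Normalize each polyphase branch (residue class of tap index mod L) to
  # 1/L so that, with edge replication, DC is preserved exactly.
  ph <- (seq_len(ntaps) - 1L) %% L
  branch_sum <- vapply(0:(L - 1L), function(p) sum(h[ph == p]), numeric(1))
  h <- h / (L * branch_sum[ph + 1L])

  y <- numeric(n_out)
  if (n_out == 0L) return(y)
  minv <- .mod_inverse(M %% L, L)
  D <- half
  n_all <- 0:(n_out - 1L)
  for (m in 0:(ntaps - 1L)) {
    hm <- h[m + 1L]
    if (hm == 0) next
    # output indices n whose upsampled position n*M + D - m lands on an
    # input sample: n*M = m - D (mod L)
    r <- ((m - D) %% L + L) %% L
    n0 <- if (L == 1L) 0L else (r * minv) %% L
    if (n0 > n_out - 1L) next
    n <- seq.int(n0, n_out - 1L, by = max(L, 1L))
    k <- (n * M + D - m) %/% L
    k <- pmin(pmax(k, 0L), n_in - 1L)   # edge replication
    y[n + 1L] <- y[n + 1L] + hm * x[k + 1L]
  }
  y * L
}

#' Resample a trace to a new rate with anti-aliasing
#'
#' Rational polyphase resampling: the rate ratio is approximated by `L/M`
#' (exact for the usual 1000 Hz to 64 Hz and 1000 Hz to 4 Hz conversions),
#' the signal is conceptually upsampled by `L`, filtered by a
#' Kaiser-windowed sinc low-pass at the narrower of the two Nyquist
#' frequencies, and decimated by `M`. Edges are handled by replicating the
#' first and last sample, and each polyphase branch is normalized so a
#' constant signal is reproduced exactly. Output length is
#' `round(n * target_rate / source_rate)`.
#'
#' When the target rate already equals the trace rate (relative difference
#' below 1e-9) the trace is returned unchanged.
#'
#' @param trace a [signal_trace()].
#' @param target_rate desired rate in Hz (> 0).
#' @return a [signal_trace()] at `target_rate`, same channel and offset.
#' @examples
#' tr <- signal_trace(rep(5, 1000), 1000, "EDA")
#' resample_trace(tr, 4)
#' @export
resample_trace <- function(trace, target_rate) {
  stopifnot(inherits(trace, "signal_trace"))
  if (!is.finite(target_rate) || target_rate <= 0) {
    stop("resample_trace: 'target_rate' must be positive", call. = FALSE)
  }
  if (abs(target_rate - trace$sampling_rate) <= 1e-9 * trace$sampling_rate) {
    return(trace)
  }
  lm <- .rational_approx(target_rate / trace$sampling_rate)
  y <- .resample_poly(trace$samples, as.integer(lm["num"]),
                      as.integer(lm["den"]))
  if (length(y) == 0L) {
    stop("resample_trace: trace too short for requested rate", call. = FALSE)
  }
  signal_trace(y, target_rate, trace$channel, trace$start_offset)
}
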