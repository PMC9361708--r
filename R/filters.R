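# Zero-phase IIR filtering.
#
# A single forward pass uses steady-state initial conditions derived from the
# first sample (the filter starts as if the signal had been at that value
# forever), so a constant input maps to a constant output with no boundary
# transient. The zero-phase version runs the pass forward and backward over an
# odd-reflection padded copy of the signal, the standard way to cancel group
# delay while keeping end effects small.

.lfilter <- function(b, a, x) {
  b <- b / a[1]; a <- a / a[1]
  nb <- length(b); na <- length(a)
  x0 <- x[1]
  gain <- sum(b) / sum(a)       # DC gain
  xx <- c(rep(x0, nb - 1L), x)  # constant past input
  u <- stats::filter(xx, b, method = "convolution", sides = 1)
  u <- as.numeric(u)[(nb - 1L) + seq_along(x)]
  if (na > 1L)
    as.numeric(stats::filter(u, -a[-1L], method = "recursive",
                             init = rep(x0 * gain, na - 1L)))
  else u
}

.zerophase_filter <- function(b, a, x) {
  n <- length(x)
  npad <- min(n - 1L, 3L * (max(length(a), length(b)) - 1L))
  if (npad > 0L) {
    head_pad <- 2 * x[1] - x[seq(npad + 1L, 2L)]
    tail_pad <- 2 * x[n] - x[seq(n - 1L, n - npad)]
    xp <- c(head_pad, x, tail_pad)
  } else xp <- x
  y <- .lfilter(b, a, xp)
  y <- rev(.lfilter(b, a, rev(y)))
  if (npad > 0L) y <- y[npad + seq_len(n)]
  y
}

.butter_coeffs <- function(order, cutoff, fs, type) {
  w <- cutoff / (fs / 2)
  if (any(w <= 0) || any(w >= 1))
    stop("invalid-rate: cut-off must lie strictly inside (0, fs/2)",
         call. = FALSE)
  flt <- signal::butter(order, w, type = type)
  list(b = flt$b, a = flt$a)
}
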