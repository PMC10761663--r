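# Closed-form building blocks for the Feng input function and its
# convolutions. All take vectorized time arguments in minutes and return 0
# for t <= 0 (curves start at injection). Internal.

# Feng curve f(t) = A1 t e^{-mu1 t} + A2 (e^{-mu2 t} - e^{-mu1 t})
.feng_f <- function(p, t) {
  pos <- t > 0
  out <- numeric(length(t))
  tt <- t[pos]
  out[pos] <- p[["A1"]] * tt * exp(-p[["mu1"]] * tt) +
    p[["A2"]] * (exp(-p[["mu2"]] * tt) - exp(-p[["mu1"]] * tt))
  out
}

# Antiderivative F(t) = int_0^t f, exact.
.feng_F <- function(p, t) {
  t <- pmax(t, 0)
  m1 <- p[["mu1"]]; m2 <- p[["mu2"]]
  p[["A1"]] * (1 - exp(-m1 * t) * (1 + m1 * t)) / m1^2 +
    p[["A2"]] * ((1 - exp(-m2 * t)) / m2 - (1 - exp(-m1 * t)) / m1)
}

# e^{-b u} convolved with e^{-mu u} on [0, u]; limit u e^{-bu} when b == mu.
.econv_exp <- function(u, mu, b) {
  k <- b - mu
  if (abs(k) < 1e-9) u * exp(-b * u) else (exp(-mu * u) - exp(-b * u)) / k
}

# e^{-b u} convolved with u e^{-mu u} on [0, u].
.econv_ramp <- function(u, mu, b) {
  k <- b - mu
  if (abs(k) < 1e-9) 0.5 * u^2 * exp(-b * u)
  else u * exp(-mu * u) / k - (exp(-mu * u) - exp(-b * u)) / k^2
}

# (e^{-b t} conv f)(t) for a single injection at time zero.
.feng_econv <- function(p, t, b) {
  pos <- t > 0
  out <- numeric(length(t))
  u <- t[pos]
  out[pos] <- p[["A1"]] * .econv_ramp(u, p[["mu1"]], b) +
    p[["A2"]] * (.econv_exp(u, p[["mu2"]], b) - .econv_exp(u, p[["mu1"]], b))
  out
}

# Sum a single-injection kernel over an impulse train.
.inj_sum <- function(fun, t, injections, ...) {
  out <- 0
  for (j in seq_len(nrow(injections))) {
    out <- out + injections$dose_fraction[j] *
      fun(t - injections$injection_time[j], ...)
  }
  out
}

# Plasma curve, its running integral, and its exponential convolution for a
# multi-injection protocol; vectorized over t (any shape, shape preserved).
.cp <- function(p, injections, t) {
  d <- dim(t)
  out <- .inj_sum(function(u) .feng_f(p, u), t, injections)
  dim(out) <- d
  out
}
.cp_int <- function(p, injections, t) {
  d <- dim(t)
  out <- .inj_sum(function(u) .feng_F(p, u), t, injections)
  dim(out) <- d
  out
}
.cp_econv <- function(p, injections, t, b) {
  d <- dim(t)
  out <- .inj_sum(function(u) .feng_econv(p, u, b), t, injections)
  dim(out) <- d
  out
}

# Composite-Simpson sub-frame nodes for frame averaging of curves that have
# no closed-form antiderivative (2TCM output). `nsub` must be even. Frames
# containing a `breaks` time (an injection) are split there, since the
# input function has a derivative kink at each injection; the pieces are
# re-merged by duration weighting in .frame_average_nodes.
.frame_nodes <- function(schedule, nsub = 8L, breaks = numeric(0)) {
  stopifnot(nsub %% 2L == 0L)
  starts <- schedule$frame_start
  durs <- schedule$frame_duration
  map <- seq_along(starts)
  wmap <- rep(1, length(starts))
  for (b in breaks) {
    hit <- which(b > starts + 1e-12 & b < starts + durs - 1e-12)
    for (i in hit) {
      d1 <- b - starts[i]; d2 <- starts[i] + durs[i] - b
      frac <- d1 / durs[i]
      starts <- c(starts, b); durs <- c(durs, d2)
      map <- c(map, map[i]); wmap <- c(wmap, wmap[i] * (1 - frac))
      durs[i] <- d1; wmap[i] <- wmap[i] * frac
    }
  }
  frac <- seq(0, 1, length.out = nsub + 1L)
  t <- outer(frac, durs) + rep(starts, each = nsub + 1L)
  w <- c(1, rep(c(4, 2), length.out = nsub - 1L), 1)
  list(t = t, w = w / sum(w), map = map, wmap = wmap,
       n_frames = nrow(schedule))
}

# Frame averages from values at Simpson nodes, re-merging split frames.
.frame_average_nodes <- function(values, nodes) {
  piece <- colSums(values * nodes$w) * nodes$wmap
  as.vector(rowsum(piece, nodes$map, reorder = TRUE))
}
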