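# Maximal-overlap discrete wavelet transform (MODWT, "a trous" pyramid).
# Undecimated, works for any signal length, and reconstructs exactly under
# circular convolution; reflection extension gives symmetric boundaries.

# orthonormal scaling (low-pass) filters, extremal-phase Daubechies family
.scaling_filter <- function(name) {
  s3 <- sqrt(3)
  switch(name,
    haar = c(1, 1) / sqrt(2),
    db2 = c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2)),
    db4 = c(0.23037781330885523, 0.71484657055254153,
            0.63088076792959036, -0.02798376941698385,
            -0.18703481171888114, 0.03084138183598697,
            0.03288301166698295, -0.01059740178499728),
    stop("unsupported wavelet '", name, "'; use 'db4', 'db2' or 'haar'"))
}

# quadrature-mirror wavelet (high-pass) filter: g_l = (-1)^l h_{L-1-l}
.wavelet_filter <- function(h) ((-1)^(seq_along(h) - 1)) * rev(h)

.modwt <- function(x, name = "db4", levels = 4L) {
  h <- .scaling_filter(name) / sqrt(2)
  g <- .wavelet_filter(.scaling_filter(name)) / sqrt(2)
  N <- length(x)
  L <- length(h)
  V <- x
  W <- vector("list", levels)
  for (j in seq_len(levels)) {
    shift <- 2^(j - 1)
    Wj <- numeric(N); Vj <- numeric(N)
    for (l in 0:(L - 1)) {
      idx <- ((seq_len(N) - 1 - shift * l) %% N) + 1
      Wj <- Wj + g[l + 1] * V[idx]
      Vj <- Vj + h[l + 1] * V[idx]
    }
    W[[j]] <- Wj
    V <- Vj
  }
  list(W = W, V = V, wavelet = name, N = N)
}

.imodwt <- function(dec) {
  h <- .scaling_filter(dec$wavelet) / sqrt(2)
  g <- .wavelet_filter(.scaling_filter(dec$wavelet)) / sqrt(2)
  N <- dec$N
  L <- length(h)
  V <- dec$V
  for (j in rev(seq_along(dec$W))) {
    shift <- 2^(j - 1)
    V0 <- numeric(N)
    Wj <- dec$W[[j]]
    for (l in 0:(L - 1)) {
      idx <- ((seq_len(N) - 1 + shift * l) %% N) + 1
      V0 <- V0 + h[l + 1] * V[idx] + g[l + 1] * Wj[idx]
    }
    V <- V0
  }
  V
}

# apply f to the MODWT coefficients of x and reconstruct; boundary "reflect"
# runs the circular transform on c(x, rev(x)) and keeps the first half
.wavelet_apply <- function(x, name, levels, boundary, f) {
  N <- length(x)
  xe <- if (boundary == "reflect") c(x, rev(x)) else x
  dec <- .modwt(xe, name, levels)
  dec <- f(dec, N)
  y <- .imodwt(dec)
  y[seq_len(N)]
}
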