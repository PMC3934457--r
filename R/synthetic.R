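# Seeded generator of labelled synthetic pulse data: clean normalized
# periods of the five morphology classes, and raw noisy drifting
# multi-period records with exact ground truth.

# run code under a temporary RNG state
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Class templates: sums of Gaussian bumps on normalized period time
# u in [0, 1). Components are (amplitude, center, width); classes with
# several typical shapes carry multiple variants with equal weight.
# The parameters are generator configuration chosen to match the
# qualitative morphology of the five patterns (percussion P, tidal T,
# dicrotic D waves), not measured values.
.class_templates <- function() {
  bump <- function(amp, center, width)
    c(amp = amp, center = center, width = width)
  # every variant ends with a broad low "runoff" component: the diastolic
  # pressure decay that keeps the waveform sloping down into the next foot
  # (without it the tail is identically zero and the foot is ill-defined)
  list(
    moderate = list(list(bumps = rbind(bump(1.00, 0.13, 0.045),
                                       bump(0.45, 0.30, 0.070),
                                       bump(0.30, 0.55, 0.050),
                                       bump(0.15, 0.72, 0.150)))),
    slippery = list(list(bumps = rbind(bump(1.00, 0.12, 0.040),
                                       bump(0.15, 0.22, 0.060),
                                       bump(0.40, 0.50, 0.050),
                                       bump(0.15, 0.72, 0.150)))),
    taut = list(
      # plateau systole
      list(bumps = rbind(bump(1.00, 0.12, 0.040),
                         bump(0.85, 0.25, 0.120),
                         bump(0.15, 0.55, 0.050),
                         bump(0.12, 0.75, 0.150))),
      # high distinct tidal wave
      list(bumps = rbind(bump(1.00, 0.12, 0.040),
                         bump(0.90, 0.28, 0.050),
                         bump(0.15, 0.55, 0.050),
                         bump(0.12, 0.75, 0.150))),
      # double hump of equal height
      list(bumps = rbind(bump(0.90, 0.12, 0.045),
                         bump(0.90, 0.27, 0.050),
                         bump(0.15, 0.55, 0.050),
                         bump(0.12, 0.75, 0.150)))),
    hollow = list(list(bumps = rbind(bump(1.00, 0.11, 0.035),
                                     bump(0.50, 0.45, 0.050),
                                     bump(0.08, 0.75, 0.150)))),
    # percussion centred late enough that the period opens near its foot
    # (an early broad bump would leave a step at the period boundary)
    unsmooth = list(list(bumps = rbind(bump(0.50, 0.20, 0.090),
                                       bump(0.10, 0.36, 0.060),
                                       bump(0.10, 0.58, 0.050),
                                       bump(0.05, 0.76, 0.150)),
                         ripple = 0.02))
  )
}

.eval_bumps <- function(bumps, u) {
  y <- numeric(length(u))
  for (r in seq_len(nrow(bumps)))
    y <- y + bumps[r, "amp"] *
      exp(-(u - bumps[r, "center"])^2 / (2 * bumps[r, "width"]^2))
  y
}

# smooth monotone warp w(u) = u + sum_k eps_k sin(pi k u); coefficients are
# redrawn until w is strictly increasing on [0, 1]
.draw_warp <- function(sd = 0.005, k = 3L) {
  grid <- seq(0, 1, length.out = 201L)
  repeat {
    eps <- stats::rnorm(k, 0, sd)
    deriv <- 1 + colSums(eps * pi * seq_len(k) *
                           t(outer(grid, seq_len(k),
                                   function(u, kk) cos(pi * kk * u))))
    if (all(deriv > 0)) return(eps)
  }
}

.apply_warp <- function(u, eps) {
  w <- u
  for (k in seq_along(eps)) w <- w + eps[k] * sin(pi * k * u)
  w
}

#' Warp a waveform by a smooth monotone time distortion
#'
#' Resamples \code{values} at \eqn{w(u) = u + \sum_k \epsilon_k \sin(\pi k u)}
#' with small random (or supplied) coefficients, emulating the local time
#' shifts seen between beats. Endpoints are fixed.
#'
#' @param values numeric waveform samples.
#' @param eps warp coefficients; drawn as Normal(0, 0.005^2), truncated to
#'   keep \eqn{w} strictly increasing, when NULL.
#' @return Numeric vector of the same length.
#' @export
warpValues <- function(values, eps = NULL) {
  if (is.null(eps)) eps <- .draw_warp()
  n <- length(values)
  u <- (seq_len(n) - 1) / (n - 1)
  w <- .apply_warp(u, eps)
  stats::approx(u, values, xout = pmin(pmax(w, 0), 1), rule = 2)$y
}

# evaluate one jittered, warped instance of a class template at n points;
# the default jitter scales model cohort-level (between-subject) morphology
# diversity — strong enough that atypical members of one class resemble
# another, as real pulse classes do
.instance_values <- function(label, n = 150L, variant = NULL,
                             ampJitter = 0.20, centerJitter = 0.020,
                             widthJitter = 0.20, warpSd = 0.005) {
  tmpl <- .class_templates()[[label]]
  if (is.null(variant)) variant <- sample.int(length(tmpl), 1L)
  shape <- tmpl[[variant]]
  b <- shape$bumps
  b[, "amp"] <- b[, "amp"] * (1 + stats::rnorm(nrow(b), 0, ampJitter))
  b[, "amp"] <- pmax(b[, "amp"], 0)
  b[, "center"] <- b[, "center"] + stats::rnorm(nrow(b), 0, centerJitter)
  b[, "width"] <- b[, "width"] * (1 + stats::rnorm(nrow(b), 0, widthJitter))
  b[, "width"] <- pmax(b[, "width"], 1e-3)
  u <- (seq_len(n) - 1) / (n - 1)
  eps <- .draw_warp(warpSd)
  y <- .eval_bumps(b, .apply_warp(u, eps))
  if (!is.null(shape$ripple) && shape$ripple > 0) {
    # roughness rides on the wave (amplitude-modulated), so the quiet foot
    # region stays smooth and the period boundary remains well defined
    phase <- stats::runif(1, 0, 2 * pi)
    y <- y * (1 + shape$ripple * sin(2 * pi * 12 * u + phase))
  }
  y
}

#' Clean class template of a pulse pattern
#'
#' The unjittered, unwarped waveform of one class (variant) evaluated on the
#' normalized 150-point grid; the ground truth against which preprocessing
#' recovery is measured.
#'
#' @param label one of \code{pulseClasses()}.
#' @param variant variant index (taut has three typical shapes).
#' @param n number of samples (default 150).
#' @return Numeric vector of length \code{n}.
#' @export
cleanTemplate <- function(label, variant = 1L, n = 150L) {
  label <- match.arg(label, pulseClasses())
  tmpl <- .class_templates()[[label]]
  u <- (seq_len(n) - 1) / (n - 1)
  .eval_bumps(tmpl[[min(variant, length(tmpl))]]$bumps, u)
}

#' Generate one synthetic normalized pulse period
#'
#' Draws a sub-variant of the class template, jitters bump amplitudes,
#' centers and widths, applies a smooth monotone time warp, and evaluates
#' the result on the 150-point grid.
#'
#' @param label one of \code{pulseClasses()}.
#' @param seed optional seed; when NULL the current RNG state is used.
#' @return A labelled \linkS4class{PulsePeriod}.
#' @export
#' @examples
#' p <- generatePeriod("moderate", seed = 1)
generatePeriod <- function(label, seed = NULL) {
  label <- match.arg(label, pulseClasses())
  .with_seed(seed, pulsePeriod(.instance_values(label), label))
}

#' Generate a raw multi-period synthetic record with ground truth
#'
#' Concatenates \code{nPeriods} jittered class periods with jittered
#' durations (base duration drawn in 0.6–1.1 s), resampled at the record's
#' sampling rate, then adds sinusoidal baseline drift, powerline
#' interference and white measurement noise per the \linkS4class{NoiseConfig}.
#'
#' @param label one of \code{pulseClasses()}.
#' @param nPeriods number of periods (>= 2).
#' @param noise a \linkS4class{NoiseConfig}.
#' @param samplingRate sampling frequency, Hz (default 150).
#' @param seed optional seed.
#' @param corruptPeriod optional index of a period to corrupt with a large
#'   motion-artifact spike (for period-selection tests).
#' @return A list with \code{record} (\linkS4class{PulseRecord}),
#'   \code{onsets} (1-based start sample of each period), \code{template}
#'   (the clean 150-point class template of the drawn variant), and
#'   \code{clean} (the noise-free concatenated signal).
#' @export
generateRecord <- function(label, nPeriods = 8L, noise = noiseConfig(),
                           samplingRate = 150, seed = NULL,
                           corruptPeriod = NULL) {
  label <- match.arg(label, pulseClasses())
  nPeriods <- as.integer(nPeriods)
  if (nPeriods < 2L) stop("nPeriods must be >= 2")
  .with_seed(seed, {
    tmpl <- .class_templates()[[label]]
    variant <- sample.int(length(tmpl), 1L)
    base <- stats::runif(1, 0.6, 1.1)
    segs <- list()
    onsets <- integer(nPeriods)
    pos <- 1L
    for (i in seq_len(nPeriods)) {
      dur <- base * (1 + stats::rnorm(1, 0, noise@periodJitter))
      nsamp <- max(30L, as.integer(round(dur * samplingRate)))
      # beat-to-beat variability within one subject's record is much
      # smaller than the cohort-level jitter used for dataset generation
      seg <- .instance_values(label, n = nsamp, variant = variant,
                              ampJitter = 0.05, centerJitter = 0.008,
                              widthJitter = 0.08)
      if (!is.null(corruptPeriod) && i == corruptPeriod) {
        at <- sample.int(nsamp - 10L, 1L) + 5L
        seg[at + (-2:2)] <- seg[at + (-2:2)] + 3 * max(abs(seg))
      }
      onsets[i] <- pos
      segs[[i]] <- seg
      pos <- pos + nsamp
    }
    clean <- unlist(segs)
    n <- length(clean)
    tsec <- (seq_len(n) - 1) / samplingRate
    pp <- max(clean) - min(clean)
    y <- clean
    if (noise@driftRel > 0) {
      f <- stats::runif(1, noise@driftHz[1L], noise@driftHz[2L])
      y <- y + noise@driftRel * pp * sin(2 * pi * f * tsec +
                                           stats::runif(1, 0, 2 * pi))
    }
    if (noise@powerlineRel > 0)
      y <- y + noise@powerlineRel * pp *
        sin(2 * pi * noise@powerlineHz * tsec + stats::runif(1, 0, 2 * pi))
    if (is.finite(noise@snrDb)) {
      sig <- sqrt(mean((clean - mean(clean))^2))
      y <- y + stats::rnorm(n, 0, sig * 10^(-noise@snrDb / 20))
    }
    list(record = pulseRecord(y, samplingRate),
         onsets = onsets,
         template = cleanTemplate(label, variant),
         variant = variant,
         clean = clean)
  })
}

#' Generate a labelled synthetic dataset of clean periods
#'
#' The default per-class counts, 80/55/80/16/16 (total 247), scale down the
#' class proportions of the reference clinical collection
#' (800/550/800/160/160) by a factor of ten.
#'
#' @param counts named integer vector of per-class counts; names must be
#'   from \code{pulseClasses()}.
#' @param seed seed making the dataset reproducible.
#' @return A \linkS4class{PulseSet}.
#' @export
#' @examples
#' ds <- generateDataset(c(moderate = 2, taut = 2), seed = 1)
generateDataset <- function(counts = c(moderate = 80, slippery = 55,
                                       taut = 80, hollow = 16,
                                       unsmooth = 16),
                            seed = 1L) {
  if (is.null(names(counts)) || !all(names(counts) %in% pulseClasses()))
    stop("counts must be named with classes from pulseClasses()")
  if (any(counts < 1L)) stop("every requested class needs a count >= 1")
  .with_seed(seed, {
    classes <- pulseClasses()[pulseClasses() %in% names(counts)]
    vals <- list()
    labs <- character()
    for (cl in classes) {
      for (i in seq_len(counts[[cl]])) {
        vals[[length(vals) + 1L]] <- .instance_values(cl)
        labs <- c(labs, cl)
      }
    }
    PulseSet(vapply(vals, identity, numeric(150)), labs)
  })
}
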