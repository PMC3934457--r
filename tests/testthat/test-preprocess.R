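# Wavelet machinery and the preprocessing chain on generator ground truth.

test_that("db filters are orthonormal and the MODWT reconstructs exactly", {
  for (w in c("haar", "db2", "db4")) {
    h <- PulseTWED:::.scaling_filter(w)
    expect_equal(sum(h), sqrt(2), tolerance = 1e-12)
    expect_equal(sum(h^2), 1, tolerance = 1e-12)
    if (length(h) > 2)
      expect_equal(sum(h[1:(length(h) - 2)] * h[3:length(h)]), 0,
                   tolerance = 1e-12)
    set.seed(50)
    x <- stats::rnorm(300)
    dec <- PulseTWED:::.modwt(x, w, 5L)
    expect_equal(PulseTWED:::.imodwt(dec), x, tolerance = 1e-9)
  }
  expect_error(PulseTWED:::.scaling_filter("sym8"), "unsupported wavelet")
})

test_that("denoising preserves zero and length, and reduces noise RMS", {
  cfg <- preprocessConfig()
  z <- pulseRecord(rep(0, 512))
  expect_identical(tsValues(denoiseRecord(z, cfg)), rep(0, 512))
  set.seed(51)
  worse <- 0L
  for (s in 1:50) {
    g <- generateRecord("moderate", 8,
                        noise = noiseConfig(snrDb = 20, powerlineRel = 0,
                                            driftRel = 0),
                        seed = s)
    den <- denoiseRecord(g$record, cfg)
    expect_identical(length(tsValues(den)), length(tsValues(g$record)))
    rms_in <- sqrt(mean((tsValues(g$record) - g$clean)^2))
    rms_out <- sqrt(mean((tsValues(den) - g$clean)^2))
    if (rms_out >= rms_in) worse <- worse + 1L
  }
  expect_identical(worse, 0L)
  expect_error(denoiseRecord(pulseRecord(c(1, 2)), cfg), "requires at least")
})

test_that("baseline removal takes out slow drift and spares the waveform", {
  cfg <- preprocessConfig()
  fs <- 150
  t <- (0:(30 * fs - 1)) / fs
  slow <- pulseRecord(sin(2 * pi * 0.2 * t), fs)
  out <- tsValues(removeBaseline(slow, cfg))
  expect_lt(sqrt(mean(out^2)), 0.1 * sqrt(mean(tsValues(slow)^2)))
  # drift-free pulse train: distortion beyond the removed near-DC part
  # stays below 10% of signal RMS (the [0, 0.59] Hz cut that removes the
  # whole drift band necessarily grazes the slowest cardiac fundamentals;
  # a higher cut would leave 0.2 Hz drift at 14% instead)
  g <- generateRecord("moderate", 30,
                      noise = noiseConfig(snrDb = Inf, powerlineRel = 0,
                                          driftRel = 0), seed = 4)
  x <- tsValues(g$record)
  y <- tsValues(removeBaseline(g$record, cfg))
  ac <- x - mean(x)
  expect_lt(sqrt(mean((y - ac)^2)), 0.10 * sqrt(mean(ac^2)))
  expect_identical(tsValues(removeBaseline(pulseRecord(rep(0, 512)), cfg)),
                   rep(0, 512))
})

test_that("onset detection recovers generator ground truth", {
  cfg <- preprocessConfig()
  expect_error(detectOnsets(pulseRecord(rep(1, 600)), cfg),
               "insufficient beats")
  ok <- 0L
  for (s in 1:50) {
    cls <- pulseClasses()[(s %% 5) + 1]
    g <- generateRecord(cls, 8, seed = s)
    r <- removeBaseline(denoiseRecord(g$record, cfg), cfg)
    det <- onsetIndices(detectOnsets(r, cfg))
    hits <- sum(vapply(g$onsets, function(o) any(abs(det - o) <= 7.5),
                       logical(1)))
    if (hits >= 7L) ok <- ok + 1L
  }
  expect_gte(ok, 48L)
  # two clean periods: 2 or 3 onsets (trailing partial tolerated)
  g2 <- generateRecord("moderate", 2,
                       noise = noiseConfig(snrDb = Inf, powerlineRel = 0,
                                           driftRel = 0), seed = 6)
  n2 <- length(onsetIndices(detectOnsets(g2$record, cfg)))
  expect_true(n2 %in% c(2L, 3L))
})

test_that("extractPeriod picks a representative, artifact-free segment", {
  cfg <- preprocessConfig()
  # identical periods: the first segment is returned
  tmpl <- cleanTemplate("moderate")
  rec <- pulseRecord(rep(tmpl, 6))
  onsets <- new("OnsetList", indices = as.integer(seq(1, by = 150,
                                                      length.out = 6)))
  seg <- extractPeriod(rec, onsets, cfg)
  expect_equal(tsValues(seg), tmpl[1:150], tolerance = 1e-12)
  # spike-corrupted period is avoided
  dodged <- 0L
  for (s in 1:50) {
    g <- generateRecord("moderate", 8, seed = s, corruptPeriod = 4L,
                        noise = noiseConfig(snrDb = 40, powerlineRel = 0,
                                            driftRel = 0))
    onsets <- new("OnsetList", indices = as.integer(g$onsets))
    seg <- extractPeriod(g$record, onsets, cfg)
    # locate the chosen segment by its start value
    starts <- g$onsets[-length(g$onsets)]
    lens <- diff(g$onsets)
    chosen <- which(vapply(seq_along(starts), function(i)
      lens[i] == length(tsValues(seg)) &&
        isTRUE(all.equal(tsValues(g$record)[starts[i]:(starts[i] + lens[i] - 1)],
                         tsValues(seg))), logical(1)))
    if (!any(chosen == 4L)) dodged <- dodged + 1L
  }
  expect_identical(dodged, 50L)
  # single complete period comes back as-is
  one <- new("OnsetList", indices = c(1L, 151L))
  expect_identical(length(tsValues(extractPeriod(rec, one, cfg))), 150L)
})

test_that("normalizePeriod lands on 150 samples with optional amplitude scaling", {
  cfg <- preprocessConfig()
  seg <- makeTimeSeries(cleanTemplate("taut")[seq(1, 150, by = 2)])
  out <- normalizePeriod(seg, cfg)
  expect_identical(length(out@values), 150L)
  v <- stats::rnorm(150)
  expect_equal(normalizePeriod(makeTimeSeries(v), cfg)@values, v,
               tolerance = 1e-12)
  amp <- preprocessConfig(amplitudeNormalize = TRUE)
  nv <- normalizePeriod(makeTimeSeries(c(0, 2, 0)), amp)@values
  expect_identical(max(nv), 1)
  expect_identical(nv[1L], 0)
  expect_identical(nv[150L], 0)
  expect_error(normalizePeriod(makeTimeSeries(rep(1, 5)),
                               preprocessConfig(amplitudeNormalize = TRUE)),
               "zero range")
})

test_that("the full pipeline recovers the clean template and is deterministic", {
  cfg <- preprocessConfig()
  corrs <- numeric(50)
  for (s in 1:50) {
    cls <- pulseClasses()[(s %% 5) + 1]
    g <- generateRecord(cls, 8, seed = s)
    out <- preprocessPipeline(g$record, cfg)
    expect_identical(length(out@values), 150L)
    expect_true(all(is.finite(out@values)))
    corrs[s] <- stats::cor(out@values, g$template)
  }
  expect_gt(mean(corrs), 0.95)
  g <- generateRecord("slippery", 8, seed = 123)
  expect_identical(preprocessPipeline(g$record, cfg)@values,
                   preprocessPipeline(g$record, cfg)@values)
  short <- pulseRecord(cleanTemplate("moderate")[1:140])
  expect_error(preprocessPipeline(short, cfg), "stage '")
})

test_that("onset counts are stable under denoising of clean records", {
  cfg <- preprocessConfig()
  same <- 0L
  for (s in 1:50) {
    g <- generateRecord("taut", 8,
                        noise = noiseConfig(snrDb = Inf, powerlineRel = 0,
                                            driftRel = 0), seed = s)
    n1 <- length(onsetIndices(detectOnsets(g$record, cfg)))
    n2 <- length(onsetIndices(detectOnsets(denoiseRecord(g$record, cfg), cfg)))
    if (n1 == n2) same <- same + 1L
  }
  expect_identical(same, 50L)
})
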