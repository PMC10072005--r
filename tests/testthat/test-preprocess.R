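bandlimited <- function(nch = 3, seed = 1, duration = 360)
  simulateRecording(diag(nch), fs = 10, duration = duration,
                    globalAmplitude = 0, seed = seed)

test_that("detectArtifacts flags spikes and spares clean band-limited signal", {
  # clean in-band signal: essentially no false positives
  frac <- vapply(1:3, function(s)
    mean(detectArtifacts(bandlimited(seed = s))@mask), numeric(1))
  expect_lt(max(frac), 0.01)

  # a single large spike yields exactly one segment containing its sample
  rec <- bandlimited(nch = 1, seed = 4)
  x <- sigData(rec)
  spikeAt <- 1800
  x[1, spikeAt] <- x[1, spikeAt] + 20 * sd(x[1, ])
  m <- detectArtifacts(HemodynamicRecording(x, 10))
  expect_equal(nrow(m@segments), 1L)
  expect_true(m@segments$start[1] <= spikeAt && m@segments$end[1] >= spikeAt)

  # constant channels are never flagged
  const <- HemodynamicRecording(matrix(1, 2, 500), 10)
  expect_equal(nrow(detectArtifacts(const)@segments), 0L)

  expect_error(detectArtifacts(HemodynamicRecording(matrix(rnorm(20), 1), 10),
                               window = 10), "window longer")
})

test_that("spline correction removes spikes and preserves clean structure", {
  rec <- bandlimited(nch = 2, seed = 5)
  # empty mask: identity
  m0 <- new("ArtifactMask", mask = matrix(FALSE, 2, nSamples(rec)),
            segments = data.frame(channel = integer(0), start = integer(0),
                                  end = integer(0)))
  expect_identical(sigData(correctArtifactsSpline(rec, m0)), sigData(rec))

  # injected 20-SD spike reduced by >= 90% at its peak
  art <- injectArtifacts(rec, 2, 20, seed = 6)
  m <- detectArtifacts(art$recording)
  fixed <- correctArtifactsSpline(art$recording, m)
  for (i in seq_len(nrow(art$positions))) {
    p <- art$positions[i, ]
    before <- abs(sigData(art$recording)[p$channel, p$peak] -
                    sigData(rec)[p$channel, p$peak])
    after <- abs(sigData(fixed)[p$channel, p$peak] -
                   sigData(rec)[p$channel, p$peak])
    expect_lt(after, 0.1 * before)
  }

  # clean sinusoid with a flagged 1-s mid-cycle segment: correction is gentle
  t <- seq(0, 100, by = 0.1)
  y <- sin(2 * pi * 0.05 * t)
  sin2 <- HemodynamicRecording(rbind(y, y), 10)
  mask <- matrix(FALSE, 2, length(t))
  mask[1, 500:510] <- TRUE
  ms <- new("ArtifactMask", mask = mask,
            segments = data.frame(channel = 1L, start = 500L, end = 510L))
  out <- correctArtifactsSpline(sin2, ms)
  rmsDiff <- sqrt(mean((sigData(out)[1, ] - y)^2))
  expect_lt(rmsDiff, 0.1 * sqrt(mean(y^2)))

  # a whole-channel segment is left unchanged with a warning
  mall <- new("ArtifactMask", mask = matrix(TRUE, 2, length(t))[, , drop = FALSE],
              segments = data.frame(channel = 1L, start = 1L,
                                    end = length(t)))
  expect_warning(out2 <- correctArtifactsSpline(sin2, mall), "entire channel")
  expect_identical(sigData(out2)[1, ], sigData(sin2)[1, ])
})

test_that("bandpass matches the analytic Butterworth response", {
  fs <- 10
  t <- seq(0, 600 - 0.1, by = 1 / fs)
  mid <- seq(1500, length(t) - 1500) # steady-state portion

  # DC rejection (the 0.01 Hz pole settles with a ~16 s time constant,
  # so judge the residual well away from the edges)
  tl <- seq(0, 1500 - 0.1, by = 1 / fs)
  dc <- HemodynamicRecording(matrix(1, 1, length(tl)), fs)
  expect_lt(max(abs(sigData(bandpass(dc))[1, 6000:9000])), 1e-6)

  # 0.05 Hz passband tone: gain within +-1 dB of unity
  s1 <- HemodynamicRecording(matrix(sin(2 * pi * 0.05 * t), 1), fs)
  g1 <- sd(sigData(bandpass(s1))[1, mid]) / sd(sigData(s1)[1, mid])
  expect_lt(abs(20 * log10(g1)), 1)

  # 0.5 Hz stopband tone: attenuated by >= 20 dB
  s2 <- HemodynamicRecording(matrix(sin(2 * pi * 0.5 * t), 1), fs)
  g2 <- sd(sigData(bandpass(s2))[1, mid]) / sd(sigData(s2)[1, mid])
  expect_lt(20 * log10(g2), -20)

  # near-idempotence in the passband
  g11 <- sd(sigData(bandpass(bandpass(s1)))[1, mid]) /
    sd(sigData(bandpass(s1))[1, mid])
  expect_lt(abs(20 * log10(g11)), 1)

  expect_error(bandpass(s1, low = 0.2, high = 0.1), "band")
})

test_that("common average reference zeroes the cross-channel mean", {
  rec <- bandlimited(nch = 4, seed = 7, duration = 100)
  out <- commonAverageReference(rec)
  expect_lt(max(abs(colMeans(sigData(out)))), 1e-12)

  # identical channels collapse to zero
  same <- HemodynamicRecording(matrix(rep(sin(1:100 / 5), each = 2), 2,
                                      byrow = FALSE), 10)
  same@data <- rbind(sin(1:100 / 5), sin(1:100 / 5))
  expect_lt(max(abs(sigData(commonAverageReference(same)))), 1e-12)

  # a zero-mean channel pair {s, -s} is left unchanged
  s <- sin(1:200 / 7)
  pair <- HemodynamicRecording(rbind(s, -s), 10)
  expect_equal(sigData(commonAverageReference(pair)), sigData(pair),
               tolerance = 1e-12)

  expect_error(commonAverageReference(
    HemodynamicRecording(matrix(rnorm(50), 1), 10)), "single channel")
})

test_that("trimEdges removes exactly the requested seconds", {
  rec <- bandlimited(nch = 2, seed = 8)
  expect_equal(nSamples(trimEdges(rec, 5, 5)), 3500L)
  expect_identical(sigData(trimEdges(rec, 0, 0)), sigData(rec))
  short <- HemodynamicRecording(matrix(rnorm(200), 2, 100), 10)
  expect_equal(nSamples(trimEdges(short, 4, 4)), 20L)
  expect_error(trimEdges(short, 5, 5), "leaves nothing")
  # composition is additive in seconds
  expect_equal(sigData(trimEdges(trimEdges(rec, 2, 3), 3, 2)),
               sigData(trimEdges(rec, 5, 5)))
})

test_that("the composite preprocess pipeline hits the documented durations", {
  coh <- tinyCohort(seed = 9, duration = 360)
  out <- preprocess(coh[[1]])
  expect_equal(nSamples(out), 3500L)
  log <- attr(out, "preprocessLog")
  expect_false(log$fallback)
  expect_lt(max(abs(colMeans(sigData(out)))), 1e-10)

  # determinism
  out2 <- preprocess(coh[[1]])
  expect_identical(sigData(out), sigData(out2))

  # heavy corruption triggers the 180-s fallback window
  heavy <- injectArtifacts(simulateRecording(diag(4), 10, 360, seed = 1),
                           spikeRate = 60, amplitude = 30,
                           seed = 2)$recording
  outH <- preprocess(heavy)
  expect_equal(nSamples(outH), 1800L)
  expect_true(attr(outH, "preprocessLog")$fallback)

  # channel-permutation equivariance of the full pipeline
  rec <- coh[[2]]
  perm <- c(3, 1, 4, 2, 5:nChannels(rec))
  recP <- rec
  recP@data <- sigData(rec)[perm, ]
  expect_equal(sigData(preprocess(recP)), sigData(preprocess(rec))[perm, ],
               tolerance = 1e-10)
})
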