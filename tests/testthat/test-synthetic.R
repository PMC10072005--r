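test_that("makeGroupNetwork builds exact ring lattices and is deterministic", {
  # no rewiring: pure ring lattice with k = 4 neighbours
  a <- makeGroupNetwork(22, 44 / 231, 0, seed = 1)
  expect_true(all(rowSums(a) == 4))
  # closed-form lattice clustering 3(k-2)/(4(k-1)) = 0.5 for k = 4
  expect_equal(clusteringCoef(a), 0.5)
  expect_identical(a, makeGroupNetwork(22, 44 / 231, 0, seed = 99))

  # rewired: edge count preserved, deterministic under seed
  b1 <- makeGroupNetwork(20, 0.3, 0.4, seed = 5)
  b2 <- makeGroupNetwork(20, 0.3, 0.4, seed = 5)
  expect_identical(b1, b2)
  expect_equal(sum(b1) / 2, round(0.3 * 20 * 19 / 2))
  expect_true(all(b1 == t(b1)) && all(diag(b1) == 0))

  expect_error(makeGroupNetwork(22, 0.02, 0), "density too low")
})

test_that("latentWeightMatrix is symmetric, seeded, and group-ordered", {
  W <- latentWeightMatrix(22, 0.4, seed = 3)
  expect_equal(W, t(W))
  expect_true(all(diag(W) == 0))
  expect_identical(W, latentWeightMatrix(22, 0.4, seed = 3))
  # latent regularity ordering on the binary ground-truth graphs
  latC <- function(p) mean(vapply(1:15, function(s) {
    W <- latentWeightMatrix(22, p, seed = s)
    clusteringCoef(adjacency(proportionalThreshold(ZMatrix(W), 0.8)))
  }, numeric(1)))
  cH <- latC(0.65); cM <- latC(0.45); cS <- latC(0.15)
  expect_true(cS > cM && cM > cH)
})

test_that("networkToCovariance honors the binary contract and stays PD", {
  # no edges: diagonal matrix
  expect_equal(networkToCovariance(matrix(0, 4, 4), 0.5), diag(4))
  # isolated connected pair: implied correlation equals edgeStrength
  s2 <- networkToCovariance(matrix(c(0, 1, 1, 0), 2), 0.6)
  expect_equal(cov2cor(s2)[1, 2], 0.6)
  # always positive definite, even for dense adjacencies
  for (seed in 1:5) {
    a <- randomAdj(10, 0.6, seed)
    s <- networkToCovariance(a, 0.7)
    expect_gt(min(eigen(s, symmetric = TRUE, only.values = TRUE)$values), 0)
    # connected pairs get higher covariance than unconnected
    ut <- upper.tri(a)
    if (any(a[ut] == 1) && any(a[ut] == 0))
      expect_gt(min(s[ut][a[ut] == 1]), max(s[ut][a[ut] == 0]))
  }
})

test_that("simulateRecording yields band-limited series with the target geometry", {
  rec <- simulateRecording(diag(3), fs = 10, duration = 360, seed = 1)
  expect_equal(dim(sigData(rec)), c(3L, 3600L))
  expect_error(simulateRecording(diag(3), fs = 10, duration = 10),
               "at least 600")
  expect_error(simulateRecording(matrix(c(1, 2, 2, 1), 2), 10, 360),
               "positive definite")

  # independent channels: finite-sample correlations stay near zero
  # (band-limiting leaves ~60 effective samples at 350 s)
  rec <- simulateRecording(diag(5), fs = 10, duration = 350,
                           globalAmplitude = 0, seed = 2)
  r <- correlationMatrix(rec)
  expect_lt(mean(abs(r[upper.tri(r)])), 0.2)

  # a strongly connected pair is recovered within Monte-Carlo tolerance
  sig <- matrix(c(1, 0.8, 0.8, 1), 2)
  rs <- vapply(1:20, function(s) {
    rec <- simulateRecording(sig, 10, 350, globalAmplitude = 0, seed = s)
    correlationMatrix(rec)[1, 2]
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.8), 0.15)

  # determinism
  r1 <- simulateRecording(diag(3), 10, 120, seed = 9)
  r2 <- simulateRecording(diag(3), 10, 120, seed = 9)
  expect_identical(sigData(r1), sigData(r2))
})

test_that("injectArtifacts adds seeded transient spikes with exact positions", {
  rec <- simulateRecording(diag(4), 10, 360, globalAmplitude = 0, seed = 3)
  # zero rate: identity
  out0 <- injectArtifacts(rec, 0, 5)
  expect_identical(sigData(out0$recording), sigData(rec))
  expect_equal(nrow(out0$positions), 0L)

  # spike counts follow the Poisson law (rate 2/min over 6 min = 12)
  counts <- vapply(1:50, function(s)
    nrow(injectArtifacts(rec, 2, 5, seed = s)$positions), numeric(1))
  total <- sum(counts) # ~ Poisson(600)
  expect_true(abs(total - 600) < 3 * sqrt(600))

  # 20-SD spikes exceed 10x the clean channel SD at their peak
  art <- injectArtifacts(rec, 2, 20, seed = 4)
  for (i in seq_len(nrow(art$positions))) {
    p <- art$positions[i, ]
    dev <- abs(sigData(art$recording)[p$channel, p$peak] -
                 sigData(rec)[p$channel, p$peak])
    expect_gt(dev, 10 * sd(sigData(rec)[p$channel, ]))
  }
  # spikes are transient: at most 1 s support
  expect_true(all(art$positions$end - art$positions$start + 1 <=
                    samplingRate(rec)))
})

test_that("generateCohort respects group sizes, FMA rules and determinism", {
  coh <- tinyCohort(seed = 5)
  meta <- cohortMeta(coh)
  expect_equal(nrow(meta), 6L)
  expect_equal(as.vector(table(meta$group)[c("Healthy", "Mild", "MtS")]),
               c(2L, 2L, 2L))
  expect_true(all(is.na(meta$FMA[meta$group == "Healthy"])))
  expect_true(all(meta$FMA[meta$group == "Mild"] >= 85))
  expect_true(all(meta$FMA[meta$group == "MtS"] < 85))

  # no Mild subjects: nobody carries FMA >= 85
  coh0 <- generateCohort(cohortConfig(n_healthy = 2, n_mild = 0, n_mts = 2,
                                      duration = 120, seed = 1))
  expect_false(any(cohortMeta(coh0)$FMA >= 85, na.rm = TRUE))

  # byte-identical reproduction from the same seed
  coh2 <- tinyCohort(seed = 5)
  expect_identical(meta, cohortMeta(coh2))
  expect_identical(sigData(coh[[3]]), sigData(coh2[[3]]))

  # ground truth is symmetric, binary, zero-diagonal
  tr <- cohortTruth(coh)[[1]]
  expect_true(all(tr$adjacency %in% 0:1))
  expect_equal(tr$adjacency, t(tr$adjacency))

  # invalid configs are rejected
  expect_error(cohortConfig(group_rewiring = c(Healthy = 0.2, Mild = 0.4,
                                               MtS = 0.6)), "ordered")
  expect_error(cohortConfig(latent_density = 0), "latent_density")
})

test_that("cohorts round-trip through the CSV dialect", {
  coh <- tinyCohort(seed = 2, duration = 80)
  dir <- file.path(tempdir(), "cohort-rt")
  writeCohort(coh, dir)
  back <- readCohort(dir, fs = 10)
  expect_equal(length(back), length(coh))
  expect_equal(sigData(back[[4]]), sigData(coh[[4]]), tolerance = 1e-12)
  expect_equal(cohortMeta(back)$FMA, cohortMeta(coh)$FMA)
  unlink(dir, recursive = TRUE)
})
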