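#' Configuration for the synthetic resting-state cohort generator
#'
#' Bundles every knob of the synthetic cohort: group sizes, recording
#' geometry (channels, sampling rate, duration), the latent-network
#' parameters that differentiate the groups, signal and artifact scales,
#' and the master seed. Defaults reproduce the study conditions the
#' pipeline is designed for: 11 Healthy / 15 Mild / 16 MtS subjects,
#' 22 channels sampled at 10 Hz for 6 minutes, with group-dependent
#' modular segregation of the latent motor network (Healthy most
#' integrated, MtS most regular/segregated) so that clustering, local
#' efficiency and transitivity rise -- and global efficiency falls --
#' with dyskinesia severity.
#'
#' @param n_healthy,n_mild,n_mts group sizes.
#' @param n_channels number of NIRS channels (network nodes).
#' @param fs sampling rate in Hz.
#' @param duration recording length in seconds.
#' @param group_rewiring named vector of mean rewiring / integration
#'   levels per group (the knob of \code{\link{latentWeightMatrix}});
#'   must satisfy Healthy > Mild > MtS (lower = more regular and
#'   segregated = more clustered).
#' @param latent_density fraction of node pairs connected in the binary
#'   ground-truth network (the strongest-weight pairs of the latent
#'   weight matrix).
#' @param n_modules number of latent modules (motor subregions).
#' @param weight_jitter SD of per-pair latent weight noise.
#' @param edge_strength target correlation magnitude for connected pairs
#'   (before positive-definiteness loading).
#' @param global_amplitude scale of the shared superficial component,
#'   relative to the mean channel SD.
#' @param artifact_spike_rate motion-artifact events per minute.
#' @param artifact_amplitude spike peak height in multiples of the clean
#'   channel SD.
#' @param fma_coupling within-group shift of the rewiring probability per
#'   unit of normalized FMA, tying motor score to latent regularity.
#' @param rewiring_jitter SD of the per-subject rewiring noise.
#' @param group_age_mean,group_age_sd,group_male_frac named per-group age
#'   and gender distribution parameters.
#' @param seed integer master seed.
#' @return A validated list of class \code{"CohortConfig"}.
#' @examples
#' cfg <- cohortConfig(n_healthy = 2, n_mild = 2, n_mts = 2, duration = 120)
#' @export
cohortConfig <- function(n_healthy = 11, n_mild = 15, n_mts = 16,
                         n_channels = 22, fs = 10, duration = 360,
                         group_rewiring = c(Healthy = 0.65, Mild = 0.45,
                                            MtS = 0.15),
                         latent_density = 0.2,
                         n_modules = 5,
                         weight_jitter = 0.03,
                         edge_strength = 0.6,
                         global_amplitude = 1,
                         artifact_spike_rate = 0.5,
                         artifact_amplitude = 8,
                         fma_coupling = 0.06,
                         rewiring_jitter = 0.02,
                         group_age_mean = c(Healthy = 50.9, Mild = 65.3,
                                            MtS = 59.7),
                         group_age_sd = c(Healthy = 3.1, Mild = 8.1,
                                          MtS = 11.0),
                         group_male_frac = c(Healthy = 10 / 11,
                                             Mild = 13 / 15, MtS = 12 / 16),
                         seed = 1L) {
  cfg <- list(
    n_healthy = as.integer(n_healthy), n_mild = as.integer(n_mild),
    n_mts = as.integer(n_mts), n_channels = as.integer(n_channels),
    fs = fs, duration = duration, group_rewiring = group_rewiring,
    latent_density = latent_density, n_modules = as.integer(n_modules),
    weight_jitter = weight_jitter, edge_strength = edge_strength,
    global_amplitude = global_amplitude,
    artifact_spike_rate = artifact_spike_rate,
    artifact_amplitude = artifact_amplitude,
    fma_coupling = fma_coupling, rewiring_jitter = rewiring_jitter,
    group_age_mean = group_age_mean, group_age_sd = group_age_sd,
    group_male_frac = group_male_frac, seed = as.integer(seed)
  )
  class(cfg) <- "CohortConfig"
  validateCohortConfig(cfg)
  cfg
}

validateCohortConfig <- function(cfg) {
  groups <- c("Healthy", "Mild", "MtS")
  stopifnot2(all(c(cfg$n_healthy, cfg$n_mild, cfg$n_mts) >= 0) &&
             cfg$n_healthy + cfg$n_mild + cfg$n_mts > 0,
             "group sizes must be non-negative and sum to > 0")
  stopifnot2(cfg$n_channels >= 2, "need at least 2 channels")
  stopifnot2(cfg$fs > 0 && cfg$duration > 0, "fs and duration must be > 0")
  stopifnot2(cfg$latent_density > 0 && cfg$latent_density <= 1,
             "latent_density must be in (0, 1]")
  stopifnot2(cfg$edge_strength > 0 && cfg$edge_strength < 1,
             "edge_strength must be in (0, 1)")
  stopifnot2(all(groups %in% names(cfg$group_rewiring)),
             "group_rewiring needs Healthy, Mild and MtS entries")
  rw <- cfg$group_rewiring[groups]
  stopifnot2(all(rw >= 0 & rw <= 1), "rewiring probabilities must be in [0, 1]")
  stopifnot2(rw["Healthy"] > rw["Mild"] && rw["Mild"] > rw["MtS"],
             "rewiring must be ordered Healthy > Mild > MtS")
  stopifnot2(cfg$artifact_spike_rate >= 0, "artifact_spike_rate must be >= 0")
  stopifnot2(cfg$artifact_amplitude > 0, "artifact_amplitude must be > 0")
  invisible(cfg)
}

#' Generate a group-specific latent network
#'
#' Builds a ring lattice with the requested edge count (edges added in
#' order of ring distance, then node index) and then rewires each edge
#' independently with probability \code{rewiringProb} to a uniformly
#' chosen non-adjacent partner, Watts-Strogatz style. Low rewiring yields
#' the regular, highly clustered topology; high rewiring approaches a
#' random graph of the same density.
#'
#' @param nNodes number of nodes.
#' @param density fraction of the \code{nNodes*(nNodes-1)/2} possible
#'   edges present; must allow at least a full ring.
#' @param rewiringProb per-edge rewiring probability in [0, 1].
#' @param seed optional integer seed (deterministic output when given).
#' @return Symmetric 0/1 adjacency matrix with zero diagonal and exactly
#'   \code{round(density * nNodes * (nNodes - 1) / 2)} edges.
#' @examples
#' a <- makeGroupNetwork(22, 44 / 231, 0, seed = 1) # ring lattice, k = 4
#' all(rowSums(a) == 4)
#' @export
makeGroupNetwork <- function(nNodes, density, rewiringProb, seed = NULL) {
  stopifnot2(nNodes >= 3, "need at least 3 nodes")
  stopifnot2(rewiringProb >= 0 && rewiringProb <= 1,
             "rewiringProb must be in [0, 1]")
  npairs <- nNodes * (nNodes - 1) / 2
  m <- round(density * npairs)
  if (m < nNodes)
    stop("density too low: ", m, " edges cannot form the ring-lattice base (need >= ",
         nNodes, ")", call. = FALSE)
  # ring-lattice edge order: distance 1 ring first, then distance 2, ...
  maxd <- floor(nNodes / 2)
  eList <- vector("list", maxd)
  for (d in seq_len(maxd)) {
    i <- seq_len(if (2 * d == nNodes) nNodes / 2 else nNodes)
    j <- ((i - 1 + d) %% nNodes) + 1
    eList[[d]] <- cbind(pmin(i, j), pmax(i, j))
  }
  edges <- do.call(rbind, eList)[seq_len(m), , drop = FALSE]
  adj <- matrix(0L, nNodes, nNodes)
  adj[edges] <- 1L
  adj[edges[, c(2, 1), drop = FALSE]] <- 1L
  withSeed(seed, {
    for (e in seq_len(m)) {
      if (runif(1) >= rewiringProb) next
      u <- edges[e, 1]; v <- edges[e, 2]
      cand <- which(adj[u, ] == 0L)
      cand <- cand[cand != u]
      if (!length(cand)) next
      w <- if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)]
      adj[u, v] <- adj[v, u] <- 0L
      adj[u, w] <- adj[w, u] <- 1L
      edges[e, ] <- c(min(u, w), max(u, w))
    }
  })
  dimnames(adj) <- list(paste0("Ch", seq_len(nNodes)),
                        paste0("Ch", seq_len(nNodes)))
  adj
}

#' Latent connectivity weights with group-dependent modular segregation
#'
#' Builds the latent pairwise connection-strength matrix of one subject's
#' motor network. Channels are organized into modules (motor subregions);
#' within-module pairs are strongly connected, between-module pairs
#' weakly. The single group knob \code{rewiringProb} moves the network
#' from a segregated, regular topology (low values: crisp strong modules,
#' high clustering, low integration -- the moderate-to-severe profile)
#' toward an integrated one (high values: the within/between contrast
#' shrinks and a fraction \code{rewiringProb / 2} of pair weights is
#' shuffled across the network -- the healthy profile). Small Gaussian
#' jitter individualizes subjects.
#'
#' The weight of a channel pair combines four physiological layers:
#' hierarchical modularity (between-module strength decays with module
#' distance), a spatial gradient (optode neighbours share cortex, so
#' strength decays with channel distance), and a hemispheric factor
#' (cross-hemisphere pairs are weaker except homologous ones). Only the
#' modular layer depends on the group knob; the spatial and hemispheric
#' layers are common anatomy shared by all groups.
#'
#' @param nNodes number of channels.
#' @param rewiringProb integration level in [0, 1]; low = regular.
#' @param edgeStrength overall connection-strength scale in (0, 1).
#' @param seed optional integer seed.
#' @param nModules number of modules (default 5).
#' @param jitter SD of per-pair weight noise.
#' @param spatial,spatialDecay amplitude and per-step decay of the
#'   channel-distance gradient.
#' @param crossHemisphere,homologous multipliers for cross-hemisphere
#'   and homologous channel pairs.
#' @return Symmetric weight matrix (zero diagonal) in correlation units.
#' @export
latentWeightMatrix <- function(nNodes = 22, rewiringProb = 0.5,
                               edgeStrength = 0.6, seed = NULL,
                               nModules = 5, jitter = 0.04,
                               spatial = 0.15, spatialDecay = 0.7,
                               crossHemisphere = 0.15 + 0.55 * rewiringProb,
                               homologous = 0.55 + 0.55 * rewiringProb,
                               hemiBaseline = 0.2) {
  stopifnot2(rewiringProb >= 0 && rewiringProb <= 1,
             "rewiringProb must be in [0, 1]")
  stopifnot2(nModules >= 2 && nModules < nNodes,
             "nModules must be in [2, nNodes)")
  mod <- sort(rep_len(seq_len(nModules), nNodes))
  p <- rewiringProb
  within <- edgeStrength * (17 / 15 - 2 / 3 * p)
  between <- edgeStrength * (1 / 15 + 1 / 2 * p)
  md <- outer(mod, mod, function(a, b) pmin(abs(a - b), nModules - abs(a - b)))
  cd <- outer(seq_len(nNodes), seq_len(nNodes),
              function(i, j) pmin(abs(i - j), nNodes - abs(i - j)))
  W <- ifelse(md == 0, within, between * (1.3 - 0.3 * md)) +
    spatial * spatialDecay^(cd - 1)
  half <- ceiling(nNodes / 2)
  hemi <- rep(1:2, c(half, nNodes - half))
  sameH <- outer(hemi, hemi, "==")
  hf <- ifelse(sameH, 1,
               ifelse(abs(outer(seq_len(nNodes), seq_len(nNodes), "-")) ==
                        half, homologous, crossHemisphere))
  W <- W * hf + hemiBaseline * sameH
  withSeed(seed, {
    ut <- which(upper.tri(W))
    W[ut] <- W[ut] + rnorm(length(ut), 0, jitter)
    pick <- ut[runif(length(ut)) < p / 2]
    if (length(pick) > 1) {
      v <- W[pick]
      W[pick] <- v[sample(length(v))]
    }
  })
  W[lower.tri(W)] <- t(W)[lower.tri(W)]
  diag(W) <- 0
  dimnames(W) <- list(paste0("Ch", seq_len(nNodes)),
                      paste0("Ch", seq_len(nNodes)))
  W
}

#' Map a latent network to a target signal covariance
#'
#' For a binary adjacency, connected channel pairs receive off-diagonal
#' covariance \code{edgeStrength} and unconnected pairs 0; a weighted
#' matrix (in correlation units) is used as-is with
#' \code{edgeStrength = 1}. The diagonal starts at \code{diagonalLoad}
#' and is inflated automatically until the matrix is positive definite,
#' so the implied correlation of connected pairs is
#' \code{edgeStrength / diag} (exactly \code{edgeStrength} whenever no
#' extra loading is needed, e.g. for an isolated pair).
#'
#' @param adjacency symmetric 0/1 matrix, or a symmetric weight matrix
#'   from \code{\link{latentWeightMatrix}}.
#' @param edgeStrength target covariance for connected pairs, in (0, 1];
#'   use 1 for an already-weighted matrix.
#' @param diagonalLoad initial diagonal value.
#' @return Symmetric positive-definite covariance matrix.
#' @export
networkToCovariance <- function(adjacency, edgeStrength, diagonalLoad = 1) {
  a <- as.matrix(adjacency)
  stopifnot2(isTRUE(all.equal(a, t(a))), "adjacency must be symmetric")
  stopifnot2(diagonalLoad > 0, "diagonalLoad must be > 0")
  s <- edgeStrength * a
  diag(s) <- diagonalLoad
  repeat {
    ev <- min(eigen(s, symmetric = TRUE, only.values = TRUE)$values)
    if (ev > 1e-8) break
    diag(s) <- diag(s) + (abs(ev) + 0.01 * diagonalLoad)
  }
  s
}

#' Simulate one band-limited resting-state recording
#'
#' Draws samples from a zero-mean multivariate normal with the given
#' channel covariance, band-pass filters every channel into the
#' low-frequency hemodynamic band (the cross-channel correlation
#' structure is preserved because the same linear filter is applied to
#' all channels), and adds a shared band-limited superficial component of
#' scale \code{globalAmplitude} (relative to the mean channel SD) that a
#' common-average-reference filter can remove. The output is scaled by a
#' single common factor so channel fluctuations are of realistic
#' magnitude (median SD 0.02 mM·mm).
#'
#' @param covariance positive-definite channel covariance matrix.
#' @param fs sampling rate in Hz.
#' @param duration recording length in seconds; \code{fs * duration} must
#'   be at least 600 samples.
#' @param globalAmplitude superficial-component scale (0 disables it).
#' @param seed optional integer seed.
#' @param band analysis band in Hz used to shape the spectrum.
#' @param subjectId,chromophore passed to the recording.
#' @return A \linkS4class{HemodynamicRecording} of
#'   \code{nrow(covariance)} channels by \code{round(fs * duration)}
#'   samples.
#' @export
simulateRecording <- function(covariance, fs = 10, duration = 360,
                              globalAmplitude = 1, seed = NULL,
                              band = c(0.01, 0.1), subjectId = "sim",
                              chromophore = "HbO2") {
  sigma <- as.matrix(covariance)
  nch <- nrow(sigma)
  nt <- round(fs * duration)
  stopifnot2(nt >= 600, "duration * fs must be at least 600 samples")
  ev <- min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 0) stop("covariance must be positive definite", call. = FALSE)
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  x <- withSeed(seed, {
    raw <- MASS::mvrnorm(nt, mu = rep(0, nch), Sigma = sigma)
    filt <- apply(raw, 2, function(ch) signal::filtfilt(bf, ch))
    x <- t(filt) # channels x samples
    if (globalAmplitude > 0) {
      g <- signal::filtfilt(bf, rnorm(nt))
      g <- g / sd(g) * globalAmplitude * mean(apply(x, 1, sd))
      x <- sweep(x, 2, g, "+")
    }
    x
  })
  unit <- 0.02 / median(apply(x, 1, sd))
  HemodynamicRecording(x * unit, fs = fs, subjectId = subjectId,
                       chromophore = chromophore)
}

#' Inject transient motion-artifact spikes
#'
#' Adds short (at most 1 s) Gaussian-bump deflections at Poisson-random
#' times on randomly chosen channels, with peak height
#' \code{amplitude} times the channel's clean SD and random sign.
#'
#' @param recording a \linkS4class{HemodynamicRecording}.
#' @param spikeRate events per minute (0 leaves the recording untouched).
#' @param amplitude peak height in multiples of the channel SD; > 0.
#' @param seed optional integer seed.
#' @return A list with elements \code{recording} (corrupted copy) and
#'   \code{positions} (data.frame channel, start, end, peak sample, peak
#'   height).
#' @export
injectArtifacts <- function(recording, spikeRate, amplitude, seed = NULL) {
  stopifnot2(amplitude > 0, "amplitude must be > 0")
  x <- sigData(recording)
  fs <- samplingRate(recording)
  nt <- ncol(x)
  minutes <- nt / fs / 60
  empty <- data.frame(channel = integer(0), start = integer(0),
                      end = integer(0), peak = integer(0),
                      height = numeric(0))
  if (spikeRate == 0)
    return(list(recording = recording, positions = empty))
  pos <- empty
  withSeed(seed, {
    nspike <- rpois(1, spikeRate * minutes)
    for (s in seq_len(nspike)) {
      ch <- sample.int(nrow(x), 1)
      width <- max(2L, round(runif(1, 0.2, 0.8) * fs / 2)) # half-width, <= 1 s total
      center <- sample.int(nt, 1)
      idx <- max(1, center - width):min(nt, center + width)
      height <- amplitude * sd(x[ch, ]) * sample(c(-1, 1), 1)
      bump <- height * exp(-0.5 * ((idx - center) / (width / 3))^2)
      x[ch, idx] <- x[ch, idx] + bump
      pos <- rbind(pos, data.frame(channel = ch, start = min(idx),
                                   end = max(idx), peak = center,
                                   height = height))
    }
  })
  out <- recording
  out@data <- x
  list(recording = out, positions = pos)
}

#' Generate a full synthetic cohort
#'
#' Draws, per subject: an FMA score within the group's clinical range
#' (Mild >= 85, MtS < 85, absent for Healthy), a latent rewiring /
#' integration level centred on the group mean and shifted within-group
#' by the subject's FMA (higher FMA = less regular = more integrated),
#' the latent modular weight matrix and its binary ground-truth network,
#' the implied channel covariance, a band-limited recording with a shared
#' superficial component, and injected motion artifacts. Ages and genders follow per-group distributions. Everything
#' is reproducible from the config seed, and adding subjects does not
#' perturb existing subjects' random streams.
#'
#' @param config a \code{\link{cohortConfig}}.
#' @return A \linkS4class{NirsCohort}; per-subject ground truth (latent
#'   adjacency, rewiring probability, FMA) is kept in the \code{truth}
#'   slot.
#' @examples
#' coh <- generateCohort(cohortConfig(n_healthy = 1, n_mild = 1, n_mts = 1,
#'                                    duration = 120, seed = 7))
#' cohortMeta(coh)
#' @export
generateCohort <- function(config) {
  validateCohortConfig(config)
  groups <- rep(c("Healthy", "Mild", "MtS"),
                c(config$n_healthy, config$n_mild, config$n_mts))
  n <- length(groups)
  fmaRange <- list(Mild = c(85, 99), MtS = c(15, 84))
  recordings <- vector("list", n)
  truth <- vector("list", n)
  meta <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)), group = groups,
    age = NA_real_, gender = NA_character_, FMA = NA_real_,
    rewiring = NA_real_, sim_seed = NA_integer_,
    stringsAsFactors = FALSE
  )
  for (k in seq_len(n)) {
    g <- groups[k]
    demoSeed <- deriveSeed(config$seed, 100, k)
    fma <- NA_real_
    rw <- withSeed(demoSeed, {
      if (g == "Healthy") {
        config$group_rewiring[[g]] + rnorm(1, 0, 0.05)
      } else {
        r <- fmaRange[[g]]
        fma <- round(runif(1, r[1], r[2]))
        mid <- mean(r); half <- diff(r) / 2
        config$group_rewiring[[g]] +
          config$fma_coupling * (fma - mid) / half +
          rnorm(1, 0, config$rewiring_jitter)
      }
    })
    rw <- min(max(rw, 0.01), 0.95)
    age <- withSeed(deriveSeed(config$seed, 101, k), {
      a <- rnorm(1, config$group_age_mean[[g]], config$group_age_sd[[g]])
      gender <- if (runif(1) < config$group_male_frac[[g]]) "male" else "female"
      c(round(min(max(a, 30), 80)), gender)
    })
    W <- latentWeightMatrix(config$n_channels, rewiringProb = rw,
                            edgeStrength = config$edge_strength,
                            seed = deriveSeed(config$seed, 102, k),
                            nModules = config$n_modules,
                            jitter = config$weight_jitter)
    adjacency <- adjacency(proportionalThreshold(
      ZMatrix(W), 1 - config$latent_density))
    sigma <- networkToCovariance(W, edgeStrength = 1)
    simSeed <- deriveSeed(config$seed, 103, k)
    rec <- simulateRecording(sigma, fs = config$fs,
                             duration = config$duration,
                             globalAmplitude = config$global_amplitude,
                             seed = simSeed,
                             subjectId = meta$subject_id[k])
    art <- injectArtifacts(rec, config$artifact_spike_rate,
                           config$artifact_amplitude,
                           seed = deriveSeed(config$seed, 104, k))
    recordings[[k]] <- art$recording
    truth[[k]] <- list(adjacency = adjacency, rewiring = rw, fma = fma,
                       artifacts = art$positions)
    meta$age[k] <- as.numeric(age[1])
    meta$gender[k] <- age[2]
    meta$FMA[k] <- fma
    meta$rewiring[k] <- rw
    meta$sim_seed[k] <- simSeed
  }
  new("NirsCohort", recordings = recordings, meta = meta, truth = truth)
}

#' Write a cohort to per-subject CSV files plus a metadata table
#'
#' Signal files have one column per channel (header \code{Ch1..ChN}) and
#' one row per sample; the metadata table is \code{meta.csv}.
#'
#' @param cohort a \linkS4class{NirsCohort}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- cohortMeta(cohort)
  paths <- character(length(cohort))
  for (k in seq_len(length(cohort))) {
    rec <- cohort[[k]]
    df <- as.data.frame(t(sigData(rec)))
    names(df) <- channelNames(rec)
    paths[k] <- file.path(dir, paste0(meta$subject_id[k], ".csv"))
    write.csv(df, paths[k], row.names = FALSE)
  }
  metaPath <- file.path(dir, "meta.csv")
  write.csv(meta, metaPath, row.names = FALSE)
  invisible(c(paths, metaPath))
}

#' Read one subject's signal CSV (samples x channels with a header row)
#'
#' @param path CSV path.
#' @param fs sampling rate in Hz of the stored signal.
#' @param subjectId optional identifier; defaults to the file name.
#' @param chromophore chromophore label.
#' @return A \linkS4class{HemodynamicRecording}.
#' @export
readRecording <- function(path, fs, subjectId = NULL,
                          chromophore = "HbO2") {
  df <- read.csv(path, check.names = FALSE)
  if (is.null(subjectId)) subjectId <- sub("\\.csv$", "", basename(path))
  if (anyNA(df)) stop("missing values in ", path, call. = FALSE)
  HemodynamicRecording(t(as.matrix(df)), fs = fs, subjectId = subjectId,
                       chromophore = chromophore)
}

#' Read a cohort previously written by \code{writeCohort}
#'
#' @param dir directory containing per-subject CSVs and \code{meta.csv}.
#' @param fs sampling rate in Hz.
#' @return A \linkS4class{NirsCohort} (without ground truth).
#' @export
readCohort <- function(dir, fs) {
  meta <- read.csv(file.path(dir, "meta.csv"), stringsAsFactors = FALSE)
  recordings <- lapply(meta$subject_id, function(sid)
    readRecording(file.path(dir, paste0(sid, ".csv")), fs = fs,
                  subjectId = sid))
  new("NirsCohort", recordings = recordings, meta = meta, truth = list())
}
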