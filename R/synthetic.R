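#' Construct a stimulation pattern specification
#'
#' @param label pattern label token (e.g. \code{"F10"}, \code{"vB"}).
#' @param modality \code{"tactile"}, \code{"visual"} or
#'   \code{"visuotactile"}.
#' @param duration pattern duration in ms.
#' @param pulseTimes pulse onset times in ms since pattern onset.
#' @param colorSeq integer colour index (1-4) per pulse, visual patterns
#'   only.
#' @param condition condition flag (\code{"+V"}, \code{"-V"} or \code{""}).
#' @return a \linkS4class{PatternSpec}.
#' @export
patternSpec <- function(label, modality, duration, pulseTimes,
                        colorSeq = integer(0), condition = "") {
  new("PatternSpec", label = label, modality = modality,
      duration = as.numeric(duration), pulseTimes = as.numeric(pulseTimes),
      colorSeq = as.integer(colorSeq), condition = condition)
}

#' Default pattern sets of the emulated experiment
#'
#' Builds the stimulation pattern sets the generator emulates. The tactile
#' set holds four patterns labelled F5, F10, F20 and Finf: pulse trains
#' whose inter-pulse interval shrinks with the nominal frequency label, with
#' durations between 200 and 340 ms; Finf is a quasi-continuous train. The
#' visual set holds four patterns vA-vD, each 215 ms long with 8 colour
#' pulses of 5 ms at 25 ms spacing (two pulses per colour); the patterns
#' differ only in their colour sequence. The visuo-tactile set pairs every
#' tactile pattern with a +V and a -V condition: +V trials carry a
#' simultaneous non-patterned visual pulse train, modelled as a
#' rate-conserving within-window redistribution of the tactile response
#' (see \code{\link{visualModulation}}).
#'
#' @param type \code{"tactile"}, \code{"visual"} or \code{"visuotactile"}.
#' @return list of \linkS4class{PatternSpec}.
#' @export
defaultPatternSet <- function(type = c("tactile", "visual",
                                       "visuotactile")) {
  type <- match.arg(type)
  tactile <- list(
    patternSpec("F5",   "tactile", 340, seq(0, 320, by = 80)),
    patternSpec("F10",  "tactile", 300, seq(0, 280, by = 40)),
    patternSpec("F20",  "tactile", 250, seq(0, 240, by = 20)),
    patternSpec("Finf", "tactile", 200, seq(0, 195, by = 5)))
  if (type == "tactile") return(tactile)
  if (type == "visual") {
    pulses <- seq(0, by = 25, length.out = 8)
    seqs <- list(vA = c(1L, 2L, 3L, 4L, 1L, 2L, 3L, 4L),
                 vB = c(4L, 3L, 2L, 1L, 4L, 3L, 2L, 1L),
                 vC = c(1L, 3L, 2L, 4L, 2L, 4L, 1L, 3L),
                 vD = c(2L, 4L, 1L, 3L, 3L, 1L, 4L, 2L))
    return(lapply(names(seqs), function(nm)
      patternSpec(nm, "visual", 215, pulses, colorSeq = seqs[[nm]])))
  }
  c(lapply(tactile, function(p)
      patternSpec(p@label, "visuotactile", p@duration, p@pulseTimes,
                  condition = "-V")),
    lapply(tactile, function(p)
      patternSpec(p@label, "visuotactile", p@duration, p@pulseTimes,
                  condition = "+V")))
}

#' Construct a synthetic session configuration
#'
#' Defaults emulate one recording session of the modelled experiment at its
#' published design: 4 tactile patterns repeated 200 times each at about
#' 1.8 s (uniformly jittered by +/- 0.2 s), with strongly fluctuating
#' shared spontaneous dynamics (12 OU latent factors, 15 ms timescale) as
#' seen in synchronised cortical states under anaesthesia. See the package
#' vignette for the rationale behind each default.
#'
#' @param nNeurons number of neurons.
#' @param sessionLength seconds; \code{NA} (default) derives it from the
#'   stimulation timeline.
#' @param baselineRateRange Hz pair for the uniform baseline draw.
#' @param nLatents,latentTimescale,latentSd spontaneous latent-factor count,
#'   OU timescale (ms) and total log-rate SD.
#' @param patternSet list of \linkS4class{PatternSpec}; defaults to the
#'   tactile set.
#' @param repsPerPattern repetitions per pattern.
#' @param interStimulusInterval,isiJitter onset spacing in seconds (mean and
#'   uniform half-width).
#' @param evokedGain evoked effect size (peak evoked rate add, in units of
#'   the mean baseline rate).
#' @param visualGainMod strength of the +V within-window redistribution
#'   (0 disables it; must stay below 1).
#' @param persistenceTau,persistenceAmplitude post-offset persistence decay
#'   (ms; 0 disables) and amplitude (units of mean baseline rate).
#' @param refractoryMs absolute refractory period of the emitted trains,
#'   ms (0 for a pure Poisson process).
#' @param seed integer RNG seed.
#' @return a \linkS4class{SimConfig}.
#' @export
simConfig <- function(nNeurons = 60L, sessionLength = NA_real_,
                      baselineRateRange = c(4, 12), nLatents = 12L,
                      latentTimescale = 15, latentSd = 1.8,
                      patternSet = defaultPatternSet("tactile"),
                      repsPerPattern = 200L,
                      interStimulusInterval = 1.8, isiJitter = 0.2,
                      evokedGain = 3, visualGainMod = 0.8,
                      persistenceTau = 150, persistenceAmplitude = 10,
                      refractoryMs = 2, seed = 1L) {
  new("SimConfig", nNeurons = as.integer(nNeurons),
      sessionLength = as.numeric(sessionLength),
      baselineRateRange = as.numeric(baselineRateRange),
      nLatents = as.integer(nLatents),
      latentTimescale = as.numeric(latentTimescale),
      latentSd = as.numeric(latentSd), patternSet = patternSet,
      repsPerPattern = as.integer(repsPerPattern),
      interStimulusInterval = as.numeric(interStimulusInterval),
      isiJitter = as.numeric(isiJitter),
      evokedGain = as.numeric(evokedGain),
      visualGainMod = as.numeric(visualGainMod),
      persistenceTau = as.numeric(persistenceTau),
      persistenceAmplitude = as.numeric(persistenceAmplitude),
      refractoryMs = as.numeric(refractoryMs), seed = as.integer(seed))
}

#' Post-offset persistence perturbation
#'
#' Pattern-specific rate perturbation after stimulus offset: an
#' exponentially decaying push of the population rate along a fixed
#' direction associated with the pattern label,
#' \code{amplitude * exp(-t / tau) * direction}. With a unit-norm
#' direction the vector magnitude at time t equals
#' \code{amplitude * exp(-t / tau)}; \code{amplitude = 0} gives the zero
#' vector and \code{tau = 0} disables the term entirely.
#'
#' @param tSinceOffset numeric vector of times since stimulus offset, ms
#'   (all >= 0).
#' @param amplitude perturbation amplitude.
#' @param tau decay time constant in ms (>= 0).
#' @param direction numeric direction vector (one entry per neuron);
#'   normally unit-norm, see \code{\link{patternDirections}}.
#' @return matrix \code{length(tSinceOffset)} x \code{length(direction)}.
#' @export
persistenceTerm <- function(tSinceOffset, amplitude, tau, direction) {
  if (tau < 0) stop("tau must be >= 0")
  if (any(tSinceOffset < 0)) stop("tSinceOffset must be >= 0")
  if (tau == 0 || amplitude == 0)
    return(matrix(0, length(tSinceOffset), length(direction)))
  outer(amplitude * exp(-tSinceOffset / tau), direction)
}

#' Fixed persistence directions per pattern label
#'
#' Draws one fixed non-negative unit-norm direction vector per pattern
#' label, deterministically from the seed. Non-negative entries keep the
#' perturbed rate positive without clipping; distinct labels get distinct
#' directions.
#'
#' @param labels character vector of pattern labels.
#' @param nNeurons number of neurons.
#' @param seed integer seed.
#' @return named list of unit-norm numeric vectors.
#' @export
patternDirections <- function(labels, nNeurons, seed) {
  labels <- unique(labels)
  set.seed(seed)
  dirs <- lapply(labels, function(l) {
    u <- abs(stats::rnorm(nNeurons))
    u / sqrt(sum(u^2))
  })
  names(dirs) <- labels
  dirs
}

#' Visual modulation of a tactile response profile
#'
#' Models the effect of a simultaneous non-patterned visual pulse train on
#' a tactile response (+V trials) as a pure redistribution of firing rate
#' within the first 300 ms of the response window: each neuron's profile is
#' reweighted in time by a smooth periodic weight (with a neuron-specific
#' phase) and then rescaled so that its window-integrated rate is exactly
#' conserved. Coarse (300 ms) binning therefore provably removes the +V/-V
#' difference, while fine binning retains it.
#'
#' @param profile bins x neurons rate profile at 1 ms resolution.
#' @param visualGainMod modulation strength in [0, 1); 0 returns the
#'   profile unchanged.
#' @param modWindow portion of the window that is reweighted, ms
#'   (default 300).
#' @return modified profile of identical dimensions; column sums over the
#'   modulated portion conserved to machine precision.
#' @export
visualModulation <- function(profile, visualGainMod, modWindow = 300) {
  if (visualGainMod == 0) return(profile)
  if (visualGainMod < 0 || visualGainMod >= 1)
    stop("visualGainMod must lie in [0, 1)")
  nb <- min(nrow(profile), modWindow)
  n <- ncol(profile)
  tt <- seq_len(nb)
  # golden-ratio phase spread: deterministic, neuron-specific
  phase <- 2 * pi * ((seq_len(n) * 0.6180339887498949) %% 1)
  w <- 1 + visualGainMod *
    sin(outer(2 * pi * tt / nb, rep(1, n)) + rep(phase, each = nb))
  seg <- profile[tt, , drop = FALSE]
  mod <- seg * w
  s0 <- colSums(seg)
  s1 <- colSums(mod)
  scale <- ifelse(s1 > 0, s0 / s1, 1)
  profile[tt, ] <- sweep(mod, 2L, scale, `*`)
  profile
}

# per-neuron evoked rate profiles for one pattern (bins x neurons):
# gamma-shaped transient (shape 2, scale 5 ms, peak-normalised) per pulse,
# shifted by each neuron's latency
.buildProfile <- function(spec, gains, latency, colorWeights = NULL) {
  nb <- as.integer(spec@duration)
  n <- length(gains)
  kern <- function(t) ifelse(t > 0, (t / 5) * exp(1 - t / 5), 0)
  prof <- matrix(0, nb, n)
  tt <- seq_len(nb) - 0.5
  for (p in seq_along(spec@pulseTimes)) {
    tp <- spec@pulseTimes[p]
    g <- gains
    if (!is.null(colorWeights) && length(spec@colorSeq) >= p)
      g <- gains * colorWeights[, spec@colorSeq[p]]
    # each neuron sees the pulse with its own latency
    K <- kern(outer(tt - tp, latency, `-`))
    prof <- prof + K * rep(g, each = nb)
  }
  prof
}

#' Generate a synthetic session
#'
#' Draws a full session from the generative model described in
#' \code{\link{simConfig}}: a randomised stimulus timeline (every pattern
#' repeated exactly \code{repsPerPattern} times), Ornstein-Uhlenbeck latent
#' factors driving shared log-rate fluctuations, pattern-specific evoked
#' transients (with +V modulation on visuo-tactile +V trials), a
#' pattern-specific exponentially decaying persistence term after stimulus
#' offset, and inhomogeneous-Poisson spike emission on a 1 ms rate grid
#' with spike times jittered uniformly within the bin and reported at
#' 0.1 ms resolution. Identical configurations (including the seed)
#' regenerate bit-identical sessions.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return a \linkS4class{SpikeSession}.
#' @export
generateSession <- function(config) {
  validObject(config)
  set.seed(config@seed)
  n <- config@nNeurons
  specs <- config@patternSet
  nPat <- length(specs)

  # --- stimulus timeline ---------------------------------------------------
  if (nPat > 0L) {
    minGap <- config@interStimulusInterval - config@isiJitter
    if (minGap <= 1.3)
      stop("inter-stimulus interval too short: gaps must exceed the ",
           "1000 ms post + 300 ms pre window")
    nEvents <- nPat * config@repsPerPattern
    order <- sample(rep(seq_len(nPat), config@repsPerPattern))
    gaps <- config@interStimulusInterval +
      stats::runif(nEvents - 1L, -config@isiJitter, config@isiJitter)
    onsets <- round(cumsum(c(2, gaps)), 3)  # aligned to the 1 ms grid
    durs <- vapply(specs, function(s) s@duration, 0)
    log <- data.frame(
      onset = onsets,
      label = vapply(specs, function(s) s@label, "")[order],
      modality = vapply(specs, function(s) s@modality, "")[order],
      duration = durs[order],
      condition = vapply(specs, function(s) s@condition, "")[order],
      stringsAsFactors = FALSE)
    sessionLength <- if (is.na(config@sessionLength))
      ceiling(max(onsets) + 1.5) else config@sessionLength
    if (max(onsets) + 1.3 > sessionLength)
      stop("sessionLength too short to fit all stimulation events")
  } else {
    log <- data.frame(onset = numeric(0), label = character(0),
                      modality = character(0), duration = numeric(0),
                      condition = character(0), stringsAsFactors = FALSE)
    if (is.na(config@sessionLength))
      stop("sessionLength must be given when the pattern set is empty")
    sessionLength <- config@sessionLength
  }
  Tms <- as.integer(round(sessionLength * 1000))

  # --- neuron parameters ---------------------------------------------------
  base <- stats::runif(n, config@baselineRateRange[1L],
                       config@baselineRateRange[2L])
  L <- if (config@nLatents > 0L)
    matrix(stats::rnorm(n * config@nLatents,
                        sd = config@latentSd / sqrt(config@nLatents)),
           n, config@nLatents) else matrix(0, n, 0)
  sig2 <- rowSums(L^2)

  # evoked gains: per-neuron tactile responsiveness and colour tuning
  tactGain <- abs(stats::rnorm(n)) * stats::rbinom(n, 1L, 0.8)
  colorWeights <- matrix(abs(stats::rnorm(n * 4L)), n, 4L) *
    matrix(stats::rbinom(n * 4L, 1L, 0.6), n, 4L)
  latency <- stats::runif(n, 3, 15)

  rateScale <- mean(base)
  profiles <- lapply(specs, function(s) {
    P <- .buildProfile(s, tactGain, latency,
                       if (s@modality == "visual") colorWeights else NULL)
    P <- P * config@evokedGain * rateScale
    if (s@modality == "visuotactile" && s@condition == "+V")
      P <- visualModulation(P, config@visualGainMod)
    P
  })
  dirs <- if (nPat > 0L) {
    labs <- unique(vapply(specs, function(s) s@label, ""))
    d <- lapply(labs, function(l) {
      u <- abs(stats::rnorm(n)); u / sqrt(sum(u^2))
    })
    names(d) <- labs
    d
  } else list()

  # --- latent factors ------------------------------------------------------
  if (config@nLatents > 0L) {
    a <- exp(-1 / config@latentTimescale)
    innovSd <- sqrt(1 - a^2)
    z <- matrix(stats::rnorm(Tms * config@nLatents), Tms, config@nLatents)
    z[1L, ] <- z[1L, ]  # stationary start: first row already N(0, 1)
    for (j in seq_len(config@nLatents))
      z[, j] <- as.numeric(stats::filter(z[, j] * innovSd, a,
                                         method = "recursive",
                                         init = z[1L, j]))
  } else z <- NULL

  # --- additive evoked/persistence schedule per event ----------------------
  persistLen <- if (config@persistenceTau > 0 &&
                    config@persistenceAmplitude != 0)
    as.integer(min(6 * config@persistenceTau, 900)) else 0L

  # --- chunked rate assembly and Poisson emission --------------------------
  chunk <- 120000L
  spkNeuron <- vector("list", 64L); spkTime <- vector("list", 64L)
  nOut <- 0L
  evOnsetMs <- as.integer(round(log$onset * 1000))
  evPat <- if (nPat > 0L) order else integer(0)
  for (lo in seq.int(1L, Tms, by = chunk)) {
    hi <- min(lo + chunk - 1L, Tms)
    idx <- lo:hi
    if (!is.null(z)) {
      lograte <- z[idx, , drop = FALSE] %*% t(L)
      lograte <- sweep(lograte, 2L, log(base) - sig2 / 2, `+`)
      rate <- exp(lograte)
    } else {
      rate <- matrix(base, length(idx), n, byrow = TRUE)
    }
    if (nPat > 0L) {
      for (e in seq_along(evOnsetMs)) {
        P <- profiles[[evPat[e]]]
        st <- evOnsetMs[e] + 1L            # first ms bin of the stimulus
        en <- st + nrow(P) - 1L
        # evoked transient
        o1 <- max(st, lo); o2 <- min(en, hi)
        if (o1 <= o2)
          rate[(o1 - lo + 1L):(o2 - lo + 1L), ] <-
            rate[(o1 - lo + 1L):(o2 - lo + 1L), ] +
            P[(o1 - st + 1L):(o2 - st + 1L), , drop = FALSE]
        # persistence after offset
        if (persistLen > 0L) {
          ps <- en + 1L; pe <- en + persistLen
          p1 <- max(ps, lo); p2 <- min(pe, hi)
          if (p1 <= p2) {
            tRel <- (p1:p2) - ps  # ms since offset
            rate[(p1 - lo + 1L):(p2 - lo + 1L), ] <-
              rate[(p1 - lo + 1L):(p2 - lo + 1L), ] +
              persistenceTerm(tRel,
                config@persistenceAmplitude * rateScale,
                config@persistenceTau, dirs[[log$label[e]]])
          }
        }
      }
    }
    counts <- matrix(stats::rpois(length(rate), rate * 1e-3),
                     nrow(rate), n)
    nz <- which(counts > 0L)
    if (length(nz)) {
      cnt <- counts[nz]
      binRow <- ((nz - 1L) %% nrow(rate)) + 1L
      neurCol <- ((nz - 1L) %/% nrow(rate)) + 1L
      reps <- rep.int(seq_along(nz), cnt)
      tms <- (lo - 1L + binRow[reps] - 1L + stats::runif(length(reps))) / 1000
      nOut <- nOut + 1L
      spkNeuron[[nOut]] <- neurCol[reps]
      spkTime[[nOut]] <- round(tms, 4)  # 0.1 ms resolution
    }
  }
  neuron <- unlist(spkNeuron[seq_len(nOut)], use.names = FALSE)
  time <- unlist(spkTime[seq_len(nOut)], use.names = FALSE)
  ord <- order(neuron, time)
  neuron <- neuron[ord]; time <- time[ord]
  dup <- c(FALSE, diff(time) == 0 & diff(neuron) == 0L)
  neuron <- as.integer(neuron[!dup]); time <- time[!dup]
  if (config@refractoryMs > 0 && length(time)) {
    dead <- config@refractoryMs / 1000 - 1e-9
    keep <- logical(length(time))
    last <- -Inf; lastN <- 0L
    for (i in seq_along(time)) {
      if (neuron[i] != lastN || time[i] - last >= dead) {
        keep[i] <- TRUE
        last <- time[i]; lastN <- neuron[i]
      }
    }
    neuron <- neuron[keep]; time <- time[keep]
  }
  sp <- data.frame(neuron = neuron, time = time)
  new("SpikeSession", spikes = sp, stimulusLog = log,
      sessionLength = sessionLength, nNeurons = n)
}

#' Read and write spike tables, stimulus logs and configurations
#'
#' Sessions are persisted as two headered comma-separated files: the spike
#' table (\code{neuron,time}, times in seconds with 6 decimals) and the
#' stimulus log (\code{onset,label,modality,duration,condition}).
#' Configurations round-trip through flat YAML (pattern sets are rebuilt
#' from \code{\link{defaultPatternSet}} by type).
#'
#' @param session a \linkS4class{SpikeSession}.
#' @param spikeFile,logFile file paths.
#' @name session-io
NULL

#' @rdname session-io
#' @export
writeSession <- function(session, spikeFile, logFile) {
  sp <- spikes(session)
  sp$time <- sprintf("%.6f", sp$time)
  utils::write.csv(sp, spikeFile, row.names = FALSE, quote = FALSE)
  utils::write.csv(stimulusLog(session), logFile, row.names = FALSE,
                   quote = FALSE)
  invisible(c(spikeFile, logFile))
}

#' @rdname session-io
#' @param sessionLength session length in seconds; when \code{NA} it is
#'   taken as the last spike or stimulus time plus 1.5 s.
#' @param nNeurons neuron count; when \code{NA}, the largest id present.
#' @export
readSession <- function(spikeFile, logFile, sessionLength = NA_real_,
                        nNeurons = NA_integer_) {
  sp <- utils::read.csv(spikeFile, colClasses = c("integer", "numeric"))
  lg <- utils::read.csv(logFile, colClasses = c("numeric", "character",
    "character", "numeric", "character"))
  if (is.na(sessionLength))
    sessionLength <- max(c(sp$time, lg$onset + lg$duration / 1000, 0)) + 1.5
  if (is.na(nNeurons)) nNeurons <- max(sp$neuron)
  ord <- order(sp$neuron, sp$time)
  new("SpikeSession", spikes = sp[ord, , drop = FALSE],
      stimulusLog = lg, sessionLength = sessionLength,
      nNeurons = as.integer(nNeurons))
}

#' @rdname session-io
#' @param config a \linkS4class{SimConfig}.
#' @param file YAML path.
#' @param patternType pattern-set type used to rebuild the set on read.
#' @export
writeSimConfig <- function(config, file) {
  type <- if (length(config@patternSet))
    config@patternSet[[1L]]@modality else "tactile"
  yaml::write_yaml(list(
    nNeurons = config@nNeurons, sessionLength = config@sessionLength,
    baselineRateRange = config@baselineRateRange,
    nLatents = config@nLatents, latentTimescale = config@latentTimescale,
    latentSd = config@latentSd, patternType = type,
    repsPerPattern = config@repsPerPattern,
    interStimulusInterval = config@interStimulusInterval,
    isiJitter = config@isiJitter, evokedGain = config@evokedGain,
    visualGainMod = config@visualGainMod,
    persistenceTau = config@persistenceTau,
    persistenceAmplitude = config@persistenceAmplitude,
    refractoryMs = config@refractoryMs, seed = config@seed), file)
  invisible(file)
}

#' @rdname session-io
#' @export
readSimConfig <- function(file) {
  v <- yaml::read_yaml(file)
  if (is.null(v$sessionLength) || is.na(v$sessionLength))
    v$sessionLength <- NA_real_
  simConfig(nNeurons = v$nNeurons, sessionLength = v$sessionLength,
    baselineRateRange = unlist(v$baselineRateRange),
    nLatents = v$nLatents, latentTimescale = v$latentTimescale,
    latentSd = v$latentSd,
    patternSet = defaultPatternSet(v$patternType),
    repsPerPattern = v$repsPerPattern,
    interStimulusInterval = v$interStimulusInterval,
    isiJitter = v$isiJitter, evokedGain = v$evokedGain,
    visualGainMod = v$visualGainMod, persistenceTau = v$persistenceTau,
    persistenceAmplitude = v$persistenceAmplitude,
    refractoryMs = v$refractoryMs, seed = v$seed)
}
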