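#' Run the full analysis pipeline from a single configuration
#'
#' Orchestrates simulate -> preprocess -> statespace -> decode -> cnn ->
#' stats from one configuration list (or YAML file), writing every
#' intermediate artifact into the output directory together with a JSON
#' manifest (stage list, file digests, seeds). Stages can be restricted
#' via \code{stages}; a failing stage halts with its name while earlier
#' outputs are preserved.
#'
#' The configuration has blocks \code{simulate} (fields of
#' \code{\link{simConfig}}), \code{analysis} (\code{binWidth}, \code{pre},
#' \code{post}, \code{groupSize}, \code{kernelWidth}, \code{fraction},
#' \code{k}, \code{nReps}, \code{nShuffles}, \code{windowWidth},
#' \code{span}), \code{cnn} (\code{binWidth}, \code{epochs},
#' \code{nRestarts}) and a master \code{seed}.
#'
#' @param config list or path to a YAML file.
#' @param outDir output directory (created if missing).
#' @param stages character subset of
#'   \code{c("simulate","preprocess","statespace","decode","cnn","stats")}.
#' @param verbose print stage progress.
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config, outDir,
                        stages = c("simulate", "preprocess", "statespace",
                                   "decode", "cnn", "stats"),
                        verbose = TRUE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  an <- config$analysis
  gv <- function(nm, def) if (is.null(an[[nm]])) def else an[[nm]]
  note <- function(...) if (verbose) message("[", format(Sys.time(),
    "%H:%M:%S"), "] ", ...)
  manifest <- list(seed = seed, stages = list(), files = character(0))
  fns <- character(0)
  keep <- function(...) fns <<- c(fns, ...)
  done <- function(stage) manifest$stages[[stage]] <<- "completed"

  runStage <- function(stage, fn) {
    note("stage ", stage)
    tryCatch(fn(), error = function(e) {
      stop("pipeline halted in stage '", stage, "': ",
           conditionMessage(e), call. = FALSE)
    })
    done(stage)
  }

  env <- new.env()
  if ("simulate" %in% stages) runStage("simulate", function() {
    sc <- config$simulate
    args <- sc[setdiff(names(sc), "patternType")]
    if (!is.null(sc$patternType))
      args$patternSet <- defaultPatternSet(sc$patternType)
    if (is.null(args$seed)) args$seed <- seed
    cfg <- do.call(simConfig, args)
    env$session <- generateSession(cfg)
    f1 <- file.path(outDir, "spikes.csv")
    f2 <- file.path(outDir, "stimulus_log.csv")
    writeSession(env$session, f1, f2)
    writeSimConfig(cfg, file.path(outDir, "sim_config.yaml"))
    keep(f1, f2, file.path(outDir, "sim_config.yaml"))
  })
  if (any(c("preprocess", "statespace", "decode", "cnn", "stats")
          %in% stages) && is.null(env$session)) {
    if (!is.null(config$spikeFile)) {
      env$session <- readSession(config$spikeFile, config$logFile)
    } else {
      f1 <- file.path(outDir, "spikes.csv")
      if (!file.exists(f1))
        stop("no session available: provide spikeFile/logFile or run the ",
             "simulate stage first")
      env$session <- readSession(f1, file.path(outDir, "stimulus_log.csv"))
    }
  }
  if ("preprocess" %in% stages) runStage("preprocess", function() {
    qc <- qcFilter(env$session)
    env$keepIds <- qc$keep
    utils::write.csv(qc$report, file.path(outDir, "qc_report.csv"),
                     row.names = FALSE)
    tens <- extractTrials(env$session, pre = gv("pre", 300),
                          post = gv("post", 1000),
                          binWidth = gv("binWidth", 1),
                          neuronIds = env$keepIds)
    env$preT <- smoothGaussian(
      averageSequential(tens$pre, gv("groupSize", 50L)),
      gv("kernelWidth", 10))
    env$postT <- smoothGaussian(
      averageSequential(tens$post, gv("groupSize", 50L)),
      gv("kernelWidth", 10))
    saveRDS(list(pre = env$preT, post = env$postT),
            file.path(outDir, "tensors.rds"))
    keep(file.path(outDir, "qc_report.csv"),
         file.path(outDir, "tensors.rds"))
  })
  if (any(c("statespace", "decode", "cnn", "stats") %in% stages) &&
      is.null(env$preT)) {
    tl <- readRDS(file.path(outDir, "tensors.rds"))
    env$preT <- tl$pre; env$postT <- tl$post
  }
  if ("statespace" %in% stages) runStage("statespace", function() {
    env$model <- fitSpontaneous(env$preT)
    saveRDS(env$model, file.path(outDir, "pc_model.rds"))
    spec <- data.frame(component = seq_along(eigenvalues(env$model)),
                       eigenvalue = eigenvalues(env$model),
                       varianceRatio = varianceRatios(env$model))
    utils::write.csv(spec, file.path(outDir, "pc_spectrum.csv"),
                     row.names = FALSE)
    keep(file.path(outDir, "pc_model.rds"),
         file.path(outDir, "pc_spectrum.csv"))
  })
  if (any(c("decode", "stats") %in% stages) && is.null(env$model))
    env$model <- readRDS(file.path(outDir, "pc_model.rds"))
  if ("decode" %in% stages) runStage("decode", function() {
    nc <- nComponentsFor(env$model, gv("fraction", 0.95))
    pts <- combineScoredPoints(
      projectActivity(env$model, env$preT, nc),
      projectActivity(env$model, env$postT, nc))
    env$curve <- windowedDecoding(pts, width = gv("windowWidth", 10),
      span = unlist(gv("span", c(-200, 1000))), k = gv("k", 5L),
      nReps = gv("nReps", 50L), nShuffles = gv("nShuffles", 50L),
      seed = seed)
    saveRDS(env$curve, file.path(outDir, "windowed_curve.rds"))
    utils::write.csv(windowSummary(env$curve),
                     file.path(outDir, "windowed_summary.csv"),
                     row.names = FALSE)
    keep(file.path(outDir, "windowed_curve.rds"),
         file.path(outDir, "windowed_summary.csv"))
  })
  if ("cnn" %in% stages) runStage("cnn", function() {
    cb <- config$cnn
    gc2 <- function(nm, def) if (is.null(cb[[nm]])) def else cb[[nm]]
    tens <- extractTrials(env$session, pre = 300, post = 300,
                          binWidth = gc2("binWidth", 10),
                          neuronIds = env$keepIds)
    spec <- cnnSpec(dim(activity(tens$pre))[3L],
                    dim(activity(tens$pre))[2L],
                    epochs = gc2("epochs", 550L),
                    nRestarts = gc2("nRestarts", 24L))
    res <- trainCNN(tens$pre, tens$post, spec, seed = seed)
    utils::write.csv(data.frame(
      restart = seq_along(res@included), included = res@included,
      testLoss = res@testLosses,
      t(apply(res@confusions, 1L, as.vector))),
      file.path(outDir, "cnn_restarts.csv"), row.names = FALSE)
    avg <- res@averagedConfusion
    utils::write.csv(data.frame(f1 = res@f1,
      tn = avg[1, 1], fp = avg[1, 2], fn = avg[2, 1], tp = avg[2, 2]),
      file.path(outDir, "cnn_summary.csv"), row.names = FALSE)
    keep(file.path(outDir, "cnn_restarts.csv"),
         file.path(outDir, "cnn_summary.csv"))
  })
  if ("stats" %in% stages) runStage("stats", function() {
    if (is.null(env$curve))
      env$curve <- readRDS(file.path(outDir, "windowed_curve.rds"))
    starts <- env$curve@windows$start
    lo <- min(starts)
    spans <- list(pre = c(lo, 0))
    postLim <- max(starts) + env$curve@windows$width[1L]
    step <- -lo  # poststimulus spans sized like the prestimulus one
    if (step > 0) {
      ps <- seq(0, postLim - step, by = step)
      for (i in seq_along(ps))
        spans[[sprintf("post_%d_%d", ps[i] + 1, ps[i] + step)]] <-
          c(ps[i], ps[i] + step)
    }
    grp <- buildGroupedF1(list(env$curve), spans)
    rep <- effectReport(grp$pre, grp[-1L])
    utils::write.csv(rep, file.path(outDir, "effect_report.csv"),
                     row.names = FALSE)
    keep(file.path(outDir, "effect_report.csv"))
  })
  manifest$files <- lapply(unique(fns), function(f)
    list(path = basename(f), md5 = unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Plot a windowed decoding curve
#'
#' Base-graphics plot of the smoothed mean F1 with its 95\% CI band and
#' the shuffled-null band per window.
#'
#' @param curve a \linkS4class{WindowedCurve}.
#' @param ... passed to \code{plot}.
#' @export
plotWindowedCurve <- function(curve, ...) {
  s <- windowSummary(curve)
  xx <- s$start + s$width / 2
  plot(xx, s$smoothedF1, type = "l", lwd = 2, ylim = c(0, 1),
       xlab = "time from stimulus onset (ms)", ylab = "F1 score", ...)
  graphics::polygon(c(xx, rev(xx)), c(s$ciLo, rev(s$ciHi)),
                    col = grDevices::adjustcolor("grey40", 0.3),
                    border = NA)
  if (!is.null(s$nullMean)) {
    graphics::lines(xx, s$nullMean, col = "red")
    graphics::polygon(c(xx, rev(xx)),
                      c(s$nullMean - 2 * s$nullSd,
                        rev(s$nullMean + 2 * s$nullSd)),
                      col = grDevices::adjustcolor("red", 0.2),
                      border = NA)
  }
  graphics::abline(v = 0, lty = 3)
  invisible(s)
}
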