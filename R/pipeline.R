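## End-to-end orchestration: enhance -> tile -> train -> predict -> stitch
## -> evaluate, plus the beta- and kernel-sweep experiment runner.

patchToMatrix <- function(patch) {
  d <- dim(patch)
  matrix(patch, d[1] * d[2], d[3])
}

#' Train a segmentation network on a patch set
#'
#' Mini-batch Adam training with mean-over-pixels loss, an optional held-out
#' validation fraction, early stopping, and best-validation-weights
#' restoration. Batch normalization uses batch statistics during training
#' and updates running statistics with momentum 0.1; validation and
#' prediction use the running statistics. With a fixed seed the training
#' history is reproducible on one machine.
#'
#' @param network a \linkS4class{SegmentationNetwork}.
#' @param patches a \linkS4class{PatchSet} carrying mask windows; all
#'   windows must share one shape compatible with the network.
#' @param loss a \linkS4class{LossConfig} (default balanced cross-entropy
#'   with beta = 0.99).
#' @param epochs maximum epochs (default 100).
#' @param batchSize patches per Adam step (default 8).
#' @param learningRate Adam step size (default 1e-3).
#' @param patience early-stopping patience in epochs without validation
#'   improvement (default 10).
#' @param valFraction fraction of patches held out for validation (default
#'   0.1; 0 disables the split and early stopping monitors training loss).
#' @param seed integer controlling the validation split and batch order.
#' @param verbose print per-epoch losses.
#' @return List with \code{network} (trained, best-validation parameters)
#'   and \code{history} (data.frame epoch/trainLoss/valLoss).
#' @export
trainModel <- function(network, patches, loss = lossConfig("bce"),
    epochs = 100L, batchSize = 8L, learningRate = 1e-3, patience = 10L,
    valFraction = 0.1, seed = 1L, verbose = FALSE) {
  stopifnot(is(network, "SegmentationNetwork"), is(patches, "PatchSet"),
    is(loss, "LossConfig"))
  n <- nPatches(patches)
  if (n < 1L) stop("no patches to train on")
  if (length(patches@maskWindows) == 0)
    stop("training requires mask windows")
  first <- checkPatchForNetwork(network, patches@imageWindows[[1]])
  d <- dim(first)
  for (i in seq_len(n))
    if (!identical(dim(patches@imageWindows[[i]]), d))
      stop("all patches must share one shape")

  Xs <- lapply(patches@imageWindows, patchToMatrix)
  Ys <- lapply(patches@maskWindows, as.vector)

  set.seed(seed)
  nVal <- floor(valFraction * n)
  valIdx <- if (nVal > 0) sample.int(n, nVal) else integer(0)
  trIdx <- setdiff(seq_len(n), valIdx)
  if (length(trIdx) == 0L) stop("validation split left no training patches")

  ops <- network@graph
  params <- network@params
  adam <- adamInit(params)
  bestParams <- params
  bestLoss <- Inf
  sinceBest <- 0L
  hist <- data.frame(epoch = integer(0), trainLoss = numeric(0),
    valLoss = numeric(0))

  evalLossOn <- function(params, idx) {
    if (length(idx) == 0) return(NA_real_)
    tot <- 0
    for (i in idx) {
      fwd <- nnForward(ops, params, Xs[[i]], d[1], d[2], train = FALSE)
      tot <- tot + evaluateLoss(loss, Ys[[i]], fwd$score)
    }
    tot / length(idx)
  }

  for (ep in seq_len(epochs)) {
    ord <- sample(trIdx)
    epochLoss <- 0
    bStart <- seq(1, length(ord), by = batchSize)
    for (bs in bStart) {
      batch <- ord[bs:min(bs + batchSize - 1L, length(ord))]
      acc <- NULL
      for (i in batch) {
        fwd <- nnForward(ops, params, Xs[[i]], d[1], d[2], train = TRUE,
          keepCache = TRUE)
        phat <- fwd$score
        lossVal <- evaluateLoss(loss, Ys[[i]], phat)
        if (!is.finite(lossVal))
          stop("training diverged: non-finite loss at epoch ", ep,
            ", patch ", i)
        epochLoss <- epochLoss + lossVal
        dZ <- lossGradLogit(Ys[[i]], phat, loss@kind, loss@beta)
        g <- nnBackward(ops, params, fwd, dZ)
        acc <- accumulateGrads(acc, g)
        ## fold in updated batch-norm running statistics as we go
        for (j in seq_along(fwd$bnNew)) {
          if (is.null(fwd$bnNew[[j]])) next
          params[[j]]$rm <- fwd$bnNew[[j]]$rm
          params[[j]]$rv <- fwd$bnNew[[j]]$rv
        }
      }
      acc <- scaleGrads(acc, 1 / length(batch))
      stepRes <- adamStep(params, acc, adam, learningRate)
      params <- stepRes$params
      adam <- stepRes$state
    }
    trainLoss <- epochLoss / length(ord)
    valLoss <- evalLossOn(params, valIdx)
    monitor <- if (is.na(valLoss)) trainLoss else valLoss
    hist <- rbind(hist, data.frame(epoch = ep, trainLoss = trainLoss,
      valLoss = valLoss))
    if (verbose)
      message(sprintf("epoch %d: train %.5f val %s", ep, trainLoss,
        ifelse(is.na(valLoss), "-", sprintf("%.5f", valLoss))))
    if (monitor < bestLoss - 1e-12) {
      bestLoss <- monitor
      bestParams <- params
      sinceBest <- 0L
    } else {
      sinceBest <- sinceBest + 1L
      if (sinceBest >= patience) break
    }
  }

  network@params <- bestParams
  network@trained <- TRUE
  list(network = network, history = hist)
}

#' Predict a full scene by tiling
#'
#' Extracts non-overlapping windows, runs the network on each, and stitches
#' the per-patch score grids back into a full-scene map. uint8 scenes are
#' rescaled to [0,1] before the forward pass. Pixels not covered by any full
#' window come back as \code{NA}, to be excluded from evaluation.
#'
#' @param network a \linkS4class{SegmentationNetwork}.
#' @param scene a \linkS4class{SceneImage}.
#' @param spec a non-overlapping \linkS4class{TileSpec} whose window is
#'   divisible by \code{2^poolingDepth}.
#' @return \code{height x width} score matrix with \code{NA} at uncovered
#'   pixels.
#' @export
predictScene <- function(network, scene, spec) {
  stopifnot(is(network, "SegmentationNetwork"), is(scene, "SceneImage"))
  if (spec@strideX < spec@windowW || spec@strideY < spec@windowH)
    stop("predictScene requires a non-overlapping spec (stride >= window)")
  px <- scene@pixels
  if (scene@valueRange == "uint8") px <- px / 255
  ps <- extractPatches(px, mask = NULL, spec = spec)
  scores <- lapply(seq_len(nPatches(ps)), function(i)
    predictPatch(network, ps@imageWindows[[i]]))
  stitchPredictions(scores, ps, dim(px)[1:2], spec)
}

#' Configure an end-to-end experiment
#'
#' Bundles every knob of a run: which models to fit, which enhancement
#' kernels to sweep (\code{"none"} is the no-enhancement ablation arm),
#' which loss betas, the tiling geometry, and the training hyperparameters.
#' One global seed fans out deterministically to patch subsampling,
#' parameter initialization and batch shuffling.
#'
#' @param models character vector of model names (see
#'   \code{\link{buildModel}}).
#' @param kernels character vector from \code{"none"}, \code{"godec"},
#'   \code{"pcp"}.
#' @param lossKind \code{"bce"}, \code{"wce"} or \code{"ce"}.
#' @param betas numeric vector of loss betas (a single NA for
#'   \code{lossKind = "ce"}).
#' @param rpca \linkS4class{RpcaConfig} template; its kernel slot is
#'   overridden by each swept kernel.
#' @param trainSpec,testSpec \linkS4class{TileSpec}s for training (may
#'   overlap) and testing (non-overlapping).
#' @param epochs,batchSize,learningRate,patience,valFraction training
#'   hyperparameters, as in \code{\link{trainModel}}.
#' @param maxTrainPatches cap on the number of training patches (seeded
#'   subsample; \code{NA} = use all). A compute-scaling control for
#'   desk-scale runs.
#' @param threshold hard-decision threshold for evaluation (default 0.5).
#' @param seed global integer seed.
#' @param outDir optional directory for artifacts (CSV report, tri-color
#'   maps, manifest); \code{NA} writes nothing.
#' @return A named list of settings (class \code{"nglsegRunConfig"}).
#' @export
runConfig <- function(models = "3l_usn", kernels = "godec",
    lossKind = "bce", betas = 0.99, rpca = rpcaConfig("godec"),
    trainSpec = tileSpec(128, 96, 32, 24),
    testSpec = tileSpec(128, 96, 128, 96),
    epochs = 100L, batchSize = 8L, learningRate = 1e-3, patience = 10L,
    valFraction = 0.1, maxTrainPatches = NA_integer_, threshold = 0.5,
    seed = 1L, outDir = NA_character_) {
  stopifnot(all(models %in% .modelNames),
    all(kernels %in% c("none", "godec", "pcp")),
    lossKind %in% c("ce", "wce", "bce"))
  cfg <- list(models = models, kernels = kernels, lossKind = lossKind,
    betas = betas, rpca = rpca, trainSpec = trainSpec, testSpec = testSpec,
    epochs = as.integer(epochs), batchSize = as.integer(batchSize),
    learningRate = learningRate, patience = as.integer(patience),
    valFraction = valFraction,
    maxTrainPatches = as.integer(maxTrainPatches), threshold = threshold,
    seed = as.integer(seed), outDir = outDir)
  class(cfg) <- "nglsegRunConfig"
  cfg
}

asUnitScene <- function(scene) {
  if (scene@valueRange == "uint8")
    SceneImage(scene@pixels / 255, "unit")
  else scene
}

#' Run a (model x kernel x beta) experiment grid
#'
#' For each combination: optionally sparse-enhance both scenes (identical
#' configuration for train and test), tile the training area, subsample
#' training patches if requested, build and train the model, predict the
#' test area with the non-overlapping test spec, and evaluate. Identical
#' config and seed reproduce identical rows on one machine.
#'
#' @param cfg a config from \code{\link{runConfig}}.
#' @param train,test lists with elements \code{image}
#'   (\linkS4class{SceneImage}) and \code{mask} (binary matrix), e.g. from
#'   \code{\link{generateScene}}.
#' @param verbose print progress.
#' @return data.frame with one row per combination: \code{model},
#'   \code{kernel}, \code{beta}, \code{auc}, \code{tpr}, \code{fpr},
#'   \code{acc}, \code{kappa}, \code{epochsRun}, \code{nTrainPatches}.
#' @export
runExperiment <- function(cfg, train, test, verbose = FALSE) {
  stopifnot(inherits(cfg, "nglsegRunConfig"))
  outDir <- cfg$outDir
  writeOut <- !is.na(outDir)
  if (writeOut) dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  ## enhancement is independent of model/beta: compute once per kernel
  scenePair <- list()
  for (k in unique(cfg$kernels)) {
    if (k == "none") {
      scenePair[[k]] <- list(train = asUnitScene(train$image),
        test = asUnitScene(test$image))
    } else {
      rc <- cfg$rpca
      rc@kernel <- k
      scenePair[[k]] <- list(
        train = asUnitScene(sparseEnhance(train$image, rc)),
        test = asUnitScene(sparseEnhance(test$image, rc)))
    }
  }

  rows <- list()
  for (k in cfg$kernels) for (m in cfg$models) for (b in cfg$betas) {
    if (verbose)
      message(sprintf("run: model=%s kernel=%s beta=%s", m, k, b))
    trScene <- scenePair[[k]]$train
    teScene <- scenePair[[k]]$test
    patches <- extractPatches(trScene, train$mask, cfg$trainSpec)
    nAll <- nPatches(patches)
    if (!is.na(cfg$maxTrainPatches) && cfg$maxTrainPatches < nAll) {
      set.seed(cfg$seed)
      keep <- sort(sample.int(nAll, cfg$maxTrainPatches))
      patches <- new("PatchSet",
        origins = patches@origins[keep, , drop = FALSE],
        imageWindows = patches@imageWindows[keep],
        maskWindows = patches@maskWindows[keep],
        windowW = patches@windowW, windowH = patches@windowH,
        sourceHeight = patches@sourceHeight,
        sourceWidth = patches@sourceWidth)
    }
    net <- buildModel(m, inputChannels = dim(trScene)[3], seed = cfg$seed)
    lcfg <- if (cfg$lossKind == "ce") lossConfig("ce") else
      lossConfig(cfg$lossKind, b)
    fit <- trainModel(net, patches, lcfg, epochs = cfg$epochs,
      batchSize = cfg$batchSize, learningRate = cfg$learningRate,
      patience = cfg$patience, valFraction = cfg$valFraction,
      seed = cfg$seed)
    scores <- predictScene(fit$network, teScene, cfg$testSpec)
    rep <- evaluateSegmentation(scores, test$mask, cfg$threshold)
    row <- cbind(data.frame(model = m, kernel = k, beta = b), rep,
      data.frame(epochsRun = nrow(fit$history),
        nTrainPatches = nPatches(patches)))
    rows[[length(rows) + 1L]] <- row
    if (writeOut) {
      tag <- sprintf("%s_%s_beta%s", m, k, b)
      pred <- matrix(0L, nrow(scores), ncol(scores))
      pred[!is.na(scores) & scores >= cfg$threshold] <- 1L
      writeScene(renderResultMap(pred, test$mask, teScene),
        file.path(outDir, paste0("map_", tag, ".png")))
    }
  }
  report <- do.call(rbind, rows)
  if (writeOut) {
    utils::write.csv(report, file.path(outDir, "report.csv"),
      row.names = FALSE)
    manifest <- list(seed = cfg$seed, models = cfg$models,
      kernels = cfg$kernels, lossKind = cfg$lossKind, betas = cfg$betas,
      epochs = cfg$epochs, batchSize = cfg$batchSize,
      learningRate = cfg$learningRate,
      maxTrainPatches = cfg$maxTrainPatches, threshold = cfg$threshold)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
      auto_unbox = TRUE, pretty = TRUE)
  }
  report
}
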