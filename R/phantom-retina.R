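#' RetinaPhantomParams: configuration of the synthetic retina generator
#'
#' Describes a synthetic cSLO-like retinal field: a mosaic of parenchymal
#' microglia tiling the retina plus a cluster of cells at the optic nerve head
#' (ONH), each rendered as a bright soma disk of known area with a few short,
#' dimmer processes, over Gaussian background noise. Soma areas are drawn from
#' a three-component Gaussian mixture whose components correspond to small
#' cells, non-activated microglia and activated microglia.
#'
#' @slot fieldWidthPx,fieldHeightPx image size in pixels.
#' @slot pixelScale micrometres per pixel.
#' @slot nParenchymalCells number of parenchymal cells outside the ONH.
#' @slot nOnhCells number of cells clustered within the ONH.
#' @slot onhCenter (x, y) of the ONH center, micrometres.
#' @slot onhRadius radius (um) of the ONH cluster.
#' @slot somaAreaWeights,somaAreaMeans,somaAreaSds mixture weights, mean soma
#'   areas (um^2) and spreads of the soma-area distribution.
#' @slot processCountRange integer range of process strokes per cell.
#' @slot backgroundLevel mean background intensity.
#' @slot backgroundNoiseSd Gaussian background noise sd.
#' @slot cellPeakIntensity soma peak intensity above background.
#' @slot minCenterSpacing minimum pairwise distance between cell centers (um).
#' @slot blurSigmaPx Gaussian blur sigma (px) emulating optical spread.
#' @slot activationAreaMin,nonactivatedAreaMin soma-area bin edges (um^2) used
#'   to label the ground-truth class of each generated cell.
#' @slot seed RNG seed.
#' @seealso [retinaPhantomParams()], [generateRetinaPhantom()]
#' @export
setClass("RetinaPhantomParams",
  representation(
    fieldWidthPx = "integer", fieldHeightPx = "integer",
    pixelScale = "numeric",
    nParenchymalCells = "integer", nOnhCells = "integer",
    onhCenter = "numeric", onhRadius = "numeric",
    somaAreaWeights = "numeric", somaAreaMeans = "numeric",
    somaAreaSds = "numeric",
    processCountRange = "integer",
    backgroundLevel = "numeric", backgroundNoiseSd = "numeric",
    cellPeakIntensity = "numeric",
    minCenterSpacing = "numeric", blurSigmaPx = "numeric",
    activationAreaMin = "numeric", nonactivatedAreaMin = "numeric",
    seed = "integer"
  )
)

setValidity("RetinaPhantomParams", function(object) {
  msg <- character()
  if (object@fieldWidthPx <= 0L || object@fieldHeightPx <= 0L)
    msg <- c(msg, "field dimensions must be positive")
  if (object@pixelScale <= 0)
    msg <- c(msg, "pixelScale must be > 0")
  if (object@nParenchymalCells < 0L || object@nOnhCells < 0L)
    msg <- c(msg, "cell counts must be >= 0")
  if (object@minCenterSpacing < 0)
    msg <- c(msg, "minCenterSpacing must be >= 0")
  k <- length(object@somaAreaWeights)
  if (k == 0L || length(object@somaAreaMeans) != k ||
      length(object@somaAreaSds) != k)
    msg <- c(msg, "soma-area mixture weights/means/sds must have equal length")
  if (any(object@somaAreaWeights < 0) || sum(object@somaAreaWeights) <= 0)
    msg <- c(msg, "soma-area mixture weights must be non-negative, not all zero")
  if (any(object@somaAreaMeans <= 0))
    msg <- c(msg, "mean soma areas must be positive")
  if (length(object@processCountRange) != 2L ||
      any(object@processCountRange < 0L) ||
      object@processCountRange[1L] > object@processCountRange[2L])
    msg <- c(msg, "processCountRange must be a non-decreasing pair of non-negative integers")
  lim <- c(object@fieldWidthPx, object@fieldHeightPx) * object@pixelScale
  if (any(object@onhCenter < 0) || any(object@onhCenter > lim))
    msg <- c(msg, "onhCenter must lie inside the field")
  if (length(msg)) msg else TRUE
})

#' Parameters for a synthetic retina phantom
#'
#' Defaults emulate a cSLO frame of the central retina: a 1.5 x 1.5 mm field
#' at 1 um/px tiled by 250 parenchymal cells, with 15 cells clustered within
#' 100 um of the ONH center. The soma-area mixture places roughly 10% of cells
#' below 10 um^2, 75% in the non-activated band and 15% above the activation
#' threshold.
#'
#' @param fieldWidthPx,fieldHeightPx image size in pixels (default 1500).
#' @param pixelScale micrometres per pixel (default 1).
#' @param nParenchymalCells parenchymal cells (default 250).
#' @param nOnhCells ONH-cluster cells (default 15).
#' @param onhCenter (x, y) um; default field center.
#' @param onhRadius um (default 100).
#' @param somaAreaWeights,somaAreaMeans,somaAreaSds soma-area mixture; defaults
#'   `c(0.10, 0.75, 0.15)`, `c(7, 28, 70)` um^2, `c(1.5, 8, 12)`.
#' @param processCountRange strokes per cell (default 0 to 4).
#' @param backgroundLevel background intensity (default 30).
#' @param backgroundNoiseSd noise sd (default 8).
#' @param cellPeakIntensity soma peak above background (default 120).
#' @param minCenterSpacing um (default 20).
#' @param blurSigmaPx blur sigma in px (default 0.8).
#' @param activationAreaMin,nonactivatedAreaMin ground-truth class bin edges
#'   (defaults 50 and 10 um^2).
#' @param seed RNG seed (default 1).
#' @return A [RetinaPhantomParams-class] object.
#' @examples
#' p <- retinaPhantomParams(nParenchymalCells = 20L, nOnhCells = 3L,
#'                          fieldWidthPx = 400L, fieldHeightPx = 400L,
#'                          onhCenter = c(200, 200))
#' @export
retinaPhantomParams <- function(fieldWidthPx = 1500L, fieldHeightPx = 1500L,
                                pixelScale = 1,
                                nParenchymalCells = 250L, nOnhCells = 15L,
                                onhCenter = NULL, onhRadius = 100,
                                somaAreaWeights = c(0.10, 0.75, 0.15),
                                somaAreaMeans = c(7, 28, 70),
                                somaAreaSds = c(1.5, 8, 12),
                                processCountRange = c(0L, 4L),
                                backgroundLevel = 30, backgroundNoiseSd = 8,
                                cellPeakIntensity = 120,
                                minCenterSpacing = 20, blurSigmaPx = 0.8,
                                activationAreaMin = 50,
                                nonactivatedAreaMin = 10,
                                seed = 1L) {
  if (is.null(onhCenter))
    onhCenter <- c(fieldWidthPx, fieldHeightPx) * pixelScale / 2
  new("RetinaPhantomParams",
      fieldWidthPx = as.integer(fieldWidthPx),
      fieldHeightPx = as.integer(fieldHeightPx),
      pixelScale = pixelScale,
      nParenchymalCells = as.integer(nParenchymalCells),
      nOnhCells = as.integer(nOnhCells),
      onhCenter = as.numeric(onhCenter), onhRadius = onhRadius,
      somaAreaWeights = somaAreaWeights, somaAreaMeans = somaAreaMeans,
      somaAreaSds = somaAreaSds,
      processCountRange = as.integer(processCountRange),
      backgroundLevel = backgroundLevel,
      backgroundNoiseSd = backgroundNoiseSd,
      cellPeakIntensity = cellPeakIntensity,
      minCenterSpacing = minCenterSpacing, blurSigmaPx = blurSigmaPx,
      activationAreaMin = activationAreaMin,
      nonactivatedAreaMin = nonactivatedAreaMin,
      seed = as.integer(seed))
}

## Draw soma areas from the truncated (> 1 um^2) Gaussian mixture.
sampleSomaAreas <- function(n, weights, means, sds) {
  if (n == 0L) return(numeric(0))
  comp <- sample.int(length(weights), n, replace = TRUE,
                     prob = weights / sum(weights))
  areas <- stats::rnorm(n, means[comp], sds[comp])
  bad <- which(areas <= 1)
  while (length(bad)) {
    areas[bad] <- stats::rnorm(length(bad), means[comp[bad]], sds[comp[bad]])
    bad <- bad[areas[bad] <= 1]
  }
  areas
}

## Rejection-sample `n` centers satisfying `proposal()` and pairwise spacing
## against rows already in `placed` (2-col matrix, um). 10,000 attempts/cell.
placeCenters <- function(n, placed, minSpacing, proposal) {
  maxAttempts <- 10000L
  for (i in seq_len(n)) {
    ok <- FALSE
    for (a in seq_len(maxAttempts)) {
      pt <- proposal()
      if (nrow(placed) == 0L ||
          min((placed[, 1L] - pt[1L])^2 + (placed[, 2L] - pt[2L])^2) >=
            minSpacing^2) {
        placed <- rbind(placed, pt)
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("cell placement failed after 10000 attempts: ",
           "density too high for minCenterSpacing")
  }
  placed
}

#' Generate a synthetic retina phantom with known ground truth
#'
#' Renders each cell as a filled soma disk of the requested area at full peak
#' intensity plus 0-4 thin process strokes at 40% of the soma peak, applies a
#' small Gaussian blur emulating optical spread, and adds Gaussian background
#' noise (clamped at zero). Cell centers are rejection-sampled so that all
#' pairs are at least `minCenterSpacing` apart; ONH-cluster cells fall within
#' `onhRadius` of the ONH center and parenchymal cells outside it. The same
#' parameters and seed always give bit-identical output.
#'
#' @param params a [RetinaPhantomParams-class] object.
#' @param eyeId,ageMonths metadata stored in the returned frame.
#' @return A list with elements `frame` (a [RetinaFrame-class]) and `truth`
#'   (a data.frame with one row per generated cell: `x_um`, `y_um`,
#'   `true_soma_area_um2`, `true_class`, `in_onh`).
#' @examples
#' ph <- generateRetinaPhantom(retinaPhantomParams(
#'   fieldWidthPx = 300L, fieldHeightPx = 300L, nParenchymalCells = 10L,
#'   nOnhCells = 2L, onhCenter = c(150, 150), seed = 7L))
#' nrow(ph$truth)
#' @export
generateRetinaPhantom <- function(params, eyeId = "phantom",
                                  ageMonths = NA_real_) {
  stopifnot(is(params, "RetinaPhantomParams"))
  validObject(params)
  withSeed(params@seed, {
    scale <- params@pixelScale
    W <- params@fieldWidthPx
    H <- params@fieldHeightPx
    wUm <- (W - 1) * scale
    hUm <- (H - 1) * scale
    cx <- params@onhCenter[1L]
    cy <- params@onhCenter[2L]

    nTot <- params@nParenchymalCells + params@nOnhCells
    areas <- sampleSomaAreas(nTot, params@somaAreaWeights,
                             params@somaAreaMeans, params@somaAreaSds)

    placed <- matrix(numeric(0), 0L, 2L)
    ## ONH cluster first: uniform over the ONH disk.
    placed <- placeCenters(params@nOnhCells, placed, params@minCenterSpacing,
      proposal = function() {
        r <- params@onhRadius * sqrt(stats::runif(1))
        th <- stats::runif(1, 0, 2 * pi)
        c(cx + r * cos(th), cy + r * sin(th))
      })
    ## Parenchymal mosaic: uniform over the field, excluding the ONH disk.
    margin <- min(10, wUm / 4, hUm / 4)
    placed <- placeCenters(params@nParenchymalCells, placed,
                           params@minCenterSpacing,
      proposal = function() {
        repeat {
          pt <- c(stats::runif(1, margin, wUm - margin),
                  stats::runif(1, margin, hUm - margin))
          if ((pt[1L] - cx)^2 + (pt[2L] - cy)^2 > params@onhRadius^2)
            return(pt)
        }
      })

    img <- matrix(params@backgroundLevel, H, W)
    peak <- params@backgroundLevel + params@cellPeakIntensity
    procLevel <- 0.4 * peak   # process strokes at 40% of the soma peak
    nProcRange <- params@processCountRange

    if (nTot > 0L) {
      for (i in seq_len(nTot)) {
        px <- placed[i, 1L] / scale
        py <- placed[i, 2L] / scale
        rpx <- sqrt(areas[i] / pi) / scale
        ## soma disk
        r0 <- max(1L, floor(py - rpx) + 1L); r1 <- min(H, ceiling(py + rpx) + 1L)
        c0 <- max(1L, floor(px - rpx) + 1L); c1 <- min(W, ceiling(px + rpx) + 1L)
        rows <- r0:r1; cols <- c0:c1
        d2 <- outer(((rows - 1) - py)^2, ((cols - 1) - px)^2, "+")
        patch <- img[rows, cols, drop = FALSE]
        patch[d2 <= rpx^2] <- pmax(patch[d2 <= rpx^2], peak)
        img[rows, cols] <- patch
        ## process strokes
        nProc <- if (nProcRange[2L] > nProcRange[1L])
          sample(nProcRange[1L]:nProcRange[2L], 1L) else nProcRange[1L]
        if (nProc > 0L) {
          for (k in seq_len(nProc)) {
            ang <- stats::runif(1, 0, 2 * pi)
            lenPx <- stats::runif(1, 8, 20) / scale
            tt <- seq(0, lenPx, by = 0.5)
            xs <- round(px + (rpx + tt) * cos(ang)) + 1L
            ys <- round(py + (rpx + tt) * sin(ang)) + 1L
            keep <- xs >= 1L & xs <= W & ys >= 1L & ys <= H
            idx <- cbind(ys[keep], xs[keep])
            img[idx] <- pmax(img[idx], procLevel)
          }
        }
      }
    }

    if (params@blurSigmaPx > 0)
      img <- as.matrix(EBImage::gblur(img, sigma = params@blurSigmaPx,
                                      boundary = "replicate"))
    if (params@backgroundNoiseSd > 0)
      img <- img + matrix(stats::rnorm(H * W, 0, params@backgroundNoiseSd), H, W)
    img <- pmax(img, 0)

    truth <- data.frame(
      x_um = placed[, 1L] %||% numeric(0),
      y_um = placed[, 2L] %||% numeric(0),
      true_soma_area_um2 = areas,
      true_class = vapply(areas, function(a) {
        if (a > params@activationAreaMin) "activated"
        else if (a >= params@nonactivatedAreaMin) "non_activated"
        else "small"
      }, character(1)),
      in_onh = seq_len(nTot) <= params@nOnhCells,
      stringsAsFactors = FALSE
    )
    if (nTot == 0L)
      truth <- data.frame(x_um = numeric(0), y_um = numeric(0),
                          true_soma_area_um2 = numeric(0),
                          true_class = character(0), in_onh = logical(0),
                          stringsAsFactors = FALSE)

    list(frame = retinaFrame(img, scale, params@onhCenter, eyeId = eyeId,
                             ageMonths = ageMonths),
         truth = truth)
  })
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a
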