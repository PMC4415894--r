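#' Classify microglial activation from soma area
#'
#' Activation state is a pure function of the soma area and two bin edges:
#' `activated` above `activationAreaMin` (default 50 um^2), `non_activated` on
#' the closed interval from `nonactivatedAreaMin` (default 10 um^2) up to and
#' including `activationAreaMin`, and `small` below 10 um^2. The three bins are
#' exhaustive and mutually exclusive over positive areas.
#'
#' @param somaArea soma area(s) in um^2; must be positive.
#' @param config a [MorphometryConfig-class]; only the bin edges are used.
#' @return Character vector of `"activated"`, `"non_activated"` or `"small"`.
#' @examples
#' classifyActivation(c(8, 10, 55))
#' @export
classifyActivation <- function(somaArea, config = morphometryConfig()) {
  if (any(!is.finite(somaArea)) || any(somaArea <= 0))
    stop("soma areas must be positive and finite")
  ifelse(somaArea > config@activationAreaMin, "activated",
         ifelse(somaArea >= config@nonactivatedAreaMin,
                "non_activated", "small"))
}

#' Assign cells to radial sectors around the optic disc
#'
#' Cells are mapped to `sectorCount` equal angular wedges over the annulus
#' between `onhExclusionRadius` and `analysisOuterRadius`. The angle is
#' measured counter-clockwise from the +x axis (with image y pointing down,
#' so "counter-clockwise" matches the displayed image), in [0, 360) degrees;
#' sector `k` covers angles `[k * 360/n, (k+1) * 360/n)`. Radial distances
#' exactly on a bound belong to the inner region: a cell at exactly the ONH
#' exclusion radius is excluded from sectors (`NA`), one at exactly the outer
#' radius is included.
#'
#' @param x either a numeric vector of x coordinates (um) or a cell data.frame
#'   with `x_um`/`y_um` columns as returned by [segmentCells()].
#' @param y numeric y coordinates (um), ignored when `x` is a data.frame.
#' @param frame the [RetinaFrame-class] supplying the ONH center.
#' @param config a [MorphometryConfig-class].
#' @return Integer sector indices in `0:(sectorCount-1)`, `NA` outside the
#'   annulus.
#' @export
assignSector <- function(x, y = NULL, frame, config = morphometryConfig()) {
  if (is.data.frame(x)) {
    y <- x$y_um
    x <- x$x_um
  }
  ctr <- onhCenter(frame)
  dx <- x - ctr[1L]
  dy <- y - ctr[2L]
  d <- sqrt(dx^2 + dy^2)
  ang <- atan2(-dy, dx)            # CCW from +x in displayed orientation
  ang <- ang %% (2 * pi)
  sector <- as.integer(floor(ang / (2 * pi / config@sectorCount)))
  sector[sector >= config@sectorCount] <- config@sectorCount - 1L  # guard fp
  sector[d <= config@onhExclusionRadius | d > config@analysisOuterRadius] <- NA_integer_
  sector
}

#' Segment GFP+ cells and measure soma areas in a retinal image
#'
#' Two-level intensity thresholding: the background is estimated as the median
#' image intensity and the cell mask keeps pixels more than
#' `cellThresholdK` MADs above it; within each connected component, the soma
#' mask keeps pixels above `somaRelativeThreshold` of that component's peak
#' intensity (peaks and the soma mask are taken on a lightly smoothed copy of
#' the image so single noisy pixels do not set the peak). Components whose
#' soma mask contains more than
#' one blob with centers farther apart than `peakSeparationMin` are split into
#' one cell per soma, with the component's pixels divided among somata by
#' seeded region growing (soma blobs closer than the separation are merged,
#' keeping the brighter peak's component). The image is never modified.
#'
#' @param frame a [RetinaFrame-class].
#' @param config a [MorphometryConfig-class].
#' @return A data.frame with one row per cell: `eye_id`, `age_months`,
#'   `x_um`, `y_um` (soma centroid), `soma_area_um2`, `component_area_um2`,
#'   `class` (see [classifyActivation()]), `sector` (see [assignSector()]) and
#'   `in_onh` (centroid within the ONH exclusion radius, boundary inclusive).
#'   Empty (zero rows) for a pure-noise or constant image.
#' @examples
#' ph <- generateRetinaPhantom(retinaPhantomParams(
#'   fieldWidthPx = 300L, fieldHeightPx = 300L, nParenchymalCells = 8L,
#'   nOnhCells = 0L, onhCenter = c(150, 150), seed = 11L))
#' cells <- segmentCells(ph$frame)
#' nrow(cells)
#' @export
segmentCells <- function(frame, config = morphometryConfig()) {
  stopifnot(is(frame, "RetinaFrame"))
  validObject(frame)
  validObject(config)
  px <- frame@pixels
  if (any(!is.finite(px)))
    stop("image contains non-finite pixels")
  scale <- frame@pixelScale

  bg <- stats::median(px)
  spread <- stats::mad(px)
  emptyCells <- data.frame(
    eye_id = character(0), age_months = numeric(0),
    x_um = numeric(0), y_um = numeric(0),
    soma_area_um2 = numeric(0), component_area_um2 = numeric(0),
    class = character(0), sector = integer(0), in_onh = logical(0),
    stringsAsFactors = FALSE)
  if (spread == 0) return(emptyCells)   # constant or near-constant image

  thr <- bg + config@cellThresholdK * spread
  mask <- px > thr
  if (!any(mask)) return(emptyCells)

  lab <- EBImage::bwlabel(mask + 0)
  lab <- matrix(as.integer(lab), nrow(px), ncol(px))
  idxAll <- which(lab > 0L)
  compSize <- tabulate(lab[idxAll])
  keepComp <- compSize >= config@minComponentPx
  if (!any(keepComp)) return(emptyCells)

  ## soma measurement uses a lightly smoothed copy so a single noisy pixel
  ## does not set the component peak; the threshold is a fixed fraction of
  ## each component's (smoothed) peak intensity
  pxS <- as.matrix(EBImage::gblur(px, sigma = 1, boundary = "replicate"))
  peakByComp <- rep(-Inf, length(compSize))
  vals <- pxS[idxAll]
  ord <- order(lab[idxAll])
  labSorted <- lab[idxAll][ord]
  valsSorted <- vals[ord]
  peaks <- vapply(split(valsSorted, labSorted), max, numeric(1))
  peakByComp[as.integer(names(peaks))] <- peaks
  somaThrByComp <- config@somaRelativeThreshold * peakByComp

  somaMask <- matrix(FALSE, nrow(px), ncol(px))
  ok <- keepComp[lab[idxAll]] & (vals >= somaThrByComp[lab[idxAll]])
  somaMask[idxAll[ok]] <- TRUE
  if (!any(somaMask)) return(emptyCells)

  somaLab <- EBImage::bwlabel(somaMask + 0)
  somaLab <- matrix(as.integer(somaLab), nrow(px), ncol(px))

  ## blob bookkeeping: pixel lists, centroids, parent component, peak value
  sIdx <- which(somaLab > 0L)
  blobsOf <- split(sIdx, somaLab[sIdx])
  blobIds <- as.integer(names(blobsOf))
  nr <- nrow(px)
  blobInfo <- lapply(blobsOf, function(ii) {
    rows <- ((ii - 1L) %% nr)            # 0-based y
    cols <- ((ii - 1L) %/% nr)           # 0-based x
    list(idx = ii,
         cx = mean(cols) * scale, cy = mean(rows) * scale,
         comp = lab[ii[1L]], peak = max(px[ii]))
  })

  ## merge soma blobs of the same component closer than peakSeparationMin
  comps <- vapply(blobInfo, function(b) b$comp, numeric(1))
  merged <- blobInfo
  for (cmp in unique(comps[duplicated(comps)])) {
    members <- which(vapply(merged, function(b)
      !is.null(b) && b$comp == cmp, logical(1)))
    repeat {
      if (length(members) < 2L) break
      cxs <- vapply(merged[members], `[[`, numeric(1), "cx")
      cys <- vapply(merged[members], `[[`, numeric(1), "cy")
      dm <- crossDist(cbind(cxs, cys), cbind(cxs, cys))
      diag(dm) <- Inf
      mn <- which(dm == min(dm), arr.ind = TRUE)[1L, ]
      if (dm[mn[1L], mn[2L]] >= config@peakSeparationMin) break
      a <- members[mn[1L]]; b <- members[mn[2L]]
      keep <- if (merged[[a]]$peak >= merged[[b]]$peak) a else b
      drop <- if (keep == a) b else a
      ii <- c(merged[[keep]]$idx, merged[[drop]]$idx)
      rows <- ((ii - 1L) %% nr); cols <- ((ii - 1L) %/% nr)
      merged[[keep]] <- list(idx = ii, cx = mean(cols) * scale,
                             cy = mean(rows) * scale, comp = cmp,
                             peak = max(merged[[keep]]$peak,
                                        merged[[drop]]$peak))
      merged[[drop]] <- NULL
      members <- which(vapply(merged, function(b)
        !is.null(b) && b$comp == cmp, logical(1)))
    }
  }
  merged <- Filter(Negate(is.null), merged)

  ## divide component pixels among their somata by seeded region growing
  seeds <- matrix(0L, nrow(px), ncol(px))
  for (i in seq_along(merged)) seeds[merged[[i]]$idx] <- i
  cellMask <- matrix(FALSE, nrow(px), ncol(px))
  cellMask[idxAll[keepComp[lab[idxAll]]]] <- TRUE
  parts <- EBImage::propagate(EBImage::Image(px / max(px)), seeds,
                              mask = cellMask)
  parts <- matrix(as.integer(parts), nrow(px), ncol(px))
  partSize <- tabulate(parts[parts > 0L], nbins = length(merged))

  somaArea <- vapply(merged, function(b) length(b$idx), numeric(1)) * scale^2
  compArea <- pmax(partSize, vapply(merged, function(b) length(b$idx),
                                    numeric(1))) * scale^2
  xs <- vapply(merged, `[[`, numeric(1), "cx")
  ys <- vapply(merged, `[[`, numeric(1), "cy")
  ctr <- onhCenter(frame)
  dCtr <- sqrt((xs - ctr[1L])^2 + (ys - ctr[2L])^2)

  cells <- data.frame(
    eye_id = eyeId(frame), age_months = ageMonths(frame),
    x_um = xs, y_um = ys,
    soma_area_um2 = somaArea, component_area_um2 = compArea,
    class = classifyActivation(somaArea, config),
    sector = assignSector(xs, ys, frame = frame, config = config),
    in_onh = dCtr <= config@onhExclusionRadius,
    stringsAsFactors = FALSE)
  rownames(cells) <- NULL
  cells
}

#' Summarize cell counts per radial sector
#'
#' @param cells cell data.frame from [segmentCells()] (needs `sector` and
#'   `class` columns).
#' @param config a [MorphometryConfig-class] supplying the sector geometry.
#' @return A data.frame with one row per sector: `sector`, `total_cells`,
#'   `activated_cells`, `inner_radius_um`, `outer_radius_um`,
#'   `angular_span_deg`. Cells without a sector are excluded; totals over
#'   sectors equal the number of sector-assigned cells.
#' @export
summarizeSectors <- function(cells, config = morphometryConfig()) {
  k <- config@sectorCount
  sec <- cells$sector
  inSec <- !is.na(sec)
  total <- tabulate(sec[inSec] + 1L, nbins = k)
  act <- tabulate(sec[inSec & cells$class == "activated"] + 1L, nbins = k)
  data.frame(
    sector = 0:(k - 1L),
    total_cells = total,
    activated_cells = act,
    inner_radius_um = config@onhExclusionRadius,
    outer_radius_um = config@analysisOuterRadius,
    angular_span_deg = 360 / k)
}

#' Evaluate segmentation against phantom ground truth
#'
#' Greedy nearest-centroid bipartite matching: detected cells and ground-truth
#' cells are paired closest-first while the distance is at most `matchRadius`;
#' each cell matches at most once.
#'
#' @param cells data.frame from [segmentCells()].
#' @param truth ground-truth data.frame from [generateRetinaPhantom()].
#' @param matchRadius matching radius in um (default from `config`).
#' @param config a [MorphometryConfig-class].
#' @return A list: `recall`, `precision`, `nMatched`, `somaAbsRelError`
#'   (mean |measured - true| / true over matched pairs) and `matches`
#'   (data.frame of matched index pairs with areas).
#' @export
evaluateSegmentation <- function(cells, truth, matchRadius = NULL,
                                 config = morphometryConfig()) {
  if (is.null(matchRadius)) matchRadius <- config@matchRadius
  nD <- nrow(cells); nT <- nrow(truth)
  if (nT == 0L)
    return(list(recall = NA_real_, precision = if (nD) 0 else NA_real_,
                nMatched = 0L, somaAbsRelError = NA_real_,
                matches = NULL))
  if (nD == 0L)
    return(list(recall = 0, precision = NA_real_, nMatched = 0L,
                somaAbsRelError = NA_real_, matches = NULL))
  dm <- crossDist(cbind(cells$x_um, cells$y_um),
                  cbind(truth$x_um, truth$y_um))
  pairs <- list()
  repeat {
    mn <- min(dm)
    if (!is.finite(mn) || mn > matchRadius) break
    w <- which(dm == mn, arr.ind = TRUE)[1L, ]
    pairs[[length(pairs) + 1L]] <- w
    dm[w[1L], ] <- Inf
    dm[, w[2L]] <- Inf
  }
  nM <- length(pairs)
  matches <- NULL
  err <- NA_real_
  if (nM > 0L) {
    pm <- do.call(rbind, pairs)
    matches <- data.frame(
      cell = pm[, 1L], truth = pm[, 2L],
      soma_area_um2 = cells$soma_area_um2[pm[, 1L]],
      true_soma_area_um2 = truth$true_soma_area_um2[pm[, 2L]])
    err <- mean(abs(matches$soma_area_um2 - matches$true_soma_area_um2) /
                  matches$true_soma_area_um2)
  }
  list(recall = nM / nT, precision = nM / nD, nMatched = nM,
       somaAbsRelError = err, matches = matches)
}
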