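## Reading and writing images, tables and configuration.

#' Read a retinal fluorescence image into a RetinaFrame
#'
#' TIFF or PNG; multichannel images are averaged to grayscale. Intensities
#' are kept on the scale returned by the reader (the analysis is
#' threshold-relative, so absolute scaling is immaterial).
#'
#' @param path image file (TIFF/PNG).
#' @param pixelScale micrometres per pixel.
#' @param onhCenter (x, y) of the optic-disc center in um; defaults to the
#'   image center.
#' @param eyeId,ageMonths metadata.
#' @return A [RetinaFrame-class].
#' @export
readRetinaImage <- function(path, pixelScale, onhCenter = NULL,
                            eyeId = basename(path), ageMonths = NA_real_) {
  img <- EBImage::readImage(path)
  d <- dim(img)
  m <- if (length(d) == 3L)
    t(apply(EBImage::imageData(img), c(1L, 2L), mean))
  else t(EBImage::imageData(img))
  if (is.null(onhCenter))
    onhCenter <- (dim(m)[c(2L, 1L)] - 1L) * pixelScale / 2
  retinaFrame(m, pixelScale, onhCenter, eyeId = eyeId, ageMonths = ageMonths)
}

#' Read an optic-nerve cross-section image into a NerveSection
#'
#' RGB images are honored by taking the red channel; grayscale images are
#' treated as the red channel. Optional masks are 0/255 (or 0/1) images.
#'
#' @param path image file (TIFF/PNG).
#' @param pixelScale micrometres per pixel.
#' @param nerveMaskPath,vesselMaskPath,meningesMaskPath optional mask images.
#' @param sectionId identifier.
#' @return A [NerveSection-class].
#' @export
readNerveImage <- function(path, pixelScale, nerveMaskPath = NULL,
                           vesselMaskPath = NULL, meningesMaskPath = NULL,
                           sectionId = basename(path)) {
  img <- EBImage::readImage(path)
  d <- dim(img)
  m <- if (length(d) == 3L) t(EBImage::imageData(img)[, , 1L])
       else t(EBImage::imageData(img))
  readMask <- function(p) {
    if (is.null(p)) return(NULL)
    mm <- EBImage::readImage(p)
    if (length(dim(mm)) == 3L) mm <- mm[, , 1L]
    t(EBImage::imageData(mm)) > 0.5
  }
  nerveSection(m, pixelScale,
               nerveMask = readMask(nerveMaskPath),
               vesselMask = readMask(vesselMaskPath),
               meningesMask = readMask(meningesMaskPath),
               sectionId = sectionId)
}

#' Write a retina phantom to disk
#'
#' The image goes out as a single-channel 16-bit TIFF (intensities scaled to
#' [0, 1] by the image maximum) and the ground truth as JSON.
#'
#' @param phantom list from [generateRetinaPhantom()].
#' @param dir output directory (created if needed).
#' @param name file stem.
#' @return Invisibly, the two paths written.
#' @export
writeRetinaPhantom <- function(phantom, dir, name = "retina_phantom") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img <- imageData2d(phantom$frame)
  imgPath <- file.path(dir, paste0(name, ".tiff"))
  EBImage::writeImage(EBImage::Image(t(img / max(img, 1))), imgPath,
                      bits.per.sample = 16L)
  truthPath <- file.path(dir, paste0(name, "_truth.json"))
  jsonlite::write_json(list(
    pixel_scale_um_per_px = pixelScale(phantom$frame),
    onh_center_um = onhCenter(phantom$frame),
    cells = phantom$truth), truthPath, auto_unbox = TRUE, digits = NA)
  invisible(c(imgPath, truthPath))
}

#' Write a nerve phantom to disk
#'
#' Image as 16-bit TIFF, masks (nerve/vessels/meninges/glia truth) as 0/255
#' 8-bit PNGs.
#'
#' @param phantom list from [generateNervePhantom()].
#' @param dir output directory.
#' @param name file stem.
#' @return Invisibly, the paths written.
#' @export
writeNervePhantom <- function(phantom, dir, name = "nerve_phantom") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sec <- phantom$section
  paths <- file.path(dir, paste0(name, c(".tiff", "_nerve.png",
                                         "_vessels.png", "_meninges.png",
                                         "_glia_truth.png")))
  EBImage::writeImage(EBImage::Image(t(imageData2d(sec))), paths[1L],
                      bits.per.sample = 16L)
  masks <- list(sec@nerveMask, sec@vesselMask, sec@meningesMask,
                phantom$gliaTruth)
  for (i in seq_along(masks))
    EBImage::writeImage(EBImage::Image(t(masks[[i]] + 0)), paths[i + 1L])
  invisible(paths)
}

#' Read a morphometry configuration from YAML or JSON
#'
#' Keys are the [morphometryConfig()] arguments; unknown keys are an error and
#' missing keys take their defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A [MorphometryConfig-class].
#' @export
morphometryConfigFromFile <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(morphometryConfig))
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown morphometry config keys: ", paste(bad, collapse = ", "))
  do.call(morphometryConfig, cfg)
}

#' Read or write a cohort table CSV
#'
#' Canonical columns: `eye_id`, `age_months`, `onh_count`, `treated`,
#' `glial_fraction_pct` (and optionally `category`).
#'
#' @param path CSV file.
#' @return `readCohortCsv`: the cohort data.frame.
#' @export
readCohortCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("eye_id", "age_months", "onh_count", "treated")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("cohort CSV lacks columns: ", paste(missing, collapse = ", "))
  df$treated <- as.logical(df$treated)
  df
}

#' @rdname readCohortCsv
#' @param cohort cohort data.frame.
#' @export
writeCohortCsv <- function(cohort, path) {
  keep <- intersect(c("eye_id", "age_months", "onh_count", "treated",
                      "glial_fraction_pct", "category"), names(cohort))
  writeCsv(cohort[keep], path)
}
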