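## File interfaces: NIfTI and multi-page TIFF volumes, PNG/TIFF stained
## fields, CSV spectra, and the JSON study manifest.

#' Read / write a 3D volume
#'
#' NIfTI files go through RNifti; `.tif`/`.tiff` files are read as
#' multi-page stacks.  The voxel size (um) must be supplied for TIFF
#' stacks; for NIfTI it is taken from the header (mm converted to um)
#' unless overridden.
#'
#' @param path file path (`.nii`, `.nii.gz`, `.tif`, `.tiff`).
#' @param voxelSizeUm isotropic voxel size in micrometres.
#' @param tumorMask optional logical array.
#' @return a [VolumeImage].
#' @export
readVolume <- function(path, voxelSizeUm = NULL, tumorMask = NULL) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    vox <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
    for (i in seq_along(pages)) {
      p <- pages[[i]]
      if (length(dim(p)) == 3) p <- p[, , 1]
      vox[, , i] <- p
    }
    if (is.null(voxelSizeUm)) stop("voxelSizeUm is required for TIFF stacks")
  } else {
    img <- RNifti::readNifti(path)
    vox <- array(as.numeric(img), dim(img))
    if (is.null(voxelSizeUm)) {
      pd <- RNifti::pixdim(img)
      voxelSizeUm <- pd[1] * 1000
    }
  }
  VolumeImage(vox, voxelSizeUm, tumorMask)
}

#' @rdname readVolume
#' @param volume a [VolumeImage] to write.
#' @export
writeVolume <- function(volume, path) {
  stopifnot(is(volume, "VolumeImage"))
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    d <- dim(volume@voxels)
    vx <- volume@voxels
    rng <- range(vx)
    if (diff(rng) > 0) vx <- (vx - rng[1]) / diff(rng)
    pages <- lapply(seq_len(d[3]), function(i) vx[, , i])
    tiff::writeTIFF(pages, path)
  } else {
    img <- RNifti::asNifti(volume@voxels)
    RNifti::pixdim(img) <- rep(volume@voxelSize / 1000, 3)
    RNifti::writeNifti(img, path)
  }
  invisible(path)
}

#' Read / write a dynamic series as 4D NIfTI
#'
#' The fourth dimension is time; the frame interval is stored in the
#' temporal pixdim (seconds).
#'
#' @param path NIfTI file path.
#' @param frameInterval,baselineFrames timing metadata; `frameInterval`
#'   defaults to the header's temporal spacing.
#' @param roi optional logical 3D mask.
#' @return a [DynamicSeries].
#' @export
readDynamicSeries <- function(path, frameInterval = NULL, baselineFrames,
                              roi = NULL) {
  img <- RNifti::readNifti(path)
  sig <- array(as.numeric(img), dim(img))
  if (is.null(frameInterval)) {
    pd <- RNifti::pixdim(img)
    frameInterval <- if (length(pd) >= 4) pd[4] else stop("no temporal spacing in header")
  }
  DynamicSeries(sig, frameInterval, baselineFrames, roi)
}

#' @rdname readDynamicSeries
#' @param series a [DynamicSeries] to write.
#' @export
writeDynamicSeries <- function(series, path) {
  stopifnot(is(series, "DynamicSeries"))
  img <- RNifti::asNifti(series@signal)
  RNifti::pixdim(img) <- c(1, 1, 1, series@frameInterval)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read / write a stained field image
#'
#' @param path `.png` or `.tif`/`.tiff` path.
#' @param umPerPx pixel size in micrometres.
#' @param magnification optional tag.
#' @return a [StainField].
#' @export
readStainField <- function(path, umPerPx, magnification = "") {
  img <- if (grepl("\\.png$", path, ignore.case = TRUE))
    png::readPNG(path) else tiff::readTIFF(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  StainField(img[, , 1:3], umPerPx, magnification)
}

#' @rdname readStainField
#' @param field a [StainField] to write.
#' @export
writeStainField <- function(field, path) {
  stopifnot(is(field, "StainField"))
  if (grepl("\\.png$", path, ignore.case = TRUE))
    png::writePNG(field@rgb, path)
  else tiff::writeTIFF(field@rgb, path)
  invisible(path)
}

#' Read / write spectra as CSV
#'
#' The matrix layout has ppm in the first column and one column per sample;
#' labels travel in a companion two-column CSV (`sample`, `label`).
#'
#' @param path spectra CSV path.
#' @param labelsPath labels CSV path.
#' @return a [SpectrumSet].
#' @export
readSpectraCsv <- function(path, labelsPath) {
  df <- read.csv(path, check.names = FALSE)
  ppm <- df[[1]]
  x <- t(as.matrix(df[, -1, drop = FALSE]))
  lab <- read.csv(labelsPath)
  labels <- lab$label[match(rownames(x), lab$sample)]
  SpectrumSet(x, ppm, labels)
}

#' @rdname readSpectraCsv
#' @param spectra a [SpectrumSet] to write.
#' @export
writeSpectraCsv <- function(spectra, path, labelsPath) {
  stopifnot(is(spectra, "SpectrumSet"))
  x <- intensities(spectra)
  sample <- rownames(x)
  if (is.null(sample)) sample <- paste0("s", seq_len(nrow(x)))
  df <- data.frame(ppm = ppmAxis(spectra), t(x), check.names = FALSE)
  colnames(df) <- c("ppm", sample)
  write.csv(df, path, row.names = FALSE)
  write.csv(data.frame(sample = sample, label = as.character(classLabels(spectra))),
            labelsPath, row.names = FALSE)
  invisible(path)
}

# write a generated study to disk with a JSON manifest
writeStudy <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (arm in names(study$arms)) {
    for (tumor in study$arms[[arm]]) {
      base <- file.path(dir, tumor$id)
      writeVolume(tumor$microct$volume, paste0(base, "_microct.nii.gz"))
      for (day in names(tumor$dce))
        writeDynamicSeries(tumor$dce[[day]]$series,
                           paste0(base, "_dce_day", day, ".nii.gz"))
      writeStainField(tumor$histKi67$field, paste0(base, "_ki67.png"))
      writeStainField(tumor$histSma$field, paste0(base, "_sma.png"))
    }
  }
  writeSpectraCsv(study$spectra, file.path(dir, "spectra.csv"),
                  file.path(dir, "spectra_labels.csv"))
  manifest <- study$manifest
  manifest$tumors <- as.list(manifest$tumors)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Serialize a study report
#'
#' Writes the comparison table and per-tumor metrics as CSV and the full
#' report (including chemometrics and provenance) as JSON.
#'
#' @param report a `StudyReport`.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
writeStudyReport <- function(report, dir) {
  stopifnot(inherits(report, "StudyReport"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$comparisons, file.path(dir, "comparisons.csv"),
            row.names = FALSE)
  write.csv(report$perTumor, file.path(dir, "per_tumor.csv"), row.names = FALSE)
  js <- list(
    comparisons = report$comparisons,
    plsda = list(
      looSensitivity = report$plsda$model@cvSensitivity,
      looSpecificity = report$plsda$model@cvSpecificity,
      permutationP = if (!is.null(report$plsda$permutation))
        report$plsda$permutation$pValue else NULL,
      region = report$plsda$region),
    exclusions = report$exclusions,
    provenance = report$provenance[c("seed", "package", "effectSizes")])
  jsonlite::write_json(js, file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}
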