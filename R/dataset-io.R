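# Disk layout: <path>/images/<stem>.png|tif + <path>/masks/<stem>.png|tif
# with matching stems, masks stored as {0, 255} 8-bit, plus a JSON
# manifest (style, seed, n, optional split plan).

read_image_file <- function(f) {
  ext <- tolower(tools::file_ext(f))
  img <- switch(ext,
                png = png::readPNG(f),
                tif = ,
                tiff = tiff::readTIFF(f),
                stop("unsupported image format: .", ext))
  if (length(dim(img)) == 2L) img <- array(img, dim = c(dim(img), 1L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]  # drop alpha
  img
}

write_image_file <- function(img, f) {
  ext <- tolower(tools::file_ext(f))
  if (length(dim(img)) == 3L && dim(img)[3] == 1L) img <- img[, , 1L]
  switch(ext,
         png = png::writePNG(img, f),
         tif = ,
         tiff = tiff::writeTIFF(img, f, bits.per.sample = 8L),
         stop("unsupported image format: .", ext))
  invisible(f)
}

#' Write a dataset to disk
#'
#' @param dataset a `seg_dataset` (see [synthesize_dataset()])
#' @param path target directory (created if missing); gets `images/` and
#'   `masks/` subdirectories plus `manifest.json`
#' @param format `"png"` (default) or `"tif"`
#' @param splits optional [make_splits()] plan recorded in the manifest
#' @export
write_dataset <- function(dataset, path, format = c("png", "tif"),
                          splits = NULL) {
  format <- match.arg(format)
  stopifnot(inherits(dataset, "seg_dataset"))
  dir.create(file.path(path, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(path, "masks"), recursive = TRUE, showWarnings = FALSE)
  n <- length(dataset$images)
  stems <- sprintf("img_%04d", seq_len(n))
  for (i in seq_len(n)) {
    write_image_file(dataset$images[[i]],
                     file.path(path, "images", paste0(stems[i], ".", format)))
    write_image_file(dataset$masks[[i]],
                     file.path(path, "masks", paste0(stems[i], ".", format)))
  }
  manifest <- list(style = unclass(dataset$style), seed = dataset$seed,
                   n = n, format = format, stems = stems)
  if (!is.null(splits))
    manifest$splits <- list(n = splits$n, subset = splits$subset,
                            test_subset = splits$test_subset,
                            seed = splits$seed,
                            folds = lapply(splits$folds, unclass))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a dataset from disk
#'
#' Expects the layout written by [write_dataset()]: every image in
#' `images/` must have a mask in `masks/` with the same stem; masks must
#' be strictly binary ({0, 255} on disk) and are read back to \{0, 1\}.
#'
#' @param path dataset directory
#' @return a `seg_dataset`
#' @export
read_dataset <- function(path) {
  imgdir <- file.path(path, "images"); mskdir <- file.path(path, "masks")
  imgs <- sort(list.files(imgdir, pattern = "\\.(png|tif|tiff)$",
                          ignore.case = TRUE))
  if (length(imgs) == 0L) {
    warning("no images found under ", imgdir, "; returning empty dataset")
    return(structure(list(images = list(), masks = list(), style = NULL,
                          seed = NA_integer_), class = "seg_dataset"))
  }
  msks <- list.files(mskdir, pattern = "\\.(png|tif|tiff)$",
                     ignore.case = TRUE)
  msk_stems <- tools::file_path_sans_ext(msks)
  images <- vector("list", length(imgs)); masks <- vector("list", length(imgs))
  for (i in seq_along(imgs)) {
    stem <- tools::file_path_sans_ext(imgs[i])
    j <- match(stem, msk_stems)
    if (is.na(j))
      stop("missing mask for image ", imgs[i])
    images[[i]] <- read_image_file(file.path(imgdir, imgs[i]))
    m <- read_image_file(file.path(mskdir, msks[j]))[, , 1L]
    vals <- sort(unique(round(as.numeric(m) * 255)))
    if (!all(vals %in% c(0, 255)))
      stop("mask ", msks[j], " is not binary: found 8-bit values ",
           paste(setdiff(vals, c(0, 255)), collapse = ", "),
           " (expected only 0 and 255)")
    masks[[i]] <- matrix(as.numeric(m > 0.5), nrow(m), ncol(m))
  }
  style <- NULL; seed <- NA_integer_
  mf <- file.path(path, "manifest.json")
  if (file.exists(mf)) {
    man <- jsonlite::read_json(mf, simplifyVector = TRUE)
    seed <- if (!is.null(man$seed)) as.integer(man$seed) else NA_integer_
    if (!is.null(man$style))
      style <- tryCatch(
        synthetic_style(man$style$name, man$style$image_size,
                        man$style$channels, man$style$noise_sigma,
                        man$style$speckle, man$style$n_objects),
        error = function(e) NULL)
  }
  structure(list(images = images, masks = masks, style = style, seed = seed),
            class = "seg_dataset")
}
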