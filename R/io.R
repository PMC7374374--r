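#' Read a grayscale image
#'
#' PNG/TIFF images are read through EBImage (multichannel inputs are
#' averaged to gray); NIfTI volumes (`.nii`/`.nii.gz`, requires the RNifti
#' package) yield a single sagittal slice.
#'
#' @param path image file path.
#' @param slice sagittal slice index (first array dimension), for NIfTI
#'   input only.
#' @return grayscale matrix (rows = y, cols = x) with the file's intensity
#'   range (PNG/TIFF land in `[0, 1]`).
#' @export
read_gray_image <- function(path, slice = NULL) {
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("NIfTI input requires the RNifti package")
    vol <- RNifti::asNifti(RNifti::readNifti(path))
    if (is.null(slice)) stop("supply `slice` for NIfTI input")
    return(t(vol[slice, , ]))
  }
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) == 3) dat <- apply(dat, c(1, 2), mean)
  t(dat)
}

#' Write / read a binary mask as PNG (0/255)
#'
#' @param mask binary matrix.
#' @param path PNG file path.
#' @return `write_mask_png` returns `path` invisibly; `read_mask_png`
#'   returns a binary matrix.
#' @export
write_mask_png <- function(mask, path) {
  assert_binary_mask(mask)
  EBImage::writeImage(EBImage::Image(t(mask)), path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  m <- read_gray_image(path)
  matrix(as.numeric(m > 0.5), nrow(m), ncol(m))
}

#' Write a grayscale image as 8-bit PNG
#'
#' @param img matrix with values in `[0, 1]`.
#' @param path PNG file path.
#' @return `path`, invisibly.
#' @export
write_gray_png <- function(img, path) {
  EBImage::writeImage(EBImage::Image(t(pmin(pmax(img, 0), 1))), path)
  invisible(path)
}

#' Write / read a fixture set as paired PNGs plus a manifest
#'
#' Each item becomes `img_NNN.png` (8-bit gray) and `mask_NNN.png` (0/255);
#' `manifest.yaml` records kind, generator parameters and seed per item.
#' Accepts a list of fixtures or an `lbseg_augset`.
#'
#' @param x list of `lbseg_fixture` objects, a single fixture, or an
#'   `lbseg_augset`.
#' @param dir output directory (created if missing).
#' @return `write_fixtures` returns `dir` invisibly; `read_fixtures`
#'   returns a list of items, each with `image`, `truth` and the manifest
#'   metadata.
#' @export
write_fixtures <- function(x, dir) {
  if (inherits(x, "lbseg_fixture")) x <- list(x)
  items <- if (inherits(x, "lbseg_augset")) x$items else x
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- vector("list", length(items))
  for (i in seq_along(items)) {
    it <- items[[i]]
    img_f <- sprintf("img_%03d.png", i)
    msk_f <- sprintf("mask_%03d.png", i)
    write_gray_png(it$image, file.path(dir, img_f))
    write_mask_png(it$truth, file.path(dir, msk_f))
    manifest[[i]] <- list(
      image = img_f, mask = msk_f,
      kind = if (is.null(it$kind)) "unknown" else it$kind,
      params = it$params, seed = it$seed,
      angle_deg = it$angle_deg, base_index = it$base_index)
  }
  yaml::write_yaml(list(n = length(items), items = manifest),
                   file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' @rdname write_fixtures
#' @export
read_fixtures <- function(dir) {
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  lapply(man$items, function(it) {
    c(list(image = read_gray_image(file.path(dir, it$image)),
           truth = read_mask_png(file.path(dir, it$mask))),
      it[setdiff(names(it), c("image", "mask"))])
  })
}

#' Read / write a run configuration as YAML
#'
#' The YAML mirrors the [run_config()] structure: a `contour` block
#' (lambda, alpha, mu, epsilon, sigma, c, dt, tau_factor, max_iter, tol,
#' patience, boundary, reinit), a `dbn` block (the [dbn_config()] fields)
#' and a top-level `seed`. Missing keys keep their defaults.
#'
#' @param path YAML file path.
#' @param cfg a [run_config()].
#' @return `read_run_config` returns an `lbseg_run_config`;
#'   `write_run_config` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cc <- do.call(contour_config,
                y$contour[names(y$contour) %in%
                            names(formals(contour_config))])
  dc <- do.call(dbn_config,
                y$dbn[names(y$dbn) %in% names(formals(dbn_config))])
  run_config(contour = cc, dbn = dc,
             seed = if (is.null(y$seed)) 1L else y$seed)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "lbseg_run_config"))
  yaml::write_yaml(list(contour = unclass(cfg$contour),
                        dbn = unclass(cfg$dbn), seed = cfg$seed), path)
  invisible(path)
}
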