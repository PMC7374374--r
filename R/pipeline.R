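#' Full-run configuration
#'
#' Bundles the contour/solver configuration, the DBN hyperparameters and
#' the run seed.
#'
#' @param contour a [contour_config()].
#' @param dbn a [dbn_config()].
#' @param seed integer run seed.
#' @return list of class `lbseg_run_config`.
#' @export
run_config <- function(contour = contour_config(), dbn = dbn_config(),
                       seed = 1) {
  structure(list(contour = contour, dbn = dbn, seed = as.integer(seed)),
            class = "lbseg_run_config")
}

#' Min-max normalize a grayscale image to [0, 1]
#'
#' @param img numeric matrix.
#' @return matrix with values in `[0, 1]` (a constant image maps to 0).
#' @export
normalize_gray <- function(img) {
  rng <- range(img)
  if (rng[2] == rng[1]) return(img * 0)
  (img - rng[1]) / (rng[2] - rng[1])
}

#' Conform an image to the working resolution
#'
#' Larger inputs are center-cropped (default) or resampled to `target`;
#' a warning reports the adjustment. Smaller inputs are an error.
#'
#' @param img grayscale matrix.
#' @param target target dimensions `(h, w)`.
#' @param method `"crop"` or `"resize"`.
#' @return matrix of dimensions `target`.
#' @export
conform_gray <- function(img, target = c(100, 100),
                         method = c("crop", "resize")) {
  method <- match.arg(method)
  if (identical(dim(img), as.integer(target)) ||
      identical(dim(img), target)) return(img)
  if (any(dim(img) < target))
    stop(sprintf("image %s is smaller than the working resolution %s",
                 paste(dim(img), collapse = "x"),
                 paste(target, collapse = "x")))
  warning(sprintf("conforming %s image to %s by %s",
                  paste(dim(img), collapse = "x"),
                  paste(target, collapse = "x"), method))
  if (method == "crop") {
    r0 <- floor((nrow(img) - target[1]) / 2)
    c0 <- floor((ncol(img) - target[2]) / 2)
    img[r0 + seq_len(target[1]), c0 + seq_len(target[2])]
  } else {
    t(EBImage::imageData(EBImage::resize(EBImage::Image(t(img)),
                                         w = target[2], h = target[1])))
  }
}

#' Segment an image with the DBN-driven lattice-Boltzmann model
#'
#' The trained DBN infers a patient-specific shape mask from the image;
#' that mask builds both the shape-prior field `psi` and the three-level
#' initial level-set field `phi0`; the lattice-Boltzmann evolution then
#' refines the contour under the edge-gated curvature, balloon and
#' shape-prior forces. The final mask is `{phi < 0}`.
#'
#' @param image grayscale matrix in `[0, 1]` matching the model input size
#'   (use [normalize_gray()] / [conform_gray()] upstream for raw inputs).
#' @param model a trained `lbseg_dbn`.
#' @param cfg a [run_config()].
#' @return list of class `lbseg_segmentation`: `mask`, `inference` (the
#'   [infer_shape()] result), `iterations`, `energy`, `lb` (the full
#'   [lb_run()] result).
#' @export
segment_image <- function(image, model, cfg = run_config()) {
  inf <- infer_shape(image, model, cfg$dbn, seed = cfg$seed)
  if (sum(inf$mask) == 0)
    stop("inferred shape mask is empty: no contour to evolve")
  cc <- cfg$contour
  psi <- shape_prior_field(inf$mask, cc$c)
  phi0 <- init_levelset(inf$mask, cc$c)
  res <- lb_run(phi0, image = image, psi = psi, cfg = cc)
  structure(list(mask = res$mask, inference = inf,
                 iterations = res$iterations, energy = res$energy,
                 lb = res),
            class = "lbseg_segmentation")
}

#' @export
print.lbseg_segmentation <- function(x, ...) {
  cat(sprintf(
    "<lbseg_segmentation> mask area %d px, %d LB iterations, %d Gibbs sweeps\n",
    sum(x$mask), x$iterations, x$inference$gibbs_iters_used))
  invisible(x)
}

#' Shape-term ablation
#'
#' Runs [segment_image()] twice, with the shape weight `mu` as configured
#' and with `mu = 0` (the `mu = 0` path never evaluates the prior field in
#' the force), and scores both masks against the ground truth.
#'
#' @param image grayscale matrix.
#' @param model a trained `lbseg_dbn`.
#' @param truth binary ground-truth mask.
#' @param cfg a [run_config()].
#' @return list with `with_prior`, `without_prior` (each an
#'   `lbseg_segmentation`), `dice_with`, `dice_without`.
#' @export
ablate_shape_term <- function(image, model, truth, cfg = run_config()) {
  cfg0 <- cfg
  cfg0$contour$mu <- 0
  a <- segment_image(image, model, cfg)
  b <- segment_image(image, model, cfg0)
  list(with_prior = a, without_prior = b,
       dice_with = dice(a$mask, truth),
       dice_without = dice(b$mask, truth))
}
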