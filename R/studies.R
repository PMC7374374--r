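#' Reference synthetic studies
#'
#' Canonical fixture families, training configurations and held-out test
#' sets for the package's built-in synthetic experiments: a graded ellipse
#' family (size recovery at unseen rotations), a single-ellipse family
#' (occlusion and missing parts), a graded fish family (convergence speed)
#' and a blob family with adjustable atrophy (shape-prior efficacy under
#' weak boundaries). Families are graded deliberately: neighbouring shapes
#' overlap enough that the Gibbs chain can climb between modes, mirroring
#' the anatomical continuity of real training sets.
#'
#' @name reference_studies
NULL

#' @rdname reference_studies
#' @param level `"standard"` (the graded ellipse study), `"fish"` (the
#'   fish study, trained longer and inferred with more restarts), or
#'   `"light"` (the single-family studies, where memorization is easier).
#' @return `study_dbn_config`: a [dbn_config()].
#' @export
study_dbn_config <- function(level = c("standard", "fish", "light")) {
  level <- match.arg(level)
  switch(level,
    standard = dbn_config(n_hidden1 = 300, n_hidden2 = 300, cd_k = 3,
                          epochs1 = 80, epochs2 = 300, sparsity_cost = 1,
                          gibbs_tol = 0, gibbs_iters = 250, restarts = 3),
    fish = dbn_config(n_hidden1 = 300, n_hidden2 = 300, cd_k = 3,
                      epochs1 = 80, epochs2 = 500, sparsity_cost = 1,
                      gibbs_tol = 0, gibbs_iters = 300, restarts = 6),
    light = dbn_config(n_hidden1 = 150, n_hidden2 = 150, cd_k = 3,
                       epochs1 = 40, epochs2 = 150, sparsity_cost = 1,
                       gibbs_tol = 0, gibbs_iters = 200, restarts = 2))
}

#' @rdname reference_studies
#' @return `study_ellipse_family`: five clean ellipses of graded size.
#' @export
study_ellipse_family <- function() {
  axes <- list(c(14, 9), c(16, 10.5), c(18, 12), c(20, 13), c(22, 14))
  lapply(seq_along(axes), function(i)
    make_ellipse(axes = axes[[i]], seed = 100 + i))
}

#' @rdname reference_studies
#' @param n number of held-out fixtures.
#' @param seed_base offset for the per-fixture noise seeds.
#' @return `study_heldout_ellipses`: `n` fixtures cycling through the
#'   family shapes at rotations 5, 15, ..., 55 degrees (absent from the
#'   0..60-by-10 training grid), with fresh noise.
#' @export
study_heldout_ellipses <- function(n = 30, seed_base = 300) {
  axes <- list(c(14, 9), c(16, 10.5), c(18, 12), c(20, 13), c(22, 14))
  lapply(seq_len(n), function(i) {
    sh <- ((i - 1) %% length(axes)) + 1
    ang <- 5 + 10 * (((i - 1) %/% length(axes)) %% 6)
    make_ellipse(axes = axes[[sh]], angle = ang, seed = seed_base + i)
  })
}

#' @rdname reference_studies
#' @return `study_fish_family`: five fish silhouettes graded in scale and
#'   bend.
#' @export
study_fish_family <- function() {
  pars <- study_fish_params()
  lapply(seq_along(pars), function(i)
    make_fish(scale = pars[[i]][1], bend = pars[[i]][2], seed = 20 + i))
}

study_fish_params <- function() {
  list(c(0.7, -0.2), c(0.8, -0.1), c(0.9, 0), c(1.0, 0.1), c(1.1, 0.2))
}

#' @rdname reference_studies
#' @return `study_fish_tests`: `n` fish fixtures with the family's shape
#'   parameters and fresh noise realizations.
#' @export
study_fish_tests <- function(n = 7, seed_base = 600) {
  pars <- study_fish_params()
  lapply(seq_len(n), function(i) {
    p <- pars[[((i - 1) %% length(pars)) + 1]]
    make_fish(scale = p[1], bend = p[2], seed = seed_base + i)
  })
}

#' @rdname reference_studies
#' @return `study_blob_family`: three blobs at atrophy 0, 0.35 and 0.7.
#' @export
study_blob_family <- function() {
  lapply(c(0, 0.35, 0.7), function(a)
    make_hc_blob(atrophy = a, seed = round(10 + 10 * a)))
}

#' @rdname reference_studies
#' @param gap boundary fraction with suppressed contrast.
#' @param seed noise seed of the test blob.
#' @return `study_blob_test`: a mid-atrophy blob with the requested
#'   edge gap.
#' @export
study_blob_test <- function(gap = 0.4, seed = 77) {
  make_hc_blob(atrophy = 0.35, edge_gap_fraction = gap, seed = seed)
}

#' Train a shape model on the rotation-augmented family
#'
#' Convenience wrapper: augments the base fixtures over 0..60 degrees in
#' 10-degree steps (the standard augmentation scheme) and trains the DBN.
#'
#' @param base list of `lbseg_fixture` objects.
#' @param config a [dbn_config()].
#' @param seed training seed.
#' @return an `lbseg_dbn`.
#' @export
train_on_rotations <- function(base, config = study_dbn_config(), seed = 1) {
  aug <- augment_rotations(base, 60, 10)
  train_dbn(lapply(aug$items, `[[`, "image"),
            lapply(aug$items, `[[`, "truth"),
            config, seed = seed)
}
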