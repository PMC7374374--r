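#' Contour configuration
#'
#' Bundles the weights and numerical parameters of the level-set energy
#' `E = lambda * L_g(phi) + alpha * A_g(phi) + mu * S(phi, psi)` and of the
#' lattice-Boltzmann evolution that minimizes it.
#'
#' @param lambda weight of the edge-weighted contour-length term (> 0).
#' @param alpha weight of the edge-weighted region (balloon) term; its sign
#'   sets the inward/outward pressure.
#' @param mu weight of the shape-prior distance term (> 0).
#' @param epsilon width of the regularized Heaviside/Dirac band, grid units.
#' @param sigma Gaussian kernel sd (px) of the edge indicator.
#' @param gray_scale factor mapping the `[0, 1]` working intensities back
#'   to gray levels before the edge indicator's gradient is taken (default
#'   255, the 8-bit convention under which the classic weight settings
#'   were calibrated; with 1, unit-range images yield gradients too small
#'   for the edge gate to act).
#' @param c plateau constant of the level-set field and shape prior; must
#'   exceed `epsilon` so the prior saturates the regularized Heaviside.
#' @param dt lattice time step.
#' @param tau_factor coefficient linking `lambda * g * dirac` to the BGK
#'   relaxation time, `tau = tau_factor * lambda * g * dirac + 1/2`. The
#'   model's printed coupling uses 5; 2.5 reproduces the diffusion weight
#'   implied by matching the macroscopic limit term by term.
#' @param max_iter,tol,patience solver stopping rule: stop once the number
#'   of mask pixels changing per iteration is `<= tol` for `patience`
#'   consecutive iterations.
#' @param boundary streaming boundary handling, `"replicate"` or
#'   `"periodic"`.
#' @param reinit if `TRUE`, `phi` is re-projected to the three-level
#'   `{-c, 0, c}` profile each iteration (off by default; the evolution is
#'   run without reinitialization).
#' @return a list of class `lbseg_contour_config`.
#' @export
contour_config <- function(lambda = 10, alpha = 0.5, mu = 50,
                           epsilon = 1.5, sigma = 1.5, c = 2, dt = 0.1,
                           tau_factor = 5, max_iter = 300, tol = 0,
                           patience = 2, boundary = c("replicate", "periodic"),
                           gray_scale = 255, reinit = FALSE) {
  boundary <- match.arg(boundary)
  stopifnot(lambda > 0, mu >= 0, epsilon > 0, sigma > 0, c > 0, dt > 0,
            tau_factor > 0, max_iter >= 0, tol >= 0, patience >= 1,
            gray_scale > 0)
  if (c <= epsilon)
    warning("`c` <= `epsilon`: the shape prior no longer saturates the ",
            "regularized Heaviside")
  structure(list(lambda = lambda, alpha = alpha, mu = mu, epsilon = epsilon,
                 sigma = sigma, c = c, dt = dt, tau_factor = tau_factor,
                 max_iter = max_iter, tol = tol, patience = patience,
                 boundary = boundary, gray_scale = gray_scale,
                 reinit = reinit),
            class = "lbseg_contour_config")
}

#' Regularized Heaviside function
#'
#' Smoothed step `H_eps(x)`: `0` for `x < -eps`, `1` for `x > eps`, and
#' `0.5 * (1 + x/eps + sin(pi * x / eps) / pi)` inside the band, which is
#' continuous at `x = +/- eps` and whose derivative is [dirac_eps()].
#'
#' @param x numeric vector or matrix.
#' @param eps band half-width (> 0).
#' @return values in `[0, 1]`, same shape as `x`.
#' @export
heaviside_eps <- function(x, eps) {
  stopifnot(eps > 0)
  out <- 0.5 * (1 + x / eps + sin(pi * x / eps) / pi)
  out[x > eps] <- 1
  out[x < -eps] <- 0
  out
}

#' Regularized Dirac delta
#'
#' `(1 + cos(pi * x / eps)) / (2 * eps)` for `|x| <= eps`, zero outside;
#' integrates to 1 and equals the derivative of [heaviside_eps()].
#'
#' @inheritParams heaviside_eps
#' @return nonnegative values, same shape as `x`.
#' @export
dirac_eps <- function(x, eps) {
  stopifnot(eps > 0)
  out <- (1 + cos(pi * x / eps)) / (2 * eps)
  out[abs(x) > eps] <- 0
  out
}

# Central differences with replicate padding; returns list(gx, gy).
grad_central <- function(m) {
  h <- nrow(m); w <- ncol(m)
  xl <- cbind(m[, 1, drop = FALSE], m[, -w, drop = FALSE])
  xr <- cbind(m[, -1, drop = FALSE], m[, w, drop = FALSE])
  yu <- rbind(m[1, , drop = FALSE], m[-h, , drop = FALSE])
  yd <- rbind(m[-1, , drop = FALSE], m[h, , drop = FALSE])
  list(gx = (xr - xl) / 2, gy = (yd - yu) / 2)
}

#' Edge indicator
#'
#' `g = 1 / (1 + |grad(G_sigma * I)|^2)`: close to 1 in flat regions, small
#' on strong edges. Smoothing uses an isotropic Gaussian kernel; the
#' gradient uses central differences with replicate borders.
#'
#' @param I grayscale image matrix with values in `[0, 1]`.
#' @param sigma Gaussian kernel sd in pixels (> 0).
#' @return matrix of values in `(0, 1]`, same shape as `I`.
#' @export
edge_indicator <- function(I, sigma = 1.5) {
  stopifnot(sigma > 0)
  sm <- EBImage::gblur(I, sigma = sigma)
  gr <- grad_central(sm)
  1 / (1 + gr$gx^2 + gr$gy^2)
}

#' Two-valued shape-prior field
#'
#' Builds `psi` from a binary mask `s`: `-c` where `s = 1` (inside the
#' prior shape), `+c` where `s = 0`.
#'
#' @param s binary mask matrix.
#' @param c plateau constant (> 0).
#' @return matrix `psi` taking exactly the values `{-c, +c}`.
#' @export
shape_prior_field <- function(s, c = 2) {
  assert_binary_mask(s, "s")
  stopifnot(c > 0)
  c * (1 - 2 * s)
}

#' Three-level level-set initialization from a mask
#'
#' `phi = -c` strictly inside the mask, `+c` outside, and `0` on the contour
#' pixels, taken as the inner boundary (mask pixels 4-adjacent to
#' background).
#'
#' @inheritParams shape_prior_field
#' @return a level-set field matrix taking values in `{-c, 0, +c}`.
#' @export
init_levelset <- function(s, c = 2) {
  assert_binary_mask(s, "s")
  stopifnot(c > 0)
  if (all(s == 0) || all(s == 1)) {
    warning("mask is empty or full: no contour exists")
    return(c * (1 - 2 * s))
  }
  phi <- c * (1 - 2 * s)
  phi[boundary_pixels(s) == 1] <- 0
  phi
}

#' Discrete energy terms of the contour model
#'
#' Computes the edge-weighted contour length
#' `L_g = sum g * dirac(phi) * |grad phi|`, the edge-weighted inside area
#' `A_g = sum g * H(-phi)`, and the shape distance
#' `S = sum (H(-phi) - H(-psi))^2`, all as pixel sums (pixel area 1).
#'
#' @param phi level-set field matrix.
#' @param psi shape-prior field matrix.
#' @param g edge-indicator matrix.
#' @param cfg a [contour_config()].
#' @return named numeric vector `c(Lg, Ag, S)`.
#' @export
energy_terms <- function(phi, psi, g, cfg = contour_config()) {
  stopifnot_same_dim(phi, psi, "phi/psi")
  stopifnot_same_dim(phi, g, "phi/g")
  eps <- cfg$epsilon
  gr <- grad_central(phi)
  Lg <- sum(g * dirac_eps(phi, eps) * sqrt(gr$gx^2 + gr$gy^2))
  Ag <- sum(g * heaviside_eps(-phi, eps))
  S <- sum((heaviside_eps(-phi, eps) - heaviside_eps(-psi, eps))^2)
  c(Lg = Lg, Ag = Ag, S = S)
}

#' Total contour energy
#'
#' `E = lambda * Lg + alpha * Ag + mu * S`; see [energy_terms()].
#'
#' @inheritParams energy_terms
#' @return scalar energy.
#' @export
contour_energy <- function(phi, psi, g, cfg = contour_config()) {
  e <- energy_terms(phi, psi, g, cfg)
  unname(cfg$lambda * e["Lg"] + cfg$alpha * e["Ag"] + cfg$mu * e["S"])
}

#' External force of the contour evolution
#'
#' `F = alpha * g * dirac(phi) + mu * dirac(phi) * (H(-phi) - H(-psi))`:
#' the balloon pressure plus the shape-prior restoring force, both confined
#' to the band `|phi| <= epsilon`.
#'
#' @inheritParams energy_terms
#' @return matrix `F`, same shape as `phi`.
#' @export
external_force <- function(phi, psi, g, cfg = contour_config()) {
  stopifnot_same_dim(phi, psi, "phi/psi")
  stopifnot_same_dim(phi, g, "phi/g")
  d <- dirac_eps(phi, cfg$epsilon)
  cfg$alpha * g * d +
    cfg$mu * d * (heaviside_eps(-phi, cfg$epsilon) -
                    heaviside_eps(-psi, cfg$epsilon))
}

#' Per-pixel BGK relaxation time
#'
#' `tau = tau_factor * lambda * g * dirac(phi) + 1/2` (default
#' `tau_factor = 5`): the relaxation time encodes the edge-gated diffusion
#' of the contour-length term; away from the contour `tau = 1/2` and the
#' lattice evolution is frozen.
#'
#' @inheritParams energy_terms
#' @return matrix `tau >= 1/2`, same shape as `phi`.
#' @export
tau_field <- function(phi, g, cfg = contour_config()) {
  stopifnot_same_dim(phi, g, "phi/g")
  cfg$tau_factor * cfg$lambda * g * dirac_eps(phi, cfg$epsilon) + 0.5
}

#' Split a force field over the five lattice directions
#'
#' Each of the five D2Q5 directions receives `F / 5`, so that one collision
#' step injects `dt * F` into the macroscopic field.
#'
#' @param F force matrix.
#' @return 3D array `(h, w, 5)` with each slice `F / 5`.
#' @export
force_per_direction <- function(F) {
  array(F / 5, dim = c(nrow(F), ncol(F), 5))
}
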