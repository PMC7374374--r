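#' D2Q5 lattice
#'
#' The five-direction 2D lattice: rest vector `(0,0)` plus the four axis
#' unit vectors, uniform weights `1/5`. Its second velocity moment is
#' `(2/5) * I`, which fixes the macroscopic diffusion coefficient
#' `D = (2/5) * (tau - 1/2)` of the BGK evolution.
#'
#' @format integer matrix `5 x 2`, one `(ex, ey)` displacement per row.
#' @export
D2Q5_E <- matrix(c(0L, 0L, 1L, 0L, 0L, 1L, -1L, 0L, 0L, -1L),
                 ncol = 2, byrow = TRUE,
                 dimnames = list(NULL, c("ex", "ey")))

# D2Q9 displacement family (documentation/reference only; the solver is D2Q5):
# (0,0), the four axis vectors, and the four diagonals (+-1, +-1).

#' Macroscopic field of a distribution state
#'
#' @param f distribution array `(h, w, 5)`.
#' @return matrix `(h, w)`, the per-pixel sum over the five directions.
#' @export
lb_macro <- function(f) {
  f[, , 1] + f[, , 2] + f[, , 3] + f[, , 4] + f[, , 5]
}

#' Equilibrium distribution
#'
#' Pure-diffusion equilibrium: each of the five directions carries
#' `macro / 5` (no velocity-dependent terms). The macroscopic field may be
#' signed; the level-set field is.
#'
#' @param macro matrix `(h, w)`.
#' @return distribution array `(h, w, 5)`.
#' @export
lb_equilibrium <- function(macro) {
  array(macro / 5, dim = c(nrow(macro), ncol(macro), 5))
}

#' BGK collision with force injection
#'
#' `f_a <- f_a + (1/tau) * (f_a^eq - f_a) + dt * F_a`, with the equilibrium
#' recomputed from the current macroscopic field. Collision conserves the
#' macroscopic value when the force is zero.
#'
#' @param f distribution array `(h, w, 5)`.
#' @param tau relaxation-time matrix `(h, w)`, all entries `>= 1/2`.
#' @param force_dir per-direction force array `(h, w, 5)`, or `NULL`.
#' @param dt time step.
#' @return updated distribution array.
#' @export
lb_collide <- function(f, tau, force_dir = NULL, dt = 1) {
  if (any(tau < 0.5))
    stop("relaxation time tau < 1/2: unstable regime, aborting")
  macro5 <- lb_macro(f) / 5
  inv_tau <- 1 / tau
  for (a in 1:5) f[, , a] <- f[, , a] + inv_tau * (macro5 - f[, , a])
  if (!is.null(force_dir)) f <- f + dt * force_dir
  f
}

shift_idx <- function(n, by, boundary) {
  # index vector such that new[i] = old[idx[i]] shifts content by `by`
  if (by == 0) return(seq_len(n))
  if (boundary == "periodic") ((seq_len(n) - 1 - by) %% n) + 1
  else pmin(pmax(seq_len(n) - by, 1), n)
}

#' Streaming step
#'
#' Shifts each directional population one lattice unit along its
#' displacement vector. `"periodic"` wraps; `"replicate"` pulls the border
#' population inward (zero-gradient boundaries).
#'
#' @param f distribution array `(h, w, 5)`.
#' @param boundary `"replicate"` or `"periodic"`.
#' @return streamed distribution array.
#' @export
lb_stream <- function(f, boundary = c("replicate", "periodic")) {
  boundary <- match.arg(boundary)
  h <- dim(f)[1]; w <- dim(f)[2]
  for (a in 2:5) {
    ex <- D2Q5_E[a, 1]; ey <- D2Q5_E[a, 2]
    ri <- shift_idx(h, ey, boundary)   # row index = y
    ci <- shift_idx(w, ex, boundary)   # col index = x
    f[, , a] <- f[ri, ci, a]
  }
  f
}

#' One outer iteration of the contour evolution
#'
#' Recomputes the relaxation time ([tau_field()]) and external force
#' ([external_force()]) from the current level-set field, then performs one
#' collision and one streaming step and recovers
#' `phi <- sum_a f_a`.
#'
#' @param f distribution array `(h, w, 5)`.
#' @param phi current level-set field.
#' @param psi shape-prior field.
#' @param g edge-indicator matrix.
#' @param cfg a [contour_config()].
#' @return list with updated `f` and `phi`.
#' @export
lb_step <- function(f, phi, psi, g, cfg = contour_config()) {
  tau <- tau_field(phi, g, cfg)
  fd <- force_per_direction(external_force(phi, psi, g, cfg))
  f <- lb_collide(f, tau, fd, cfg$dt)
  f <- lb_stream(f, cfg$boundary)
  list(f = f, phi = lb_macro(f))
}

#' Run the lattice-Boltzmann contour evolution
#'
#' Initializes the distributions at equilibrium of `phi0` and iterates
#' [lb_step()] until the segmentation mask `{phi < 0}` changes by at most
#' `cfg$tol` pixels for `cfg$patience` consecutive iterations, or
#' `cfg$max_iter` is reached. The contour energy is recorded at every
#' iteration.
#'
#' @param phi0 initial level-set field.
#' @param image grayscale image (used to build the edge indicator), or
#'   `NULL` if `g` is supplied.
#' @param psi shape-prior field.
#' @param cfg a [contour_config()].
#' @param g optional precomputed edge indicator.
#' @return list of class `lbseg_lb_result`: `phi`, `mask` (0/1 matrix),
#'   `iterations`, `energy` (length `iterations + 1`, starting at
#'   `phi0`), `changed` (mask pixels changed per iteration), `converged`.
#' @export
lb_run <- function(phi0, image = NULL, psi, cfg = contour_config(),
                   g = NULL) {
  if (is.null(g)) {
    if (is.null(image)) stop("supply either `image` or a precomputed `g`")
    g <- edge_indicator(image * cfg$gray_scale, cfg$sigma)
  }
  stopifnot_same_dim(phi0, psi, "phi0/psi")
  stopifnot_same_dim(phi0, g, "phi0/g")
  phi <- phi0
  f <- lb_equilibrium(phi)
  mask <- phi < 0
  energy <- contour_energy(phi, psi, g, cfg)
  changed <- integer(0)
  calm <- 0L
  iter <- 0L
  while (iter < cfg$max_iter) {
    st <- lb_step(f, phi, psi, g, cfg)
    f <- st$f; phi <- st$phi
    iter <- iter + 1L
    if (!all(is.finite(phi)))
      stop(sprintf("non-finite level-set field at iteration %d", iter))
    if (cfg$reinit) {
      phi <- init_levelset(matrix(as.numeric(phi < 0), nrow(phi), ncol(phi)),
                           cfg$c)
      f <- lb_equilibrium(phi)
    }
    new_mask <- phi < 0
    nch <- sum(new_mask != mask)
    changed <- c(changed, nch)
    mask <- new_mask
    energy <- c(energy, contour_energy(phi, psi, g, cfg))
    calm <- if (nch <= cfg$tol) calm + 1L else 0L
    if (calm >= cfg$patience) break
  }
  structure(list(phi = phi,
                 mask = matrix(as.numeric(mask), nrow(phi), ncol(phi)),
                 iterations = iter, energy = energy, changed = changed,
                 converged = calm >= cfg$patience),
            class = "lbseg_lb_result")
}

#' @export
print.lbseg_lb_result <- function(x, ...) {
  cat(sprintf(
    "<lbseg_lb_result> %d iterations (%s), mask area %d px, final energy %.3f\n",
    x$iterations, if (x$converged) "converged" else "max_iter reached",
    sum(x$mask), x$energy[length(x$energy)]))
  invisible(x)
}

#' Macroscopic diffusion coefficient of the D2Q5 BGK evolution
#'
#' `D = (2/5) * (tau - 1/2)`, from the Chapman-Enskog expansion of the
#' collision-streaming dynamics on the D2Q5 lattice.
#'
#' @param tau relaxation time (scalar or array), `>= 1/2`.
#' @return diffusion coefficient, same shape as `tau`.
#' @export
diffusion_coefficient <- function(tau) {
  if (any(tau < 0.5)) stop("tau must be >= 1/2")
  (2 / 5) * (tau - 0.5)
}
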