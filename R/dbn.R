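#' Logistic sigmoid
#'
#' `sigma(x) = 1 / (1 + exp(-x))`, evaluated through [stats::plogis()] for
#' numerical stability at large `|x|`.
#'
#' @param x numeric vector, matrix or array.
#' @return values in `(0, 1)`, same shape as `x`.
#' @export
sigmoid <- function(x) {
  out <- stats::plogis(x)
  if (!is.null(dim(x))) dim(out) <- dim(x)
  out
}

# Add a bias row-vector to every row of a matrix.
add_bias <- function(M, b) M + matrix(b, nrow(M), length(b), byrow = TRUE)

new_rbm <- function(W, b_vis, b_hid, recon_error = NULL, meta = NULL) {
  stopifnot(nrow(W) == length(b_vis), ncol(W) == length(b_hid),
            all(is.finite(W)), all(is.finite(b_vis)), all(is.finite(b_hid)))
  structure(list(W = W, b_vis = b_vis, b_hid = b_hid,
                 recon_error = recon_error, meta = meta),
            class = "lbseg_rbm")
}

#' @export
print.lbseg_rbm <- function(x, ...) {
  cat(sprintf("<lbseg_rbm> %d visible x %d hidden", nrow(x$W), ncol(x$W)))
  if (!is.null(x$recon_error))
    cat(sprintf("; recon error %.4g -> %.4g over %d epochs",
                x$recon_error[1], x$recon_error[length(x$recon_error)],
                length(x$recon_error)))
  cat("\n")
  invisible(x)
}

#' Hidden activation probabilities of an RBM
#'
#' `P(h_j = 1 | v) = sigma(b_hid_j + v . W[, j])`. The visible bias plays no
#' role in this conditional.
#'
#' @param v visible vector (length `n_vis`) or matrix (`n x n_vis`) with
#'   values in `[0, 1]`.
#' @param rbm an `lbseg_rbm`.
#' @return activation probabilities, vector or `n x n_hid` matrix.
#' @export
prop_up <- function(v, rbm) {
  vec <- is.null(dim(v))
  if (vec) v <- matrix(v, nrow = 1)
  if (ncol(v) != nrow(rbm$W))
    stop(sprintf("visible dimension %d does not match RBM (%d)",
                 ncol(v), nrow(rbm$W)))
  p <- sigmoid(add_bias(v %*% rbm$W, rbm$b_hid))
  if (vec) drop(p) else p
}

# Visible reconstruction probabilities P(v = 1 | h).
prop_down <- function(h, rbm) {
  vec <- is.null(dim(h))
  if (vec) h <- matrix(h, nrow = 1)
  p <- sigmoid(add_bias(h %*% t(rbm$W), rbm$b_vis))
  if (vec) drop(p) else p
}

#' Bernoulli sampling of a probability field
#'
#' Draws each component independently with its own success probability,
#' preserving the shape of `p`.
#'
#' @param p probabilities in `[0, 1]` (vector, matrix or array).
#' @param seed optional integer seed; when supplied the draw is made under
#'   that seed without disturbing the caller's RNG stream.
#' @return binary object of the same shape as `p`.
#' @export
sample_bernoulli <- function(p, seed = NULL) {
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  draw <- function() {
    out <- as.numeric(runif(length(p)) < p)
    dim(out) <- dim(p)
    out
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Train an RBM by contrastive divergence
#'
#' Stochastic minibatch CD-k with Bernoulli hidden units and `[0, 1]`-valued
#' visible units interpreted as Bernoulli means (visible reconstructions use
#' probabilities, not samples). Weights start from Gaussian noise of sd
#' `init_sd`, biases from zero. The mean squared one-step reconstruction
#' error is recorded per epoch.
#'
#' @param data numeric matrix (`n_items x n_vis`) with values in `[0, 1]`.
#' @param n_hidden number of hidden units.
#' @param cd_k number of Gibbs half-step pairs in the negative phase.
#' @param epochs number of passes over the data.
#' @param lr learning rate.
#' @param batch minibatch size.
#' @param seed integer seed; training is fully deterministic given it.
#' @param init_sd sd of the Gaussian weight initialization.
#' @param bias_init `"logodds"` starts the visible biases at the logit of
#'   the per-unit data mean (so the weights model structure beyond the
#'   marginal, the usual symmetry-breaking practice); `"zero"` starts them
#'   at zero.
#' @param sparsity_target,sparsity_cost when `sparsity_cost > 0`, a
#'   sparsity penalty nudges each hidden unit's mean activation toward
#'   `sparsity_target` (gradient `sparsity_cost * (target - mean activity)`
#'   applied to the hidden biases and, scaled by the mean visible input, to
#'   the weights), encouraging distributed feature codes.
#' @return an `lbseg_rbm` with a `recon_error` vector (one entry per epoch).
#' @export
train_rbm_cd <- function(data, n_hidden, cd_k = 1, epochs = 30, lr = 0.05,
                         batch = 32, seed = 1, init_sd = 0.01,
                         bias_init = c("logodds", "zero"),
                         sparsity_target = 0.1, sparsity_cost = 0) {
  data <- as.matrix(data)
  bias_init <- match.arg(bias_init)
  if (any(data < 0 | data > 1)) stop("training data must lie in [0, 1]")
  stopifnot(n_hidden >= 1, cd_k >= 1, epochs >= 1, batch >= 1, lr >= 0)
  n <- nrow(data); nv <- ncol(data)
  with_seed(seed, {
    W <- matrix(rnorm(nv * n_hidden, 0, init_sd), nv, n_hidden)
    b_vis <- if (bias_init == "logodds") {
      pm <- pmin(pmax(colMeans(data), 1e-3), 1 - 1e-3)
      log(pm / (1 - pm))
    } else numeric(nv)
    b_hid <- numeric(n_hidden)
    recon <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = batch)
      err <- 0
      for (s in starts) {
        idx <- ord[s:min(s + batch - 1, n)]
        v0 <- data[idx, , drop = FALSE]
        m <- nrow(v0)
        h0p <- sigmoid(add_bias(v0 %*% W, b_hid))
        hs <- (matrix(runif(m * n_hidden), m) < h0p) * 1
        for (k in seq_len(cd_k)) {
          vkp <- sigmoid(add_bias(hs %*% t(W), b_vis))
          hkp <- sigmoid(add_bias(vkp %*% W, b_hid))
          if (k < cd_k) hs <- (matrix(runif(m * n_hidden), m) < hkp) * 1
        }
        if (lr > 0) {
          W <- W + lr * (crossprod(v0, h0p) - crossprod(vkp, hkp)) / m
          b_vis <- b_vis + lr * colMeans(v0 - vkp)
          b_hid <- b_hid + lr * colMeans(h0p - hkp)
          if (sparsity_cost > 0) {
            sp <- sparsity_cost * (sparsity_target - colMeans(h0p))
            b_hid <- b_hid + lr * sp
            W <- W + lr * outer(colMeans(v0), sp)
          }
        }
        if (any(!is.finite(W)))
          stop(sprintf("non-finite RBM parameters at epoch %d", ep))
        err <- err + sum((v0 - vkp)^2)
      }
      recon[ep] <- err / (n * nv)
    }
    new_rbm(W, b_vis, b_hid, recon,
            meta = list(cd_k = cd_k, epochs = epochs, lr = lr,
                        batch = batch, seed = seed, init_sd = init_sd))
  })
}

new_top_rbm <- function(W2, WL, b2, a1, aL) {
  stopifnot(ncol(W2) == ncol(WL), ncol(W2) == length(b2),
            nrow(W2) == length(a1), nrow(WL) == length(aL))
  structure(list(W2 = W2, WL = WL, b2 = b2, a1 = a1, aL = aL),
            class = "lbseg_top_rbm")
}

#' Energy of the top joint RBM
#'
#' `E(h2, h1, L) = -b2.h2 - a1.h1 - aL.L - h1' W2 h2 - L' WL h2`, the
#' standard RBM energy with all linear terms negative, for the joint model
#' of the feature layer `h1` and the label layer `L` under the hidden layer
#' `h2`.
#'
#' @param h2,h1,L binary vectors of matching dimensions.
#' @param top an `lbseg_top_rbm` (`W2`: `n_h1 x n_h2`; `WL`: `n_L x n_h2`).
#' @return scalar energy.
#' @export
top_energy <- function(h2, h1, L, top) {
  if (length(h1) != nrow(top$W2) || length(L) != nrow(top$WL) ||
      length(h2) != ncol(top$W2))
    stop("dimension mismatch between configuration and top RBM parameters")
  -sum(top$b2 * h2) - sum(top$a1 * h1) - sum(top$aL * L) -
    drop(h1 %*% top$W2 %*% h2) - drop(L %*% top$WL %*% h2)
}

# Conditionals of the top RBM.
top_p_h2 <- function(h1, L, top)
  sigmoid(top$b2 + drop(h1 %*% top$W2) + drop(L %*% top$WL))
top_p_h1 <- function(h2, top) sigmoid(top$a1 + drop(top$W2 %*% h2))
top_p_L <- function(h2, top) sigmoid(top$aL + drop(top$WL %*% h2))

#' Free energy of a visible configuration of the top RBM
#'
#' `F(h1, L) = -a1.h1 - aL.L - sum_k softplus(b2_k + W2[,k].h1 + WL[,k].L)`,
#' the negative log unnormalized marginal probability of the visible pair
#' with the hidden layer summed out. Lower is more probable under the
#' model; used to rank candidate shape inferences from independent Gibbs
#' restarts.
#'
#' @param h1 feature-layer vector (binary or activation probabilities).
#' @param L label-layer vector (binary).
#' @param top an `lbseg_top_rbm`.
#' @return scalar free energy.
#' @export
top_free_energy <- function(h1, L, top) {
  x <- top$b2 + drop(h1 %*% top$W2) + drop(L %*% top$WL)
  softplus <- ifelse(x > 30, x, log1p(exp(x)))
  -sum(top$a1 * h1) - sum(top$aL * L) - sum(softplus)
}

#' Blocked Gibbs chain on the top RBM
#'
#' Alternates sampling `h2 | (h1, L)` and `(h1, L) | h2` (the two
#' conditionals factorize over units by the bipartite structure) and
#' records the sampled states, one row per sweep. Mainly used to validate
#' the sampler against exhaustive enumeration on toy models.
#'
#' @param top an `lbseg_top_rbm`.
#' @param sweeps number of Gibbs sweeps.
#' @param seed integer seed.
#' @param init optional list with binary start states `h1` and `L`
#'   (defaults to zeros).
#' @return list of sample matrices `h2`, `h1`, `L` (`sweeps x n_units`) and
#'   `pL` (the conditional `P(L = 1 | h2)` at each sweep).
#' @export
top_gibbs_chain <- function(top, sweeps, seed = 1, init = NULL) {
  n1 <- nrow(top$W2); nL <- nrow(top$WL); n2 <- ncol(top$W2)
  h1 <- if (is.null(init$h1)) numeric(n1) else init$h1
  L <- if (is.null(init$L)) numeric(nL) else init$L
  H2 <- matrix(0, sweeps, n2); H1 <- matrix(0, sweeps, n1)
  LS <- matrix(0, sweeps, nL); PL <- matrix(0, sweeps, nL)
  with_seed(seed, {
    for (t in seq_len(sweeps)) {
      h2 <- (runif(n2) < top_p_h2(h1, L, top)) * 1
      pL <- top_p_L(h2, top)
      L <- (runif(nL) < pL) * 1
      h1 <- (runif(n1) < top_p_h1(h2, top)) * 1
      H2[t, ] <- h2; H1[t, ] <- h1; LS[t, ] <- L; PL[t, ] <- pL
    }
  })
  list(h2 = H2, h1 = H1, L = LS, pL = PL)
}

#' Configuration of the DBN shape model
#'
#' Layer sizes and training/inference hyperparameters. The canonical layout
#' has a 100 x 100 input layer, two hidden layers of 1000 units each and a
#' 100 x 100 label layer; smaller hidden layers train much faster and are
#' adequate for narrow shape families.
#'
#' @param n_hidden1,n_hidden2 hidden layer sizes.
#' @param cd_k contrastive-divergence order.
#' @param epochs1,epochs2 training epochs for the first and top RBM.
#' @param lr learning rate.
#' @param batch minibatch size.
#' @param init_sd sd of weight initialization.
#' @param gibbs_iters cap on Gibbs sweeps during inference.
#' @param gibbs_tol stop once the mean absolute change of the label
#'   probability map between sweeps falls below this.
#' @param gibbs_avg number of final sweeps over which the probability map
#'   is averaged.
#' @param threshold probability threshold for the inferred mask.
#' @param sparsity_target,sparsity_cost sparsity regularization of the
#'   first (feature) RBM; see [train_rbm_cd()].
#' @param h1_mode during inference, `"recondition"` redraws the feature
#'   layer from the image-conditioned activation probabilities at every
#'   sweep (the image evidence persists along the chain);
#'   `"resample"` draws it from the top RBM given `h2`, so the image
#'   enters only through the initial state.
#' @param restarts number of independent Gibbs chains per inference; with
#'   more than one, the candidate with the lowest clamped free energy
#'   ([top_free_energy()] of the image features and the thresholded mask)
#'   is returned.
#' @return a list of class `lbseg_dbn_config`.
#' @export
dbn_config <- function(n_hidden1 = 1000, n_hidden2 = 1000, cd_k = 1,
                       epochs1 = 30, epochs2 = 60, lr = 0.05, batch = 32,
                       init_sd = 0.01, gibbs_iters = 200, gibbs_tol = 1e-3,
                       gibbs_avg = 10, threshold = 0.5,
                       sparsity_target = 0.1, sparsity_cost = 0,
                       h1_mode = c("recondition", "resample"),
                       restarts = 1) {
  structure(list(n_hidden1 = n_hidden1, n_hidden2 = n_hidden2, cd_k = cd_k,
                 epochs1 = epochs1, epochs2 = epochs2, lr = lr,
                 batch = batch, init_sd = init_sd,
                 gibbs_iters = gibbs_iters, gibbs_tol = gibbs_tol,
                 gibbs_avg = gibbs_avg, threshold = threshold,
                 sparsity_target = sparsity_target,
                 sparsity_cost = sparsity_cost,
                 h1_mode = match.arg(h1_mode), restarts = restarts),
            class = "lbseg_dbn_config")
}

flatten_grids <- function(grids) {
  do.call(rbind, lapply(grids, function(m) as.vector(m)))
}

#' Train the stacked-RBM shape model
#'
#' Greedy two-stage training: the first RBM is trained unsupervised on the
#' grayscale images; its hidden activation probabilities `h1` then form,
#' together with the binary label masks `L`, the visible layer of the top
#' joint RBM, which is trained by CD with hidden layer `h2`. Both stages
#' minimize one-step reconstruction error.
#'
#' @param images list of grayscale matrices in `[0, 1]` (all of one size).
#' @param labels list of binary mask matrices, paired with `images`.
#' @param config a [dbn_config()].
#' @param seed integer seed controlling both training stages.
#' @return an object of class `lbseg_dbn`: `rbm1`, `top`
#'   (an `lbseg_top_rbm`), `dim` (grid size), `layer_sizes`,
#'   `training_meta`.
#' @export
train_dbn <- function(images, labels, config = dbn_config(), seed = 1) {
  if (length(images) == 0 || length(labels) == 0)
    stop("`images` and `labels` must be nonempty")
  if (length(images) != length(labels))
    stop(sprintf("%d images vs %d labels: pairs required",
                 length(images), length(labels)))
  dm <- dim(images[[1]])
  for (i in seq_along(images)) {
    stopifnot_same_dim(images[[i]], labels[[i]], "image/label pair")
    assert_binary_mask(labels[[i]], sprintf("labels[[%d]]", i))
  }
  V <- flatten_grids(images)
  Lm <- flatten_grids(labels)
  rbm1 <- train_rbm_cd(V, config$n_hidden1, config$cd_k, config$epochs1,
                       config$lr, config$batch, seed = seed,
                       init_sd = config$init_sd,
                       sparsity_target = config$sparsity_target,
                       sparsity_cost = config$sparsity_cost)
  h1p <- prop_up(V, rbm1)
  joint <- train_rbm_cd(cbind(h1p, Lm), config$n_hidden2, config$cd_k,
                        config$epochs2, config$lr, config$batch,
                        seed = seed + 1L, init_sd = config$init_sd)
  n1 <- config$n_hidden1
  top <- new_top_rbm(
    W2 = joint$W[seq_len(n1), , drop = FALSE],
    WL = joint$W[-seq_len(n1), , drop = FALSE],
    b2 = joint$b_hid,
    a1 = joint$b_vis[seq_len(n1)],
    aL = joint$b_vis[-seq_len(n1)])
  structure(list(
    rbm1 = rbm1, top = top, dim = dm,
    layer_sizes = c(input = prod(dm), h1 = config$n_hidden1,
                    h2 = config$n_hidden2, label = prod(dm)),
    training_meta = list(config = config, seed = seed, n_items = nrow(V),
                         recon_error_rbm1 = rbm1$recon_error,
                         recon_error_top = joint$recon_error)),
    class = "lbseg_dbn")
}

#' @export
print.lbseg_dbn <- function(x, ...) {
  cat(sprintf("<lbseg_dbn> layers %s, trained on %d items\n",
              paste(x$layer_sizes, collapse = "-"),
              x$training_meta$n_items))
  invisible(x)
}

# One Gibbs chain of the shape inference; returns prob vector + diagnostics.
infer_chain <- function(h1p, model, config, seed) {
  top <- model$top
  nL <- nrow(top$WL); n1 <- nrow(top$W2); n2 <- ncol(top$W2)
  navg <- max(1, config$gibbs_avg)
  with_seed(seed, {
    h1 <- (runif(n1) < h1p) * 1
    L <- numeric(nL)
    pL_prev <- top_p_L(numeric(n2), top)   # h2 = 0 baseline
    buf <- list()
    used <- 0L; converged <- FALSE
    while (used < config$gibbs_iters) {
      h2 <- (runif(n2) < top_p_h2(h1, L, top)) * 1
      pL <- top_p_L(h2, top)
      L <- (runif(nL) < pL) * 1
      h1 <- if (config$h1_mode == "recondition")
        (runif(n1) < h1p) * 1
      else
        (runif(n1) < top_p_h1(h2, top)) * 1
      used <- used + 1L
      if (!all(is.finite(pL)))
        stop(sprintf("non-finite activations at Gibbs sweep %d", used))
      buf <- c(buf, list(pL))
      if (length(buf) > navg) buf <- buf[-1]
      if (mean(abs(pL - pL_prev)) < config$gibbs_tol) {
        converged <- TRUE
        break
      }
      pL_prev <- pL
    }
    prob <- if (length(buf) == 0) pL_prev else Reduce(`+`, buf) / length(buf)
    list(prob = prob, used = used, converged = converged)
  })
}

#' Infer a patient-specific shape mask
#'
#' Bottom-up pass: the image activates `h1` through the first RBM. The
#' label layer is initialized to zero and blocked Gibbs sampling alternates
#' `h2 | (h1, L)` and `(h1, L) | h2` until the mean absolute change of the
#' label probability map between sweeps falls below `config$gibbs_tol` or
#' `config$gibbs_iters` sweeps are reached. By default (`h1_mode =
#' "recondition"`) the feature layer is redrawn from the image-conditioned
#' activation probabilities at every sweep, keeping the image evidence in
#' the chain; `h1_mode = "resample"` draws it from the top RBM instead.
#' The probability map is the average of `P(L = 1 | h2)` over the final
#' `config$gibbs_avg` sweeps; the mask thresholds it at
#' `config$threshold`. With `config$restarts > 1`, independent chains are
#' run and the candidate whose thresholded mask has the lowest clamped
#' free energy ([top_free_energy()]) against the image features is kept.
#'
#' @param image grayscale matrix matching the model's input size.
#' @param model an `lbseg_dbn`.
#' @param config a [dbn_config()] (only the inference fields are used).
#' @param seed integer seed for the Gibbs chain(s).
#' @return an object of class `lbseg_shape_inference`: `prob_map`, `mask`,
#'   `gibbs_iters_used`, `converged`, `restart_energies`.
#' @export
infer_shape <- function(image, model, config = dbn_config(), seed = 1) {
  if (!identical(dim(image), model$dim))
    stop(sprintf("image is %s but the model expects %s",
                 paste(dim(image), collapse = "x"),
                 paste(model$dim, collapse = "x")))
  h1p <- prop_up(as.vector(image), model$rbm1)
  nrest <- max(1L, as.integer(config$restarts))
  chains <- lapply(seq_len(nrest), function(r)
    infer_chain(h1p, model, config, seed + (r - 1L)))
  energies <- vapply(chains, function(ch)
    top_free_energy(h1p, as.numeric(ch$prob >= config$threshold),
                    model$top), numeric(1))
  best <- chains[[which.min(energies)]]
  prob_map <- matrix(best$prob, model$dim[1], model$dim[2])
  structure(list(
    prob_map = prob_map,
    mask = matrix(as.numeric(prob_map >= config$threshold),
                  model$dim[1], model$dim[2]),
    gibbs_iters_used = best$used, converged = best$converged,
    restart_energies = energies),
    class = "lbseg_shape_inference")
}

#' @export
print.lbseg_shape_inference <- function(x, ...) {
  cat(sprintf(
    "<lbseg_shape_inference> mask area %d px after %d Gibbs sweeps (%s)\n",
    sum(x$mask), x$gibbs_iters_used,
    if (x$converged) "converged" else "cap reached"))
  invisible(x)
}

#' Serialize / load a trained shape model
#'
#' The model is written as a versioned hierarchical container (R
#' serialization of the parameter list) and round-trips bit-exactly.
#'
#' @param model an `lbseg_dbn`.
#' @param path file path (conventionally `.rds`).
#' @return `write_dbn` returns `path` invisibly; `read_dbn` returns the
#'   model.
#' @export
write_dbn <- function(model, path) {
  stopifnot(inherits(model, "lbseg_dbn"))
  saveRDS(list(format = "lbseg_dbn", version = 1L, model = model), path)
  invisible(path)
}

#' @rdname write_dbn
#' @export
read_dbn <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "lbseg_dbn"))
    stop("not an lbseg DBN model file")
  obj$model
}
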