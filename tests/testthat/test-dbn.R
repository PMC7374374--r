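# Exhaustive-enumeration helpers for toy top RBMs (<= 3 units per layer).
enum_configs <- function(n) {
  as.matrix(do.call(expand.grid, rep(list(c(0, 1)), n)))
}

toy_top <- function(seed = 3, n1 = 2, nL = 2, n2 = 2, scale = 0.8) {
  set.seed(seed)
  lbseg:::new_top_rbm(
    W2 = matrix(rnorm(n1 * n2, 0, scale), n1, n2),
    WL = matrix(rnorm(nL * n2, 0, scale), nL, n2),
    b2 = rnorm(n2, 0, scale), a1 = rnorm(n1, 0, scale),
    aL = rnorm(nL, 0, scale))
}

# Joint Boltzmann distribution over (h2, h1, L) from the energy function.
enum_joint <- function(top) {
  n1 <- nrow(top$W2); nL <- nrow(top$WL); n2 <- ncol(top$W2)
  H2 <- enum_configs(n2); H1 <- enum_configs(n1); LL <- enum_configs(nL)
  out <- expand.grid(i2 = seq_len(nrow(H2)), i1 = seq_len(nrow(H1)),
                     iL = seq_len(nrow(LL)))
  out$energy <- mapply(function(i2, i1, iL)
    top_energy(H2[i2, ], H1[i1, ], LL[iL, ], top),
    out$i2, out$i1, out$iL)
  out$p <- exp(-out$energy) / sum(exp(-out$energy))
  list(tab = out, H2 = H2, H1 = H1, LL = LL)
}

test_that("sigmoid is stable and symmetric", {
  expect_equal(sigmoid(0), 0.5)
  x <- c(-3.2, 0.7, 12)
  expect_equal(sigmoid(x) + sigmoid(-x), rep(1, 3))
  expect_lt(abs(sigmoid(700) - 1), 1e-12)
  expect_equal(sigmoid(-700), 0, tolerance = 1e-12)
  expect_false(any(is.nan(sigmoid(c(-1e3, 1e3)))))
})

test_that("prop_up evaluates the hidden conditional and ignores b_vis", {
  rbm0 <- lbseg:::new_rbm(matrix(0, 3, 4), numeric(3), numeric(4))
  expect_equal(prop_up(c(0.2, 0.9, 0.5), rbm0), rep(0.5, 4))
  rbm1 <- lbseg:::new_rbm(matrix(2, 1, 1), 0, 0)
  expect_equal(prop_up(1, rbm1), 1 / (1 + exp(-2)), tolerance = 1e-12)
  rbm2 <- lbseg:::new_rbm(matrix(2, 1, 1), 57, 0)   # shifted visible bias
  expect_identical(prop_up(1, rbm1), prop_up(1, rbm2))
  expect_error(prop_up(c(1, 0), rbm1), "dimension")
})

test_that("Bernoulli sampling respects degenerate and generic probabilities", {
  expect_identical(sample_bernoulli(rep(0, 50), seed = 1), rep(0, 50))
  expect_identical(sample_bernoulli(rep(1, 50), seed = 1), rep(1, 50))
  draws <- sample_bernoulli(rep(0.3, 1e4), seed = 2)
  se <- sqrt(0.3 * 0.7 / 1e4)
  expect_lt(abs(mean(draws) - 0.3), 3 * se)
  p <- matrix(c(0, 1, 0.5, 0.5), 2, 2)
  expect_equal(dim(sample_bernoulli(p, seed = 3)), c(2, 2))
  expect_error(sample_bernoulli(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("top RBM energy vanishes for zero states or zero parameters", {
  top <- toy_top()
  expect_equal(top_energy(c(0, 0), c(0, 0), c(0, 0), top), 0)
  zero <- lbseg:::new_top_rbm(matrix(0, 2, 2), matrix(0, 2, 2),
                              numeric(2), numeric(2), numeric(2))
  for (h2 in list(c(0, 0), c(1, 0), c(1, 1)))
    expect_equal(top_energy(h2, c(1, 0), c(0, 1), zero), 0)
  expect_error(top_energy(c(1, 0, 0), c(0, 0), c(0, 0), top), "mismatch")
})

test_that("Boltzmann probabilities from the energy normalize and factorize", {
  top <- toy_top()
  en <- enum_joint(top)
  expect_equal(sum(en$tab$p), 1, tolerance = 1e-12)
  # conditional P(h2 | h1, L) from enumeration matches the sigmoid product
  h1 <- c(1, 0); L <- c(0, 1)
  rows <- en$tab[en$tab$i1 == which(apply(en$H1, 1, identical,
                                          as.numeric(h1))) &
                   en$tab$iL == which(apply(en$LL, 1, identical,
                                            as.numeric(L))), ]
  cond <- rows$p / sum(rows$p)
  p2 <- lbseg:::top_p_h2(h1, L, top)
  for (r in seq_len(nrow(rows))) {
    h2 <- en$H2[rows$i2[r], ]
    expect_equal(cond[r], prod(ifelse(h2 == 1, p2, 1 - p2)),
                 tolerance = 1e-10)
  }
})

test_that("free energy equals the log-sum over hidden configurations", {
  top <- toy_top(seed = 8)
  h1 <- c(1, 1); L <- c(0, 1)
  H2 <- enum_configs(2)
  direct <- -log(sum(sapply(seq_len(nrow(H2)), function(i)
    exp(-top_energy(H2[i, ], h1, L, top)))))
  expect_equal(top_free_energy(h1, L, top), direct, tolerance = 1e-10)
})

test_that("Gibbs-sampled label marginals match exhaustive enumeration", {
  top <- toy_top(seed = 12, scale = 0.7)
  en <- enum_joint(top)
  exact <- sapply(1:2, function(j)
    sum(en$tab$p[en$LL[en$tab$iL, j] == 1]))
  sweeps <- 2e4
  ch <- top_gibbs_chain(top, sweeps, seed = 5)
  keep <- ch$L[-(1:1000), ]
  est <- colMeans(keep)
  # batch-means standard error accounts for chain autocorrelation
  nb <- 38
  bsz <- floor(nrow(keep) / nb)
  for (j in 1:2) {
    bm <- sapply(seq_len(nb), function(b)
      mean(keep[((b - 1) * bsz + 1):(b * bsz), j]))
    se <- sd(bm) / sqrt(nb)
    expect_lt(abs(est[j] - exact[j]), 3 * se + 1e-6)
  }
})

test_that("contrastive divergence memorizes a single repeated pattern", {
  pat <- c(1, 0, 1, 0)
  data <- matrix(rep(pat, 60), ncol = 4, byrow = TRUE)
  rbm <- train_rbm_cd(data, n_hidden = 2, epochs = 200, lr = 0.1,
                      batch = 16, seed = 3, bias_init = "zero")
  err <- rbm$recon_error
  expect_lt(err[length(err)], 0.1 * err[1])
  expect_lt(err[length(err)], err[1])
})

test_that("zero learning rate leaves parameters at their initialization", {
  set.seed(4)
  data <- matrix(runif(80), 10, 8)
  r0 <- train_rbm_cd(data, 3, epochs = 1, lr = 0, seed = 9)
  r5 <- train_rbm_cd(data, 3, epochs = 5, lr = 0, seed = 9)
  expect_identical(r0$W, r5$W)
  expect_identical(r0$b_vis, r5$b_vis)
  expect_identical(r0$b_hid, r5$b_hid)
})

test_that("training is bit-deterministic under a fixed seed", {
  set.seed(4)
  data <- matrix(runif(160), 20, 8)
  a <- train_rbm_cd(data, 3, epochs = 10, seed = 11)
  b <- train_rbm_cd(data, 3, epochs = 10, seed = 11)
  expect_identical(a$W, b$W)
  c2 <- train_rbm_cd(data, 3, epochs = 10, seed = 12)
  expect_false(identical(a$W, c2$W))
})

test_that("train_dbn validates pairing and records the layer layout", {
  img <- matrix(runif(25), 5, 5)
  lab <- matrix(rbinom(25, 1, 0.4), 5, 5)
  expect_error(train_dbn(list(), list()), "nonempty")
  expect_error(train_dbn(list(img), list(lab, lab)), "pairs")
  expect_error(train_dbn(list(img), list(matrix(0.5, 5, 5))), "binary")
  cfg <- dbn_config(n_hidden1 = 4, n_hidden2 = 3, epochs1 = 2, epochs2 = 2)
  m <- train_dbn(list(img, img), list(lab, lab), cfg, seed = 1)
  expect_equal(unname(m$layer_sizes), c(25, 4, 3, 25))
  # canonical full-size layout is accepted
  cfg_full <- dbn_config(epochs1 = 1, epochs2 = 1)
  big <- matrix(runif(1e4), 100, 100)
  bigl <- matrix(rbinom(1e4, 1, 0.3), 100, 100)
  mf <- train_dbn(list(big, big), list(bigl, bigl), cfg_full, seed = 1)
  expect_equal(unname(mf$layer_sizes), c(10000, 1000, 1000, 10000))
})

test_that("model serialization round-trips bit-exactly", {
  img <- matrix(runif(25), 5, 5)
  lab <- matrix(rbinom(25, 1, 0.4), 5, 5)
  cfg <- dbn_config(n_hidden1 = 4, n_hidden2 = 3, epochs1 = 2, epochs2 = 2)
  m <- train_dbn(list(img, img), list(lab, lab), cfg, seed = 1)
  f <- tempfile(fileext = ".rds")
  write_dbn(m, f)
  expect_identical(read_dbn(f), m)
  saveRDS(list(format = "other"), f)
  expect_error(read_dbn(f), "not an lbseg")
})

test_that("inference degenerate settings behave as forced by the update order", {
  img <- matrix(runif(25), 5, 5)
  lab <- matrix(rbinom(25, 1, 0.4), 5, 5)
  cfg <- dbn_config(n_hidden1 = 4, n_hidden2 = 3, epochs1 = 3, epochs2 = 3)
  m <- train_dbn(list(img, img), list(lab, lab), cfg, seed = 2)
  # no sweeps: the probability map is sigma(aL), no h2 influence
  cfg0 <- cfg; cfg0$gibbs_iters <- 0
  inf0 <- infer_shape(img, m, cfg0, seed = 1)
  expect_equal(as.vector(inf0$prob_map), unname(sigmoid(m$top$aL)),
               tolerance = 1e-12)
  expect_equal(inf0$gibbs_iters_used, 0)
  # zero threshold: every pixel with positive probability is foreground
  cfgt <- cfg; cfgt$threshold <- 0
  inft <- infer_shape(img, m, cfgt, seed = 1)
  expect_true(all(inft$mask == 1))
  expect_error(infer_shape(matrix(0.5, 4, 4), m, cfg), "expects")
})
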