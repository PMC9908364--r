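# Inter-Encoder layers, readout, head and loss

test_that("gcn_layer reproduces hand-worked propagation examples", {
  # single node: self-loop-only normalisation is the identity
  expect_equal(gcn_layer(matrix(1), no_links, matrix(1)), matrix(1))
  # two linked nodes: D^-1/2 (A+I) D^-1/2 = [[.5,.5],[.5,.5]]
  out <- gcn_layer(matrix(c(1, 0), 2, 1), cbind(1, 2), matrix(1))
  expect_equal(out, matrix(c(0.5, 0.5), 2, 1))
  # zero weights annihilate everything
  H <- matrix(rnorm(12), 4, 3)
  expect_equal(gcn_layer(H, cbind(c(1, 2), c(3, 4)), matrix(0, 3, 2)),
               matrix(0, 4, 2))
  expect_error(gcn_layer(matrix(1, 2, 3), no_links, matrix(1, 2, 2)),
               "ncol")
})

test_that("gcn_layer with identity weights and no links conserves input", {
  H <- matrix(abs(rnorm(15)), 5, 3)
  expect_equal(gcn_layer(H, no_links, diag(3), activate = FALSE), H)
})

test_that("gcn_layer equals dense normalised-adjacency evaluation", {
  set.seed(31)
  for (rep in 1:100) {
    n <- sample(2:8, 1)
    d_in <- sample(1:4, 1); d_out <- sample(1:4, 1)
    H <- matrix(rnorm(n * d_in), n, d_in)
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    links <- pairs[runif(nrow(pairs)) < 0.4, , drop = FALSE]
    W <- matrix(rnorm(d_in * d_out), d_in, d_out)
    act <- rep %% 2 == 0
    expect_equal(gcn_layer(H, links, W, activate = act),
                 dense_gcn(H, links, W, activate = act),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("gin_layer matches the epsilon-0 neighbourhood-sum definition", {
  id_mlp <- list(Wa = matrix(1), ba = 0, Wb = matrix(1), bb = 0)
  # isolated node, identity mlp: unchanged
  expect_equal(gin_layer(matrix(2), no_links, id_mlp), matrix(2))
  # two linked nodes with features 1 and 2 -> both 3
  expect_equal(gin_layer(matrix(c(1, 2), 2, 1), cbind(1, 2), id_mlp),
               matrix(c(3, 3), 2, 1))
  # zero input, zero-bias mlp -> zero output
  mlp <- list(Wa = matrix(rnorm(6), 2, 3), ba = rep(0, 3),
              Wb = matrix(rnorm(6), 3, 2), bb = rep(0, 2))
  expect_equal(gin_layer(matrix(0, 3, 2), cbind(1, 3), mlp), matrix(0, 3, 2))
})

test_that("readout_sum pools columns and is permutation invariant", {
  H <- matrix(c(1, 3, 2, 4), 2, 2)
  expect_equal(readout_sum(H), c(4, 6))
  expect_equal(readout_sum(H[1, , drop = FALSE]), H[1, ])
  set.seed(4)
  H2 <- matrix(rnorm(35), 7, 5)
  expect_equal(readout_sum(H2), readout_sum(H2[sample(7), ]))
  expect_error(readout_sum(H2[0, ]), "empty")
})

test_that("predict_head is a monotone sigmoid of the affine map", {
  head <- list(W = matrix(0, 3, 2), b = c(0, 0))
  expect_equal(predict_head(rep(0, 3), head), c(0.5, 0.5))
  head2 <- list(W = matrix(1, 1, 1), b = 0)
  xs <- seq(-3, 3, by = 0.5)
  ps <- vapply(xs, function(x) predict_head(x, head2), numeric(1))
  expect_true(all(diff(ps) > 0))
  expect_true(all(ps > 0 & ps < 1))
})

test_that("masked_bce averages over observed labels only", {
  expect_equal(masked_bce(0.5, 1), log(2))
  expect_equal(masked_bce(c(0.5, 0.5), c(NA, NA)), 0)
  expect_equal(masked_bce(c(0.5, 0.5), c(1, NA)), log(2))
  expect_equal(masked_bce(c(0.9, 0.1), c(1, 0)),
               -mean(log(c(0.9, 0.9))))
  # clamping keeps the loss finite at the boundaries
  expect_true(is.finite(masked_bce(c(0, 1), c(1, 0))))
  expect_error(masked_bce(0.5, c(1, 0)), "length")
})

test_that("molecule embeddings are invariant to node relabelling", {
  mols <- random_molecule_pool(50, seed = 37)
  cfg <- fingerprint_config(128, 2)
  set.seed(99)
  W1 <- matrix(rnorm(128 * 8, sd = 0.3), 128, 8)
  W2 <- matrix(rnorm(64, sd = 0.3), 8, 8)
  mlp1 <- list(Wa = W1, ba = rnorm(8), Wb = matrix(rnorm(64, sd = .3), 8, 8),
               bb = rnorm(8))
  mlp2 <- list(Wa = matrix(rnorm(64, sd = .3), 8, 8), ba = rnorm(8),
               Wb = matrix(rnorm(64, sd = .3), 8, 8), bb = rnorm(8))
  for (m in mols) {
    hg <- build_hypergraph(extract_substructures(m, cfg), cfg)
    X <- as.matrix(hg$features)
    n <- nrow(X)
    perm <- sample(n)
    links_p <- hg$pos_links
    if (nrow(links_p) > 0) {
      links_p <- cbind(match(hg$pos_links[, 1], perm),
                       match(hg$pos_links[, 2], perm))
    }
    # GCN embedding
    e1 <- readout_sum(gcn_layer(gcn_layer(X, hg$pos_links, W1), hg$pos_links,
                                W2, activate = FALSE))
    e2 <- readout_sum(gcn_layer(gcn_layer(X[perm, , drop = FALSE], links_p,
                                          W1), links_p, W2,
                                activate = FALSE))
    expect_equal(e1, e2, tolerance = 1e-6)
    # GIN embedding
    g1 <- readout_sum(gin_layer(gin_layer(X, hg$pos_links, mlp1),
                                hg$pos_links, mlp2))
    g2 <- readout_sum(gin_layer(gin_layer(X[perm, , drop = FALSE], links_p,
                                          mlp1), links_p, mlp2))
    expect_equal(g1, g2, tolerance = 1e-6)
  }
})

test_that("analytic gradients match finite differences on tiny instances", {
  ds <- generate_molecules(6, seed = 3, n_tasks = 2)
  cfg <- fingerprint_config(32, 2)
  pres <- lapply(ds$molecules, hypermol:::.hm_precompute, cfg = cfg)
  y <- ds$labels; y[2, 1] <- NA
  batch <- hypermol:::.hm_batch(pres)
  lossfn <- function(p) {
    f <- hypermol:::.hm_forward(p, batch)
    mask <- !is.na(y)
    pm <- pmin(pmax(f$prob[mask], 1e-7), 1 - 1e-7)
    -mean(y[mask] * log(pm) + (1 - y[mask]) * log(1 - pm))
  }
  for (bb in c("gcn", "gin")) {
    set.seed(42)
    params <- shrink_params(hypermol:::.hm_init_params(bb, 32, 5, 2, 2))
    fw <- hypermol:::.hm_forward(params, batch)
    bw <- hypermol:::.hm_backward(params, batch, fw, y)
    eps <- 1e-6
    check <- function(get, set, g_ana) {
      v <- get(params)
      for (i in sample(length(v), min(6, length(v)))) {
        vp <- v; vp[i] <- vp[i] + eps
        vm <- v; vm[i] <- vm[i] - eps
        g_num <- (lossfn(set(params, vp)) - lossfn(set(params, vm))) /
          (2 * eps)
        expect_equal(g_num, as.matrix(g_ana)[i], tolerance = 1e-4)
      }
    }
    check(function(p) p$head$W, function(p, v) { p$head$W <- v; p },
          bw$grads$head$W)
    check(function(p) p$head$b, function(p, v) { p$head$b <- v; p },
          bw$grads$head$b)
    for (k in 1:2) for (nm in names(params$layers[[k]])) {
      check(function(p) p$layers[[k]][[nm]],
            function(p, v) { p$layers[[k]][[nm]] <- v; p },
            bw$grads$layers[[k]][[nm]])
    }
  }
})

test_that("batched block-diagonal processing equals per-molecule processing", {
  ds <- generate_molecules(10, seed = 13)
  cfg <- fingerprint_config(64, 2)
  pres <- lapply(ds$molecules, hypermol:::.hm_precompute, cfg = cfg)
  for (bb in c("gcn", "gin")) {
    set.seed(7)
    params <- shrink_params(hypermol:::.hm_init_params(bb, 64, 6, 2, 1))
    together <- hypermol:::.hm_forward(params, hypermol:::.hm_batch(pres))$prob
    single <- do.call(rbind, lapply(pres, function(p) {
      hypermol:::.hm_forward(params, hypermol:::.hm_batch(list(p)))$prob
    }))
    expect_equal(together, single, tolerance = 1e-6)
  }
})
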