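# The Inter-Encoder: fingerprint-level message passing over positive
# hyperlinks (GCN or GIN), sum-pooling readout, sigmoid head and the masked
# multitask binary cross-entropy. Exported functions are the pure per-graph
# operations; the batched trainer (block-diagonal sparse adjacency over a
# mini-batch, manual backprop, Adam) lives in the .hm_* internals below.

.relu <- function(x) { x[x < 0] <- 0; x }
.sigmoid <- function(x) 1 / (1 + exp(-x))
.BCE_EPS <- 1e-7

# symmetric-normalised adjacency with self-loops: D^-1/2 (A + I) D^-1/2
.norm_adj <- function(n, links) {
  i <- c(seq_len(n), links[, 1], links[, 2])
  j <- c(seq_len(n), links[, 2], links[, 1])
  A <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
  d <- Matrix::rowSums(A)
  s <- 1 / sqrt(d)
  Matrix::Diagonal(n, s) %*% A %*% Matrix::Diagonal(n, s)
}

# A + I without normalisation (GIN aggregation with epsilon = 0)
.raw_adj_self <- function(n, links) {
  i <- c(seq_len(n), links[, 1], links[, 2])
  j <- c(seq_len(n), links[, 2], links[, 1])
  Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
}

#' One GCN propagation layer
#'
#' Computes `sigma(D^-1/2 (A+I) D^-1/2 H W)` over the positive hyperlinks,
#' with the rectifier as `sigma` when `activate` is set and the identity
#' otherwise (the convention for the final layer before readout).
#'
#' @param H node feature matrix (one row per hypergraph node).
#' @param links two-column integer matrix of undirected node index pairs.
#' @param W weight matrix, `ncol(H)` x output width.
#' @param activate apply the rectifier (default `TRUE`).
#' @return the propagated node matrix.
#' @export
gcn_layer <- function(H, links, W, activate = TRUE) {
  H <- as.matrix(H); W <- as.matrix(W)
  if (ncol(H) != nrow(W)) stop("gcn_layer: ncol(H) != nrow(W)")
  if (length(links) > 0 && max(links) > nrow(H)) {
    stop("gcn_layer: link index out of range")
  }
  out <- as.matrix(.norm_adj(nrow(H), links) %*% (H %*% W))
  if (activate) out <- .relu(out)
  out
}

#' One GIN propagation layer
#'
#' Per node v: `mlp((1 + eps) H_v + sum_{u in N(v)} H_u)` with a fixed
#' `eps = 0` and a two-layer perceptron `linear -> rectifier -> linear`.
#'
#' @param H node feature matrix.
#' @param links two-column integer matrix of undirected node index pairs.
#' @param mlp list with `Wa`, `ba`, `Wb`, `bb` (first/second linear maps).
#' @return the propagated node matrix.
#' @export
gin_layer <- function(H, links, mlp) {
  H <- as.matrix(H)
  if (ncol(H) != nrow(mlp$Wa)) stop("gin_layer: ncol(H) != nrow(Wa)")
  if (ncol(mlp$Wa) != nrow(mlp$Wb)) stop("gin_layer: Wa/Wb widths disagree")
  U <- as.matrix(.raw_adj_self(nrow(H), links) %*% H)
  P <- .relu(sweep(U %*% mlp$Wa, 2, mlp$ba, "+"))
  sweep(P %*% mlp$Wb, 2, mlp$bb, "+")
}

#' Sum-pooling readout
#'
#' Column-wise sum over hypergraph nodes; permutation invariant.
#'
#' @param H node feature matrix with at least one row.
#' @return numeric vector of length `ncol(H)` (the molecule embedding).
#' @export
readout_sum <- function(H) {
  H <- as.matrix(H)
  if (nrow(H) < 1) stop("readout_sum: empty node matrix")
  colSums(H)
}

#' Sigmoid prediction head
#'
#' @param embedding molecule embedding vector, or a matrix with one row per
#'   molecule.
#' @param head list with `W` (hidden x n_tasks) and `b` (length n_tasks).
#' @return per-task probabilities in (0, 1), same shape convention as input.
#' @export
predict_head <- function(embedding, head) {
  E <- if (is.matrix(embedding)) embedding else matrix(embedding, nrow = 1)
  if (ncol(E) != nrow(head$W)) stop("predict_head: width mismatch")
  P <- .sigmoid(sweep(E %*% head$W, 2, head$b, "+"))
  if (is.matrix(embedding)) P else drop(P)
}

#' Masked binary cross-entropy
#'
#' Mean of `-(y log p + (1-y) log(1-p))` over non-missing labels, with
#' probabilities clamped to `[1e-7, 1 - 1e-7]` before the logarithms. An
#' all-missing label vector contributes zero loss with zero weight.
#'
#' @param prob predicted probabilities.
#' @param label labels in {0, 1, NA}, same length.
#' @return scalar loss.
#' @export
masked_bce <- function(prob, label) {
  if (length(prob) != length(label)) stop("masked_bce: length mismatch")
  m <- !is.na(label)
  if (!any(m)) return(0)
  p <- pmin(pmax(prob[m], .BCE_EPS), 1 - .BCE_EPS)
  y <- label[m]
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

## ---- internal batched trainer -------------------------------------------

# per-molecule precomputation: hypergraph -> compact arrays for batching
.hm_precompute <- function(mol, cfg) {
  hg <- build_hypergraph(extract_substructures(mol, cfg), cfg)
  n <- length(hg$nodes)
  links <- hg$pos_links
  An <- .norm_adj(n, links)
  Tn <- methods::as(An, "TsparseMatrix")
  list(n = n,
       bits = vapply(hg$nodes, `[[`, 0L, "bit") + 1L,
       norm = cbind(Tn@i + 1L, Tn@j + 1L, Tn@x),
       raw = cbind(c(seq_len(n), links[, 1], links[, 2]),
                   c(seq_len(n), links[, 2], links[, 1])))
}

# block-diagonal batch over a list of precomputed molecules
.hm_batch <- function(pres) {
  ns <- vapply(pres, `[[`, 0L, "n")
  off <- c(0L, cumsum(ns))
  N <- off[length(off)]
  nm <- do.call(rbind, lapply(seq_along(pres), function(k) {
    p <- pres[[k]]$norm
    cbind(p[, 1] + off[k], p[, 2] + off[k], p[, 3])
  }))
  rm_ <- do.call(rbind, lapply(seq_along(pres), function(k) {
    pres[[k]]$raw + off[k]
  }))
  list(
    Ahat = Matrix::sparseMatrix(i = nm[, 1], j = nm[, 2], x = nm[, 3],
                                dims = c(N, N)),
    S = Matrix::sparseMatrix(i = rm_[, 1], j = rm_[, 2], x = 1,
                             dims = c(N, N)),
    bits = unlist(lapply(pres, `[[`, "bits"), use.names = FALSE),
    molidx = rep(seq_along(pres), ns),
    n_mol = length(pres))
}

.glorot <- function(nr, nc) {
  s <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -s, s), nr, nc)
}

# parameter initialisation from the current RNG stream
.hm_init_params <- function(backbone, fp_length, hidden_dim, n_layers,
                            n_tasks) {
  layers <- vector("list", n_layers)
  d_in <- fp_length
  for (k in seq_len(n_layers)) {
    if (backbone == "gcn") {
      layers[[k]] <- list(W = .glorot(d_in, hidden_dim))
    } else {
      layers[[k]] <- list(Wa = .glorot(d_in, hidden_dim),
                          ba = numeric(hidden_dim),
                          Wb = .glorot(hidden_dim, hidden_dim),
                          bb = numeric(hidden_dim))
    }
    d_in <- hidden_dim
  }
  list(backbone = backbone,
       layers = layers,
       head = list(W = .glorot(hidden_dim, n_tasks), b = numeric(n_tasks)))
}

# forward pass over one assembled batch; returns probabilities and caches
.hm_forward <- function(params, batch) {
  L <- length(params$layers)
  Hs <- vector("list", L)   # post-activation node matrices
  H <- NULL
  for (k in seq_len(L)) {
    if (params$backbone == "gcn") {
      W <- params$layers[[k]]$W
      HW <- if (k == 1) W[batch$bits, , drop = FALSE] else H %*% W
      Z <- as.matrix(batch$Ahat %*% HW)
      H <- if (k < L) .relu(Z) else Z
    } else {
      ly <- params$layers[[k]]
      if (k == 1) {
        # U = S X is never materialised (X is one-hot): U Wa = S Wa[bits, ]
        M <- as.matrix(batch$S %*% ly$Wa[batch$bits, , drop = FALSE])
        Hs[[k]] <- list()
      } else {
        U <- as.matrix(batch$S %*% H)     # aggregate, cached for gradients
        Hs[[k]] <- list(U = U)
        M <- U %*% ly$Wa
      }
      M <- sweep(M, 2, ly$ba, "+")
      P <- .relu(M)
      Hs[[k]]$P <- P
      H <- sweep(P %*% ly$Wb, 2, ly$bb, "+")
    }
    Hs[[k]]$H <- H
  }
  E <- rowsum(H, batch$molidx)
  dimnames(E) <- NULL
  logits <- sweep(E %*% params$head$W, 2, params$head$b, "+")
  list(prob = .sigmoid(logits), E = E, Hs = Hs)
}

# masked BCE + analytic gradients for all parameters on one batch
.hm_backward <- function(params, batch, fw, y) {
  mask <- !is.na(y)
  m <- sum(mask)
  p <- fw$prob
  grads <- list(layers = vector("list", length(params$layers)),
                head = NULL)
  dlogit <- p - ifelse(mask, y, 0)
  dlogit[!mask] <- 0
  if (m > 0) dlogit <- dlogit / m
  grads$head <- list(W = crossprod(fw$E, dlogit), b = colSums(dlogit))
  dE <- dlogit %*% t(params$head$W)
  dH <- dE[batch$molidx, , drop = FALSE]
  L <- length(params$layers)
  for (k in L:1) {
    if (params$backbone == "gcn") {
      # Z_k = Ahat (H_{k-1} W_k); activation belongs to layer k (k < L)
      Hin <- if (k > 1) fw$Hs[[k - 1]]$H else NULL
      dZ <- dH
      G <- as.matrix(batch$Ahat %*% dZ)          # Ahat symmetric
      if (k > 1) {
        grads$layers[[k]] <- list(W = crossprod(Hin, G))
        dH <- G %*% t(params$layers[[k]]$W)
        dH <- dH * (Hin > 0)                     # relu of layer k-1
      } else {
        rs <- rowsum(G, batch$bits)
        dW <- matrix(0, nrow(params$layers[[1]]$W),
                     ncol(params$layers[[1]]$W))
        dW[as.integer(rownames(rs)), ] <- rs
        grads$layers[[1]] <- list(W = dW)
      }
    } else {
      ly <- params$layers[[k]]
      P <- fw$Hs[[k]]$P
      dWb <- crossprod(P, dH); dbb <- colSums(dH)
      dP <- dH %*% t(ly$Wb)
      dM <- dP * (P > 0)
      dba <- colSums(dM)
      if (k > 1) {
        Hin <- fw$Hs[[k - 1]]$H
        U <- fw$Hs[[k]]$U
        dWa <- crossprod(U, dM)
        dU <- dM %*% t(ly$Wa)
        dH <- as.matrix(batch$S %*% dU)          # S symmetric
      } else {
        SdM <- as.matrix(batch$S %*% dM)
        rs <- rowsum(SdM, batch$bits)
        dWa <- matrix(0, nrow(ly$Wa), ncol(ly$Wa))
        dWa[as.integer(rownames(rs)), ] <- rs
      }
      grads$layers[[k]] <- list(Wa = dWa, ba = dba, Wb = dWb, bb = dbb)
    }
  }
  # loss value (clamped), for the curve and divergence checks
  pm <- pmin(pmax(p[mask], .BCE_EPS), 1 - .BCE_EPS)
  ym <- y[mask]
  loss <- if (m > 0) -mean(ym * log(pm) + (1 - ym) * log(1 - pm)) else 0
  list(grads = grads, loss = loss)
}

## ---- Adam over nested parameter lists -----------------------------------

.adam_init <- function(params) {
  zero <- function(x) {
    if (is.list(x)) lapply(x, zero)
    else if (is.numeric(x)) x * 0
    else x
  }
  list(m = zero(params), v = zero(params), t = 0L)
}

.adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  walk <- function(p, g, m, v) {
    if (is.numeric(p) && !is.null(g)) {
      g <- as.matrix(g)
      dim(g) <- dim(as.matrix(p))
      if (is.null(dim(p))) g <- as.numeric(g)
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      mh <- m / (1 - beta1^t)
      vh <- v / (1 - beta2^t)
      list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
    } else if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (nm in names(p)) {
        if (is.null(g[[nm]]) && !is.list(p[[nm]])) next
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out_p[[nm]] <- r$p; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
      }
      # unnamed list components (layer lists)
      if (is.null(names(p))) {
        for (k in seq_along(p)) {
          r <- walk(p[[k]], g[[k]], m[[k]], v[[k]])
          out_p[[k]] <- r$p; out_m[[k]] <- r$m; out_v[[k]] <- r$v
        }
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      list(p = p, m = m, v = v)
    }
  }
  r <- walk(params[c("layers", "head")], grads, state$m[c("layers", "head")],
            state$v[c("layers", "head")])
  params$layers <- r$p$layers; params$head <- r$p$head
  state$m[c("layers", "head")] <- r$m[c("layers", "head")]
  state$v[c("layers", "head")] <- r$v[c("layers", "head")]
  list(params = params, state = state)
}

# scores for a set of molecules, processed in chunks (no gradients)
.hm_scores <- function(params, pres, idx, chunk = 256L) {
  out <- matrix(NA_real_, length(idx), ncol(params$head$W))
  done <- 0L
  while (done < length(idx)) {
    take <- idx[(done + 1L):min(done + chunk, length(idx))]
    batch <- .hm_batch(pres[take])
    fw <- .hm_forward(params, batch)
    out[(done + 1L):(done + length(take)), ] <- fw$prob
    done <- done + length(take)
  }
  out
}
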