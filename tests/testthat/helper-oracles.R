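# Independent brute-force oracles and small fixture builders shared by the
# suite. Oracles are written against the definitions, not the package
# internals, so they can catch implementation defects.

# all-pairs ROC-AUC: fraction of (positive, negative) pairs with the
# positive scored higher, ties 0.5
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# dense evaluation of the symmetric-normalised GCN propagation rule
dense_gcn <- function(H, links, W, activate = TRUE) {
  n <- nrow(H)
  A <- matrix(0, n, n)
  if (nrow(links) > 0) {
    for (k in seq_len(nrow(links))) {
      A[links[k, 1], links[k, 2]] <- 1
      A[links[k, 2], links[k, 1]] <- 1
    }
  }
  At <- A + diag(n)
  d <- rowSums(At)
  N <- diag(1 / sqrt(d)) %*% At %*% diag(1 / sqrt(d))
  out <- N %*% H %*% W
  if (activate) out[out < 0] <- 0
  out
}

# brute-force positive hyperlinks: double loop over atom-set intersections
brute_links <- function(subs) {
  n <- length(subs)
  out <- NULL
  if (n >= 2) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (length(intersect(subs[[i]]$atoms, subs[[j]]$atoms)) > 0) {
        out <- rbind(out, c(i, j))
      }
    }
  }
  if (is.null(out)) out <- matrix(integer(0), ncol = 2)
  out
}

# hand-built substructure list (for degenerate hypergraph cases)
fake_subs <- function(atom_sets, bits, fp_length = 8L) {
  subs <- lapply(seq_along(atom_sets), function(k) {
    list(center = atom_sets[[k]][1], radius = 0L,
         atoms = sort(atom_sets[[k]]),
         bonds = matrix(integer(0), ncol = 2), bit = bits[k])
  })
  structure(subs, class = "hm_substructures",
            fp_length = fp_length, max_radius = 0L)
}

no_links <- matrix(integer(0), ncol = 2)

# pool of random small-molecule SMILES drawn from the synthetic generator
random_molecule_pool <- function(n, seed) {
  ds <- generate_molecules(n, seed = seed, n_tasks = 2,
                           positive_fraction = 0.4)
  ds$molecules
}

# a tiny 4-row CSV in the standard dialect
write_tiny_csv <- function(path, smiles = c("CCO", "CC", "c1ccccc1", "CCN"),
                           labels = c(1, 0, 1, 0)) {
  df <- data.frame(smiles = smiles, activity = labels)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# uniformly scale model parameters (keeps gradient checks off the clamped
# saturation plateau of the loss)
shrink_params <- function(params, f = 0.15) {
  sc <- function(x) if (is.list(x)) lapply(x, sc)
        else if (is.numeric(x)) x * f else x
  params$layers <- sc(params$layers)
  params$head <- sc(params$head)
  params
}
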