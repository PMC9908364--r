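# Circular (extended-connectivity) fingerprint substructures.
#
# For every atom and every radius 0..max_radius, the ball of that radius
# around the atom is a candidate substructure; a candidate is emitted only
# when the ball grew relative to the previous radius (the standard ECFP
# duplicate-environment suppression). Each emitted environment carries a
# folded bit index produced by iterative neighbourhood hashing of the atom
# invariants (element, degree, charge, attached-H count, aromaticity).

#' Fingerprint configuration
#'
#' @param fp_length folded fingerprint length (number of bit positions);
#'   default 2048.
#' @param max_radius maximum environment radius in bonds; default 2.
#' @return an object of class `hm_fp_config`.
#' @export
fingerprint_config <- function(fp_length = 2048L, max_radius = 2L) {
  fp_length <- as.integer(fp_length); max_radius <- as.integer(max_radius)
  if (is.na(fp_length) || fp_length < 1) stop("fp_length must be positive")
  if (is.na(max_radius) || max_radius < 0) stop("max_radius must be >= 0")
  structure(list(fp_length = fp_length, max_radius = max_radius),
            class = "hm_fp_config")
}

# 31-bit polynomial hash combine; exact in doubles (products stay < 2^53)
.HASH_MOD <- 2147483647
.hash_combine <- function(h, x) (h * 131 + x) %% .HASH_MOD

.atom_init_hash <- function(atoms) {
  z <- .ELEMENTS[atoms$element]
  z[is.na(z)] <- 0L
  h <- rep(17, nrow(atoms))
  h <- .hash_combine(h, z)
  h <- .hash_combine(h, atoms$degree)
  h <- .hash_combine(h, atoms$charge + 16)
  h <- .hash_combine(h, atoms$n_h)
  h <- .hash_combine(h, as.integer(atoms$aromatic))
  h
}

# adjacency list: for each atom, matrix of (neighbour, bond order, bond row)
.adjacency <- function(mol) {
  na <- nrow(mol$atoms)
  adj <- vector("list", na)
  for (a in seq_len(na)) adj[[a]] <- cbind(integer(0), integer(0), integer(0))
  bonds <- mol$bonds
  for (k in seq_len(nrow(bonds))) {
    i <- bonds$a1[k]; j <- bonds$a2[k]; o <- bonds$order[k]
    adj[[i]] <- rbind(adj[[i]], c(j, o, k))
    adj[[j]] <- rbind(adj[[j]], c(i, o, k))
  }
  adj
}

#' Breadth-first ball around an atom (test oracle)
#'
#' Plain BFS returning all atoms at graph distance at most `radius` from
#' `center`. Kept deliberately independent of [extract_substructures()] so it
#' can validate the latter's atom sets.
#'
#' @param mol an `hm_mol`.
#' @param center 1-based atom index.
#' @param radius non-negative integer.
#' @return sorted integer vector of 1-based atom indices.
#' @export
ball_oracle <- function(mol, center, radius) {
  stopifnot(inherits(mol, "hm_mol"))
  na <- nrow(mol$atoms)
  if (center < 1 || center > na) stop("center atom out of range")
  if (radius < 0) stop("radius must be >= 0")
  dist <- rep(Inf, na); dist[center] <- 0
  frontier <- center
  d <- 0
  while (length(frontier) > 0 && d < radius) {
    nxt <- integer(0)
    for (a in frontier) {
      nb <- c(mol$bonds$a2[mol$bonds$a1 == a], mol$bonds$a1[mol$bonds$a2 == a])
      new <- nb[dist[nb] == Inf]
      dist[new] <- d + 1
      nxt <- c(nxt, new)
    }
    frontier <- unique(nxt)
    d <- d + 1
  }
  sort(which(dist <= radius))
}

#' Extract circular fingerprint substructures
#'
#' Emits one substructure per (center atom, radius) pair whose ball grew
#' relative to the previous radius, ordered by center then radius, then
#' deduplicated on identical (bit index, atom set) keeping the first. The
#' bond set of an environment contains every bond lying on a path of length
#' at most `radius` from the center, i.e. bonds whose nearer endpoint is at
#' distance < radius.
#'
#' @param mol an `hm_mol` with at least one atom.
#' @param cfg an `hm_fp_config` (default: length 2048, radius 2).
#' @return a list of class `hm_substructures`; each element has fields
#'   `center` (atom index), `radius`, `atoms` (sorted atom indices),
#'   `bonds` (two-column matrix of atom index pairs), and `bit`
#'   (0-based folded bit index in `[0, fp_length)`).
#' @examples
#' subs <- extract_substructures(parse_smiles("CCO"), fingerprint_config(16, 1))
#' length(subs)  # 6: three radius-0 atoms and three grown radius-1 balls
#' @export
extract_substructures <- function(mol, cfg = fingerprint_config()) {
  stopifnot(inherits(mol, "hm_mol"), inherits(cfg, "hm_fp_config"))
  na <- nrow(mol$atoms)
  if (na < 1) stop("molecule has no atoms")
  adj <- .adjacency(mol)

  # iterative neighbourhood hashing, all atoms in lockstep
  hashes <- matrix(0, nrow = na, ncol = cfg$max_radius + 1)
  hashes[, 1] <- .atom_init_hash(mol$atoms)
  if (cfg$max_radius > 0) {
    for (r in seq_len(cfg$max_radius)) {
      prev <- hashes[, r]
      for (a in seq_len(na)) {
        h <- .hash_combine(.hash_combine(17, r), prev[a])
        nb <- adj[[a]]
        if (nrow(nb) > 0) {
          ord <- order(nb[, 2], prev[nb[, 1]], method = "radix")
          for (k in ord) {
            h <- .hash_combine(h, nb[k, 2])
            h <- .hash_combine(h, prev[nb[k, 1]])
          }
        }
        hashes[a, r + 1] <- h
      }
    }
  }

  out <- vector("list", na * (cfg$max_radius + 1))
  cnt <- 0L
  for (a in seq_len(na)) {
    # single BFS from a gives distances for all radii
    dist <- rep(Inf, na); dist[a] <- 0
    frontier <- a; d <- 0
    while (length(frontier) > 0 && d < cfg$max_radius) {
      nxt <- integer(0)
      for (v in frontier) {
        nb <- adj[[v]][, 1]
        new <- nb[dist[nb] == Inf]
        dist[new] <- d + 1
        nxt <- c(nxt, new)
      }
      frontier <- unique(nxt); d <- d + 1
    }
    prev_size <- 0L
    for (r in 0:cfg$max_radius) {
      ball <- which(dist <= r)
      if (r > 0 && length(ball) == prev_size) next  # ball did not grow
      prev_size <- length(ball)
      if (r == 0) {
        bmat <- matrix(integer(0), ncol = 2)
      } else {
        sel <- dist[mol$bonds$a1] <= r & dist[mol$bonds$a2] <= r &
          pmin(dist[mol$bonds$a1], dist[mol$bonds$a2]) <= r - 1
        bmat <- cbind(mol$bonds$a1[sel], mol$bonds$a2[sel])
      }
      cnt <- cnt + 1L
      out[[cnt]] <- list(center = a, radius = r, atoms = sort(ball),
                         bonds = bmat,
                         bit = as.integer(hashes[a, r + 1] %% cfg$fp_length))
    }
  }
  out <- out[seq_len(cnt)]
  ord <- order(vapply(out, `[[`, 0L, "center"),
               vapply(out, `[[`, 0L, "radius"))
  out <- out[ord]
  key <- vapply(out, function(s) {
    paste(s$bit, paste(s$atoms, collapse = ","))
  }, character(1))
  out <- out[!duplicated(key)]
  structure(out, class = "hm_substructures",
            fp_length = cfg$fp_length, max_radius = cfg$max_radius)
}

#' @export
print.hm_substructures <- function(x, ...) {
  cat("<hm_substructures> ", length(x), " environments (fp_length ",
      attr(x, "fp_length"), ", max radius ", attr(x, "max_radius"), ")\n",
      sep = "")
  invisible(x)
}

#' Tabulate substructures
#'
#' @param subs an `hm_substructures` list.
#' @return data frame with columns `center`, `radius`, `bit` and a
#'   comma-separated `atoms` column (1-based indices).
#' @export
substructure_table <- function(subs) {
  stopifnot(inherits(subs, "hm_substructures"))
  data.frame(
    center = vapply(subs, `[[`, 0L, "center"),
    radius = vapply(subs, `[[`, 0L, "radius"),
    bit = vapply(subs, `[[`, 0L, "bit"),
    atoms = vapply(subs, function(s) paste(s$atoms, collapse = ","),
                   character(1)),
    stringsAsFactors = FALSE)
}

#' Export a per-molecule substructure table as TSV
#' @param subs an `hm_substructures` list.
#' @param path output file.
#' @export
write_substructure_table <- function(subs, path) {
  utils::write.table(substructure_table(subs), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
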