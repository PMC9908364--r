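# Bemis-Murcko scaffold grouping and the deterministic greedy scaffold split.

#' Bemis-Murcko scaffold key of a molecule
#'
#' Strips side chains by iteratively deleting terminal (degree-1) heavy atoms
#' until only ring systems and the linkers between them remain, then returns
#' the canonical SMILES of the remaining subgraph as a grouping key. Acyclic
#' molecules reduce to the empty scaffold `""` and thus form one shared group.
#' Exocyclic substituents (including double-bonded ones such as carbonyl
#' oxygens) are removed; this is a deliberate, deterministic variant of the
#' scaffold convention and is applied uniformly to every molecule.
#'
#' @param mol an `hm_mol`.
#' @return a single character scaffold key (`""` for acyclic molecules).
#' @export
murcko_scaffold <- function(mol) {
  stopifnot(inherits(mol, "hm_mol"))
  keep <- seq_len(nrow(mol$atoms))
  b1 <- mol$bonds$a1; b2 <- mol$bonds$a2
  repeat {
    deg <- tabulate(c(b1, b2), nbins = nrow(mol$atoms))
    drop <- intersect(keep, which(deg <= 1))
    if (length(drop) == 0 || length(keep) == 0) break
    keep <- setdiff(keep, drop)
    sel <- b1 %in% keep & b2 %in% keep
    b1 <- b1[sel]; b2 <- b2[sel]
  }
  if (length(keep) == 0) return("")
  out <- ChemmineOB::convertFormat(
    "SDF", "CAN", source = .mol_to_sdf(mol, keep = keep, title = "scaffold"),
    options = .ob_options())
  key <- strsplit(out, "[\t\n]")[[1]][1]
  if (is.na(key) || !nzchar(key)) {
    # canonicaliser refused the pruned subgraph; fall back to a deterministic
    # degree-sequence key so grouping still works
    key <- paste0("raw:", paste(sort(table(mol$atoms$element[keep])),
                                collapse = ","), ":", length(b1))
  }
  key
}

#' Deterministic scaffold-based train/validation/test split
#'
#' Molecules are grouped by Bemis-Murcko scaffold; groups are ordered by
#' decreasing size, ties broken lexicographically on the scaffold string, and
#' assigned greedily: a group goes to train while the train partition has
#' room, then to validation, then to test (cumulative capacity rule). All
#' members of a scaffold group land in the same partition, so no scaffold
#' straddles partitions, and the result is a pure function of the dataset.
#'
#' @param dataset an `hm_dataset`.
#' @param ratios numeric triple of positive fractions summing to 1
#'   (default `c(0.8, 0.1, 0.1)`).
#' @return an object of class `hm_split`: list with integer vectors
#'   `train_idx`, `valid_idx`, `test_idx` and a `scaffolds` character vector
#'   (one key per molecule).
#' @export
scaffold_split <- function(dataset, ratios = c(0.8, 0.1, 0.1)) {
  stopifnot(inherits(dataset, "hm_dataset"))
  if (length(ratios) != 3 || any(ratios <= 0) ||
      abs(sum(ratios) - 1) > 1e-8) {
    stop("ratios must be three positive fractions summing to 1")
  }
  n <- length(dataset$molecules)
  keys <- vapply(dataset$molecules, murcko_scaffold, character(1))
  groups <- split(seq_len(n), keys)
  if (length(groups) < 3) {
    stop("scaffold split needs at least 3 scaffold groups, found ",
         length(groups))
  }
  sizes <- lengths(groups)
  ord <- order(-sizes, names(groups), method = "radix")
  groups <- groups[ord]

  train_cut <- ratios[1] * n
  valid_cut <- (ratios[1] + ratios[2]) * n
  eps <- 1e-9
  train <- integer(0); valid <- integer(0); test <- integer(0)
  for (g in groups) {
    if (length(train) + length(g) <= train_cut + eps) {
      train <- c(train, g)
    } else if (length(train) + length(valid) + length(g) <= valid_cut + eps) {
      valid <- c(valid, g)
    } else {
      test <- c(test, g)
    }
  }
  if (length(valid) == 0 || length(test) == 0) {
    stop("scaffold groups too coarse to fill all three partitions")
  }
  structure(list(train_idx = sort(train), valid_idx = sort(valid),
                 test_idx = sort(test), scaffolds = keys),
            class = "hm_split")
}

#' @export
print.hm_split <- function(x, ...) {
  cat("<hm_split> train/valid/test = ",
      length(x$train_idx), "/", length(x$valid_idx), "/",
      length(x$test_idx), " (", length(unique(x$scaffolds)),
      " scaffold groups)\n", sep = "")
  invisible(x)
}
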