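# Molecular hypergraph: substructure nodes, positive hyperlinks between
# atom-sharing substructures, and one-hot substructure features.
#
# A pair of substructures sharing at least one atom receives a positive
# hyperlink; pairs with disjoint atom sets are negative hyperlinks and are
# represented implicitly by the absence of an edge (message passing uses a
# binary adjacency over positive links only; self-loops are added by the
# GCN propagation rule, not here).

#' Build the hypergraph of one molecule
#'
#' Iterates all unordered substructure pairs and inserts a positive hyperlink
#' whenever the two atom sets intersect.
#'
#' @param subs an `hm_substructures` list (at least one element).
#' @param cfg the `hm_fp_config` used for extraction; supplies the one-hot
#'   feature width.
#' @return an object of class `hm_hypergraph`: list with `nodes` (the
#'   substructures), `pos_links` (two-column integer matrix of node index
#'   pairs, `i < j`), `features` (sparse |nodes| x fp_length one-hot matrix),
#'   and `n_pair_comparisons`.
#' @examples
#' cfg <- fingerprint_config(16, 1)
#' hg <- build_hypergraph(extract_substructures(parse_smiles("CCO"), cfg), cfg)
#' nrow(hg$pos_links)  # 10
#' @export
build_hypergraph <- function(subs, cfg = fingerprint_config()) {
  if (!inherits(subs, "hm_substructures") || length(subs) < 1) {
    stop("build_hypergraph() needs a non-empty substructure list")
  }
  n <- length(subs)
  atom_sets <- lapply(subs, `[[`, "atoms")
  li <- integer(0); lj <- integer(0)
  comparisons <- 0L
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      ai <- atom_sets[[i]]
      for (j in (i + 1):n) {
        comparisons <- comparisons + 1L
        if (any(ai %in% atom_sets[[j]])) {
          li <- c(li, i); lj <- c(lj, j)
        }
      }
    }
  }
  structure(list(nodes = subs,
                 pos_links = cbind(i = li, j = lj),
                 features = onehot_encode(subs, attr(subs, "fp_length")),
                 n_pair_comparisons = comparisons),
            class = "hm_hypergraph")
}

#' @export
print.hm_hypergraph <- function(x, ...) {
  cat("<hm_hypergraph> ", length(x$nodes), " substructure nodes, ",
      nrow(x$pos_links), " positive hyperlinks\n", sep = "")
  invisible(x)
}

#' One-hot substructure features
#'
#' Row k is all zeros except a single 1 at the folded bit index of
#' substructure k. The vocabulary is the global folded bit space of size
#' `fp_length`, shared across molecules, so encoder weights can be shared.
#' Folding collisions are tolerated: two distinct nodes may carry identical
#' rows.
#'
#' @param subs an `hm_substructures` list.
#' @param fp_length number of columns.
#' @return a sparse `Matrix::sparseMatrix` of 0/1 with one 1 per row.
#' @export
onehot_encode <- function(subs, fp_length) {
  bits <- vapply(subs, `[[`, 0L, "bit")
  if (any(bits < 0 | bits >= fp_length)) {
    stop("bit index out of range [0, fp_length)")
  }
  Matrix::sparseMatrix(i = seq_along(bits), j = bits + 1L, x = 1,
                       dims = c(length(bits), fp_length))
}

#' Number of pair comparisons performed when linking substructures
#'
#' Hyperlink generation examines every unordered pair once, i.e.
#' |S|(|S|-1)/2 comparisons for |S| substructures.
#'
#' @param subs an `hm_substructures` list or an integer count.
#' @return integer number of comparisons.
#' @export
pair_count_probe <- function(subs) {
  n <- if (is.numeric(subs)) as.integer(subs) else length(subs)
  as.integer(n * (n - 1) / 2)
}

#' Export the hypergraph edge list as TSV (and optionally GraphML)
#'
#' @param hg an `hm_hypergraph`.
#' @param path output TSV path (columns `node_i`, `node_j`).
#' @param graphml_path optional path for a GraphML export with center,
#'   radius and bit node attributes.
#' @export
write_hypergraph <- function(hg, path, graphml_path = NULL) {
  stopifnot(inherits(hg, "hm_hypergraph"))
  utils::write.table(
    data.frame(node_i = hg$pos_links[, 1], node_j = hg$pos_links[, 2]),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(graphml_path)) {
    tab <- substructure_table(hg$nodes)
    nodes <- paste0(
      sprintf("    <node id=\"n%d\">", seq_along(hg$nodes)),
      sprintf("<data key=\"center\">%d</data>", tab$center),
      sprintf("<data key=\"radius\">%d</data>", tab$radius),
      sprintf("<data key=\"bit\">%d</data></node>", tab$bit))
    edges <- if (nrow(hg$pos_links) > 0) {
      sprintf("    <edge source=\"n%d\" target=\"n%d\"/>",
              hg$pos_links[, 1], hg$pos_links[, 2])
    } else character(0)
    writeLines(c(
      "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
      "<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">",
      "  <key id=\"center\" for=\"node\" attr.name=\"center\" attr.type=\"int\"/>",
      "  <key id=\"radius\" for=\"node\" attr.name=\"radius\" attr.type=\"int\"/>",
      "  <key id=\"bit\" for=\"node\" attr.name=\"bit\" attr.type=\"int\"/>",
      "  <graph edgedefault=\"undirected\">",
      nodes, edges,
      "  </graph>", "</graphml>"), graphml_path)
  }
  invisible(path)
}
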