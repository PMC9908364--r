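# Property datasets: CSV ingestion in the MoleculeNet dialect (one SMILES
# column, one or more binary task columns, empty cells = missing labels).

#' Assemble a property dataset from SMILES and a label matrix
#'
#' @param smiles character vector of SMILES strings.
#' @param labels numeric matrix (or vector for a single task) with entries in
#'   {0, 1, NA}; one row per molecule.
#' @param task_names optional character vector of task names.
#' @param skip_unparsable drop molecules whose SMILES cannot be read (with a
#'   warning) instead of failing.
#' @return an object of class `hm_dataset`: list with `molecules` (list of
#'   [parse_smiles()] graphs), `smiles`, `labels` (matrix with `NA` for
#'   missing), `task_names`, and `n_skipped`.
#' @export
make_dataset <- function(smiles, labels, task_names = NULL,
                         skip_unparsable = TRUE) {
  stopifnot(is.character(smiles), length(smiles) >= 1)
  labels <- as.matrix(labels)
  if (nrow(labels) != length(smiles)) {
    stop("labels must have one row per molecule")
  }
  if (is.null(task_names)) {
    task_names <- colnames(labels)
    if (is.null(task_names)) task_names <- paste0("task_", seq_len(ncol(labels)))
  }
  bad_vals <- labels[!is.na(labels) & !(labels %in% c(0, 1))]
  if (length(bad_vals) > 0) {
    stop("labels must be 0, 1 or missing; found: ",
         paste(utils::head(unique(bad_vals), 3), collapse = ", "))
  }
  can <- canonical_smiles(smiles)
  bad <- which(is.na(can))
  if (length(bad) > 0) {
    if (!skip_unparsable) {
      stop("unparsable SMILES: '", smiles[bad[1]], "'")
    }
    warning(length(bad), " molecule(s) with unparsable SMILES skipped")
    keep <- setdiff(seq_along(smiles), bad)
  } else {
    keep <- seq_along(smiles)
  }
  if (length(keep) == 0) stop("no parsable molecules in dataset")
  labels <- labels[keep, , drop = FALSE]
  mols <- lapply(can[keep], function(s) {
    g <- .read_smiles_graph(s)
    structure(list(atoms = g$atoms, bonds = g$bonds, smiles = s,
                   source_smiles = s), class = "hm_mol")
  })
  empty_task <- colSums(!is.na(labels)) == 0
  if (any(empty_task)) {
    stop("task(s) with no observed labels: ",
         paste(task_names[empty_task], collapse = ", "))
  }
  colnames(labels) <- task_names
  rownames(labels) <- NULL
  structure(list(molecules = mols, smiles = can[keep], labels = labels,
                 task_names = task_names, n_skipped = length(bad)),
            class = "hm_dataset")
}

#' Read a property-prediction CSV
#'
#' Expects a header row, one SMILES column and one or more binary task
#' columns; empty cells become missing labels. Rows whose SMILES cannot be
#' parsed are dropped with a warning and counted in `n_skipped`.
#'
#' @param path CSV file path.
#' @param smiles_column name of the SMILES column (default `"smiles"`).
#' @param task_columns character vector of label column names; by default all
#'   non-SMILES columns are used.
#' @return an `hm_dataset`; see [make_dataset()].
#' @export
read_dataset <- function(path, smiles_column = "smiles", task_columns = NULL) {
  if (!file.exists(path)) stop("dataset file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!smiles_column %in% names(df)) {
    stop("SMILES column '", smiles_column, "' not present in ", path)
  }
  if (is.null(task_columns)) {
    task_columns <- setdiff(names(df), smiles_column)
  } else {
    missing_cols <- setdiff(task_columns, names(df))
    if (length(missing_cols) > 0) {
      stop("task column(s) not present: ", paste(missing_cols, collapse = ", "))
    }
  }
  if (length(task_columns) == 0) stop("no task columns in ", path)
  labels <- as.matrix(df[, task_columns, drop = FALSE])
  storage.mode(labels) <- "numeric"
  make_dataset(df[[smiles_column]], labels, task_names = task_columns)
}

#' @export
print.hm_dataset <- function(x, ...) {
  cat("<hm_dataset> ", length(x$molecules), " molecules, ",
      length(x$task_names), " task(s)\n", sep = "")
  obs <- colSums(!is.na(x$labels))
  pos <- colSums(x$labels == 1, na.rm = TRUE)
  for (k in seq_along(x$task_names)) {
    cat(sprintf("  %s: %d observed, %d positive\n",
                x$task_names[k], obs[k], pos[k]))
  }
  if (x$n_skipped > 0) cat("  (", x$n_skipped, " unparsable rows skipped)\n", sep = "")
  invisible(x)
}

#' @export
length.hm_dataset <- function(x) length(x$molecules)

#' Subset a dataset by molecule indices
#' @param dataset an `hm_dataset`.
#' @param idx integer vector of molecule indices.
#' @return an `hm_dataset` restricted to `idx`.
#' @export
dataset_slice <- function(dataset, idx) {
  stopifnot(inherits(dataset, "hm_dataset"))
  structure(list(molecules = dataset$molecules[idx],
                 smiles = dataset$smiles[idx],
                 labels = dataset$labels[idx, , drop = FALSE],
                 task_names = dataset$task_names,
                 n_skipped = 0L),
            class = "hm_dataset")
}

#' Write a split manifest
#'
#' Three-column tab-separated text: molecule index (1-based), SMILES and the
#' partition it was assigned to.
#'
#' @param dataset an `hm_dataset`.
#' @param split an `hm_split` from [scaffold_split()].
#' @param path output file.
#' @export
write_split_manifest <- function(dataset, split, path) {
  part <- character(length(dataset$molecules))
  part[split$train_idx] <- "train"
  part[split$valid_idx] <- "valid"
  part[split$test_idx] <- "test"
  utils::write.table(
    data.frame(index = seq_along(part), smiles = dataset$smiles,
               partition = part),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
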