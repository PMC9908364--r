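# Synthetic motif-labelled molecules: a fragment grammar assembles
# guaranteed-valid SMILES; the label of each task is presence of that task's
# chemical motif, optionally corrupted by independent flip noise. The
# grammar deliberately avoids every built-in motif (no carbonyl, sulfur,
# nitrile or CF3 fragments), so motif presence is controlled exactly by the
# generator, and the default motif (carboxylic acid) is detectable at
# fingerprint radius 1.

# templates with one substitution slot; rings give scaffold diversity
.SYNTH_TEMPLATES <- c(
  "C%s", "CC%s", "CCC%s", "CCCC%s", "CC(C)C%s",
  "c1ccccc1%s", "c1ccc(cc1)%s", "C1CCCCC1%s", "C1CCCC1%s",
  "c1ccnc(c1)%s", "C1CCOC1%s", "c1ccc2ccccc2c1%s"
)
# chain units appended after the template slot (motif-free by construction)
.SYNTH_UNITS <- c("C", "CC", "CO", "CN", "CCl", "COC", "CN(C)C", "CCO", "")

# one distinct motif per task, in order of task index
.SYNTH_MOTIFS <- c("C(=O)O", "S(=O)(=O)N", "C#N", "C(F)(F)F")

#' Test whether a molecule contains a chemical motif
#'
#' Substructure match via OpenBabel SMARTS search; used both to label
#' synthetic molecules and as the ground-truth oracle in tests.
#'
#' @param mol an `hm_mol`, or a SMILES string.
#' @param motif SMARTS/SMILES pattern text.
#' @return `TRUE` if the motif occurs in the molecule.
#' @export
motif_present <- function(mol, motif) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  stopifnot(inherits(mol, "hm_mol"))
  if (!is.character(motif) || length(motif) != 1 || !nzchar(motif)) {
    stop("motif must be one non-empty pattern string")
  }
  sdf <- ChemmineR::read.SDFset(ChemmineR::read.SDFstr(
    textConnection(.mol_to_sdf(mol))))
  hits <- tryCatch(
    ChemmineR::smartsSearchOB(sdf, motif, uniqueMatches = FALSE),
    error = function(e) stop("invalid motif pattern '", motif, "': ",
                             conditionMessage(e)))
  as.vector(hits)[1] > 0
}

#' Generate a synthetic motif-labelled property dataset
#'
#' Molecules are assembled by seeded random draws from a built-in fragment
#' grammar (alkyl chains, ring fragments, ether/amine/halide decorations).
#' For each task, a fixed-size subset of molecules (`round(n *
#' positive_fraction)`) receives that task's motif fragment; the task label
#' is motif presence, then flipped independently with probability
#' `label_noise`. Every emitted SMILES re-parses by construction. With the
#' same spec and seed the output (and any CSV written) is byte-identical.
#'
#' @param n_molecules number of molecules.
#' @param motif motif of the first task (default carboxylic acid
#'   `"C(=O)O"`); tasks beyond the first use further built-in motifs.
#' @param positive_fraction fraction of motif-bearing molecules per task,
#'   in (0, 1).
#' @param label_noise independent label flip probability in [0, 0.5).
#' @param n_tasks number of tasks (at most 4).
#' @param seed RNG seed; the generator restores the caller's RNG state.
#' @param csv_path optional path; when given, the dataset is also written as
#'   a CSV in the standard dialect (a `smiles` column plus one column per
#'   task).
#' @return an `hm_dataset` with an extra attribute `motif_truth` (logical
#'   matrix of actual motif presence, before noise) and `motifs` (the motif
#'   per task).
#' @export
generate_molecules <- function(n_molecules, motif = "C(=O)O",
                               positive_fraction = 0.5, label_noise = 0,
                               n_tasks = 1L, seed = 1L, csv_path = NULL) {
  stopifnot(n_molecules >= 4, positive_fraction > 0, positive_fraction < 1,
            label_noise >= 0, label_noise < 0.5, n_tasks >= 1)
  if (n_tasks > length(.SYNTH_MOTIFS)) {
    stop("at most ", length(.SYNTH_MOTIFS), " built-in task motifs")
  }
  motifs <- .SYNTH_MOTIFS
  motifs[1] <- motif
  motifs <- motifs[seq_len(n_tasks)]

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(seed)

  tmpl <- sample(.SYNTH_TEMPLATES, n_molecules, replace = TRUE)
  tails <- vapply(seq_len(n_molecules), function(i) {
    paste(sample(.SYNTH_UNITS, sample(1:2, 1), replace = TRUE),
          collapse = "")
  }, character(1))

  n_pos <- round(n_molecules * positive_fraction)
  truth <- matrix(FALSE, n_molecules, n_tasks)
  for (t in seq_len(n_tasks)) {
    truth[sample.int(n_molecules, n_pos), t] <- TRUE
  }
  # each motif hangs off its own anchor carbon placed before the decoration
  # tail, so terminal fragments (e.g. -Cl) never gain an extra bond
  smiles <- vapply(seq_len(n_molecules), function(i) {
    anchors <- paste(sprintf("C(%s)", motifs[truth[i, ]]), collapse = "")
    sprintf(tmpl[i], paste0(anchors, tails[i]))
  }, character(1))
  labels <- matrix(as.numeric(truth), n_molecules, n_tasks)
  if (label_noise > 0) {
    flips <- matrix(stats::runif(n_molecules * n_tasks) < label_noise,
                    n_molecules, n_tasks)
    labels[flips] <- 1 - labels[flips]
  }
  task_names <- paste0("task_", seq_len(n_tasks))
  colnames(labels) <- task_names

  if (!is.null(csv_path)) {
    df <- data.frame(smiles = smiles, labels, check.names = FALSE)
    utils::write.csv(df, csv_path, row.names = FALSE, quote = FALSE)
  }
  ds <- make_dataset(smiles, labels, task_names = task_names,
                     skip_unparsable = FALSE)
  attr(ds, "motif_truth") <- truth
  attr(ds, "motifs") <- motifs
  ds
}
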