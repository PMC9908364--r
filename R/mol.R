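# Molecule ingestion: SMILES -> heavy-atom molecular graph.
#
# Parsing strategy: OpenBabel (via ChemmineOB) canonicalises the input SMILES,
# fixing atom order and aromaticity perception; the canonical string is then
# read into an atom/bond table. Hydrogens stay implicit (counted per atom).

# bond-order codes used throughout: 1 single, 2 double, 3 triple, 4 aromatic
BOND_SINGLE <- 1L
BOND_DOUBLE <- 2L
BOND_TRIPLE <- 3L
BOND_AROMATIC <- 4L

.ob_options <- function() {
  # -e: continue past unreadable records so batch conversion keeps row names
  data.frame(names = "e", args = "", stringsAsFactors = FALSE)
}

#' Canonicalise SMILES strings with OpenBabel
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of the same length with canonical SMILES, `NA`
#'   where OpenBabel could not read the input.
#' @keywords internal
canonical_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1)
  ids <- sprintf("hm%09d", seq_along(smiles))
  src <- paste0(paste(smiles, ids, sep = "\t", collapse = "\n"), "\n")
  out <- ChemmineOB::convertFormat("SMI", "CAN", source = src,
                                   options = .ob_options())
  res <- rep(NA_character_, length(smiles))
  if (nzchar(out)) {
    lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    for (p in parts) {
      if (length(p) >= 2) {
        k <- match(p[[2]], ids)
        if (!is.na(k)) res[k] <- p[[1]]
      }
    }
  }
  res
}

.ELEMENTS <- c(
  H = 1L, He = 2L, Li = 3L, Be = 4L, B = 5L, C = 6L, N = 7L, O = 8L, F = 9L,
  Ne = 10L, Na = 11L, Mg = 12L, Al = 13L, Si = 14L, P = 15L, S = 16L,
  Cl = 17L, Ar = 18L, K = 19L, Ca = 20L, Ti = 22L, Cr = 24L, Mn = 25L,
  Fe = 26L, Co = 27L, Ni = 28L, Cu = 29L, Zn = 30L, As = 33L, Se = 34L,
  Br = 35L, Ag = 47L, Sn = 50L, Sb = 51L, Te = 52L, I = 53L, Ba = 56L,
  Pt = 78L, Au = 79L, Hg = 80L, Pb = 82L, Bi = 83L
)

# Daylight-style default valences for implicit-hydrogen filling
.VALENCES <- list(B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5),
                  S = c(2, 4, 6), F = 1, Cl = 1, Br = 1, I = 1)

.implicit_h <- function(element, aromatic, bracket, explicit_h, order_sum) {
  if (bracket) return(explicit_h)
  vals <- .VALENCES[[element]]
  if (is.null(vals)) return(0L)
  # one aromatic bond contributes an extra half-pair; the usual approximation
  # adds 1 to the bond-order sum of an aromatic atom
  bs <- order_sum + if (aromatic) 1L else 0L
  v <- vals[vals >= bs]
  if (length(v) == 0) return(0L)
  as.integer(v[1] - bs)
}

# Reads one canonical SMILES string (organic subset + bracket atoms, branches,
# ring closures incl. %nn, dot-separated fragments). Chirality and isotopes
# are accepted and discarded; cis/trans bond marks are read as single bonds.
.read_smiles_graph <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  elem <- character(0); arom <- logical(0); charge <- integer(0)
  brack <- logical(0); exph <- integer(0)
  b1 <- integer(0); b2 <- integer(0); bo <- integer(0)
  prev <- 0L                       # index of previous atom (0 = none)
  pending <- NA_integer_           # explicit bond symbol awaiting next atom
  stack <- integer(0)
  rings <- list()                  # closure digit -> c(atom, order-or-NA)
  i <- 1L

  add_atom <- function(el, ar, ch, br, eh) {
    elem[length(elem) + 1L] <<- el
    arom[length(arom) + 1L] <<- ar
    charge[length(charge) + 1L] <<- ch
    brack[length(brack) + 1L] <<- br
    exph[length(exph) + 1L] <<- eh
    a <- length(elem)
    if (prev > 0L) {
      o <- pending
      if (is.na(o)) o <- if (ar && arom[prev]) BOND_AROMATIC else BOND_SINGLE
      b1[length(b1) + 1L] <<- prev; b2[length(b2) + 1L] <<- a
      bo[length(bo) + 1L] <<- o
    }
    pending <<- NA_integer_
    prev <<- a
    invisible(a)
  }
  close_ring <- function(key) {
    o <- pending; pending <<- NA_integer_
    if (is.null(rings[[key]])) {
      rings[[key]] <<- c(prev, if (is.na(o)) NA_integer_ else o)
    } else {
      open <- rings[[key]]; rings[[key]] <<- NULL
      a <- open[1]
      oo <- if (!is.na(open[2])) open[2] else o
      if (is.na(oo)) oo <- if (arom[a] && arom[prev]) BOND_AROMATIC else BOND_SINGLE
      b1[length(b1) + 1L] <<- a; b2[length(b2) + 1L] <<- prev
      bo[length(bo) + 1L] <<- oo
    }
  }

  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unbalanced bracket in SMILES: ", s)
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      m <- regmatches(body, regexec(
        "^([0-9]*)([A-Z][a-z]?|[a-z][a-z]?|\\*)(@{0,2}|@TH[12])(H[0-9]*)?([+-][0-9]*|\\+*|-*)?(:[0-9]+)?$",
        body))[[1]]
      if (length(m) == 0) stop("cannot read bracket atom [", body, "] in: ", s)
      sym <- m[3]
      ar <- sym %in% c("b", "c", "n", "o", "p", "s", "as", "se", "te")
      el <- if (ar) paste0(toupper(substr(sym, 1, 1)), substring(sym, 2)) else sym
      hh <- m[5]
      eh <- if (is.na(hh) || hh == "") 0L
            else if (hh == "H") 1L else as.integer(substring(hh, 2))
      cs <- m[6]
      cg <- 0L
      if (!is.na(cs) && nzchar(cs)) {
        if (grepl("^[+-][0-9]+$", cs)) {
          cg <- as.integer(cs)
        } else {
          cg <- nchar(cs) * (if (substr(cs, 1, 1) == "+") 1L else -1L)
        }
      }
      add_atom(el, ar, cg, TRUE, eh)
      i <- j + 1L
    } else if (ch %in% c("C", "B", "N", "O", "P", "S", "F", "I")) {
      two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
      if (two %in% c("Cl", "Br")) {
        add_atom(two, FALSE, 0L, FALSE, 0L); i <- i + 2L
      } else {
        add_atom(ch, FALSE, 0L, FALSE, 0L); i <- i + 1L
      }
    } else if (ch %in% c("c", "b", "n", "o", "p", "s")) {
      add_atom(toupper(ch), TRUE, 0L, FALSE, 0L); i <- i + 1L
    } else if (ch == "-") { pending <- BOND_SINGLE; i <- i + 1L
    } else if (ch == "=") { pending <- BOND_DOUBLE; i <- i + 1L
    } else if (ch == "#") { pending <- BOND_TRIPLE; i <- i + 1L
    } else if (ch == ":") { pending <- BOND_AROMATIC; i <- i + 1L
    } else if (ch == "/" || ch == "\\") { pending <- BOND_SINGLE; i <- i + 1L
    } else if (ch == "(") { stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0) stop("unbalanced parenthesis in SMILES: ", s)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch == ".") { prev <- 0L; pending <- NA_integer_; i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      close_ring(ch); i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n) stop("truncated ring closure in SMILES: ", s)
      close_ring(paste0(chars[i + 1L], chars[i + 2L])); i <- i + 3L
    } else {
      stop("unexpected character '", ch, "' in SMILES: ", s)
    }
  }
  if (length(rings) > 0) stop("unclosed ring bond in SMILES: ", s)
  if (length(elem) == 0) stop("SMILES contains no atoms: ", s)

  na <- length(elem)
  deg <- integer(na); osum <- numeric(na)
  if (length(b1) > 0) {
    key <- paste(pmin(b1, b2), pmax(b1, b2))
    if (anyDuplicated(key)) stop("duplicate bond in SMILES: ", s)
    for (k in seq_along(b1)) {
      o <- if (bo[k] == BOND_AROMATIC) 1L else bo[k]
      deg[b1[k]] <- deg[b1[k]] + 1L; deg[b2[k]] <- deg[b2[k]] + 1L
      osum[b1[k]] <- osum[b1[k]] + o; osum[b2[k]] <- osum[b2[k]] + o
    }
  }
  n_h <- integer(na)
  for (a in seq_len(na)) {
    n_h[a] <- .implicit_h(elem[a], arom[a], brack[a], exph[a], osum[a])
  }
  atoms <- data.frame(element = elem, charge = charge, degree = deg,
                      n_h = n_h, aromatic = arom, stringsAsFactors = FALSE)
  bonds <- data.frame(a1 = pmin(b1, b2), a2 = pmax(b1, b2), order = bo)
  bonds <- bonds[order(bonds$a1, bonds$a2), , drop = FALSE]
  rownames(bonds) <- NULL
  list(atoms = atoms, bonds = bonds)
}

#' Parse a SMILES string into a molecular graph
#'
#' The string is first canonicalised by OpenBabel (which also perceives
#' aromaticity); the canonical form is then read into an atom/bond table.
#' Hydrogens are implicit: only heavy atoms appear, each carrying its
#' attached-hydrogen count. Atom order is OpenBabel's canonical order and is
#' therefore fixed for a given input.
#'
#' @param smiles a single SMILES string.
#' @return an object of class `hm_mol`: a list with `atoms` (data frame with
#'   columns `element`, `charge`, `degree`, `n_h`, `aromatic`), `bonds`
#'   (data frame with 1-based atom indices `a1 < a2` and `order` coded
#'   1 = single, 2 = double, 3 = triple, 4 = aromatic), and `smiles`
#'   (the canonical SMILES).
#' @examples
#' m <- parse_smiles("CCO")
#' nrow(m$atoms)  # 3 heavy atoms
#' @export
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1 || is.na(smiles) ||
      !nzchar(trimws(smiles))) {
    stop("parse_smiles() expects one non-empty SMILES string")
  }
  can <- canonical_smiles(smiles)
  if (is.na(can)) stop("unparsable SMILES: '", smiles, "'")
  g <- .read_smiles_graph(can)
  structure(list(atoms = g$atoms, bonds = g$bonds, smiles = can,
                 source_smiles = smiles),
            class = "hm_mol")
}

#' @export
print.hm_mol <- function(x, ...) {
  cat("<hm_mol> ", x$smiles, "\n", sep = "")
  cat("  ", nrow(x$atoms), " heavy atoms, ", nrow(x$bonds), " bonds, ",
      sum(x$atoms$aromatic), " aromatic atoms\n", sep = "")
  invisible(x)
}

# V2000 SDF text for a molecular graph (or an atom subset); used for
# round-tripping through OpenBabel (canonical SMILES, SMARTS matching).
.mol_to_sdf <- function(mol, keep = NULL, title = "hm_mol") {
  atoms <- mol$atoms; bonds <- mol$bonds
  if (!is.null(keep)) {
    keep <- sort(unique(keep))
    remap <- match(seq_len(nrow(atoms)), keep)
    atoms <- atoms[keep, , drop = FALSE]
    sel <- bonds$a1 %in% keep & bonds$a2 %in% keep
    bonds <- bonds[sel, , drop = FALSE]
    bonds$a1 <- remap[bonds$a1]; bonds$a2 <- remap[bonds$a2]
  }
  na <- nrow(atoms); nb <- nrow(bonds)
  header <- c(title, "  hypermol", "",
              sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb))
  atom_lines <- sprintf("    0.0000    0.0000    0.0000 %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                        atoms$element)
  bond_lines <- if (nb > 0) {
    sprintf("%3d%3d%3d  0", bonds$a1, bonds$a2, bonds$order)
  } else character(0)
  chg <- which(atoms$charge != 0)
  chg_lines <- if (length(chg) > 0) {
    sprintf("M  CHG%3d%s", length(chg),
            paste(sprintf(" %3d %3d", chg, atoms$charge[chg]), collapse = ""))
  } else character(0)
  paste(c(header, atom_lines, bond_lines, chg_lines, "M  END", "$$$$", ""),
        collapse = "\n")
}

#' Write a molecular graph back to canonical SMILES
#'
#' Serialises the graph to an SDF record and lets OpenBabel emit canonical
#' SMILES, so `parse_smiles(write_smiles(m))` returns an isomorphic graph.
#'
#' @param mol an `hm_mol` object.
#' @return a single canonical SMILES string.
#' @export
write_smiles <- function(mol) {
  stopifnot(inherits(mol, "hm_mol"))
  out <- ChemmineOB::convertFormat("SDF", "CAN", source = .mol_to_sdf(mol),
                                   options = .ob_options())
  out <- strsplit(out, "[\t\n]")[[1]]
  if (length(out) == 0 || !nzchar(out[1])) {
    stop("could not serialise molecule to SMILES")
  }
  out[1]
}

# Canonical invariant key of a whole graph (used to compare graphs up to
# isomorphism in tests): canonical SMILES of the graph itself.
.graph_key <- function(mol) {
  if (nrow(mol$atoms) == 0) return("")
  out <- ChemmineOB::convertFormat("SDF", "CAN", source = .mol_to_sdf(mol),
                                   options = .ob_options())
  strsplit(out, "[\t\n]")[[1]][1]
}
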