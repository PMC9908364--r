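# SMILES parsing, dataset ingestion and the scaffold split

test_that("parse_smiles builds the expected heavy-atom graphs", {
  eth <- parse_smiles("CCO")
  expect_equal(nrow(eth$atoms), 3)
  expect_equal(nrow(eth$bonds), 2)
  expect_equal(sort(eth$atoms$element), c("C", "C", "O"))

  methane <- parse_smiles("C")
  expect_equal(nrow(methane$atoms), 1)
  expect_equal(nrow(methane$bonds), 0)
  expect_equal(methane$atoms$n_h, 4)

  benzene <- parse_smiles("c1ccccc1")
  expect_equal(nrow(benzene$atoms), 6)
  expect_equal(nrow(benzene$bonds), 6)
  expect_true(all(benzene$atoms$aromatic))
  expect_true(all(benzene$bonds$order == 4))
  # kekulised input gets the same aromatic perception
  kek <- parse_smiles("C1=CC=CC=C1")
  expect_identical(kek$smiles, benzene$smiles)
})

test_that("parse_smiles rejects bad input with the offending string", {
  expect_error(parse_smiles("xyz(("), "xyz")
  expect_error(parse_smiles(""), "non-empty")
  expect_error(parse_smiles(c("C", "CC")), "one non-empty")
})

test_that("bond endpoints are valid and duplicate-free for random molecules", {
  mols <- random_molecule_pool(40, seed = 91)
  for (m in mols) {
    na <- nrow(m$atoms)
    expect_true(all(m$bonds$a1 >= 1 & m$bonds$a2 <= na))
    expect_true(all(m$bonds$a1 < m$bonds$a2))
    expect_false(any(duplicated(paste(m$bonds$a1, m$bonds$a2))))
  }
})

test_that("parse -> write_smiles -> parse round trip is isomorphic", {
  pool <- c("CCO", "CC(=O)Oc1ccccc1C(=O)O", "C[N+](C)(C)C", "c1ccc2ccccc2c1",
            "CC(=O)[O-]", "C1CCOC1CCl")
  for (s in pool) {
    m <- parse_smiles(s)
    m2 <- parse_smiles(write_smiles(m))
    expect_identical(m2$smiles, m$smiles)
    expect_equal(m2$atoms, m$atoms)
    expect_equal(m2$bonds, m$bonds)
  }
})

test_that("read_dataset handles clean, corrupt and incomplete tables", {
  p <- withr::local_tempfile(fileext = ".csv")
  write_tiny_csv(p)
  ds <- read_dataset(p)
  expect_s3_class(ds, "hm_dataset")
  expect_equal(length(ds$molecules), 4)
  expect_equal(dim(ds$labels), c(4, 1))
  expect_equal(ds$n_skipped, 0)

  write_tiny_csv(p, smiles = c("CCO", "not_a_smiles", "c1ccccc1", "CCN"))
  expect_warning(ds2 <- read_dataset(p), "skipped")
  expect_equal(length(ds2$molecules), 3)
  expect_equal(ds2$n_skipped, 1)

  writeLines(c("smiles,t1,t2", "CCO,1,0", "CC,,1", "CCN,0,1"), p)
  ds3 <- read_dataset(p)
  expect_equal(sum(is.na(ds3$labels)), 1)
  expect_true(is.na(ds3$labels[2, "t1"]))

  expect_error(read_dataset(p, smiles_column = "smi"), "not present")
  expect_error(read_dataset(p, task_columns = "missing_col"), "not present")
  writeLines(c("smiles,t1", "bad_smiles_1,1", "bad_smiles_2,0"), p)
  expect_error(suppressWarnings(read_dataset(p)), "no parsable")
})

test_that("murcko scaffolds strip side chains and pool acyclic molecules", {
  expect_identical(murcko_scaffold(parse_smiles("CCCCC")), "")
  tol <- murcko_scaffold(parse_smiles("Cc1ccccc1"))
  benz <- murcko_scaffold(parse_smiles("c1ccccc1"))
  expect_identical(tol, benz)
  expect_false(murcko_scaffold(parse_smiles("C1CCCCC1")) == benz)
})

test_that("scaffold split respects ratios and group atomicity", {
  # ten distinct single-molecule scaffolds -> exact 8/1/1
  smi <- c("c1ccccc1C", "c1ccncc1C", "C1CCCCC1C", "C1CCCC1C", "C1CCOC1C",
           "c1ccc2ccccc2c1C", "C1CCNC1C", "c1cncnc1C", "C1CCOCC1C",
           "c1ccoc1C")
  ds <- make_dataset(smi, rep(c(0, 1), 5))
  sp <- scaffold_split(ds, c(0.8, 0.1, 0.1))
  expect_equal(lengths(sp[c("train_idx", "valid_idx", "test_idx")]),
               c(train_idx = 8L, valid_idx = 1L, test_idx = 1L))

  # one shared scaffold cannot be divided
  ds1 <- make_dataset(paste0("c1ccccc1", c("C", "CC", "CCC", "N")),
                      c(0, 1, 0, 1))
  expect_error(scaffold_split(ds1), "at least 3 scaffold groups")

  # greedy assignment on groups of sizes 4, 3, 1, 1, 1
  smi2 <- c(paste0("c1ccccc1", c("C", "CC", "CCC", "CCCC")),  # benzene x4
            paste0("C1CCCCC1", c("C", "CC", "CCC")),          # cyclohexane x3
            "C1CCCC1C", "C1CCOC1C", "c1ccncc1C")              # singletons
  ds2 <- make_dataset(smi2, rep(c(0, 1), 5))
  sp2 <- scaffold_split(ds2, c(0.8, 0.1, 0.1))
  expect_equal(length(sp2$train_idx), 8)
  expect_equal(length(sp2$valid_idx), 1)
  expect_equal(length(sp2$test_idx), 1)
  expect_true(all(1:7 %in% sp2$train_idx))  # the two big groups train together
})

test_that("scaffold split is an exhaustive, pure, scaffold-tight partition", {
  ds <- generate_molecules(120, seed = 5)
  sp <- scaffold_split(ds)
  idx <- c(sp$train_idx, sp$valid_idx, sp$test_idx)
  expect_equal(sort(idx), seq_along(ds$molecules))  # disjoint + exhaustive
  part <- character(length(ds$molecules))
  part[sp$train_idx] <- "train"; part[sp$valid_idx] <- "valid"
  part[sp$test_idx] <- "test"
  expect_true(all(tapply(part, sp$scaffolds,
                         function(x) length(unique(x))) == 1))
  sp2 <- scaffold_split(ds)
  expect_identical(sp, sp2)  # determinism
})

test_that("split manifest lists every molecule once with its partition", {
  ds <- generate_molecules(50, seed = 9)
  sp <- scaffold_split(ds)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_split_manifest(ds, sp, p)
  man <- read.delim(p)
  expect_equal(nrow(man), 50)
  expect_equal(sort(unique(man$partition)), c("test", "train", "valid"))
  expect_equal(man$index, 1:50)
})
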