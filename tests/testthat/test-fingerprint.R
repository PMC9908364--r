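# Circular fingerprint substructure extraction

test_that("methane yields exactly one radius-0 environment", {
  subs <- extract_substructures(parse_smiles("C"), fingerprint_config(2048, 2))
  expect_length(subs, 1)
  expect_equal(subs[[1]]$center, 1)
  expect_equal(subs[[1]]$radius, 0)
  expect_equal(subs[[1]]$atoms, 1)
})

test_that("ethanol at radius 1 yields the six hand-enumerated balls", {
  subs <- extract_substructures(parse_smiles("CCO"), fingerprint_config(2048, 1))
  expect_length(subs, 6)
  got <- lapply(subs, `[[`, "atoms")
  # the heavy-atom graph is the path 1-2-3 (OpenBabel order C-C-O)
  expect_setequal(vapply(got, paste, "", collapse = ","),
                  c("1", "2", "3", "1,2", "1,2,3", "2,3"))
  # the three radius-0 environments have pairwise distinct invariants
  bits0 <- vapply(Filter(function(s) s$radius == 0, subs), `[[`, 0L, "bit")
  expect_length(unique(bits0), 3)
  # ordered by (center, radius)
  cr <- t(vapply(subs, function(s) c(s$center, s$radius), numeric(2)))
  expect_equal(order(cr[, 1], cr[, 2]), seq_len(nrow(cr)))
})

test_that("ball_oracle matches hand-derived balls", {
  path3 <- parse_smiles("CCO")  # path graph 1-2-3
  expect_equal(ball_oracle(path3, 2, 1), c(1, 2, 3))
  expect_equal(ball_oracle(path3, 1, 0), 1)
  benzene <- parse_smiles("c1ccccc1")
  for (c_ in 1:6) expect_equal(ball_oracle(benzene, c_, 3), 1:6)
})

test_that("every extracted atom set is a BFS ball and nesting is strict", {
  mols <- random_molecule_pool(60, seed = 17)
  cfg <- fingerprint_config(2048, 2)
  for (m in mols) {
    subs <- extract_substructures(m, cfg)
    expect_lte(length(subs), nrow(m$atoms) * (cfg$max_radius + 1))
    by_center <- split(subs, vapply(subs, `[[`, 0L, "center"))
    for (s in subs) {
      expect_equal(s$atoms, ball_oracle(m, s$center, s$radius))
      expect_true(s$center %in% s$atoms)
      expect_true(s$bit >= 0 && s$bit < cfg$fp_length)
      # bond set: both endpoints in the ball, nearer endpoint inside radius-1
      if (nrow(s$bonds) > 0) {
        inner <- ball_oracle(m, s$center, s$radius - 1)
        expect_true(all(s$bonds[, 1] %in% s$atoms & s$bonds[, 2] %in% s$atoms))
        expect_true(all(s$bonds[, 1] %in% inner | s$bonds[, 2] %in% inner))
      }
    }
    for (grp in by_center) {
      sets <- lapply(grp, `[[`, "atoms")
      if (length(sets) > 1) {
        for (k in 2:length(sets)) {
          expect_true(all(sets[[k - 1]] %in% sets[[k]]))
          expect_gt(length(sets[[k]]), length(sets[[k - 1]]))
        }
      }
    }
  }
})

test_that("non-growing balls are suppressed and dedup keeps first", {
  # in ethane both radius-1 balls equal the whole molecule and the two
  # centers are symmetric: identical hash + atom set collapse to one node
  subs <- extract_substructures(parse_smiles("CC"), fingerprint_config(2048, 2))
  tab <- substructure_table(subs)
  # radius-0 environments of the two equivalent carbons share a bit but have
  # different atom sets, so both survive; the radius-1 balls coincide in bit
  # and atom set and collapse to one node; radius-2 balls never grow
  expect_length(subs, 3)
  expect_equal(sum(tab$radius == 0), 2)
  expect_equal(sum(tab$radius == 1), 1)
  expect_equal(sum(tab$radius == 2), 0)
})

test_that("substructure table export round-trips through TSV", {
  subs <- extract_substructures(parse_smiles("CCO"), fingerprint_config(64, 1))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_substructure_table(subs, p)
  tab <- read.delim(p)
  expect_equal(nrow(tab), 6)
  expect_named(tab, c("center", "radius", "bit", "atoms"))
})
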