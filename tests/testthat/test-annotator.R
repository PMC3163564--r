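# SMILES parsing, substructure matching, disjoint selection, and profile
# assembly.

test_that("parse_molecule builds graphs with stable atom order", {
  mol <- parse_molecule("CCO")
  expect_equal(mol$natoms, 3L)
  expect_identical(mol$atoms$elem, c("C", "C", "O"))
  expect_equal(mol$atoms$nH, c(3L, 2L, 1L))

  pg <- parse_molecule(pg_smiles())
  expect_equal(pg$natoms, 26L)
  expect_equal(sum(pg$atoms$in_ring), 5L)  # the cyclopentane ring

  expect_error(parse_molecule("C1CC"), "cannot parse")
  expect_error(parse_molecule("notasmiles"), "cannot parse")
  expect_error(parse_molecule(""), "non-empty")
})

test_that("find_matches enumerates unique matches deterministically", {
  expect_identical(find_matches(parse_molecule("C=CC=C"), "C=C"),
                   list(c(1L, 2L), c(3L, 4L)))
  expect_identical(find_matches(parse_molecule("CCO"), "C=C"), list())
  # hydroxyls on sp3 carbons of the prostaglandin example
  expect_length(find_matches(parse_molecule(pg_smiles()), "[OX2H1][CX4]"), 3L)
  # aromatic bonds never count as alkenes
  expect_length(find_matches(parse_molecule("c1ccccc1C=C"), "C=C"), 1L)
})

test_that("matching agrees with an independent SMARTS engine", {
  # OpenBabel's own SMARTS matcher (match counts with unique filtering) as
  # the external oracle, over the shipped patterns and assorted molecules
  lib <- lc_lib()
  mols <- c(pg_smiles(), epoxy_trienoic_smiles(), "CCO", "CCOO", "CCOOCC",
            "CC(=O)OC", "C1CCCC1", "c1ccccc1CC=CO",
            "CCCCC(O)C=CCC=CCC=CCCCCCCC(=O)O")
  for (smi in mols) {
    mol <- parse_molecule(smi)
    ob <- ChemmineOB::forEachMol("SMILES", smi, identity)
    for (pat in lib$patterns) {
      if (pat$id == "carbon_atom") next  # trivially every carbon
      got <- length(find_matches(mol, pat))
      want <- unname(ChemmineOB::smartsSearch_OB(ob, pat$smarts,
                                                 uniqueMatches = TRUE))
      expect_equal(got, want,
                   info = sprintf("pattern %s on %s", pat$id, smi))
    }
  }
})

test_that("select_disjoint picks a maximum disjoint subset, deterministically", {
  expect_identical(select_disjoint(list(c(1L, 2L), c(2L, 3L))),
                   list(c(1L, 2L)))
  expect_identical(select_disjoint(list(c(1L, 2L), c(3L, 4L))),
                   list(c(1L, 2L), c(3L, 4L)))
  expect_identical(select_disjoint(list(c(1L, 2L), c(2L, 3L), c(3L, 4L))),
                   list(c(1L, 2L), c(3L, 4L)))
})

test_that("disjoint selection equals the exhaustive maximum independent set", {
  lib <- lc_lib()
  mols <- c(pg_smiles(), epoxy_trienoic_smiles(),
            "CCCCCCCCCC", "CC(C)CC(C)CC(C)C", "C=CC=CC=CC=C",
            "OCC(O)C(O)C(O)CO")
  checked <- 0L
  for (smi in mols) {
    mol <- parse_molecule(smi)
    for (pat in lib$patterns) {
      matches <- find_matches(mol, pat)
      if (length(matches) < 2L || length(matches) > 12L) next
      expect_equal(length(select_disjoint(matches)), brute_mis_size(matches),
                   info = sprintf("pattern %s on %s", pat$id, smi))
      checked <- checked + 1L
    }
  }
  expect_gte(checked, 10L)
})

test_that("annotate assembles closed-world profiles", {
  lib <- lc_lib()
  p <- annotate("CCO", lib)
  expect_s3_class(p, "fg_profile")
  expect_equal(p$counts[["Alcohol"]], 1L)
  expect_true(p$exact[["Alcohol"]])
  # ubiquitous classes appear at most once, flagged inexact
  for (cl in intersect(names(p$counts), c("Carbon_Atom", "Methyl"))) {
    expect_equal(p$counts[[cl]], 1L)
    expect_false(p$exact[[cl]])
  }

  pg <- annotate(list(uri = "urn:x", smiles = pg_smiles()), lib)
  expect_true(all(c("Propyl", "Alcohol") %in% pg$occurrences$group_class))
  expect_equal(pg$counts[["Alcohol"]], 3L)
  expect_equal(pg$counts[["Alkenyl_Group"]], 1L)
  expect_equal(pg$counts[["Cyclopentane_Ring"]], 1L)
  expect_equal(pg$counts[["Primary_Acyl_Chain"]], 1L)
  expect_false("Epoxy" %in% names(pg$counts))

  # no matches at all
  empty <- annotate("O=O", lib)
  expect_equal(nrow(empty$occurrences), 0L)
  expect_length(empty$counts, 0L)
})

test_that("within each pattern the selected occurrences are atom-disjoint", {
  lib <- lc_lib()
  for (smi in c(pg_smiles(), epoxy_trienoic_smiles(), "C=CC=CC=C")) {
    p <- annotate(smi, lib)
    for (pid in unique(p$occurrences$pattern_id)) {
      atoms <- p$occurrences$atoms[p$occurrences$pattern_id == pid]
      all_atoms <- unlist(atoms)
      expect_equal(length(all_atoms), length(unique(all_atoms)),
                   info = sprintf("pattern %s on %s", pid, smi))
    }
  }
})

test_that("annotation counts are invariant under SMILES rewriting", {
  lib <- lc_lib()
  pairs <- list(
    c("CCO", "OCC"),
    c("CCCC(=O)O", "OC(=O)CCC"),
    c("CC(O)CC", "CCC(C)O"),
    c("CCCCC1OC1C=CCC=CCC=CCCCCCC(=O)O",
      "OC(=O)CCCCCC=CCC=CCC=CC1OC1CCCC")
  )
  for (pr in pairs) {
    c1 <- annotate(pr[1], lib)$counts
    c2 <- annotate(pr[2], lib)$counts
    expect_identical(c1[sort(names(c1))], c2[sort(names(c2))],
                     info = paste(pr, collapse = " vs "))
  }
})

test_that("annotate is reproducible across calls", {
  lib <- lc_lib()
  p1 <- annotate(epoxy_trienoic_smiles(), lib)
  p2 <- annotate(epoxy_trienoic_smiles(), lib)
  expect_identical(p1$counts, p2$counts)
  expect_identical(p1$occurrences$atoms, p2$occurrences$atoms)
})
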