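one_atom_pdb <- function() {
  path <- withr::local_tempfile(fileext = ".pdb", .local_envir = parent.frame())
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00 80.00           N",
    "END"
  ), path)
  path
}

test_that("a single-atom PDB parses to one atom at the origin", {
  atoms <- read_complex(one_atom_pdb())
  expect_equal(nrow(atoms), 1L)
  expect_equal(unlist(atoms[1, c("x", "y", "z")]), c(x = 0, y = 0, z = 0))
  expect_equal(atoms$element, "N")
  expect_equal(atoms$residue, "A1")
  expect_false(atoms$is_hetatm)
})

test_that("toy-complex atom counts match the generator spec", {
  pl <- toy_placements(res_seq = c(248, 252), distance = c(3.0, 4.5),
                       direction = c(0, 0, 1))
  toy <- make_toy_complex(pl, n_res = 8)
  atoms <- read_complex(toy$path)
  # 8 scaffold residues x 5 heavy atoms + 2 ligand atoms
  expect_equal(nrow(atoms), 8 * 5 + 2)
  expect_equal(sum(atoms$is_hetatm), 2L)
})

test_that("parse-write-parse round trips preserve atoms and coordinates", {
  toy <- make_toy_complex(toy_placements(res_seq = 249, distance = 3.2),
                          seed = 7)
  a1 <- read_complex(toy$path)
  for (fmt in c("pdb", "cif")) {
    out <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_complex(a1, out, format = fmt)
    a2 <- read_complex(out, format = fmt)
    expect_equal(nrow(a2), nrow(a1))
    expect_equal(a2$x, a1$x, tolerance = 0, ignore_attr = TRUE)
    expect_true(max(abs(a2$x - a1$x), abs(a2$y - a1$y), abs(a2$z - a1$z)) <= 1e-3)
    expect_equal(a2$residue, a1$residue)
  }
})

test_that("mmCIF parsing honours author numbering and HETATM flags", {
  toy <- make_toy_complex(toy_placements(res_seq = 252, distance = 3.0))
  atoms <- read_complex(toy$path)
  cif <- withr::local_tempfile(fileext = ".cif")
  write_complex(atoms, cif)
  back <- read_complex(cif)
  expect_equal(back$seq_number, atoms$seq_number)
  expect_equal(sum(back$is_hetatm), 1L)
  expect_equal(back$residue[back$is_hetatm], "LIG1")
})

test_that("unreadable and empty structures error", {
  expect_error(read_complex("no/such/file.pdb"), "not found")
  empty <- withr::local_tempfile(fileext = ".pdb")
  writeLines("END", empty)
  expect_error(read_complex(empty))
})

test_that("altloc atoms collapse to the highest-occupancy conformer", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40 10.00           C",
    "ATOM      2  CA BALA A   1       1.000   0.000   0.000  0.60 10.00           C",
    "ATOM      3  N   ALA A   1       2.000   0.000   0.000  1.00 10.00           N",
    "END"
  ), path)
  atoms <- read_complex(path)
  expect_equal(nrow(atoms), 2L)
  expect_equal(atoms$x[atoms$atom_name == "CA"], 1.0)
})

test_that("hydrogens are parsed but flagged and excluded from contacts", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00 10.00           N",
    "ATOM      2  H   ALA A   1       0.500   0.500   0.000  1.00 10.00           H",
    "HETATM    3  O1  LIG L   2       3.000   0.000   0.000  1.00  0.00           O",
    "END"
  ), path)
  atoms <- read_complex(path)
  expect_equal(sum(atoms$is_hydrogen), 1L)
  parts <- split_receptor_ligand(atoms, "hetatm")
  contacts <- enumerate_contacts(parts$receptor, parts$ligand)
  # only the N-O1 pair counts; the H (2.55 A from O1) is ignored
  expect_equal(nrow(contacts), 1L)
  expect_equal(contacts$receptor_atom, "N")
})

test_that("selector grammar covers hetatm, chain, resname and conjunctions", {
  toy <- make_toy_complex(toy_placements(res_seq = c(247, 250), distance = c(3, 5)))
  atoms <- read_complex(toy$path)
  by_het <- split_receptor_ligand(atoms, "hetatm")
  expect_equal(nrow(by_het$ligand), 2L)
  expect_equal(nrow(by_het$receptor) + nrow(by_het$ligand), nrow(atoms))
  by_chain <- split_receptor_ligand(atoms, "chain L")
  expect_equal(by_chain$ligand$serial, by_het$ligand$serial)
  by_res <- split_receptor_ligand(atoms, "resname LIG")
  expect_equal(by_res$ligand$serial, by_het$ligand$serial)
  combo <- split_receptor_ligand(atoms, "chain L and resname LIG")
  expect_equal(nrow(combo$ligand), 2L)
  expect_error(split_receptor_ligand(atoms, "resname XYZ"), "no atoms")
  expect_error(split_receptor_ligand(atoms, "chain A or chain L"), "every atom")
  expect_error(split_receptor_ligand(atoms, "gibberish here"), "selector")
})

test_that("peptide-ligand chains select as whole ligands", {
  # an 11-residue peptide ligand on its own chain (LFcinB11-style)
  toy <- make_toy_complex(toy_placements(res_seq = 252, distance = 3.0))
  atoms <- toy$atoms
  pep <- atoms[atoms$is_hetatm, ][rep(1, 11), ]
  pep$chain <- "B"
  pep$seq_number <- 1:11
  pep$res_name <- "ARG"
  pep$is_hetatm <- FALSE
  pep$x <- pep$x + seq(0, 30, length.out = 11)
  pep$serial <- max(atoms$serial) + 1:11
  pep$residue <- residue_label(pep$res_name, pep$seq_number)
  all_atoms <- dplyr::bind_rows(atoms[!atoms$is_hetatm, ], pep)
  parts <- split_receptor_ligand(all_atoms, "chain B")
  expect_equal(nrow(parts$ligand), 11L)
  expect_true(all(parts$receptor$chain == "A"))
})

test_that("pLDDT fractions and categories follow the confidence bands", {
  toy <- make_toy_complex(toy_placements(res_seq = 250, distance = 3),
                          n_res = 10, plddt = 95)
  conf <- plddt_confidence(read_complex(toy$path), c(246, 255))
  expect_equal(conf$fractions$fraction[conf$fractions$category == "very_high"], 1.0)

  half <- make_toy_complex(toy_placements(res_seq = 250, distance = 3),
                           n_res = 10, plddt = rep(c(40, 95), each = 5))
  conf2 <- plddt_confidence(read_complex(half$path), c(246, 255))
  fr <- setNames(conf2$fractions$fraction, conf2$fractions$category)
  expect_equal(unname(fr[c("very_low", "very_high")]), c(0.5, 0.5))

  mixed <- make_toy_complex(toy_placements(res_seq = 250, distance = 3),
                            n_res = 8, plddt = rep(c(48, 65, 85, 95), 2))
  conf3 <- plddt_confidence(read_complex(mixed$path), c(246, 253))
  counts <- table(conf3$residues$category)
  expect_equal(unname(counts[c("very_low", "low", "high", "very_high")]),
               array(c(2L, 2L, 2L, 2L)))
})

test_that("pLDDT fractions sum to one and missing ranges error", {
  toy <- make_toy_complex(toy_placements(res_seq = 250, distance = 3),
                          n_res = 6, plddt = c(10, 55, 72, 91, 90, 70))
  conf <- plddt_confidence(read_complex(toy$path), c(246, 251))
  expect_true(all(conf$fractions$fraction >= 0 & conf$fractions$fraction <= 1))
  expect_equal(sum(conf$fractions$fraction), 1, tolerance = 1e-12)
  # boundary values: 90 is high, 91 very high, 70 high, 55 low
  cats <- setNames(conf$residues$category, conf$residues$seq_number)
  expect_equal(unname(cats[c("249", "250", "251")]), c("very_high", "high", "high"))
  expect_error(plddt_confidence(read_complex(toy$path), c(246, 260)),
               "absent")
  expect_s3_class(tidy(conf), "tbl_df")
  expect_equal(nrow(glance(conf)), 1L)
})

test_that("B-factors above 100 trigger a pLDDT range warning", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00150.00           N",
    "END"
  ), path)
  expect_warning(read_complex(path), "pLDDT")
})
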