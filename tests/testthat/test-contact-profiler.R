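test_that("distance classification matches the published class of every transcribed distance", {
  scheme <- bin_scheme()
  for (lig in c("cmp", "lmwh", "lfcinb11")) {
    tab <- read_distance_fixture(lig)
    expect_equal(as.character(classify_distance(tab$distance_A, scheme)),
                 tab$reported_class, label = lig)
  }
})

test_that("classification edges behave as half-open upper-inclusive bins", {
  expect_equal(as.character(classify_distance(3.2)), "moderate_hbond")
  expect_equal(as.character(classify_distance(3.3)), "moderate_hbond")
  expect_equal(as.character(classify_distance(4.0)), "weak_hbond_vdw")
  expect_equal(as.character(classify_distance(2.4)), "moderate_hbond")
  expect_true(is.na(classify_distance(7.5)))
  expect_error(classify_distance(-1), "positive")
  expect_error(classify_distance(0), "positive")
})

test_that("every distance in (0, hi_max] gets exactly one class, monotone in d", {
  for (preset in c("default", "text", "table")) {
    scheme <- bin_preset(preset)
    d <- seq(scheme$lo + 1e-9, scheme$hydrophobic_max, length.out = 400)
    cls <- classify_distance(d, scheme)
    expect_true(!anyNA(cls), label = preset)
    # monotone: class index never decreases as d grows
    expect_true(all(diff(as.integer(cls)) >= 0), label = preset)
  }
  # outside the partition: below lo or above hi_max
  txt <- bin_preset("text")
  expect_true(is.na(classify_distance(2.4, txt)))
  expect_true(is.na(classify_distance(6.95, txt)))
})

test_that("invalid bin schemes are rejected", {
  expect_error(bin_scheme(4, 3.5, 7), "increasing")
  expect_error(bin_scheme(3.3, 4, 12), "10")
})

test_that("atom roles follow residue chemistry", {
  toy <- make_toy_complex(toy_placements(res_seq = 249, distance = 3.0),
                          n_res = 12)  # residues 256+ are alanine
  roles <- assign_atom_roles(toy$atoms)
  leu_n <- roles[roles$res_name == "LEU" & roles$atom_name == "N", ]
  expect_true(leu_n$donor)
  # ligand oxygen (phosphate-like): generic rule flags it an acceptor
  lig_o <- roles[roles$is_hetatm, ]
  expect_true(all(lig_o$acceptor))
  cb <- roles[roles$res_name == "ALA" & roles$atom_name == "CB", ][1, ]
  expect_true(cb$hydrophobic)
  expect_false(cb$donor)
  expect_false(cb$acceptor)
  bad <- toy$atoms
  bad$res_name[bad$seq_number == 247 & !bad$is_hetatm] <- "XXX"
  expect_warning(assign_atom_roles(bad), "XXX")
})

test_that("a single placed ligand atom yields exactly its designed contact", {
  toy <- make_toy_complex(toy_placements(res_seq = 248, distance = 3.0,
                                         direction = c(0, 0, 1)))
  parts <- split_receptor_ligand(read_complex(toy$path), "hetatm")
  contacts <- enumerate_contacts(parts$receptor, parts$ligand)
  expect_equal(nrow(contacts), 1L)
  expect_equal(contacts$residue, "K248")
  expect_equal(as.character(contacts$contact_class), "moderate_hbond")
  expect_equal(contacts$distance, 3.0, tolerance = 1e-6)
})

test_that("a ligand atom beyond the outer bound produces no contacts", {
  toy <- make_toy_complex(toy_placements(res_seq = 248, distance = 8.0,
                                         direction = c(0, 0, 1)))
  parts <- split_receptor_ligand(read_complex(toy$path), "hetatm")
  contacts <- enumerate_contacts(parts$receptor, parts$ligand)
  expect_equal(nrow(contacts), 0L)
  expect_error(enumerate_contacts(parts$receptor[0, ], parts$ligand), "heavy atoms")
})

test_that("cell-list enumeration equals the brute-force all-pairs oracle", {
  withr::local_seed(421)
  for (rep in 1:25) {
    pair <- random_structure_pair(n_rec = 200, n_lig = 20)
    fast <- enumerate_contacts(pair$receptor, pair$ligand)
    slow <- brute_force_contacts(pair$receptor, pair$ligand)
    expect_equal(nrow(fast), nrow(slow))
    expect_setequal(contact_key(fast), contact_key(slow))
    expect_equal(sort(fast$distance), sort(slow$distance), tolerance = 1e-9)
  }
})

test_that("reduction rules keep the documented pair multisets", {
  withr::local_seed(99)
  pair <- random_structure_pair(n_rec = 120, n_lig = 10)
  all_p <- enumerate_contacts(pair$receptor, pair$ligand, reduction = "all")
  closest <- enumerate_contacts(pair$receptor, pair$ligand, reduction = "closest")
  per_res <- enumerate_contacts(pair$receptor, pair$ligand,
                                reduction = "closest_per_residue")
  expect_true(nrow(per_res) <= nrow(closest))
  expect_true(nrow(closest) <= nrow(all_p))
  # closest: at most one contact per (residue, ligand atom)
  expect_false(anyDuplicated(paste(closest$residue, closest$ligand_atom)) > 0)
  # closest_per_residue: one contact per residue
  expect_false(anyDuplicated(per_res$residue) > 0)
})

test_that("the chemistry gate demotes distance-only moderate contacts", {
  # carbon-only receptor residue: no donor/acceptor pairing possible
  pair <- random_structure_pair(n_rec = 4, n_lig = 1)
  pair$receptor[, c("x", "y", "z")] <- matrix(c(0, 0, 0, 20, 0, 0, 40, 0, 0, 60, 0, 0),
                                              ncol = 3, byrow = TRUE)
  pair$ligand[, c("x", "y", "z")] <- matrix(c(3, 0, 0), ncol = 3)
  plain <- enumerate_contacts(pair$receptor, pair$ligand, bin_scheme())
  gated <- enumerate_contacts(pair$receptor, pair$ligand,
                              bin_scheme(chemistry_gate = TRUE))
  expect_equal(as.character(plain$contact_class), "moderate_hbond")
  expect_equal(as.character(gated$contact_class), "weak_hbond_vdw")
})

test_that("summaries count, average and locate the hotspot correctly", {
  cmp <- read_distance_fixture("cmp")
  s <- profile_from_distance_table(cmp, ligand_id = "CMP")
  expect_equal(s$total_sites, 17L)
  expect_equal(round(s$mean_distance, 2), 4.55)
  expect_equal(s$binding_range, c("N247", "Y255"))
  expect_equal(s$hotspot, "R252")
  g <- glance(s)
  expect_equal(g$n_moderate, 2L)
  expect_equal(g$n_weak, 4L)
  expect_equal(g$n_hydrophobic, 11L)
  # conservation: class counts sum to total sites, per residue and overall
  expect_equal(sum(tidy(s)$total), s$total_sites)
  expect_true(all(tidy(s)$total == tidy(s)$moderate_hbond +
                    tidy(s)$weak_hbond_vdw + tidy(s)$hydrophobic))
  expect_true(all(vapply(tidy(s)$distances, length, 1L) == tidy(s)$total))
  # mean equals independent summation
  expect_equal(s$mean_distance, sum(cmp$distance_A) / nrow(cmp))
})

test_that("summaries are invariant to contact order", {
  withr::local_seed(5)
  tab <- read_distance_fixture("lfcinb11")
  s1 <- profile_from_distance_table(tab, ligand_id = "x")
  s2 <- profile_from_distance_table(tab[sample(nrow(tab)), ], ligand_id = "x")
  expect_equal(glance(s1), glance(s2))
  expect_equal(tidy(s1)[, 1:6], tidy(s2)[, 1:6])
})

test_that("an empty contact set yields a flagged zero-site summary", {
  s <- summarize_contacts(classify_table(tibble::tibble(
    residue = character(0), distance_A = numeric(0)
  )), ligand_id = "none")
  expect_equal(s$total_sites, 0L)
  expect_true(s$empty)
  expect_true(is.na(s$binding_range[1]))
})

test_that("hotspot ties break to the lowest sequence number and are reported", {
  tab <- tibble::tibble(residue = c("N247", "N247", "Y255", "Y255"),
                        distance_A = c(3.0, 4.5, 3.1, 4.4))
  s <- profile_from_distance_table(tab)
  expect_equal(s$hotspot, "N247")
  expect_equal(s$hotspot_ties, c("N247", "Y255"))
})

test_that("distance tables with bad rows fail loudly", {
  expect_error(
    profile_from_distance_table(tibble::tibble(residue = "???", distance_A = 3)),
    "Unparsable"
  )
  expect_error(
    profile_from_distance_table(tibble::tibble(residue = "R252", distance_A = -3)),
    "row"
  )
})

test_that("contact CSV and JSON exports round numbers as documented", {
  s <- profile_from_distance_table(read_distance_fixture("cmp"), ligand_id = "CMP")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_contacts_csv(s$contacts, csv)
  back <- readr::read_csv(csv, show_col_types = FALSE)
  expect_equal(nrow(back), 17)
  expect_equal(back$distance_display, round(back$distance_A, 1))
  js <- jsonlite::fromJSON(docking_summary_json(s))
  expect_equal(js$total_sites, 17)
  expect_equal(js$mean_distance_display, 4.55)
  expect_equal(js$mean_distance, s$mean_distance, tolerance = 1e-12)
})
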