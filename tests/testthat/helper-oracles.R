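# Independent brute-force contact oracle: all receptor x ligand heavy-atom
# pairs by direct distance computation (no spatial index), reduced and
# classified with plain base R. Deliberately shares no code with
# enumerate_contacts().
brute_force_contacts <- function(receptor, ligand, scheme = bin_scheme(),
                                 reduction = "closest") {
  rec <- receptor[!receptor$is_hydrogen, ]
  lig <- ligand[!ligand$is_hydrogen, ]
  rows <- list()
  for (i in seq_len(nrow(rec))) {
    for (j in seq_len(nrow(lig))) {
      d <- sqrt((rec$x[i] - lig$x[j])^2 + (rec$y[i] - lig$y[j])^2 +
                (rec$z[i] - lig$z[j])^2)
      if (d <= scheme$hydrophobic_max) {
        rows[[length(rows) + 1L]] <- data.frame(
          rec_i = i, lig_j = j, d = d,
          res_key = paste(rec$chain[i], rec$seq_number[i], rec$ins_code[i]),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(residue = character(0), receptor_atom = character(0),
                      ligand_atom = character(0), distance = numeric(0),
                      contact_class = character(0)))
  }
  all <- do.call(rbind, rows)
  if (reduction == "closest") {
    keep <- unlist(lapply(split(seq_len(nrow(all)),
                                paste(all$res_key, all$lig_j)), function(k) {
      k[which.min(all$d[k])]
    }))
    all <- all[sort(keep), ]
  }
  cls <- as.character(classify_distance(all$d, scheme))
  out <- data.frame(
    residue = rec$residue[all$rec_i],
    seq_number = rec$seq_number[all$rec_i],
    receptor_atom = rec$atom_name[all$rec_i],
    ligand_atom = lig$atom_name[all$lig_j],
    distance = all$d,
    contact_class = cls,
    stringsAsFactors = FALSE
  )
  out <- out[!is.na(out$contact_class), ]
  out[order(out$seq_number, out$distance, out$ligand_atom), ]
}

# random atom tables in a cubic box: clustered residues so that contacts at
# all three classes actually occur
random_structure_pair <- function(n_rec = 200, n_lig = 20, box = 25) {
  n_res <- ceiling(n_rec / 4)
  centers <- matrix(stats::runif(3 * n_res, 0, box), ncol = 3)
  idx <- rep(seq_len(n_res), length.out = n_rec)
  coords <- centers[idx, , drop = FALSE] + matrix(stats::rnorm(3 * n_rec, 0, 1.5), ncol = 3)
  rec <- tibble::tibble(
    serial = seq_len(n_rec),
    atom_name = paste0("C", seq_len(n_rec)),
    element = "C",
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    chain = "A", seq_number = idx, ins_code = NA_character_,
    res_name = "ALA",
    residue = paste0("A", idx),
    b_factor = 90, is_hetatm = FALSE, is_hydrogen = FALSE
  )
  lcoords <- matrix(stats::runif(3 * n_lig, 0, box), ncol = 3)
  lig <- tibble::tibble(
    serial = n_rec + seq_len(n_lig),
    atom_name = paste0("O", seq_len(n_lig)),
    element = "O",
    x = lcoords[, 1], y = lcoords[, 2], z = lcoords[, 3],
    chain = "L", seq_number = 1L, ins_code = NA_character_,
    res_name = "LIG", residue = "LIG1",
    b_factor = 0, is_hetatm = TRUE, is_hydrogen = FALSE
  )
  list(receptor = rec, ligand = lig)
}

contact_key <- function(df) {
  paste(df$residue, df$ligand_atom, round(df$distance, 9))
}
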