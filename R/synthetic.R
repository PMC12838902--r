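# N-terminal PSTD residue identities (ST8Sia4 author numbering); positions
# without a published identity fall back to alanine in toy fixtures
.PSTD_NTERM <- c(
  "246" = "LYS", "247" = "ASN", "248" = "LYS", "249" = "LEU", "250" = "LYS",
  "251" = "VAL", "252" = "ARG", "253" = "THR", "254" = "ALA", "255" = "TYR"
)

pstd_res_name <- function(seq_number) {
  out <- .PSTD_NTERM[as.character(seq_number)]
  ifelse(is.na(out), "ALA", out)
}

#' Build a ligand placement table for toy complexes
#'
#' Convenience constructor for the placement spec consumed by
#' [make_toy_complex()]: each row places one ligand heavy atom at a
#' prescribed distance from a named receptor atom along a direction.
#'
#' @param res_seq integer vector of target residue numbers.
#' @param distance prescribed distances in Å, each in (2, 10).
#' @param atom receptor atom name targeted (recycled), default `"N"`.
#' @param element ligand atom element (recycled), default `"O"`.
#' @param direction either `NULL` (unit vectors drawn at random, see the
#'   `seed` of [make_toy_complex()]), a single 3-vector used for all rows,
#'   or a list of unit 3-vectors.
#' @return A placements tibble.
#' @export
toy_placements <- function(res_seq, distance, atom = "N", element = "O",
                           direction = NULL) {
  n <- max(length(res_seq), length(distance))
  dir_col <- if (is.null(direction)) {
    rep(list(NULL), n)
  } else if (is.numeric(direction) && length(direction) == 3L) {
    rep(list(direction), n)
  } else {
    direction
  }
  tibble(
    res_seq = as.integer(rep_len(res_seq, n)),
    atom = rep_len(atom, n),
    distance = rep_len(distance, n),
    element = rep_len(element, n),
    direction = dir_col
  )
}

# idealised residue geometry: local offsets of the five heavy atoms from a
# residue origin; residues are strung along x. All offsets keep z <= 0 so
# that ligand atoms placed along +z stay closest to their own residue.
.RES_OFFSETS <- matrix(
  c(-0.5, 1.2, 0,    # N
     0.0, 0.0, 0,    # CA
     1.3, 0.6, 0,    # C
     1.5, 1.8, 0,    # O
    -0.4, -1.0, -1.0),  # CB
  ncol = 3, byrow = TRUE,
  dimnames = list(c("N", "CA", "C", "O", "CB"), c("x", "y", "z"))
)

#' Generate a toy protein-ligand complex with known contact geometry
#'
#' Builds a minimal extended scaffold of idealised residues (five heavy
#' atoms each, strung along the x axis) and places ligand heavy atoms at
#' prescribed distances from named receptor atoms. Coordinates are snapped
#' to the 0.001 Å PDB grid at generation time, so the realised distance to
#' each target atom equals the prescribed distance to within the grid
#' resolution (about 1e-3 Å) and the written file reproduces the truth
#' table's geometry exactly.
#' The returned ground truth is computed by an exhaustive nearest-atom scan
#' over all receptor heavy atoms (independently of the package's cell-list
#' contact search), listing each ligand atom's nearest residue, atom,
#' distance and expected contact class under `scheme`.
#'
#' Toy receptors aim at controlled geometry, not stereochemical realism:
#' residue spacing is wide enough that only deliberately placed contacts
#' fall within a typical classification scheme's outer bound.
#'
#' @param placements tibble from [toy_placements()].
#' @param n_res number of scaffold residues; default covers the targeted
#'   residues plus one flanking residue each side.
#' @param first_seq sequence number of the first scaffold residue
#'   (default 246, the PSTD numbering; residues 246-255 take their PSTD
#'   identities, others alanine).
#' @param spacing inter-residue spacing in Å (default 10, wide enough that
#'   a ligand atom placed above one residue is out of range of its
#'   neighbours under the default scheme).
#' @param plddt per-residue B-factor values (recycled), default 95.
#' @param scheme [bin_scheme()] used for the expected classes in the truth
#'   table.
#' @param path output PDB path (default a tempfile).
#' @param seed integer seed for random placement directions; identical
#'   specs and seeds produce byte-identical files.
#' @return List with `path` (written PDB), `atoms` (the atom tibble),
#'   `truth` (ground-truth contact table: `ligand_atom`, `residue`,
#'   `seq_number`, `target_atom`, `nearest_atom`, `prescribed_distance`,
#'   `distance`, `contact_class`).
#' @examples
#' toy <- make_toy_complex(toy_placements(res_seq = 248, distance = 3.0))
#' toy$truth
#' @export
make_toy_complex <- function(placements, n_res = NULL, first_seq = 246L,
                             spacing = 10, plddt = 95, scheme = bin_scheme(),
                             path = tempfile(fileext = ".pdb"), seed = NULL) {
  stopifnot(nrow(placements) >= 1L)
  if (any(placements$distance <= 2 | placements$distance >= 10)) {
    abort("Prescribed placement distances must lie in (2, 10) Angstrom")
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
  }
  if (is.null(n_res)) {
    n_res <- max(placements$res_seq) - first_seq + 2L
  }
  seqs <- seq(first_seq, first_seq + n_res - 1L)
  if (!all(placements$res_seq %in% seqs)) {
    abort("Placement targets fall outside the scaffold residue range")
  }

  res_names <- pstd_res_name(seqs)
  atom_rows <- purrr::map2_dfr(seqs, res_names, function(s, rn) {
    off <- .RES_OFFSETS
    if (rn == "GLY") off <- off[rownames(off) != "CB", , drop = FALSE]
    tibble(
      atom_name = rownames(off),
      element = substr(rownames(off), 1, 1),
      x = off[, "x"] + (s - first_seq) * spacing,
      y = off[, "y"], z = off[, "z"],
      chain = "A", seq_number = s, ins_code = NA_character_, res_name = rn,
      is_hetatm = FALSE
    )
  })
  plddt_res <- rep_len(plddt, n_res)
  atom_rows$b_factor <- plddt_res[match(atom_rows$seq_number, seqs)]

  # place ligand atoms
  lig_rows <- purrr::pmap_dfr(
    list(seq_len(nrow(placements)), placements$res_seq, placements$atom,
         placements$distance, placements$element, placements$direction),
    function(i, rs, at, d, el, dir) {
      tgt <- atom_rows[atom_rows$seq_number == rs & atom_rows$atom_name == at, ]
      if (nrow(tgt) != 1L) {
        abort(sprintf("Placement %d: no atom '%s' in residue %d", i, at, rs))
      }
      if (is.null(dir)) {
        # random direction in a narrow cone around +z, away from the
        # scaffold, so the targeted residue is the only one in range
        dir <- c(0.15 * stats::runif(2, -1, 1), 1)
      }
      dir <- dir / sqrt(sum(dir^2))
      tibble(
        atom_name = paste0(toupper(el), i),
        element = toupper(el),
        x = tgt$x + d * dir[1], y = tgt$y + d * dir[2], z = tgt$z + d * dir[3],
        chain = "L", seq_number = 1L, ins_code = NA_character_,
        res_name = "LIG", is_hetatm = TRUE, b_factor = 0
      )
    }
  )

  atoms <- dplyr::bind_rows(atom_rows, lig_rows)
  # snap to the 0.001 A PDB coordinate grid at generation time, so the
  # written file, the collision check and the ground truth all describe the
  # same geometry exactly
  atoms$x <- round(atoms$x, 3)
  atoms$y <- round(atoms$y, 3)
  atoms$z <- round(atoms$z, 3)
  atoms$serial <- seq_len(nrow(atoms))
  atoms$residue <- residue_label(atoms$res_name, atoms$seq_number, atoms$ins_code)
  atoms$is_hydrogen <- FALSE
  atoms <- as_tibble(atoms[, c("serial", "atom_name", "element", "x", "y", "z",
                               "chain", "seq_number", "ins_code", "res_name",
                               "residue", "b_factor", "is_hetatm", "is_hydrogen")])

  # collision check: a placed atom closer than 2 A to anything but its target
  rec <- atoms[!atoms$is_hetatm, ]
  lig <- atoms[atoms$is_hetatm, ]
  for (i in seq_len(nrow(lig))) {
    tgt <- placements[i, ]
    others_rec <- !(rec$seq_number == tgt$res_seq & rec$atom_name == tgt$atom)
    d_rec <- sqrt((rec$x - lig$x[i])^2 + (rec$y - lig$y[i])^2 + (rec$z - lig$z[i])^2)
    d_lig <- sqrt((lig$x - lig$x[i])^2 + (lig$y - lig$y[i])^2 + (lig$z - lig$z[i])^2)
    if (any(d_rec[others_rec] < 2) || any(d_lig[-i] < 2)) {
      abort(sprintf("Placement %d collides (< 2 A) with a non-target atom", i))
    }
  }

  # ground truth by exhaustive nearest-atom scan (independent of the
  # cell-list search used by enumerate_contacts)
  truth <- purrr::map_dfr(seq_len(nrow(lig)), function(i) {
    d <- sqrt((rec$x - lig$x[i])^2 + (rec$y - lig$y[i])^2 + (rec$z - lig$z[i])^2)
    j <- which.min(d)
    tibble(
      ligand_atom = lig$atom_name[i],
      residue = rec$residue[j],
      seq_number = rec$seq_number[j],
      target_atom = placements$atom[i],
      nearest_atom = rec$atom_name[j],
      prescribed_distance = placements$distance[i],
      distance = unname(d[j])
    )
  })
  truth$contact_class <- classify_distance_safe(truth$distance, scheme)

  write_complex(atoms, path, format = "pdb")
  list(path = path, atoms = atoms, truth = truth)
}

#' Generate a synthetic CSP titration fixture
#'
#' Emulates the canonical shape of a binding-site CSP curve: a flat
#' background, a contiguous plateau of strongly perturbed residues, and a
#' single peak residue inside the plateau (the N247-Y255 / R252 pattern of
#' the PSTD systems). Residues 246-255 carry their PSTD identities; other
#' scaffold positions are alanine.
#'
#' Free amide shifts are deterministic plausible values (1H near 8 ppm,
#' 15N near 115 ppm); bound shifts are displaced so that the combined CSP
#' ([combined_csp()]) reproduces the prescribed per-residue value exactly:
#' the prescribed CSP `c` is split as \eqn{\Delta\delta_H = 0.6 c} and
#' \eqn{\Delta\delta_N = 0.8 \alpha c} (a 3-4-5 split). Optional noise is
#' truncated Gaussian (clipped at ±2 sd) added to the prescribed CSP; the
#' admissibility bound `noise_sd < (peak - plateau) / 4` is enforced, which
#' together with the clipping guarantees the peak residue is always
#' recovered.
#'
#' @param residues integer vector of residue numbers, default `246:277`
#'   (the PSTD span).
#' @param peak_residue peak residue number, default 252.
#' @param peak_value peak combined CSP in ppm, default 0.151.
#' @param plateau inclusive residue-number interval of the elevated region,
#'   default `c(247, 255)`.
#' @param plateau_level plateau height as a fraction of the peak, default
#'   0.6 (comfortably above the 0.5 significance threshold).
#' @param background_level background height as a fraction of the peak,
#'   default 0.1.
#' @param noise_sd sd of the truncated Gaussian CSP noise (ppm), default 0.
#' @param alpha nitrogen scaling divisor used in the split, default 5.
#' @param seed integer seed for the noise.
#' @return List with tibbles `free` and `bound` (columns `residue`,
#'   `delta_H_ppm`, `delta_N_ppm`), `csp` (`residue`, `csp_ppm` — the
#'   realised values), and the generating parameters in `params`.
#' @examples
#' fx <- make_csp_fixture(noise_sd = 0)
#' csp_profile(fx$free, fx$bound)$peak_value
#' @export
make_csp_fixture <- function(residues = 246:277, peak_residue = 252L,
                             peak_value = 0.151, plateau = c(247, 255),
                             plateau_level = 0.6, background_level = 0.1,
                             noise_sd = 0, alpha = 5, seed = NULL) {
  if (!(peak_residue %in% residues)) abort("peak_residue must be among residues")
  if (!(peak_residue >= plateau[1] && peak_residue <= plateau[2])) {
    abort("peak_residue must lie inside the plateau interval")
  }
  plateau_ppm <- plateau_level * peak_value
  background_ppm <- background_level * peak_value
  if (!(peak_value > plateau_ppm && plateau_ppm > background_ppm && background_ppm >= 0)) {
    abort("Need peak > plateau level > background level >= 0")
  }
  if (noise_sd < 0) abort("noise_sd must be non-negative")
  if (noise_sd > 0 && noise_sd >= (peak_value - plateau_ppm) / 4) {
    abort("noise_sd too large: must be below (peak - plateau) / 4 to keep the peak identifiable")
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
  }

  residues <- sort(unique(as.integer(residues)))
  labels <- residue_label(pstd_res_name(residues), residues)
  csp <- ifelse(residues >= plateau[1] & residues <= plateau[2],
                plateau_ppm, background_ppm)
  csp[residues == peak_residue] <- peak_value
  if (noise_sd > 0) {
    eps <- pmin(pmax(stats::rnorm(length(csp), 0, noise_sd), -2 * noise_sd),
                2 * noise_sd)
    csp <- pmax(csp + eps, 0)
  }

  i <- seq_along(residues)
  free <- tibble(
    residue = labels,
    delta_H_ppm = 8.2 + 0.013 * (i %% 7),
    delta_N_ppm = 112 + 0.83 * (i %% 11)
  )
  bound <- tibble(
    residue = labels,
    delta_H_ppm = free$delta_H_ppm + 0.6 * csp,
    delta_N_ppm = free$delta_N_ppm + 0.8 * alpha * csp
  )
  list(
    free = free,
    bound = bound,
    csp = tibble(residue = labels, csp_ppm = csp),
    params = list(
      residues = residues, peak_residue = peak_residue, peak_value = peak_value,
      plateau = plateau, plateau_level = plateau_level,
      background_level = background_level, noise_sd = noise_sd,
      alpha = alpha, seed = seed
    )
  )
}
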