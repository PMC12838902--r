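# Side-chain donor/acceptor atoms of the standard amino acids.
# Backbone N is always a donor and backbone O always an acceptor; histidine
# ring nitrogens are treated as both (protonation unknown in a single pose).
.SIDECHAIN_DONORS <- list(
  ARG = c("NE", "NH1", "NH2"), ASN = "ND2", GLN = "NE2",
  HIS = c("ND1", "NE2"), LYS = "NZ", SER = "OG", THR = "OG1",
  TRP = "NE1", TYR = "OH", CYS = "SG"
)
.SIDECHAIN_ACCEPTORS <- list(
  ASN = "OD1", ASP = c("OD1", "OD2"), GLN = "OE1", GLU = c("OE1", "OE2"),
  HIS = c("ND1", "NE2"), SER = "OG", THR = "OG1", TYR = "OH", MET = "SD"
)

#' Assign hydrogen-bond and hydrophobic roles to atoms
#'
#' Flags each heavy atom as hydrogen-bond donor, acceptor and/or
#' hydrophobic, from a packaged residue-chemistry table covering the
#' standard amino acids (backbone N-H donor, backbone carbonyl O acceptor,
#' side-chain atoms per residue) plus a generic rule for ligands and
#' unknown residues: nitrogen and oxygen are flagged both donor and
#' acceptor (an element-based over-approximation, since without explicit
#' hydrogens protonation cannot be resolved), and aliphatic/aromatic
#' carbons and sulfurs are hydrophobic. Unknown protein residues fall back
#' to the same element rules with a warning.
#'
#' @param atoms atom tibble from [read_complex()].
#' @return The input with logical columns `donor`, `acceptor`,
#'   `hydrophobic` appended.
#' @examples
#' toy <- make_toy_complex(toy_placements(res_seq = 2, distance = 3.0))
#' roles <- assign_atom_roles(read_complex(toy$path))
#' roles[roles$atom_name == "N", c("residue", "donor", "acceptor")]
#' @export
assign_atom_roles <- function(atoms) {
  res <- toupper(atoms$res_name)
  el <- toupper(atoms$element)
  nm <- toupper(atoms$atom_name)
  standard <- res %in% names(.AA1)
  unknown_protein <- !standard & !atoms$is_hetatm & !atoms$is_hydrogen
  if (any(unknown_protein)) {
    warn(paste0(
      "Unknown protein residue(s) ",
      paste(unique(res[unknown_protein]), collapse = ", "),
      "; falling back to element-based donor/acceptor rules"
    ))
  }

  donor <- acceptor <- rep(FALSE, nrow(atoms))

  # standard amino acids: backbone + residue-specific side chains
  donor[standard & nm == "N"] <- TRUE
  acceptor[standard & nm %in% c("O", "OXT")] <- TRUE
  for (r in names(.SIDECHAIN_DONORS)) {
    donor[standard & res == r & nm %in% .SIDECHAIN_DONORS[[r]]] <- TRUE
  }
  for (r in names(.SIDECHAIN_ACCEPTORS)) {
    acceptor[standard & res == r & nm %in% .SIDECHAIN_ACCEPTORS[[r]]] <- TRUE
  }

  # ligand / unknown-residue rule: N and O over-approximated as both roles
  generic <- !standard
  donor[generic & el %in% c("N", "O")] <- TRUE
  acceptor[generic & el %in% c("N", "O")] <- TRUE

  hydrophobic <- el %in% c("C", "S")
  # polar sulfurs already assigned a role stay polar-capable but sulfur
  # surface is still counted hydrophobic (aliphatic/aromatic C and S rule)

  atoms$donor <- donor & !atoms$is_hydrogen
  atoms$acceptor <- acceptor & !atoms$is_hydrogen
  atoms$hydrophobic <- hydrophobic & !atoms$is_hydrogen
  atoms
}
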