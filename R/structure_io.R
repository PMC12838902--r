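#' Read a protein-ligand complex from PDB or mmCIF
#'
#' Parses a structure file into a flat atom table. Heavy atoms and hydrogens
#' are both retained; hydrogens are flagged (`is_hydrogen`) and excluded from
#' all downstream distance work. For atoms with alternate locations only the
#' highest-occupancy conformer is kept (ties resolved to the first
#' encountered), so every atom appears once. The B-factor column is kept
#' verbatim: for AlphaFold-style models it carries the per-residue pLDDT
#' confidence (a warning is emitted when values exceed 100, since genuine
#' pLDDT lives on 0-100).
#'
#' @param path path to a `.pdb` or `.cif`/`.mmcif` file.
#' @param format `"auto"` (default, by extension), `"pdb"` or `"cif"`.
#'   mmCIF author (`auth_`) numbering is used so residue labels match
#'   published residue names such as N247.
#' @return A tibble with one row per atom and columns `serial`, `atom_name`,
#'   `element`, `x`, `y`, `z`, `chain`, `seq_number`, `ins_code`, `res_name`,
#'   `residue` (compact label), `b_factor`, `is_hetatm`, `is_hydrogen`.
#'   The source format is recorded in attribute `source_format`.
#' @seealso [write_complex()], [split_receptor_ligand()]
#' @examples
#' toy <- make_toy_complex(toy_placements(res_seq = 2, distance = 3.0))
#' atoms <- read_complex(toy$path)
#' nrow(atoms)
#' @export
read_complex <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("Structure file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  atoms <- if (format == "pdb") read_pdb_atoms(path) else read_cif_atoms(path)
  if (nrow(atoms) == 0L) abort(paste0("No atoms parsed from ", path))
  atoms <- drop_altloc(atoms)
  atoms$residue <- residue_label(atoms$res_name, atoms$seq_number, atoms$ins_code)
  atoms$is_hydrogen <- atoms$element %in% c("H", "D")
  if (any(atoms$b_factor > 100, na.rm = TRUE)) {
    warn("B-factor values exceed 100; they cannot be pLDDT confidences")
  }
  atoms <- atoms[order_residues(atoms), , drop = FALSE]
  out <- as_tibble(atoms[setdiff(names(atoms), c("alt", "occupancy"))])
  attr(out, "source_format") <- format
  out
}

read_pdb_atoms <- function(path) {
  p <- tryCatch(
    bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE),
    error = function(e) abort(paste0("Failed to parse PDB file ", path, ": ", conditionMessage(e)))
  )
  a <- p$atom
  el <- a$elesy
  miss <- is.na(el) | !nzchar(trimws(el))
  el[miss] <- guess_element(a$elety[miss])
  tibble(
    serial = as.integer(a$eleno),
    atom_name = trimws(a$elety),
    element = toupper(trimws(el)),
    x = a$x, y = a$y, z = a$z,
    chain = ifelse(is.na(a$chain), "", a$chain),
    seq_number = as.integer(a$resno),
    ins_code = ifelse(is.na(a$insert) | !nzchar(a$insert), NA_character_, a$insert),
    res_name = trimws(a$resid),
    b_factor = as.numeric(a$b),
    is_hetatm = a$type == "HETATM",
    alt = ifelse(is.na(a$alt), "", a$alt),
    occupancy = ifelse(is.na(a$o), 1, as.numeric(a$o))
  )
}

# Minimal mmCIF atom_site reader: whitespace-delimited loop_ table with the
# standard atom_site tags; auth_* fields are preferred so numbering matches
# author residue labels.
read_cif_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr_idx <- grep("^_atom_site\\.", lines)
  if (length(hdr_idx) == 0L) abort(paste0("No _atom_site loop in ", path))
  tags <- sub("^_atom_site\\.", "", trimws(lines[hdr_idx]))
  body_start <- max(hdr_idx) + 1L
  body <- character(0)
  for (i in seq(body_start, length(lines))) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (grepl("^(#|loop_|_|data_)", ln)) break
    body <- c(body, ln)
  }
  if (length(body) == 0L) abort(paste0("Empty _atom_site loop in ", path))
  fields <- strsplit(body, "\\s+")
  nf <- lengths(fields)
  if (any(nf != length(tags))) {
    abort(sprintf(
      "mmCIF atom_site row %d has %d fields, expected %d (%s)",
      which(nf != length(tags))[1], nf[nf != length(tags)][1], length(tags), path
    ))
  }
  m <- do.call(rbind, fields)
  colnames(m) <- tags
  col <- function(primary, fallback = NULL, default = NA_character_) {
    if (primary %in% tags) return(m[, primary])
    if (!is.null(fallback) && fallback %in% tags) return(m[, fallback])
    rep(default, nrow(m))
  }
  unq <- function(v) ifelse(v %in% c(".", "?"), NA_character_, v)
  tibble(
    serial = as.integer(col("id")),
    atom_name = gsub('"', "", unq(col("auth_atom_id", "label_atom_id"))),
    element = toupper(unq(col("type_symbol"))),
    x = as.numeric(col("Cartn_x")),
    y = as.numeric(col("Cartn_y")),
    z = as.numeric(col("Cartn_z")),
    chain = ifelse(is.na(unq(col("auth_asym_id", "label_asym_id"))), "",
                   unq(col("auth_asym_id", "label_asym_id"))),
    seq_number = as.integer(unq(col("auth_seq_id", "label_seq_id"))),
    ins_code = unq(col("pdbx_PDB_ins_code")),
    res_name = unq(col("auth_comp_id", "label_comp_id")),
    b_factor = as.numeric(ifelse(is.na(unq(col("B_iso_or_equiv"))), "0",
                                 unq(col("B_iso_or_equiv")))),
    is_hetatm = col("group_PDB", default = "ATOM") == "HETATM",
    alt = ifelse(is.na(unq(col("label_alt_id"))), "", unq(col("label_alt_id"))),
    occupancy = as.numeric(ifelse(is.na(unq(col("occupancy"))), "1", unq(col("occupancy"))))
  )
}

guess_element <- function(atom_name) {
  nm <- gsub("[^A-Za-z]", "", trimws(atom_name))
  two <- toupper(substr(nm, 1, 2))
  one <- toupper(substr(nm, 1, 1))
  ifelse(two %in% c("CL", "BR", "FE", "ZN", "MG", "MN", "NA", "SE"), two, one)
}

# keep the highest-occupancy altloc per (chain, seq, ins, atom name);
# ties go to the first conformer encountered
drop_altloc <- function(atoms) {
  if (all(atoms$alt == "")) return(atoms)
  key <- paste(atoms$chain, atoms$seq_number, atoms$ins_code, atoms$res_name,
               atoms$atom_name, sep = "\r")
  keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(i) {
    i[which.max(atoms$occupancy[i])]
  }), use.names = FALSE)
  atoms[sort(keep), , drop = FALSE]
}

order_residues <- function(atoms) {
  order(atoms$is_hetatm, atoms$chain, atoms$seq_number,
        ifelse(is.na(atoms$ins_code), "", atoms$ins_code), atoms$serial)
}

#' Write an atom table back to PDB or mmCIF
#'
#' Coordinates are written at standard PDB precision (0.001 Å), so a
#' parse-write-parse round trip preserves the atom count exactly and the
#' coordinates to within 1e-3 Å.
#'
#' @param atoms atom tibble as returned by [read_complex()].
#' @param path output path; format from extension unless `format` given.
#' @param format `"auto"`, `"pdb"` or `"cif"`.
#' @return `path`, invisibly.
#' @export
write_complex <- function(atoms, path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  if (format == "pdb") {
    bio3d::write.pdb(
      file = path,
      xyz = as.numeric(t(as.matrix(atoms[, c("x", "y", "z")]))),
      type = ifelse(atoms$is_hetatm, "HETATM", "ATOM"),
      eleno = atoms$serial,
      elety = atoms$atom_name,
      resid = atoms$res_name,
      chain = atoms$chain,
      resno = atoms$seq_number,
      insert = ifelse(is.na(atoms$ins_code), "", atoms$ins_code),
      b = atoms$b_factor,
      elesy = atoms$element
    )
  } else {
    hdr <- c(
      "data_dockcsp", "#", "loop_",
      paste0("_atom_site.", c(
        "group_PDB", "id", "type_symbol", "auth_atom_id", "auth_comp_id",
        "auth_asym_id", "auth_seq_id", "pdbx_PDB_ins_code",
        "Cartn_x", "Cartn_y", "Cartn_z", "occupancy", "B_iso_or_equiv"
      ))
    )
    rows <- sprintf(
      "%-6s %d %s %s %s %s %d %s %.3f %.3f %.3f %.2f %.2f",
      ifelse(atoms$is_hetatm, "HETATM", "ATOM"), atoms$serial, atoms$element,
      atoms$atom_name, atoms$res_name,
      ifelse(nzchar(atoms$chain), atoms$chain, "."), atoms$seq_number,
      ifelse(is.na(atoms$ins_code), "?", atoms$ins_code),
      atoms$x, atoms$y, atoms$z, 1, atoms$b_factor
    )
    writeLines(c(hdr, rows, "#"), path)
  }
  invisible(path)
}

#' Split a complex into receptor and ligand atom sets
#'
#' The selector is a small expression language naming the ligand:
#' * `"hetatm"` — all HETATM-record atoms;
#' * `"chain B"` — all atoms of a chain (peptide ligands such as LFcinB11
#'   are usually a separate chain);
#' * `"resname CMP"` — all atoms of a residue name;
#' * clauses combined with `and` / `or`, e.g. `"chain B and resname CMP"`.
#'
#' The split is exhaustive and disjoint: every atom lands in exactly one of
#' the two sets.
#'
#' @param atoms atom tibble from [read_complex()].
#' @param ligand_selector selector string (see Details).
#' @return A list with tibbles `receptor` and `ligand`.
#' @examples
#' toy <- make_toy_complex(toy_placements(res_seq = 2, distance = 3.0))
#' parts <- split_receptor_ligand(read_complex(toy$path), "hetatm")
#' nrow(parts$ligand)
#' @export
split_receptor_ligand <- function(atoms, ligand_selector) {
  sel <- eval_selector(atoms, ligand_selector)
  if (!any(sel)) abort(paste0("Ligand selector '", ligand_selector, "' matches no atoms"))
  if (all(sel)) abort(paste0("Ligand selector '", ligand_selector, "' matches every atom; no receptor left"))
  list(receptor = atoms[!sel, , drop = FALSE], ligand = atoms[sel, , drop = FALSE])
}

eval_selector <- function(atoms, expr) {
  expr <- trimws(expr)
  for (conj in c(" or ", " and ")) {
    if (grepl(conj, expr, fixed = TRUE)) {
      parts <- strsplit(expr, conj, fixed = TRUE)[[1]]
      masks <- lapply(parts, eval_selector, atoms = atoms)
      return(Reduce(if (conj == " or ") `|` else `&`, masks))
    }
  }
  toks <- strsplit(expr, "\\s+")[[1]]
  kw <- tolower(toks[1])
  if (kw == "hetatm" && length(toks) == 1L) return(atoms$is_hetatm)
  if (kw == "chain" && length(toks) == 2L) return(atoms$chain == toks[2])
  if (kw == "resname" && length(toks) == 2L) return(atoms$res_name == toupper(toks[2]))
  abort(paste0(
    "Cannot parse selector clause '", expr,
    "'; expected 'hetatm', 'chain <id>' or 'resname <name>'"
  ))
}

#' Per-residue pLDDT confidence over a residue range
#'
#' AlphaFold stores its per-residue confidence (pLDDT, 0-100) in the
#' B-factor column. This summarises a residue range into the four standard
#' confidence categories: very low (pLDDT < 50), low (50-70), high (70-90)
#' and very high (pLDDT > 90). Per-residue pLDDT is the mean of the
#' residue's atom B-factors.
#'
#' @param atoms atom tibble from [read_complex()].
#' @param residue_range inclusive range: `"N247-Y255"`, `c(247, 255)`, or
#'   `NULL` for all receptor residues.
#' @param thresholds increasing category boundaries, default `c(50, 70, 90)`.
#' @return An object of class `plddt_confidence`: list with `residues`
#'   (per-residue tibble: `chain`, `seq_number`, `res_name`, `residue`,
#'   `plddt`, `category`) and `fractions` (per-category residue fractions,
#'   summing to 1). [tidy()][generics::tidy] returns the per-residue table,
#'   [glance()][generics::glance] a one-row fraction summary.
#' @examples
#' toy <- make_toy_complex(toy_placements(res_seq = 2, distance = 3.0),
#'                         plddt = c(95, 95, 95))
#' conf <- plddt_confidence(read_complex(toy$path), c(1, 3))
#' conf$fractions
#' @export
plddt_confidence <- function(atoms, residue_range = NULL, thresholds = c(50, 70, 90)) {
  stopifnot(length(thresholds) == 3L, !is.unsorted(thresholds))
  prot <- atoms[!atoms$is_hetatm, , drop = FALSE]
  per_res <- prot |>
    dplyr::group_by(.data$chain, .data$seq_number, .data$res_name, .data$residue) |>
    dplyr::summarise(plddt = mean(.data$b_factor), .groups = "drop") |>
    dplyr::arrange(.data$chain, .data$seq_number)
  if (!is.null(residue_range)) {
    want <- range_to_seq(residue_range)
    missing <- setdiff(want, per_res$seq_number)
    if (length(missing) > 0L) {
      abort(paste0(
        "Residue range covers residues absent from the structure: ",
        paste(missing, collapse = ", ")
      ))
    }
    per_res <- per_res[per_res$seq_number %in% want, , drop = FALSE]
  }
  per_res$category <- plddt_category(per_res$plddt, thresholds)
  lv <- c("very_low", "low", "high", "very_high")
  fr <- as.numeric(table(factor(per_res$category, levels = lv))) / nrow(per_res)
  out <- list(
    residues = per_res,
    fractions = tibble(category = lv, fraction = fr),
    thresholds = thresholds
  )
  class(out) <- "plddt_confidence"
  out
}

plddt_category <- function(p, thresholds = c(50, 70, 90)) {
  dplyr::case_when(
    p < thresholds[1] ~ "very_low",
    p < thresholds[2] ~ "low",
    p <= thresholds[3] ~ "high",
    TRUE ~ "very_high"
  )
}

#' @export
print.plddt_confidence <- function(x, ...) {
  cat("pLDDT confidence over", nrow(x$residues), "residues\n")
  fr <- x$fractions
  cat(paste(sprintf("  %-9s %5.1f%%", fr$category, 100 * fr$fraction), collapse = "\n"), "\n")
  invisible(x)
}

#' @rdname plddt_confidence
#' @param x a `plddt_confidence` object.
#' @param ... unused.
#' @export
tidy.plddt_confidence <- function(x, ...) x$residues

#' @rdname plddt_confidence
#' @export
glance.plddt_confidence <- function(x, ...) {
  fr <- stats::setNames(x$fractions$fraction, paste0("fraction_", x$fractions$category))
  dplyr::bind_cols(tibble(n_residues = nrow(x$residues)), as_tibble(as.list(fr)))
}

#' Write the per-residue pLDDT table as CSV
#'
#' @param x a `plddt_confidence` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_plddt_csv <- function(x, path) {
  readr::write_csv(
    x$residues[, c("chain", "seq_number", "res_name", "plddt", "category")], path
  )
  invisible(path)
}
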