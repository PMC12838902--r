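#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

# one-letter <-> three-letter amino acid tables (bio3d::aa321 covers the
# standard set; keep a local map so ligand/het residues fall through cleanly)
.AA3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
  E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL"
)
.AA1 <- stats::setNames(names(.AA3), .AA3)

aa_one_letter <- function(res_name) {
  out <- unname(.AA1[toupper(res_name)])
  ifelse(is.na(out), toupper(res_name), out)
}

#' Compact residue labels
#'
#' A residue is identified throughout the package by a compact label:
#' one-letter amino acid code followed by the author sequence number, e.g.
#' `"R252"` for arginine 252. Non-standard residues keep their full residue
#' name (`"CMP1"`). Insertion codes, when present, are appended (`"K100A"` is
#' avoided by requiring the numeric part to be maximal, so `"K100"` +
#' insertion `"A"` renders as `"K100.A"`).
#'
#' @param res_name character vector of 3-letter (or het) residue names.
#' @param seq_number integer vector of author residue numbers.
#' @param ins_code optional character vector of insertion codes (`NA` for none).
#' @return character vector of labels.
#' @examples
#' residue_label("ARG", 252)
#' @export
residue_label <- function(res_name, seq_number, ins_code = NA_character_) {
  lab <- paste0(aa_one_letter(res_name), seq_number)
  ins <- !is.na(ins_code) & nzchar(ins_code)
  lab[ins] <- paste0(lab[ins], ".", ins_code[ins])
  lab
}

#' Parse compact residue labels
#'
#' Inverse of [residue_label()]: splits labels such as `"R252"`, `"CMP1"` or
#' `"K100.A"` into residue code, sequence number and insertion code.
#'
#' @param label character vector of compact residue labels.
#' @return A tibble with columns `label`, `res_code`, `seq_number`,
#'   `ins_code`.
#' @examples
#' parse_residue_label(c("N247", "R252"))
#' @export
parse_residue_label <- function(label) {
  m <- regmatches(label, regexec("^([A-Za-z][A-Za-z0-9]{0,2}?)(\\d+)(?:\\.([A-Za-z]))?$", label))
  bad <- vapply(m, length, integer(1)) == 0L
  if (any(bad)) {
    abort(paste0(
      "Unparsable residue label(s): ",
      paste(sprintf("'%s' (row %d)", label[bad], which(bad)), collapse = ", ")
    ))
  }
  tibble(
    label = label,
    res_code = toupper(vapply(m, `[`, "", 2L)),
    seq_number = as.integer(vapply(m, `[`, "", 3L)),
    ins_code = dplyr::na_if(vapply(m, `[`, "", 4L), "")
  )
}

# expand "N247-Y255" (or c(247, 255), or c("N247","Y255")) to an integer
# sequence-number vector
range_to_seq <- function(residue_range) {
  if (is.numeric(residue_range)) {
    stopifnot(length(residue_range) == 2L)
    return(seq(as.integer(residue_range[1]), as.integer(residue_range[2])))
  }
  if (length(residue_range) == 1L) {
    residue_range <- strsplit(residue_range, "[-–]")[[1]]
  }
  if (length(residue_range) != 2L) {
    abort("residue_range must be two endpoints or a single 'A-B' string")
  }
  ends <- parse_residue_label(trimws(residue_range))$seq_number
  seq(ends[1], ends[2])
}

# parse "1mM", "80uM", "60-80uM" (takes lower bound), or numeric molar
parse_concentration <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  if (is.na(x) || !nzchar(x)) return(NA_real_)
  m <- regexec("^\\s*([0-9.]+)(?:\\s*[-–]\\s*[0-9.]+)?\\s*(mM|uM|µM|nM|M)\\s*$", x)
  g <- regmatches(x, m)[[1]]
  if (length(g) == 0L) return(NA_real_)
  mult <- c(M = 1, mM = 1e-3, uM = 1e-6, "µM" = 1e-6, nM = 1e-9)[[g[3]]]
  as.numeric(g[2]) * mult
}
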