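#' Transcribed reference fixtures
#'
#' The package ships the published per-residue interaction distance lists
#' for the three ST8Sia4 inhibitor systems (CMP, LMWH, LFcinB11) and the
#' accompanying docking/NMR binding summary, transcribed verbatim as CSV.
#' The docked-pose coordinate files were never deposited, so these distance
#' lists are the only coordinates-free record of the docking models and the
#' inputs from which the published binding-site summaries are reproduced.
#'
#' `reference_fixtures()` returns the installed file paths together with
#' per-file metadata (row counts, reported reference values, and
#' discrepancy annotations — the LMWH and LFcinB11 sources are internally
#' inconsistent between their distance lists and their printed totals and
#' means; the metadata records both accounts without adjudicating).
#'
#' @return A list with `files` (named character vector of paths) and
#'   `metadata` (the parsed annotation list).
#' @examples
#' fx <- reference_fixtures()
#' names(fx$files)
#' fx$metadata$lmwh_distances$discrepancy
#' @export
reference_fixtures <- function() {
  dir <- system.file("extdata", package = "dockcsp")
  meta <- jsonlite::read_json(file.path(dir, "fixtures.json"))
  files <- vapply(meta$files, function(f) file.path(dir, f$file), character(1))
  list(files = files, metadata = meta$files, source = meta$source)
}

#' @rdname reference_fixtures
#' @param ligand `"cmp"`, `"lmwh"` or `"lfcinb11"`.
#' @return `read_distance_fixture()`: tibble with columns `residue`,
#'   `distance_A`, `reported_class` (the class under which each distance
#'   was originally listed).
#' @export
read_distance_fixture <- function(ligand = c("cmp", "lmwh", "lfcinb11")) {
  ligand <- match.arg(ligand)
  path <- reference_fixtures()$files[[paste0(ligand, "_distances")]]
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname reference_fixtures
#' @return `read_binding_summary()`: one row per ligand with the reported
#'   docking range, CSP range, hotspot residue and contact count, peak
#'   combined CSP (ppm) and ligand concentration.
#' @export
read_binding_summary <- function() {
  path <- reference_fixtures()$files[["binding_summary"]]
  readr::read_csv(path, show_col_types = FALSE)
}
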