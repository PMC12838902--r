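#' Cross-check a docking summary against a CSP profile
#'
#' Measures the agreement between the binding map implied by a docked pose
#' (residues bearing classified contacts) and the NMR perturbation map
#' (residues in the CSP significant range). Agreement on the residue sets
#' is the Jaccard index |intersection| / |union|; by default the actual
#' contact-bearing residue set is used, so interior gaps in either map
#' count against the overlap (`mode = "interval"` instead fills each set to
#' its min-max interval). The verdicts are:
#'
#' * `consistent` — Jaccard at least the upper threshold *and* the docking
#'   hotspot equals the CSP peak residue;
#' * `partial` — Jaccard at least the lower threshold;
#' * `inconsistent` — otherwise, or when the docking summary has no
#'   contacts (reason recorded).
#'
#' @param docking a `docking_summary` (see [summarize_contacts()]).
#' @param csp a `csp_profile` (see [csp_profile()]).
#' @param jaccard_thresholds `c(lower, upper)` verdict thresholds,
#'   default `c(0.4, 0.8)`.
#' @param mode `"set"` (default) or `"interval"` residue sets for the
#'   Jaccard computation.
#' @return An object of class `consistency_report`; [tidy()][generics::tidy]
#'   returns it as a one-row tibble.
#' @examples
#' s <- profile_from_distance_table(read_distance_fixture("cmp"), ligand_id = "CMP")
#' fx <- make_csp_fixture(peak_value = 0.087, noise_sd = 0)
#' p <- csp_profile(fx$free, fx$bound, ligand_id = "CMP", concentration = "1mM")
#' compare_docking_csp(s, p)
#' @export
compare_docking_csp <- function(docking, csp,
                                jaccard_thresholds = c(0.4, 0.8),
                                mode = c("set", "interval")) {
  stopifnot(inherits(docking, "docking_summary"), inherits(csp, "csp_profile"))
  mode <- match.arg(mode)
  if (!identical(docking$ligand_id, csp$ligand_id)) {
    warn(sprintf("Comparing different ligand ids: '%s' (docking) vs '%s' (CSP)",
                 docking$ligand_id, csp$ligand_id))
  }
  lo <- jaccard_thresholds[1]; hi <- jaccard_thresholds[2]
  stopifnot(lo <= hi)

  if (docking$total_sites == 0L) {
    rep <- new_consistency_report(
      docking$ligand_id, docking, csp, jaccard = 0, hotspot_match = FALSE,
      verdict = "inconsistent", reason = "docking range undefined (no contacts)",
      mode = mode
    )
    return(rep)
  }
  dock_set <- docking$profiles$seq_number
  csp_set <- if (csp$peak_defined) csp$significant_range$seq_numbers else integer(0)
  if (mode == "interval") {
    dock_set <- seq(min(dock_set), max(dock_set))
    if (length(csp_set)) csp_set <- seq(min(csp_set), max(csp_set))
  }
  jac <- residue_jaccard(dock_set, csp_set)
  hmatch <- csp$peak_defined && !is.na(docking$hotspot) &&
    identical(docking$hotspot, csp$peak_residue)
  verdict <- if (jac >= hi && hmatch) "consistent"
             else if (jac >= lo) "partial"
             else "inconsistent"
  new_consistency_report(docking$ligand_id, docking, csp, jac, hmatch, verdict,
                         reason = NA_character_, mode = mode)
}

residue_jaccard <- function(a, b) {
  u <- union(a, b)
  if (length(u) == 0L) return(0)
  length(intersect(a, b)) / length(u)
}

new_consistency_report <- function(ligand_id, docking, csp, jaccard,
                                   hotspot_match, verdict, reason, mode) {
  out <- list(
    ligand_id = ligand_id,
    docking_range = docking$binding_range,
    csp_range = if (csp$peak_defined) {
      c(csp$significant_range$from, csp$significant_range$to)
    } else c(NA_character_, NA_character_),
    range_jaccard = jaccard,
    hotspot_docking = docking$hotspot,
    hotspot_csp = csp$peak_residue,
    hotspot_match = hotspot_match,
    docking_hotspot_count = docking$hotspot_count,
    csp_peak_value = csp$peak_value,
    verdict = verdict,
    reason = reason,
    mode = mode
  )
  class(out) <- "consistency_report"
  out
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf(
    "Consistency report for %s: %s\n  docking %s-%s vs CSP %s-%s (Jaccard %.2f)\n  hotspots: docking %s (%d contacts) vs CSP %s (%.3f ppm) -> %s\n",
    x$ligand_id, toupper(x$verdict),
    x$docking_range[1], x$docking_range[2], x$csp_range[1], x$csp_range[2],
    x$range_jaccard, x$hotspot_docking, x$docking_hotspot_count,
    x$hotspot_csp, x$csp_peak_value,
    if (x$hotspot_match) "match" else "mismatch"
  ))
  if (!is.na(x$reason)) cat("  reason:", x$reason, "\n")
  invisible(x)
}

#' @rdname compare_docking_csp
#' @param x a `consistency_report`.
#' @param ... unused.
#' @export
tidy.consistency_report <- function(x, ...) {
  tibble(
    ligand_id = x$ligand_id,
    docking_from = x$docking_range[1], docking_to = x$docking_range[2],
    csp_from = x$csp_range[1], csp_to = x$csp_range[2],
    range_jaccard = x$range_jaccard,
    hotspot_docking = x$hotspot_docking,
    docking_hotspot_count = x$docking_hotspot_count,
    hotspot_csp = x$hotspot_csp,
    csp_peak_value = x$csp_peak_value,
    hotspot_match = x$hotspot_match,
    verdict = x$verdict,
    reason = x$reason
  )
}

#' Render consistency reports as a document
#'
#' One row per ligand, ordered strongest CSP first (ranking order), with
#' the binding-range / CSP-range / hotspot columns and the verdict.
#' Numeric fields are lossless (full precision) in `csv` and `json`;
#' `markdown` displays 2 decimals.
#'
#' @param reports a `consistency_report` or list of them.
#' @param format `"csv"`, `"json"` or `"markdown"`.
#' @return A character scalar (the document).
#' @export
render_report <- function(reports, format = c("csv", "json", "markdown")) {
  if (inherits(reports, "consistency_report")) reports <- list(reports)
  if (length(reports) == 0L) abort("Need at least one report")
  format <- match.arg(format)
  tab <- purrr::map_dfr(reports, tidy)
  tab <- tab[order(-replace(tab$csp_peak_value, is.na(tab$csp_peak_value), -Inf),
                   tab$ligand_id), , drop = FALSE]
  switch(format,
    csv = readr::format_csv(tab),
    json = as.character(jsonlite::toJSON(tab, auto_unbox = TRUE, digits = NA,
                                         na = "null")),
    markdown = {
      disp <- tab
      disp$range_jaccard <- sprintf("%.2f", disp$range_jaccard)
      disp$csp_peak_value <- sprintf("%.2f", disp$csp_peak_value)
      cols <- names(disp)
      rows <- apply(disp, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
      paste(c(
        paste0("| ", paste(cols, collapse = " | "), " |"),
        paste0("|", paste(rep("---", length(cols)), collapse = "|"), "|"),
        rows
      ), collapse = "\n")
    }
  )
}

#' Plot docking vs CSP residue-range agreement
#'
#' Horizontal range bars per ligand: docking binding range vs CSP
#' significant range, hotspot residues marked.
#'
#' @param object a `consistency_report` or list of them.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.consistency_report <- function(object, ...) {
  if (inherits(object, "consistency_report")) object <- list(object)
  tab <- purrr::map_dfr(object, tidy)
  seg <- dplyr::bind_rows(
    tab |> dplyr::transmute(
      ligand = .data$ligand_id, source = "docking",
      from = parse_residue_label(.data$docking_from)$seq_number,
      to = parse_residue_label(.data$docking_to)$seq_number,
      hotspot = parse_residue_label(.data$hotspot_docking)$seq_number
    ),
    tab |> dplyr::transmute(
      ligand = .data$ligand_id, source = "CSP",
      from = parse_residue_label(.data$csp_from)$seq_number,
      to = parse_residue_label(.data$csp_to)$seq_number,
      hotspot = parse_residue_label(.data$hotspot_csp)$seq_number
    )
  )
  ggplot2::ggplot(seg, ggplot2::aes(y = interaction(.data$ligand, .data$source),
                                    colour = .data$source)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$from, xend = .data$to,
                                       yend = interaction(.data$ligand, .data$source)),
                          linewidth = 3) +
    ggplot2::geom_point(ggplot2::aes(x = .data$hotspot), size = 3, shape = 18) +
    ggplot2::labs(x = "residue number", y = NULL,
                  title = "Docking vs CSP binding ranges (diamond = hotspot)") +
    ggplot2::theme_minimal()
}
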