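#' Combined amide chemical shift perturbation
#'
#' Combines the 1H and 15N amide shift changes of a residue into a single
#' perturbation magnitude using the standard Euclidean form
#' \deqn{CSP = \sqrt{\Delta\delta_H^2 + (\Delta\delta_N/\alpha)^2}}
#' where `alpha` down-weights the wider 15N dispersion. The default
#' `alpha = 5` is a common choice for amide HSQC titrations; another
#' widespread convention weights nitrogen by 0.14, i.e. `alpha ~ 7.14`.
#' The result is non-negative, zero only when both shifts are zero, and
#' invariant to the sign of either shift.
#'
#' @param delta_H 1H shift change in ppm (bound minus free).
#' @param delta_N 15N shift change in ppm.
#' @param alpha positive nitrogen scaling divisor.
#' @return Numeric vector of combined CSPs in ppm.
#' @examples
#' combined_csp(0.03, 0.5) # sqrt(0.03^2 + 0.1^2)
#' @export
combined_csp <- function(delta_H, delta_N, alpha = 5) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0) {
    abort("alpha must be a single positive number")
  }
  sqrt(delta_H^2 + (delta_N / alpha)^2)
}

#' Read amide shift and CSP tables
#'
#' `read_shift_table()` reads a delimited table with header
#' `residue,delta_H_ppm,delta_N_ppm`; `read_csp_table()` reads a direct
#' per-residue CSP table with header `residue,csp_ppm` (the format used for
#' fixtures transcribing published CSP curves). Residues are compact labels
#' such as `"R252"`.
#'
#' @param path file path.
#' @return A tibble.
#' @export
read_shift_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("residue", "delta_H_ppm", "delta_N_ppm")
  if (!all(need %in% names(tab))) {
    abort(paste0("Shift table must have columns ", paste(need, collapse = ", ")))
  }
  tab
}

#' @rdname read_shift_table
#' @export
read_csp_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("residue", "csp_ppm") %in% names(tab))) {
    abort("CSP table must have columns residue, csp_ppm")
  }
  tab
}

new_csp_profile <- function(data, ligand_id, concentration, alpha,
                            fraction_of_max = 0.5) {
  data <- data[order(data$seq_number), , drop = FALSE]
  pk <- which.max(data$csp_ppm)
  peak_defined <- nrow(data) > 0 && data$csp_ppm[pk] > 0
  out <- list(
    ligand_id = ligand_id,
    concentration = concentration,
    alpha = alpha,
    data = data,
    peak_residue = if (peak_defined) data$residue[pk] else NA_character_,
    peak_value = if (peak_defined) data$csp_ppm[pk] else NA_real_,
    peak_defined = peak_defined
  )
  class(out) <- "csp_profile"
  out$significant_range <- if (peak_defined) {
    significant_range(out, fraction_of_max)
  } else NULL
  out
}

#' Per-residue CSP profile from free and bound shift tables
#'
#' Matches the free and ligand-bound amide shift tables residue by residue,
#' computes the combined CSP for every residue present in both, and locates
#' the peak residue and the significant perturbation range. Residues
#' present in only one table are reported with a warning, never silently
#' dropped.
#'
#' @param free,bound tibbles with columns `residue`, `delta_H_ppm`,
#'   `delta_N_ppm` (see [read_shift_table()]).
#' @param ligand_id ligand identifier.
#' @param concentration ligand concentration: molar numeric or a string
#'   such as `"80uM"` / `"1mM"` (used only for ranking tie-breaks and
#'   reporting).
#' @param alpha nitrogen scaling divisor for [combined_csp()].
#' @param fraction_of_max threshold for [significant_range()].
#' @return An object of class `csp_profile`: per-residue `data` tibble
#'   (`residue`, `seq_number`, `csp_ppm`), `peak_residue`, `peak_value`,
#'   `significant_range`, plus ligand metadata. When every CSP is zero the
#'   peak is flagged undefined (`peak_defined = FALSE`).
#' @examples
#' fx <- make_csp_fixture(noise_sd = 0)
#' prof <- csp_profile(fx$free, fx$bound, ligand_id = "toy")
#' prof$peak_residue
#' @export
csp_profile <- function(free, bound, ligand_id = "ligand",
                        concentration = NA, alpha = 5,
                        fraction_of_max = 0.5) {
  free <- as_tibble(free); bound <- as_tibble(bound)
  if (anyDuplicated(free$residue) || anyDuplicated(bound$residue)) {
    abort("Residues must be unique within each shift table")
  }
  common <- intersect(free$residue, bound$residue)
  if (length(common) == 0L) abort("Free and bound tables share no residues")
  unmatched <- c(setdiff(free$residue, common), setdiff(bound$residue, common))
  if (length(unmatched) > 0L) {
    warn(paste0(
      "Residue(s) present in only one table, excluded from the profile: ",
      paste(unmatched, collapse = ", ")
    ))
  }
  merged <- dplyr::inner_join(
    free, bound, by = "residue", suffix = c("_free", "_bound")
  )
  data <- tibble(
    residue = merged$residue,
    seq_number = parse_residue_label(merged$residue)$seq_number,
    delta_H = merged$delta_H_ppm_bound - merged$delta_H_ppm_free,
    delta_N = merged$delta_N_ppm_bound - merged$delta_N_ppm_free
  )
  data$csp_ppm <- combined_csp(data$delta_H, data$delta_N, alpha)
  new_csp_profile(data, ligand_id, parse_concentration(concentration), alpha,
                  fraction_of_max)
}

#' @rdname csp_profile
#' @param table tibble with columns `residue`, `csp_ppm` — a directly
#'   transcribed CSP curve.
#' @export
csp_profile_from_table <- function(table, ligand_id = "ligand",
                                   concentration = NA,
                                   fraction_of_max = 0.5) {
  table <- as_tibble(table)
  if (!all(c("residue", "csp_ppm") %in% names(table))) {
    abort("CSP table must have columns residue, csp_ppm")
  }
  if (any(table$csp_ppm < 0)) abort("CSP values must be non-negative")
  data <- tibble(
    residue = table$residue,
    seq_number = parse_residue_label(table$residue)$seq_number,
    delta_H = NA_real_, delta_N = NA_real_,
    csp_ppm = table$csp_ppm
  )
  new_csp_profile(data, ligand_id, parse_concentration(concentration),
                  NA_real_, fraction_of_max)
}

#' Significant perturbation range of a CSP profile
#'
#' The maximal contiguous run of residues (in sequence order, among the
#' residues present) whose CSP is at least `fraction_of_max` times the peak
#' value and which contains the peak residue. This is the profile's
#' "largest CSP" region; with the default fraction 0.5 a plateau of
#' strongly perturbed residues around the peak is returned as one interval.
#' The range can only shrink as `fraction_of_max` grows.
#'
#' @param profile a `csp_profile`.
#' @param fraction_of_max threshold in (0, 1], default 0.5.
#' @return A list with `from`, `to` (residue labels), `residues`
#'   (label vector) and `seq_numbers`.
#' @examples
#' fx <- make_csp_fixture(noise_sd = 0)
#' significant_range(csp_profile(fx$free, fx$bound), 0.5)
#' @export
significant_range <- function(profile, fraction_of_max = 0.5) {
  stopifnot(inherits(profile, "csp_profile"))
  if (!is.numeric(fraction_of_max) || fraction_of_max <= 0 || fraction_of_max > 1) {
    abort("fraction_of_max must be in (0, 1]")
  }
  d <- profile$data[order(profile$data$seq_number), , drop = FALSE]
  if (nrow(d) == 0L || max(d$csp_ppm) <= 0) {
    abort("Profile has no strictly positive CSP; significant range undefined")
  }
  pk <- which.max(d$csp_ppm)
  above <- d$csp_ppm >= fraction_of_max * d$csp_ppm[pk]
  lo <- pk
  while (lo > 1L && above[lo - 1L]) lo <- lo - 1L
  hi <- pk
  while (hi < nrow(d) && above[hi + 1L]) hi <- hi + 1L
  list(
    from = d$residue[lo], to = d$residue[hi],
    residues = d$residue[lo:hi], seq_numbers = d$seq_number[lo:hi]
  )
}

#' @export
print.csp_profile <- function(x, ...) {
  cat("CSP profile for", x$ligand_id)
  if (!is.na(x$concentration)) cat(sprintf(" (%.3g M)", x$concentration))
  cat(":", nrow(x$data), "residues\n")
  if (x$peak_defined) {
    cat(sprintf("  peak %.3f ppm at %s; significant range %s-%s\n",
                x$peak_value, x$peak_residue,
                x$significant_range$from, x$significant_range$to))
  } else {
    cat("  all CSPs zero; peak undefined\n")
  }
  invisible(x)
}

#' @rdname csp_profile
#' @param x a `csp_profile`.
#' @param ... unused.
#' @export
tidy.csp_profile <- function(x, ...) x$data

#' @rdname csp_profile
#' @export
glance.csp_profile <- function(x, ...) {
  tibble(
    ligand_id = x$ligand_id,
    concentration_M = x$concentration,
    n_residues = nrow(x$data),
    peak_residue = x$peak_residue,
    peak_csp_ppm = x$peak_value,
    range_from = if (x$peak_defined) x$significant_range$from else NA_character_,
    range_to = if (x$peak_defined) x$significant_range$to else NA_character_
  )
}

#' Plot a CSP profile
#'
#' Per-residue CSP bars with the significance threshold line and the
#' significant range shaded.
#'
#' @param object a `csp_profile`.
#' @param fraction_of_max threshold shown, default 0.5.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.csp_profile <- function(object, fraction_of_max = 0.5, ...) {
  d <- object$data
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$seq_number, y = .data$csp_ppm)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(
      x = "residue number", y = "combined CSP (ppm)",
      title = paste0("CSP profile: ", object$ligand_id)
    ) +
    ggplot2::theme_minimal()
  if (object$peak_defined) {
    rng <- significant_range(object, fraction_of_max)
    p <- p +
      ggplot2::annotate("rect",
        xmin = min(rng$seq_numbers) - 0.5, xmax = max(rng$seq_numbers) + 0.5,
        ymin = 0, ymax = Inf, alpha = 0.15, fill = "steelblue"
      ) +
      ggplot2::geom_hline(
        yintercept = fraction_of_max * object$peak_value, linetype = "dashed"
      )
  }
  p
}

#' Export a CSP profile as CSV (residue order preserved)
#'
#' @param x a `csp_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_csp_csv <- function(x, path) {
  readr::write_csv(x$data[, c("residue", "csp_ppm")], path)
  invisible(path)
}

#' Rank ligands by CSP strength
#'
#' Orders ligand profiles from strongest to weakest perturbation:
#' descending peak CSP; ties broken toward the lower ligand concentration
#' (a larger perturbation at a lower concentration indicates tighter
#' binding); residual ties alphabetical by ligand id. When tied peaks
#' cannot be separated by concentration (missing or equal values), the
#' `tie_flag` column marks the affected rows.
#'
#' @param profiles list of `csp_profile` objects (length >= 1).
#' @return A tibble ordered strongest-first with columns `rank`,
#'   `ligand_id`, `peak_residue`, `peak_csp_ppm`, `concentration_M`,
#'   `tie_flag`.
#' @examples
#' fx <- read_binding_summary()
#' profs <- purrr::pmap(
#'   fx[, c("ligand", "hotspot", "peak_csp_ppm", "concentration")],
#'   function(ligand, hotspot, peak_csp_ppm, concentration) {
#'     csp_profile_from_table(
#'       tibble::tibble(residue = hotspot, csp_ppm = peak_csp_ppm),
#'       ligand_id = ligand, concentration = concentration
#'     )
#'   }
#' )
#' rank_ligands(profs)
#' @export
rank_ligands <- function(profiles) {
  if (inherits(profiles, "csp_profile")) profiles <- list(profiles)
  if (length(profiles) == 0L) abort("Need at least one profile")
  tab <- purrr::map_dfr(profiles, function(p) {
    tibble(
      ligand_id = p$ligand_id,
      peak_residue = p$peak_residue,
      peak_csp_ppm = p$peak_value,
      concentration_M = p$concentration
    )
  })
  tab <- tab[order(-tab$peak_csp_ppm, tab$concentration_M, tab$ligand_id), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  # flag peak ties that concentration could not (or can only dubiously) break
  tab$tie_flag <- FALSE
  dup <- duplicated(tab$peak_csp_ppm) | duplicated(tab$peak_csp_ppm, fromLast = TRUE)
  conc_tie <- dup & (is.na(tab$concentration_M) |
    (duplicated(paste(tab$peak_csp_ppm, tab$concentration_M)) |
     duplicated(paste(tab$peak_csp_ppm, tab$concentration_M), fromLast = TRUE)))
  tab$tie_flag[conc_tie] <- TRUE
  tab[, c("rank", "ligand_id", "peak_residue", "peak_csp_ppm",
          "concentration_M", "tie_flag")]
}
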