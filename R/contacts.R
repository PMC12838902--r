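#' Enumerate receptor-ligand heavy-atom contacts
#'
#' Finds all receptor/ligand heavy-atom pairs within the scheme's outer
#' distance bound using a uniform cell-list spatial index (cell edge equal
#' to the bound, so candidate pairs come from the 27 neighbouring cells),
#' reduces the candidate set with the chosen rule, and classifies each
#' retained pair with [classify_distance()]. Hydrogens never enter the
#' distance computation.
#'
#' Reduction rules:
#' * `"closest"` (default) — for each (receptor residue, ligand heavy atom)
#'   pair, keep only the closest receptor atom. One ligand atom can thus
#'   contribute one contact per residue, which yields multi-contact
#'   residues without counting a single ligand atom several times against
#'   the same residue.
#' * `"all"` — every pair within range.
#' * `"closest_per_residue"` — a single closest pair per receptor residue.
#'
#' @param receptor,ligand atom tibbles (see [split_receptor_ligand()]);
#'   both must contain at least one heavy atom.
#' @param scheme a [bin_scheme()]. With `chemistry_gate = TRUE`, pairs in
#'   the moderate distance bin that lack donor-acceptor complementarity
#'   are demoted to the weak class.
#' @param reduction `"closest"`, `"all"` or `"closest_per_residue"`.
#' @return Tibble of contact records sorted by residue then distance:
#'   `chain`, `seq_number`, `res_name`, `residue`, `receptor_atom`,
#'   `ligand_atom`, `distance`, `contact_class`.
#' @examples
#' toy <- make_toy_complex(toy_placements(res_seq = 2, distance = 3.0))
#' parts <- split_receptor_ligand(read_complex(toy$path), "hetatm")
#' enumerate_contacts(parts$receptor, parts$ligand)
#' @export
enumerate_contacts <- function(receptor, ligand, scheme = bin_scheme(),
                               reduction = c("closest", "all", "closest_per_residue")) {
  reduction <- match.arg(reduction)
  rec <- receptor[!receptor$is_hydrogen, , drop = FALSE]
  lig <- ligand[!ligand$is_hydrogen, , drop = FALSE]
  if (nrow(rec) == 0L) abort("Receptor has no heavy atoms")
  if (nrow(lig) == 0L) abort("Ligand has no heavy atoms")

  pairs <- cell_list_pairs(rec, lig, cutoff = scheme$hydrophobic_max)
  if (nrow(pairs) > 0L) {
    pairs <- switch(reduction,
      all = pairs,
      closest = pairs |>
        dplyr::group_by(.data$rec_res_key, .data$lig_idx) |>
        dplyr::slice_min(.data$distance, n = 1, with_ties = FALSE) |>
        dplyr::ungroup(),
      closest_per_residue = pairs |>
        dplyr::group_by(.data$rec_res_key) |>
        dplyr::slice_min(.data$distance, n = 1, with_ties = FALSE) |>
        dplyr::ungroup()
    )
  }

  out <- tibble(
    chain = rec$chain[pairs$rec_idx],
    seq_number = rec$seq_number[pairs$rec_idx],
    res_name = rec$res_name[pairs$rec_idx],
    residue = rec$residue[pairs$rec_idx],
    receptor_atom = rec$atom_name[pairs$rec_idx],
    ligand_atom = lig$atom_name[pairs$lig_idx],
    distance = pairs$distance
  )
  out$contact_class <- classify_distance_safe(out$distance, scheme)
  if (scheme$chemistry_gate && nrow(out) > 0L) {
    rroles <- assign_atom_roles(rec)
    lroles <- assign_atom_roles(lig)
    ok <- (rroles$donor[pairs$rec_idx] & lroles$acceptor[pairs$lig_idx]) |
      (rroles$acceptor[pairs$rec_idx] & lroles$donor[pairs$lig_idx])
    demote <- !is.na(out$contact_class) & out$contact_class == "moderate_hbond" & !ok
    out$contact_class[demote] <- "weak_hbond_vdw"
  }
  out <- out[!is.na(out$contact_class), , drop = FALSE]
  out[order(out$chain, out$seq_number, out$distance), , drop = FALSE]
}

classify_distance_safe <- function(d, scheme) {
  if (length(d) == 0L) return(factor(character(0), levels = CONTACT_CLASSES))
  classify_distance(d, scheme)
}

# all (receptor, ligand) heavy-atom pairs with distance <= cutoff, found by
# hashing receptor atoms into cubic cells of edge `cutoff` and scanning the
# 27-cell neighbourhood of each ligand atom
cell_list_pairs <- function(rec, lig, cutoff) {
  key <- function(i, j, k) paste(i, j, k, sep = ",")
  ri <- floor(rec$x / cutoff); rj <- floor(rec$y / cutoff); rk <- floor(rec$z / cutoff)
  cells <- split(seq_len(nrow(rec)), key(ri, rj, rk))
  res <- vector("list", nrow(lig))
  for (a in seq_len(nrow(lig))) {
    ci <- floor(lig$x[a] / cutoff); cj <- floor(lig$y[a] / cutoff); ck <- floor(lig$z[a] / cutoff)
    cand <- integer(0)
    for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
      hit <- cells[[key(ci + di, cj + dj, ck + dk)]]
      if (!is.null(hit)) cand <- c(cand, hit)
    }
    if (length(cand) == 0L) next
    d <- sqrt((rec$x[cand] - lig$x[a])^2 +
              (rec$y[cand] - lig$y[a])^2 +
              (rec$z[cand] - lig$z[a])^2)
    keep <- d <= cutoff
    if (any(keep)) {
      res[[a]] <- tibble(rec_idx = cand[keep], lig_idx = a, distance = d[keep])
    }
  }
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0L) {
    return(tibble(rec_idx = integer(0), lig_idx = integer(0),
                  distance = numeric(0), rec_res_key = character(0)))
  }
  out$rec_res_key <- paste(rec$chain[out$rec_idx], rec$seq_number[out$rec_idx],
                           rec$ins_code[out$rec_idx], sep = "\r")
  out
}

#' Aggregate contacts into a per-residue docking summary
#'
#' Builds the per-residue interaction profile (counts per contact class plus
#' the distance list), the binding range (first to last residue with at
#' least one contact), the total number of binding sites, the mean contact
#' distance, and the hotspot residue (maximal total contact count;
#' ties broken to the lowest sequence number and reported).
#'
#' @param contacts contact tibble from [enumerate_contacts()] or
#'   [profile_from_distance_table()]'s internal classification; an empty
#'   tibble yields a zero-site summary with an undefined binding range.
#' @param ligand_id identifier for the ligand the contacts belong to.
#' @return An object of class `docking_summary` with fields `ligand_id`,
#'   `profiles` (per-residue tibble), `total_sites`, `mean_distance`,
#'   `binding_range` (character 2-vector of residue labels, `NA` when
#'   empty), `hotspot`, `hotspot_count`, `hotspot_ties`, `contacts`.
#'   [tidy()][generics::tidy] returns the per-residue profile,
#'   [glance()][generics::glance] a one-row summary.
#' @examples
#' fx <- reference_fixtures()
#' tab <- read_distance_fixture("cmp")
#' summarize_contacts(classify_table(tab), ligand_id = "CMP")
#' @export
summarize_contacts <- function(contacts, ligand_id = "ligand") {
  if (nrow(contacts) == 0L) {
    out <- list(
      ligand_id = ligand_id,
      profiles = tibble(
        residue = character(0), seq_number = integer(0),
        moderate_hbond = integer(0), weak_hbond_vdw = integer(0),
        hydrophobic = integer(0), total = integer(0), distances = list()
      ),
      total_sites = 0L, mean_distance = NA_real_,
      binding_range = c(NA_character_, NA_character_),
      hotspot = NA_character_, hotspot_count = 0L, hotspot_ties = character(0),
      contacts = contacts, empty = TRUE
    )
    class(out) <- "docking_summary"
    return(out)
  }
  profiles <- contacts |>
    dplyr::count(.data$residue, .data$seq_number, .data$contact_class) |>
    tidyr::pivot_wider(
      names_from = "contact_class", values_from = "n", values_fill = 0L,
      names_expand = TRUE
    ) |>
    dplyr::left_join(
      contacts |>
        dplyr::group_by(.data$residue, .data$seq_number) |>
        dplyr::summarise(distances = list(.data$distance), .groups = "drop"),
      by = c("residue", "seq_number")
    ) |>
    dplyr::mutate(total = .data$moderate_hbond + .data$weak_hbond_vdw + .data$hydrophobic) |>
    dplyr::arrange(.data$seq_number) |>
    dplyr::select("residue", "seq_number", "moderate_hbond", "weak_hbond_vdw",
                  "hydrophobic", "total", "distances")

  top <- max(profiles$total)
  ties <- profiles$residue[profiles$total == top]
  out <- list(
    ligand_id = ligand_id,
    profiles = profiles,
    total_sites = nrow(contacts),
    mean_distance = mean(contacts$distance),
    binding_range = c(profiles$residue[1], profiles$residue[nrow(profiles)]),
    hotspot = ties[1],
    hotspot_count = as.integer(top),
    hotspot_ties = ties,
    contacts = contacts,
    empty = FALSE
  )
  class(out) <- "docking_summary"
  out
}

#' Classify a labelled distance table into contact records
#'
#' @param table tibble/data frame with columns `residue` (compact label,
#'   e.g. `"R252"`) and `distance_A` (Å; `distance` also accepted).
#' @param scheme a [bin_scheme()].
#' @return Contact tibble in the [enumerate_contacts()] layout (atom names
#'   `NA`); rows whose distance falls outside every bin are dropped.
#' @export
classify_table <- function(table, scheme = bin_scheme()) {
  table <- as_tibble(table)
  if (!"distance_A" %in% names(table) && "distance" %in% names(table)) {
    table$distance_A <- table$distance
  }
  if (!all(c("residue", "distance_A") %in% names(table))) {
    abort("Distance table needs columns 'residue' and 'distance_A'")
  }
  if (any(!is.finite(table$distance_A)) || any(table$distance_A <= 0)) {
    bad <- which(!is.finite(table$distance_A) | table$distance_A <= 0)
    abort(paste0("Non-positive distance in row(s) ", paste(bad, collapse = ", ")))
  }
  keys <- parse_residue_label(table$residue)
  res3 <- unname(.AA3[keys$res_code])
  out <- tibble(
    chain = "A",
    seq_number = keys$seq_number,
    res_name = ifelse(is.na(res3), keys$res_code, res3),
    residue = table$residue,
    receptor_atom = NA_character_,
    ligand_atom = NA_character_,
    distance = table$distance_A,
    contact_class = classify_distance_safe(table$distance_A, scheme)
  )
  out <- out[!is.na(out$contact_class), , drop = FALSE]
  out[order(out$seq_number, out$distance), , drop = FALSE]
}

#' Summarise a per-residue distance table directly
#'
#' Bypasses 3D geometry entirely: each row of a labelled distance table
#' (the coordinates-free record of a docking model, as printed in published
#' per-residue interaction lists) is classified with [classify_distance()]
#' and the rows aggregated with [summarize_contacts()]. This is the entry
#' point used to reproduce published binding-site summaries from
#' transcribed distance lists.
#'
#' @inheritParams classify_table
#' @param ligand_id identifier for the ligand.
#' @return A `docking_summary` (see [summarize_contacts()]).
#' @examples
#' cmp <- read_distance_fixture("cmp")
#' s <- profile_from_distance_table(cmp, ligand_id = "CMP")
#' s$total_sites
#' round(s$mean_distance, 2)
#' @export
profile_from_distance_table <- function(table, scheme = bin_scheme(),
                                        ligand_id = "ligand") {
  summarize_contacts(classify_table(table, scheme), ligand_id = ligand_id)
}

#' @export
print.docking_summary <- function(x, ...) {
  cat("Docking contact summary for", x$ligand_id, "\n")
  if (x$total_sites == 0L) {
    cat("  no contacts (binding range undefined)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "  %d binding sites over %s-%s; mean distance %.2f A\n  hotspot %s (%d contacts%s)\n",
    x$total_sites, x$binding_range[1], x$binding_range[2], x$mean_distance,
    x$hotspot, x$hotspot_count,
    if (length(x$hotspot_ties) > 1) paste0(", ties: ", paste(x$hotspot_ties, collapse = ", ")) else ""
  ))
  cls_tot <- colSums(x$profiles[, CONTACT_CLASSES])
  cat(sprintf("  classes: %d moderate H-bond, %d weak H-bond/vdW, %d hydrophobic\n",
              cls_tot[1], cls_tot[2], cls_tot[3]))
  invisible(x)
}

#' @rdname summarize_contacts
#' @param x a `docking_summary`.
#' @param ... unused.
#' @export
tidy.docking_summary <- function(x, ...) x$profiles

#' @rdname summarize_contacts
#' @export
glance.docking_summary <- function(x, ...) {
  cls_tot <- if (nrow(x$profiles)) colSums(x$profiles[, CONTACT_CLASSES]) else
    stats::setNames(c(0L, 0L, 0L), CONTACT_CLASSES)
  tibble(
    ligand_id = x$ligand_id,
    total_sites = x$total_sites,
    n_moderate = as.integer(cls_tot[["moderate_hbond"]]),
    n_weak = as.integer(cls_tot[["weak_hbond_vdw"]]),
    n_hydrophobic = as.integer(cls_tot[["hydrophobic"]]),
    mean_distance = x$mean_distance,
    binding_from = x$binding_range[1],
    binding_to = x$binding_range[2],
    hotspot = x$hotspot,
    hotspot_count = x$hotspot_count
  )
}

#' Plot a per-residue contact profile
#'
#' Stacked per-residue contact counts coloured by contact class; the
#' hotspot residue is marked.
#'
#' @param object a `docking_summary`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.docking_summary <- function(object, ...) {
  long <- object$profiles |>
    dplyr::select("residue", "seq_number", dplyr::all_of(CONTACT_CLASSES)) |>
    tidyr::pivot_longer(dplyr::all_of(CONTACT_CLASSES),
                        names_to = "class", values_to = "n") |>
    dplyr::mutate(class = factor(.data$class, levels = CONTACT_CLASSES))
  ggplot2::ggplot(long, ggplot2::aes(
    x = stats::reorder(.data$residue, .data$seq_number),
    y = .data$n, fill = .data$class
  )) +
    ggplot2::geom_col() +
    ggplot2::annotate("text",
      x = object$hotspot, y = object$hotspot_count,
      label = "★", vjust = -0.3
    ) +
    ggplot2::labs(
      x = "residue", y = "contacts",
      title = paste0("Contact profile: ", object$ligand_id),
      fill = "contact class"
    ) +
    ggplot2::theme_minimal()
}

#' Export contacts and summaries
#'
#' `write_contacts_csv()` writes the contact records with distances at full
#' precision plus a display column rounded to 0.1 Å;
#' `docking_summary_json()` serialises a summary (rounded display mean
#' alongside the full-precision mean).
#'
#' @param contacts contact tibble.
#' @param path output path (`NULL` for `docking_summary_json()` returns the
#'   JSON string).
#' @return `path` (or JSON string), invisibly.
#' @export
write_contacts_csv <- function(contacts, path) {
  out <- contacts |>
    dplyr::mutate(distance_display = round(.data$distance, 1)) |>
    dplyr::select("residue", "receptor_atom", "ligand_atom",
                  distance_A = "distance", "distance_display", class = "contact_class")
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_contacts_csv
#' @param x a `docking_summary`.
#' @export
docking_summary_json <- function(x, path = NULL) {
  payload <- list(
    ligand_id = x$ligand_id,
    total_sites = x$total_sites,
    mean_distance = x$mean_distance,
    mean_distance_display = round(x$mean_distance, 2),
    binding_range = x$binding_range,
    hotspot = x$hotspot,
    hotspot_count = x$hotspot_count,
    hotspot_ties = x$hotspot_ties,
    profiles = x$profiles[, setdiff(names(x$profiles), "distances")]
  )
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
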