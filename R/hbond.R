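#' Default intermolecular bond-class registry
#'
#' The census considers a fixed set of donor-class / acceptor-class pairs
#' between guest and cyclodextrin. Guest donors are the phenol hydroxyls;
#' guest acceptors the iron atom, the phenol oxygens and the two imide
#' carbonyl oxygens. CD donors are the site hydroxyls; CD acceptors the
#' hydroxyl, ether and anomeric oxygens. The default registry enumerates
#' seven pairs: the Fe...H(O-CD) class, the two imide carbonyls and the
#' phenol-O accepting a CD hydroxyl, and the three phenol-OH to CD-oxygen
#' classes. The registry is a plain tibble; drop or add rows to change what
#' [detect_hbonds()] reports.
#'
#' @return Tibble with columns `donor_class`, `acceptor_class`.
#' @export
default_bond_registry <- function() {
  tibble::tribble(
    ~donor_class,     ~acceptor_class,
    "cd_hydroxyl_OH", "fe",
    "cd_hydroxyl_OH", "imide_O1",
    "cd_hydroxyl_OH", "imide_O2",
    "cd_hydroxyl_OH", "phenol_O",
    "phenol_OH",      "cd_hydroxyl_O",
    "phenol_OH",      "cd_ether_O",
    "phenol_OH",      "cd_anomeric_O"
  )
}

#' Length and angle of a donor-H...acceptor contact
#'
#' @param donor,hydrogen,acceptor Numeric 3-vectors (Angstrom).
#' @return Named list: `length` = |H - acceptor| in Angstrom; `angle` =
#'   donor-H...acceptor angle at the hydrogen, in degrees (180 = linear).
#' @export
#' @examples
#' bond_geometry(c(0, 0, 0), c(1, 0, 0), c(3, 0, 0)) # 2 A, 180 deg
bond_geometry <- function(donor, hydrogen, acceptor) {
  v1 <- donor - hydrogen
  v2 <- acceptor - hydrogen
  n1 <- sqrt(sum(v1^2))
  n2 <- sqrt(sum(v2^2))
  if (!all(is.finite(c(donor, hydrogen, acceptor))) || n1 == 0 || n2 == 0) {
    abort("degenerate geometry: coincident or non-finite points")
  }
  cosang <- sum(v1 * v2) / (n1 * n2)
  cosang <- min(1, max(-1, cosang))
  list(length = n2, angle = 180 / pi * acos(cosang))
}

donor_table <- function(model) {
  topo <- model$topology
  el <- model$atoms$element[topo$substituent]
  cd_don <- tibble::tibble(
    donor_heavy = topo$oxygen[el == "H"],
    hydrogen = topo$substituent[el == "H"],
    donor_class = "cd_hydroxyl_OH",
    site_id = topo$site_id[el == "H"],
    molecule = paste0("cd", topo$cd[el == "H"])
  )
  g <- model$guest
  guest_don <- tibble::tibble(
    donor_heavy = c(g$ph1$o, g$ph2$o),
    hydrogen = c(g$ph1$h, g$ph2$h),
    donor_class = "phenol_OH",
    site_id = NA_integer_,
    molecule = "guest"
  )
  dplyr::bind_rows(cd_don, guest_don)
}

acceptor_table <- function(model) {
  g <- model$guest
  topo <- model$topology
  el <- model$atoms$element[topo$substituent]
  dplyr::bind_rows(
    tibble::tibble(acceptor = g$fe, acceptor_class = "fe", molecule = "guest"),
    tibble::tibble(acceptor = c(g$ph1$o, g$ph2$o),
                   acceptor_class = "phenol_O", molecule = "guest"),
    tibble::tibble(acceptor = g$imide_o,
                   acceptor_class = paste0("imide_O", seq_along(g$imide_o)),
                   molecule = "guest"),
    tibble::tibble(acceptor = topo$oxygen[el == "H"],
                   acceptor_class = "cd_hydroxyl_O",
                   molecule = paste0("cd", topo$cd[el == "H"])),
    tibble::tibble(acceptor = model$cd_acceptors$index,
                   acceptor_class = model$cd_acceptors$class,
                   molecule = paste0("cd", model$cd_acceptors$cd))
  )
}

#' Detect intermolecular hydrogen bonds in an annotated geometry
#'
#' Every donor-hydrogen / acceptor pair whose classes appear in the registry,
#' whose atoms lie in different molecules, and whose H...acceptor distance is
#' at most `cutoff` is reported once, with its geometry. Detection is purely
#' distance-based by default; the donor-H...acceptor angle is always computed
#' and reported, and an optional minimum-angle gate can be switched on.
#'
#' @param model A `cd_model` from [annotate()].
#' @param cutoff Maximum H...acceptor distance in Angstrom (default 2.0).
#' @param registry Bond-class registry tibble; see [default_bond_registry()].
#' @param angle_min Optional minimum donor-H...acceptor angle in degrees;
#'   `NULL` (default) applies no angle gate.
#' @return Tibble sorted by length: `donor_heavy`, `hydrogen`, `acceptor`
#'   (atom indices), `donor_class`, `acceptor_class`, `bond_class`
#'   ("donor->acceptor"), `site_id` (CD site of the donor, NA for guest
#'   donors), `length`, `angle`, `intermolecular`.
#' @export
detect_hbonds <- function(model, cutoff = 2.0,
                          registry = default_bond_registry(),
                          angle_min = NULL) {
  if (!is.numeric(cutoff) || cutoff <= 0) abort("cutoff must be > 0")
  don <- donor_table(model)
  acc <- acceptor_table(model)
  pairs <- dplyr::cross_join(
    dplyr::rename(don, donor_molecule = "molecule"),
    dplyr::rename(acc, acceptor_molecule = "molecule")
  )
  pairs <- dplyr::inner_join(pairs, registry,
                             by = c("donor_class", "acceptor_class"))
  pairs <- dplyr::filter(
    pairs,
    .data$donor_molecule != .data$acceptor_molecule,
    .data$acceptor != .data$donor_heavy,
    .data$acceptor != .data$hydrogen
  )
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  dv <- xyz[pairs$acceptor, , drop = FALSE] - xyz[pairs$hydrogen, , drop = FALSE]
  pairs$length <- sqrt(rowSums(dv^2))
  v1 <- xyz[pairs$donor_heavy, , drop = FALSE] - xyz[pairs$hydrogen, , drop = FALSE]
  cosang <- rowSums(v1 * dv) / (sqrt(rowSums(v1^2)) * pairs$length)
  pairs$angle <- 180 / pi * acos(pmin(1, pmax(-1, cosang)))
  pairs <- dplyr::filter(pairs, .data$length <= cutoff)
  if (!is.null(angle_min)) {
    pairs <- dplyr::filter(pairs, .data$angle >= angle_min)
  }
  pairs |>
    dplyr::mutate(
      bond_class = paste0(.data$donor_class, "->", .data$acceptor_class),
      intermolecular = TRUE
    ) |>
    dplyr::select("donor_heavy", "hydrogen", "acceptor", "donor_class",
                  "acceptor_class", "bond_class", "site_id", "length",
                  "angle", "intermolecular") |>
    dplyr::arrange(.data$length)
}

#' Detect clamps among detected hydrogen bonds
#'
#' A clamp is a pair of simultaneous O-H...acceptor bonds donated by the
#' position-2 and position-3 hydroxyls of one anhydroglucose unit to a single
#' shared acceptor (the paradigm case being the two Fe...H-O bonds of the
#' ferrocene clamp). A clamp is symmetric when both bond lengths are within
#' `cutoff`; asymmetric clamps (detectable by running [detect_hbonds()] at a
#' widened cutoff) are retained in the output but flagged, and census totals
#' exclude them.
#'
#' @param bonds Bond tibble from [detect_hbonds()] over the same model.
#' @param model The annotated `cd_model`.
#' @param cutoff Symmetry cutoff in Angstrom (the census cutoff, default 2.0).
#' @return Tibble: `acceptor`, `acceptor_class`, `cd`, `glucose_unit`,
#'   `site_a`, `site_b` (position-2 and position-3 site ids), `length_a`,
#'   `length_b`, `symmetric`.
#' @export
detect_clamps <- function(bonds, model, cutoff = 2.0) {
  cd_bonds <- dplyr::filter(bonds, !is.na(.data$site_id))
  empty <- tibble::tibble(
    acceptor = integer(), acceptor_class = character(), cd = integer(),
    glucose_unit = integer(), site_a = integer(), site_b = integer(),
    length_a = numeric(), length_b = numeric(), symmetric = logical()
  )
  if (!nrow(cd_bonds)) return(empty)
  topo <- model$topology[, c("site_id", "cd", "glucose_unit", "position")]
  cd_bonds <- dplyr::inner_join(cd_bonds, topo, by = "site_id")
  # keep the shortest bond per (acceptor, site) so a site pairs at most once
  cd_bonds <- cd_bonds |>
    dplyr::group_by(.data$acceptor, .data$site_id) |>
    dplyr::slice_min(.data$length, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  p2 <- dplyr::filter(cd_bonds, .data$position == 2L)
  p3 <- dplyr::filter(cd_bonds, .data$position == 3L)
  clamps <- dplyr::inner_join(
    dplyr::select(p2, "acceptor", "acceptor_class", "cd", "glucose_unit",
                  site_a = "site_id", length_a = "length"),
    dplyr::select(p3, "acceptor", "cd", "glucose_unit",
                  site_b = "site_id", length_b = "length"),
    by = c("acceptor", "cd", "glucose_unit")
  )
  if (!nrow(clamps)) return(empty)
  clamps |>
    dplyr::mutate(symmetric = .data$length_a <= cutoff & .data$length_b <= cutoff) |>
    dplyr::arrange(.data$acceptor, .data$cd, .data$glucose_unit)
}

#' Count methyl groups close to the ferrocenyl moiety
#'
#' Counts methyl carbons (site substituents with element C) whose minimum
#' distance to any atom of the guest's Fc moiety set is at most
#' `proximity_cutoff`. This is the per-model "NbMeFc" statistic.
#'
#' @param model A `cd_model`.
#' @param proximity_cutoff Distance cutoff in Angstrom; default 4.0 (van der
#'   Waals contact scale).
#' @return Integer count.
#' @export
count_methyls_near_fc <- function(model, proximity_cutoff = 4.0) {
  if (!is.numeric(proximity_cutoff) || proximity_cutoff <= 0) {
    abort("proximity_cutoff must be > 0")
  }
  el <- model$atoms$element[model$topology$substituent]
  me <- model$topology$substituent[el == "C"]
  fc <- model$guest$moieties$fc
  if (!length(me) || !length(fc)) return(0L)
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  n_close <- vapply(me, function(i) {
    d2 <- rowSums((xyz[fc, , drop = FALSE] -
                     matrix(xyz[i, ], length(fc), 3, byrow = TRUE))^2)
    min(d2) <= proximity_cutoff^2
  }, logical(1))
  sum(n_close)
}

#' Hydrogen-bond census over a set of grouped models
#'
#' Aggregates hydrogen-bond and clamp counts per bond class across models
#' labelled into groups (typically "best" and "worse" halves of a series),
#' mirroring the per-series bond bookkeeping codes: total bonds per class and
#' group, symmetric-clamp totals per acceptor class (asymmetric clamps are
#' excluded from totals), and mean methyl-near-Fc count per group.
#'
#' @param models List of `cd_model` objects.
#' @param groups Character vector of group labels, one per model.
#' @param cutoff H...acceptor cutoff in Angstrom.
#' @param registry Bond-class registry.
#' @param proximity_cutoff Cutoff for [count_methyls_near_fc()].
#' @return List of class `cd_census`: `bonds` (bond_class x group counts),
#'   `clamps` (acceptor_class x group symmetric-clamp counts), `nbmefc`
#'   (group means), `n_models` (models per group).
#' @export
census <- function(models, groups, cutoff = 2.0,
                   registry = default_bond_registry(),
                   proximity_cutoff = 4.0) {
  if (length(models) != length(groups) || anyNA(groups)) {
    abort("every model needs exactly one non-missing group label")
  }
  per_model <- purrr::map2(models, groups, function(m, grp) {
    bonds <- detect_hbonds(m, cutoff = cutoff, registry = registry)
    clamps <- detect_clamps(bonds, m, cutoff = cutoff)
    list(
      bonds = dplyr::mutate(bonds, group = grp),
      clamps = dplyr::mutate(clamps, group = grp),
      nbmefc = tibble::tibble(group = grp,
                              nbmefc = count_methyls_near_fc(m, proximity_cutoff))
    )
  })
  bonds <- dplyr::bind_rows(purrr::map(per_model, "bonds"))
  clamps <- dplyr::bind_rows(purrr::map(per_model, "clamps"))
  nbme <- dplyr::bind_rows(purrr::map(per_model, "nbmefc"))
  structure(list(
    bonds = dplyr::count(bonds, .data$bond_class, .data$group, name = "n_bonds"),
    clamps = clamps |>
      dplyr::filter(.data$symmetric) |>
      dplyr::count(.data$acceptor_class, .data$group, name = "n_clamps"),
    nbmefc = nbme |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(mean_nbmefc = mean(.data$nbmefc), .groups = "drop"),
    n_models = dplyr::count(tibble::tibble(group = groups), .data$group,
                            name = "n_models")
  ), class = "cd_census")
}

#' @export
print.cd_census <- function(x, ...) {
  cat("<cd_census>\n")
  cat("bonds per class and group:\n")
  print(x$bonds)
  cat("symmetric clamps per acceptor class and group:\n")
  print(x$clamps)
  cat("mean methyls near Fc per group:\n")
  print(x$nbmefc)
  invisible(x)
}
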