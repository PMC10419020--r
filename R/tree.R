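#' Complexation energy difference of an assembly
#'
#' The stabilization of a host-guest assembly relative to its separated
#' components at identical geometry:
#' for one CD, `dE = E_assembly - E_guest - E_CD1`; for two CDs the second
#' CD energy is subtracted as well. All energies are heats of formation in
#' kJ/mol; negative values mean a stabilized assembly.
#'
#' @param e_assembly,e_guest,e_cd1 Heats of formation, kJ/mol (vectorized).
#' @param e_cd2 Second-CD heat of formation, or `NULL`/`NA` for 1-CD systems.
#' @return Numeric: the signed energy difference, kJ/mol.
#' @export
#' @examples
#' delta_e(-500, -100, -250) # -150
delta_e <- function(e_assembly, e_guest, e_cd1, e_cd2 = NULL) {
  out <- e_assembly - e_guest - e_cd1
  if (!is.null(e_cd2)) {
    out <- out - ifelse(is.na(e_cd2), 0, e_cd2)
  }
  out
}

#' Enumerate the one-site mutants of a methylation state
#'
#' Child `k` inverts the methylation of site `k` only, so a 1-CD state has
#' exactly 21 children and a 2-CD state 42, ordered by site id. Applying the
#' same inversion twice restores the parent (the move set is an involution).
#'
#' @param state Logical state vector (length 21 or 42).
#' @return List of logical vectors, one per site, each Hamming distance 1
#'   from `state`.
#' @export
enumerate_children <- function(state) {
  state <- check_state(state)
  lapply(seq_along(state), function(k) {
    child <- state
    child[k] <- !child[k]
    child
  })
}

#' Select the generation-0 model per insertion combination
#'
#' Given candidate (moiety, insertion-side, well-defined-CD) models with
#' their complexation energies, keeps for every (moiety, side) group the
#' candidate with the most negative energy difference; ties resolve to the
#' lexicographically smallest CD label. These winners seed the series trees.
#'
#' @param candidates Tibble with columns `moiety`, `side`, `cd_label`,
#'   `delta_e` (kJ/mol); extra columns are carried through.
#' @return Tibble with one row per (moiety, side) group.
#' @export
select_g0 <- function(candidates) {
  need <- c("moiety", "side", "cd_label", "delta_e")
  if (!all(need %in% names(candidates))) {
    abort("candidates need columns moiety, side, cd_label, delta_e")
  }
  if (!nrow(candidates)) abort("no candidates supplied")
  candidates |>
    dplyr::group_by(.data$moiety, .data$side) |>
    dplyr::arrange(.data$delta_e, .data$cd_label, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
}

#' The six well-defined methylated beta-CD starting patterns
#'
#' Each pattern methylates the same position set on all seven glucose units:
#' 2-Me, 3-Me, 6-Me and the three di-methyl combinations.
#'
#' @param n_cd 1 or 2; for 2 the same pattern is applied to both CDs.
#' @return Named list of logical state vectors.
#' @export
well_defined_states <- function(n_cd = 1) {
  pats <- list(
    "2-Me" = 2L, "3-Me" = 3L, "6-Me" = 6L,
    "2,3-diMe" = c(2L, 3L), "2,6-diMe" = c(2L, 6L), "3,6-diMe" = c(3L, 6L)
  )
  lapply(pats, function(pos) {
    bits <- rep(FALSE, 21L)
    bits[glucose_to_site(rep(1:7, each = length(pos)), rep(pos, times = 7))] <- TRUE
    if (n_cd == 2) bits <- c(bits, bits)
    bits
  })
}

eval_oracle <- function(oracle, state) {
  e <- oracle(state)
  need <- c("e_assembly", "e_guest", "e_cd1")
  if (!all(need %in% names(e))) {
    abort("oracle must return e_assembly, e_guest, e_cd1 (and e_cd2 for 2-CD)")
  }
  e_cd2 <- if ("e_cd2" %in% names(e)) as.numeric(e[["e_cd2"]]) else NA_real_
  vals <- c(as.numeric(e[["e_assembly"]]), as.numeric(e[["e_guest"]]),
            as.numeric(e[["e_cd1"]]))
  if (anyNA(vals) || any(!is.finite(vals))) {
    abort(sprintf("energy oracle failed on state %s", format_state(state)))
  }
  list(e_assembly = vals[1], e_guest = vals[2], e_cd1 = vals[3], e_cd2 = e_cd2,
       delta_e = delta_e(vals[1], vals[2], vals[3],
                         if (is.na(e_cd2)) NULL else e_cd2))
}

#' Grow a greedy methylation mutation tree
#'
#' Starting from a generation-0 state, every generation inverts the
#' methylation of each site of the current expansion node in turn (21
#' children for 1-CD systems, 42 for 2-CD), scores each child through the
#' energy oracle, and expands the lowest-dE child of the new generation to
#' create the next one. Exploration stops after `patience` consecutive
#' generations fail to improve the best dE seen, or at `max_generations`.
#' Ties on dE resolve to the lowest site id. Node ids are assigned
#' sequentially in creation order.
#'
#' @param oracle Energy oracle: a function taking a logical state vector and
#'   returning a list/vector with `e_assembly`, `e_guest`, `e_cd1` (and
#'   `e_cd2` for 2-CD systems), heats of formation in kJ/mol. Must be
#'   deterministic. See [make_oracle()] and [oracle_from_table()].
#' @param g0_state Logical state vector of the generation-0 model.
#' @param patience Consecutive non-improving generations tolerated before
#'   stopping (default 4).
#' @param max_generations Hard cap on the number of generations expanded.
#' @param id_base First node id (default 1).
#' @param series Optional series label carried into the output.
#' @return A tibble of class `cd_tree`, one row per evaluated model:
#'   `id`, `parent_id`, `generation`, `series`, `state` (0/1 string),
#'   `e_assembly`, `e_guest`, `e_cd1`, `e_cd2`, `delta_e`, `deltadelta`
#'   (dE minus parent dE; NA for G0).
#' @export
run_tree <- function(oracle, g0_state, patience = 4, max_generations = 100,
                     id_base = 1, series = NA_character_) {
  g0_state <- check_state(g0_state)
  if (patience < 0) abort("patience must be >= 0")
  e0 <- eval_oracle(oracle, g0_state)
  rows <- list(tibble::tibble(
    id = as.integer(id_base), parent_id = NA_integer_, generation = 0L,
    series = series, state = format_state(g0_state),
    e_assembly = e0$e_assembly, e_guest = e0$e_guest,
    e_cd1 = e0$e_cd1, e_cd2 = e0$e_cd2,
    delta_e = e0$delta_e, deltadelta = NA_real_
  ))
  next_id <- as.integer(id_base) + 1L
  expand_state <- g0_state
  expand_id <- as.integer(id_base)
  expand_de <- e0$delta_e
  best_de <- e0$delta_e
  stall <- 0L
  gen <- 0L
  while (gen < max_generations && stall < patience) {
    gen <- gen + 1L
    children <- enumerate_children(expand_state)
    evals <- lapply(children, function(s) eval_oracle(oracle, s))
    des <- vapply(evals, `[[`, numeric(1), "delta_e")
    ids <- next_id + seq_along(children) - 1L
    rows[[length(rows) + 1L]] <- tibble::tibble(
      id = ids, parent_id = expand_id, generation = gen, series = series,
      state = vapply(children, format_state, character(1)),
      e_assembly = vapply(evals, `[[`, numeric(1), "e_assembly"),
      e_guest = vapply(evals, `[[`, numeric(1), "e_guest"),
      e_cd1 = vapply(evals, `[[`, numeric(1), "e_cd1"),
      e_cd2 = vapply(evals, `[[`, numeric(1), "e_cd2"),
      delta_e = des,
      deltadelta = des - expand_de
    )
    next_id <- next_id + length(children)
    k <- which.min(des)
    if (des[k] < best_de) {
      best_de <- des[k]
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    expand_state <- children[[k]]
    expand_id <- ids[k]
    expand_de <- des[k]
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cd_tree", class(out))
  out
}

as_cd_tree <- function(x) {
  if (!inherits(x, "cd_tree")) class(x) <- c("cd_tree", class(x))
  x
}

#' Main route of a tree
#'
#' The unique parent chain from the lowest-dE node back to generation 0,
#' returned G0-first. A tie for the best node resolves to the lowest id with
#' a warning.
#'
#' @param tree A `cd_tree` tibble (or any tibble with the same columns).
#' @return Tibble of the route nodes ordered by generation.
#' @export
main_route <- function(tree) {
  best <- min(tree$delta_e)
  cand <- tree$id[tree$delta_e == best]
  if (length(cand) > 1) {
    warn(sprintf("%d nodes tie for best delta_e; taking lowest id %d",
                 length(cand), min(cand)))
  }
  id <- min(cand)
  route <- integer()
  repeat {
    route <- c(id, route)
    parent <- tree$parent_id[match(id, tree$id)]
    if (is.na(parent)) break
    if (!parent %in% tree$id) abort(sprintf("node %d has missing parent %d", id, parent))
    id <- parent
  }
  as_cd_tree(tree[match(route, tree$id), ])
}

#' Rank tree experiments by their generation-over-generation energy change
#'
#' Orders all non-root experiments by `deltadelta` ascending (the most
#' stabilizing single inversion first), ties by id. Sorting on this field is
#' how anomalously large stabilizations - the signature of clamp formation -
#' are surfaced from a series database.
#'
#' @param tree A `cd_tree` tibble.
#' @return The non-root rows, ordered.
#' @export
rank_by_deltadelta <- function(tree) {
  tree |>
    dplyr::filter(!is.na(.data$deltadelta)) |>
    dplyr::arrange(.data$deltadelta, .data$id)
}

#' File-backed energy oracle
#'
#' Wraps a lookup table of precomputed energies (for example a series
#' database export) as an energy oracle, letting [run_tree()] replay
#' recorded evaluations.
#'
#' @param table Tibble with columns `state` (0/1 string), `e_assembly`,
#'   `e_guest`, `e_cd1`, and optionally `e_cd2`.
#' @return An oracle function; it errors on states absent from the table.
#' @export
oracle_from_table <- function(table) {
  need <- c("state", "e_assembly", "e_guest", "e_cd1")
  if (!all(need %in% names(table))) {
    abort("oracle table needs columns state, e_assembly, e_guest, e_cd1")
  }
  has_cd2 <- "e_cd2" %in% names(table)
  function(state) {
    key <- format_state(check_state(state))
    i <- match(key, table$state)
    if (is.na(i)) abort(sprintf("state %s not present in oracle table", key))
    list(
      e_assembly = table$e_assembly[i], e_guest = table$e_guest[i],
      e_cd1 = table$e_cd1[i],
      e_cd2 = if (has_cd2) table$e_cd2[i] else NA_real_
    )
  }
}
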