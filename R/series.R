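#' Save a tree-experiment table to CSV
#'
#' Writes the column contract shared with [load_database()]: `id`,
#' `parent_id`, `generation`, `series`, `state` (0/1 string), the four
#' component energies, `delta_e` and `deltadelta`.
#'
#' @param tree A `cd_tree` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  cols <- c("id", "parent_id", "generation", "series", "state",
            "e_assembly", "e_guest", "e_cd1", "e_cd2", "delta_e", "deltadelta")
  readr::write_csv(tree[, intersect(cols, names(tree))], path)
  invisible(path)
}

#' Load a tree-experiment database export
#'
#' Reads a CSV of tree experiments (the [write_tree()] contract, or an
#' external export mapped onto it via `col_map`) and validates the tree
#' structure: unique ids and no orphan parent references.
#'
#' @param path CSV path.
#' @param col_map Optional named character vector mapping contract column
#'   names to the file's column names, e.g.
#'   `c(deltadelta = "ddE", id = "model_id")`.
#' @return A `cd_tree` tibble.
#' @export
load_database <- function(path, col_map = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      if (!col_map[[std]] %in% names(df)) {
        abort(sprintf("mapped column '%s' not in file", col_map[[std]]))
      }
      names(df)[names(df) == col_map[[std]]] <- std
    }
  }
  need <- c("id", "parent_id", "generation", "state", "delta_e")
  if (!all(need %in% names(df))) {
    abort(sprintf("database missing columns: %s",
                  paste(setdiff(need, names(df)), collapse = ", ")))
  }
  df$id <- as.integer(df$id)
  df$parent_id <- as.integer(df$parent_id)
  dup <- df$id[duplicated(df$id)]
  if (length(dup)) {
    abort(sprintf("duplicate ids: %s", paste(unique(dup), collapse = ", ")))
  }
  orphan <- setdiff(df$parent_id[!is.na(df$parent_id)], df$id)
  if (length(orphan)) {
    abort(sprintf("orphan parent ids: %s", paste(orphan, collapse = ", ")))
  }
  as_cd_tree(tibble::as_tibble(df))
}

state_matrix <- function(states) {
  do.call(rbind, lapply(states, function(s) as.integer(parse_state(s))))
}

#' Summarize one series tree
#'
#' Computes the per-series statistics of the tree bookkeeping: the
#' generation-0 and best energies, the average energy over all experiments,
#' generations reached, and methylation statistics over the "improved" set -
#' experiments whose dE is strictly below the G0 value. Average methylation
#' (mean methyls per glucose unit) is reported per CD slot; the methylation
#' domain is the min-max rate over improved models, pooled across slots for
#' 2-CD series. `n_free_cds` counts distinct per-CD methylation-state
#' vectors across the whole series, pooling the two slots of 2-CD models
#' (each freed CD is a candidate CD in its own right).
#'
#' @param tree A `cd_tree` tibble for a single series.
#' @param g0_id Id of the generation-0 experiment; defaults to the root
#'   (the node without a parent).
#' @return A one-row tibble (class `cd_series_summary`).
#' @export
summarize_series <- function(tree, g0_id = NULL) {
  if (is.null(g0_id)) {
    roots <- tree$id[is.na(tree$parent_id)]
    if (length(roots) != 1) abort("tree must have exactly one root or an explicit g0_id")
    g0_id <- roots
  }
  ig0 <- match(g0_id, tree$id)
  if (is.na(ig0)) abort(sprintf("g0 id %s not present in tree", g0_id))
  de_g0 <- tree$delta_e[ig0]
  best_i <- which.min(tree$delta_e)
  n_bits <- nchar(tree$state[1])
  n_cd <- n_bits %/% 21L

  bits <- state_matrix(tree$state)
  improved <- tree$delta_e < de_g0
  rate_slot <- function(rows, slot) {
    cols <- ((slot - 1L) * 21L + 1L):(slot * 21L)
    rowSums(bits[rows, cols, drop = FALSE]) / 7
  }
  avg_me <- if (any(improved)) {
    vapply(seq_len(n_cd), function(s) mean(rate_slot(improved, s)), numeric(1))
  } else {
    rep(NA_real_, n_cd)
  }
  dom <- if (any(improved)) {
    range(unlist(lapply(seq_len(n_cd), function(s) rate_slot(improved, s))))
  } else {
    c(NA_real_, NA_real_)
  }
  per_cd_states <- unlist(lapply(seq_len(n_cd), function(s) {
    cols <- ((s - 1L) * 21L + 1L):(s * 21L)
    apply(bits[, cols, drop = FALSE], 1, paste, collapse = "")
  }))
  out <- tibble::tibble(
    series = tree$series[1] %||% NA_character_,
    delta_e_g0 = de_g0,
    average_delta_e = mean(tree$delta_e),
    best_delta_e = tree$delta_e[best_i],
    max_g = max(tree$generation),
    g_best = tree$generation[best_i],
    average_me_cd1 = avg_me[1],
    average_me_cd2 = if (n_cd == 2) avg_me[2] else NA_real_,
    me_domain_min = dom[1],
    me_domain_max = dom[2],
    n_improved = sum(improved),
    n_samples = nrow(tree),
    n_free_cds = length(unique(per_cd_states))
  )
  class(out) <- c("cd_series_summary", class(out))
  out
}

#' Per-generation energy trace along the main route
#'
#' The route from G0 to the best model with the dE reached at each
#' generation - the standard way to display a series tree. Endpoints equal
#' the G0 and best energies of [summarize_series()].
#'
#' @param tree A `cd_tree` tibble.
#' @return Tibble with columns `generation`, `delta_e`, `id`, `state`.
#' @export
fig_trace <- function(tree) {
  route <- main_route(tree)
  tibble::tibble(
    generation = route$generation,
    delta_e = route$delta_e,
    id = route$id,
    state = route$state
  )
}

#' Plot the main-route energy trace of one or more trees
#'
#' @param object A `cd_tree` tibble (possibly several series bound together,
#'   distinguished by the `series` column).
#' @param ... Unused.
#' @return A ggplot object: dE (kJ/mol) against generation along each
#'   series' main route.
#' @exportS3Method ggplot2::autoplot
autoplot.cd_tree <- function(object, ...) {
  traces <- object |>
    dplyr::group_by(.data$series) |>
    dplyr::group_modify(~ fig_trace(as_cd_tree(.x))) |>
    dplyr::ungroup()
  ggplot2::ggplot(traces, ggplot2::aes(x = .data$generation, y = .data$delta_e,
                                       colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "generation", y = expression(Delta * E ~ "(kJ/mol)"),
                  colour = "series") +
    ggplot2::theme_minimal()
}
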