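#' Map a substitution-site id to its glucose unit and position
#'
#' A beta-cyclodextrin has 7 glucose units, each carrying substitutable
#' oxygens at positions 2, 3 and 6, giving 21 sites per CD. Sites are
#' numbered contiguously around the ring: site `s` lies on glucose unit
#' `ceiling(s / 3)` at position `c(2, 3, 6)[(s - 1) %% 3 + 1]`. This is the
#' unique contiguous scheme under which the site pairs (19, 20) and (10, 11)
#' are each the position-2/position-3 pair of one anhydroglucose unit, as
#' required for clamp bookkeeping. For sites on a second CD (ids 22-42),
#' subtract 21 first.
#'
#' @param site_id Integer vector of site ids in 1..21.
#' @return A tibble with columns `site_id`, `glucose_unit` (1..7) and
#'   `position` (2, 3 or 6).
#' @export
#' @examples
#' site_to_glucose(c(19, 20)) # positions 2 and 3 of glucose unit 7
site_to_glucose <- function(site_id) {
  site_id <- as.integer(site_id)
  if (any(is.na(site_id) | site_id < 1L | site_id > 21L)) {
    abort("site_id must lie in 1..21 (subtract 21 for second-CD sites)")
  }
  tibble::tibble(
    site_id = site_id,
    glucose_unit = (site_id - 1L) %/% 3L + 1L,
    position = c(2L, 3L, 6L)[(site_id - 1L) %% 3L + 1L]
  )
}

#' Inverse of [site_to_glucose()]
#'
#' @param glucose_unit Integer vector in 1..7.
#' @param position Integer vector with values in {2, 3, 6}.
#' @return Integer vector of site ids in 1..21.
#' @export
glucose_to_site <- function(glucose_unit, position) {
  glucose_unit <- as.integer(glucose_unit)
  pos_idx <- match(as.integer(position), c(2L, 3L, 6L))
  if (any(is.na(glucose_unit) | glucose_unit < 1L | glucose_unit > 7L) ||
      any(is.na(pos_idx))) {
    abort("glucose_unit must be in 1..7 and position one of 2, 3, 6")
  }
  (glucose_unit - 1L) * 3L + pos_idx
}

#' Attach a sidecar annotation to an atom table
#'
#' The sidecar (JSON; written by [make_geometry()] and hand-writable for
#' external models) supplies everything that cannot be perceived reliably
#' from bare coordinates: molecule membership (guest / CD1 / CD2), the
#' mapping of the 21 substitution sites per CD to their oxygen and
#' substituent atoms, the CD ether and anomeric acceptor oxygens, and the
#' guest's functional roles (Fe atom, phenol O-H pairs, imide carbonyl
#' oxygens, moiety atom sets).
#'
#' @param atoms Atom tibble from [read_xyz()].
#' @param sidecar Path to a sidecar JSON file, or an already-parsed list.
#' @return An object of class `cd_model`: a list with elements
#'   \describe{
#'     \item{atoms}{the atom tibble with a `membership` column added
#'       (`"guest"`, `"cd1"` or `"cd2"`),}
#'     \item{topology}{one row per substitution site: `site_id` (global,
#'       1..21 for CD1, 22..42 for CD2), `cd`, `glucose_unit`, `position`,
#'       `oxygen`, `substituent` (atom indices),}
#'     \item{cd_acceptors}{ether/anomeric oxygens: `index`, `cd`, `class`,}
#'     \item{guest}{list with `fe`, `ph1`, `ph2`, `imide_o`, `moieties`,}
#'     \item{n_cd}{1 or 2.}
#'   }
#' @export
annotate <- function(atoms, sidecar) {
  sc <- if (is.character(sidecar)) {
    jsonlite::read_json(sidecar, simplifyVector = TRUE)
  } else {
    sidecar
  }
  n <- nrow(atoms)
  n_cd <- as.integer(sc$n_cd %||% 1L)
  if (!n_cd %in% c(1L, 2L)) abort("sidecar n_cd must be 1 or 2")

  mem_idx <- list(
    guest = as.integer(sc$membership$guest),
    cd1 = as.integer(sc$membership$cd1),
    cd2 = as.integer(sc$membership$cd2 %||% integer())
  )
  all_idx <- unlist(mem_idx)
  if (any(all_idx < 1L | all_idx > n)) {
    abort("sidecar membership index out of atom range")
  }
  if (anyDuplicated(all_idx) || length(all_idx) != n) {
    abort("sidecar membership must label every atom exactly once")
  }
  if (n_cd == 1L && length(mem_idx$cd2)) {
    abort("n_cd = 1 but sidecar labels CD2 atoms")
  }
  membership <- character(n)
  membership[mem_idx$guest] <- "guest"
  membership[mem_idx$cd1] <- "cd1"
  membership[mem_idx$cd2] <- "cd2"
  atoms$membership <- membership

  sites <- if (is.data.frame(sc$sites)) {
    tibble::as_tibble(sc$sites)
  } else {
    dplyr::bind_rows(lapply(sc$sites, tibble::as_tibble))
  }
  if (!all(c("site_id", "oxygen", "substituent") %in% names(sites))) {
    abort("sidecar sites need columns site_id, oxygen, substituent")
  }
  sites <- dplyr::mutate(sites, dplyr::across(dplyr::everything(), as.integer))
  expected <- seq_len(21L * n_cd)
  if (nrow(sites) != length(expected) ||
      !setequal(sites$site_id, expected) || anyDuplicated(sites$site_id)) {
    abort(sprintf(
      "sidecar must assign each of the %d site ids exactly once (duplicate or missing site)",
      length(expected)
    ))
  }
  if (any(sites$oxygen < 1L | sites$oxygen > n) ||
      any(sites$substituent < 1L | sites$substituent > n)) {
    abort("sidecar site atom index out of range")
  }
  local_id <- (sites$site_id - 1L) %% 21L + 1L
  cd <- (sites$site_id - 1L) %/% 21L + 1L
  gp <- site_to_glucose(local_id)
  topology <- tibble::tibble(
    site_id = sites$site_id,
    cd = cd,
    glucose_unit = gp$glucose_unit,
    position = gp$position,
    oxygen = sites$oxygen,
    substituent = sites$substituent
  )
  topology <- dplyr::arrange(topology, .data$site_id)
  # site oxygens must live on their own CD
  cd_lab <- paste0("cd", topology$cd)
  if (any(membership[topology$oxygen] != cd_lab)) {
    abort("sidecar site oxygen not labelled as its CD")
  }

  acc <- sc$cd_acceptors %||% list()
  cd_acceptors <- dplyr::bind_rows(
    tibble::tibble(index = as.integer(acc$ether %||% integer()), class = "cd_ether_O"),
    tibble::tibble(index = as.integer(acc$anomeric %||% integer()), class = "cd_anomeric_O")
  )
  if (nrow(cd_acceptors)) {
    if (any(cd_acceptors$index < 1L | cd_acceptors$index > n)) {
      abort("sidecar cd_acceptors index out of range")
    }
    cd_acceptors$cd <- match(membership[cd_acceptors$index], c("cd1", "cd2"))
    if (anyNA(cd_acceptors$cd)) abort("cd acceptor oxygen not labelled as a CD atom")
  } else {
    cd_acceptors <- tibble::tibble(index = integer(), class = character(), cd = integer())
  }

  g <- sc$guest
  fe <- as.integer(g$fe)
  if (length(fe) != 1L || is.na(fe) || membership[fe] != "guest") {
    abort("sidecar guest$fe must be a single atom labelled guest")
  }
  guest <- list(
    fe = fe,
    ph1 = list(o = as.integer(g$ph1$o), h = as.integer(g$ph1$h)),
    ph2 = list(o = as.integer(g$ph2$o), h = as.integer(g$ph2$h)),
    imide_o = as.integer(g$imide_o),
    moieties = lapply(g$moieties, as.integer)
  )
  msets <- guest$moieties
  if (length(msets)) {
    pooled <- unlist(msets, use.names = FALSE)
    if (anyDuplicated(pooled)) abort("guest moiety atom sets must be disjoint")
    if (!is.null(msets$fc) && !fe %in% msets$fc) {
      abort("guest fe atom must belong to the fc moiety set")
    }
  }

  structure(
    list(atoms = atoms, topology = topology, cd_acceptors = cd_acceptors,
         guest = guest, n_cd = n_cd),
    class = "cd_model"
  )
}

#' @export
print.cd_model <- function(x, ...) {
  counts <- table(x$atoms$membership)
  cat(sprintf(
    "<cd_model> %d atoms (%s), %d CD(s), %d substitution sites\n",
    nrow(x$atoms),
    paste(sprintf("%s: %d", names(counts), counts), collapse = ", "),
    x$n_cd, nrow(x$topology)
  ))
  st <- extract_methylation_state(x)
  cat(sprintf(
    "methylation: %d/%d sites (%s)\n",
    sum(st), length(st), format_state(st)
  ))
  invisible(x)
}

#' Read the methylation state off an annotated geometry
#'
#' Each substitution site bears either a hydroxyl hydrogen or a methyl
#' carbon; the element of the substituent atom decides the bit (C = true =
#' methylated, H = false = hydroxyl).
#'
#' @param model A `cd_model` from [annotate()].
#' @return A logical vector of length 21 (1 CD) or 42 (2 CDs), named by
#'   global site id; `TRUE` means methylated.
#' @export
extract_methylation_state <- function(model) {
  el <- model$atoms$element[model$topology$substituent]
  if (!all(el %in% c("H", "C"))) {
    bad <- model$topology$site_id[!el %in% c("H", "C")][1]
    abort(sprintf("substituent of site %d is neither H nor C", bad))
  }
  setNames(el == "C", model$topology$site_id)
}

#' Per-CD methylation rate of a state
#'
#' @param state Logical state vector (length 21 or 42).
#' @return Numeric vector, one value per CD: methyl count / 7 (mean methyls
#'   per glucose unit, in 0..3).
#' @export
methylation_rate <- function(state) {
  state <- check_state(state)
  n_cd <- length(state) %/% 21L
  vapply(seq_len(n_cd), function(k) {
    sum(state[((k - 1L) * 21L + 1L):(k * 21L)]) / 7
  }, numeric(1))
}

check_state <- function(state) {
  if (!is.logical(state) || !length(state) %in% c(21L, 42L) || anyNA(state)) {
    abort("state must be a logical vector of length 21 or 42 with no NA")
  }
  state
}

format_state <- function(state) paste(as.integer(state), collapse = "")

parse_state <- function(s) {
  bits <- strsplit(s, "")[[1]]
  if (!all(bits %in% c("0", "1"))) abort("state string must be 0/1 characters")
  check_state(bits == "1")
}
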