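#' Specification for a synthetic host-guest geometry fixture
#'
#' Describes a stylized 1- or 2-CD assembly: seven pseudo-glucose fragments
#' per CD on a ring (each carrying position-2/3/6 oxygens with an H or CH3
#' substituent, plus ether and anomeric ring oxygens) and a guest bearing an
#' Fe atom with a small carbon ring (Fc), two phenol O-H groups, and two
#' imide carbonyl oxygens. Planted contacts reposition the donor hydrogen
#' (and its heavy atom) on the line towards the requested acceptor so the
#' H...acceptor distance is met exactly. The fixtures are geometric test
#' articles, not chemically realistic conformers: the detection engine only
#' needs correctly classed atoms at controlled distances.
#'
#' @param n_cd 1 or 2.
#' @param state Logical methylation state (length 21 * n_cd); default all
#'   hydroxyl.
#' @param contacts List of planted contacts, each a list with `donor` (a
#'   global site id, or `"ph1"`/`"ph2"` for a guest phenol donor),
#'   `acceptor` (one of `"fe"`, `"phenol_o:1"`, `"phenol_o:2"`,
#'   `"imide_o:1"`, `"imide_o:2"`, `"cd_hydroxyl:<site>"`,
#'   `"cd_ether:<cd>:<unit>"`, `"cd_anomeric:<cd>:<unit>"`) and `distance`
#'   (H...acceptor, Angstrom).
#' @param ring_radius CD ring radius, Angstrom.
#' @param jitter_sd Gaussian positional jitter (Angstrom) applied to atoms
#'   not involved in planted contacts; 0 keeps the layout exact.
#' @param seed Seed for the jitter.
#' @return A `geometry_spec` list.
#' @export
geometry_spec <- function(n_cd = 1, state = rep(FALSE, 21 * n_cd),
                          contacts = list(), ring_radius = 6,
                          jitter_sd = 0, seed = 1) {
  state <- check_state(state)
  if (length(state) != 21L * n_cd) abort("state length must be 21 * n_cd")
  for (ct in contacts) {
    if (!is.numeric(ct$distance) || ct$distance <= 0) {
      abort("planted contact distance must be > 0")
    }
  }
  structure(list(n_cd = as.integer(n_cd), state = state, contacts = contacts,
                 ring_radius = ring_radius, jitter_sd = jitter_sd,
                 seed = as.integer(seed)),
            class = "geometry_spec")
}

unit_vec <- function(v) v / sqrt(sum(v^2))

#' Build a synthetic annotated geometry
#'
#' Realizes a [geometry_spec()] as an annotated model. Every planted contact
#' is realized with its H...acceptor distance exact to machine precision;
#' all other donor/acceptor pairs are laid out several Angstrom apart so
#' that nothing else falls under a 2 Angstrom cutoff.
#'
#' @param spec A `geometry_spec`.
#' @return List with elements `model` (a `cd_model`), `atoms` (the raw atom
#'   tibble), `sidecar` (the annotation list), and `spec`.
#' @seealso [write_geometry()] to persist the XYZ + JSON pair.
#' @export
make_geometry <- function(spec) {
  stopifnot(inherits(spec, "geometry_spec"))
  R <- spec$ring_radius
  atoms <- list()   # rows: element, x, y, z
  push <- function(element, pos) {
    atoms[[length(atoms) + 1L]] <<- list(element = element,
                                         x = pos[1], y = pos[2], z = pos[3])
    length(atoms)
  }

  # --- guest -----------------------------------------------------------
  fe <- push("Fe", c(0, 0, 4))
  fc_c <- vapply(0:4, function(k) {
    th <- 2 * pi * k / 5
    push("C", c(1.7 * cos(th), 1.7 * sin(th), 5.2))
  }, integer(1))
  ph1_c <- push("C", c(0, -2.2, 6.2))
  ph1_o <- push("O", c(0, -2.9, 7.0))
  ph1_h <- push("H", c(0, -2.9, 7.0) + 0.96 * unit_vec(c(0, -0.66, 0.75)))
  ph2_c <- push("C", c(0, 2.2, 6.2))
  ph2_o <- push("O", c(0, 2.9, 7.0))
  ph2_h <- push("H", c(0, 2.9, 7.0) + 0.96 * unit_vec(c(0, 0.66, 0.75)))
  succ_c1 <- push("C", c(1.3, 0, 7.6))
  im_o1 <- push("O", c(2.4, 0, 8.0))
  succ_c2 <- push("C", c(-1.3, 0, 7.6))
  im_o2 <- push("O", c(-2.4, 0, 8.0))
  guest_idx <- c(fe, fc_c, ph1_c, ph1_o, ph1_h, ph2_c, ph2_o, ph2_h,
                 succ_c1, im_o1, succ_c2, im_o2)

  # --- cyclodextrins ---------------------------------------------------
  sites <- list()
  ether_idx <- list()
  anomeric_idx <- list()
  cd_idx <- list()
  for (k in seq_len(spec$n_cd)) {
    z0 <- (k - 1) * 10
    first <- length(atoms) + 1L
    for (g in 1:7) {
      th <- 2 * pi * (g - 1) / 7
      dir <- c(cos(th), sin(th), 0)
      dir3 <- c(cos(th + 0.3), sin(th + 0.3), 0)
      push("C", R * dir + c(0, 0, z0))
      anomeric_idx[[length(anomeric_idx) + 1L]] <-
        push("O", R * c(cos(th + pi / 7), sin(th + pi / 7), 0) + c(0, 0, z0))
      ether_idx[[length(ether_idx) + 1L]] <-
        push("O", R * dir + c(0, 0, z0 - 1.2))
      place_site <- function(pos_label, o_pos, out_dir) {
        site_local <- glucose_to_site(g, pos_label)
        site_global <- (k - 1L) * 21L + site_local
        methylated <- spec$state[site_global]
        o <- push("O", o_pos)
        sub_len <- if (methylated) 1.43 else 0.96
        sub_el <- if (methylated) "C" else "H"
        s <- push(sub_el, o_pos + sub_len * out_dir)
        sites[[length(sites) + 1L]] <<- list(site_id = site_global,
                                             oxygen = o, substituent = s)
      }
      place_site(2L, (R + 1.2) * dir + c(0, 0, z0 + 1.0), unit_vec(c(dir[1:2], 0.4)))
      place_site(3L, (R + 1.2) * dir3 + c(0, 0, z0 + 1.4), unit_vec(c(dir3[1:2], 0.4)))
      place_site(6L, (R + 1.0) * dir + c(0, 0, z0 - 1.6), unit_vec(c(dir[1:2], -0.4)))
    }
    cd_idx[[k]] <- first:length(atoms)
  }
  atoms <- dplyr::bind_rows(lapply(atoms, tibble::as_tibble))
  atoms <- tibble::tibble(index = seq_len(nrow(atoms)), atoms)
  site_tab <- dplyr::bind_rows(lapply(sites, tibble::as_tibble))
  site_tab <- dplyr::arrange(site_tab, .data$site_id)

  # optional jitter on atoms not pinned by planted contacts
  pinned <- integer()
  get_pos <- function(i) c(atoms$x[i], atoms$y[i], atoms$z[i])
  set_pos <- function(i, p) {
    atoms$x[i] <<- p[1]; atoms$y[i] <<- p[2]; atoms$z[i] <<- p[3]
  }
  resolve_acceptor <- function(a) {
    if (identical(a, "fe")) return(fe)
    parts <- strsplit(a, ":")[[1]]
    switch(parts[1],
      phenol_o = c(ph1_o, ph2_o)[as.integer(parts[2])],
      imide_o = c(im_o1, im_o2)[as.integer(parts[2])],
      cd_hydroxyl = {
        s <- as.integer(parts[2])
        site_tab$oxygen[match(s, site_tab$site_id)]
      },
      cd_ether = {
        k <- as.integer(parts[2]); g <- as.integer(parts[3])
        unlist(ether_idx)[(k - 1L) * 7L + g]
      },
      cd_anomeric = {
        k <- as.integer(parts[2]); g <- as.integer(parts[3])
        unlist(anomeric_idx)[(k - 1L) * 7L + g]
      },
      abort(sprintf("unknown acceptor '%s'", a))
    )
  }
  for (ct in spec$contacts) {
    acc <- resolve_acceptor(ct$acceptor)
    if (is.na(acc)) abort("contact acceptor could not be resolved")
    a_pos <- get_pos(acc)
    if (is.numeric(ct$donor)) {
      i <- match(as.integer(ct$donor), site_tab$site_id)
      if (is.na(i)) abort(sprintf("donor site %s not in topology", ct$donor))
      if (spec$state[site_tab$site_id[i]]) {
        abort(sprintf("site %d is methylated: no hydroxyl hydrogen to plant",
                      site_tab$site_id[i]))
      }
      o_atom <- site_tab$oxygen[i]
      h_atom <- site_tab$substituent[i]
    } else if (ct$donor %in% c("ph1", "ph2")) {
      o_atom <- if (ct$donor == "ph1") ph1_o else ph2_o
      h_atom <- if (ct$donor == "ph1") ph1_h else ph2_h
    } else {
      abort(sprintf("unknown donor '%s'", ct$donor))
    }
    u <- unit_vec(get_pos(o_atom) - a_pos)
    set_pos(h_atom, a_pos + ct$distance * u)
    set_pos(o_atom, a_pos + (ct$distance + 0.96) * u)
    pinned <- c(pinned, o_atom, h_atom, acc)
  }
  if (spec$jitter_sd > 0) {
    free <- setdiff(atoms$index, pinned)
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(spec$seed)
    atoms$x[free] <- atoms$x[free] + rnorm(length(free), 0, spec$jitter_sd)
    atoms$y[free] <- atoms$y[free] + rnorm(length(free), 0, spec$jitter_sd)
    atoms$z[free] <- atoms$z[free] + rnorm(length(free), 0, spec$jitter_sd)
  }
  # verify planted distances
  for (ct in spec$contacts) {
    acc <- resolve_acceptor(ct$acceptor)
    h_atom <- if (is.numeric(ct$donor)) {
      site_tab$substituent[match(as.integer(ct$donor), site_tab$site_id)]
    } else if (ct$donor == "ph1") ph1_h else ph2_h
    d <- sqrt(sum((get_pos(h_atom) - get_pos(acc))^2))
    if (abs(d - ct$distance) > 1e-6) {
      abort("planted contact could not be realized to 1e-6 Angstrom")
    }
  }

  sidecar <- list(
    n_cd = spec$n_cd,
    membership = list(guest = guest_idx, cd1 = cd_idx[[1]],
                      cd2 = if (spec$n_cd == 2) cd_idx[[2]] else integer()),
    sites = lapply(seq_len(nrow(site_tab)), function(i) {
      list(site_id = site_tab$site_id[i], oxygen = site_tab$oxygen[i],
           substituent = site_tab$substituent[i])
    }),
    cd_acceptors = list(ether = unlist(ether_idx), anomeric = unlist(anomeric_idx)),
    guest = list(
      fe = fe,
      ph1 = list(o = ph1_o, h = ph1_h),
      ph2 = list(o = ph2_o, h = ph2_h),
      imide_o = c(im_o1, im_o2),
      moieties = list(
        fc = c(fe, fc_c),
        ph1 = c(ph1_c, ph1_o, ph1_h),
        ph2 = c(ph2_c, ph2_o, ph2_h),
        succ = c(succ_c1, im_o1, succ_c2, im_o2)
      )
    )
  )
  attr(atoms, "comment") <- sprintf("synthetic %d-CD fixture", spec$n_cd)
  class(atoms) <- c("cd_atoms", class(atoms))
  model <- annotate(atoms, sidecar)
  list(model = model, atoms = atoms, sidecar = sidecar, spec = spec)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Write a generated geometry to an XYZ file and its sidecar JSON
#'
#' @param gen Result of [make_geometry()].
#' @param dir Output directory (created if missing).
#' @param name Basename for the `.xyz`/`.json` pair.
#' @return Named character vector with paths `xyz` and `sidecar`.
#' @export
write_geometry <- function(gen, dir, name = "model") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  xyz <- file.path(dir, paste0(name, ".xyz"))
  sidecar <- file.path(dir, paste0(name, ".json"))
  write_xyz(gen$atoms, xyz)
  jsonlite::write_json(gen$sidecar, sidecar, auto_unbox = TRUE, digits = NA)
  c(xyz = xyz, sidecar = sidecar)
}

#' Specification for a synthetic energy landscape
#'
#' Defines an additive-plus-interactions landscape over methylation states,
#' used by [make_oracle()]: per-site energy terms, optional symmetric
#' pairwise interaction terms, and an optional clamp bonus added when the
#' position-2 and position-3 sites of a designated glucose unit are both
#' unmethylated (emulating the formation of an Fe clamp upon demethylation
#' and its breaking upon re-methylation).
#'
#' @param site_terms Numeric vector (length 21 or 42), kJ/mol added to the
#'   assembly energy when the site is methylated.
#' @param interactions Tibble with columns `i`, `j`, `value`: `value` is
#'   added when sites `i` and `j` are both methylated (stored symmetrically).
#' @param clamp_bonus kJ/mol added when the clamp unit's 2/3 sites are both
#'   unmethylated (negative = stabilizing).
#' @param clamp_unit,clamp_cd Glucose unit (1..7) and CD slot of the clamp.
#' @param e_guest,e_cd Component heats of formation, kJ/mol.
#' @param offset Assembly-energy offset so that dE of the all-hydroxyl,
#'   clamp-open state equals `offset + clamp_bonus`.
#' @return A `landscape_spec` list.
#' @export
landscape_spec <- function(site_terms,
                           interactions = tibble::tibble(i = integer(),
                                                         j = integer(),
                                                         value = numeric()),
                           clamp_bonus = 0, clamp_unit = 7, clamp_cd = 1,
                           e_guest = -150, e_cd = -2400, offset = -100) {
  n <- length(site_terms)
  if (!n %in% c(21L, 42L) || anyNA(site_terms) || !all(is.finite(site_terms))) {
    abort("site_terms must be 21 or 42 finite values")
  }
  if (nrow(interactions)) {
    if (any(interactions$i < 1 | interactions$i > n |
            interactions$j < 1 | interactions$j > n |
            interactions$i == interactions$j)) {
      abort("interaction indices must be distinct sites within range")
    }
  }
  structure(list(site_terms = site_terms, interactions = interactions,
                 clamp_bonus = clamp_bonus, clamp_unit = as.integer(clamp_unit),
                 clamp_cd = as.integer(clamp_cd), e_guest = e_guest,
                 e_cd = e_cd, offset = offset, n_sites = n),
            class = "landscape_spec")
}

#' Closed-form landscape energy of a state
#'
#' The planted dE of a [landscape_spec()] for a given state; [make_oracle()]
#' is constructed so that [delta_e()] of its outputs reduces to this value
#' exactly.
#'
#' @param spec A `landscape_spec`.
#' @param state Logical state vector.
#' @return dE in kJ/mol.
#' @export
landscape_delta_e <- function(spec, state) {
  state <- check_state(state)
  if (length(state) != spec$n_sites) abort("state length mismatch with landscape")
  e <- spec$offset + sum(spec$site_terms[state])
  if (nrow(spec$interactions)) {
    both <- state[spec$interactions$i] & state[spec$interactions$j]
    e <- e + sum(spec$interactions$value[both])
  }
  s2 <- (spec$clamp_cd - 1L) * 21L + glucose_to_site(spec$clamp_unit, 2L)
  s3 <- (spec$clamp_cd - 1L) * 21L + glucose_to_site(spec$clamp_unit, 3L)
  if (!state[s2] && !state[s3]) e <- e + spec$clamp_bonus
  e
}

#' Build a deterministic synthetic energy oracle
#'
#' Returns an energy-oracle function for [run_tree()]: component energies
#' are the spec's constants and the assembly energy is their sum plus the
#' planted landscape, so the resulting [delta_e()] equals
#' [landscape_delta_e()] exactly. The oracle is pure: identical states give
#' identical energies.
#'
#' @param spec A `landscape_spec`.
#' @return Function `state -> list(e_assembly, e_guest, e_cd1, e_cd2)`.
#' @export
make_oracle <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  n_cd <- spec$n_sites %/% 21L
  function(state) {
    de <- landscape_delta_e(spec, state)
    e_cd2 <- if (n_cd == 2) spec$e_cd else NA_real_
    list(
      e_assembly = spec$e_guest + spec$e_cd * n_cd + de,
      e_guest = spec$e_guest, e_cd1 = spec$e_cd, e_cd2 = e_cd2
    )
  }
}

#' Random separable landscape
#'
#' Independent per-site terms drawn uniformly from `[-scale, scale]`; the
#' global optimum is the state methylating exactly the negative-term sites,
#' with dE `offset + sum(pmin(terms, 0))` - the closed form greedy search is
#' tested against.
#'
#' @param n_sites 21 or 42.
#' @param seed Integer seed.
#' @param scale Term magnitude bound, kJ/mol.
#' @return A `landscape_spec` with no interactions and no clamp bonus.
#' @export
random_separable_landscape <- function(n_sites = 21, seed = 1, scale = 10) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  landscape_spec(site_terms = runif(n_sites, -scale, scale))
}

#' Simulate a 1:1 titration dataset
#'
#' Draws absorbance changes from the 1:1 binding isotherm
#' `dA = eps_c_l * s_total * Ka * [CD0] / (1 + Ka * [CD0])` with additive
#' Gaussian noise. Negative draws are clipped to zero with a warning.
#'
#' @param ka Association constant, M^-1.
#' @param eps_c_l Product of the complexation molar-absorptivity change and
#'   the path length, M^-1.
#' @param s_total Guest concentration, M.
#' @param cd0_grid Host concentrations, M (strictly increasing). The default
#'   spans the micromolar range of a UV titration.
#' @param noise_sd Absorbance noise standard deviation. The default is
#'   calibrated so that fitted-Ka sampling spread is about +/-10% at the
#'   default 8-point grid.
#' @param seed Integer seed.
#' @return Tibble `cd0`, `delta_a`, with the generating parameters stored in
#'   attribute `"params"`.
#' @export
make_titration <- function(ka = 50.618, eps_c_l = 2e5, s_total = 2.5e-5,
                           cd0_grid = seq(2e-6, 2.5e-4, length.out = 8),
                           noise_sd = 2.5e-7, seed = 1) {
  if (ka <= 0 || eps_c_l <= 0 || s_total <= 0) {
    abort("ka, eps_c_l and s_total must be > 0")
  }
  if (!length(cd0_grid)) abort("cd0_grid must be non-empty")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  mu <- eps_c_l * s_total * ka * cd0_grid / (1 + ka * cd0_grid)
  da <- mu + rnorm(length(cd0_grid), 0, noise_sd)
  if (any(da < 0)) {
    warn(sprintf("%d negative absorbance draw(s) clipped to 0", sum(da < 0)))
    da <- pmax(da, 0)
  }
  out <- tibble::tibble(cd0 = cd0_grid, delta_a = da)
  attr(out, "params") <- list(ka = ka, eps_c_l = eps_c_l, s_total = s_total,
                              noise_sd = noise_sd, seed = seed)
  out
}

#' Simulate a phase-solubility profile
#'
#' Generates `S([CD]) = s0 * (1 + k1*[CD] + k1*k2*[CD]^2)` plus Gaussian
#' noise: `k2 = 0` yields a linear (AL-type) diagram, `k2 > 0` a positively
#' curved (Ap-type) one, and `k1 = 0` a flat diagram.
#'
#' @param s0 Intrinsic solubility, M.
#' @param k1 First (1:1) association constant, M^-1.
#' @param k2 Second (1:2) association constant, M^-1.
#' @param cd_grid Host concentrations, M; default spans the millimolar range
#'   of a phase-solubility experiment.
#' @param noise_sd Solubility noise standard deviation (same unit as `s0`).
#' @param seed Integer seed.
#' @return Tibble `cd_conc`, `solubility` with attribute `"params"`.
#' @export
make_phase_profile <- function(s0 = 5e-6, k1 = 50, k2 = 5,
                               cd_grid = seq(0.005, 0.16, length.out = 8),
                               noise_sd = 0, seed = 1) {
  if (s0 <= 0 || k1 < 0 || k2 < 0) abort("need s0 > 0, k1 >= 0, k2 >= 0")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  mu <- s0 * (1 + k1 * cd_grid + k1 * k2 * cd_grid^2)
  s <- mu + rnorm(length(cd_grid), 0, noise_sd)
  out <- tibble::tibble(cd_conc = cd_grid, solubility = s)
  attr(out, "params") <- list(s0 = s0, k1 = k1, k2 = k2, noise_sd = noise_sd,
                              seed = seed)
  out
}
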