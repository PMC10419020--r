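test_that("bond_geometry returns exact lengths and angles", {
  g <- bond_geometry(c(0, 0, 0), c(1, 0, 0), c(3, 0, 0))
  expect_equal(g$length, 2)
  expect_equal(g$angle, 180)
  g <- bond_geometry(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  expect_equal(g$length, 1)
  expect_equal(g$angle, 90)
  expect_error(bond_geometry(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)), "degenerate")
})

test_that("bond_geometry inverts a contact constructed from length and angle", {
  # place H at origin, acceptor along +x at the target length, donor in the
  # xy-plane at the O-H covalent distance and the target angle from +x:
  # the published DFT and PM3 clamp geometries are recovered exactly
  cases <- data.frame(length = c(2.774, 2.694, 1.933, 1.896),
                      angle = c(159, 166, 167, 177))
  for (i in seq_len(nrow(cases))) {
    len <- cases$length[i]; ang <- cases$angle[i] * pi / 180
    donor <- 0.98 * c(cos(ang), sin(ang), 0)
    g <- bond_geometry(donor, c(0, 0, 0), c(len, 0, 0))
    expect_equal(g$length, cases$length[i], tolerance = 1e-12)
    expect_equal(g$angle, cases$angle[i], tolerance = 1e-9)
  }
})

test_that("planted contacts are detected inside the cutoff and not beyond", {
  near <- make_geometry(geometry_spec(contacts = list(
    list(donor = "ph1", acceptor = "cd_hydroxyl:5", distance = 1.90)
  )))
  b <- detect_hbonds(near$model)
  expect_equal(nrow(b), 1)
  expect_equal(b$length, 1.90, tolerance = 1e-9)
  expect_equal(b$bond_class, "phenol_OH->cd_hydroxyl_O")

  far <- make_geometry(geometry_spec(contacts = list(
    list(donor = "ph1", acceptor = "cd_hydroxyl:5", distance = 2.10)
  )))
  expect_equal(nrow(detect_hbonds(far$model)), 0)
  expect_equal(nrow(detect_hbonds(far$model, cutoff = 2.2)), 1)
  expect_error(detect_hbonds(far$model, cutoff = -1), "cutoff")
})

test_that("bond sets are monotone in the cutoff and invariant under rigid motion", {
  gen <- random_fixture(7)
  cuts <- c(1.6, 1.9, 2.0, 2.3, 2.6)
  sets <- lapply(cuts, function(cc) bond_key(detect_hbonds(gen$model, cutoff = cc)))
  for (i in seq_along(cuts)[-1]) {
    expect_true(all(sets[[i - 1]] %in% sets[[i]]))
  }
  b0 <- detect_hbonds(gen$model, cutoff = 2.5)
  for (s in 1:5) {
    bt <- detect_hbonds(rigid_transform(gen, seed = s), cutoff = 2.5)
    expect_equal(bond_key(bt), bond_key(b0))
    expect_equal(sort(bt$length), sort(b0$length), tolerance = 1e-9)
  }
})

test_that("detect_hbonds agrees with the brute-force all-pairs scan", {
  for (seed in 1:20) {
    gen <- random_fixture(seed)
    got <- detect_hbonds(gen$model)
    want <- brute_force_hbonds(gen)
    expect_equal(bond_key(got), bond_key(want))
    got <- got[order(got$donor_heavy, got$hydrogen, got$acceptor), ]
    expect_equal(got$length, want$length, tolerance = 1e-12)
  }
})

test_that("a symmetric Fe clamp is one clamp built from two position-2/3 bonds", {
  gen <- make_geometry(geometry_spec(contacts = list(
    list(donor = 19, acceptor = "fe", distance = 1.95),
    list(donor = 20, acceptor = "fe", distance = 1.95)
  )))
  b <- detect_hbonds(gen$model)
  expect_equal(nrow(b), 2)
  expect_true(all(b$bond_class == "cd_hydroxyl_OH->fe"))
  cl <- detect_clamps(b, gen$model)
  expect_equal(nrow(cl), 1)
  expect_true(cl$symmetric)
  expect_equal(cl$glucose_unit, 7L)
  expect_equal(c(cl$site_a, cl$site_b), c(19L, 20L))
})

test_that("positions 2 and 6 of a unit do not form a clamp", {
  gen <- make_geometry(geometry_spec(contacts = list(
    list(donor = 19, acceptor = "fe", distance = 1.95),
    list(donor = 21, acceptor = "fe", distance = 1.95)
  )))
  b <- detect_hbonds(gen$model)
  expect_equal(nrow(b), 2)
  expect_equal(nrow(detect_clamps(b, gen$model)), 0)
})

test_that("asymmetric clamps are flagged and excluded from census totals", {
  gen <- make_geometry(geometry_spec(contacts = list(
    list(donor = 10, acceptor = "fe", distance = 1.9),
    list(donor = 11, acceptor = "fe", distance = 2.4)
  )))
  wide <- detect_hbonds(gen$model, cutoff = 2.5)
  cl <- detect_clamps(wide, gen$model, cutoff = 2.0)
  expect_equal(nrow(cl), 1)
  expect_false(cl$symmetric)

  cen <- census(list(gen$model), "best")
  expect_equal(nrow(cen$clamps), 0) # no symmetric clamp at the 2 A cutoff
  expect_equal(cen$bonds$n_bonds[cen$bonds$bond_class == "cd_hydroxyl_OH->fe"], 1L)
})

test_that("each symmetric clamp contributes exactly two bonds to its class", {
  gen <- make_geometry(geometry_spec(contacts = list(
    list(donor = 19, acceptor = "fe", distance = 1.93),
    list(donor = 20, acceptor = "fe", distance = 1.90)
  )))
  cen <- census(list(gen$model, gen$model), c("best", "best"))
  fe_bonds <- cen$bonds$n_bonds[cen$bonds$bond_class == "cd_hydroxyl_OH->fe"]
  fe_clamps <- cen$clamps$n_clamps[cen$clamps$acceptor_class == "fe"]
  expect_equal(fe_bonds, 4L)
  expect_equal(fe_clamps, 2L)
  expect_equal(fe_bonds, 2L * fe_clamps)
})

test_that("census splits groups and averages methyl proximity", {
  one_bond <- make_geometry(geometry_spec(contacts = list(
    list(donor = 5, acceptor = "fe", distance = 1.8)
  )))
  plain <- make_geometry(geometry_spec())
  cen <- census(list(one_bond$model, one_bond$model, plain$model),
                c("best", "best", "worse"))
  fe <- dplyr::filter(cen$bonds, bond_class == "cd_hydroxyl_OH->fe")
  expect_equal(fe$n_bonds[fe$group == "best"], 2L)
  expect_false("worse" %in% fe$group)
  expect_equal(sort(cen$nbmefc$group), c("best", "worse"))
  expect_error(census(list(plain$model), NA_character_), "group label")
})

test_that("methyl-near-Fc counting matches a brute-force double loop", {
  for (seed in 1:10) {
    gen <- random_fixture(seed + 100)
    at <- gen$atoms
    me <- gen$model$topology$substituent[at$element[gen$model$topology$substituent] == "C"]
    fc <- gen$model$guest$moieties$fc
    for (cutoff in c(3, 4, 6, 12)) {
      want <- 0L
      for (i in me) {
        dmin <- Inf
        for (j in fc) {
          dmin <- min(dmin, sqrt((at$x[i] - at$x[j])^2 + (at$y[i] - at$y[j])^2 +
                                   (at$z[i] - at$z[j])^2))
        }
        if (dmin <= cutoff) want <- want + 1L
      }
      expect_equal(count_methyls_near_fc(gen$model, cutoff), want)
    }
  }
  plain <- make_geometry(geometry_spec())
  expect_equal(count_methyls_near_fc(plain$model, 100), 0L)
  expect_error(count_methyls_near_fc(plain$model, 0), "proximity_cutoff")
})
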