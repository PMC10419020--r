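test_that("delta_e subtracts component heats of formation", {
  expect_equal(delta_e(0, 0, 0), 0)
  expect_equal(delta_e(-500, -100, -250), -150)
  expect_equal(delta_e(-900, -100, -250, -300), -250)
  # oracle energies recombine to the planted landscape by hand
  spec <- landscape_spec(site_terms = seq(-10, 10, length.out = 21),
                         clamp_bonus = -50, clamp_unit = 7)
  oracle <- make_oracle(spec)
  st <- rep(c(TRUE, FALSE), length.out = 21)
  e <- oracle(st)
  hand <- spec$offset + sum(spec$site_terms[st]) # clamp open: site 19 TRUE
  expect_equal(delta_e(e$e_assembly, e$e_guest, e$e_cd1), hand)
})

test_that("enumerate_children yields one Hamming-1 mutant per site, in order", {
  st <- rep(FALSE, 21)
  kids <- enumerate_children(st)
  expect_length(kids, 21)
  for (k in seq_along(kids)) {
    expect_equal(sum(kids[[k]] != st), 1)
    expect_true(kids[[k]][k])
    expect_equal(enumerate_children(kids[[k]])[[k]], st) # involution
  }
  st2 <- runif(42) < 0.5
  kids2 <- enumerate_children(st2)
  expect_length(kids2, 42)
  expect_true(all(vapply(seq_along(kids2),
                         function(k) sum(kids2[[k]] != st2) == 1, logical(1))))
})

test_that("select_g0 keeps the most negative candidate per insertion group", {
  cand <- tibble::tibble(
    moiety = c("Fc", "Fc"), side = c("NS", "NS"),
    cd_label = c("2-Me", "3-Me"), delta_e = c(-122, -83)
  )
  expect_equal(select_g0(cand)$cd_label, "2-Me")

  single <- tibble::tibble(moiety = "Succ", side = "WS", cd_label = "3,6-diMe",
                           delta_e = -111)
  expect_equal(select_g0(single), single)

  # 4 moieties x 2 sides x 6 well-defined CDs -> 8 winners
  set.seed(1)
  full <- tidyr::expand_grid(
    moiety = c("Fc", "Ph1", "Ph2", "Succ"), side = c("NS", "WS"),
    cd_label = names(well_defined_states())
  )
  full$delta_e <- round(runif(nrow(full), -200, -40))
  g0 <- select_g0(full)
  expect_equal(nrow(g0), 8)
  check <- dplyr::summarise(dplyr::group_by(full, moiety, side),
                            best = min(delta_e), .groups = "drop")
  expect_equal(sort(g0$delta_e), sort(check$best))

  # ties break lexicographically on the CD label
  tie <- tibble::tibble(moiety = "Fc", side = "NS",
                        cd_label = c("3-Me", "2-Me"), delta_e = c(-100, -100))
  expect_equal(select_g0(tie)$cd_label, "2-Me")
  expect_error(select_g0(tie[0, ]), "candidates")
})

test_that("greedy search attains the closed-form optimum of separable landscapes", {
  for (seed in c(2, 11, 23)) {
    spec <- random_separable_landscape(seed = seed)
    tr <- run_tree(make_oracle(spec), rep(FALSE, 21))
    opt <- spec$offset + sum(pmin(spec$site_terms, 0))
    expect_equal(min(tr$delta_e), opt, tolerance = 1e-12)
    best_state <- parse_state(tr$state[which.min(tr$delta_e)])
    expect_equal(best_state, unname(spec$site_terms < 0))
    expect_lte(max(tr$generation), 21 + 4)
  }
})

test_that("a flat landscape stops after `patience` non-improving generations", {
  spec <- landscape_spec(site_terms = rep(0, 21), offset = -100)
  tr <- run_tree(make_oracle(spec), rep(FALSE, 21), patience = 4)
  expect_equal(max(tr$generation), 4)
  expect_equal(nrow(tr), 1 + 4 * 21)
  expect_equal(min(tr$delta_e), tr$delta_e[1])
  tr0 <- run_tree(make_oracle(spec), rep(FALSE, 21), patience = 0)
  expect_equal(nrow(tr0), 1)
})

test_that("tree bookkeeping invariants hold on an epistatic landscape", {
  set.seed(5)
  inter <- tibble::tibble(i = sample(1:12, 8), j = sample(10:21, 8),
                          value = runif(8, -30, 30))
  inter <- inter[inter$i != inter$j, ]
  spec <- landscape_spec(site_terms = runif(21, -10, 10), interactions = inter,
                         clamp_bonus = -40)
  tr <- run_tree(make_oracle(spec), rep(FALSE, 21), patience = 3)
  # parent links: generation increments, Hamming distance one, exact deltadelta
  kids <- tr[!is.na(tr$parent_id), ]
  pi <- match(kids$parent_id, tr$id)
  expect_equal(kids$generation, tr$generation[pi] + 1L)
  expect_equal(kids$deltadelta, kids$delta_e - tr$delta_e[pi])
  hd <- mapply(function(a, b) sum(parse_state(a) != parse_state(b)),
               kids$state, tr$state[pi])
  expect_true(all(hd == 1))
  expect_true(all(table(tr$generation[-1]) == 21))
  # determinism
  tr2 <- run_tree(make_oracle(spec), rep(FALSE, 21), patience = 3)
  expect_identical(tr, tr2)
})

test_that("greedy is bounded below by exhaustive search over free sites", {
  set.seed(9)
  free <- 1:12
  inter <- tibble::tibble(i = sample(free, 6, replace = TRUE),
                          j = sample(free, 6, replace = TRUE),
                          value = runif(6, -40, 40))
  inter <- unique(inter[inter$i != inter$j, ])
  terms <- c(runif(12, -15, 15), rep(1000, 9)) # out-of-play sites penalized
  spec <- landscape_spec(site_terms = terms, interactions = inter,
                         clamp_bonus = 0)
  # independent oracle: enumerate all 2^12 states over the free sites
  oracle <- make_oracle(spec)
  exhaustive <- min(vapply(0:(2^12 - 1), function(m) {
    st <- rep(FALSE, 21)
    st[free] <- bitwAnd(m, 2^(free - 1)) > 0
    e <- oracle(st)
    delta_e(e$e_assembly, e$e_guest, e$e_cd1)
  }, numeric(1)))
  tr <- run_tree(oracle, rep(FALSE, 21), patience = 4)
  expect_gte(min(tr$delta_e), exhaustive - 1e-9)
})

test_that("main_route walks from G0 to the best node and is length Gbest + 1", {
  spec <- random_separable_landscape(seed = 31)
  tr <- run_tree(make_oracle(spec), rep(FALSE, 21))
  route <- suppressWarnings(main_route(tr))
  expect_equal(route$generation, 0:(nrow(route) - 1))
  expect_equal(route$delta_e[1], tr$delta_e[1])
  expect_equal(route$delta_e[nrow(route)], min(tr$delta_e))
  expect_true(all(diff(route$delta_e) <= 0))
  expect_equal(nrow(route), tr$generation[which.min(tr$delta_e)] + 1)

  single <- run_tree(make_oracle(spec), rep(FALSE, 21), patience = 0)
  expect_equal(nrow(main_route(single)), 1)
})

test_that("rank_by_deltadelta orders inversions most-stabilizing first", {
  tr <- tibble::tibble(
    id = 1:4, parent_id = c(NA, 1L, 1L, 1L), generation = c(0L, 1L, 1L, 1L),
    state = rep("0", 4), delta_e = c(0, -5, -139, 176),
    deltadelta = c(NA, -5, -139, 176)
  )
  expect_equal(rank_by_deltadelta(tr)$deltadelta, c(-139, -5, 176))
  expect_equal(nrow(rank_by_deltadelta(tr[1, ])), 0)
})

test_that("a file-backed oracle replays recorded energies and rejects unknown states", {
  spec <- random_separable_landscape(seed = 8)
  live <- make_oracle(spec)
  tr <- run_tree(live, rep(FALSE, 21), patience = 1)
  tab <- dplyr::distinct(tr[, c("state", "e_assembly", "e_guest", "e_cd1", "e_cd2")],
                         state, .keep_all = TRUE)
  replay <- oracle_from_table(tab)
  tr2 <- run_tree(replay, rep(FALSE, 21), patience = 1)
  expect_equal(tr2$delta_e, tr$delta_e)
  expect_error(replay(rep(TRUE, 21)), "not present")
})
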