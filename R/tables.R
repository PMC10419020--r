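#' Published per-series statistics of the SuccFerr methylation trees
#'
#' The per-series bookkeeping of the twelve published mutation trees (eight
#' 1-CD series S1-S8 and four 2-CD series S1-S4): inserted moiety and side
#' (NS = narrow side, WS = wide side), the well-defined CD chosen at G0, the
#' G0 / average / best complexation energies (kJ/mol), generations reached,
#' experiment counts and distinct freed-CD counts. Useful as worked input
#' for [select_g0()] and for cross-checking series aggregation (for example,
#' the 1-CD sample counts total 8892 calculated experiments).
#'
#' @return A tibble with one row per series.
#' @export
succferr_series_table <- function() {
  tibble::tribble(
    ~series,    ~n_cd, ~moiety, ~side, ~g0_cd,      ~delta_e_g0, ~average_delta_e, ~best_delta_e, ~max_g, ~g_best, ~samples, ~id_g0, ~free_cds,
    "1-CD S1",  1L,    "Fc",    "NS",  "2-Me",      -122,        -154,             -194,          33L,    29L,     2726L,    1L,     2690L,
    "1-CD S2",  1L,    "Fc",    "WS",  "3-Me",      -83,         -144,             -261,          19L,    18L,     1994L,    2727L,  1877L,
    "1-CD S3",  1L,    "Ph1",   "NS",  "2-Me",      -111,        -127,             -142,          13L,    12L,     571L,     4721L,  550L,
    "1-CD S4",  1L,    "Ph1",   "WS",  "3,6-diMe",  -141,        -177,             -204,          13L,    10L,     326L,     5292L,  305L,
    "1-CD S5",  1L,    "Ph2",   "NS",  "2-Me",      -48,         -68,              -127,          12L,    11L,     187L,     5618L,  166L,
    "1-CD S6",  1L,    "Ph2",   "WS",  "6-Me",      -49,         -98,              -169,          4L,     4L,      79L,      5805L,  57L,
    "1-CD S7",  1L,    "Succ",  "NS",  "2,3-diMe",  -161,        -187,             -219,          18L,    17L,     1106L,    5884L,  1084L,
    "1-CD S8",  1L,    "Succ",  "WS",  "3,6-diMe",  -111,        -274,             -302,          21L,    16L,     1903L,    6990L,  1872L,
    "2-CD S1",  2L,    "Fc",    "NS",  "3-Me",      -278,        -271,             -330,          22L,    19L,     1138L,    1L,     495L,
    "2-CD S2",  2L,    "Fc",    "NS",  "3-Me",      -208,        -293,             -338,          15L,    15L,     642L,     1139L,  253L,
    "2-CD S3",  2L,    "Fc",    "NS",  "2,3-diMe",  -203,        -248,             -296,          12L,    11L,     449L,     1781L,  195L,
    "2-CD S4",  2L,    "Succ",  "NS",  "2-Me",      -236,        -283,             -326,          27L,    26L,     1229L,    2230L,  451L
  )
}

#' Published NBO E(2) contributions of the atypical Fe...H-O contacts
#'
#' The second-order perturbation stabilization energies of the two
#' Fe...H-O hydrogen bonds of the ferrocene clamp in the best 1-CD model
#' (DFT/NBO), eight donor-acceptor orbital contributions per contact.
#' Feeding each contact's rows to [sum_nbo_contributions()] gives the
#' published totals of 86.45 kJ/mol (O19 contact) and 119.24 kJ/mol (O20
#' contact).
#'
#' @return Tibble with columns `contact` ("O19" or "O20"), `donor`,
#'   `acceptor`, `e2_kj_mol`.
#' @export
succferr_nbo_contributions <- function() {
  tibble::tribble(
    ~contact, ~donor,       ~acceptor,      ~e2_kj_mol,
    "O19",    "LP(Fe)",     "Rydberg(H)",   1.13,
    "O19",    "LP(Fe)",     "sigma*(H-O)",  3.80,
    "O19",    "LP*(Fe)",    "Rydberg(H)",   56.77,
    "O19",    "LP*(Fe)",    "Rydberg(O)",   9.23,
    "O19",    "LP*(Fe)",    "sigma*(H-O)",  4.48,
    "O19",    "sigma(H-O)", "LP*(Fe)",      9.83,
    "O19",    "sigma(H-O)", "Rydberg(Fe)",  0.29,
    "O19",    "LP(O)",      "LP*(Fe)",      0.92,
    "O20",    "CR(Fe)",     "Rydberg(H)",   0.21,
    "O20",    "LP(Fe)",     "Rydberg(H)",   3.14,
    "O20",    "LP(Fe)",     "sigma*(H-O)",  2.90,
    "O20",    "LP*(Fe)",    "Rydberg(H)",   98.40,
    "O20",    "LP*(Fe)",    "sigma*(H-O)",  4.43,
    "O20",    "sigma(H-O)", "LP*(Fe)",      8.61,
    "O20",    "sigma(H-O)", "Rydberg(Fe)",  0.50,
    "O20",    "LP(O)",      "LP*(Fe)",      1.05
  )
}
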