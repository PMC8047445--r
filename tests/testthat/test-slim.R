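test_that("motif scanning finds all overlapping windows", {
  q <- slim_query("[VI]x[VI]")
  expect_equal(scan_motifs("IPVPV", q), c(0L, 2L))
  expect_equal(scan_motifs("AAAA", q), integer(0))
  # the wild-type C-terminal peptide: ITI at 1, IPV at 3
  expect_equal(scan_motifs("EITIPVFE", q), c(1L, 3L))
  expect_equal(scan_motifs("IXV", q), integer(0))  # ambiguous never matches
})

test_that("scanning agrees with a nested-loop oracle on random sequences", {
  set.seed(11)
  qs <- list(slim_query("[VI]x[VI]"), slim_query("IPV"), slim_query("VxV"))
  for (i in 1:200) {
    s <- paste(sample(c("A", "I", "V", "P", "S", "X"), sample(3:30, 1),
                      replace = TRUE), collapse = "")
    q <- qs[[1 + i %% 3]]
    expect_identical(scan_motifs(s, q), scan_motifs_bruteforce(s, q))
  }
})

test_that("expected counts follow the independence product rule", {
  # worked proteome-census example with published disordered-region values
  e <- expected_count(slim_query("VSI"),
                      c(V = 0.04440, S = 0.1195, I = 0.0251), 2945909)
  expect_equal(round(e), 392)
  unif <- setNames(rep(0.05, 20), slimbind:::.AA20)
  expect_equal(expected_count(slim_query("IPV"), unif, 1e6), 125)
  expect_equal(expected_count(slim_query("IPV"), unif, 0), 0)
  # a set-valued position sums its member frequencies
  expect_equal(expected_count(slim_query("[VI]PV"), unif, 1e6), 250)
})

test_that("census counts conserve: proteome = disordered + structured", {
  for (s in 1:3) {
    g <- gen_proteome(n_proteins = 25, length_range = c(100, 300),
                      disorder_fraction = 0.35, seed = s)
    cen <- census(g$proteome, g$mask)
    expect_identical(cen$observed[, , "proteome"],
                     cen$observed[, , "disordered"] +
                       cen$observed[, , "structured"])
    expect_equal(unname(cen$window_totals["proteome"]),
                 unname(cen$window_totals["disordered"] +
                          cen$window_totals["structured"]))
  }
})

test_that("census edge cases: full disorder, empty mask, bad intervals", {
  set.seed(2)
  seqs <- setNames(paste(sample(slimbind:::.AA20, 60, TRUE), collapse = ""), "Q1")
  prot <- proteome_set(seqs)
  full <- disorder_mask(list(Q1 = matrix(c(0, 60), 1)), prot)
  cen <- census(prot, full)
  expect_true(all(cen$observed[, , "structured"] == 0))
  cen0 <- census(prot, disorder_mask(list()))
  expect_true(all(cen0$observed[, , "disordered"] == 0))
  expect_identical(cen0$observed[, , "structured"], cen0$observed[, , "proteome"])
  expect_error(disorder_mask(list(Q1 = matrix(c(50, 75), 1)), prot), "bounds")
})

test_that("planted motifs are recovered on top of the recorded background", {
  g <- gen_proteome(n_proteins = 60, disorder_fraction = 0.35,
                    planted_motifs = list(list(query = slim_query("IPV"),
                                               database = "disordered",
                                               count = 37)), seed = 9)
  cen <- census(g$proteome, g$mask)
  expect_equal(unname(cen$observed["IxV", "P", "disordered"]),
               37 + g$truth$background[["IPV|disordered"]])
})

test_that("chi-squared bookkeeping: 4 families x 20 residues give 76 df", {
  obs <- matrix(50, 4, 20, dimnames = list(c("IxI", "IxV", "VxI", "VxV"),
                                           slimbind:::.AA20))
  chi <- chi_square_total(obs, obs)
  expect_equal(chi$chi2_tot, 0)
  expect_equal(chi$df, 76)
  expect_equal(chi$p_value, 1)
  expect_error(chi_square_total(obs, obs * 0), "expected")
})

test_that("the 0.001 critical value at 76 df is 119.85", {
  # via the complemented regularized incomplete gamma function, independent of
  # the qchisq route
  upper_tail <- function(x, nu) pgamma(x / 2, nu / 2, lower.tail = FALSE)
  crit <- uniroot(function(x) upper_tail(x, 76) - 0.001, c(50, 300),
                  tol = 1e-10)$root
  expect_equal(crit, 119.85, tolerance = 1e-4)
  expect_equal(crit, qchisq(0.001, 76, lower.tail = FALSE), tolerance = 1e-8)
})

test_that("enrichment profiles sum to zero and flag planted enrichment", {
  g <- gen_proteome(n_proteins = 60, disorder_fraction = 0.35,
                    planted_motifs = list(list(query = slim_query("[VI]P[VI]"),
                                               database = "disordered",
                                               count = 60)), seed = 13)
  cen <- census(g$proteome, g$mask)
  prof <- enrichment_profile(cen)
  expect_equal(sum(prof), 0, tolerance = 1e-10)
  expect_gt(prof["P"], 0)
  expect_equal(length(prof), 20)
})

test_that("expected counts are invariant under sequence shuffling", {
  g <- gen_proteome(n_proteins = 20, disorder_fraction = 0, seed = 4)
  cen <- census(g$proteome, disorder_mask(list()))
  set.seed(1)
  shuffled <- vapply(g$proteome$records, function(s) {
    paste(sample(strsplit(s, "")[[1]]), collapse = "")
  }, character(1))
  cen2 <- census(proteome_set(shuffled), disorder_mask(list()))
  expect_equal(cen$expected[, , "proteome"], cen2$expected[, , "proteome"],
               tolerance = 1e-12)
})

test_that("interactor intersection keeps only disordered-motif carriers", {
  g <- gen_proteome(n_proteins = 10, length_range = c(150, 200),
                    disorder_fraction = 0.4,
                    planted_motifs = list(list(query = slim_query("IPV"),
                                               database = "disordered",
                                               count = 4)), seed = 17)
  planted_in <- unique(g$truth$planted[[1]]$protein_id)
  ids <- names(g$proteome$records)
  hits <- intersect_interactors(ids, g$proteome, g$mask)
  expect_true(all(planted_in %in% hits$protein_id))
  # per-protein counts reflect multiple motifs
  multi <- table(g$truth$planted[[1]]$protein_id)
  for (id in names(multi))
    expect_gte(hits$n_motifs[hits$protein_id == id], unname(multi[id]))
  expect_equal(nrow(intersect_interactors(character(0), g$proteome, g$mask)), 0)
  expect_warning(out <- intersect_interactors(c(ids[1], "nope"),
                                              g$proteome, g$mask), "unknown")
  expect_equal(attr(out, "unknown_ids"), "nope")
})
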