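toy_panel <- function(arch, mod, extra = NULL) {
  seqs <- c(arch, mod, extra)
  grp <- c(rep("archaic", length(arch)), rep("modern", length(mod)),
           rep("outgroup", length(extra)))
  names(grp) <- names(seqs)
  panel_alignment(seqs, group = grp)
}

test_that("identical panels yield no diagnostic positions", {
  p <- toy_panel(c(a1 = "ACGTACGTAC", a2 = "ACGTACGTAC"),
                 c(m1 = "ACGTACGTAC", m2 = "ACGTACGTAC"))
  expect_equal(nrow(find_diagnostic_positions(p)), 0L)
})

test_that("a single engineered fixed difference is found at column 5", {
  p <- toy_panel(c(a1 = "ACGTACGTAC", a2 = "ACGTACGTAC"),
                 c(m1 = "ACGTATGTAC", m2 = "ACGTATGTAC"))
  d <- find_diagnostic_positions(p)
  expect_equal(d$pos, 5L)
  expect_equal(d$archaic_state, "C")
  expect_equal(d$modern_state, "T")
})

test_that("within-group variation, gaps and N disqualify a column", {
  p <- toy_panel(c(a1 = "AC-TNCGTAC", a2 = "ACGTACGTAC"),
                 c(m1 = "GCGTATGTAC", m2 = "GAGTATGTAC"))
  d <- find_diagnostic_positions(p)
  # col 0: fixed A vs fixed G -> diagnostic; col 1: modern varies;
  # col 2: archaic gap; col 4: archaic N; col 5: fixed C vs T
  expect_equal(d$pos, c(0L, 5L))
})

test_that("diagnostic scan equals the exhaustive column oracle", {
  cfg <- sim_config(ref_len = 3000, seed = 61)
  p <- simulate_panel(cfg)
  d <- find_diagnostic_positions(p)
  expect_gt(nrow(d), 0L)
  expect_identical(d$pos, oracle_diagnostics(p))
})

test_that("per-fragment majority vote covers all four call outcomes", {
  # two diagnostic sites at positions 2 (arch G / mod A) and 6
  # (arch C / mod T); four fragments engineered to match 2-0, 0-1,
  # 1-1 and none
  diag <- data.frame(pos = c(2L, 6L), archaic_state = c("G", "C"),
                     modern_state = c("A", "T"))
  f1 <- frag(0, "AAGAAACAAA", read_id = "both_archaic")
  f2 <- frag(4, "AATAAA", read_id = "one_modern")
  f3 <- frag(0, "AAGAAATAAA", read_id = "tie")
  f4 <- frag(10, "AAAAAA", read_id = "outside")
  asg <- classify_fragments(rbind(f1, f2, f3, f4), diag)
  expect_identical(asg$call, c("endogenous", "contaminant", "ambiguous",
                               "uninformative"))
  expect_equal(asg$n_informative, c(2L, 1L, 2L, 0L))
  expect_true(all(asg$n_archaic_match + asg$n_modern_match <=
                    asg$n_informative))
})

test_that("a pure undamaged endogenous stream matches archaic fully", {
  cfg <- sim_config(ref_len = 4000, contamination_frac = 0,
                    deam_pmax = 0, deam_baseline = 0,
                    contam_deam_pmax = 0, contam_deam_baseline = 0,
                    seq_error = 0, seed = 71)
  ds <- simulate_dataset(cfg, n_fragments = 1500)
  d <- find_diagnostic_positions(ds$panel)
  asg <- classify_fragments(ds$fragments, d, ds$ref)
  s <- attr(asg, "summary")
  expect_equal(s$fraction_archaic_overall, 1.0)
  expect_equal(sum(asg$call == "contaminant"), 0L)
})

test_that("archaic-match fraction reflects the mixing proportion", {
  cfg <- sim_config(ref_len = 16569, contamination_frac = 0.30,
                    deam_pmax = 0, deam_baseline = 0,
                    contam_deam_pmax = 0, contam_deam_baseline = 0,
                    seq_error = 0, seed = 81)
  ds <- simulate_dataset(cfg, n_fragments = 5000)
  d <- find_diagnostic_positions(ds$panel)
  asg <- classify_fragments(ds$fragments, d, ds$ref)
  s <- attr(asg, "summary")
  n_state <- sum(asg$n_archaic_match + asg$n_modern_match)
  se <- sqrt(0.7 * 0.3 / n_state)
  expect_lt(abs(s$fraction_archaic_overall - 0.70), 3 * se + 0.01)
})

test_that("classification is invariant under fragment reordering", {
  cfg <- sim_config(ref_len = 2000, contamination_frac = 0.2, seed = 91)
  ds <- simulate_dataset(cfg, n_fragments = 400)
  d <- find_diagnostic_positions(ds$panel)
  a1 <- classify_fragments(ds$fragments, d, ds$ref)
  set.seed(1)
  perm <- sample(nrow(ds$fragments))
  a2 <- classify_fragments(ds$fragments[perm, ], d, ds$ref)
  expect_identical(a1$call[perm], a2$call)
  expect_identical(a1$n_informative[perm], a2$n_informative)
})

test_that("removing diagnostic positions never raises informativeness", {
  cfg <- sim_config(ref_len = 2000, contamination_frac = 0.2, seed = 92)
  ds <- simulate_dataset(cfg, n_fragments = 300)
  d <- find_diagnostic_positions(ds$panel)
  a_full <- classify_fragments(ds$fragments, d, ds$ref)
  d_sub <- d[seq(1, nrow(d), by = 2), , drop = FALSE]
  a_sub <- classify_fragments(ds$fragments, d_sub, ds$ref)
  expect_true(all(a_sub$n_informative <= a_full$n_informative))
})

test_that("Wilson interval matches the textbook formula", {
  est <- list(
    c(x = 10, n = 40),
    c(x = 0, n = 50),
    c(x = 49, n = 50),
    c(x = 250, n = 1000))
  for (e in est) {
    asg <- data.frame(
      read_id = sprintf("r%d", seq_len(e["n"])), library = "L1",
      truth_label = NA_character_, n_informative = 1L,
      n_archaic_match = rep(c(0L, 1L), c(e["x"], e["n"] - e["x"])),
      n_modern_match = rep(c(1L, 0L), c(e["x"], e["n"] - e["x"])),
      call = rep(c("contaminant", "endogenous"),
                 c(e["x"], e["n"] - e["x"])))
    class(asg) <- c("fragment_assignments", "data.frame")
    got <- estimate_contamination(asg)
    want <- oracle_wilson(e[["x"]], e[["n"]])
    expect_equal(got$point, e[["x"]] / e[["n"]])
    expect_equal(got$ci_low, unname(want["low"]), tolerance = 1e-10)
    expect_equal(got$ci_high, unname(want["high"]), tolerance = 1e-10)
    expect_true(got$ci_low <= got$point && got$point <= got$ci_high)
  }
  # boundary: 0 contaminants of 50 decided
  asg0 <- data.frame(read_id = sprintf("r%d", 1:50), library = "L1",
                     truth_label = NA_character_, n_informative = 1L,
                     n_archaic_match = 1L, n_modern_match = 0L,
                     call = "endogenous")
  class(asg0) <- c("fragment_assignments", "data.frame")
  got0 <- estimate_contamination(asg0)
  expect_equal(got0$point, 0)
  expect_equal(got0$ci_low, 0)
  expect_equal(got0$ci_high, unname(oracle_wilson(0, 50)["high"]),
               tolerance = 1e-10)
})

test_that("estimation refuses a stream with no decided fragments", {
  asg <- data.frame(read_id = "r1", library = "L1",
                    truth_label = NA_character_, n_informative = 0L,
                    n_archaic_match = 0L, n_modern_match = 0L,
                    call = "uninformative")
  class(asg) <- c("fragment_assignments", "data.frame")
  expect_error(estimate_contamination(asg), "estimation error")
})

test_that("conditioning on deaminated fragments lowers the estimate", {
  # damage on the endogenous pool only: deaminated-only scope should
  # not exceed the all-fragments estimate (in expectation; checked on
  # three seeds)
  lower <- 0L
  for (s in 1:3) {
    cfg <- sim_config(ref_len = 8000, contamination_frac = 0.3,
                      contam_deam_pmax = 0, contam_deam_baseline = 0,
                      seed = 600 + s)
    ds <- simulate_dataset(cfg, n_fragments = 3000)
    d <- find_diagnostic_positions(ds$panel)
    est_all <- estimate_contamination(
      classify_fragments(ds$fragments, d, ds$ref), "all")
    sel <- select_deaminated(ds$fragments, ds$ref)
    est_deam <- estimate_contamination(
      classify_fragments(sel, d, ds$ref), "deaminated_only")
    if (est_deam$point <= est_all$point) lower <- lower + 1L
  }
  expect_gte(lower, 2L)
})
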