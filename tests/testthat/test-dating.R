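test_that("pairwise differences exclude masked columns symmetrically", {
  a <- strrep("ACGT", 25)
  expect_equal(pairwise_differences(a, a),
               list(n_diff = 0L, n_compared = 100L))

  # 3 engineered differences plus 2 N-masked columns in one sequence
  b <- strsplit(a, "")[[1]]
  b[c(1, 10, 50)] <- c("T", "A", "G")
  b[c(20, 70)] <- "N"
  b <- paste(b, collapse = "")
  expect_equal(pairwise_differences(a, b),
               list(n_diff = 3L, n_compared = 98L))
  expect_equal(pairwise_differences(b, a), pairwise_differences(a, b))

  expect_error(pairwise_differences("ACGT", "ACG"), "alignment error")
})

test_that("distance matrix matches the closed form and ape's dist.dna", {
  # closed-form JC at d_raw = 0.03
  d_raw <- 0.03
  v <- strsplit(strrep("A", 100), "")[[1]]
  w <- v; w[1:3] <- "G"
  p <- panel_alignment(c(x = paste(v, collapse = ""),
                         y = paste(w, collapse = "")))
  got <- distance_matrix(p, "jukes_cantor")
  expect_equal(got["x", "y"], -0.75 * log(1 - 4 / 3 * d_raw),
               tolerance = 1e-12)

  # identical taxa -> zero matrix; JC >= raw elsewhere
  cfg <- sim_config(ref_len = 2000, seed = 51)
  panel <- simulate_panel(cfg)
  raw <- distance_matrix(panel, "raw")
  jc <- distance_matrix(panel, "jukes_cantor")
  expect_true(all(diag(raw) == 0))
  expect_true(all(jc >= raw - 1e-12))
  expect_identical(raw, t(raw))

  # independent route: ape::dist.dna with pairwise deletion
  seqs <- lapply(rownames(panel), function(n)
    tolower(panel[n, ]))
  names(seqs) <- rownames(panel)
  dna <- ape::as.DNAbin(seqs)
  expect_equal(unname(as.matrix(ape::dist.dna(dna, model = "raw",
                                              pairwise.deletion = TRUE))),
               unname(raw), tolerance = 1e-12)
  expect_equal(unname(as.matrix(ape::dist.dna(dna, model = "JC69",
                                              pairwise.deletion = TRUE))),
               unname(jc), tolerance = 1e-12)
})

test_that("generating-tree tip ages match their construction", {
  tr <- dating_tree(100000)
  ages <- tip_ages(tr)
  expect_equal(unname(ages["Q"]), 100000)
  expect_equal(unname(ages["M1"]), 0)
  expect_equal(unname(ages["O1"]), 0)
})

test_that("a query identical to the modern tips dates to exactly 0", {
  set.seed(55)
  L <- 2000L
  modern <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
  outg <- strsplit(modern, "")[[1]]
  flip <- sample.int(L, 100)
  outg[flip] <- ifelse(outg[flip] == "A", "G", "A")
  p <- panel_alignment(
    c(O1 = paste(outg, collapse = ""), M1 = modern, M2 = modern,
      Q = modern),
    group = c(O1 = "outgroup", M1 = "modern", M2 = "modern",
              Q = "query"))
  est <- estimate_tip_age(p, "Q", rate = 2.5e-8, bootstrap_B = 100,
                          seed = 1)
  expect_equal(est$delta, 0)
  expect_equal(est$age_point, 0)
})

test_that("constructed extra-substitution counts give exact arithmetic", {
  # moderns carry exactly k more derived substitutions toward the
  # outgroup than the query over L compared sites, no homoplasy:
  # age = (jc(d0 + k/L) - jc(d0)) / rate by hand
  L <- 10000L
  k <- 25L
  base <- rep("A", L)
  outg <- base; outg[1:400] <- "G"          # outgroup-only changes
  query <- base; query[401:500] <- "C"      # shared drift: 100 subs
  modern <- query; modern[501:(500 + k)] <- "T"  # k extra on moderns
  p <- panel_alignment(
    c(O1 = paste(outg, collapse = ""),
      M1 = paste(modern, collapse = ""), M2 = paste(modern, collapse = ""),
      Q = paste(query, collapse = "")),
    group = c(O1 = "outgroup", M1 = "modern", M2 = "modern", Q = "query"))
  rate <- 2.5e-8
  est <- estimate_tip_age(p, "Q", rate = rate, bootstrap_B = 50, seed = 1)
  jc <- function(d) -0.75 * log(1 - 4 / 3 * d)
  want <- (jc((400 + 100 + k) / L) - jc((400 + 100) / L)) / rate
  expect_equal(est$age_point, want, tolerance = 1e-10)
})

test_that("rescaling the clock rate rescales the age exactly", {
  cfg <- sim_config(ref_len = 5000, tree = dating_tree(80000),
                    groups = attr(dating_tree(80000), "group"), seed = 57)
  panel <- simulate_panel(cfg)
  e1 <- estimate_tip_age(panel, "Q", rate = 2.5e-8, bootstrap_B = 50,
                         seed = 4)
  e2 <- estimate_tip_age(panel, "Q", rate = 5.0e-8, bootstrap_B = 50,
                         seed = 4)
  expect_equal(e1$age_point, 2 * e2$age_point, tolerance = 1e-12)
  expect_equal(e1$ci_high, 2 * e2$ci_high, tolerance = 1e-12)
})

test_that("the estimator is deterministic under a fixed seed", {
  cfg <- sim_config(ref_len = 4000, tree = dating_tree(60000),
                    groups = attr(dating_tree(60000), "group"), seed = 58)
  panel <- simulate_panel(cfg)
  e1 <- estimate_tip_age(panel, "Q", bootstrap_B = 100, seed = 9)
  e2 <- estimate_tip_age(panel, "Q", bootstrap_B = 100, seed = 9)
  expect_identical(e1, e2)
})

test_that("the companion taxon has fewest differences to the query", {
  # the query splits basally with one companion (A1); on simulated
  # panels the companion should be its nearest neighbour by pairwise
  # differences
  hits <- 0L
  for (s in 1:3) {
    cfg <- sim_config(ref_len = 12000, tree = dating_tree(100000),
                      groups = attr(dating_tree(100000), "group"),
                      seed = 700 + s)
    panel <- simulate_panel(cfg)
    d <- distance_matrix(panel, "raw")
    others <- setdiff(rownames(panel), "Q")
    if (names(which.min(d["Q", others]))[1] == "A1") hits <- hits + 1L
  }
  expect_gte(hits, 2L)
})

test_that("bootstrap CI width shrinks roughly as 1/sqrt(L)", {
  # run at a higher rate so the missing-evolution signal is resolved
  # even at the shortest alignment (no clamping at 0)
  widths <- vapply(c(3000L, 12000L, 48000L), function(L) {
    cfg <- sim_config(ref_len = L, tree = dating_tree(100000),
                      groups = attr(dating_tree(100000), "group"),
                      subst_rate = 1e-7, seed = 59)
    panel <- simulate_panel(cfg)
    e <- estimate_tip_age(panel, "Q", rate = 1e-7, bootstrap_B = 200,
                          seed = 2)
    e$ci_high - e$ci_low
  }, numeric(1))
  expect_true(widths[1] > widths[2] && widths[2] > widths[3])
  # quadrupling L should roughly halve the width (within a factor ~2)
  expect_lt(widths[3] / widths[1], 0.7)
})

test_that("estimator rejects panels without the required groups", {
  p <- panel_alignment(c(a = "ACGT", b = "ACGT", q = "ACGT"),
                       group = c(a = "modern", b = "modern",
                                 q = "query"))
  expect_error(estimate_tip_age(p, "q"), "outgroup")
  expect_error(estimate_tip_age(p, "zz", rate = 1e-8), "outgroup|query")
})
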