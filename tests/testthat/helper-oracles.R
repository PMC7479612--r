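# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately re-derive results by the most literal
# route available (explicit loops, textbook formulas) so they share no
# code with the implementation under test.

# fragment builder: place seq on ref at start (0-based), defaults benign
frag <- function(start, seq, read_id = "r1", strand = "+", mapq = 37L,
                 library = "L1", truth_label = NA_character_) {
  aligned_fragments(read_id = read_id, ref_id = "MT", start = start,
                    end = start + nchar(seq), strand = strand,
                    mapq = mapq, library = library, seq = seq,
                    truth_label = truth_label)
}

frag_table <- function(...) {
  do.call(rbind, list(...))
}

random_ref <- function(L, seed = 1) {
  set.seed(seed)
  mt_reference("MT", paste(sample(c("A", "C", "G", "T"), L,
                                  replace = TRUE), collapse = ""))
}

# random fragments drawn directly on the reference (no damage), with
# optional per-base substitution noise
random_frags <- function(ref, n, len_range = c(35, 60), noise = 0,
                         seed = 1) {
  set.seed(seed)
  L <- nchar(ref$seq)
  lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  starts <- sample.int(L, n, replace = TRUE) - 1L
  doubled <- paste0(ref$seq, ref$seq)
  seqs <- substring(doubled, starts + 1L, starts + lens)
  if (noise > 0) {
    seqs <- vapply(seqs, function(s) {
      v <- strsplit(s, "")[[1]]
      hit <- runif(length(v)) < noise
      if (any(hit))
        v[hit] <- vapply(v[hit], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
      paste(v, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  aligned_fragments(read_id = sprintf("r%05d", seq_len(n)),
                    ref_id = "MT", start = starts, end = starts + lens,
                    strand = "+", mapq = 37L, library = "L1", seq = seqs)
}

# textbook Wilson score interval, coded independently of the package
oracle_wilson <- function(x, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(low = centre - half, high = centre + half)
}

# brute-force per-position consensus recount: independent tally via
# explicit loops over fragments and positions
oracle_consensus <- function(frags, ref, cov_threshold, support_threshold) {
  L <- nchar(ref$seq)
  counts <- matrix(0L, L, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  for (i in seq_len(nrow(frags))) {
    v <- strsplit(frags$seq[i], "")[[1]]
    for (j in seq_along(v)) {
      p <- (frags$start[i] + j - 1L) %% L
      if (v[j] %in% c("A", "C", "G", "T"))
        counts[p + 1L, v[j]] <- counts[p + 1L, v[j]] + 1L
    }
  }
  called <- character(L)
  for (p in seq_len(L)) {
    cov <- sum(counts[p, ])
    if (cov < cov_threshold) { called[p] <- "N"; next }
    mx <- max(counts[p, ])
    if (sum(counts[p, ] == mx) > 1L) { called[p] <- "N"; next }
    if (mx / cov < support_threshold - 1e-9) { called[p] <- "N"; next }
    called[p] <- names(which.max(counts[p, ]))
  }
  list(counts = counts, called = called)
}

# brute-force terminal C->T window scan
oracle_select_deaminated <- function(frags, ref, k_term) {
  L <- nchar(ref$seq)
  keep <- logical(nrow(frags))
  for (i in seq_len(nrow(frags))) {
    v <- strsplit(frags$seq[i], "")[[1]]
    n <- length(v)
    for (j in seq_len(n)) {
      if (j - 1L >= k_term && n - j >= k_term) next
      p <- (frags$start[i] + j - 1L) %% L
      rb <- substr(ref$seq, p + 1L, p + 1L)
      if (rb == "C" && v[j] == "T") { keep[i] <- TRUE; break }
    }
  }
  keep
}

# independent piecewise-linear interpolation
oracle_interp <- function(x0, y0, x) {
  vapply(x, function(xx) {
    i <- findInterval(xx, x0)
    if (i == 0) return(NA_real_)
    if (i >= length(x0)) return(if (xx == x0[length(x0)])
      y0[length(x0)] else NA_real_)
    w <- (xx - x0[i]) / (x0[i + 1] - x0[i])
    (1 - w) * y0[i] + w * y0[i + 1]
  }, numeric(1))
}

# diagnostic positions by exhaustive column scan
oracle_diagnostics <- function(panel) {
  grp <- attr(panel, "group")
  arch <- panel[names(grp)[grp == "archaic"], , drop = FALSE]
  mod <- panel[names(grp)[grp == "modern"], , drop = FALSE]
  hits <- integer(0)
  for (j in seq_len(ncol(panel))) {
    a <- unique(arch[, j]); m <- unique(mod[, j])
    if (length(a) == 1 && length(m) == 1 &&
        a %in% c("A", "C", "G", "T") && m %in% c("A", "C", "G", "T") &&
        a != m)
      hits <- c(hits, j - 1L)
  }
  hits
}

# generating tree with an ancient query tip: the query's terminal
# branch stops query_age years short of the present
dating_tree <- function(query_age = 100000) {
  txt <- sprintf(paste0(
    "(O1:1000000,((Q:%d,A1:130000):320000,((M1:120000,M2:120000):60000,",
    "(M3:150000,(M4:100000,M5:100000):50000):30000):270000):550000);"),
    130000 - query_age)
  tr <- ape::read.tree(text = txt)
  grp <- c(O1 = "outgroup", Q = "query", A1 = "archaic", M1 = "modern",
           M2 = "modern", M3 = "modern", M4 = "modern", M5 = "modern")
  attr(tr, "group") <- grp
  tr
}

# identity calibration curve mu(theta) = theta with constant sigma
identity_curve <- function(lo = 0, hi = 20000, step = 5, sigma = 1e-6) {
  grid <- seq(lo, hi, by = step)
  calibration_curve(grid, grid, rep(sigma, length(grid)))
}
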