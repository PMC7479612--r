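#' Configuration for the synthetic ancient-DNA generator
#'
#' Bundles every knob of the generator: the reference length, the
#' generating tree (an [ape::phylo] with edge lengths in years) with a
#' taxon-to-group map, the substitution rate, the fragmentation model
#' (truncated-normal lengths with a 35 bp floor), target coverage, the
#' contamination fraction, the terminal-deamination damage parameters for
#' the endogenous and the contaminant pool, the uniform sequencing-error
#' rate, and the seed. Identical configurations (same seed) produce
#' bit-identical datasets.
#'
#' Damage follows a single exponential decay from the nearer fragment
#' end, symmetric at both ends as in single-stranded library
#' preparations: a C at distance `i` (0-based) from the nearer end reads
#' as T with probability
#' `deam_baseline + (deam_pmax - deam_baseline) * exp(-deam_lambda * i)`.
#'
#' @param ref_len Reference length in sites.
#' @param tree Generating tree (`phylo`, edge lengths in years); default
#'   [default_panel_tree()].
#' @param groups Named character vector taxon -> group
#'   (archaic/modern/outgroup/query); defaults to the `group` attribute
#'   of `tree`.
#' @param subst_rate Substitutions per site per year.
#' @param frag_len_mean,frag_len_sd,min_len Fragment length model (bp).
#' @param target_coverage Mean fold-coverage to aim for.
#' @param contamination_frac Proportion of contaminant fragments in the
#'   mixture, in `[0, 1]`.
#' @param deam_pmax,deam_lambda,deam_baseline Damage parameters of the
#'   endogenous pool.
#' @param contam_deam_pmax,contam_deam_lambda,contam_deam_baseline Damage
#'   parameters of the contaminant pool (present-day contamination in
#'   ancient specimens is typically much less damaged, but rarely
#'   damage-free).
#' @param seq_error Per-base uniform sequencing-error probability.
#' @param seed Integer seed governing all randomness.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(ref_len = 16569L,
                       tree = default_panel_tree(),
                       groups = attr(tree, "group"),
                       subst_rate = 2.5e-8,
                       frag_len_mean = 50, frag_len_sd = 10, min_len = 35L,
                       target_coverage = 15,
                       contamination_frac = 0.02,
                       deam_pmax = 0.30, deam_lambda = 0.30,
                       deam_baseline = 0.01,
                       contam_deam_pmax = 0.06, contam_deam_lambda = 0.30,
                       contam_deam_baseline = 0.01,
                       seq_error = 0.001,
                       seed = 1L) {
  cfg <- list(ref_len = as.integer(ref_len), tree = tree, groups = groups,
              subst_rate = subst_rate, frag_len_mean = frag_len_mean,
              frag_len_sd = frag_len_sd, min_len = as.integer(min_len),
              target_coverage = target_coverage,
              contamination_frac = contamination_frac,
              deam_pmax = deam_pmax, deam_lambda = deam_lambda,
              deam_baseline = deam_baseline,
              contam_deam_pmax = contam_deam_pmax,
              contam_deam_lambda = contam_deam_lambda,
              contam_deam_baseline = contam_deam_baseline,
              seq_error = seq_error, seed = as.integer(seed))
  if (cfg$ref_len < cfg$min_len) stop("config error: ref_len < min_len")
  if (cfg$subst_rate < 0) stop("config error: subst_rate must be >= 0")
  if (cfg$contamination_frac < 0 || cfg$contamination_frac > 1)
    stop("config error: contamination_frac outside [0,1]")
  for (pre in c("deam", "contam_deam")) {
    p <- cfg[[paste0(pre, "_pmax")]]; b <- cfg[[paste0(pre, "_baseline")]]
    if (!(b <= p && p <= 1 && b >= 0))
      stop("config error: need 0 <= ", pre, "_baseline <= ", pre,
           "_pmax <= 1")
  }
  if (cfg$seq_error < 0 || cfg$seq_error > 1)
    stop("config error: seq_error outside [0,1]")
  if (cfg$target_coverage < 0)
    stop("config error: target_coverage must be >= 0")
  class(cfg) <- "sim_config"
  cfg
}

#' Default two-population generating tree
#'
#' A fixed ten-taxon topology emulating the comparative setting of
#' archaic-hominin mtDNA studies: an outgroup lineage splitting 1 Ma ago,
#' an archaic clade and a modern clade splitting 450 ka ago, with
#' within-clade diversification between 90 and 180 ka. Edge lengths are
#' in years; all tips are at the present (tip age 0). Ancient query tips
#' are added by shortening terminal branches (see [tip_ages()]).
#'
#' @return An [ape::phylo] tree with a `group` attribute mapping each
#'   taxon to archaic/modern/outgroup.
#' @export
default_panel_tree <- function() {
  txt <- paste0(
    "(O1:1000000,((A1:130000,(A2:90000,A3:90000):40000):320000,",
    "((M1:120000,M2:120000):60000,(M3:150000,(M4:100000,M5:100000)",
    ":50000):30000):270000):550000);")
  tr <- ape::read.tree(text = txt)
  grp <- c(O1 = "outgroup", A1 = "archaic", A2 = "archaic", A3 = "archaic",
           M1 = "modern", M2 = "modern", M3 = "modern", M4 = "modern",
           M5 = "modern")
  attr(tr, "group") <- grp
  tr
}

#' Tip ages implied by a generating tree
#'
#' Ages (years before present) computed from root-to-tip path lengths:
#' the deepest tip is taken to be at the present, shallower tips are
#' older by the difference. This is how ancient tips are encoded in a
#' generating tree: their terminal branch stops short.
#'
#' @param tree An [ape::phylo] with edge lengths in years.
#' @return Named numeric vector of tip ages.
#' @export
tip_ages <- function(tree) {
  d <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  stats::setNames(max(d) - d, tree$tip.label)
}

BASES <- c("A", "C", "G", "T")

#' Simulate an aligned sequence panel along a tree
#'
#' Draws a random root sequence and lets each branch accumulate a
#' Poisson(rate x duration x length) number of substitutions, placed
#' uniformly at random sites with a uniformly chosen different target
#' base (no indels, so the result is an alignment by construction).
#'
#' @param cfg A [sim_config()].
#' @param seed Seed; defaults to `cfg$seed`.
#' @return A [panel_alignment()] carrying the generating tree as
#'   attribute `tree`.
#' @export
simulate_panel <- function(cfg, seed = cfg$seed) {
  set.seed(seed)
  tree <- cfg$tree
  if (is.null(tree$edge.length) || any(tree$edge.length < 0))
    stop("config error: tree must have non-negative branch durations")
  L <- cfg$ref_len
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  seqs <- vector("list", nnode)
  seqs[[root]] <- sample(BASES, L, replace = TRUE)
  # preorder edge walk: ape trees store edges parent-before-child after
  # reorder(); cladewise order guarantees the parent sequence exists
  tree <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1L]; chi <- tree$edge[e, 2L]
    s <- seqs[[par]]
    nsub <- stats::rpois(1L, cfg$subst_rate * tree$edge.length[e] * L)
    if (nsub > 0L) {
      pos <- sample.int(L, nsub, replace = TRUE)
      shift <- sample.int(3L, nsub, replace = TRUE)
      cur <- match(s[pos], BASES)
      s[pos] <- BASES[((cur - 1L + shift) %% 4L) + 1L]
    }
    seqs[[chi]] <- s
  }
  m <- do.call(rbind, seqs[seq_len(ntip)])
  rownames(m) <- tree$tip.label
  out <- panel_alignment(m, group = cfg$groups)
  attr(out, "tree") <- cfg$tree
  out
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- round(stats::rnorm(n, mean, sd))
    out <- c(out, x[x >= lo & x <= hi])
  }
  as.integer(out[seq_len(n)])
}

#' Fragment a source sequence into aligned ancient-DNA-sized pieces
#'
#' Emits `round(target_coverage * ref_len / frag_len_mean)` fragments
#' with starts uniform on the circular reference and lengths from a
#' truncated normal (floor `min_len`); fragments may span the origin, in
#' which case `end` exceeds the reference length and bases continue from
#' position 0. Fragments carry undamaged source bases; pass them through
#' [apply_deamination()] to add damage and sequencing error.
#'
#' @param source_seq Source sequence: a string, an `mt_reference`, or a
#'   (panel, taxon) pair given as `panel_seq(panel, taxon)`.
#' @param cfg A [sim_config()].
#' @param library Library label stamped on each fragment.
#' @param truth_label Ground-truth label (`endogenous`/`contaminant`).
#' @param n Override the fragment count (default from coverage).
#' @param seed Seed; defaults to `cfg$seed`.
#' @return An `aligned_fragments` data frame.
#' @export
simulate_fragments <- function(source_seq, cfg, library = "L1",
                               truth_label = "endogenous", n = NULL,
                               seed = cfg$seed) {
  if (inherits(source_seq, "mt_reference")) source_seq <- source_seq$seq
  L <- nchar(source_seq)
  if (L < cfg$min_len) stop("source sequence shorter than min fragment")
  if (cfg$target_coverage < 0) stop("config error: negative coverage")
  set.seed(seed)
  if (is.null(n)) n <- round(cfg$target_coverage * L / cfg$frag_len_mean)
  if (n == 0L) {
    return(as_fragments(data.frame(
      read_id = character(0), ref_id = character(0), start = integer(0),
      end = integer(0), strand = character(0), mapq = integer(0),
      library = character(0), seq = character(0),
      truth_label = character(0), stringsAsFactors = FALSE)))
  }
  lens <- rtrunc_norm(n, cfg$frag_len_mean, cfg$frag_len_sd,
                      cfg$min_len, min(L, 10L * cfg$frag_len_mean))
  starts <- sample.int(L, n, replace = TRUE) - 1L
  doubled <- paste0(source_seq, source_seq)
  seqs <- substring(doubled, starts + 1L, starts + lens)
  as_fragments(data.frame(
    read_id = sprintf("%s_f%06d", library, seq_len(n)),
    ref_id = "MT", start = starts, end = starts + lens,
    strand = sample(c("+", "-"), n, replace = TRUE),
    mapq = 37L, library = library, seq = seqs,
    truth_label = truth_label, stringsAsFactors = FALSE))
}

#' Apply terminal deamination damage and sequencing error
#'
#' Each C in a fragment flips to T independently with probability
#' `baseline + (pmax - baseline) * exp(-lambda * i)` where `i` is the
#' 0-based distance to the nearer fragment end (both ends damaged
#' symmetrically, the single-stranded library behaviour; only the C->T
#' channel is modelled). Uniform sequencing error is applied afterwards:
#' every base independently becomes one of the three other bases with
#' probability `seq_error`.
#'
#' @param frags An `aligned_fragments` data frame with undamaged bases.
#' @param pmax,lambda,baseline Damage parameters (defaults from `cfg`).
#' @param seq_error Per-base error rate (default from `cfg`).
#' @param cfg Optional [sim_config()] supplying defaults.
#' @param seed Seed.
#' @return Fragments with damaged/error-bearing sequences; all other
#'   fields untouched.
#' @export
apply_deamination <- function(frags, cfg = NULL,
                              pmax = cfg$deam_pmax,
                              lambda = cfg$deam_lambda,
                              baseline = cfg$deam_baseline,
                              seq_error = cfg$seq_error,
                              seed = cfg$seed) {
  if (is.null(pmax) || is.null(lambda) || is.null(baseline) ||
      is.null(seq_error))
    stop("config error: supply cfg or all of pmax/lambda/baseline/seq_error")
  if (!(baseline <= pmax && pmax <= 1 && baseline >= 0))
    stop("config error: need 0 <= baseline <= pmax <= 1")
  if (nrow(frags) == 0L) return(frags)
  if (is.null(seed)) seed <- 1L
  set.seed(seed)
  bt <- fragment_base_table(frags)
  i_near <- pmin(bt$off, bt$len - 1L - bt$off)
  p <- baseline + (pmax - baseline) * exp(-lambda * i_near)
  base <- bt$base
  hit <- base == "C" & stats::runif(length(base)) < p
  base[hit] <- "T"
  if (seq_error > 0) {
    err <- stats::runif(length(base)) < seq_error & base != "N"
    if (any(err)) {
      shift <- sample.int(3L, sum(err), replace = TRUE)
      cur <- match(base[err], BASES)
      base[err] <- BASES[((cur - 1L + shift) %% 4L) + 1L]
    }
  }
  frags$seq <- vapply(split(base, bt$row), paste, character(1),
                      collapse = "")
  frags
}

#' Mix endogenous and contaminant fragment pools
#'
#' Builds a mixture of `n_total` fragments in which each slot is drawn
#' from the contaminant pool independently with probability
#' `contamination_frac` (so the realised contaminant count is
#' Binomial(n_total, frac)). Fragments are sampled from each pool
#' without replacement while the pool lasts (each simulated molecule is
#' distinct; amplification duplicates are the business of
#' [dedup_fragments()]'s input, not the mixer), falling back to
#' replacement only when a pool is smaller than its demand. Truth labels
#' are preserved; read identifiers are re-stamped to stay unique. Damage
#' is applied to each pool before mixing, with its own parameters —
#' present-day contamination typically carries far less deamination than
#' the endogenous fraction.
#'
#' @param endogenous_frags,contaminant_frags The two pools.
#' @param contamination_frac Probability a slot is contaminant.
#' @param n_total Mixture size (default: size of the endogenous pool).
#' @param seed Seed.
#' @return An `aligned_fragments` mixture.
#' @export
mix_contamination <- function(endogenous_frags, contaminant_frags,
                              contamination_frac,
                              n_total = nrow(endogenous_frags), seed = 1L) {
  if (contamination_frac < 0 || contamination_frac > 1)
    stop("config error: contamination_frac outside [0,1]")
  if (contamination_frac > 0 && contamination_frac < 1 &&
      (nrow(endogenous_frags) == 0L || nrow(contaminant_frags) == 0L))
    stop("config error: both pools must be non-empty for a true mixture")
  set.seed(seed)
  is_cont <- stats::runif(n_total) < contamination_frac
  pick <- integer(n_total)
  draw <- function(pool_n, k) sample.int(pool_n, k, replace = k > pool_n)
  if (any(!is_cont))
    pick[!is_cont] <- draw(nrow(endogenous_frags), sum(!is_cont))
  if (any(is_cont))
    pick[is_cont] <- draw(nrow(contaminant_frags), sum(is_cont))
  pool <- rbind(as.data.frame(endogenous_frags)[need_cols()],
                as.data.frame(contaminant_frags)[need_cols()])
  out <- pool[pick + ifelse(is_cont, nrow(endogenous_frags), 0L), ,
              drop = FALSE]
  out$read_id <- sprintf("mix_%06d_%s", seq_len(n_total), out$read_id)
  rownames(out) <- NULL
  as_fragments(out)
}

#' Simulate a full labelled ancient-DNA dataset
#'
#' End-to-end generator: simulates the panel along the configured tree,
#' takes a modern taxon as the mapping reference (the real pipeline maps
#' against the modern human rCRS), fragments one archaic taxon as the
#' endogenous source and a second modern taxon as the present-day
#' contaminant, damages each pool with its own parameters, and mixes them
#' at the configured contamination fraction.
#'
#' @param cfg A [sim_config()].
#' @param endo_taxon,contam_taxon,ref_taxon Taxon names used as the
#'   endogenous source, the contaminant source, and the mapping
#'   reference.
#' @param n_fragments Override the mixture size (default: fragment count
#'   implied by `target_coverage`).
#' @return A list of class `sim_dataset` with elements `ref`
#'   (`mt_reference`), `panel` (`panel_alignment`), `fragments`
#'   (labelled mixture), and `cfg`.
#' @export
simulate_dataset <- function(cfg, endo_taxon = "A1", contam_taxon = "M2",
                             ref_taxon = "M1", n_fragments = NULL) {
  panel <- simulate_panel(cfg, seed = cfg$seed)
  ref <- mt_reference("MT", panel_seq(panel, ref_taxon))
  n_total <- if (!is.null(n_fragments)) as.integer(n_fragments)
             else round(cfg$target_coverage * cfg$ref_len / cfg$frag_len_mean)
  endo <- simulate_fragments(panel_seq(panel, endo_taxon), cfg,
                             library = "L1", truth_label = "endogenous",
                             n = n_total, seed = cfg$seed + 1L)
  cont <- simulate_fragments(panel_seq(panel, contam_taxon), cfg,
                             library = "L1", truth_label = "contaminant",
                             n = n_total, seed = cfg$seed + 2L)
  endo <- apply_deamination(endo, pmax = cfg$deam_pmax,
                            lambda = cfg$deam_lambda,
                            baseline = cfg$deam_baseline,
                            seq_error = cfg$seq_error, seed = cfg$seed + 3L)
  cont <- apply_deamination(cont, pmax = cfg$contam_deam_pmax,
                            lambda = cfg$contam_deam_lambda,
                            baseline = cfg$contam_deam_baseline,
                            seq_error = cfg$seq_error, seed = cfg$seed + 4L)
  frags <- mix_contamination(endo, cont, cfg$contamination_frac,
                             n_total = n_total, seed = cfg$seed + 5L)
  structure(list(ref = ref, panel = panel, fragments = frags, cfg = cfg),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("<sim_dataset>\n  "); print(x$ref)
  cat("  "); print(x$panel)
  cat("  "); print(x$fragments)
  cat(sprintf("  contamination_frac=%.3g seed=%d\n",
              x$cfg$contamination_frac, x$cfg$seed))
  invisible(x)
}
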