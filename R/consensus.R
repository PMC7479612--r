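#' Collapse PCR duplicates by alignment coordinates
#'
#' Fragments with identical alignment start and end points (and, by
#' default, strand) are treated as PCR copies of one original molecule
#' and collapsed to a single fragment whose per-position base is the
#' within-group majority; ties become N. The group size is recorded as a
#' `;dup=k` suffix on the surviving read identifier. Idempotent.
#'
#' @param frags An `aligned_fragments` data frame.
#' @param use_strand Include strand in the duplicate key (the
#'   conservative reading of "identical start and end points"); set
#'   `FALSE` to collapse across strands.
#' @return Deduplicated `aligned_fragments`.
#' @export
dedup_fragments <- function(frags, use_strand = TRUE) {
  if (nrow(frags) == 0L) return(frags)
  key <- if (use_strand) paste(frags$start, frags$end, frags$strand)
         else paste(frags$start, frags$end)
  grp <- split(seq_len(nrow(frags)), key)
  first <- vapply(grp, `[`, integer(1), 1L)
  out <- frags[sort(first), , drop = FALSE]
  multi <- grp[lengths(grp) > 1L]
  if (length(multi)) {
    for (g in multi) {
      m <- do.call(rbind, strsplit(frags$seq[g], ""))
      cons <- apply(m, 2L, function(col) {
        col <- col[col != "N"]
        if (!length(col)) return("N")
        tb <- table(col)
        top <- names(tb)[tb == max(tb)]
        if (length(top) == 1L) top else "N"
      })
      i <- match(g[1L], sort(first))
      out$seq[i] <- paste(cons, collapse = "")
      out$read_id[i] <- sprintf("%s;dup=%d", frags$read_id[g[1L]],
                                length(g))
    }
  }
  rownames(out) <- NULL
  out
}

#' Call a consensus sequence with coverage and support thresholds
#'
#' Builds a per-position pileup of unique fragments (duplicates are
#' collapsed first unless `dedup = FALSE`) and calls, at every reference
#' position, the majority base provided the position is covered by at
#' least `cov_threshold` unique fragments and the majority base is
#' supported by at least `support_threshold` of them; otherwise N with
#' the corresponding exclusion flag. The support comparison is
#' inclusive: with the default 2/3 threshold a 2-of-3 position passes —
#' positions are excluded only when strictly fewer than two thirds of
#' the fragments agree. Majority ties give N with the low-support flag.
#' N read bases contribute to neither counts nor coverage. No randomness
#' anywhere: the calls are a deterministic function of the pileup.
#'
#' @param frags An `aligned_fragments` data frame.
#' @param ref The `mt_reference`.
#' @param cov_threshold Minimum unique-fragment coverage (default 3,
#'   i.e. positions covered by two or fewer sequences are excluded).
#' @param support_threshold Minimum majority support (default 2/3).
#' @param dedup Collapse duplicates first (default TRUE).
#' @param use_strand Passed to [dedup_fragments()].
#' @return A data frame of class `consensus_calls` with one row per
#'   reference position: `pos`, base counts `A`,`C`,`G`,`T`, `coverage`,
#'   `support` (NA at coverage 0), `called`, `flag_low_coverage`,
#'   `flag_low_support`; attributes `consensus` (the called sequence as
#'   one string), `cov_threshold`, `support_threshold`.
#' @export
call_consensus <- function(frags, ref, cov_threshold = 3L,
                           support_threshold = 2 / 3, dedup = TRUE,
                           use_strand = TRUE) {
  L <- nchar(ref$seq)
  if (nrow(frags) > 0L) {
    if (!ref$circular && any(frags$end > L))
      stop("record error: fragment outside linear reference")
    if (any(frags$end - frags$start > L))
      stop("record error: fragment longer than the reference")
    if (dedup) frags <- dedup_fragments(frags, use_strand = use_strand)
  }
  counts <- matrix(0L, nrow = L, ncol = 4L,
                   dimnames = list(NULL, BASES))
  if (nrow(frags) > 0L) {
    bt <- fragment_base_table(frags, ref)
    bi <- match(bt$base, BASES)
    ok <- !is.na(bi)
    tab <- tabulate((bt$pos[ok]) * 4L + bi[ok], nbins = 4L * L)
    counts <- matrix(tab, nrow = L, ncol = 4L, byrow = TRUE,
                     dimnames = list(NULL, BASES))
  }
  coverage <- rowSums(counts)
  maxc <- pmax(counts[, 1], counts[, 2], counts[, 3], counts[, 4])
  n_top <- rowSums(counts == maxc) * (maxc > 0L)
  support <- ifelse(coverage > 0L, maxc / coverage, NA_real_)
  eps <- 1e-9
  ok_cov <- coverage >= cov_threshold
  ok_sup <- !is.na(support) & support >= support_threshold - eps &
    n_top == 1L
  called <- rep("N", L)
  hit <- ok_cov & ok_sup
  called[hit] <- BASES[max.col(counts[hit, , drop = FALSE],
                               ties.method = "first")]
  out <- data.frame(pos = 0:(L - 1L), counts, coverage = coverage,
                    support = support, called = called,
                    flag_low_coverage = !ok_cov,
                    flag_low_support = ok_cov & !ok_sup)
  attr(out, "consensus") <- paste(called, collapse = "")
  attr(out, "cov_threshold") <- cov_threshold
  attr(out, "support_threshold") <- support_threshold
  class(out) <- c("consensus_calls", "data.frame")
  out
}

#' @export
print.consensus_calls <- function(x, ...) {
  cat(sprintf(
    "<consensus_calls> %d positions, mean coverage %.1f, %d called N (%d low-coverage, %d low-support)\n",
    nrow(x), mean(x$coverage), sum(x$called == "N"),
    sum(x$flag_low_coverage), sum(x$flag_low_support)))
  invisible(x)
}

#' Extract the consensus sequence
#'
#' @param calls A `consensus_calls` data frame.
#' @param id Label for the resulting reference.
#' @return An `mt_reference` holding the called sequence (N at excluded
#'   positions).
#' @export
consensus_sequence <- function(calls, id = "consensus") {
  mt_reference(id, attr(calls, "consensus"))
}

#' Audit consensus coverage and exclusion counts
#'
#' Summarises a consensus run the way ancient-mtDNA studies report it:
#' the number of positions excluded for low coverage (covered by fewer
#' than `cov_threshold` unique fragments), the number excluded for low
#' support (adequate coverage but under the support threshold, including
#' majority ties), and the mean unique-fragment coverage over all
#' reference positions.
#'
#' @param calls A `consensus_calls` data frame covering every reference
#'   position.
#' @param ref_len Reference length the calls must span.
#' @param cov_threshold,support_threshold Thresholds to audit at
#'   (default: the ones stored on `calls`).
#' @return An object of class `consensus_audit`: list with
#'   `n_low_coverage`, `n_low_support`, `mean_coverage`.
#' @export
audit_consensus <- function(calls, ref_len,
                            cov_threshold = attr(calls, "cov_threshold"),
                            support_threshold = attr(calls,
                                                     "support_threshold")) {
  if (nrow(calls) != ref_len || !all(calls$pos == seq_len(ref_len) - 1L))
    stop("audit error: calls must cover positions 0..ref_len-1 exactly")
  eps <- 1e-9
  cnt <- as.matrix(calls[, BASES])
  maxc <- pmax(cnt[, 1], cnt[, 2], cnt[, 3], cnt[, 4])
  tie <- rowSums(cnt == maxc) > 1L & maxc > 0L
  low_cov <- calls$coverage <= cov_threshold - 1L
  low_sup <- !low_cov &
    (tie | ifelse(calls$coverage > 0L, maxc / calls$coverage, 0) <
       support_threshold - eps)
  structure(list(n_low_coverage = sum(low_cov),
                 n_low_support = sum(low_sup),
                 mean_coverage = mean(calls$coverage)),
            class = "consensus_audit")
}

#' @export
print.consensus_audit <- function(x, ...) {
  cat(sprintf(
    "<consensus_audit> mean coverage %.1f-fold; %d low-coverage and %d low-support positions\n",
    x$mean_coverage, x$n_low_coverage, x$n_low_support))
  invisible(x)
}
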