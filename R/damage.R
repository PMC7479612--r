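#' Profile terminal C-to-T deamination damage
#'
#' For each offset `0..K-1` from the 5' end (and, separately, from the
#' 3' end) computes the C->T mismatch frequency against the reference:
#' the number of fragments whose reference base at that offset is C and
#' whose read base is T, divided by the number of fragments whose
#' reference base there is C. Elevated frequencies at the ends, decaying
#' towards the interior, are the classic authenticity signature of
#' ancient DNA from single-stranded libraries.
#'
#' A position of a fragment shorter than `2K` is counted towards the
#' nearer end only (ties go to the 5' end), so no base is double-counted.
#' Read-side N bases are excluded from numerator and denominator.
#'
#' @param frags An `aligned_fragments` data frame.
#' @param ref The `mt_reference` the fragments are aligned to.
#' @param K Number of terminal offsets to profile.
#' @return An object of class `damage_profile`: list with `offsets`
#'   (0-based), `ct_freq_5p`, `ct_freq_3p` (NA where there were no
#'   reference-C opportunities), and a `counts` data frame
#'   (offset, end, opportunities, mismatches, freq).
#' @export
profile_damage <- function(frags, ref, K = 15L) {
  stopifnot(K >= 1L)
  opp5 <- mis5 <- opp3 <- mis3 <- integer(K)
  if (nrow(frags) > 0L) {
    bt <- fragment_base_table(frags, ref)
    rb <- ref_bases_at(ref, bt$pos)
    i5 <- bt$off
    i3 <- bt$len - 1L - bt$off
    to5 <- i5 <= i3            # nearer the 5' end (ties to 5')
    is_opp <- rb == "C" & bt$base != "N"
    is_mis <- is_opp & bt$base == "T"
    sel5 <- to5 & i5 < K & is_opp
    sel3 <- !to5 & i3 < K & is_opp
    opp5 <- tabulate(i5[sel5] + 1L, K)
    mis5 <- tabulate(i5[sel5 & is_mis] + 1L, K)
    opp3 <- tabulate(i3[sel3] + 1L, K)
    mis3 <- tabulate(i3[sel3 & is_mis] + 1L, K)
  }
  f5 <- ifelse(opp5 > 0L, mis5 / opp5, NA_real_)
  f3 <- ifelse(opp3 > 0L, mis3 / opp3, NA_real_)
  counts <- data.frame(
    offset = rep(0:(K - 1L), 2L),
    end = rep(c("5p", "3p"), each = K),
    opportunities = c(opp5, opp3),
    mismatches = c(mis5, mis3),
    freq = c(f5, f3))
  structure(list(offsets = 0:(K - 1L), ct_freq_5p = f5, ct_freq_3p = f3,
                 counts = counts, n_fragments = nrow(frags)),
            class = "damage_profile")
}

#' @export
print.damage_profile <- function(x, ...) {
  cat(sprintf("<damage_profile> %d fragments, K=%d\n", x$n_fragments,
              length(x$offsets)))
  show <- seq_len(min(5L, length(x$offsets)))
  cat("  offset :", sprintf("%6d", x$offsets[show]), "\n")
  cat("  C>T 5' :", sprintf("%6.3f", x$ct_freq_5p[show]), "\n")
  cat("  C>T 3' :", sprintf("%6.3f", x$ct_freq_3p[show]), "\n")
  invisible(x)
}

#' @method plot damage_profile
#' @export
plot.damage_profile <- function(x, ...) {
  ylim <- c(0, max(0.05, x$ct_freq_5p, x$ct_freq_3p, na.rm = TRUE))
  graphics::plot(x$offsets, x$ct_freq_5p, type = "b", pch = 16, col = "red3",
                 ylim = ylim, xlab = "distance from fragment end (bp)",
                 ylab = "C>T mismatch frequency", ...)
  graphics::lines(x$offsets, x$ct_freq_3p, type = "b", pch = 1,
                  col = "blue3")
  graphics::legend("topright", c("5' end", "3' end"),
                   col = c("red3", "blue3"), pch = c(16, 1), lty = 1,
                   bty = "n")
  invisible(x)
}

#' Select putatively deaminated fragments
#'
#' Keeps fragments showing at least one C(reference) -> T(read) mismatch
#' within the first `k_term` positions from the 5' end or the last
#' `k_term` positions from the 3' end. Restricting analyses to this
#' subset enriches for genuinely ancient molecules, since present-day
#' contamination carries little terminal deamination. With
#' `both_channels = TRUE` the G->A channel is also accepted (the
#' double-stranded library signature); the default models single-stranded
#' libraries, which show C->T at both ends.
#'
#' Idempotent; enlarging `k_term` never shrinks the selection; input
#' order is preserved.
#'
#' @param frags An `aligned_fragments` data frame.
#' @param ref The `mt_reference`.
#' @param k_term Terminal window size in bp.
#' @param both_channels Also accept G->A mismatches.
#' @return The selected subset, same class.
#' @export
select_deaminated <- function(frags, ref, k_term = 3L,
                              both_channels = FALSE) {
  stopifnot(k_term >= 1L)
  if (nrow(frags) == 0L) return(frags)
  bt <- fragment_base_table(frags, ref)
  rb <- ref_bases_at(ref, bt$pos)
  i5 <- bt$off
  i3 <- bt$len - 1L - bt$off
  term <- i5 < k_term | i3 < k_term
  hit <- term & rb == "C" & bt$base == "T"
  if (both_channels) hit <- hit | (term & rb == "G" & bt$base == "A")
  keep_rows <- sort(unique(bt$row[hit]))
  out <- frags[keep_rows, , drop = FALSE]
  rownames(out) <- NULL
  out
}
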