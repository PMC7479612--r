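#' Derive diagnostic positions from an alignment panel
#'
#' A diagnostic position is an alignment column at which every archaic
#' taxon shares one non-N state and every modern taxon shares a
#' different non-N state — the fixed differences that let individual
#' short fragments be assigned to a source population. Columns with any
#' within-group variation, any gap, or any N in either group are
#' excluded. Outgroup and query rows are ignored.
#'
#' @param panel A [panel_alignment()] with a `group` attribute containing
#'   at least one `archaic` and one `modern` taxon.
#' @return A data frame of class `diagnostic_positions` with columns
#'   `pos` (0-based alignment column), `archaic_state`, `modern_state`,
#'   sorted by position.
#' @export
find_diagnostic_positions <- function(panel) {
  grp <- attr(panel, "group")
  if (is.null(grp)) stop("config error: panel has no group attribute")
  arch <- panel[names(grp)[grp == "archaic"], , drop = FALSE]
  mod <- panel[names(grp)[grp == "modern"], , drop = FALSE]
  if (nrow(arch) == 0L || nrow(mod) == 0L)
    stop("config error: panel needs >=1 archaic and >=1 modern taxon")
  fixed_state <- function(m) {
    s <- m[1L, ]
    ok <- colSums(m == rep(s, each = nrow(m))) == nrow(m) &
      s %in% c("A", "C", "G", "T")
    s[!ok] <- NA_character_
    s
  }
  sa <- fixed_state(arch)
  sm <- fixed_state(mod)
  keep <- which(!is.na(sa) & !is.na(sm) & sa != sm)
  out <- data.frame(pos = keep - 1L, archaic_state = sa[keep],
                    modern_state = sm[keep], row.names = NULL)
  class(out) <- c("diagnostic_positions", "data.frame")
  out
}

#' Classify fragments at diagnostic positions
#'
#' Assigns each fragment to a putative source by majority vote over the
#' diagnostic positions it overlaps: `endogenous` if it matches the
#' archaic state more often than the modern state, `contaminant` if the
#' reverse, `ambiguous` on a tie with at least one informative position,
#' and `uninformative` if it overlaps none. Third states (the fragment
#' base equals neither panel state — damage or sequencing error) count
#' towards `n_informative` by default but match neither state; set
#' `third_state = "skip"` to drop them from the informative count.
#'
#' `exclude_damage_like = TRUE` removes diagnostic positions whose
#' archaic/modern contrast is C/T or G/A before counting, since terminal
#' deamination mimics those contrasts.
#'
#' The summary attribute reports, overall and per library, the fraction
#' of state matches that hit the archaic state:
#' `sum(n_archaic_match) / sum(n_archaic_match + n_modern_match)`.
#'
#' @param frags An `aligned_fragments` data frame.
#' @param diagnostics A `diagnostic_positions` data frame.
#' @param ref Optional `mt_reference` (needed only so fragments spanning
#'   the circular origin are placed modulo the reference length).
#' @param third_state `"count"` (default) or `"skip"`.
#' @param exclude_damage_like Drop C/T and G/A contrasts.
#' @return A data frame of class `fragment_assignments` with one row per
#'   fragment (`read_id`, `library`, `truth_label`, `n_informative`,
#'   `n_archaic_match`, `n_modern_match`, `call`) and attribute
#'   `summary`: list with `fraction_archaic_overall`, `per_library`
#'   (data frame), and call counts.
#' @export
classify_fragments <- function(frags, diagnostics, ref = NULL,
                               third_state = c("count", "skip"),
                               exclude_damage_like = FALSE) {
  third_state <- match.arg(third_state)
  if (nrow(diagnostics) == 0L)
    stop("config error: no diagnostic positions supplied")
  if (exclude_damage_like) {
    pair <- paste(pmin(diagnostics$archaic_state, diagnostics$modern_state),
                  pmax(diagnostics$archaic_state, diagnostics$modern_state))
    diagnostics <- diagnostics[!pair %in% c("C T", "A G"), , drop = FALSE]
  }
  n <- nrow(frags)
  n_inf <- n_arch <- n_mod <- integer(n)
  if (n > 0L && nrow(diagnostics) > 0L) {
    L <- if (!is.null(ref)) nchar(ref$seq) else NA_integer_
    lens <- frags$end - frags$start
    for (k in seq_len(nrow(diagnostics))) {
      p <- diagnostics$pos[k]
      off <- p - frags$start
      if (!is.na(L)) off <- off %% L
      idx <- which(off >= 0L & off < lens)
      if (!length(idx)) next
      b <- substring(frags$seq[idx], off[idx] + 1L, off[idx] + 1L)
      a_hit <- b == diagnostics$archaic_state[k]
      m_hit <- b == diagnostics$modern_state[k]
      informative <- if (third_state == "count") b != "N" else a_hit | m_hit
      n_inf[idx] <- n_inf[idx] + informative
      n_arch[idx] <- n_arch[idx] + a_hit
      n_mod[idx] <- n_mod[idx] + m_hit
    }
  }
  call <- rep("uninformative", n)
  call[n_inf > 0L & n_arch > n_mod] <- "endogenous"
  call[n_inf > 0L & n_mod > n_arch] <- "contaminant"
  call[n_inf > 0L & n_arch == n_mod] <- "ambiguous"
  out <- data.frame(read_id = frags$read_id, library = frags$library,
                    truth_label = frags$truth_label,
                    n_informative = n_inf, n_archaic_match = n_arch,
                    n_modern_match = n_mod, call = call,
                    stringsAsFactors = FALSE)
  frac <- function(a, m) if (a + m > 0) a / (a + m) else NA_real_
  per_lib <- do.call(rbind, lapply(split(out, out$library), function(d) {
    data.frame(library = d$library[1],
               fraction_archaic = frac(sum(d$n_archaic_match),
                                       sum(d$n_modern_match)),
               n_fragments = nrow(d), row.names = NULL)
  }))
  attr(out, "summary") <- list(
    fraction_archaic_overall = frac(sum(n_arch), sum(n_mod)),
    per_library = per_lib,
    calls = table(factor(call, levels = c("endogenous", "contaminant",
                                          "ambiguous", "uninformative"))))
  class(out) <- c("fragment_assignments", "data.frame")
  out
}

#' @export
print.fragment_assignments <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("<fragment_assignments> %d fragments\n", nrow(x)))
  cat("  calls:", paste(sprintf("%s=%d", names(s$calls), s$calls),
                        collapse = ", "), "\n")
  cat(sprintf("  fraction matching archaic state: %.3f\n",
              s$fraction_archaic_overall))
  invisible(x)
}

# Wilson score interval via prop.test (no continuity correction)
wilson_ci <- function(x, n, conf = 0.95) {
  ci <- stats::prop.test(x, n, correct = FALSE,
                         conf.level = conf)$conf.int
  c(low = ci[1], high = ci[2])
}

#' Estimate present-day contamination from fragment assignments
#'
#' Point estimate: the fraction of decided fragments (calls `endogenous`
#' or `contaminant`) that were called contaminant; ambiguous and
#' uninformative fragments are excluded. The 95% interval is the Wilson
#' score interval, which behaves sensibly at small counts and at 0.
#' Reported overall and per library. To condition on putatively
#' deaminated fragments, pass the output of [select_deaminated()]
#' through [classify_fragments()] first and set
#' `scope = "deaminated_only"` (a label recording that provenance).
#'
#' @param assignments A `fragment_assignments` data frame.
#' @param scope `"all"` or `"deaminated_only"`; metadata describing the
#'   upstream fragment stream.
#' @return An object of class `contamination_estimate`: list with
#'   `point`, `ci_low`, `ci_high`, `n_informative_frags` (decided
#'   fragments), `n_endogenous`, `n_contaminant`, `scope`, `per_library`
#'   (data frame with the same fields per library).
#' @export
estimate_contamination <- function(assignments,
                                   scope = c("all", "deaminated_only")) {
  scope <- match.arg(scope)
  est_one <- function(d) {
    n_e <- sum(d$call == "endogenous")
    n_c <- sum(d$call == "contaminant")
    if (n_e + n_c == 0L) return(NULL)
    ci <- wilson_ci(n_c, n_e + n_c)
    list(point = n_c / (n_e + n_c), ci_low = unname(ci["low"]),
         ci_high = unname(ci["high"]), n_informative_frags = n_e + n_c,
         n_endogenous = n_e, n_contaminant = n_c)
  }
  overall <- est_one(assignments)
  if (is.null(overall))
    stop("estimation error: no fragments with a decided ",
         "(endogenous/contaminant) call")
  per_lib <- do.call(rbind, lapply(split(assignments, assignments$library),
    function(d) {
      e <- est_one(d)
      if (is.null(e)) return(NULL)
      data.frame(library = d$library[1], point = e$point,
                 ci_low = e$ci_low, ci_high = e$ci_high,
                 n_informative_frags = e$n_informative_frags,
                 row.names = NULL)
    }))
  structure(c(overall, list(scope = scope, per_library = per_lib)),
            class = "contamination_estimate")
}

#' @export
print.contamination_estimate <- function(x, ...) {
  cat(sprintf(
    "<contamination_estimate> scope=%s\n  point %.4f (95%% Wilson CI %.4f-%.4f), %d decided fragments (%d contaminant)\n",
    x$scope, x$point, x$ci_low, x$ci_high, x$n_informative_frags,
    x$n_contaminant))
  invisible(x)
}
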