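write_kv <- function(x, path) {
  writeLines(sprintf("%s=%s", names(x), vapply(x, format, character(1))),
             path)
  invisible(path)
}

#' Run the full ancient-mtDNA analysis pipeline
#'
#' Chains the package's stages in the standard order — length/MAPQ
#' filter, duplicate collapse, damage profiling, deaminated-fragment
#' selection, diagnostic-position classification with contamination
#' estimates (all fragments and deaminated-only), consensus calling with
#' audit, and optionally branch-shortening tip dating — writing one
#' plain-text artifact per stage plus a manifest with MD5 checksums of
#' inputs and outputs. The pipeline itself is deterministic except for
#' the dating bootstrap, which is governed by `seed`; rerunning with the
#' same inputs and seed reproduces byte-identical artifacts.
#'
#' @param fragments An `aligned_fragments` data frame, or a path to a
#'   fragment TSV/SAM file.
#' @param ref An `mt_reference` or FASTA path.
#' @param panel A [panel_alignment()] or aligned-FASTA path (requires
#'   `panel_groups` when read from file).
#' @param out_dir Output directory (created if needed).
#' @param panel_groups Named group vector for a panel read from file.
#' @param min_len,min_mapq Fragment filter thresholds.
#' @param k_term Terminal window for deaminated-fragment selection.
#' @param cov_threshold,support_threshold Consensus thresholds.
#' @param query_name Optional taxon to date by branch shortening.
#' @param rate,bootstrap_B Dating parameters.
#' @param dialect Fragment file dialect when `fragments` is a path.
#' @param seed Seed for the dating bootstrap.
#' @return Invisibly, a list with the per-stage results and the artifact
#'   paths.
#' @export
run_pipeline <- function(fragments, ref, panel, out_dir,
                         panel_groups = NULL,
                         min_len = 35L, min_mapq = 25L, k_term = 3L,
                         cov_threshold = 3L, support_threshold = 2 / 3,
                         query_name = NULL, rate = 2.5e-8,
                         bootstrap_B = 500L,
                         dialect = c("tsv", "sam"), seed = 1L) {
  dialect <- match.arg(dialect)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- character(0)
  if (is.character(fragments)) {
    inputs <- c(inputs, fragments = fragments)
    fragments <- read_fragments(fragments, dialect)
  }
  if (is.character(ref)) {
    inputs <- c(inputs, ref = ref)
    ref <- read_fasta(ref, "reference")
  }
  if (is.character(panel)) {
    inputs <- c(inputs, panel = panel)
    panel <- read_fasta(panel, "panel", group = panel_groups)
  }
  art <- function(f) file.path(out_dir, f)
  paths <- character(0)
  step <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  filtered <- step("filter",
                   filter_fragments(fragments, min_len, min_mapq))
  write_fragments(filtered, paths["filtered"] <- art("filtered.tsv"))

  unique_frags <- step("dedup", dedup_fragments(filtered))
  write_fragments(unique_frags, paths["dedup"] <- art("unique.tsv"))

  prof <- step("damage", profile_damage(unique_frags, ref))
  utils::write.table(prof$counts,
                     paths["damage"] <- art("damage_profile.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  deam <- step("select_deaminated",
               select_deaminated(unique_frags, ref, k_term))
  write_fragments(deam, paths["deaminated"] <- art("deaminated.tsv"))

  diag <- step("diagnostics", find_diagnostic_positions(panel))
  utils::write.table(as.data.frame(diag),
                     paths["diagnostics"] <- art("diagnostic_positions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  asg_all <- step("classify", classify_fragments(unique_frags, diag, ref))
  utils::write.table(as.data.frame(asg_all),
                     paths["assignments"] <- art("assignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  asg_deam <- step("classify_deaminated",
                   classify_fragments(deam, diag, ref))

  est_all <- step("contamination",
                  estimate_contamination(asg_all, "all"))
  est_deam <- tryCatch(estimate_contamination(asg_deam, "deaminated_only"),
                       error = function(e) NULL)
  s_all <- attr(asg_all, "summary")
  s_deam <- attr(asg_deam, "summary")
  kv <- c(fraction_archaic_all = s_all$fraction_archaic_overall,
          fraction_archaic_deaminated = s_deam$fraction_archaic_overall,
          contamination_all = est_all$point,
          contamination_all_ci_low = est_all$ci_low,
          contamination_all_ci_high = est_all$ci_high)
  if (!is.null(est_deam))
    kv <- c(kv, contamination_deaminated = est_deam$point,
            contamination_deaminated_ci_low = est_deam$ci_low,
            contamination_deaminated_ci_high = est_deam$ci_high)
  write_kv(kv, paths["contamination"] <- art("contamination.txt"))

  calls <- step("consensus",
                call_consensus(unique_frags, ref, cov_threshold,
                               support_threshold, dedup = FALSE))
  utils::write.table(as.data.frame(calls),
                     paths["consensus_tsv"] <- art("consensus.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_fasta(consensus_sequence(calls),
              paths["consensus_fasta"] <- art("consensus.fasta"))
  audit <- step("audit",
                audit_consensus(calls, nchar(ref$seq)))
  write_kv(list(mean_coverage = audit$mean_coverage,
                n_low_coverage = audit$n_low_coverage,
                n_low_support = audit$n_low_support),
           paths["audit"] <- art("audit.txt"))

  dating <- NULL
  if (!is.null(query_name)) {
    dating <- step("dating",
                   estimate_tip_age(panel, query_name, rate = rate,
                                    bootstrap_B = bootstrap_B,
                                    seed = seed))
    write_kv(list(age_point = dating$age_point, ci_low = dating$ci_low,
                  ci_high = dating$ci_high, rate = dating$rate_used,
                  n_sites = dating$n_sites, delta = dating$delta),
             paths["dating"] <- art("dating.txt"))
  }

  manifest <- c(
    sprintf("ancientmt_version=%s",
            as.character(utils::packageVersion("ancientmt"))),
    sprintf("seed=%d", seed),
    sprintf("param_%s=%s",
            c("min_len", "min_mapq", "k_term", "cov_threshold",
              "support_threshold", "rate", "bootstrap_B"),
            c(min_len, min_mapq, k_term, cov_threshold,
              format(support_threshold, digits = 12), format(rate),
              bootstrap_B)),
    if (length(inputs)) sprintf("input_%s_md5=%s", names(inputs),
                                tools::md5sum(inputs)),
    sprintf("artifact_%s_md5=%s", names(paths), tools::md5sum(paths)))
  writeLines(manifest, art("manifest.txt"))
  paths["manifest"] <- art("manifest.txt")

  invisible(list(filtered = filtered, unique_fragments = unique_frags,
                 damage = prof, deaminated = deam, diagnostics = diag,
                 assignments = asg_all, assignments_deaminated = asg_deam,
                 contamination_all = est_all,
                 contamination_deaminated = est_deam,
                 consensus = calls, audit = audit, dating = dating,
                 paths = paths))
}
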