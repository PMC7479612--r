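#' Read a FASTA file as a reference or an alignment panel
#'
#' Single-record files (or `what = "reference"`) become an
#' [mt_reference()]; multi-record files become a [panel_alignment()] with
#' equal record lengths enforced. Sequences are uppercased; IUPAC
#' ambiguity codes other than N are mapped to N with a warning; characters
#' outside the IUPAC alphabet are a format error.
#'
#' @param path FASTA file.
#' @param what `"auto"` (default: one record = reference, several =
#'   panel), `"reference"`, or `"panel"`.
#' @param group Optional named group vector passed to [panel_alignment()].
#' @param circular For reference mode, whether the sequence is circular.
#' @return An `mt_reference` or `panel_alignment`.
#' @export
read_fasta <- function(path, what = c("auto", "reference", "panel"),
                       group = NULL, circular = TRUE) {
  what <- match.arg(what)
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("format error: FASTA file has no records")
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  if (any(nchar(seqs) == 0L)) stop("format error: empty FASTA record")
  iupac <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "U")
  has_amb <- any(vapply(seqs, function(s)
    grepl(paste0("[", paste(iupac, collapse = ""), "]"), s), logical(1)))
  if (has_amb) {
    warning("IUPAC ambiguity codes mapped to N")
    seqs <- vapply(seqs, function(s)
      gsub(paste0("[", paste(iupac, collapse = ""), "]"), "N", s),
      character(1))
  }
  bad <- gsub("[ACGTN-]", "", paste(seqs, collapse = ""))
  if (nchar(bad) > 0L)
    stop("format error: non-IUPAC characters in FASTA: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ","))
  if (what == "reference" || (what == "auto" && length(seqs) == 1L)) {
    if (length(seqs) != 1L)
      stop("reference mode expects exactly one record, found ", length(seqs))
    s <- gsub("-", "", seqs[[1]])
    return(mt_reference(names(seqs)[1], s, circular = circular))
  }
  panel_alignment(seqs, group = group)
}

#' Write sequences to FASTA
#'
#' @param x An `mt_reference`, `panel_alignment`, or named character
#'   vector of sequences.
#' @param path Output file.
#' @param width Line wrap width.
#' @export
write_fasta <- function(x, path, width = 70L) {
  if (inherits(x, "mt_reference")) {
    seqs <- stats::setNames(x$seq, x$id)
  } else if (inherits(x, "panel_alignment")) {
    seqs <- stats::setNames(apply(x, 1L, paste, collapse = ""), rownames(x))
  } else {
    seqs <- x
  }
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read aligned fragments from TSV or SAM
#'
#' The TSV dialect is tab-separated with mandatory header
#' `read_id ref_id start end strand mapq library seq` (optional trailing
#' `truth_label` column, `#` comment lines allowed) and 0-based half-open
#' coordinates. The SAM dialect accepts the minimal subset the pipeline
#' needs: mapped, indel-free records (CIGAR one match-run, e.g. `35M`);
#' unmapped or indel-containing records are skipped and counted in the
#' `skipped` attribute of the result. SAM's 1-based `POS` is converted to
#' the internal 0-based convention at this boundary.
#'
#' @param path Input file.
#' @param dialect `"tsv"` or `"sam"`.
#' @return An `aligned_fragments` data frame; for SAM input it carries an
#'   integer attribute `skipped` (records dropped) .
#' @export
read_fragments <- function(path, dialect = c("tsv", "sam")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "tsv") read_fragments_tsv(path) else read_fragments_sam(path)
}

read_fragments_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", header = TRUE,
                          colClasses = "character",
                          stringsAsFactors = FALSE)
  need <- c("read_id", "ref_id", "start", "end", "strand", "mapq",
            "library", "seq")
  if (!all(need %in% names(df)))
    stop("format error: TSV header must contain: ",
         paste(need, collapse = " "))
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$mapq <- as.integer(df$mapq)
  df$seq <- toupper(df$seq)
  if (!"truth_label" %in% names(df)) df$truth_label <- NA_character_
  df$truth_label[df$truth_label %in% c("", "NA")] <- NA_character_
  bad <- which(df$end - df$start != nchar(df$seq))
  if (length(bad))
    stop("record error: end - start != len(seq) for read(s): ",
         paste(utils::head(df$read_id[bad], 5), collapse = ","))
  as_fragments(df[need_cols()])
}

need_cols <- function() c("read_id", "ref_id", "start", "end", "strand",
                          "mapq", "library", "seq", "truth_label")

read_fragments_sam <- function(path) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "strand", "mapq", "cigar", "seq"),
    tag = "RG")
  rec <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(rec$qname)
  mapped <- !is.na(rec$pos) & !is.na(rec$cigar)
  clean <- mapped & grepl("^[0-9]+M$", rec$cigar)
  skipped <- sum(!clean)
  if (skipped > 0L)
    warning(skipped, " SAM record(s) skipped (unmapped or not a single ",
            "indel-free match-run)")
  keep <- which(clean)
  seqs <- as.character(rec$seq[keep])
  lib <- rec$tag$RG
  lib <- if (is.null(lib)) rep("NA", n) else as.character(lib)
  lib[is.na(lib)] <- "NA"
  df <- data.frame(read_id = rec$qname[keep],
                   ref_id = as.character(rec$rname[keep]),
                   start = rec$pos[keep] - 1L,
                   end = rec$pos[keep] - 1L + nchar(seqs),
                   strand = as.character(rec$strand[keep]),
                   mapq = as.integer(rec$mapq[keep]),
                   library = lib[keep],
                   seq = toupper(seqs),
                   truth_label = NA_character_,
                   stringsAsFactors = FALSE)
  out <- as_fragments(df)
  attr(out, "skipped") <- skipped
  out
}

#' Write aligned fragments to the TSV dialect
#'
#' Writes every field verbatim so that a write/read round trip is exact,
#' including `truth_label` ground truth from the simulator.
#'
#' @param frags An `aligned_fragments` data frame.
#' @param path Output file.
#' @export
write_fragments <- function(frags, path) {
  df <- as.data.frame(frags)[need_cols()]
  if (all(is.na(df$truth_label))) df$truth_label <- NULL
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Length and mapping-quality filter for aligned fragments
#'
#' The standard ancient-DNA inclusion rule: keep fragments at least
#' `min_len` bases long with mapping quality at least `min_mapq`
#' (defaults 35 bp and MAPQ 25). Order is preserved; the filter is
#' idempotent.
#'
#' @param frags An `aligned_fragments` data frame.
#' @param min_len Minimum fragment length in bp.
#' @param min_mapq Minimum mapping quality.
#' @return The surviving fragments, same class and column order.
#' @export
filter_fragments <- function(frags, min_len = 35L, min_mapq = 25L) {
  stopifnot(min_len >= 1L, min_mapq >= 0L)
  if (nrow(frags) == 0L) return(frags)
  keep <- (frags$end - frags$start) >= min_len & frags$mapq >= min_mapq
  out <- frags[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
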