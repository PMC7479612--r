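#' Mitochondrial reference sequence
#'
#' Container for a circular mitochondrial reference genome. Positions are
#' 0-based throughout the package; position arithmetic on circular
#' references is modulo the reference length, so aligned fragments may run
#' past the origin (their `end` exceeds the reference length and their
#' bases continue from position 0).
#'
#' @param id Sequence label.
#' @param seq Base string over A, C, G, T, N (uppercased on construction).
#' @param circular Logical; mitochondrial genomes are circular.
#' @return An object of class `mt_reference` with fields `id`, `seq`,
#'   `circular`.
#' @export
mt_reference <- function(id, seq, circular = TRUE) {
  seq <- toupper(as.character(seq))
  if (nchar(seq) == 0L) stop("reference sequence is empty")
  bad <- gsub("[ACGTN]", "", seq)
  if (nchar(bad) > 0L) {
    stop("reference contains characters outside {A,C,G,T,N}: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ","))
  }
  structure(list(id = as.character(id), seq = seq,
                 circular = isTRUE(circular)),
            class = "mt_reference")
}

#' @export
print.mt_reference <- function(x, ...) {
  cat(sprintf("<mt_reference> %s: %d bp%s\n", x$id, nchar(x$seq),
              if (x$circular) " (circular)" else ""))
  invisible(x)
}

#' @export
length.mt_reference <- function(x) nchar(x$seq)

# reference bases at 0-based positions, modulo length when circular
ref_bases_at <- function(ref, pos) {
  L <- nchar(ref$seq)
  if (ref$circular) pos <- pos %% L
  if (any(pos < 0L | pos >= L)) stop("position outside linear reference")
  substring(ref$seq, pos + 1L, pos + 1L)
}

#' Multiple sequence alignment panel
#'
#' A panel of equal-length aligned mtDNA sequences with a population label
#' per taxon (`archaic`, `modern`, `outgroup` or `query`). Stored as a
#' character matrix (taxa in rows, alignment columns in columns) so that
#' column-wise operations (diagnostic-position scans, bootstrap column
#' resampling) are cheap.
#'
#' @param seqs Named character vector of aligned sequences (equal lengths,
#'   alphabet A, C, G, T, N, -), or a character matrix of single bases with
#'   taxon rownames.
#' @param group Named character vector mapping each taxon to one of
#'   `archaic`, `modern`, `outgroup`, `query`.
#' @return An object of class `panel_alignment`: character matrix with a
#'   `group` attribute.
#' @export
panel_alignment <- function(seqs, group = NULL) {
  if (is.matrix(seqs)) {
    m <- seqs
  } else {
    seqs <- stats::setNames(toupper(as.character(seqs)), names(seqs))
    if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
      stop("panel sequences must have unique names")
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L)
      stop("alignment error: aligned sequences have unequal lengths (",
           paste(range(lens), collapse = "-"), ")")
    m <- do.call(rbind, strsplit(seqs, ""))
    rownames(m) <- names(seqs)
  }
  if (is.null(rownames(m))) stop("panel matrix must have taxon rownames")
  ok <- m %in% c("A", "C", "G", "T", "N", "-")
  if (!all(ok)) {
    m[!ok] <- "N"
    warning("non-ACGTN- characters in panel mapped to N")
  }
  if (!is.null(group)) {
    group <- group[rownames(m)]
    if (anyNA(group)) stop("group map must cover every taxon")
    bad <- setdiff(unique(group), c("archaic", "modern", "outgroup", "query"))
    if (length(bad))
      stop("unknown group label(s): ", paste(bad, collapse = ","))
    names(group) <- rownames(m)
  }
  structure(m, group = group, class = c("panel_alignment", "matrix", "array"))
}

#' @export
print.panel_alignment <- function(x, ...) {
  g <- attr(x, "group")
  cat(sprintf("<panel_alignment> %d taxa x %d columns\n", nrow(x), ncol(x)))
  if (!is.null(g)) {
    tb <- table(g)
    cat("  groups:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "),
        "\n")
  }
  invisible(x)
}

# collapse a panel row back to a string
panel_seq <- function(panel, taxon) paste(panel[taxon, ], collapse = "")

#' Construct a table of aligned fragments
#'
#' The package-wide fragment container: a data frame with one row per
#' aligned, indel-free sequence fragment. Coordinates are 0-based,
#' half-open (`end` exclusive), matching the internal convention of every
#' operation in the package. On a circular reference a fragment spanning
#' the origin keeps `end > reference length`; its bases continue from
#' position 0.
#'
#' @param read_id,ref_id,start,end,strand,mapq,library,seq,truth_label
#'   Per-fragment fields; `truth_label` (one of `endogenous`,
#'   `contaminant`, `unknown`) is optional ground truth carried by
#'   simulated data.
#' @return A data frame of class `aligned_fragments`.
#' @export
aligned_fragments <- function(read_id, ref_id, start, end, strand, mapq,
                              library, seq, truth_label = NA_character_) {
  df <- data.frame(read_id = as.character(read_id),
                   ref_id = as.character(ref_id),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand), mapq = as.integer(mapq),
                   library = as.character(library), seq = toupper(seq),
                   truth_label = as.character(truth_label),
                   stringsAsFactors = FALSE)
  validate_fragments(df)
  class(df) <- c("aligned_fragments", "data.frame")
  df
}

validate_fragments <- function(df) {
  stopifnot(all(c("read_id", "ref_id", "start", "end", "strand", "mapq",
                  "library", "seq") %in% names(df)))
  if (nrow(df) == 0L) return(invisible(df))
  if (any(df$start < 0L) || any(df$end <= df$start))
    stop("fragment coordinates must satisfy 0 <= start < end")
  bad_len <- df$end - df$start != nchar(df$seq)
  if (any(bad_len))
    stop("end - start != sequence length for read(s): ",
         paste(utils::head(df$read_id[bad_len], 5), collapse = ","))
  if (!all(df$strand %in% c("+", "-")))
    stop("format error: unknown strand symbol ",
         paste(setdiff(unique(df$strand), c("+", "-")), collapse = ","))
  if (any(df$mapq < 0L)) stop("mapq must be >= 0")
  if (any(grepl("[^ACGTN]", df$seq)))
    stop("fragment sequences must be over {A,C,G,T,N}")
  invisible(df)
}

as_fragments <- function(df) {
  validate_fragments(df)
  if (!"truth_label" %in% names(df)) df$truth_label <- NA_character_
  class(df) <- c("aligned_fragments", "data.frame")
  df
}

#' @export
print.aligned_fragments <- function(x, ...) {
  cat(sprintf("<aligned_fragments> %d fragments", nrow(x)))
  if (nrow(x)) {
    cat(sprintf(", lengths %d-%d, %d library(ies)",
                min(x$end - x$start), max(x$end - x$start),
                length(unique(x$library))))
    tl <- x$truth_label[!is.na(x$truth_label)]
    if (length(tl)) {
      tb <- table(tl)
      cat("; truth: ",
          paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), sep = "")
    }
  }
  cat("\n")
  invisible(x)
}

# unlist fragment sequences into one character vector of bases, with
# parallel vectors of fragment row index, 0-based within-fragment offset
# and 0-based reference position (modulo L when circular)
fragment_base_table <- function(frags, ref = NULL) {
  lens <- frags$end - frags$start
  base <- unlist(strsplit(frags$seq, ""), use.names = FALSE)
  off <- sequence(lens) - 1L
  row <- rep.int(seq_len(nrow(frags)), lens)
  pos <- rep.int(frags$start, lens) + off
  if (!is.null(ref) && ref$circular) pos <- pos %% nchar(ref$seq)
  list(row = row, off = off, pos = pos, base = base,
       len = rep.int(lens, lens))
}
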