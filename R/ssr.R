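#' Read BAC-end sequences from FASTA
#'
#' Reads are kept as plain character strings so that soft-masking
#' (lowercase) survives; hard-masked bases are `N`. By default the header is
#' parsed as `<clone>_SP6` / `<clone>_T7` to recover the clone id and the
#' sequenced end.
#'
#' @param path FASTA path.
#' @param parse_ends Parse clone/end from the header (default `TRUE`).
#' @return A data frame of class `"bes_set"`: `read_id`, `clone_id`, `end`
#'   (`"SP6"`, `"T7"` or `NA`), `sequence`.
#' @export
read_bes_fasta <- function(path, parse_ends = TRUE) {
  ss <- Biostrings::readBStringSet(path)
  ids <- names(ss)
  ids <- sub("\\s.*$", "", ids)
  out <- data.frame(read_id = ids, clone_id = ids, end = NA_character_,
                    sequence = as.character(ss), stringsAsFactors = FALSE)
  if (parse_ends) {
    has <- grepl("_(SP6|T7)$", ids)
    out$end[has] <- sub("^.*_(SP6|T7)$", "\\1", ids[has])
    out$clone_id[has] <- sub("_(SP6|T7)$", "", ids[has])
  }
  rownames(out) <- NULL
  class(out) <- c("bes_set", "data.frame")
  out
}

#' Write reads as FASTA
#'
#' @param reads A `"bes_set"` data frame (or any with `read_id`,
#'   `sequence`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bes_fasta <- function(reads, path) {
  ss <- Biostrings::BStringSet(reads$sequence)
  names(ss) <- reads$read_id
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

# unmasked length: uppercase A/C/G/T only
.effective_length <- function(seq) {
  nchar(gsub("[^ACGT]", "", seq))
}

#' Select qualified reads
#'
#' A read qualifies when its unmasked length (uppercase `A`/`C`/`G`/`T`
#' bases; masked runs are lowercase or `N`) exceeds 100 bp, i.e. is at least
#' `min_len = 101`.
#'
#' @param reads A `"bes_set"` data frame.
#' @param min_len Minimum unmasked length (default 101, "more than 100 bp").
#' @return The qualifying rows with an added `effective_length` column.
#' @export
qualify_reads <- function(reads, min_len = 101L) {
  if (nrow(reads) == 0L) {
    warning("no reads supplied")
    reads$effective_length <- integer(0)
    return(reads)
  }
  eff <- .effective_length(reads$sequence)
  keep <- eff >= min_len
  message(sprintf("qualified %d / %d reads (unmasked length >= %d)",
                  sum(keep), nrow(reads), min_len))
  out <- reads[keep, , drop = FALSE]
  out$effective_length <- eff[keep]
  rownames(out) <- NULL
  out
}

#' GC content of a read set
#'
#' Percent G+C over unmasked bases only: `100 (G + C) / (A + C + G + T)`,
#' uppercase bases; `N` and soft-masked (lowercase) bases are excluded.
#'
#' @param reads A `"bes_set"` data frame or character vector of sequences.
#' @return GC percentage.
#' @examples
#' gc_content("ATGC")  # 50
#' @export
gc_content <- function(reads) {
  seqs <- if (is.data.frame(reads)) reads$sequence else reads
  all_bases <- paste(seqs, collapse = "")
  gc <- nchar(gsub("[^GC]", "", all_bases))
  acgt <- nchar(gsub("[^ACGT]", "", all_bases))
  if (acgt == 0L) stop("no unmasked bases: GC content undefined")
  100 * gc / acgt
}

# smallest string among all rotations of u and of its reverse complement
.canonical_unit <- function(unit) {
  rots <- function(u) {
    n <- nchar(u)
    vapply(seq_len(n), function(i)
      paste0(substr(u, i, n), substr(u, 1L, i - 1L)), character(1L))
  }
  min(c(rots(unit), rots(.revcomp(unit))))
}

.revcomp <- function(seq) {
  chartr("ACGT", "TGCA",
         vapply(seq, function(s)
           paste(rev(strsplit(s, "")[[1L]]), collapse = ""),
           character(1L), USE.NAMES = FALSE))
}

.unit_class_names <- c("monomer", "dimer", "trimer", "tetramer", "pentamer",
                       "hexamer", "heptamer", "octomer", "nanomer",
                       "decamer")

#' Canonical SSR unit and class label
#'
#' The canonical repeat unit is the lexicographically smallest string among
#' all rotations of the unit and of its reverse complement, so `CA`, `AC`,
#' `TG` and `GT` all canonicalize to `AC`; the class label pairs it with its
#' reverse complement (`"AC/GT"`), the conventional strand-invariant naming.
#'
#' @param unit Repeat unit(s).
#' @return `canonical_unit()`: the canonical unit; `unit_label()`: the
#'   `"unit/revcomp"` class label.
#' @examples
#' canonical_unit(c("TG", "CA", "GTT"))
#' unit_label("TG")
#' @export
canonical_unit <- function(unit) {
  vapply(toupper(unit), .canonical_unit, character(1L), USE.NAMES = FALSE)
}

#' @rdname canonical_unit
#' @export
unit_label <- function(unit) {
  cu <- canonical_unit(unit)
  paste0(cu, "/", .revcomp(cu))
}

# primitive check: is the unit itself a repetition of a shorter unit?
.is_primitive <- function(unit) {
  n <- nchar(unit)
  for (k in seq_len(n %/% 2)) {
    if (n %% k == 0L &&
        unit == strrep(substr(unit, 1L, k), n %/% k))
      return(FALSE)
  }
  TRUE
}

#' Find perfect SSR motifs in a read
#'
#' Scans for maximal perfect tandem repeats with unit lengths 1 to
#' `max_unit` and at least `min_copies` complete copies. Only unmasked
#' sequence is searched (masked `N` or lowercase bases break an array).
#' Arrays are reported at their primitive unit (an `ACACAC...` run is an
#' `AC` repeat, never an `ACAC` repeat) with canonical strand-invariant
#' naming, so coordinates for the same unit never overlap.
#'
#' The default `min_copies = 7` reads the "more than six repeats" rule
#' strictly; pass 6 for the inclusive reading.
#'
#' @param read A single sequence (character) or a one-row `"bes_set"`.
#' @param min_copies Minimum complete copies (default 7).
#' @param max_unit Maximum unit length (default 10).
#' @param read_id Identifier used in the output.
#' @return A data frame of class `"ssr_motifs"`: `read_id`, `unit` (as
#'   observed), `canonical`, `label`, `unit_class`, `unit_length`, `copies`,
#'   `start`, `end` (1-based inclusive), `length_bp`.
#' @examples
#' find_ssrs(strrep("AC", 8))
#' @export
find_ssrs <- function(read, min_copies = 7L, max_unit = 10L,
                      read_id = NULL) {
  if (is.data.frame(read)) {
    if (is.null(read_id)) read_id <- read$read_id[1L]
    read <- read$sequence[1L]
  }
  if (is.null(read_id)) read_id <- "read"
  stopifnot(length(read) == 1L, nchar(read) >= 1L)
  hits <- list()
  for (k in seq_len(max_unit)) {
    if (nchar(read) < k * min_copies) break
    pat <- sprintf("([ACGT]{%d})\\1{%d,}", k, min_copies - 1L)
    m <- gregexpr(pat, read, perl = TRUE)[[1L]]
    if (m[1L] == -1L) next
    starts <- as.integer(m)
    lens <- attr(m, "match.length")
    for (i in seq_along(starts)) {
      unit <- substr(read, starts[i], starts[i] + k - 1L)
      if (!.is_primitive(unit)) next
      copies <- lens[i] %/% k
      hits[[length(hits) + 1L]] <-
        data.frame(read_id = read_id, unit = unit,
                   start = starts[i],
                   end = starts[i] + copies * k - 1L,
                   unit_length = k, copies = copies,
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) {
    out <- data.frame(read_id = character(0), unit = character(0),
                      canonical = character(0), label = character(0),
                      unit_class = character(0), unit_length = integer(0),
                      copies = integer(0), start = integer(0),
                      end = integer(0), length_bp = integer(0))
    class(out) <- c("ssr_motifs", "data.frame")
    return(out)
  }
  df <- do.call(rbind, hits)
  df$canonical <- canonical_unit(df$unit)
  df$label <- unit_label(df$unit)
  df$unit_class <- .unit_class_names[df$unit_length]
  df$length_bp <- df$copies * df$unit_length
  df <- df[order(df$start, df$unit_length),
           c("read_id", "unit", "canonical", "label", "unit_class",
             "unit_length", "copies", "start", "end", "length_bp")]
  rownames(df) <- NULL
  class(df) <- c("ssr_motifs", "data.frame")
  df
}

#' Scan a whole read set for SSR motifs
#'
#' @param reads A `"bes_set"` data frame.
#' @inheritParams find_ssrs
#' @return One `"ssr_motifs"` data frame for all reads.
#' @export
find_ssrs_all <- function(reads, min_copies = 7L, max_unit = 10L) {
  out <- lapply(seq_len(nrow(reads)), function(i)
    find_ssrs(reads$sequence[i], min_copies = min_copies,
              max_unit = max_unit, read_id = reads$read_id[i]))
  out <- do.call(rbind, out)
  class(out) <- c("ssr_motifs", "data.frame")
  out
}

#' Representative motif of a read
#'
#' When a read carries several SSR motifs, the longest (most bp; ties
#' broken leftmost) represents the read for marker development.
#'
#' @param motifs An `"ssr_motifs"` data frame (motifs of one read).
#' @return A one-row data frame, or `NULL` when empty.
#' @export
pick_representative <- function(motifs) {
  if (is.null(motifs) || nrow(motifs) == 0L) return(NULL)
  ord <- order(-motifs$length_bp, motifs$start)
  motifs[ord[1L], , drop = FALSE]
}

#' Clone-level marker selection (SP6 first, then T7)
#'
#' For each BAC clone the SP6-side read is screened first; only if it
#' yields no motif is the T7-side read of the same clone used.
#'
#' @param sp6,t7 Qualified reads of one clone (one-row `"bes_set"` data
#'   frames or sequences), either may be `NULL`.
#' @param min_copies,max_unit Passed to [find_ssrs()].
#' @return A list `list(end = "SP6"|"T7", motif = <one-row data frame>)`,
#'   or `NULL` when neither read yields a motif.
#' @export
clone_marker_selection <- function(sp6 = NULL, t7 = NULL, min_copies = 7L,
                                   max_unit = 10L) {
  if (is.null(sp6) && is.null(t7)) stop("at least one read is required")
  for (end in c("SP6", "T7")) {
    read <- if (end == "SP6") sp6 else t7
    if (is.null(read)) next
    rep <- pick_representative(find_ssrs(read, min_copies = min_copies,
                                         max_unit = max_unit))
    if (!is.null(rep)) return(list(end = end, motif = rep))
  }
  NULL
}

#' Tally SSR motifs by unit class and canonical unit
#'
#' The distribution report behind marker-survey tables: counts per unit
#' class (monomer .. decamer) and per canonical unit label, total bp
#' occupied by the arrays, and -- when the total qualified sequence length
#' is supplied -- the percent of sequence they occupy.
#'
#' @param motifs An `"ssr_motifs"` data frame.
#' @param total_bp Optional total qualified sequence length (bp).
#' @return A list of class `"ssr_tally"`: `by_class` (named integer),
#'   `by_unit` (data frame `unit_class`, `label`, `n`), `n_motifs`,
#'   `bp_occupied`, `pct_of_sequence` (`NA` without `total_bp`).
#' @export
ssr_tally <- function(motifs, total_bp = NULL) {
  classes <- factor(motifs$unit_class, levels = .unit_class_names)
  by_class <- table(classes)
  if (nrow(motifs)) {
    by_unit <- as.data.frame(table(unit_class = classes,
                                   label = motifs$label),
                             stringsAsFactors = FALSE)
    by_unit <- by_unit[by_unit$Freq > 0L, ]
    by_unit <- by_unit[order(match(by_unit$unit_class, .unit_class_names),
                             -by_unit$Freq), ]
    names(by_unit)[3L] <- "n"
    rownames(by_unit) <- NULL
  } else {
    by_unit <- data.frame(unit_class = character(0), label = character(0),
                          n = integer(0))
  }
  bp <- sum(motifs$length_bp)
  structure(list(by_class = c(by_class), by_unit = by_unit,
                 n_motifs = nrow(motifs), bp_occupied = bp,
                 pct_of_sequence = if (is.null(total_bp)) NA_real_
                                   else 100 * bp / total_bp),
            class = "ssr_tally")
}

#' @export
print.ssr_tally <- function(x, ...) {
  cat(sprintf("SSR tally: %d motifs, %d bp occupied", x$n_motifs,
              x$bp_occupied))
  if (!is.na(x$pct_of_sequence))
    cat(sprintf(" (%.2f%% of sequence)", x$pct_of_sequence))
  cat("\n")
  print(x$by_class)
  invisible(x)
}

#' Write SSR motifs as TSV
#'
#' Columns: `read_id`, `unit`, `unit_class`, `copies`, `start1`, `end1`
#' (1-based inclusive coordinates).
#'
#' @param motifs An `"ssr_motifs"` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ssr_tsv <- function(motifs, path) {
  df <- data.frame(read_id = motifs$read_id, unit = motifs$unit,
                   unit_class = motifs$unit_class, copies = motifs$copies,
                   start1 = motifs$start, end1 = motifs$end)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
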