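.blast_cols <- c("query_id", "subject_id", "percent_identity",
                 "alignment_length", "mismatches", "gap_opens",
                 "query_start", "query_end", "subject_start",
                 "subject_end", "e_value", "bit_score")

#' Read BLAST tabular output (12-column dialect)
#'
#' Parses the standard tab-separated BLAST output (`qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore`).
#' Query coordinates are normalized so `query_start <= query_end` (a
#' `reversed` flag records which rows were flipped); malformed lines are
#' skipped and counted.
#'
#' @param path Path to the hit table.
#' @return A data frame of class `"blast_hits"` with the columns above plus
#'   `reversed`.
#' @export
read_blast_tabular <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) {
    warning("no hits in ", path)
    df <- as.data.frame(matrix(nrow = 0L, ncol = 12L))
    names(df) <- .blast_cols
    df$reversed <- logical(0)
    class(df) <- c("blast_hits", "data.frame")
    return(df)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(fields) == 12L
  if (any(!ok))
    message(sprintf("skipped %d malformed line(s) in %s", sum(!ok), path))
  mat <- do.call(rbind, fields[ok])
  df <- data.frame(query_id = mat[, 1L], subject_id = mat[, 2L],
                   percent_identity = as.numeric(mat[, 3L]),
                   alignment_length = as.integer(mat[, 4L]),
                   mismatches = as.integer(mat[, 5L]),
                   gap_opens = as.integer(mat[, 6L]),
                   query_start = as.integer(mat[, 7L]),
                   query_end = as.integer(mat[, 8L]),
                   subject_start = as.integer(mat[, 9L]),
                   subject_end = as.integer(mat[, 10L]),
                   e_value = as.numeric(mat[, 11L]),
                   bit_score = as.numeric(mat[, 12L]),
                   stringsAsFactors = FALSE)
  bad <- is.na(df$query_start) | is.na(df$query_end) | is.na(df$e_value)
  if (any(bad)) {
    message(sprintf("skipped %d line(s) with unparseable numbers", sum(bad)))
    df <- df[!bad, , drop = FALSE]
  }
  rev <- df$query_start > df$query_end
  tmp <- df$query_start[rev]
  df$query_start[rev] <- df$query_end[rev]
  df$query_end[rev] <- tmp
  df$reversed <- rev
  rownames(df) <- NULL
  class(df) <- c("blast_hits", "data.frame")
  df
}

#' Write hits in BLAST tabular dialect
#'
#' @param hits A `"blast_hits"` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_blast_tabular <- function(hits, path) {
  df <- as.data.frame(hits)[, .blast_cols]
  df$e_value <- formatC(df$e_value, format = "g", digits = 6)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.overlaps <- function(s1, e1, s2, e2) s1 <= e2 & s2 <= e1

# order hits by significance: e-value ascending, bit score descending
.rank_hits <- function(hits) {
  hits[order(hits$e_value, -hits$bit_score), , drop = FALSE]
}

#' Collapse overlapping hits of one query to the most significant
#'
#' Hits of the same query whose query intervals overlap by at least one
#' base are redundant placements of the same region; only the most
#' significant (lowest e-value, ties by bit score) is kept per overlap
#' cluster. Non-overlapping hits are all retained.
#'
#' @param hits A `"blast_hits"` data frame for a single query.
#' @return The retained rows, most significant first.
#' @export
dedupe_top_hits <- function(hits) {
  if (nrow(hits) <= 1L) return(hits)
  stopifnot(length(unique(hits$query_id)) == 1L)
  hits <- .rank_hits(hits)
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    ov <- keep & .overlaps(hits$query_start[i], hits$query_end[i],
                           hits$query_start, hits$query_end)
    keep[i] <- !any(ov)
  }
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Accept or reject a query's orthology assignment
#'
#' Implements the top-three e-value-ratio rule: rank the query's hits by
#' significance and consider only the first three. If the second or third
#' hit overlaps the top hit's query interval and the top hit's e-value
#' divided by that hit's e-value exceeds `ratio_threshold` (i.e. the two
#' e-values are too close to call), the query is an unclear orthologous
#' pair and is rejected; otherwise the top hit's subject is accepted. Zero
#' e-values are replaced by 1e-180 before forming ratios.
#'
#' @param hits A `"blast_hits"` data frame for one query (any order).
#' @param ratio_threshold Rejection threshold on `e1 / ek` (default 1e-3).
#' @param subject_chromosome Optional function mapping `subject_id` to a
#'   chromosome label (default: identity).
#' @return A one-row data frame of class `"ortholog_assignment"`:
#'   `query_id`, `subject_chromosome`, `accepted`, `reject_reason`
#'   (`"none"`, `"unclear_ratio"` or `"no_hit"`), `e_value`.
#' @export
assign_orthology <- function(hits, ratio_threshold = 1e-3,
                             subject_chromosome = identity) {
  if (is.null(hits) || nrow(hits) == 0L) {
    return(data.frame(query_id = NA_character_,
                      subject_chromosome = NA_character_,
                      accepted = FALSE, reject_reason = "no_hit",
                      e_value = NA_real_))
  }
  hits <- .rank_hits(hits)
  ev <- hits$e_value
  if (any(ev == 0)) {
    message(sprintf("%d zero e-value(s) replaced by 1e-180", sum(ev == 0)))
    ev[ev == 0] <- 1e-180
  }
  top <- hits[1L, ]
  reason <- "none"
  for (k in 2:3) {
    if (k > nrow(hits)) break
    if (.overlaps(top$query_start, top$query_end,
                  hits$query_start[k], hits$query_end[k]) &&
        ev[1L] / ev[k] > ratio_threshold) {
      reason <- "unclear_ratio"
      break
    }
  }
  data.frame(query_id = top$query_id,
             subject_chromosome =
               if (reason == "none") subject_chromosome(top$subject_id)
               else NA_character_,
             accepted = reason == "none", reject_reason = reason,
             e_value = top$e_value)
}

#' Assign orthology for every query in a hit table
#'
#' Applies [dedupe_top_hits()] per query (optional) and then
#' [assign_orthology()].
#'
#' @param hits A `"blast_hits"` data frame (many queries).
#' @param dedupe Collapse overlapping same-query placements first
#'   (default `FALSE`: the rejection rule already inspects overlaps).
#' @inheritParams assign_orthology
#' @return A data frame with one row per query.
#' @export
assign_orthology_all <- function(hits, ratio_threshold = 1e-3,
                                 subject_chromosome = identity,
                                 dedupe = FALSE) {
  out <- lapply(split(hits, hits$query_id), function(h) {
    if (dedupe) h <- dedupe_top_hits(h)
    assign_orthology(h, ratio_threshold = ratio_threshold,
                     subject_chromosome = subject_chromosome)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# natural sort of labels like Squ1, Squ2, ..., Squ24, Squ24'
.natural_sort <- function(x) {
  num <- suppressWarnings(as.numeric(gsub("[^0-9.]", "", x)))
  prime <- grepl("'|′", x)
  x[order(is.na(num), num, prime, x)]
}

#' Build an Oxford grid from accepted orthology assignments
#'
#' Cross-tabulates accepted query-to-chromosome assignments by the linkage
#' group of each query marker. Cells are highlighted by orthologous-pair
#' count: red for more than 10, yellow for more than 7, blue for more
#' than 5.
#'
#' @param assignments Output of [assign_orthology_all()] (or compatible
#'   data frame with `query_id`, `subject_chromosome`, `accepted`).
#' @param marker_groups Named character vector mapping marker (query) id to
#'   linkage group, or a data frame with columns `marker` and `group` (as
#'   from [map_positions()]).
#' @return An object of class `"oxford_grid"`: `counts` (linkage groups x
#'   chromosomes integer matrix, naturally sorted labels), `highlight`
#'   (same shape, `"red"`/`"yellow"`/`"blue"`/`"none"`), `n_accepted`.
#' @export
build_oxford_grid <- function(assignments, marker_groups) {
  if (is.data.frame(marker_groups)) {
    mg <- stats::setNames(as.character(marker_groups$group),
                          marker_groups$marker)
  } else mg <- marker_groups
  acc <- assignments[assignments$accepted, , drop = FALSE]
  known <- acc$query_id %in% names(mg)
  if (any(!known))
    warning(sum(!known), " accepted quer(ies) not on the map; skipped")
  acc <- acc[known, , drop = FALSE]
  lgs <- .natural_sort(unique(unname(mg)))
  chrs <- .natural_sort(unique(acc$subject_chromosome))
  counts <- table(factor(mg[acc$query_id], levels = lgs),
                  factor(acc$subject_chromosome, levels = chrs))
  counts <- matrix(as.integer(counts), nrow = length(lgs),
                   dimnames = list(linkage_group = lgs, chromosome = chrs))
  structure(list(counts = counts,
                 highlight = .grid_highlight(counts),
                 n_accepted = nrow(acc)),
            class = "oxford_grid")
}

.grid_highlight <- function(counts) {
  h <- matrix("none", nrow(counts), ncol(counts),
              dimnames = dimnames(counts))
  h[counts > 5] <- "blue"
  h[counts > 7] <- "yellow"
  h[counts > 10] <- "red"
  h
}

#' @export
print.oxford_grid <- function(x, ...) {
  cat(sprintf("Oxford grid: %d x %d, %d accepted orthologous pairs\n",
              nrow(x$counts), ncol(x$counts), x$n_accepted))
  print(x$counts)
  invisible(x)
}

#' Plot an Oxford grid
#'
#' Heat-grid of orthologous-pair counts with the conventional red (>10),
#' yellow (>7) and blue (>5) cell highlighting.
#'
#' @param x An `"oxford_grid"`.
#' @param ... Unused.
#' @method plot oxford_grid
#' @export
plot.oxford_grid <- function(x, ...) {
  cnt <- x$counts
  nr <- nrow(cnt); nc <- ncol(cnt)
  cols <- matrix("white", nr, nc)
  cols[x$highlight == "blue"] <- "#9ecae1"
  cols[x$highlight == "yellow"] <- "#ffd92f"
  cols[x$highlight == "red"] <- "#fc9272"
  graphics::plot(NA, xlim = c(0.5, nc + 0.5), ylim = c(nr + 0.5, 0.5),
                 xaxt = "n", yaxt = "n", xlab = "chromosome",
                 ylab = "linkage group", asp = 1)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    graphics::rect(j - 0.5, i - 0.5, j + 0.5, i + 0.5, col = cols[i, j],
                   border = "grey50")
    if (cnt[i, j] > 0)
      graphics::text(j, i, cnt[i, j], cex = 0.6)
  }
  graphics::axis(1, at = seq_len(nc), labels = colnames(cnt), las = 2,
                 cex.axis = 0.6)
  graphics::axis(2, at = seq_len(nr), labels = rownames(cnt), las = 2,
                 cex.axis = 0.6)
  invisible(x)
}

#' Classify linkage-group / chromosome relationships in an Oxford grid
#'
#' A linkage group is related to every chromosome whose cell exceeds
#' `min_count` pairs (default the blue cutoff, 5). Groups with exactly one
#' related chromosome are one-to-one candidates; with two, one-to-two
#' (chromosomal fusion/breakage signal). Confirmed one-to-one pairs are
#' those unique in both directions.
#'
#' @param grid An `"oxford_grid"`.
#' @param min_count Count a cell as signal when strictly above this
#'   (default 5).
#' @return A list of class `"grid_relationships"`: `one_to_one` (data frame
#'   of reciprocal pairs), `rows_one_to_two`, `cols_one_to_two` (character
#'   vectors), `by_row`, `by_col` (lists of related labels).
#' @export
grid_relationships <- function(grid, min_count = 5L) {
  cnt <- grid$counts
  sig <- cnt > min_count
  by_row <- apply(sig, 1L, function(r) colnames(cnt)[r], simplify = FALSE)
  by_col <- apply(sig, 2L, function(r) rownames(cnt)[r], simplify = FALSE)
  pairs <- which(sig, arr.ind = TRUE)
  one <- pairs[rowSums(sig)[pairs[, 1L]] == 1L &
                 colSums(sig)[pairs[, 2L]] == 1L, , drop = FALSE]
  one_to_one <- data.frame(
    linkage_group = rownames(cnt)[one[, 1L]],
    chromosome = colnames(cnt)[one[, 2L]],
    n_pairs = cnt[one])
  structure(list(one_to_one = one_to_one,
                 rows_one_to_two = names(which(rowSums(sig) == 2L)),
                 cols_one_to_two = names(which(colSums(sig) == 2L)),
                 by_row = by_row, by_col = by_col,
                 min_count = min_count),
            class = "grid_relationships")
}

#' @export
print.grid_relationships <- function(x, ...) {
  cat(sprintf("Grid relationships (cells > %d pairs):\n", x$min_count))
  cat(sprintf("  %d one-to-one pair(s); %d group(s) and %d chromosome(s) in one-to-two patterns\n",
              nrow(x$one_to_one), length(x$rows_one_to_two),
              length(x$cols_one_to_two)))
  invisible(x)
}

#' Write an Oxford grid as TSV
#'
#' Two files: the count matrix (rows = linkage groups) and, with suffix
#' `".classes.tsv"`, the per-cell highlight classes.
#'
#' @param grid An `"oxford_grid"`.
#' @param path Output path for the count matrix.
#' @return `path`, invisibly.
#' @export
write_oxford_grid <- function(grid, path) {
  utils::write.table(grid$counts, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  utils::write.table(grid$highlight, paste0(path, ".classes.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}
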