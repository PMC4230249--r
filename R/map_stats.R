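#' Average framework-marker interval of a map
#'
#' The summed length of all linkage groups divided by the number of
#' framework-marker intervals, where a group with m framework markers
#' contributes m - 1 intervals (so the total interval count is the total
#' framework count minus the number of groups).
#'
#' @param rows A data frame of per-group map summary rows with columns
#'   `n_markers`, `n_framework`, `length_cM` (see [summary.linkage_map()]
#'   and [yellowtail_map_rows()]).
#' @return Average interval d in cM.
#' @export
average_framework_interval <- function(rows) {
  rows <- .check_rows(rows)
  n_int <- sum(rows$n_framework) - nrow(rows)
  if (n_int < 1L) stop("no framework intervals: cannot estimate d")
  sum(rows$length_cM) / n_int
}

.check_rows <- function(rows) {
  rows <- as.data.frame(rows)
  need <- c("n_framework", "length_cM")
  if (!all(need %in% names(rows)))
    stop("rows must have columns ", paste(need, collapse = ", "))
  if (any(rows$length_cM < 0)) stop("negative group length")
  rows
}

#' Genome length, method 1 (interval padding)
#'
#' Adds twice the average framework-marker interval to each linkage group's
#' observed length, acknowledging that terminal markers do not reach the
#' chromosome ends.
#'
#' @inheritParams average_framework_interval
#' @param d Average interval; computed from `rows` when `NULL`.
#' @return Numeric vector of per-group L1 values (named by `group` when
#'   present), with the total in `attr(, "total")`.
#' @export
genome_length_L1 <- function(rows, d = NULL) {
  rows <- .check_rows(rows)
  if (is.null(d)) d <- average_framework_interval(rows)
  L1 <- rows$length_cM + 2 * d
  if (!is.null(rows$group)) names(L1) <- rows$group
  attr(L1, "total") <- sum(L1)
  L1
}

#' Genome length, method 2 ((m+1)/(m-1) inflation)
#'
#' Multiplies each group's length by (m + 1)/(m - 1), m being its framework
#' marker count. Groups with m <= 1 have no defined factor and contribute
#' their observed length unchanged (a zero-length group contributes 0).
#'
#' @inheritParams average_framework_interval
#' @return Numeric vector of per-group L2 values with the total in
#'   `attr(, "total")`.
#' @export
genome_length_L2 <- function(rows) {
  rows <- .check_rows(rows)
  m <- rows$n_framework
  L2 <- ifelse(m >= 2, rows$length_cM * (m + 1) / (m - 1), rows$length_cM)
  if (!is.null(rows$group)) names(L2) <- rows$group
  attr(L2, "total") <- sum(L2)
  L2
}

#' Map coverage
#'
#' Expected fraction of the genome lying within d cM of a mapped marker:
#' c = 1 - exp(-2 d n / L). Consistently with the genome-length estimators,
#' n counts framework markers and d is the framework-interval average; this
#' is the convention under which the estimator reproduces itself on its own
#' map summaries.
#'
#' @param d Average marker interval (cM), > 0.
#' @param n Number of (framework) markers, >= 1.
#' @param L Estimated genome length (cM), > 0.
#' @return Coverage as a fraction in (0, 1).
#' @examples
#' coverage_c(4.96, 232, 1274.64)  # ~0.836
#' @export
coverage_c <- function(d, n, L) {
  if (any(d <= 0) || any(L <= 0) || any(n < 1))
    stop("d and L must be positive and n >= 1")
  1 - exp(-2 * d * n / L)
}

#' Full map summary report with genome-length estimates and coverage
#'
#' Assembles, for one or both sexes, the per-group table of marker counts,
#' framework counts, observed lengths and both genome-length estimates, plus
#' totals, averages and L1-/L2-based coverage. All values are computed at
#' full precision and rounded to 2 decimals only for printing.
#'
#' @param rows_female,rows_male Per-group summary rows (see
#'   [average_framework_interval()]); `rows_male` may be `NULL` for a
#'   female-only report.
#' @return An object of class `"map_summary_report"`: a list with one
#'   element per sex, each holding `rows` (with `L1`, `L2` columns),
#'   `totals`, `d`, and `coverage` (`c_L1`, `c_L2`).
#' @export
build_map_summary <- function(rows_female, rows_male = NULL) {
  one <- function(rows) {
    rows <- .check_rows(rows)
    d <- average_framework_interval(rows)
    L1 <- genome_length_L1(rows, d)
    L2 <- genome_length_L2(rows)
    rows$L1 <- as.numeric(L1)
    rows$L2 <- as.numeric(L2)
    n_fw <- sum(rows$n_framework)
    totals <- c(n_markers = sum(rows$n_markers), n_framework = n_fw,
                length_cM = sum(rows$length_cM),
                L1 = attr(L1, "total"), L2 = attr(L2, "total"))
    list(rows = rows, totals = totals, d = d,
         coverage = c(c_L1 = coverage_c(d, n_fw, attr(L1, "total")),
                      c_L2 = coverage_c(d, n_fw, attr(L2, "total"))))
  }
  out <- list(female = one(rows_female),
              male = if (!is.null(rows_male)) one(rows_male))
  out <- out[!vapply(out, is.null, logical(1L))]
  structure(out, class = "map_summary_report")
}

#' @export
print.map_summary_report <- function(x, ...) {
  for (sex in names(x)) {
    s <- x[[sex]]
    cat(sprintf("== %s map ==\n", sex))
    df <- s$rows
    for (col in c("length_cM", "L1", "L2")) df[[col]] <- round(df[[col]], 2)
    print(df, row.names = FALSE)
    cat(sprintf("Total: %d markers (%d framework), %.2f cM; L1 = %.2f, L2 = %.2f cM\n",
                s$totals[["n_markers"]], s$totals[["n_framework"]],
                s$totals[["length_cM"]], s$totals[["L1"]], s$totals[["L2"]]))
    cat(sprintf("Average interval d = %.2f cM; coverage c = %.2f%% (L1), %.2f%% (L2)\n",
                s$d, 100 * s$coverage[["c_L1"]], 100 * s$coverage[["c_L2"]]))
  }
  invisible(x)
}

#' Write / read a map summary table
#'
#' TSV dialect: columns `group`, `n_markers`, `n_framework`, `length_cM`.
#'
#' @param rows Per-group summary rows.
#' @param path File path.
#' @return `path` (writer, invisibly) or a data frame (reader).
#' @export
write_map_summary <- function(rows, path) {
  rows <- .check_rows(rows)
  utils::write.table(rows[, c("group", "n_markers", "n_framework",
                              "length_cM")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_map_summary
#' @export
read_map_summary <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Genome size from C-value
#'
#' Converts a haploid DNA content in picograms to base pairs with the
#' standard 978 Mbp/pg flow-cytometry conversion.
#'
#' @param c_value_pg C-value in pg (> 0).
#' @return Genome size in bp.
#' @examples
#' genome_size_from_cvalue(0.7) / 1e6  # ~685 Mb
#' @export
genome_size_from_cvalue <- function(c_value_pg) {
  if (any(c_value_pg <= 0)) stop("C-value must be positive")
  c_value_pg * 0.978e9
}

#' BAC library summary statistics
#'
#' Clone counts, total insert length and fold genome coverage of an arrayed
#' large-insert library.
#'
#' @param total_clones Number of arrayed clones.
#' @param insert_rate Fraction of clones carrying an insert, in `[0, 1]`.
#' @param mean_insert_bp Mean insert size (bp).
#' @param genome_size_bp Genome size (bp).
#' @return A list of class `"library_stats"`: `total_clones`, `insert_rate`,
#'   `clones_with_insert`, `mean_insert_bp`, `total_insert_bp`,
#'   `genome_size_bp`, `fold_coverage` (raw) and `fold_coverage_rounded`.
#' @examples
#' library_stats(110592, 0.71, 140700, 685e6)
#' @export
library_stats <- function(total_clones, insert_rate, mean_insert_bp,
                          genome_size_bp) {
  if (insert_rate < 0 || insert_rate > 1)
    stop("insert_rate must lie in [0, 1]")
  if (any(c(total_clones, mean_insert_bp, genome_size_bp) <= 0))
    stop("counts and sizes must be positive")
  clones <- round(total_clones * insert_rate)
  total_insert <- clones * mean_insert_bp
  fold <- total_insert / genome_size_bp
  structure(list(total_clones = total_clones, insert_rate = insert_rate,
                 clones_with_insert = clones,
                 mean_insert_bp = mean_insert_bp,
                 total_insert_bp = total_insert,
                 genome_size_bp = genome_size_bp,
                 fold_coverage = fold,
                 fold_coverage_rounded = round(fold)),
            class = "library_stats")
}

#' @export
print.library_stats <- function(x, ...) {
  cat(sprintf("BAC library: %s clones, %.0f%% with insert -> %s clones\n",
              format(x$total_clones, big.mark = ","), 100 * x$insert_rate,
              format(x$clones_with_insert, big.mark = ",")))
  cat(sprintf("  mean insert %.1f kb; total insert %.1f Gb; %.1fx (~%dx) a %.0f Mb genome\n",
              x$mean_insert_bp / 1e3, x$total_insert_bp / 1e9,
              x$fold_coverage, x$fold_coverage_rounded,
              x$genome_size_bp / 1e6))
  invisible(x)
}

#' End-sequence survey arithmetic
#'
#' Mean read length and the fraction of the genome sampled by a set of
#' qualified end reads.
#'
#' @param total_bp Summed length of the qualified reads.
#' @param n_reads Number of qualified reads.
#' @param genome_size_bp Genome size in bp.
#' @return A list: `mean_read_bp`, `genome_fraction_pct`.
#' @examples
#' bes_stats(3074133, 4956, 685e6)
#' @export
bes_stats <- function(total_bp, n_reads, genome_size_bp) {
  if (n_reads < 1 || total_bp <= 0 || genome_size_bp <= 0)
    stop("inputs must be positive")
  list(mean_read_bp = total_bp / n_reads,
       genome_fraction_pct = 100 * total_bp / genome_size_bp)
}

#' Published yellowtail map summary rows
#'
#' Per-linkage-group marker counts, framework-marker counts and Kosambi
#' lengths of the published female and male yellowtail (*Seriola
#' quinqueradiata*) SSR maps, as shipped in `extdata`. These are the input
#' rows from which the genome-length estimators and coverage reproduce the
#' published summary; framework counts are taken as given, never recomputed.
#'
#' @param sex `"female"` or `"male"`.
#' @return A data frame with columns `group`, `n_markers`, `n_framework`,
#'   `length_cM` (25 female rows or 26 male rows).
#' @export
yellowtail_map_rows <- function(sex = c("female", "male")) {
  sex <- match.arg(sex)
  path <- system.file("extdata",
                      sprintf("yellowtail_map_%s.tsv", sex),
                      package = "seriomap", mustWork = TRUE)
  read_map_summary(path)
}
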