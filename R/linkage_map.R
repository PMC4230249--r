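#' Fit a sex-specific pseudo-testcross linkage map
#'
#' The central estimator of the package. From a set of codominant marker
#' genotypes on one outbred F1 family it builds one parent's map:
#'
#' 1. markers heterozygous in the chosen parent are converted to backcross
#'    transmission vectors ([to_backcross()]);
#' 2. every marker is tested for 1:1 segregation distortion
#'    ([segregation_test()]);
#' 3. all pairwise recombination fractions and LOD scores are computed
#'    ([two_point()], phase-folded because grandparents are unknown);
#' 4. markers are sorted into linkage groups by single linkage at the LOD
#'    threshold ([group_at_lod()]); pairs with fewer than `min_informative`
#'    joint meioses never form edges;
#' 5. each group is ordered to minimize total adjacent recombination events
#'    ([order_group()]);
#' 6. map curation, the automated analogue of manual double-recombinant
#'    checking: single-marker double recombinants (a middle call differing
#'    from both tight flanking calls, almost always a genotyping error) are
#'    set to missing (`correct_doubles`), and ordered groups are split at
#'    adjacent joints whose two-point LOD falls below the grouping threshold
#'    (`split_weak`), which removes the rare chance joins that single
#'    linkage across hundreds of thousands of marker pairs produces;
#' 7. adjacent recombination fractions are converted to Kosambi cM.
#'
#' @param x A `"genotype_set"` from [read_genotypes()] or
#'   [simulate_cross()], or a list of [marker_geno()] records.
#' @param parent Which parent's meioses to map: `"dam"` (female map) or
#'   `"sire"` (male map).
#' @param lod Minimum LOD score for linkage (default 4.0).
#' @param min_informative Minimum jointly informative meioses for a pair to
#'   support linkage (default 20).
#' @param correct_doubles Blank single-marker double recombinants before the
#'   final distance estimates (default `TRUE`).
#' @param split_weak Split ordered groups at adjacent intervals whose LOD is
#'   below `lod` (default `TRUE`).
#' @param alpha Significance level for the segregation-distortion flag.
#' @param exhaustive_max Passed to [order_group()].
#' @return An object of class `"linkage_map"` with components `parent`,
#'   `groups` (list of `"ordered_group"`), `segregation` (per-marker test
#'   table), `n_progeny`, `n_markers`, `n_double_recombinants_blanked`, and
#'   `call`. Methods: [print.linkage_map()], [summary.linkage_map()],
#'   [plot.linkage_map()].
#' @examples
#' sim <- simulate_cross(n_chromosomes = 3, markers_per_chromosome = 8,
#'                       n_progeny = 60, seed = 1)
#' map <- linkage_map(sim$genotypes, parent = "dam")
#' summary(map)
#' @export
linkage_map <- function(x, parent = c("dam", "sire"), lod = 4.0,
                        min_informative = 20L, correct_doubles = TRUE,
                        split_weak = TRUE, alpha = 0.05,
                        exhaustive_max = 8L) {
  parent <- match.arg(parent)
  cl <- match.call()
  wanted <- c("both", if (parent == "dam") "female_only" else "male_only")
  keep <- vapply(x, function(m) m$informativeness %in% wanted, logical(1L))
  if (!any(keep)) stop("no markers informative for parent '", parent, "'")
  vecs <- lapply(x[keep], to_backcross, parent = parent)
  M <- .as_code_matrix(vecs)
  n_prog <- ncol(M)

  seg <- do.call(rbind, lapply(rownames(M), function(id) {
    v <- M[id, ]
    st <- segregation_test(c(sum(v == 0, na.rm = TRUE),
                             sum(v == 1, na.rm = TRUE)), alpha = alpha)
    data.frame(marker = id, n_A = st$counts[[1L]], n_H = st$counts[[2L]],
               chi2 = st$chi2, p_value = st$p_value,
               distorted = st$distorted)
  }))
  rownames(seg) <- NULL

  tp <- .two_point_matrix(M)
  lodm <- tp$lod
  lodm[tp$n < min_informative] <- -Inf
  diag(lodm) <- -Inf
  groups <- group_at_lod(lodm, threshold = lod, markers = rownames(M))

  ordered <- lapply(seq_along(groups), function(i) {
    order_group(groups[[i]], M, group_id = names(groups)[i],
                exhaustive_max = exhaustive_max)
  })

  n_blanked <- 0L
  if (correct_doubles) {
    for (og in ordered) {
      res <- .blank_double_recombinants(og$markers, M)
      M <- res$M
      n_blanked <- n_blanked + res$n_blanked
    }
    # re-order on the corrected calls so the final order is a local optimum
    # of the cleaned data, not of the error-inflated counts
    ordered <- lapply(ordered, function(og)
      order_group(og$markers, M, group_id = og$group_id,
                  exhaustive_max = exhaustive_max))
  }

  if (split_weak) {
    # splitting a chance-merged group leaves each part ordered as it sat
    # inside the chimera; re-order every split part and re-examine it
    # (parts shrink at each split, so this terminates)
    queue <- ordered
    ordered <- list()
    while (length(queue)) {
      og <- queue[[1L]]
      queue <- queue[-1L]
      parts <- .split_weak_joints(og, M, lod)
      if (length(parts) == 1L) {
        ordered[[length(ordered) + 1L]] <- og
      } else {
        for (p in parts)
          queue[[length(queue) + 1L]] <-
            order_group(p$markers, M, group_id = p$group_id,
                        exhaustive_max = exhaustive_max)
      }
    }
  }

  # relabel groups by decreasing size, ties by first marker id
  ord <- order(-vapply(ordered, function(g) length(g$markers), integer(1L)),
               vapply(ordered, function(g) sort(g$markers)[1L],
                      character(1L)))
  ordered <- ordered[ord]
  for (i in seq_along(ordered)) ordered[[i]]$group_id <- paste0("LG", i)

  structure(list(parent = parent, lod_threshold = lod,
                 min_informative = min_informative,
                 groups = ordered, segregation = seg,
                 n_progeny = n_prog, n_markers = nrow(M),
                 n_double_recombinants_blanked = n_blanked,
                 codes = M, call = cl),
            class = "linkage_map")
}

# split an ordered group wherever the adjacent two-point LOD drops below
# the grouping threshold (no joint information counts as below)
.split_weak_joints <- function(og, M, threshold) {
  m <- length(og$markers)
  if (m < 2L) return(list(og))
  weak <- which(is.na(og$lod_adj) | og$lod_adj < threshold)
  if (!length(weak)) return(list(og))
  starts <- c(1L, weak + 1L)
  ends <- c(weak, m)
  lapply(seq_along(starts), function(k) {
    .finish_ordered_group(og$markers[starts[k]:ends[k]], M,
                          paste0(og$group_id, letters[k]))
  })
}

#' @export
print.linkage_map <- function(x, ...) {
  cat(sprintf("Pseudo-testcross linkage map (%s meioses)\n",
              if (x$parent == "dam") "female" else "male"))
  cat(sprintf("  %d markers in %d linkage groups (LOD >= %.1f), %d progeny\n",
              x$n_markers, length(x$groups), x$lod_threshold, x$n_progeny))
  cat(sprintf("  total length %.2f cM; %d distorted marker(s) at alpha = %s; %d double-recombinant call(s) blanked\n",
              sum(vapply(x$groups, function(g) max(g$positions_cM),
                         numeric(1L))),
              sum(x$segregation$distorted),
              format(attr(x$segregation, "alpha", exact = TRUE) %||% 0.05),
              x$n_double_recombinants_blanked))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarize a linkage map as per-group rows
#'
#' One row per linkage group: number of markers, number of framework markers
#' (markers at distinct map positions), and Kosambi length in cM -- the form
#' consumed by the genome-length estimators ([genome_length_L1()],
#' [genome_length_L2()], [build_map_summary()]).
#'
#' @param object A [linkage_map()].
#' @param ... Unused.
#' @return A data frame of class `"summary.linkage_map"` with columns
#'   `group`, `n_markers`, `n_framework`, `length_cM`.
#' @method summary linkage_map
#' @export
summary.linkage_map <- function(object, ...) {
  df <- do.call(rbind, lapply(object$groups, function(g)
    data.frame(group = g$group_id, n_markers = length(g$markers),
               n_framework = sum(g$framework),
               length_cM = max(g$positions_cM))))
  rownames(df) <- NULL
  structure(df, class = c("summary.linkage_map", "data.frame"),
            parent = object$parent, n_progeny = object$n_progeny)
}

#' @export
print.summary.linkage_map <- function(x, digits = 2, ...) {
  cat(sprintf("Linkage map summary (%s):\n",
              if (attr(x, "parent") == "dam") "female" else "male"))
  df <- as.data.frame(x)
  df$length_cM <- round(df$length_cM, digits)
  print(df, row.names = FALSE)
  cat(sprintf("Total: %d markers, %d framework, %.2f cM in %d groups\n",
              sum(x$n_markers), sum(x$n_framework), sum(x$length_cM),
              nrow(x)))
  invisible(x)
}

#' Plot a linkage map
#'
#' Draws each linkage group as a vertical bar with horizontal ticks at
#' marker positions, in the style of standard map-charting tools.
#'
#' @param x A [linkage_map()].
#' @param max_groups Plot at most this many groups (largest first).
#' @param ... Passed to [graphics::plot()].
#' @method plot linkage_map
#' @export
plot.linkage_map <- function(x, max_groups = 26L, ...) {
  gs <- x$groups[seq_len(min(length(x$groups), max_groups))]
  ymax <- max(vapply(gs, function(g) max(g$positions_cM), numeric(1L)), 1)
  graphics::plot(NA, xlim = c(0.5, length(gs) + 0.5), ylim = c(ymax, 0),
                 xlab = "", ylab = "Position (Kosambi cM)", xaxt = "n", ...)
  graphics::axis(1, at = seq_along(gs),
                 labels = vapply(gs, `[[`, character(1L), "group_id"),
                 las = 2, cex.axis = 0.7)
  for (i in seq_along(gs)) {
    g <- gs[[i]]
    graphics::segments(i, 0, i, max(g$positions_cM), lwd = 3,
                       col = "grey70")
    graphics::segments(i - 0.15, g$positions_cM, i + 0.15, g$positions_cM)
  }
  invisible(x)
}

#' Extract marker assignments from a linkage map
#'
#' @param map A [linkage_map()].
#' @return A data frame with columns `marker`, `group`, `position_cM`,
#'   `framework` -- the dialect written by [write_map()].
#' @export
map_positions <- function(map) {
  df <- do.call(rbind, lapply(map$groups, function(g)
    data.frame(marker = g$markers, group = g$group_id,
               position_cM = g$positions_cM, framework = g$framework)))
  rownames(df) <- NULL
  df
}

#' Write a linkage map as TSV
#'
#' Columns: `group`, `marker`, `position_cM`, `framework`.
#'
#' @param map A [linkage_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  df <- map_positions(map)[, c("group", "marker", "position_cM",
                               "framework")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
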