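#' Kosambi map function
#'
#' Converts a recombination fraction to map distance allowing for partial
#' crossover interference: d = 25 * ln((1 + 2 theta) / (1 - 2 theta)) cM.
#' `kosambi_theta()` is the exact inverse.
#'
#' @param theta Recombination fraction(s) in `[0, 0.5)`.
#' @param d Map distance(s) in centimorgans (cM), `>= 0`.
#' @return Map distance in cM, or recombination fraction.
#' @examples
#' kosambi_cm(0.1)            # 25 * log(1.5) ~ 10.14 cM
#' kosambi_theta(kosambi_cm(0.3))
#' @export
kosambi_cm <- function(theta) {
  if (any(theta < 0 | theta >= 0.5, na.rm = TRUE))
    stop("theta must lie in [0, 0.5)")
  25 * log((1 + 2 * theta) / (1 - 2 * theta))
}

#' @rdname kosambi_cm
#' @export
kosambi_theta <- function(d) {
  if (any(d < 0, na.rm = TRUE)) stop("d must be non-negative")
  0.5 * tanh(d / 50)
}

# Two-point statistics for a folded backcross pair.
# r is folded to min(r, n - r) because transmission labels are arbitrary
# (grandparent phase unknown).
.two_point_stats <- function(r, n) {
  r <- pmin(r, n - r)
  theta <- ifelse(n > 0, r / n, NA_real_)
  lod <- ifelse(
    n == 0, NA_real_,
    ifelse(theta == 0, n * log10(2),
           r * log10(ifelse(theta == 0, 1, theta)) +
             (n - r) * log10(1 - theta) + n * log10(2)))
  list(r = r, theta = theta, lod = lod)
}

#' Two-point linkage analysis of a marker pair
#'
#' Counts recombinant transmissions over progeny informative for both
#' markers. Because backcross coding is arbitrary per marker, the recombinant
#' count is folded to `min(r, n - r)` before estimating `theta = r / n`; the
#' LOD score is the standard backcross statistic
#' `r log10(theta) + (n - r) log10(1 - theta) + n log10(2)`
#' (with the limit `n log10(2)` at `theta = 0`, and 0 at `theta = 0.5`).
#'
#' @param a,b [to_backcross()] vectors from the same parent and family.
#' @return An object of class `"two_point"`: `marker_a`, `marker_b`,
#'   `n_informative`, `n_recombinant` (folded), `theta_hat`, `lod`.
#' @export
two_point <- function(a, b) {
  stopifnot(inherits(a, "backcross_vector"), inherits(b, "backcross_vector"))
  if (a$parent != b$parent)
    stop("vectors are from different parents")
  ok <- !is.na(a$codes) & !is.na(b$codes)
  n <- sum(ok)
  if (n == 0L)
    stop("no jointly informative progeny for ", a$marker_id, " and ",
         b$marker_id)
  mism <- sum(a$codes[ok] != b$codes[ok])
  st <- .two_point_stats(mism, n)
  structure(list(marker_a = a$marker_id, marker_b = b$marker_id,
                 n_informative = n, n_recombinant = st$r,
                 theta_hat = st$theta, lod = st$lod),
            class = "two_point")
}

#' @export
print.two_point <- function(x, ...) {
  cat(sprintf("%s -- %s: r = %d / n = %d, theta = %.4f, LOD = %.3f\n",
              x$marker_a, x$marker_b, x$n_recombinant, x$n_informative,
              x$theta_hat, x$lod))
  invisible(x)
}

# All-pairs two-point statistics on a 0/1/NA code matrix (markers x progeny).
# Returns folded recombinant counts, informative counts, theta and LOD as
# square matrices. Done with three matrix products, so ~700 markers is cheap.
.two_point_matrix <- function(M) {
  A <- (M == 0); A[is.na(A)] <- FALSE; storage.mode(A) <- "double"
  H <- (M == 1); H[is.na(H)] <- FALSE; storage.mode(H) <- "double"
  P <- A + H
  N <- P %*% t(P)
  mism <- A %*% t(H) + H %*% t(A)
  st <- .two_point_stats(mism, N)
  list(n = N, r = st$r, theta = st$theta, lod = st$lod)
}

#' Sort markers into linkage groups at a LOD threshold
#'
#' Markers are grouped by single linkage: two markers belong to the same
#' group whenever a chain of marker pairs with LOD at or above the threshold
#' connects them (connected components of the pairwise linkage graph).
#' Absent pairs are treated as below threshold.
#'
#' @param pairs A data frame with columns `marker_a`, `marker_b`, `lod`
#'   (e.g. rbind-ed [two_point()] results), or a symmetric LOD matrix with
#'   marker dimnames.
#' @param threshold Minimum LOD for linkage (default 4.0).
#' @param markers Optional character vector of all marker ids, so markers
#'   with no strong pair appear as singletons.
#' @return A list of class `"linkage_groups"`: character vectors of marker
#'   ids, largest first, named `"LG1"`, `"LG2"`, ...
#' @export
group_at_lod <- function(pairs, threshold = 4.0, markers = NULL) {
  if (is.matrix(pairs)) {
    stopifnot(!is.null(rownames(pairs)))
    ids <- rownames(pairs)
    idx <- which(pairs >= threshold & upper.tri(pairs), arr.ind = TRUE)
    edges <- data.frame(a = ids[idx[, 1L]], b = ids[idx[, 2L]])
    markers <- unique(c(markers, ids))
  } else {
    stopifnot(all(c("marker_a", "marker_b", "lod") %in% names(pairs)))
    keep <- !is.na(pairs$lod) & pairs$lod >= threshold
    edges <- data.frame(a = pairs$marker_a[keep], b = pairs$marker_b[keep])
    markers <- unique(c(markers, pairs$marker_a, pairs$marker_b))
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = markers))
  memb <- igraph::components(g)$membership
  groups <- split(names(memb), memb)
  ord <- order(-lengths(groups),
               vapply(groups, function(g) sort(g)[1L], character(1L)))
  groups <- lapply(groups[ord], unname)
  names(groups) <- paste0("LG", seq_along(groups))
  structure(groups, class = "linkage_groups", threshold = threshold)
}

#' @export
print.linkage_groups <- function(x, ...) {
  cat(sprintf("%d linkage groups (LOD >= %.2f): sizes %s\n", length(x),
              attr(x, "threshold"),
              paste(lengths(x), collapse = ", ")))
  invisible(x)
}

# path objective: total adjacent recombination events
.path_cost <- function(ord, R) {
  m <- length(ord)
  if (m < 2L) return(0)
  sum(R[cbind(ord[-m], ord[-1L])])
}

# all permutations of 1..n (n <= 8 in practice)
.perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .perms(n - 1L)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    out[[k]] <- cbind(k, matrix(rest[sub], nrow(sub)))
  }
  do.call(rbind, out)
}

.order_exhaustive <- function(R) {
  m <- nrow(R)
  if (m <= 2L) return(seq_len(m))
  pp <- .perms(m)
  costs <- numeric(nrow(pp))
  for (j in seq_len(m - 1L))
    costs <- costs + R[cbind(pp[, j], pp[, j + 1L])]
  best <- which(costs == min(costs))
  # deterministic tie-break: smallest marker-name sequence after orientation
  cands <- lapply(best, function(i) pp[i, ])
  keys <- vapply(cands, function(o) {
    o2 <- if (rownames(R)[o[m]] < rownames(R)[o[1L]]) rev(o) else o
    paste(rownames(R)[o2], collapse = "\r")
  }, character(1L))
  cands[[which.min(rank(keys, ties.method = "first"))]]
}

# spectral seed: order markers by the Fiedler vector of the graph
# Laplacian of the linkage similarity 1 - 2*theta (a 1-D embedding that is
# robust to the local optima greedy chaining falls into)
.spectral_seed <- function(theta) {
  W <- 1 - 2 * theta
  W[is.na(W)] <- 0
  diag(W) <- 0
  L <- diag(rowSums(W)) - W
  ev <- eigen(L, symmetric = TRUE)
  order(ev$vectors[, ncol(W) - 1L])
}

.order_heuristic <- function(R, theta = NULL) {
  m <- nrow(R)
  seeds <- list()
  best_ord <- NULL
  best_cost <- Inf
  for (start in seq_len(m)) {       # greedy nearest-neighbour from each seed
    ord <- start
    left <- setdiff(seq_len(m), start)
    while (length(left)) {
      nxt <- left[which.min(R[ord[length(ord)], left])]
      ord <- c(ord, nxt)
      left <- setdiff(left, nxt)
    }
    cost <- .path_cost(ord, R)
    if (cost < best_cost) {
      best_cost <- cost
      best_ord <- ord
    }
  }
  seeds[[1L]] <- best_ord
  if (!is.null(theta) && m >= 3L)
    seeds[[2L]] <- .spectral_seed(theta)
  refined <- lapply(seeds, .local_search, R = R)
  costs <- vapply(refined, .path_cost, numeric(1L), R = R)
  refined[[which.min(costs)]]
}

.local_search <- function(best_ord, R) {
  m <- nrow(R)
  best_cost <- .path_cost(best_ord, R)
  # local search: 2-opt segment reversals plus or-opt relocation of short
  # segments (1-3 markers), iterated to a joint local optimum
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (i in seq_len(m - 1L)) {        # 2-opt
      for (j in seq(i + 1L, m)) {
        cand <- best_ord
        cand[i:j] <- rev(cand[i:j])
        cost <- .path_cost(cand, R)
        if (cost < best_cost - 1e-9) {
          best_ord <- cand
          best_cost <- cost
          improved <- TRUE
        }
      }
    }
    for (len in 1:3) {                  # or-opt
      if (len >= m) break
      for (i in seq_len(m - len + 1L)) {
        seg <- best_ord[i:(i + len - 1L)]
        rest <- best_ord[-(i:(i + len - 1L))]
        for (k in 0:length(rest)) {
          cand <- append(rest, seg, after = k)
          cost <- .path_cost(cand, R)
          if (cost < best_cost - 1e-9) {
            best_ord <- cand
            best_cost <- cost
            improved <- TRUE
          }
        }
      }
    }
    w <- min(5L, m)                     # ripple: permute sliding windows
    if (w >= 3L) {
      pw <- .perms(w)
      for (s in seq_len(m - w + 1L)) {
        base <- best_ord
        for (p in seq_len(nrow(pw))) {
          cand <- base
          cand[s:(s + w - 1L)] <- base[s - 1L + pw[p, ]]
          cost <- .path_cost(cand, R)
          if (cost < best_cost - 1e-9) {
            best_ord <- cand
            best_cost <- cost
            improved <- TRUE
          }
        }
      }
    }
  }
  best_ord
}

#' Order the markers of a linkage group
#'
#' Finds the marker order minimizing the total number of recombination events
#' over adjacent intervals (the objective implied by double-recombinant
#' checking: spurious orders inflate adjacent recombinants). Groups of up to
#' `exhaustive_max` markers are solved exactly by enumeration; larger groups
#' use greedy nearest-neighbour seeding refined by 2-opt. The orientation is
#' normalized so the lexicographically smaller terminal marker comes first,
#' and adjacent Kosambi distances are taken from the pairwise `theta` of
#' consecutive markers.
#'
#' @param markers Character vector of marker ids forming one group.
#' @param bc A named list of [to_backcross()] vectors, or a 0/1/NA code
#'   matrix with marker rownames.
#' @param method `"auto"` (exhaustive up to `exhaustive_max`, else
#'   heuristic), `"exhaustive"`, or `"heuristic"`.
#' @param exhaustive_max Largest group size solved by enumeration (default 8).
#' @param group_id Label for the group.
#' @param theta_max Cap applied to adjacent recombination fractions before
#'   the Kosambi transform (default 0.49); pairs with no joint information
#'   are placed at the cap with a warning.
#' @return An object of class `"ordered_group"`: `group_id`,
#'   `markers` (in map order), `positions_cM` (Kosambi, starting at 0),
#'   `framework` (logical: first marker at each distinct position),
#'   `theta_adj`, `lod_adj`, `n_adj` (per adjacent interval), and `objective`
#'   (total adjacent recombination events).
#' @export
order_group <- function(markers, bc, method = c("auto", "exhaustive",
                                                "heuristic"),
                        exhaustive_max = 8L, group_id = "LG1",
                        theta_max = 0.49) {
  method <- match.arg(method)
  M <- .as_code_matrix(bc)[markers, , drop = FALSE]
  tp <- .two_point_matrix(M)
  m <- length(markers)
  if (m == 1L) {
    return(structure(list(group_id = group_id, markers = markers,
                          positions_cM = 0, framework = TRUE,
                          theta_adj = numeric(0), lod_adj = numeric(0),
                          n_adj = integer(0), objective = 0),
                     class = "ordered_group"))
  }
  R <- tp$r
  if (any(tp$n == 0 & upper.tri(tp$n)))
    warning("group ", group_id,
            ": marker pair(s) with no joint information; ",
            "theta capped at ", theta_max)
  R[tp$n == 0] <- max(tp$n)  # no evidence: treat as maximally recombinant
  diag(R) <- 0
  rownames(R) <- colnames(R) <- markers
  idx <-
    if (method == "exhaustive" || (method == "auto" && m <= exhaustive_max))
      .order_exhaustive(R)
    else
      .order_heuristic(R, theta = tp$theta)
  ord <- markers[idx]
  if (ord[length(ord)] < ord[1L]) ord <- rev(ord)
  .finish_ordered_group(ord, M, group_id, theta_max,
                        objective = .path_cost(match(ord, markers), R))
}

# compute adjacent statistics + positions for a fixed order
.finish_ordered_group <- function(ord, M, group_id, theta_max = 0.49,
                                  objective = NA_real_) {
  m <- length(ord)
  M <- M[ord, , drop = FALSE]
  if (m == 1L) {
    theta <- numeric(0); lod <- numeric(0); n <- integer(0)
  } else {
    a <- M[-m, , drop = FALSE]
    b <- M[-1L, , drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    n <- as.integer(rowSums(ok))
    mism <- rowSums(a != b, na.rm = TRUE)
    mism[n == 0L] <- 0
    st <- .two_point_stats(mism, n)
    theta <- st$theta; lod <- st$lod
  }
  theta_c <- pmin(ifelse(is.na(theta), theta_max, theta), theta_max)
  pos <- cumsum(c(0, kosambi_cm(theta_c)))
  framework <- !duplicated(round(pos, 10))
  structure(list(group_id = group_id, markers = ord, positions_cM = pos,
                 framework = framework, theta_adj = theta, lod_adj = lod,
                 n_adj = n, objective = objective),
            class = "ordered_group")
}

#' @export
print.ordered_group <- function(x, digits = 2, ...) {
  cat(sprintf("Ordered group %s: %d markers (%d framework), %.2f cM\n",
              x$group_id, length(x$markers), sum(x$framework),
              max(x$positions_cM)))
  df <- data.frame(marker = x$markers,
                   position_cM = round(x$positions_cM, digits),
                   framework = x$framework)
  print(df, row.names = FALSE)
  invisible(x)
}

# accept list of backcross_vectors or a code matrix
.as_code_matrix <- function(bc) {
  if (is.matrix(bc)) return(bc)
  if (inherits(bc, "backcross_vector")) bc <- list(bc)
  M <- t(vapply(bc, function(v) ifelse(v$codes == "A", 0, 1),
                numeric(length(bc[[1L]]$codes))))
  rownames(M) <- vapply(bc, `[[`, character(1L), "marker_id")
  M
}

#' Count double-recombination events along an ordered group
#'
#' For every progeny, the non-missing transmission codes are taken in map
#' order and each run of three consecutive informative calls is inspected: an
#' event is counted when the middle call differs from both flanking calls.
#' With tightly linked markers such events are almost always genotyping
#' errors rather than genuine double crossovers.
#'
#' @param og An [order_group()] result, or a character vector of marker ids
#'   in map order.
#' @param bc Backcross vectors or code matrix (see [order_group()]).
#' @return Integer count (0 for groups of fewer than 3 markers).
#' @export
count_double_recombinants <- function(og, bc) {
  ord <- if (inherits(og, "ordered_group")) og$markers else og
  if (length(ord) < 3L) return(0L)
  M <- .as_code_matrix(bc)[ord, , drop = FALSE]
  total <- 0L
  for (j in seq_len(ncol(M))) {
    v <- M[, j]
    v <- v[!is.na(v)]
    if (length(v) >= 3L) {
      mid <- v[c(-1L, -length(v))]
      total <- total + sum(mid != v[-c(length(v) - 1L, length(v))] &
                             mid != v[-c(1L, 2L)])
    }
  }
  total
}

# Set the middle call of every double-recombinant triple to missing.
# Returns the modified matrix and the number of calls blanked.
.blank_double_recombinants <- function(ord, M) {
  sub <- M[ord, , drop = FALSE]
  n_blank <- 0L
  if (length(ord) >= 3L) {
    for (j in seq_len(ncol(sub))) {
      v <- sub[, j]
      idx <- which(!is.na(v))
      if (length(idx) >= 3L) {
        vv <- v[idx]
        k <- 2:(length(vv) - 1L)
        bad <- k[vv[k] != vv[k - 1L] & vv[k] != vv[k + 1L]]
        if (length(bad)) {
          sub[idx[bad], j] <- NA
          n_blank <- n_blank + length(bad)
        }
      }
    }
  }
  M[ord, ] <- sub
  list(M = M, n_blanked = n_blank)
}
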