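# Independent oracles used across tests. These deliberately re-derive the
# quantities by brute force / closed form, never through the package's own
# code paths.

# exhaustive minimum of the ordering objective over all marker permutations
brute_min_path_cost <- function(M) {
  m <- nrow(M)
  folded_adj_cost <- function(ord) {
    a <- M[ord[-m], , drop = FALSE]
    b <- M[ord[-1L], , drop = FALSE]
    mm <- rowSums(a != b, na.rm = TRUE)
    nn <- rowSums(!is.na(a) & !is.na(b))
    sum(pmin(mm, nn - mm))
  }
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  min(vapply(perms(seq_len(m)), folded_adj_cost, numeric(1L)))
}

# literal restatement of the top-3 e-value-ratio orthology rule
brute_orthology <- function(hits, ratio_threshold = 1e-3) {
  if (nrow(hits) == 0L) return(list(accepted = FALSE, chr = NA_character_))
  hits <- hits[order(hits$e_value, -hits$bit_score), , drop = FALSE]
  ev <- pmax(hits$e_value, 1e-180)
  accept <- TRUE
  for (k in 2:3) {
    if (k > nrow(hits)) break
    overlap <- hits$query_start[1L] <= hits$query_end[k] &&
      hits$query_start[k] <= hits$query_end[1L]
    if (overlap && ev[1L] / ev[k] > ratio_threshold) accept <- FALSE
  }
  list(accepted = accept,
       chr = if (accept) hits$subject_id[1L] else NA_character_)
}

# random hit set for one query (<= 3 hits, random overlaps and e-values)
random_hit_set <- function(query = "q1") {
  n <- sample(1:3, 1L)
  qs <- sample(1:150, n, replace = TRUE)
  len <- sample(20:120, n, replace = TRUE)
  data.frame(query_id = query,
             subject_id = paste0("chr", sample(1:5, n, replace = TRUE)),
             percent_identity = 90, alignment_length = len,
             mismatches = 0L, gap_opens = 0L,
             query_start = qs, query_end = qs + len,
             subject_start = 1L, subject_end = len,
             e_value = 10^-sample(0:40, n, replace = TRUE),
             bit_score = round(runif(n, 40, 200), 1),
             reversed = FALSE, stringsAsFactors = FALSE)
}

# chi-square df=1 survival function via the normal tail (closed form)
chi1_p <- function(chi2) 2 * stats::pnorm(-sqrt(chi2))

# Kendall tau between recovered and true marker order, resolving
# co-segregating blocks (tied estimated positions) by the true order:
# markers at identical positions carry no order information.
order_tau <- function(est_pos, true_pos) {
  o <- order(est_pos, true_pos)
  abs(stats::cor(seq_along(o), true_pos[o], method = "kendall"))
}

# small fully-informative marker set built by hand
toy_family <- function(n = 4L) cross_family("D", "S", paste0("P", seq_len(n)))

toy_marker <- function(id, dam, sire, calls, fam = toy_family(length(calls))) {
  marker_geno(id, dam, sire, calls, fam)
}
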