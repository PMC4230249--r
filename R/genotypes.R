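#' Define a single-family mapping panel
#'
#' A pseudo-testcross panel is one outbred F1 family: two parents (dam and
#' sire) and their progeny. Each parent's heterozygous markers are analysed
#' as if segregating in a backcross, giving separate maternal and paternal
#' maps.
#'
#' @param dam_id,sire_id Identifiers of the two parents (must differ).
#' @param progeny_ids Character vector of progeny identifiers (unique,
#'   non-empty). The study scale is 90 progeny.
#' @return An object of class `"cross_family"`.
#' @examples
#' fam <- cross_family("dam", "sire", paste0("F", 1:90))
#' fam
#' @export
cross_family <- function(dam_id, sire_id, progeny_ids) {
  stopifnot(is.character(dam_id), length(dam_id) == 1L,
            is.character(sire_id), length(sire_id) == 1L)
  progeny_ids <- as.character(progeny_ids)
  if (length(progeny_ids) == 0L) stop("progeny_ids must be non-empty")
  if (anyDuplicated(progeny_ids)) stop("progeny_ids must be unique")
  if (dam_id == sire_id) stop("dam and sire ids must differ")
  if (dam_id %in% progeny_ids || sire_id %in% progeny_ids)
    stop("parent ids must not appear among progeny ids")
  structure(list(dam_id = dam_id, sire_id = sire_id,
                 progeny_ids = progeny_ids),
            class = "cross_family")
}

#' @export
print.cross_family <- function(x, ...) {
  cat("Mapping family:", x$dam_id, "x", x$sire_id,
      "with", length(x$progeny_ids), "progeny\n")
  invisible(x)
}

# tokens accepted as "missing call" in genotype tables
.missing_tokens <- c("NA", "-", "./.", ".", "")

# Parse an "x/y" genotype cell into a sorted length-2 allele vector or NA.
.parse_call <- function(cell) {
  cell <- trimws(cell)
  if (is.na(cell) || cell %in% .missing_tokens) return(NULL)
  parts <- strsplit(cell, "/", fixed = TRUE)[[1L]]
  if (length(parts) != 2L || any(!nzchar(parts))) return(NA)  # unparseable
  sort(parts)
}

#' Construct a marker genotype record
#'
#' Holds one codominant marker's alleles for dam, sire and every progeny of a
#' family, together with its informativeness class (which parents are
#' heterozygous, hence in which parental map the marker can segregate).
#'
#' @param marker_id Marker name.
#' @param dam,sire Length-2 character vectors of parental alleles (or `NA`).
#' @param progeny A 2-row character matrix (one column per progeny; `NA`
#'   columns are missing calls) or a character vector of `"x/y"` calls.
#' @param family A [cross_family()].
#' @return An object of class `"marker_geno"` with fields `marker_id`, `dam`,
#'   `sire`, `progeny` (2 x n matrix), `informativeness` and
#'   `mendelian_consistent` (per-progeny logical; `NA` where the call is
#'   missing).
#' @seealso [classify_informativeness()], [to_backcross()]
#' @export
marker_geno <- function(marker_id, dam, sire, progeny, family) {
  stopifnot(inherits(family, "cross_family"))
  n <- length(family$progeny_ids)
  if (is.character(progeny) && is.null(dim(progeny))) {
    calls <- lapply(progeny, .parse_call)
    progeny <- vapply(calls, function(p) {
      if (is.null(p) || anyNA(p)) c(NA_character_, NA_character_) else p
    }, character(2L))
  }
  stopifnot(is.matrix(progeny), nrow(progeny) == 2L, ncol(progeny) == n)
  colnames(progeny) <- family$progeny_ids
  dam <- if (is.null(dam) || anyNA(dam)) c(NA_character_, NA_character_) else sort(as.character(dam))
  sire <- if (is.null(sire) || anyNA(sire)) c(NA_character_, NA_character_) else sort(as.character(sire))
  x <- structure(list(marker_id = marker_id, dam = dam, sire = sire,
                      progeny = progeny, family = family),
                 class = "marker_geno")
  x$informativeness <- classify_informativeness(x)
  x$mendelian_consistent <- .mendel_check(x)
  x
}

# Per-progeny: can the call be explained as one dam allele + one sire allele?
.mendel_check <- function(m) {
  if (anyNA(m$dam) || anyNA(m$sire))
    return(rep(NA, ncol(m$progeny)))
  apply(m$progeny, 2L, function(call) {
    if (anyNA(call)) return(NA)
    (call[1L] %in% m$dam && call[2L] %in% m$sire) ||
      (call[2L] %in% m$dam && call[1L] %in% m$sire)
  })
}

#' @export
print.marker_geno <- function(x, ...) {
  n_miss <- sum(is.na(x$progeny[1L, ]))
  cat(sprintf("Marker %s: dam %s/%s, sire %s/%s, %d progeny (%d missing), %s\n",
              x$marker_id, x$dam[1L], x$dam[2L], x$sire[1L], x$sire[2L],
              ncol(x$progeny), n_miss, x$informativeness))
  invisible(x)
}

#' Classify a marker's informativeness
#'
#' A marker segregates in a parent's map only if that parent is heterozygous.
#' The four classes mirror the usual coding of outbred SSR panels:
#' polymorphic in both parents, in the dam only (`female_only`), in the sire
#' only (`male_only`), or in neither (`uninformative`).
#'
#' @param m A [marker_geno()] record.
#' @return One of `"both"`, `"female_only"`, `"male_only"`, `"uninformative"`.
#' @export
classify_informativeness <- function(m) {
  if (anyNA(m$dam) || anyNA(m$sire)) {
    warning("marker ", m$marker_id, ": missing parental genotype; ",
            "treated as uninformative")
    return("uninformative")
  }
  dam_het <- m$dam[1L] != m$dam[2L]
  sire_het <- m$sire[1L] != m$sire[2L]
  if (dam_het && sire_het) "both"
  else if (dam_het) "female_only"
  else if (sire_het) "male_only"
  else "uninformative"
}

#' Convert a marker to pseudo-testcross (backcross) transmissions
#'
#' For the tracked heterozygous parent, each progeny is coded by which of the
#' two parental alleles it inherited: `"A"` for the lexicographically first
#' allele, `"H"` for the second. Because grandparent genotypes are unknown the
#' labelling is arbitrary per marker, and downstream linkage analysis must
#' treat the recombination fraction phase-symmetrically.
#'
#' When the transmitted allele cannot be deduced (both decompositions of the
#' progeny call assign a different allele to the tracked parent, as for an
#' `a/b x a/b` marker with an `a/b` progeny) the progeny is coded missing.
#' Calls inconsistent with the parents are also coded missing (they are
#' flagged in `marker_geno$mendelian_consistent`).
#'
#' @param m A [marker_geno()] record.
#' @param parent `"dam"` or `"sire"`.
#' @return An object of class `"backcross_vector"`: list with `marker_id`,
#'   `parent`, `alleles` (the tracked parent's sorted alleles) and `codes`
#'   (character vector `"A"`/`"H"`/`NA` per progeny).
#' @export
to_backcross <- function(m, parent = c("dam", "sire")) {
  parent <- match.arg(parent)
  p_all <- m[[parent]]
  o_all <- m[[if (parent == "dam") "sire" else "dam"]]
  if (anyNA(p_all) || p_all[1L] == p_all[2L])
    stop("marker ", m$marker_id, " is not informative for parent '",
         parent, "'")
  codes <- apply(m$progeny, 2L, function(call) {
    if (anyNA(call)) return(NA_character_)
    transmitted <- character(0L)
    # decomposition 1: call[1] from tracked parent, call[2] from the other
    if (call[1L] %in% p_all && call[2L] %in% o_all)
      transmitted <- c(transmitted, call[1L])
    if (call[2L] %in% p_all && call[1L] %in% o_all)
      transmitted <- c(transmitted, call[2L])
    transmitted <- unique(transmitted)
    if (length(transmitted) != 1L) return(NA_character_)  # ambiguous/invalid
    if (transmitted == p_all[1L]) "A" else "H"
  })
  structure(list(marker_id = m$marker_id, parent = parent,
                 alleles = p_all, codes = codes),
            class = "backcross_vector")
}

#' @export
print.backcross_vector <- function(x, ...) {
  tab <- table(factor(x$codes, levels = c("A", "H")), useNA = "always")
  cat(sprintf("Backcross vector %s (%s): A=%d H=%d missing=%d\n",
              x$marker_id, x$parent, tab[["A"]], tab[["H"]],
              sum(is.na(x$codes))))
  invisible(x)
}

#' Chi-square test for segregation distortion
#'
#' Goodness-of-fit of the observed transmission counts against the Mendelian
#' 1:1 expectation, with 1 degree of freedom and no continuity correction:
#' chi2 = (n_A - n_H)^2 / (n_A + n_H). Missing calls are excluded.
#'
#' @param v A [to_backcross()] vector, or a length-2 integer vector of counts
#'   `c(n_A, n_H)`.
#' @param alpha Significance level for the distortion flag (default 0.05).
#' @return A list of class `"segregation_test"`: `counts`, `chi2`, `p_value`,
#'   `distorted`.
#' @examples
#' segregation_test(c(60, 30))  # chi2 = 10
#' @export
segregation_test <- function(v, alpha = 0.05) {
  if (inherits(v, "backcross_vector")) {
    counts <- c(n_A = sum(v$codes == "A", na.rm = TRUE),
                n_H = sum(v$codes == "H", na.rm = TRUE))
  } else {
    stopifnot(is.numeric(v), length(v) == 2L)
    counts <- c(n_A = v[[1L]], n_H = v[[2L]])
  }
  n <- sum(counts)
  if (n < 1L) stop("no informative progeny: cannot test segregation")
  chi2 <- (counts[[1L]] - counts[[2L]])^2 / n
  p <- stats::pchisq(chi2, df = 1L, lower.tail = FALSE)
  structure(list(counts = counts, chi2 = chi2, p_value = p,
                 distorted = p < alpha, alpha = alpha),
            class = "segregation_test")
}

#' @export
print.segregation_test <- function(x, ...) {
  cat(sprintf("1:1 segregation test: A=%d H=%d, chi2(1) = %.4g, p = %.4g%s\n",
              x$counts[[1L]], x$counts[[2L]], x$chi2, x$p_value,
              if (x$distorted) " [distorted]" else ""))
  invisible(x)
}

#' Read a genotype table
#'
#' The dialect is one marker per row, tab-separated, with a header of
#' individual ids: `marker <TAB> <dam> <TAB> <sire> <TAB> <progeny ids...>`.
#' Cells are `"allele1/allele2"`; `NA`, `-`, `./.` and empty cells are
#' missing. Unparseable cells are converted to missing, counted, and reported
#' on stderr.
#'
#' @param path Path to the TSV file.
#' @param family A [cross_family()] naming the parent and progeny columns.
#' @return A list of [marker_geno()] records (class `"genotype_set"`).
#' @export
read_genotypes <- function(path, family) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL)
  if (names(tab)[1L] != "marker")
    stop("expected first column 'marker', found '", names(tab)[1L], "'")
  ids <- names(tab)[-1L]
  for (p in c(family$dam_id, family$sire_id))
    if (!p %in% ids) stop("parent column '", p, "' missing from header")
  absent <- setdiff(family$progeny_ids, ids)
  if (length(absent))
    stop("progeny columns missing from header: ",
         paste(absent, collapse = ", "))
  if (anyDuplicated(tab$marker))
    stop("duplicate marker id(s): ",
         paste(unique(tab$marker[duplicated(tab$marker)]), collapse = ", "))
  n_bad <- 0L
  out <- lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    parse_parent <- function(id) {
      p <- .parse_call(row[[id]])
      if (is.null(p)) return(NA)
      p
    }
    calls <- lapply(family$progeny_ids, function(id) .parse_call(row[[id]]))
    bad <- vapply(calls, function(p) !is.null(p) && anyNA(p), logical(1L))
    n_bad <<- n_bad + sum(bad)
    prog <- vapply(calls, function(p) {
      if (is.null(p) || anyNA(p)) c(NA_character_, NA_character_) else p
    }, character(2L))
    marker_geno(row$marker, parse_parent(family$dam_id),
                parse_parent(family$sire_id), prog, family)
  })
  message(sprintf("read %d markers x %d progeny from %s (%d unparseable cells set missing)",
                  length(out), length(family$progeny_ids), path, n_bad))
  structure(out, class = "genotype_set",
            names = vapply(out, `[[`, character(1L), "marker_id"))
}

#' Write a genotype table
#'
#' Emits the same dialect [read_genotypes()] consumes, so tables round-trip.
#'
#' @param markers A `"genotype_set"` or list of [marker_geno()] records.
#' @param path Output path.
#' @param family A [cross_family()]; defaults to the family of the first
#'   marker.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(markers, path, family = NULL) {
  if (is.null(family)) family <- markers[[1L]]$family
  fmt <- function(al) {
    if (anyNA(al)) "NA" else paste(al, collapse = "/")
  }
  header <- c("marker", family$dam_id, family$sire_id, family$progeny_ids)
  lines <- vapply(markers, function(m) {
    cells <- apply(m$progeny, 2L, fmt)
    paste(c(m$marker_id, fmt(m$dam), fmt(m$sire), cells), collapse = "\t")
  }, character(1L))
  writeLines(c(paste(header, collapse = "\t"), lines), path)
  invisible(path)
}

#' @export
print.genotype_set <- function(x, ...) {
  info <- table(factor(vapply(x, `[[`, character(1L), "informativeness"),
                       levels = c("both", "female_only", "male_only",
                                  "uninformative")))
  cat(sprintf("Genotype set: %d markers x %d progeny\n", length(x),
              length(x[[1L]]$family$progeny_ids)))
  cat("  informativeness:",
      paste(names(info), info, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
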