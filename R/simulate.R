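# run code with a local RNG state seeded from `seed`
.with_seed <- function(seed, code) {
  if (is.null(seed)) stop("a seed is required for reproducibility")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate an outbred F1 mapping cross
#'
#' Generates a two-parent family segregating codominant markers on
#' `n_chromosomes` chromosomes under Mendelian 1:1 transmission per parent.
#' Meioses follow a no-interference model: crossovers per chromosome are
#' Poisson with mean equal to the chromosome length in Morgans, placed
#' uniformly (Haldane scale). Genotyping errors flip the transmitted allele
#' of a random parent at `error_rate` per call; missingness blanks calls at
#' `missing_rate`. The hidden truth (marker positions, per-meiosis
#' transmissions before error, error and missing masks) is returned with
#' the data.
#'
#' Defaults mirror the study scale this package is built around: 24
#' chromosomes of ~40-60 cM carrying 29 markers each, 90 progeny, 0.5%
#' genotyping error and 2% missing calls.
#'
#' @param n_chromosomes Number of chromosomes (default 24).
#' @param markers_per_chromosome Markers per chromosome (default 29).
#' @param n_progeny Progeny count (default 90).
#' @param chr_lengths_cM Chromosome lengths in cM; default: drawn uniformly
#'   in `[40, 60]`.
#' @param positions_cM Optional list (per chromosome) of marker positions;
#'   default: uniform random, sorted.
#' @param missing_rate Per-call missing probability (default 0.02).
#' @param error_rate Per-call transmission-flip probability (default 0.005).
#' @param informativeness Probabilities of the marker classes, named
#'   `both`, `female_only`, `male_only` (default all `both`: four distinct
#'   parental alleles).
#' @param seed Integer seed (mandatory).
#' @return A list of class `"sim_cross"`: `genotypes` (a `"genotype_set"`),
#'   `family`, and `truth` with `positions` (data frame `marker`,
#'   `chromosome`, `pos_cM`), `chr_lengths_cM`, `transmissions` (list of
#'   dam/sire 0/1 matrices, pre-error), `errors`, `missing` (logical
#'   matrices markers x progeny per parent / per call), `config`.
#' @examples
#' sim <- simulate_cross(n_chromosomes = 2, markers_per_chromosome = 5,
#'                       n_progeny = 30, seed = 7)
#' sim$truth$positions[1:5, ]
#' @export
simulate_cross <- function(n_chromosomes = 24L, markers_per_chromosome = 29L,
                           n_progeny = 90L, chr_lengths_cM = NULL,
                           positions_cM = NULL, missing_rate = 0.02,
                           error_rate = 0.005,
                           informativeness = c(both = 1, female_only = 0,
                                               male_only = 0),
                           seed) {
  stopifnot(n_chromosomes >= 1L, markers_per_chromosome >= 1L,
            n_progeny >= 1L, missing_rate >= 0, missing_rate <= 1,
            error_rate >= 0, error_rate <= 1)
  .with_seed(seed, {
    if (is.null(chr_lengths_cM))
      chr_lengths_cM <- stats::runif(n_chromosomes, 40, 60)
    stopifnot(length(chr_lengths_cM) == n_chromosomes)
    if (is.null(positions_cM))
      positions_cM <- lapply(chr_lengths_cM, function(L)
        sort(stats::runif(markers_per_chromosome, 0, L)))
    fam <- cross_family("dam", "sire",
                        sprintf("F%03d", seq_len(n_progeny)))
    info_p <- informativeness / sum(informativeness)

    marker_rows <- list()
    truth_pos <- list()
    trans <- list(dam = NULL, sire = NULL)
    for (chr in seq_len(n_chromosomes)) {
      pos <- positions_cM[[chr]]
      m <- length(pos)
      ids <- sprintf("M%02d_%02d", chr, seq_len(m))
      truth_pos[[chr]] <- data.frame(marker = ids, chromosome = chr,
                                     pos_cM = pos)
      for (parent in c("dam", "sire")) {
        hap <- matrix(0L, m, n_progeny)
        L_morgan <- chr_lengths_cM[chr] / 100
        for (j in seq_len(n_progeny)) {
          n_xo <- stats::rpois(1L, L_morgan)
          xo <- sort(stats::runif(n_xo, 0, chr_lengths_cM[chr]))
          start <- stats::rbinom(1L, 1L, 0.5)
          hap[, j] <- (start + findInterval(pos, xo)) %% 2L
        }
        rownames(hap) <- ids
        trans[[parent]] <- rbind(trans[[parent]], hap)
      }
    }
    truth_pos <- do.call(rbind, truth_pos)
    n_mark <- nrow(truth_pos)

    classes <- sample(names(info_p), n_mark, replace = TRUE, prob = info_p)
    dam_alleles <- lapply(classes, function(cl)
      if (cl == "male_only") c("a", "a") else c("a", "b"))
    sire_alleles <- lapply(classes, function(cl)
      if (cl == "female_only") c("c", "c") else c("c", "d"))

    err <- list(
      dam = matrix(stats::runif(n_mark * n_progeny) < error_rate,
                   n_mark, n_progeny),
      sire = matrix(stats::runif(n_mark * n_progeny) < error_rate,
                    n_mark, n_progeny))
    miss <- matrix(stats::runif(n_mark * n_progeny) < missing_rate,
                   n_mark, n_progeny)

    markers <- vector("list", n_mark)
    for (i in seq_len(n_mark)) {
      dam_tx <- (trans$dam[i, ] + err$dam[i, ]) %% 2L
      sire_tx <- (trans$sire[i, ] + err$sire[i, ]) %% 2L
      da <- dam_alleles[[i]][dam_tx + 1L]
      sa <- sire_alleles[[i]][sire_tx + 1L]
      prog <- rbind(pmin(da, sa), pmax(da, sa))
      prog[, miss[i, ]] <- NA_character_
      markers[[i]] <- marker_geno(truth_pos$marker[i], dam_alleles[[i]],
                                  sire_alleles[[i]], prog, fam)
    }
    genotypes <- structure(markers, class = "genotype_set",
                           names = truth_pos$marker)
    structure(list(
      genotypes = genotypes, family = fam,
      truth = list(positions = truth_pos, chr_lengths_cM = chr_lengths_cM,
                   transmissions = trans, errors = err, missing = miss,
                   classes = classes,
                   config = list(n_chromosomes = n_chromosomes,
                                 markers_per_chromosome = markers_per_chromosome,
                                 n_progeny = n_progeny,
                                 missing_rate = missing_rate,
                                 error_rate = error_rate, seed = seed))),
      class = "sim_cross")
  })
}

#' @export
print.sim_cross <- function(x, ...) {
  cfg <- x$truth$config
  cat(sprintf("Simulated cross: %d markers on %d chromosomes x %d progeny (seed %s)\n",
              nrow(x$truth$positions), cfg$n_chromosomes, cfg$n_progeny,
              format(cfg$seed)))
  invisible(x)
}

.bg_bases <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  sample(names(p), n, replace = TRUE, prob = p)
}

#' Generate masked end-reads with planted SSR motifs
#'
#' Background bases are i.i.d. at the target GC content; perfect SSR arrays
#' are planted at known coordinates, optional short reads are added to
#' exercise read qualification, and an optional cleanup pass mutates any
#' accidental background array at or above `clean_min_copies` copies so
#' that the planted motifs are provably the only detectable arrays. The
#' returned truth table records every planted motif and each read's
#' intended qualification status.
#'
#' @param n_reads Number of full-length reads (default 1000).
#' @param read_length Read length in bp (default 620, the survey's mean
#'   qualified read length).
#' @param gc_target Background GC percent (default 41.36).
#' @param planted_motifs Either a data frame with columns `read` (index),
#'   `unit`, `copies`, `start`, or a single integer: that many motifs are
#'   planted at random (unit drawn from common SSR units, 7-12 copies).
#' @param n_short Number of additional short (sub-100 bp) reads appended
#'   after the full-length reads (default 0).
#' @param short_length Length of the short reads (default 60).
#' @param clean_background Mutate accidental background arrays
#'   (default `TRUE`).
#' @param clean_min_copies Copy threshold for the cleanup scan (default 6,
#'   one below the detection default, leaving a safety margin).
#' @param seed Integer seed (mandatory).
#' @return A list of class `"sim_reads"`: `reads` (a `"bes_set"` data
#'   frame), `truth` (`motifs` data frame with `read_id`, `unit`, `copies`,
#'   `start`, `end`; `qualified` logical per read; `gc_target`), `config`.
#' @export
generate_ssr_reads <- function(n_reads = 1000L, read_length = 620L,
                               gc_target = 41.36, planted_motifs = 0L,
                               n_short = 0L, short_length = 60L,
                               clean_background = TRUE,
                               clean_min_copies = 6L, seed) {
  gc <- gc_target / 100
  .with_seed(seed, {
    common_units <- c("A", "AC", "AG", "AT", "AAT", "AGC", "AAC", "AAAT",
                      "AAAC", "AGAT")
    if (is.numeric(planted_motifs) && length(planted_motifs) == 1L) {
      n_mot <- as.integer(planted_motifs)
      planted_motifs <- if (n_mot > 0L) data.frame(
        read = sample(n_reads, n_mot, replace = n_mot > n_reads),
        unit = sample(common_units, n_mot, replace = TRUE),
        copies = sample(7:12, n_mot, replace = TRUE)
      ) else data.frame(read = integer(0), unit = character(0),
                        copies = integer(0))
      if (nrow(planted_motifs)) {
        span <- nchar(planted_motifs$unit) * planted_motifs$copies
        if (any(span + 2L > read_length))
          stop("planted motif longer than read")
        planted_motifs$start <- vapply(span, function(s)
          sample(2:(read_length - s), 1L), integer(1L))
      } else planted_motifs$start <- integer(0)
    }
    stopifnot(all(c("read", "unit", "copies", "start") %in%
                    names(planted_motifs)))

    reads <- vapply(seq_len(n_reads), function(i)
      paste(.bg_bases(read_length, gc), collapse = ""), character(1L))

    # plant motifs, breaking the flanking bases so an array can never
    # extend into the background by a chance extra copy
    if (nrow(planted_motifs)) {
      for (i in seq_len(nrow(planted_motifs))) {
        p <- planted_motifs[i, ]
        arr <- strrep(p$unit, p$copies)
        e <- p$start + nchar(arr) - 1L
        if (e > read_length) stop("planted motif longer than read")
        r <- reads[p$read]
        substr(r, p$start, e) <- arr
        k <- nchar(p$unit)
        if (p$start > 1L) {
          last <- substr(p$unit, k, k)
          substr(r, p$start - 1L, p$start - 1L) <-
            sample(setdiff(c("A", "C", "G", "T"), last), 1L)
        }
        if (e < read_length) {
          first <- substr(p$unit, 1L, 1L)
          substr(r, e + 1L, e + 1L) <-
            sample(setdiff(c("A", "C", "G", "T"), first), 1L)
        }
        reads[p$read] <- r
      }
    }

    # break accidental background arrays so planted motifs are the only
    # detectable ones (planted spans are left untouched)
    if (clean_background && n_reads > 0L) {
      for (pass in 1:20) {
        dirty <- FALSE
        for (ri in seq_len(n_reads)) {
          hits <- find_ssrs(reads[ri], min_copies = clean_min_copies)
          if (!nrow(hits)) next
          pl <- planted_motifs[planted_motifs$read == ri, , drop = FALSE]
          pl_end <- pl$start + nchar(pl$unit) * pl$copies - 1L
          for (hi in seq_len(nrow(hits))) {
            inside <- nrow(pl) > 0L &&
              any(hits$start[hi] >= pl$start - 1L &
                    hits$end[hi] <= pl_end + 1L)
            if (inside) next
            dirty <- TRUE
            mid <- (hits$start[hi] + hits$end[hi]) %/% 2L
            cur <- substr(reads[ri], mid, mid)
            substr(reads[ri], mid, mid) <-
              sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
          }
        }
        if (!dirty) break
      }
    }

    if (n_short > 0L)
      reads <- c(reads, vapply(seq_len(n_short), function(i)
        paste(.bg_bases(short_length, gc), collapse = ""), character(1L)))

    ids <- sprintf("clone%04d_%s", seq_along(reads),
                   rep(c("SP6", "T7"), length.out = length(reads)))
    bes <- data.frame(read_id = ids,
                      clone_id = sub("_(SP6|T7)$", "", ids),
                      end = sub("^.*_", "", ids),
                      sequence = reads, stringsAsFactors = FALSE)
    class(bes) <- c("bes_set", "data.frame")
    truth_motifs <- if (nrow(planted_motifs)) data.frame(
      read_id = ids[planted_motifs$read],
      unit = planted_motifs$unit, copies = planted_motifs$copies,
      start = planted_motifs$start,
      end = planted_motifs$start +
        nchar(planted_motifs$unit) * planted_motifs$copies - 1L
    ) else data.frame(read_id = character(0), unit = character(0),
                      copies = integer(0), start = integer(0),
                      end = integer(0))
    structure(list(
      reads = bes,
      truth = list(motifs = truth_motifs,
                   qualified = .effective_length(bes$sequence) >= 101L,
                   gc_target = gc_target),
      config = list(n_reads = n_reads, read_length = read_length,
                    n_short = n_short, seed = seed)),
      class = "sim_reads")
  })
}

#' Generate a BLAST hit table with known orthology structure
#'
#' Every mapped marker receives a rank-1 hit on its true subject chromosome
#' (given by the planted linkage-group-to-chromosome relation). A chosen
#' fraction of markers additionally receives an overlapping decoy hit whose
#' e-value is close enough to the top hit (ratio `decoy_reject_ratio`,
#' above the rejection threshold) to make the assignment unclear; another
#' fraction receives a harmless decoy (non-overlapping, or overlapping with
#' a very small ratio) that must not cause rejection. The truth table
#' records the intended accept/reject outcome per marker.
#'
#' @param marker_groups Named character vector: marker id -> linkage group.
#' @param relation Named character vector: linkage group -> subject
#'   chromosome.
#' @param reject_fraction Fraction of markers given a rejecting decoy
#'   (default 0.2).
#' @param benign_fraction Fraction of the remaining markers given a
#'   harmless decoy (default 0.3).
#' @param decoy_reject_ratio e1/e2 ratio of rejecting decoys (default
#'   1e-2, above the 1e-3 rule threshold).
#' @param decoy_benign_ratio e1/e2 ratio of overlapping harmless decoys
#'   (default 1e-4).
#' @param seed Integer seed (mandatory).
#' @return A list of class `"sim_hits"`: `hits` (a `"blast_hits"` data
#'   frame), `truth` (data frame `marker`, `group`, `chromosome`,
#'   `accept`), `config`.
#' @export
generate_blast_hits <- function(marker_groups, relation,
                                reject_fraction = 0.2,
                                benign_fraction = 0.3,
                                decoy_reject_ratio = 1e-2,
                                decoy_benign_ratio = 1e-4, seed) {
  stopifnot(all(marker_groups %in% names(relation)))
  .with_seed(seed, {
    markers <- names(marker_groups)
    n <- length(markers)
    chr <- unname(relation[marker_groups])
    e1 <- 10^-stats::runif(n, 15, 60)
    qs <- sample(1:200, n, replace = TRUE)
    qlen <- sample(80:300, n, replace = TRUE)
    reject <- stats::runif(n) < reject_fraction
    benign <- !reject & stats::runif(n) < benign_fraction
    other_chr <- vapply(chr, function(ch)
      if (length(relation) > 1L) sample(setdiff(unname(relation), ch), 1L)
      else ch, character(1L))

    row_of <- function(q, s, qstart, qend, ev) data.frame(
      query_id = q, subject_id = s,
      percent_identity = round(stats::runif(1L, 85, 99), 2),
      alignment_length = qend - qstart + 1L, mismatches = 3L,
      gap_opens = 0L, query_start = qstart, query_end = qend,
      subject_start = 1000L, subject_end = 1000L + qend - qstart,
      e_value = ev, bit_score = round(-10 * log10(ev) + 40, 1),
      reversed = FALSE, stringsAsFactors = FALSE)

    rows <- vector("list", n)
    for (i in seq_len(n)) {
      r <- list(row_of(markers[i], chr[i], qs[i], qs[i] + qlen[i], e1[i]))
      if (reject[i]) {       # overlapping, e-values too close: must reject
        r[[2L]] <- row_of(markers[i], other_chr[i], qs[i] + 10L,
                          qs[i] + qlen[i] + 10L,
                          e1[i] / decoy_reject_ratio)
      } else if (benign[i]) {  # harmless second hit: must still accept
        if (stats::runif(1L) < 0.5) {
          r[[2L]] <- row_of(markers[i], other_chr[i],   # non-overlapping
                            qs[i] + qlen[i] + 50L,
                            qs[i] + 2L * qlen[i] + 50L,
                            e1[i] * 10)
        } else {                                        # overlapping, clear
          r[[2L]] <- row_of(markers[i], other_chr[i], qs[i] + 10L,
                            qs[i] + qlen[i] + 10L,
                            e1[i] / decoy_benign_ratio)
        }
      }
      rows[[i]] <- do.call(rbind, r)
    }
    hits <- do.call(rbind, rows)
    # shuffle rows: consumers must not rely on input order
    hits <- hits[sample(nrow(hits)), , drop = FALSE]
    rownames(hits) <- NULL
    class(hits) <- c("blast_hits", "data.frame")
    structure(list(
      hits = hits,
      truth = data.frame(marker = markers, group = unname(marker_groups),
                         chromosome = chr, accept = !reject),
      config = list(reject_fraction = reject_fraction, seed = seed)),
      class = "sim_hits")
  })
}
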