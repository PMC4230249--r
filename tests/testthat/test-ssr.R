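test_that("read qualification applies the strict >100 bp rule", {
  reads <- data.frame(
    read_id = c("r1", "r2", "r3", "r4"),
    clone_id = c("c1", "c2", "c3", "c4"),
    end = "SP6",
    sequence = c(strrep("ACGT", 25),                  # 100 bp: excluded
                 paste0(strrep("ACGT", 25), "A"),     # 101 bp: included
                 strrep("N", 300),                    # fully masked
                 paste0(strrep("acgt", 40),           # 160 soft-masked +
                        strrep("ACGT", 30))),         # 120 unmasked
    stringsAsFactors = FALSE)
  q <- suppressMessages(qualify_reads(reads))
  expect_setequal(q$read_id, c("r2", "r4"))
  expect_equal(q$effective_length[q$read_id == "r4"], 120L)
  empty <- reads[0, ]
  expect_warning(qualify_reads(empty), "no reads")
})

test_that("GC content counts unmasked bases only", {
  expect_equal(gc_content("ATGC"), 50)
  expect_equal(gc_content("GGGG"), 100)
  expect_equal(gc_content("ATGCNNNNgggg"), 50)  # N and soft-masked ignored
  expect_error(gc_content("NNNN"), "no unmasked bases")
})

test_that("canonical unit naming is strand- and rotation-invariant", {
  expect_equal(canonical_unit(c("CA", "TG", "GT", "AC")),
               rep("AC", 4))
  expect_equal(unit_label("TG"), "AC/GT")
  expect_equal(unit_label("A"), "A/T")
  expect_equal(unit_label("G"), "C/G")
  expect_equal(unit_label("TAA"), "AAT/ATT")
  expect_equal(unit_label("AT"), "AT/AT")
  # idempotent
  u <- c("CAT", "GGC", "TTTA")
  expect_equal(canonical_unit(canonical_unit(u)), canonical_unit(u))
})

test_that("SSR scanning finds perfect arrays at the copy threshold", {
  hits <- find_ssrs(strrep("AC", 7))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$unit, "AC")
  expect_equal(hits$copies, 7L)
  expect_equal(hits$start, 1L)
  expect_equal(hits$end, 14L)
  expect_equal(hits$length_bp, 14L)
  # strict "over six": 6 copies are not an SSR under the default
  expect_equal(nrow(find_ssrs(strrep("AC", 6))), 0L)
  expect_equal(nrow(find_ssrs(strrep("AC", 6), min_copies = 6L)), 1L)
})

test_that("arrays are reported at their primitive unit, masked bases break them", {
  seq <- paste0("TTTT", strrep("AC", 8), "GGTT")
  hits <- find_ssrs(seq, min_copies = 7L)
  expect_equal(nrow(hits), 1L)                # not additionally as ACAC
  expect_equal(hits$unit, "AC")
  expect_equal(hits$start, 5L)
  # lowercase (soft-masked) base splits the array below threshold
  broken <- paste0(strrep("AC", 4), "ac", strrep("AC", 4))
  expect_equal(nrow(find_ssrs(broken, min_copies = 7L)), 0L)
  # same-unit intervals never overlap
  long <- paste0(strrep("A", 20), "C", strrep("A", 9))
  h <- find_ssrs(long, min_copies = 7L)
  h <- h[h$unit == "A", ]
  expect_equal(nrow(h), 2L)
  expect_true(all(h$end[-nrow(h)] < h$start[-1L]))
})

test_that("planted motifs are recovered with exact coordinates", {
  gen <- generate_ssr_reads(
    n_reads = 10L, read_length = 1000L,
    planted_motifs = data.frame(
      read = c(1:10, 3, 7),
      unit = c("AC", "A", "AAT", "AG", "AAAT", "AC", "AGC", "AT", "AAC",
               "AGAT", "AC", "AAT"),
      copies = c(7, 9, 8, 12, 7, 10, 7, 8, 9, 7, 8, 7),
      start = c(101, 201, 301, 401, 501, 601, 151, 251, 351, 451, 701,
                801)),
    seed = 77)
  found <- find_ssrs_all(gen$reads)
  truth <- gen$truth$motifs
  expect_equal(nrow(found), nrow(truth))
  key <- function(df) paste(df$read_id, canonical_unit(df$unit),
                            df$copies, df$start, df$end)
  expect_setequal(key(found), key(truth))
})

test_that("reverse-complementing reads leaves motif classes unchanged", {
  gen <- generate_ssr_reads(n_reads = 4L, read_length = 500L,
                            planted_motifs = 6L, seed = 13)
  fwd <- find_ssrs_all(gen$reads)
  rc <- gen$reads
  rc$sequence <- vapply(strsplit(chartr("ACGT", "TGCA", rc$sequence), ""),
                        function(x) paste(rev(x), collapse = ""),
                        character(1L))
  rev_hits <- find_ssrs_all(rc)
  expect_equal(sort(fwd$label), sort(rev_hits$label))
  expect_equal(sort(fwd$copies), sort(rev_hits$copies))
})

test_that("representative and clone-level selection follow precedence", {
  # spacers free of tandem repeats at the detection threshold
  sp <- "GTACGGATCCTGAACGTTAGCATGGCTTAA"
  motifs <- find_ssrs(paste0(strrep("AC", 8), sp, strrep("AAT", 9)))
  rep <- pick_representative(motifs)
  expect_equal(rep$unit, "AAT")          # 27 bp beats 16 bp
  expect_equal(rep$length_bp, 27L)
  one <- find_ssrs(strrep("AG", 7))
  expect_equal(pick_representative(one)$unit, "AG")
  expect_null(pick_representative(one[0, ]))
  # bp tie: leftmost wins
  tie <- find_ssrs(paste0(strrep("AC", 8), sp, strrep("AG", 8)))
  expect_equal(pick_representative(tie)$start, 1L)

  sp6 <- paste0(sp, strrep("AC", 7), sp)
  t7 <- paste0(sp, strrep("AAT", 9), sp)
  sel <- clone_marker_selection(sp6, t7)
  expect_equal(sel$end, "SP6")
  expect_equal(sel$motif$unit, "AC")
  sel <- clone_marker_selection(strrep(sp, 3), t7)
  expect_equal(sel$end, "T7")
  expect_null(clone_marker_selection(strrep(sp, 3), strrep(sp, 3)))
  expect_error(clone_marker_selection(NULL, NULL), "at least one read")
})

test_that("the motif tally conserves counts and occupied bp", {
  gen <- generate_ssr_reads(n_reads = 8L, read_length = 800L,
                            planted_motifs = 10L, seed = 5)
  motifs <- find_ssrs_all(gen$reads)
  tally <- ssr_tally(motifs, total_bp = sum(nchar(gen$reads$sequence)))
  expect_equal(sum(tally$by_class), nrow(motifs))
  expect_equal(sum(tally$by_unit$n), nrow(motifs))
  expect_equal(tally$bp_occupied, sum(motifs$length_bp))
  expect_gte(tally$pct_of_sequence, 0)
  expect_lte(tally$pct_of_sequence, 100)
  empty <- ssr_tally(motifs[0, ])
  expect_equal(sum(empty$by_class), 0L)
  expect_equal(empty$bp_occupied, 0L)
})

test_that("FASTA and motif TSV round-trip through their writers", {
  gen <- generate_ssr_reads(n_reads = 5L, read_length = 300L,
                            planted_motifs = 4L, seed = 31)
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_bes_fasta(gen$reads, fa)
  back <- read_bes_fasta(fa)
  expect_equal(back$sequence, gen$reads$sequence)
  expect_equal(back$clone_id, gen$reads$clone_id)
  expect_equal(back$end, gen$reads$end)

  motifs <- find_ssrs_all(gen$reads)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_ssr_tsv(motifs, tsv)
  tab <- read.delim(tsv)
  expect_equal(nrow(tab), nrow(motifs))
  expect_equal(tab$start1, motifs$start)
})
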