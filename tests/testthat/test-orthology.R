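hit_row <- function(q, s, qs, qe, ev, bs = 100) {
  data.frame(query_id = q, subject_id = s, percent_identity = 95,
             alignment_length = abs(qe - qs) + 1L, mismatches = 0L,
             gap_opens = 0L, query_start = qs, query_end = qe,
             subject_start = 1L, subject_end = 100L, e_value = ev,
             bit_score = bs, reversed = FALSE, stringsAsFactors = FALSE)
}

test_that("BLAST tabular parsing normalizes and round-trips", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "q1\tchr1\t95.0\t100\t3\t0\t10\t109\t500\t599\t1e-30\t180",
    "q2\tchr2\t90.0\t80\t5\t1\t200\t121\t700\t779\t1e-10\t95",
    "broken line without tabs"), path)
  hits <- suppressMessages(read_blast_tabular(path))
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$query_start[2L], 121L)   # reversed pair normalized
  expect_equal(hits$query_end[2L], 200L)
  expect_true(hits$reversed[2L])
  expect_false(hits$reversed[1L])

  gen <- generate_blast_hits(
    stats::setNames(rep(paste0("LG", 1:4), each = 25),
                    paste0("mk", 1:100)),
    stats::setNames(paste0("chr", 1:4), paste0("LG", 1:4)), seed = 8)
  out <- withr::local_tempfile(fileext = ".tsv")
  write_blast_tabular(gen$hits, out)
  back <- read_blast_tabular(out)
  expect_equal(nrow(back), nrow(gen$hits))
  expect_equal(back$query_id, gen$hits$query_id)
  expect_equal(back$e_value, gen$hits$e_value, tolerance = 1e-6)

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), empty)
  expect_warning(e <- read_blast_tabular(empty), "no hits")
  expect_equal(nrow(e), 0L)
})

test_that("overlapping same-query hits collapse to the most significant", {
  single <- hit_row("q", "chr1", 1, 100, 1e-20)
  expect_equal(nrow(dedupe_top_hits(single)), 1L)
  two <- rbind(hit_row("q", "chr1", 1, 100, 1e-20),
               hit_row("q", "chr2", 50, 150, 1e-15))
  kept <- dedupe_top_hits(two)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$subject_id, "chr1")
  disjoint <- rbind(hit_row("q", "chr1", 1, 100, 1e-20),
                    hit_row("q", "chr2", 200, 300, 1e-15))
  expect_equal(nrow(dedupe_top_hits(disjoint)), 2L)
  # never increases the hit count
  set.seed(42)
  for (i in 1:20) {
    h <- random_hit_set()
    expect_lte(nrow(dedupe_top_hits(h)), nrow(h))
  }
})

test_that("the e-value-ratio rule accepts clear and rejects unclear pairs", {
  clear <- rbind(hit_row("q", "chr1", 1, 100, 1e-30),
                 hit_row("q", "chr2", 50, 150, 1e-10))
  a <- assign_orthology(clear)          # ratio 1e-20 <= 1e-3
  expect_true(a$accepted)
  expect_equal(a$subject_chromosome, "chr1")

  unclear <- rbind(hit_row("q", "chr1", 1, 100, 1e-12),
                   hit_row("q", "chr2", 50, 150, 1e-10))
  a <- assign_orthology(unclear)        # ratio 1e-2 > 1e-3
  expect_false(a$accepted)
  expect_equal(a$reject_reason, "unclear_ratio")

  apart <- rbind(hit_row("q", "chr1", 1, 100, 1e-12),
                 hit_row("q", "chr2", 300, 400, 1e-10))
  expect_true(assign_orthology(apart)$accepted)  # no overlap: no veto

  expect_equal(assign_orthology(apart[0, ])$reject_reason, "no_hit")
  # a third close overlapping hit also vetoes
  third <- rbind(hit_row("q", "chr1", 1, 100, 1e-30),
                 hit_row("q", "chr2", 300, 400, 1e-28),
                 hit_row("q", "chr3", 20, 80, 1e-29))
  expect_false(assign_orthology(third)$accepted)
})

test_that("assignment equals the brute-force rule on random hit sets", {
  set.seed(99)
  for (i in 1:200) {
    h <- random_hit_set()
    got <- assign_orthology(h)
    want <- brute_orthology(h)
    expect_equal(got$accepted, want$accepted)
    if (want$accepted)
      expect_equal(got$subject_chromosome, want$chr)
  }
})

test_that("Oxford grids count, highlight, and classify relationships", {
  mg <- stats::setNames(rep(paste0("LG", 1:24), each = 8),
                        paste0("mk", 1:192))
  rel <- stats::setNames(paste0("chr", sample(1:24)), paste0("LG", 1:24))
  gen <- generate_blast_hits(mg, rel, reject_fraction = 0,
                             benign_fraction = 0, seed = 4)
  asg <- assign_orthology_all(gen$hits)
  grid <- build_oxford_grid(asg, mg)
  expect_equal(sum(grid$counts), sum(asg$accepted))
  expect_equal(sum(grid$counts), 192L)
  # permutation relation: exactly one nonzero cell per row/column
  expect_true(all(rowSums(grid$counts > 0) == 1))
  expect_true(all(colSums(grid$counts > 0) == 1))
  for (lg in names(rel))
    expect_equal(unname(grid$counts[lg, rel[lg]]), 8L)
  rels <- grid_relationships(grid)
  expect_equal(nrow(rels$one_to_one), 24L)
  expect_length(rels$rows_one_to_two, 0L)

  # highlight thresholds are strict "more than"
  cnt <- matrix(c(11L, 8L, 6L, 5L), 2, 2,
                dimnames = list(c("LG1", "LG2"), c("c1", "c2")))
  h <- seriomap:::.grid_highlight(cnt)
  expect_equal(unname(c(h)), c("red", "yellow", "blue", "none"))

  zero <- build_oxford_grid(asg[0, ], mg)
  expect_equal(sum(zero$counts), 0L)
  expect_equal(nrow(grid_relationships(zero)$one_to_one), 0L)
})

test_that("a planted chromosome fusion is reported as one-to-two", {
  mg <- stats::setNames(rep(paste0("LG", 1:3), each = 10),
                        paste0("mk", 1:30))
  # chr1 split across LG1 and LG2 (fusion/breakage signal), chr3 clean
  asg <- data.frame(query_id = names(mg),
                    subject_chromosome = c(rep("chr1", 20),
                                           rep("chr3", 10)),
                    accepted = TRUE, reject_reason = "none",
                    e_value = 1e-20)
  grid <- build_oxford_grid(asg, mg)
  rels <- grid_relationships(grid)
  expect_equal(rels$cols_one_to_two, "chr1")
  expect_true("chr3" %in% rels$one_to_one$chromosome)
})

test_that("markers missing from the map are skipped with a warning", {
  mg <- c(mk1 = "LG1")
  asg <- data.frame(query_id = c("mk1", "mk_unknown"),
                    subject_chromosome = "chr1", accepted = TRUE,
                    reject_reason = "none", e_value = 1e-9)
  expect_warning(grid <- build_oxford_grid(asg, mg), "not on the map")
  expect_equal(sum(grid$counts), 1L)
})
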