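bc <- function(id, codes, parent = "dam") {
  structure(list(marker_id = id, parent = parent, alleles = c("a", "b"),
                 codes = codes), class = "backcross_vector")
}

test_that("two-point statistics hit their closed-form landmarks", {
  v <- bc("m1", rep(c("A", "H"), 45))
  tp <- two_point(v, bc("m2", v$codes))
  expect_equal(tp$theta_hat, 0)
  expect_equal(tp$lod, 90 * log10(2), tolerance = 1e-10)   # ~27.093

  flip <- v$codes
  flip[1:45] <- ifelse(flip[1:45] == "A", "H", "A")
  tp <- two_point(v, bc("m3", flip))
  expect_equal(tp$theta_hat, 0.5)
  expect_equal(tp$lod, 0, tolerance = 1e-10)

  flip9 <- v$codes
  flip9[1:9] <- ifelse(flip9[1:9] == "A", "H", "A")
  tp <- two_point(v, bc("m4", flip9))
  expect_equal(tp$theta_hat, 0.1)
  # 9 log10(.1) + 81 log10(.9) + 90 log10(2), evaluated independently
  expect_equal(tp$lod, 14.38634, tolerance = 1e-5)
})

test_that("two-point is symmetric, folds phase, and handles missing", {
  set.seed(1)
  a <- bc("a", sample(c("A", "H", NA), 60, replace = TRUE,
                      prob = c(.45, .45, .1)))
  b <- bc("b", sample(c("A", "H", NA), 60, replace = TRUE,
                      prob = c(.45, .45, .1)))
  expect_equal(two_point(a, b)$lod, two_point(b, a)$lod)
  expect_equal(two_point(a, b)$theta_hat, two_point(b, a)$theta_hat)
  # swapping one marker's labels (phase flip) changes nothing
  b2 <- bc("b", ifelse(b$codes == "A", "H", "A"))
  expect_equal(two_point(a, b2)$theta_hat, two_point(a, b)$theta_hat)
  expect_lte(two_point(a, b)$n_recombinant, two_point(a, b)$n_informative)
  expect_error(two_point(bc("x", c("A", NA)), bc("y", c(NA, "H"))),
               "jointly informative")
})

test_that("the LOD is maximized at theta-hat (grid-scan oracle)", {
  lod_at <- function(theta, r, n)
    r * log10(theta) + (n - r) * log10(1 - theta) + n * log10(2)
  grid <- seq(0.005, 0.495, by = 0.005)
  for (case in list(c(5, 80), c(20, 90), c(1, 30), c(40, 90))) {
    r <- case[1L]; n <- case[2L]
    codes <- rep("A", n)
    flip <- codes
    flip[seq_len(r)] <- "H"
    tp <- two_point(bc("a", codes), bc("b", flip))
    scan <- vapply(grid, lod_at, numeric(1L), r = r, n = n)
    expect_lt(abs(grid[which.max(scan)] - tp$theta_hat), 0.0051)
    expect_gte(tp$lod + 1e-9, max(scan))
  }
})

test_that("Kosambi transform matches its closed form and inverts", {
  expect_equal(kosambi_cm(0), 0)
  expect_equal(kosambi_cm(0.1), 25 * log(1.5))    # ~10.137 cM
  expect_equal(kosambi_cm(0.1), 10.13663, tolerance = 1e-5)
  thetas <- seq(0.01, 0.45, by = 0.02)
  expect_equal(kosambi_theta(kosambi_cm(thetas)), thetas)
  expect_error(kosambi_cm(0.5), "theta")
  expect_error(kosambi_theta(-1), "non-negative")
})

test_that("grouping is single linkage over the LOD graph", {
  pairs <- data.frame(marker_a = c("A", "B", "A"),
                      marker_b = c("B", "C", "C"),
                      lod = c(5, 5, 1))
  gr <- group_at_lod(pairs, threshold = 4)
  expect_length(gr, 1L)
  expect_setequal(gr[[1L]], c("A", "B", "C"))

  pairs$lod <- c(0, 0, 0)
  gr <- group_at_lod(pairs, threshold = 4)
  expect_length(gr, 3L)
  expect_true(all(lengths(gr) == 1L))
})

test_that("raising the LOD threshold only refines the partition", {
  set.seed(7)
  ids <- paste0("m", 1:15)
  lodm <- matrix(0, 15, 15, dimnames = list(ids, ids))
  lodm[upper.tri(lodm)] <- runif(sum(upper.tri(lodm)), 0, 8)
  lodm <- pmax(lodm, t(lodm))
  memb_of <- function(groups) {
    m <- rep(names(groups), lengths(groups))
    names(m) <- unlist(groups)
    m
  }
  for (th in c(2, 4, 6)) {
    lo <- memb_of(group_at_lod(lodm, threshold = th))
    hi <- memb_of(group_at_lod(lodm, threshold = th + 1.5))
    expect_setequal(names(lo), ids)   # partition covers all markers
    for (pair in combn(ids, 2L, simplify = FALSE)) {
      # together at the high threshold implies together at the low one
      if (hi[pair[1L]] == hi[pair[2L]])
        expect_equal(unname(lo[pair[1L]]), unname(lo[pair[2L]]))
    }
  }
})

test_that("a two-marker group has the single order and Kosambi length", {
  sim <- simulate_cross(n_chromosomes = 1, markers_per_chromosome = 2,
                        n_progeny = 80, missing_rate = 0, error_rate = 0,
                        seed = 3)
  M <- seriomap:::.as_code_matrix(
    lapply(sim$genotypes, to_backcross, parent = "dam"))
  og <- order_group(rownames(M), M)
  expect_length(og$markers, 2L)
  tp <- two_point(to_backcross(sim$genotypes[[1L]], "dam"),
                  to_backcross(sim$genotypes[[2L]], "dam"))
  expect_equal(max(og$positions_cM), kosambi_cm(tp$theta_hat))
})

test_that("heuristic ordering attains the exhaustive minimum (6 markers)", {
  for (seed in 1:8) {
    sim <- simulate_cross(n_chromosomes = 1, markers_per_chromosome = 6,
                          chr_lengths_cM = 50, n_progeny = 35,
                          missing_rate = 0.05, seed = seed)
    M <- seriomap:::.as_code_matrix(
      lapply(sim$genotypes, to_backcross, parent = "dam"))
    ex <- order_group(rownames(M), M, method = "exhaustive")
    he <- order_group(rownames(M), M, method = "heuristic")
    expect_equal(he$objective, ex$objective)
    expect_equal(ex$objective, brute_min_path_cost(M))
  }
})

test_that("ordered groups start at zero with non-decreasing positions", {
  sim <- simulate_cross(n_chromosomes = 1, markers_per_chromosome = 12,
                        n_progeny = 60, seed = 9)
  M <- seriomap:::.as_code_matrix(
    lapply(sim$genotypes, to_backcross, parent = "dam"))
  og <- order_group(rownames(M), M)
  expect_equal(og$positions_cM[1L], 0)
  expect_true(all(diff(og$positions_cM) >= 0))
  expect_equal(length(og$positions_cM), length(og$markers))
  # orientation rule: lexicographically smaller terminal first
  expect_true(og$markers[1L] < og$markers[length(og$markers)])
  # framework markers are the distinct map positions
  expect_equal(sum(og$framework),
               length(unique(round(og$positions_cM, 10))))
})

test_that("double-recombinant counting matches manual enumeration", {
  M <- rbind(m1 = c(0, 0, 1, 0),
             m2 = c(0, 1, 1, 0),   # progeny 2: middle flip between m1/m3
             m3 = c(0, 0, 1, 0))
  # progeny 2 has codes 0,1,0 -> one event; others none
  expect_equal(count_double_recombinants(c("m1", "m2", "m3"), M), 1L)
  expect_equal(count_double_recombinants(c("m3", "m2", "m1"), M), 1L)
  expect_equal(count_double_recombinants(c("m1", "m2"), M), 0L)
  # missing middle call: flanking pair skips to the next informative call
  M2 <- rbind(m1 = c(0, 0), m2 = c(NA, 1), m3 = c(0, 0), m4 = c(0, 0))
  expect_equal(count_double_recombinants(c("m1", "m2", "m3", "m4"), M2), 1L)
})

test_that("tightly linked clean data shows (near) zero double recombinants", {
  sim <- simulate_cross(n_chromosomes = 1, markers_per_chromosome = 15,
                        chr_lengths_cM = 40, n_progeny = 90,
                        missing_rate = 0, error_rate = 0, seed = 21)
  tr <- sim$truth$positions
  ord <- tr$marker[order(tr$pos_cM)]
  M <- seriomap:::.as_code_matrix(
    lapply(sim$genotypes, to_backcross, parent = "dam"))
  n_dbl <- count_double_recombinants(ord, M)
  # ~2.9 cM spacing: expected count ~ n_triples * theta^2 ~ 1
  expect_lte(n_dbl, 4L)
})
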