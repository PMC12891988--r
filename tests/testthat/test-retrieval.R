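# Hamming/XOR machinery, archive search, majority vote, macro metrics,
# leave-one-out evaluation and group dissimilarity.

test_that("hex codes round-trip with the documented bit convention", {
  # bit at matrix cell (1,1) is the MSB of the first hex character
  expect_identical(bits_to_hex(c(1L, rep(0L, 63L))), "8000000000000000")
  expect_identical(bits_to_hex(rep(1L, 64L)), "ffffffffffffffff")
  m <- matrix(0L, 8, 8); m[2, 1] <- 1L  # position 8*(2-1)+0 = bit 8
  expect_identical(bits_to_hex(m), "0080000000000000")

  set.seed(1)
  B <- matrix(sample(0:1, 64 * 50, replace = TRUE), 50, 64)
  expect_identical(hex_to_bits(bits_to_hex(B)), B)
  expect_error(hex_to_bits("zzzz"), "hexadecimal")
  expect_error(bits_to_hex(c(1L, 0L)), "64 bits")
})

test_that("hamming distance matches a per-bit loop and is a metric", {
  a <- rep(0L, 64L)
  expect_equal(hamming(a, a), 0L)
  expect_equal(hamming(a, 1L - a), 64L)

  set.seed(2)
  for (i in 1:1000) {
    x <- sample(0:1, 64, replace = TRUE)
    y <- sample(0:1, 64, replace = TRUE)
    cnt <- 0L
    for (b in 1:64) if (x[b] != y[b]) cnt <- cnt + 1L
    expect_identical(hamming(x, y), cnt)
  }

  # symmetry + triangle inequality on random triples
  for (i in 1:50) {
    x <- sample(0:1, 64, TRUE); y <- sample(0:1, 64, TRUE)
    z <- sample(0:1, 64, TRUE)
    expect_identical(hamming(x, y), hamming(y, x))
    expect_lte(hamming(x, z), hamming(x, y) + hamming(y, z))
  }
  expect_error(hamming(x[1:10], y), "64 bits")
})

test_that("xor maps are signed differences consistent with hamming", {
  m <- matrix(sample(0:1, 64, TRUE), 8, 8)
  expect_equal(xor_map(m, m), matrix(0L, 8, 8))
  expect_equal(xor_map(matrix(0L, 8, 8), matrix(1L, 8, 8)),
               matrix(1L, 8, 8))
  set.seed(3)
  for (i in 1:20) {
    a <- matrix(sample(0:1, 64, TRUE), 8, 8)
    b <- matrix(sample(0:1, 64, TRUE), 8, 8)
    xm <- xor_map(a, b)
    expect_true(all(xm %in% c(-1L, 0L, 1L)))
    expect_equal(sum(xm != 0), hamming(a, b))
    expect_equal(sum(xm == 1L), sum(a == 0L & b == 1L))
  }
})

test_that("archive search ranks by distance with id tie-breaks", {
  arch <- random_archive(n = 20L)
  # exact match ranks first at distance 0
  res <- search_archive(arch, arch$bits[7, ], k = 3)
  expect_equal(res$patient_id[1], arch$patient_id[7])
  expect_equal(res$distance[1], 0L)

  # exhaustive-sort oracle
  q <- sample(0:1, 64, TRUE)
  res_all <- search_archive(arch, q, k = 20)
  d <- apply(arch$bits, 1, function(b) sum(b != q))
  oracle <- order(d, arch$patient_id)
  expect_equal(res_all$patient_id, arch$patient_id[oracle])
  expect_equal(res_all$distance, as.integer(d[oracle]))

  # equidistant records are ordered by ascending patient id
  bits <- rbind(rep(0L, 64L), rep(0L, 64L))
  a2 <- monogram_archive(c("p_b", "p_a"), c("X", "Y"), bits)
  r2 <- search_archive(a2, rep(0L, 64L), k = 2)
  expect_equal(r2$patient_id, c("p_a", "p_b"))

  # leave-one-out exclusion and k overflow
  r3 <- search_archive(arch, arch$bits[7, ], k = 5,
                       exclude_id = arch$patient_id[7])
  expect_false(arch$patient_id[7] %in% r3$patient_id)
  expect_warning(r4 <- search_archive(arch, q, k = 50), "exceeds")
  expect_equal(nrow(r4), 20L)
})

test_that("majority vote counts labels with rank-based tie-breaks", {
  expect_equal(majority_vote(c("A", "A", "B")), "A")
  expect_equal(majority_vote(c("A", "B")), "A")        # tie -> rank 1
  expect_equal(majority_vote(c("B", "A", "A", "B")), "B") # tie -> earliest
  expect_error(majority_vote(character(0)), "empty")

  set.seed(4)
  for (i in 1:100) {
    labs <- sample(c("A", "B", "C"), 5, replace = TRUE)
    counts <- table(labs)
    top <- names(counts)[counts == max(counts)]
    firsts <- vapply(top, function(l) which(labs == l)[1], integer(1))
    expect_equal(majority_vote(labs), top[which.min(firsts)])
  }
})

test_that("macro metrics match the confusion-matrix formulas", {
  y <- c("A", "A", "B", "B", "C")
  expect_equal(unname(macro_metrics(y, y)), rep(1, 4))
  expect_equal(unname(macro_metrics(c("A", "B"), c("B", "A"))), rep(0, 4))

  # counts: AA 3, AB 1, BB 2, BC 1, CC 2 (true -> predicted)
  y_true <- c(rep("A", 4), rep("B", 3), rep("C", 2))
  y_pred <- c("A", "A", "A", "B", "B", "B", "C", "C", "C")
  # per-class (hand computed): A: P=1, R=3/4; B: P=2/3, R=2/3; C: P=2/3, R=1
  m <- macro_metrics(y_true, y_pred)
  expect_equal(unname(m["macro_precision"]), (1 + 2 / 3 + 2 / 3) / 3)
  expect_equal(unname(m["macro_recall"]), (3 / 4 + 2 / 3 + 1) / 3)
  f1A <- 2 * 1 * (3 / 4) / (1 + 3 / 4)
  f1B <- 2 / 3
  f1C <- 2 * (2 / 3) * 1 / (2 / 3 + 1)
  expect_equal(unname(m["macro_f1"]), mean(c(f1A, f1B, f1C)))
  expect_equal(unname(m["accuracy"]), 7 / 9)

  # a class never predicted has precision 0
  m2 <- macro_metrics(c("A", "B"), c("A", "A"))
  expect_equal(unname(m2["macro_precision"]), 0.5 * (0.5 + 0))
  expect_error(macro_metrics(character(0), character(0)), "empty")
})

test_that("leave-one-out evaluation is exact on separable archives", {
  bits_a <- matrix(rep(c(0L, 1L), c(32, 32)), 3, 64, byrow = TRUE)
  bits_b <- matrix(rep(c(1L, 0L), c(32, 32)), 3, 64, byrow = TRUE)
  arch <- monogram_archive(sprintf("p%d", 1:6), rep(c("A", "B"), each = 3),
                           rbind(bits_a, bits_b))
  ev <- leave_one_out_eval(arch, ks = c(1, 3))
  expect_true(all(ev$metrics$accuracy == 1))
  expect_true(all(ev$metrics$macro_f1 == 1))

  # all-identical codes collapse to the id tie-break
  same <- monogram_archive(sprintf("p%d", 1:4), c("A", "A", "B", "B"),
                           matrix(0L, 4, 64))
  ev2 <- leave_one_out_eval(same, ks = 1)
  # each query's nearest neighbor is the lowest remaining id: p1 for
  # queries p2..p4, p2 for query p1
  expect_equal(unname(ev2$predictions[, 1]), c("A", "A", "A", "A"))
  expect_equal(unname(ev2$metrics$accuracy), 0.5)

  expect_error(leave_one_out_eval(
    monogram_archive(c("a", "b"), c("A", "A"), matrix(0L, 2, 64))
  ), "2 classes")
})

test_that("evaluation composes search + vote and ignores record order", {
  arch <- random_archive(n = 15L, n_classes = 3L, seed = 9L)
  ev <- leave_one_out_eval(arch, ks = c(1, 3, 5))
  for (q in c(1L, 8L)) {
    for (j in 1:3) {
      k <- c(1L, 3L, 5L)[j]
      nb <- search_archive(arch, arch$bits[q, ], k = k,
                           exclude_id = arch$patient_id[q])
      expect_false(arch$patient_id[q] %in% nb$patient_id)
      expect_equal(unname(ev$predictions[q, j]), majority_vote(nb$label))
    }
  }
  perm <- sample(archive_size(arch))
  arch_p <- monogram_archive(arch$patient_id[perm], arch$label[perm],
                             arch$bits[perm, ])
  ev_p <- leave_one_out_eval(arch_p, ks = c(1, 3, 5))
  expect_equal(ev_p$metrics, ev$metrics)
})

test_that("archive CSV round trip is bit-exact", {
  arch <- random_archive(n = 12L, n_classes = 3L, seed = 13L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_archive(arch, path)
  arch2 <- read_archive(path)
  expect_identical(arch2$bits, arch$bits)
  expect_identical(arch2$patient_id, arch$patient_id)
  expect_identical(arch2$label, arch$label)
})

test_that("group dissimilarity averages normalized hamming distances", {
  ids <- sprintf("p%d", 1:8)
  bits0 <- matrix(0L, 4, 64)
  bits1 <- matrix(1L, 4, 64)
  arch <- monogram_archive(ids, rep(c("A", "B"), each = 4),
                           rbind(bits0, bits1))
  H <- dissimilarity_heatmap(arch, n_per_group = 4)
  expect_equal(H["A", "A"], 0)
  expect_equal(H["B", "B"], 0)
  expect_equal(H["A", "B"], 1)

  arch3 <- random_archive(n = 12L, n_classes = 3L, seed = 21L)
  # n_per_group covers every member, so the sample is the full group and
  # the result must match an exhaustive double-loop mean
  H3 <- suppressWarnings(dissimilarity_heatmap(arch3, n_per_group = 12,
                                               seed = 2))
  expect_equal(H3, t(H3))
  groups <- sort(unique(arch3$label))
  for (a in seq_along(groups)) for (b in seq_along(groups)) {
    ia <- which(arch3$label == groups[a])
    ib <- which(arch3$label == groups[b])
    tot <- 0; cnt <- 0
    for (i in ia) for (j in ib) {
      if (a == b && i >= j) next
      tot <- tot + sum(arch3$bits[i, ] != arch3$bits[j, ]) / 64
      cnt <- cnt + 1
    }
    expect_equal(H3[a, b], tot / cnt, tolerance = 1e-12)
  }
  w <- capture_warnings(dissimilarity_heatmap(arch3, n_per_group = 100))
  expect_true(all(grepl("using all", w)) && length(w) >= 1L)
})
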