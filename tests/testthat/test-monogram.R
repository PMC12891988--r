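# Outer-product fusion, triplet loss and mining, fusion-network training
# and binarization.

test_that("outer fusion matches the double-loop product", {
  e2 <- replace(numeric(8), 3, 1)
  e5 <- replace(numeric(8), 6, 1)
  M <- outer_fuse(e2, e5)
  expect_equal(M[3, 6], 1)
  expect_equal(sum(M != 0), 1L)

  expect_equal(outer_fuse(numeric(4), rnorm(4)), matrix(0, 4, 4))

  set.seed(2)
  u <- rnorm(4); v <- rnorm(4)
  M2 <- outer_fuse(u, v)
  for (i in 1:4) for (j in 1:4) expect_identical(M2[i, j], u[i] * v[j])

  expect_error(outer_fuse(rnorm(3), rnorm(4)), "lengths differ")
})

test_that("fuse_rows flattens outer products row-major", {
  set.seed(3)
  U <- matrix(rnorm(12), 3, 4)
  V <- matrix(rnorm(12), 3, 4)
  X <- fuse_rows(U, V)
  for (r in 1:3) {
    expect_equal(X[r, ], as.vector(t(outer_fuse(U[r, ], V[r, ]))),
                 tolerance = 1e-15)
  }
})

test_that("triplet loss equals its closed form", {
  # hinge inactive: d(a,p) = 0.5, d(a,n) = 2, margin 1 -> 0
  a <- numeric(64)
  p <- replace(numeric(64), 1, 0.5)
  n <- replace(numeric(64), 1, 2)
  expect_equal(triplet_loss(a, p, n, margin = 1), 0)
  # p == n -> exactly the margin
  expect_equal(triplet_loss(a, p, p, margin = 1), 1)
  expect_equal(triplet_loss(a, p, p, margin = 0.3), 0.3)

  set.seed(4)
  for (i in 1:20) {
    ma <- matrix(tanh(rnorm(64)), 8, 8)
    mp <- matrix(tanh(rnorm(64)), 8, 8)
    mn <- matrix(tanh(rnorm(64)), 8, 8)
    al <- runif(1, 0.1, 2)
    d_ap <- sqrt(sum((ma - mp)^2))
    d_an <- sqrt(sum((ma - mn)^2))
    expect_equal(triplet_loss(ma, mp, mn, al), max(d_ap - d_an + al, 0),
                 tolerance = 1e-12)
  }
  expect_error(triplet_loss(a, p[1:10], n), "shapes")
})

test_that("hard mining matches exhaustive search", {
  for (seed in 1:4) {
    set.seed(seed)
    n <- sample(10:50, 1)
    l <- 5L
    U <- matrix(rnorm(n * l), n, l)
    V <- matrix(rnorm(n * l), n, l)
    labels <- sample(c("A", "B", "C"), n, replace = TRUE)
    while (min(table(labels)) < 2) labels <- sample(c("A", "B", "C"), n,
                                                    replace = TRUE)
    trip <- mine_triplets(U, V, labels, mode = "hard")
    feat <- cbind(U, V)
    expect_equal(nrow(trip), n)
    for (r in seq_len(nrow(trip))) {
      a <- trip$anchor[r]
      d <- sqrt(colSums((t(feat) - feat[a, ])^2))
      pos <- which(labels == labels[a]); pos <- pos[pos != a]
      neg <- which(labels != labels[a])
      expect_equal(trip$positive[r], pos[which.max(d[pos])])
      expect_equal(trip$negative[r], neg[which.min(d[neg])])
      expect_true(labels[trip$positive[r]] == labels[a])
      expect_true(labels[trip$negative[r]] != labels[a])
    }
  }
})

test_that("mining handles degenerate and random cases", {
  # identical same-class points: zero positive distance is fine
  U <- rbind(matrix(1, 3, 4), matrix(5, 2, 4))
  V <- U
  labels <- c("A", "A", "A", "B", "B")
  trip <- mine_triplets(U, V, labels, mode = "hard")
  expect_equal(nrow(trip), 5L)
  expect_true(all(labels[trip$positive] == labels[trip$anchor]))

  # singleton class anchors are skipped with a warning
  expect_warning(
    trip2 <- mine_triplets(U[1:4, ], V[1:4, ], c("A", "A", "A", "B")),
    "singleton"
  )
  expect_equal(nrow(trip2), 3L)

  # random mode is seeded
  set.seed(10)
  U3 <- matrix(rnorm(40), 10, 4); V3 <- matrix(rnorm(40), 10, 4)
  lab3 <- rep(c("A", "B"), 5)
  t1 <- mine_triplets(U3, V3, lab3, mode = "random", seed = 77)
  t2 <- mine_triplets(U3, V3, lab3, mode = "random", seed = 77)
  expect_identical(t1, t2)

  expect_error(mine_triplets(U3, V3, rep("A", 10)), "2 classes")
})

test_that("forward monograms are tanh-bounded, deterministic, batchable", {
  lat <- tiny_latents()
  model <- train_monogram_model(lat$U, lat$V, lat$labels,
                                tiny_mono_spec(seed = 5L))
  m <- forward_monogram(model, lat$U[1, ], lat$V[1, ])
  expect_equal(dim(m), c(8L, 8L))
  expect_true(all(abs(m) <= 1))

  expect_identical(forward_monogram(model, lat$U[1, ], lat$V[1, ]), m)

  out <- forward_monograms(model, lat$U, lat$V)
  expect_equal(matrix(out[1, ], 8, 8, byrow = TRUE), m, tolerance = 1e-12)
  for (r in c(2L, 7L)) {
    single <- forward_monogram(model, lat$U[r, ], lat$V[r, ])
    expect_equal(matrix(out[r, ], 8, 8, byrow = TRUE), single,
                 tolerance = 1e-12)
  }
  expect_error(forward_monograms(model, lat$U[, 1:4], lat$V), "latent width")
})

test_that("triplet training reduces loss, separates classes, reruns bitwise", {
  lat <- tiny_latents(n_per_class = 15L)
  spec <- tiny_mono_spec(seed = 21L)
  train <- c(1:10, 16:25, 31:40)
  held <- setdiff(seq_along(lat$labels), train)
  m1 <- train_monogram_model(lat$U[train, ], lat$V[train, ],
                             lat$labels[train], spec)
  m2 <- train_monogram_model(lat$U[train, ], lat$V[train, ],
                             lat$labels[train], spec)
  expect_identical(m1$net, m2$net)
  expect_identical(m1$loss_curve, m2$loss_curve)
  expect_lt(m1$loss_curve[length(m1$loss_curve)], m1$loss_curve[1])

  # held-out real monograms: intra-class closer than inter-class
  out <- forward_monograms(m1, lat$U[held, ], lat$V[held, ])
  D <- as.matrix(dist(out))
  same <- outer(lat$labels[held], lat$labels[held], "==")
  ut <- upper.tri(D)
  expect_lt(mean(D[ut & same]), mean(D[ut & !same]))
})

test_that("binarization follows the strict sign rule", {
  expect_identical(as.vector(binarize(c(-0.3, 0.7))), c(0L, 1L))
  expect_identical(as.vector(binarize(0)), 0L)      # boundary -> 0
  expect_identical(as.vector(binarize(c(0.6, 0.4), threshold = 0.5)),
                   c(1L, 0L))
  set.seed(6)
  m <- matrix(tanh(rnorm(64)), 8, 8)
  b <- binarize(m)
  for (i in 1:8) for (j in 1:8) {
    expect_identical(b[i, j], if (m[i, j] > 0) 1L else 0L)
  }
})

test_that("archive encoding composes forward + binarize per patient", {
  lat <- tiny_latents()
  model <- train_monogram_model(lat$U, lat$V, lat$labels,
                                tiny_mono_spec(seed = 8L))
  arch <- encode_monograms(model, lat$ids, lat$labels, lat$U, lat$V)
  expect_equal(archive_size(arch), length(lat$ids))
  arch2 <- encode_monograms(model, lat$ids, lat$labels, lat$U, lat$V)
  expect_identical(arch2$bits, arch$bits)
  for (r in c(1L, 9L)) {
    manual <- binarize(forward_monogram(model, lat$U[r, ], lat$V[r, ]),
                       model$spec$threshold)
    expect_identical(matrix(arch$bits[r, ], 8, 8, byrow = TRUE), manual)
  }
  # tanh keeps values in [-1, 1]; saturated units can hit the bound in
  # floating point
  expect_true(all(abs(arch$real) <= 1))
})
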