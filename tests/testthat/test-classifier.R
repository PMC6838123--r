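test_that("balancing yields exactly n samples per class, 5n total", {
  set.seed(1)
  sizes <- c(A1 = 100, A2 = 50, B1 = 30, B2 = 20, B3 = 10)
  lat <- matrix(rnorm(sum(sizes) * 6), sum(sizes), 6)
  lab <- rep(names(sizes), sizes)
  b <- balance_training_set(lat, lab, n = 120, seed = 2)
  expect_equal(nrow(b$x), 600)
  expect_equal(as.vector(table(b$labels)), rep(120, 5))
})

test_that("interpolants lie on the segment between their generating pair", {
  set.seed(3)
  lat <- matrix(rnorm(10 * 4), 10, 4)
  lab <- rep(c("A1", "A2", "B1", "B2", "B3"), each = 2)
  b <- balance_training_set(lat, lab, n = 6, seed = 4)
  # brute-force check row by row against the recorded provenance
  kept <- lat   # no NA labels, so original row indices are preserved
  for (k in seq_len(nrow(b$x))) {
    x <- kept[b$provenance$i[k], ]
    y <- kept[b$provenance$j[k], ]
    r <- b$x[k, ]
    expect_true(all(r >= pmin(x, y) - 1e-12 & r <= pmax(x, y) + 1e-12))
    expect_equal(r, x + (y - x) * b$provenance$u[k])
  }
})

test_that("interpolating between 0- and 1-vectors gives a constant vector", {
  lat <- rbind(rep(0, 5), rep(1, 5))
  b <- balance_training_set(rbind(lat, lat, lat, lat, lat),
                            rep(subcompartments(), each = 2),
                            n = 3, seed = 5)
  for (k in seq_len(nrow(b$x))) {
    expect_true(all(b$x[k, ] >= 0 & b$x[k, ] <= 1))
    expect_lt(diff(range(b$x[k, ])), 1e-12)
  }
})

test_that("balancing rejects degenerate inputs", {
  lat <- matrix(rnorm(9 * 3), 9, 3)
  lab <- c("A1", "A1", "A2", "A2", "B1", "B1", "B2", "B2", "B3")
  expect_error(balance_training_set(lat, lab, n = 10), ">= 2 members")
  lat2 <- matrix(rnorm(11 * 3), 11, 3)
  lab2 <- rep(c("A1", "A2", "B1", "B2", "B3"), c(3, 2, 2, 2, 2))
  expect_error(balance_training_set(lat2, lab2, n = 3), "exceed")
})

test_that("balancing keeps the label marginal exactly uniform", {
  set.seed(6)
  for (rep in 1:3) {
    sizes <- sample(2:30, 5)
    lat <- matrix(rnorm(sum(sizes) * 3), sum(sizes), 3)
    b <- balance_training_set(lat, rep(subcompartments(), sizes),
                              n = max(sizes) + sample(1:20, 1), seed = rep)
    expect_true(all(table(b$labels) == b$n))
  }
})

test_that("softmax probabilities are normalised and match direct formula", {
  ns <- asNamespace("hicsubcomp")
  set.seed(7)
  clf <- train_classifier(list(x = matrix(rnorm(100), 20, 5),
                               labels = rep(subcompartments(), 4)),
                          hidden = c(8, 4), epochs = 2, seed = 8)
  p <- predict(clf, matrix(rnorm(50, sd = 3), 10, 5), type = "prob")
  expect_equal(rowSums(p), rep(1, 10), tolerance = 1e-6)
  expect_true(all(p >= 0))
  z <- matrix(rnorm(40, sd = 4), 8, 5)
  sm <- ns$nn_activate(z, "softmax")
  brute <- t(apply(z, 1, function(r) exp(r) / sum(exp(r))))
  expect_equal(sm, brute, tolerance = 1e-12)
})

test_that("zero-weight classifier returns the uniform distribution", {
  clf <- train_classifier(list(x = matrix(rnorm(100), 20, 5),
                               labels = rep(subcompartments(), 4)),
                          hidden = c(8, 4), epochs = 1, seed = 9)
  clf$net$W <- lapply(clf$net$W, function(w) w * 0)
  clf$net$b <- lapply(clf$net$b, function(b) b * 0)
  p <- predict(clf, matrix(rnorm(25), 5, 5), type = "prob")
  expect_equal(p, matrix(0.2, 5, 5, dimnames = list(NULL, subcompartments())))
})

test_that("class prediction is the argmax with A1-first tie-break", {
  clf <- train_classifier(list(x = matrix(rnorm(100), 20, 5),
                               labels = rep(subcompartments(), 4)),
                          hidden = c(8, 4), epochs = 1, seed = 10)
  x <- matrix(rnorm(60), 12, 5)
  p <- predict(clf, x, type = "prob")
  cl <- predict(clf, x, type = "class")
  expect_equal(as.integer(cl), apply(p, 1, which.max))
  # exact tie: zeroed network gives all-0.2 rows -> A1 by convention
  clf$net$W <- lapply(clf$net$W, function(w) w * 0)
  clf$net$b <- lapply(clf$net$b, function(b) b * 0)
  expect_true(all(predict(clf, x, type = "class") == "A1"))
})

test_that("training rejects labels outside the five classes", {
  expect_error(balance_training_set(matrix(rnorm(20), 10, 2),
                                    rep(c("A1", "B4"), 5)),
               "unknown subcompartment")
})

test_that("a separable two-class toy problem is learned quickly", {
  set.seed(11)
  lat <- rbind(matrix(rnorm(300, 1.5, 0.3), 75, 4),
               matrix(rnorm(300, -1.5, 0.3), 75, 4))
  lab <- rep(c("A1", "B3"), each = 75)
  other <- matrix(rnorm(6 * 4, 0, 0.1), 6, 4) +
    rep(c(8, -8, 4), each = 2)   # fillers so all 5 classes exist
  b <- balance_training_set(rbind(lat, other),
                            c(lab, rep(c("A2", "B1", "B2"), each = 2)),
                            n = 100, seed = 12)
  clf <- train_classifier(b, epochs = 50, seed = 13)
  acc <- mean(predict(clf, lat) == lab)
  expect_gte(acc, 0.98)
})

test_that("classifier training is deterministic under a seed", {
  set.seed(14)
  b <- balance_training_set(matrix(rnorm(200), 40, 5),
                            rep(subcompartments(), 8), seed = 15)
  a <- train_classifier(b, hidden = c(8, 4), epochs = 3, seed = 16)
  c2 <- train_classifier(b, hidden = c(8, 4), epochs = 3, seed = 16)
  expect_identical(a$net$W, c2$net$W)
  expect_identical(a$history, c2$history)
})

test_that("both documented hidden-layer variants train successfully", {
  set.seed(17)
  b <- balance_training_set(matrix(rnorm(300), 60, 5),
                            rep(subcompartments(), 12), seed = 18)
  for (h in list(c(64, 16), c(64, 32))) {
    clf <- train_classifier(b, hidden = h, epochs = 3, seed = 19)
    expect_equal(clf$sizes, c(5, h, 5))
    expect_true(all(is.finite(clf$history)))
  }
})
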