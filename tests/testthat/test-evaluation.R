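mk_track <- function(labels, chrom = "chr1") {
  n <- length(labels)
  subcomp_track(data.frame(chrom = chrom, start = (seq_len(n) - 1) * 1e5,
                           end = seq_len(n) * 1e5), labels)
}

test_that("confusion matrix and accuracies match a brute-force tally", {
  set.seed(30)
  for (rep in 1:20) {
    n <- sample(20:100, 1)
    ref <- sample(subcompartments(), n, TRUE)
    pred <- ifelse(runif(n) < 0.7, ref, sample(subcompartments(), n, TRUE))
    ref[sample(n, 2)] <- NA
    cm <- confusion_subcomp(mk_track(pred), mk_track(ref))
    keep <- !is.na(ref)
    brute <- matrix(0, 5, 5)
    for (i in which(keep))
      brute[match(ref[i], subcompartments()),
            match(pred[i], subcompartments())] <-
        brute[match(ref[i], subcompartments()),
              match(pred[i], subcompartments())] + 1
    expect_equal(unname(cm$matrix), brute)
    expect_equal(cm$overall, sum(diag(brute)) / sum(brute))
    rs <- rowSums(brute)
    expect_equal(unname(cm$per_class), ifelse(rs > 0, diag(brute) / rs, NaN))
  }
})

test_that("perfect agreement gives unit accuracy; toy mismatch arithmetic", {
  lab <- rep(subcompartments(), 2)
  cm <- confusion_subcomp(mk_track(lab), mk_track(lab))
  expect_equal(cm$overall, 1)
  expect_equal(unname(cm$per_class), rep(1, 5))
  pred <- lab; pred[c(1, 6)] <- c("B3", "B1")
  expect_equal(confusion_subcomp(mk_track(pred), mk_track(lab))$overall, 0.8)
  expect_error(confusion_subcomp(mk_track(c(NA, NA)), mk_track(c("A1", "A2"))),
               "non-NA")
})

test_that("AUPR handles perfect and constant scorers", {
  ref <- mk_track(rep(subcompartments(), each = 4))
  perfect <- diag(5)[as.integer(ref$label), ]
  expect_equal(unname(aupr_subcomp(perfect, ref)), rep(1, 5))
  const <- matrix(0.2, 20, 5)
  expect_equal(unname(aupr_subcomp(const, ref)), rep(0.2, 5))
  ref2 <- mk_track(rep(c("A1", "A2"), 10))
  out <- aupr_subcomp(matrix(runif(100), 20, 5), ref2)
  expect_true(all(is.na(out[c("B1", "B2", "B3")])))
})

test_that("AUPR agrees with a brute-force threshold sweep", {
  ns <- asNamespace("hicsubcomp")
  brute_aupr <- function(score, truth) {
    th <- sort(unique(score), decreasing = TRUE)
    prec <- rec <- numeric(length(th))
    for (k in seq_along(th)) {
      pos <- score >= th[k]
      prec[k] <- sum(truth & pos) / sum(pos)
      rec[k] <- sum(truth & pos) / sum(truth)
    }
    sum(diff(c(0, rec)) * prec)
  }
  set.seed(31)
  for (rep in 1:20) {
    n <- 50
    truth <- runif(n) < 0.3
    if (!any(truth)) truth[1] <- TRUE
    score <- round(runif(n), sample(c(1, 2, 6), 1))  # force ties sometimes
    expect_equal(ns$aupr_step(score, truth), brute_aupr(score, truth))
  }
})

test_that("stratified folds partition the data and reproduce under seed", {
  set.seed(32)
  lat <- matrix(rnorm(150 * 4), 150, 4)
  lab <- rep(subcompartments(), 30)
  cv <- kfold_cv(lat, lab, k = 5, hidden = c(4), epochs = 1, seed = 33)
  expect_equal(sort(unique(cv$folds)), 1:5)
  expect_equal(length(cv$folds), 150)
  for (f in 1:5)
    expect_equal(as.vector(table(lab[cv$folds == f])), rep(6, 5))
  cv2 <- kfold_cv(lat, lab, k = 5, hidden = c(4), epochs = 1, seed = 33)
  expect_identical(cv$folds, cv2$folds)
  expect_identical(cv$per_class, cv2$per_class)
  expect_warning(kfold_cv(lat[1:20, ], lab[c(1:16, 1:4)], k = 10,
                          hidden = c(4), epochs = 1, seed = 34),
                 "non-stratified")
})

test_that("cross-validated accuracy is stable on separable latents", {
  set.seed(35)
  centers <- matrix(c(3, 0, 0, 0, -3, 0, 0, 0, 3, 1.5, 1.5, -1.5,
                      -2, 2, -2), 5, 3, byrow = TRUE)
  lat <- centers[rep(1:5, each = 40), ] + matrix(rnorm(600, 0, 0.3), 200, 3)
  lab <- rep(subcompartments(), each = 40)
  cv <- kfold_cv(lat, lab, k = 5, epochs = 25, seed = 36)
  expect_true(all(cv$variance < 0.01, na.rm = TRUE))
  expect_gt(mean(cv$overall), 0.9)
})

test_that("enrichment fold change is medians over bins", {
  tr <- mk_track(c("A1", "A1", "A1", "A2", "A2", "B1", "B2", "B3", "B3",
                   "B3"))
  sig <- c(4, 4, 4, 2, 2, 2, 2, 2, 2, 2)
  fc <- enrichment_fold_change(sig, tr)
  expect_equal(unname(fc["A1"]), 2)
  expect_equal(unname(fc["B3"]), 1)
  const <- enrichment_fold_change(rep(3, 10), tr)
  expect_equal(unname(const), rep(1, 5))
  set.seed(37)
  for (rep in 1:10) {
    lab <- sample(subcompartments(), 60, TRUE)
    sig <- rnorm(60)
    fc <- enrichment_fold_change(sig, mk_track(lab))
    for (cl in unique(lab))
      expect_equal(unname(fc[cl]), median(sig[lab == cl]) / median(sig))
  }
})

test_that("boundary profiles recover a step and drop truncated windows", {
  lab <- c(rep("A2", 6), rep("B1", 6))
  sig <- c(rep(1, 6), rep(0, 6))
  bp <- boundary_profile(sig, mk_track(lab), c("A2", "B1"))
  expect_equal(attr(bp, "n_boundaries"), 1)
  expect_equal(bp$mean_signal, c(1, 1, 1, 1, 0, 0, 0, 0))
  expect_equal(bp$offset, seq(-4e5, 3e5, by = 1e5))
  # boundary too close to the chromosome start: window truncated, dropped
  lab2 <- c("A2", "A2", rep("B1", 8))
  bp2 <- boundary_profile(sig[1:10], mk_track(lab2), c("A2", "B1"))
  expect_equal(attr(bp2, "n_boundaries"), 0)
  expect_true(all(is.na(bp2$mean_signal)))
  expect_error(boundary_profile(sig, mk_track(lab), c("A2", "B1"),
                                window = 2.5e5), "multiple")
})

test_that("boundary profiles match a brute-force window average", {
  set.seed(38)
  for (rep in 1:10) {
    lab <- sample(c("A2", "B1"), 40, TRUE)
    sig <- rnorm(40)
    tr <- mk_track(lab)
    bp <- boundary_profile(sig, tr, c("A2", "B1"))
    idx <- which(lab[-40] == "A2" & lab[-1] == "B1")
    idx <- idx[idx >= 4 & idx <= 36]
    if (length(idx) == 0) {
      expect_equal(attr(bp, "n_boundaries"), 0)
    } else {
      brute <- colMeans(do.call(rbind, lapply(idx, function(i)
        sig[(i - 3):(i + 4)])))
      expect_equal(bp$mean_signal, brute)
      expect_equal(attr(bp, "n_boundaries"), length(idx))
    }
  }
})

test_that("reversed-pair profiles mirror on symmetric data", {
  lab <- c(rep("A2", 5), rep("B1", 5), rep("A2", 5))
  sig <- c(rep(1, 5), rep(0, 5), rep(1, 5))
  ab <- boundary_profile(sig, mk_track(lab), c("A2", "B1"))
  ba <- boundary_profile(sig, mk_track(lab), c("B1", "A2"))
  expect_equal(ba$mean_signal, rev(ab$mean_signal))
})
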