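# a single small fitted pipeline reused across assertions in this file
fit_small <- function(seed = 21) {
  sim <- simulate_hic(small_model(seed = seed))
  args <- small_net_args()
  model <- fit_subcompartments(sim$contacts, sim$truth, keep_rate = 0.1,
                               interior = args$interior,
                               hidden = args$hidden, seed = seed)
  list(sim = sim, model = model)
}

test_that("fitting records a complete provenance manifest", {
  f <- fit_small()
  m <- f$model$manifest
  expect_equal(m$keep_rate, 0.1)
  expect_equal(m$seed, 21)
  expect_equal(m$epochs, 25)
  expect_equal(m$batch_size, 32)
  expect_equal(m$learning_rate, 0.001)
  expect_true(all(c("chr1", "chr3") %in% m$train_chroms$odd))
  expect_true(all(c("chr2", "chr4") %in% m$train_chroms$even))
  expect_equal(m$n_odd, 80)
  expect_equal(m$n_even, 80)
})

test_that("fitting reproduces bitwise under an identical seed", {
  sim <- simulate_hic(small_model(seed = 22))
  args <- small_net_args()
  a <- fit_subcompartments(sim$contacts, sim$truth, keep_rate = 0.2,
                           interior = args$interior, hidden = args$hidden,
                           seed = 5)
  b <- fit_subcompartments(sim$contacts, sim$truth, keep_rate = 0.2,
                           interior = args$interior, hidden = args$hidden,
                           seed = 5)
  expect_identical(a$odd$autoencoder$net$W, b$odd$autoencoder$net$W)
  expect_identical(a$even$classifier$net$W, b$even$classifier$net$W)
  expect_identical(a$odd$autoencoder$history, b$odd$autoencoder$history)
  sp <- downsample_contacts(sim$contacts, 0.2, seed = 6)
  expect_identical(predict(a, sp), predict(b, sp))
})

test_that("keep_rate = 1 completes with an identity-noise warning", {
  sim <- simulate_hic(small_model(seed = 23))
  args <- small_net_args()
  expect_warning(
    fit_subcompartments(sim$contacts, sim$truth, keep_rate = 1,
                        interior = args$interior, hidden = args$hidden,
                        epochs = 2, seed = 1),
    "keep_rate = 1")
})

test_that("annotation labels every covered bin and NAs the rest", {
  f <- fit_small()
  sp <- downsample_contacts(f$sim$contacts, 0.1, seed = 31)
  # zero out one row and one column entirely
  counts <- sp$counts
  counts[3, ] <- 0
  counts[, 5] <- 0
  sp2 <- inter_contacts(counts, sp$row_grid, sp$col_grid)
  ann <- predict(f$model, sp2)
  expect_equal(nrow(ann), 160)
  expect_true(is.na(ann$label[3]))
  expect_true(is.na(ann$label[80 + 5]))
  ok <- !is.na(ann$label)
  expect_true(all(as.character(ann$label[ok]) %in% subcompartments()))
  pc <- as.matrix(ann[ok, paste0("p.", subcompartments())])
  expect_equal(unname(rowSums(pc)), rep(1, sum(ok)), tolerance = 1e-6)
  # a bin's parity tag matches its grid of origin
  expect_equal(ann$parity, rep(c("odd", "even"), each = 80))
})

test_that("an all-zero matrix yields an all-NA track", {
  f <- fit_small()
  zero <- inter_contacts(matrix(0, 80, 80), f$sim$contacts$row_grid,
                         f$sim$contacts$col_grid)
  ann <- predict(f$model, zero)
  expect_true(all(is.na(ann$label)))
})

test_that("grid-width mismatches are rejected with a re-binning hint", {
  f <- fit_small()
  g <- bin_grid(c(chr1 = 30e5))
  g2 <- bin_grid(c(chr2 = 30e5))
  bad <- inter_contacts(matrix(1, 30, 30), g, g2)
  expect_error(predict(f$model, bad), "re-bin")
})

test_that("imputed matrices keep shape, range, and improve on the input", {
  f <- fit_small()
  ns <- asNamespace("hicsubcomp")
  sp <- ns$with_seed(21, downsample_contacts(f$sim$contacts, 0.1,
                                             seed = NULL))
  imp <- impute_contacts(f$model, sp)
  expect_equal(dim(imp$probs), c(80, 80))
  expect_true(all(imp$probs > 0 & imp$probs < 1))
  expect_identical(impute_contacts(f$model, sp)$probs, imp$probs)
  # even-parity pathway reconstructs through the transpose
  impe <- impute_contacts(f$model, sp, parity = "even")
  expect_equal(dim(impe$probs), c(80, 80))
  expect_true(all(impe$probs > 0 & impe$probs < 1))
})

test_that("models round-trip exactly through the JSON archive", {
  f <- fit_small()
  path <- withr::local_tempfile(fileext = ".json.gz")
  write_subcomp_model(f$model, path)
  back <- read_subcomp_model(path)
  expect_equal(back$odd$autoencoder$net$W, f$model$odd$autoencoder$net$W,
               tolerance = 0)
  expect_equal(back$even$classifier$net$b, f$model$even$classifier$net$b,
               tolerance = 0)
  expect_equal(back$even$classifier$center, f$model$even$classifier$center,
               tolerance = 0)
  expect_equal(back$manifest$seed, f$model$manifest$seed)
  sp <- downsample_contacts(f$sim$contacts, 0.1, seed = 41)
  expect_equal(predict(back, sp), predict(f$model, sp))
})

test_that("annotation tracks export to BED and read back", {
  f <- fit_small()
  sp <- downsample_contacts(f$sim$contacts, 0.1, seed = 51)
  ann <- predict(f$model, sp)
  bed <- withr::local_tempfile(fileext = ".bed")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_track_bed(ann, bed, tsv = tsv)
  n_rec <- length(readLines(bed))
  expect_equal(n_rec, sum(!is.na(ann$label)))
  back <- read_track_bed(bed, bins = ann[, c("chrom", "start", "end")])
  expect_equal(as.character(back$label), as.character(ann$label))
  full <- utils::read.delim(tsv)
  expect_equal(nrow(full), 160)
})

test_that("reference labels must cover the training chromosomes", {
  sim <- simulate_hic(small_model(seed = 24))
  ref <- sim$truth
  ref$label[ref$chrom %in% c("chr1", "chr3", "chr5", "chr7")] <- NA
  args <- small_net_args()
  expect_error(fit_subcompartments(sim$contacts, ref, epochs = 1,
                                   interior = args$interior,
                                   hidden = args$hidden, seed = 1),
               "cover")
})
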