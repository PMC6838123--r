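# Shared fixtures, built in code at test time.

# two tiny grids: 3 odd bins x 4 even bins
tiny_grids <- function() {
  list(row = bin_grid(c(chr1 = 2e5, chr3 = 1e5), bin_size = 1e5),
       col = bin_grid(c(chr2 = 3e5, chr4 = 1e5), bin_size = 1e5))
}

tiny_contacts <- function(counts = NULL) {
  g <- tiny_grids()
  if (is.null(counts)) counts <- matrix(seq_len(12), 3, 4)
  inter_contacts(counts, g$row, g$col)
}

# a small planted model that keeps network training fast in unit tests;
# mean cell count matches the default fixture (depth = 12.5 * n_odd * n_even),
# and short label runs keep every class represented in the training split
small_model <- function(seed = 1, n = 80) {
  planted_model(n_odd = n, n_even = n, depth = 12.5 * n * n,
                mean_run = 3, seed = seed)
}

# small-architecture training settings for desk-speed unit tests
small_net_args <- function() list(interior = c(32, 16, 8), hidden = c(16, 8))

# naive accumulation oracle for load_contacts
oracle_accumulate <- function(triplets, row_grid, col_grid) {
  m <- matrix(0, nrow(row_grid), nrow(col_grid))
  for (k in seq_len(nrow(triplets))) {
    i <- which(row_grid$chrom == triplets$chrom_i[k] &
                 row_grid$start == triplets$start_i[k])
    j <- which(col_grid$chrom == triplets$chrom_j[k] &
                 col_grid$start == triplets$start_j[k])
    m[i, j] <- m[i, j] + triplets$count[k]
  }
  m
}

expect_track_equal_labels <- function(a, b) {
  expect_equal(as.character(a$label), as.character(b$label))
}
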