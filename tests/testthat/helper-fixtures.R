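# small fixtures built in code; nothing is read from disk

# two tiny chromosomes, 1-kb bins: 10 + 8 bins
tiny_genome <- function() {
  genome_model(c("chrA", "chrB"), c(10000, 8000),
               centromeres = c(chrA = 4500, chrB = 3500))
}

tiny_bins <- function(binsize = 1000) bin_genome(tiny_genome(), binsize)

# deterministic dense-ish random matrix on the tiny genome
tiny_matrix <- function(seed = 1, kind = "raw", density = 0.6) {
  bins <- tiny_bins()
  n <- nrow(bins)
  set.seed(seed)
  pairs <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  keep <- sample(nrow(pairs), floor(density * nrow(pairs)))
  v <- rpois(length(keep), 6) + 1
  contact_matrix(bins, pairs[keep, 1], pairs[keep, 2], v, kind = kind)
}

# matrix with every inter-chromosomal cell set to a constant
constant_inter_matrix <- function(value = 2, binsize = 1000) {
  bins <- tiny_bins(binsize)
  nA <- sum(bins$chrom == "chrA")
  idx <- expand.grid(i = which(bins$chrom == "chrA"),
                     j = which(bins$chrom == "chrB"))
  contact_matrix(bins, idx$i, idx$j, rep(value, nrow(idx)), kind = "balanced")
}

# single-chromosome matrix whose value at distance s (bins) is fun(s)
decay_matrix <- function(n = 60, fun = function(s) s^-1.5, binsize = 1000,
                         chrom_len = NULL) {
  g <- genome_model("chrZ", if (is.null(chrom_len)) n * binsize else chrom_len,
                    centromeres = c(chrZ = floor(n / 2) * binsize + 1))
  bins <- bin_genome(g, binsize)
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)  # s >= 1
  s <- pr[, 2] - pr[, 1]
  contact_matrix(bins, pr[, 1], pr[, 2], fun(s), kind = "balanced")
}

expect_same_entries <- function(a, b) {
  expect_equal(a$entries$i, b$entries$i)
  expect_equal(a$entries$j, b$entries$j)
  expect_equal(a$entries$value, b$entries$value)
}
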