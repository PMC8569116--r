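test_that("log2 ratio map follows the pseudocount formula", {
  A <- tiny_matrix(seed = 1)
  expect_true(all(log2_ratio_map(A, A, chrom = "chrA") == 0, na.rm = TRUE))

  bins <- tiny_bins()
  A1 <- contact_matrix(bins, c(1, 2), c(3, 4), c(8, 0))
  B1 <- contact_matrix(bins, c(1, 2), c(3, 4), c(2, 5))
  m0 <- log2_ratio_map(A1, B1, chrom = "chrA", pseudocount = 0)
  expect_equal(m0[1, 3], 2)
  m1 <- log2_ratio_map(A1, B1, chrom = "chrA", pseudocount = 1)
  expect_equal(m1[2, 4], log2(1 / 6))
  # both-zero cells are missing, not 0
  expect_true(is.na(m1[5, 7]))
})

test_that("log2 ratio map is antisymmetric in its arguments", {
  A <- tiny_matrix(seed = 11)
  B <- tiny_matrix(seed = 12)
  for (cc in c("chrA", "chrB")) {
    ab <- log2_ratio_map(A, B, chrom = cc, pseudocount = 0.5)
    ba <- log2_ratio_map(B, A, chrom = cc, pseudocount = 0.5)
    fin <- is.finite(ab)
    expect_equal(ab[fin], -ba[fin])
    expect_equal(is.na(ab), is.na(ba))
  }
})

test_that("contact probability recovers an exact power-law slope", {
  cm <- decay_matrix(n = 80, fun = function(s) s^-1.5)
  prof <- contact_probability(cm, strata = "bin")
  fit <- lm(log(value) ~ log(distance), data = prof[prof$value > 0, ])
  expect_equal(unname(coef(fit)[2]), -1.5, tolerance = 0.02)

  flat <- decay_matrix(n = 50, fun = function(s) rep(2, length(s)))
  pf <- contact_probability(flat, strata = "bin")
  fitf <- lm(log(value) ~ log(distance), data = pf)
  expect_equal(unname(coef(fitf)[2]), 0, tolerance = 1e-10)
})

test_that("contact probability counts pairs even for empty matrices", {
  bins <- tiny_bins()
  empty <- contact_matrix(bins, integer(), integer(), numeric())
  prof <- contact_probability(empty, strata = "bin")
  expect_true(all(prof$value == 0))
  # 10- and 8-bin chromosomes: distance 1 has 9 + 7 pairs
  expect_equal(prof$n_pairs[1], 16)
  expect_equal(prof$n_pairs[prof$distance == 9000], 1)
})

test_that("contact probability is linear in the matrix (mixture check)", {
  A <- tiny_matrix(seed = 21)
  B <- tiny_matrix(seed = 22)
  AB <- {
    key <- function(x) paste(x$entries$i, x$entries$j)
    all <- union(key(A), key(B))
    va <- setNames(numeric(length(all)), all); va[key(A)] <- A$entries$value
    vb <- setNames(numeric(length(all)), all); vb[key(B)] <- B$entries$value
    ij <- do.call(rbind, strsplit(all, " "))
    contact_matrix(A$bins, as.integer(ij[, 1]), as.integer(ij[, 2]), va + vb)
  }
  pa <- contact_probability(A, strata = "bin")
  pb <- contact_probability(B, strata = "bin")
  pab <- contact_probability(AB, strata = "bin")
  expect_equal(pab$value, pa$value + pb$value, tolerance = 1e-12)
})

test_that("cp log2 ratio is pointwise and drops zero strata", {
  cm <- tiny_matrix(seed = 5)
  p <- contact_probability(cm, strata = "bin")
  self <- cp_log2_ratio(p, p)
  expect_true(all(self$log2_ratio == 0))

  p2 <- p; p2$value <- 2 * p$value
  doub <- cp_log2_ratio(p2, p)
  expect_true(all(abs(doub$log2_ratio - 1) < 1e-12))
  expect_equal(attr(doub, "n_dropped"), sum(!(p$value > 0)))
})

test_that("planted decay-band fold changes appear in the CP ratio curve", {
  g <- genome_model(c("cA", "cB"), c(500000, 400000),
                    centromeres = c(cA = 250500, cB = 200500))
  cfg <- synthetic_config(g, binsize = 1000, peri_amp = 1, depth = 1e6,
                          decay_bands = data.frame(s_min = 10000,
                                                   s_max = 100000,
                                                   fold = 1.3))
  Pc <- contact_probability(expected_matrix(cfg, "control"), strata = "bin")
  Pd <- contact_probability(expected_matrix(cfg, "depleted"), strata = "bin")
  ratio <- cp_log2_ratio(Pd, Pc)
  in_band <- ratio$distance >= 12000 & ratio$distance <= 90000
  out_band <- ratio$distance > 110000
  # each condition is depth-normalised, so the curve is flat at two levels
  # whose contrast is the planted fold
  expect_equal(mean(ratio$log2_ratio[in_band]) -
                 mean(ratio$log2_ratio[out_band]),
               log2(1.3), tolerance = 0.02)
  expect_lt(stats::sd(ratio$log2_ratio[in_band]), 0.01)
  expect_lt(stats::sd(ratio$log2_ratio[out_band]), 0.01)
})

test_that("SVL ratio follows its definition and edge rules", {
  bins <- tiny_bins()
  # chrA: 30 at distance 2 kb (short), 10 at 9 kb... 9 kb < 10 kb so use L = 5 kb
  cm <- contact_matrix(bins, c(1, 1), c(3, 10), c(30, 10))
  out <- suppressWarnings(svl_ratio(cm, L = 5000))
  expect_equal(out$ratio[out$chrom == "chrA"], 3)
  # all mass short on chrB
  cm2 <- contact_matrix(bins, 11, 12, 5)
  out2 <- suppressWarnings(svl_ratio(cm2, L = 5000))
  expect_true(is.infinite(out2$ratio[out2$chrom == "chrB"]))
  expect_true(out2$all_short[out2$chrom == "chrB"])
  # distance exactly L counts as long
  cmL <- contact_matrix(bins, c(1, 1), c(2, 6), c(7, 9))
  outL <- suppressWarnings(svl_ratio(cmL, L = 5000))
  expect_equal(outL$long_sum[1], 9)
  # chromosome shorter than L is missing with a warning
  expect_warning(svl_ratio(cm, L = 9000), "chrB")
  expect_error(svl_ratio(cm, L = 1500), "multiple")
})

test_that("SVL ratio is invariant under global rescaling", {
  cm <- tiny_matrix(seed = 13)
  sc <- contact_matrix(cm$bins, cm$entries$i, cm$entries$j,
                       cm$entries$value * 11.5)
  r1 <- suppressWarnings(svl_ratio(cm, L = 5000))
  r2 <- suppressWarnings(svl_ratio(sc, L = 5000))
  expect_equal(r1$ratio, r2$ratio)
})

test_that("one-sided Wilcoxon matches full enumeration on small samples", {
  # independent oracle: enumerate all C(6,3) labelings of the pooled sample
  enum_p_less <- function(x, y) {
    pooled <- c(x, y)
    r <- rank(pooled)
    w_obs <- sum(r[seq_along(x)])
    combos <- combn(length(pooled), length(x))
    ws <- apply(combos, 2, function(idx) sum(r[idx]))
    mean(ws <= w_obs)
  }
  w1 <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6), "less")
  expect_equal(w1$p.value, 0.05)
  expect_equal(w1$p.value, enum_p_less(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(w1$method, "exact")

  w2 <- wilcoxon_rank_sum(c(5, 6, 7), c(1, 2, 3), "less")
  expect_equal(w2$p.value, 1)
  expect_equal(w2$p.value, enum_p_less(c(5, 6, 7), c(1, 2, 3)))

  x <- c(1.5, 2.5, 9)
  expect_gte(wilcoxon_rank_sum(x, x, "less")$p.value, 0.5)
  expect_gte(wilcoxon_rank_sum(x, x, "greater")$p.value, 0.5)
  expect_error(wilcoxon_rank_sum(numeric(), 1), "nonempty")
})

test_that("exact and approximate Wilcoxon agree for tie-free 6+6 samples", {
  set.seed(42)
  for (rep in 1:50) {
    z <- sample(seq(0.01, 1, by = 0.01), 12)
    x <- z[1:6]; y <- z[7:12]
    pe <- wilcoxon_rank_sum(x, y, "less")$p.value
    pa <- suppressWarnings(stats::wilcox.test(x, y, alternative = "less",
                                              exact = FALSE,
                                              correct = TRUE)$p.value)
    expect_lt(abs(pe - pa), 0.01)
  }
})

test_that("large-sample Wilcoxon uses the corrected normal approximation", {
  x <- c(1, 1, 2, 3, 4, 4, 5, 6, 7)
  y <- c(2, 3, 3, 5, 6, 8, 9, 9)
  w <- wilcoxon_rank_sum(x, y, "less")
  expect_equal(w$method, "normal-approximation")
  ref <- suppressWarnings(stats::wilcox.test(x, y, alternative = "less",
                                             exact = FALSE, correct = TRUE))
  expect_equal(w$p.value, unname(ref$p.value))
})

test_that("virtual 4C returns the centromere-bin row of the matrix", {
  cm <- tiny_matrix(seed = 14)
  prof <- virtual_4c(cm, "chrA")
  bins <- cm$bins
  cen <- centromere_bin(tiny_genome(), bins, "chrA")
  S <- matrix(0, nrow(bins), nrow(bins))
  e <- cm$entries
  S[cbind(e$i, e$j)] <- e$value
  S[cbind(e$j, e$i)] <- e$value
  expect_equal(prof$value, unname(S[cen, bins$chrom == "chrA"]))
  expect_equal(prof$value, unname(S[bins$chrom == "chrA", cen]))  # symmetry
  g0 <- genome_model("chrA", 10000)
  expect_error(virtual_4c(cm, "chrA", genome = g0), "centromere")
})

test_that("virtual 4C recovers planted peri-centromeric enrichment", {
  # flat decay, enrichment amplitude 2 within +/- 20 kb of the centromere
  g <- genome_model("cZ", 400000, centromeres = c(cZ = 200500))
  cfg <- synthetic_config(g, binsize = 1000, alpha = 0, s0 = 1000,
                          peri_amp = 2, peri_sigma = 10000, depth = 1e6,
                          kappa = 1)
  E <- expected_matrix(cfg, "control")
  prof <- virtual_4c(E, "cZ")
  cen <- g$centromeres[["cZ"]]
  near <- abs(prof$start - cen) <= 20000
  arm <- abs(prof$start - cen) > 50000
  expect_gte(mean(prof$value[near]), 1.5 * median(prof$value[arm]))
})
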