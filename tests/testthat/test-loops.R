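test_that("O/E transform normalises every distance stratum to mean 1", {
  cm <- tiny_matrix(seed = 41)
  oe <- oe_transform(cm)
  bins <- cm$bins
  for (cc in c("chrA", "chrB")) {
    n <- sum(bins$chrom == cc)
    off <- min(bins$bin[bins$chrom == cc]) - 1
    e <- oe$entries
    sel <- e$i > off & e$i <= off + n
    for (s in 0:(n - 1)) {
      vals <- e$value[sel & (e$j - e$i) == s]
      if (length(vals) == 0) next
      expect_equal(sum(vals) / (n - s), 1, tolerance = 1e-12)
    }
  }
  # O/E of an expected (noiseless) decay matrix is identically 1
  dm <- decay_matrix(n = 40, fun = function(s) s^-1.2)
  oed <- oe_transform(dm)
  expect_true(all(abs(oed$entries$value - 1) < 1e-12))
})

test_that("a planted multiplicative loop appears in O/E at its strength", {
  # long chromosome so the loop's own mass barely inflates the expected curve
  g <- genome_model(c("big", "small"), c(1500000, 200000),
                    centromeres = c(big = 750500, small = 100500))
  # anchors on bin centres, so the bump is sampled at its apex
  loops <- data.frame(chrom = "big", anchor1 = 300500, anchor2 = 317500,
                      strength = 3, sigma = 2000)
  cfg <- synthetic_config(g, binsize = 1000, peri_amp = 1, loops = loops,
                          depth = 1e6)
  E <- expected_matrix(cfg, "control", scope = "intra", chroms = "big")
  oe <- oe_transform(E)
  bins <- E$bins
  i <- locate_bin(bins, "big", 300500); j <- locate_bin(bins, "big", 317500)
  at <- oe$entries$value[oe$entries$i == i & oe$entries$j == j]
  expect_equal(at, 3, tolerance = 0.01)
})

test_that("kernel correlation scores a patch equal to the kernel as 1", {
  k <- loop_kernel(7, 1)
  n <- 41
  g <- genome_model("c", n * 1000)
  bins <- bin_genome(g, 1000)
  # build O/E values so that log2(OE + 1) = kernel + 2 inside the patch
  base <- 2^2 - 1
  center <- c(20, 28)
  pr <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  vals <- rep(base, nrow(pr))
  for (q in seq_len(nrow(pr))) {
    di <- pr[q, 1] - center[1]; dj <- pr[q, 2] - center[2]
    if (abs(di) <= 3 && abs(dj) <= 3)
      vals[q] <- 2^(k[di + 4, dj + 4] + 2) - 1
  }
  oe <- contact_matrix(bins, pr[, 1], pr[, 2], vals, kind = "balanced")
  calls <- detect_loops(oe, kernel = k, score_min = 0.99, min_dist = 2000,
                        max_dist = 20000, min_center_oe = 0.5)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$i, center[1])
  expect_equal(calls$j, center[2])
  expect_equal(calls$score, 1, tolerance = 1e-9)
})

test_that("loop detection is deterministic and NMS-separated", {
  cfg <- demo_config(depth = 2e6, seed = 7)
  sim <- simulate_pair(cfg)
  oe <- oe_transform(sim$control)
  k <- loop_kernel(7, 1)
  c1 <- detect_loops(oe, kernel = k, min_dist = 4000, max_dist = 40000,
                     score_min = 0.35)
  c2 <- detect_loops(oe, kernel = k, min_dist = 4000, max_dist = 40000,
                     score_min = 0.35)
  expect_identical(c1, c2)
  # no two calls on one chromosome within the suppression radius
  for (cc in unique(c1$chrom)) {
    sub <- c1[c1$chrom == cc, ]
    if (nrow(sub) < 2) next
    for (a in seq_len(nrow(sub) - 1)) {
      cheb <- pmax(abs(sub$i[-(1:a)] - sub$i[a]), abs(sub$j[-(1:a)] - sub$j[a]))
      expect_true(all(cheb > 3))
    }
  }
  # ordering: score descending
  expect_true(all(diff(c1$score) <= 1e-12))
  expect_error(detect_loops(oe, kernel = loop_kernel(21, 3), min_dist = 4000,
                            max_dist = 20000), "band")
})

test_that("planted loops are recovered from a simulated demo map", {
  cfg <- demo_config(depth = 2e6, seed = 5)
  sim <- simulate_pair(cfg)
  oe <- oe_transform(sim$control)
  # at 2-kb bins the planted footprint is ~1 bin, so the 1-bin kernel fits
  calls <- detect_loops(oe, kernel = loop_kernel(7, 1), score_min = 0.55,
                        min_dist = 4000, max_dist = 30000)
  truth <- sim$truth$loops
  hit <- vapply(seq_len(nrow(truth)), function(q)
    any(pmax(abs(calls$i - truth$i[q]), abs(calls$j - truth$j[q])) <= 2), TRUE)
  expect_gte(mean(hit), 0.75)
  expect_gte(sum(hit) / max(1, nrow(calls)), 0.75)
})

test_that("loop quantification folds and classes behave as a partition", {
  cfg <- demo_config(depth = 2e6, seed = 9)
  sim <- simulate_pair(cfg)
  loops <- sim$truth$loops
  same <- quantify_loops(loops, sim$control, sim$control, agg_radius = 2)
  expect_true(all(same$fold == 1))
  expect_true(all(same$class == "marginal"))

  q <- quantify_loops(loops, sim$control, sim$depleted, agg_radius = 3)
  expect_equal(sum(q$class == "up") + sum(q$class == "down") +
                 sum(q$class == "marginal"), nrow(loops))
  # condition swap maps fold to 1/fold and up to down
  qr <- quantify_loops(loops, sim$depleted, sim$control, agg_radius = 3)
  expect_equal(qr$fold, 1 / q$fold, tolerance = 1e-12)
  expect_equal(qr$class == "up", q$class == "down")

  # direct example: score_iaa 3.2 vs score_con 2.0 is a 1.6-fold gain
  bins <- tiny_bins()
  mk <- function(v) contact_matrix(bins, 2, 7, v, kind = "balanced")
  one <- quantify_loops(data.frame(i = 2, j = 7), mk(2), mk(3.2),
                        agg_radius = 0)
  expect_equal(one$fold, 1.6)
  expect_equal(one$class, "up")
})

test_that("region scoring enumerates bin pairs and groups quartiles", {
  g <- genome_model("c13", 924000, centromeres = c(c13 = 268090))
  bins <- bin_genome(g, 1000)
  set.seed(8)
  sel <- locate_bin(bins, "c13", seq(620000, 639000, by = 1000))
  pr <- expand.grid(i = sel, j = sel)
  pr <- pr[pr$j >= pr$i, ]
  vc <- runif(nrow(pr), 0.5, 4)
  vi <- vc * runif(nrow(pr), 0.4, 2.6)
  Mc <- contact_matrix(bins, pr$i, pr$j, vc, kind = "balanced")
  Mi <- contact_matrix(bins, pr$i, pr$j, vi, kind = "balanced")
  tab <- score_region(Mc, Mi, list("c13", 620000, 640000))
  expect_equal(nrow(tab), choose(20, 2))
  expect_equal(nrow(tab), 190)
  tabd <- score_region(Mc, Mi, list("c13", 620000, 640000),
                       include_diagonal = TRUE)
  expect_equal(nrow(tabd), 210)
  # quartile groups partition the rows near-evenly for distinct scores
  expect_equal(sum(table(tab$group)), 190)
  expect_true(all(abs(table(tab$group) - 190 / 4) <= 1))
  # arc classes match the fold definition
  ratio <- tab$score_iaa / tab$score_con
  expect_true(all(tab$arc_class[ratio > 2] == "ge2"))
  expect_true(all(tab$arc_class[ratio > 1.5 & ratio <= 2] == "ge1.5"))
  expect_true(all(tab$arc_class[ratio <= 1.5] == "below"))
  expect_error(score_region(Mc, Mi, list("c13", 620000, 621000)), "2 bins")
})

test_that("distance histograms count rows and locate planted gains", {
  g <- genome_model("c13", 924000, centromeres = c(c13 = 268090))
  loops <- data.frame(chrom = "c13", anchor1 = 625000, anchor2 = 642000,
                      strength = 3, sigma = 1500)
  cfg <- synthetic_config(g, binsize = 1000, peri_amp = 1, loops = loops,
                          loop_fold = 2, loop_window = 3000, depth = 1e6)
  Mc <- expected_matrix(cfg, "control")
  Mi <- expected_matrix(cfg, "depleted")
  tab <- score_region(Mc, Mi, list("c13", 620000, 650000))
  h <- distance_histogram(tab)
  expect_equal(sum(h$n), nrow(tab))
  expect_equal(sum(h$rel_n), 1)
  # identical conditions give identical histograms
  h0 <- distance_histogram(score_region(Mc, Mc, list("c13", 620000, 650000)))
  expect_equal(h0$score_con, h0$score_iaa)
  # the 17-kb stratum carries the largest score-mass log2 ratio
  lr <- log2(h$score_iaa / h$score_con)
  expect_equal(h$distance[which.max(lr)], 17000)
})
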