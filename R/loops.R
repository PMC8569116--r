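#' Expected contact value by distance
#'
#' Per chromosome, the expected value at distance `s` is the mean contact
#' value over all intra-chromosomal pairs at that distance (absent cells
#' count as 0). The diagonal (s = 0) is included.
#'
#' @param cm A balanced (or raw) `ContactMatrix`.
#' @return data.frame with `chrom`, `s` (bins), `distance` (bp), `expected`.
#' @export
expected_by_distance <- function(cm) {
  bins <- cm$bins
  binsize <- bin_binsize(bins)
  g <- bin_genome_of(bins)
  ncs <- bin_counts(bins)
  intra <- cm_intra_entries(cm)
  out <- lapply(g$chroms, function(cc) {
    n <- ncs[[cc]]
    sums <- numeric(n)  # s = 0 .. n-1
    sel <- intra$chrom == cc
    if (any(sel)) {
      a <- rowsum(intra$value[sel], intra$s[sel])
      sums[as.integer(rownames(a)) + 1L] <- a
    }
    s <- 0:(n - 1L)
    data.frame(chrom = cc, s = s, distance = s * binsize,
               expected = sums / (n - s))
  })
  do.call(rbind, out)
}

#' Observed/expected transformation
#'
#' Divides every intra-chromosomal contact value by the per-chromosome
#' expected value at its distance. Inter-chromosomal entries are dropped
#' (O/E is a distance-decay detrending and has no meaning across
#' chromosomes). By construction, the per-distance mean of O/E values
#' (absent cells counted as 0) is 1 at every distance with nonzero expected.
#'
#' @param cm A balanced `ContactMatrix`.
#' @return A `ContactMatrix` of O/E values with attribute `expected`.
#' @export
oe_transform <- function(cm) {
  exp_df <- expected_by_distance(cm)
  intra <- cm_intra_entries(cm)
  key_e <- paste(exp_df$chrom, exp_df$s)
  ev <- stats::setNames(exp_df$expected, key_e)
  e_at <- ev[paste(intra$chrom, intra$s)]
  ok <- !is.na(e_at) & e_at > 0
  out <- contact_matrix(cm$bins, intra$i[ok], intra$j[ok],
                        intra$value[ok] / e_at[ok], kind = "balanced")
  attr(out, "expected") <- exp_df
  out
}

#' Gaussian dot-detection kernel
#'
#' A square Gaussian bump minus its mean: a zero-sum template whose Pearson
#' correlation with a log-O/E patch scores dot (loop) likeness.
#'
#' @param side Odd kernel side in bins (default 7).
#' @param sigma Gaussian width in bins (default 1).
#' @return `side x side` numeric matrix with mean 0.
#' @export
loop_kernel <- function(side = 7, sigma = 1) {
  side <- as.integer(side)
  if (side %% 2L == 0L) stop("'side' must be odd")
  h <- (side - 1L) %/% 2L
  d <- (-h):h
  k <- exp(-outer(d^2, d^2, "+") / (2 * sigma^2))
  k - mean(k)
}

# Pearson correlation of kernel vs local patch at pixels (i, j = i + d) with
# d in [smin, smax], computed on a skewed diagonal-band array (column k holds
# the d = dvals[k] diagonal) so the convolution touches only the band.
# Cells outside the matrix are excluded pairwise (NA in the band).
kernel_correlation_band <- function(m, kernel, smin, smax) {
  n <- nrow(m)
  h <- (nrow(kernel) - 1L) %/% 2L
  dvals <- (smin - 2L * h):(smax + 2L * h)  # diagonals touched by any patch
  B <- matrix(NA_real_, n, length(dvals))
  for (k in seq_along(dvals)) {
    d <- dvals[k]
    if (d >= 0 && d < n) {
      rows <- seq_len(n - d)
      B[rows, k] <- m[cbind(rows, rows + d)]
    } else if (d < 0 && -d < n) {
      rows <- (1L - d):n
      B[rows, k] <- m[cbind(rows, rows + d)]
    }
  }
  valid <- !is.na(B)
  B0 <- B; B0[!valid] <- 0
  B2 <- B0 * B0
  zero <- matrix(0, n, length(dvals))
  SP <- zero; SP2 <- zero; SK <- zero; SK2 <- zero; SPK <- zero; NV <- zero
  # kernel offset (di, dj) relative to centre (i, j): patch cell sits at
  # row i + di, diagonal d + (dj - di)
  for (di in -h:h) for (dj in -h:h) {
    kv <- kernel[di + h + 1L, dj + h + 1L]
    dd <- dj - di
    si <- max(1L, 1L - di):min(n, n - di)
    sk <- max(1L, 1L - dd):min(length(dvals), length(dvals) - dd)
    ti <- si + di; tk <- sk + dd
    SP[si, sk] <- SP[si, sk] + B0[ti, tk]
    SP2[si, sk] <- SP2[si, sk] + B2[ti, tk]
    SPK[si, sk] <- SPK[si, sk] + kv * B0[ti, tk]
    v <- valid[ti, tk]
    SK[si, sk] <- SK[si, sk] + kv * v
    SK2[si, sk] <- SK2[si, sk] + kv * kv * v
    NV[si, sk] <- NV[si, sk] + v
  }
  covPK <- SPK / NV - (SP / NV) * (SK / NV)
  varP <- SP2 / NV - (SP / NV)^2
  varK <- SK2 / NV - (SK / NV)^2
  r <- covPK / sqrt(pmax(varP, 0) * pmax(varK, 0))
  r[!is.finite(r)] <- NA_real_
  keep <- dvals >= smin & dvals <= smax
  list(r = r[, keep, drop = FALSE], dvals = dvals[keep])
}

#' Kernel-correlation loop detection
#'
#' At every candidate pixel `(i, j)` inside the distance band, the detection
#' score is the Pearson correlation between the kernel and the local
#' `log2(O/E + 1)` patch (cells outside the chromosome block are excluded
#' pairwise). Candidates scoring at least `score_min` whose centre O/E
#' exceeds `min_center_oe` are kept, then greedy non-maximum suppression
#' removes any call within Chebyshev distance `nms_radius` (bins) of a
#' higher-scoring call. Output ordering is deterministic: score descending,
#' then `i`, then `j`.
#'
#' @param oe An O/E `ContactMatrix` from [oe_transform()].
#' @param kernel Odd square template (default [loop_kernel()]).
#' @param score_min Minimum detection score (default 0.4).
#' @param min_dist,max_dist Anchor separation band in bp (defaults 2 kb,
#'   200 kb).
#' @param nms_radius Suppression radius in bins (default 3).
#' @param min_center_oe Minimum O/E at the call centre (default 1).
#' @param chroms Chromosomes to scan (default all).
#' @return A `LoopCall` data.frame: `chrom`, `i`, `j` (global bins, `j > i`),
#'   `start1`, `start2`, `distance`, `score`.
#' @export
detect_loops <- function(oe, kernel = loop_kernel(), score_min = 0.4,
                         min_dist = 2000, max_dist = 200000,
                         nms_radius = 3, min_center_oe = 1, chroms = NULL) {
  bins <- oe$bins
  binsize <- bin_binsize(bins)
  g <- bin_genome_of(bins)
  if (is.null(chroms)) chroms <- g$chroms
  if (nrow(kernel) != ncol(kernel) || nrow(kernel) %% 2L == 0L)
    stop("kernel must be square with odd side")
  smin <- max(1L, as.integer(ceiling(min_dist / binsize)))
  smax <- as.integer(floor(max_dist / binsize))
  if (smax - smin < nrow(kernel))
    stop("kernel larger than the distance band permits")
  offs <- bin_offsets(bins)
  calls <- list()
  for (cc in chroms) {
    D <- cm_dense_block(oe, cc)
    n <- nrow(D)
    if (n <= smin) next
    kb <- kernel_correlation_band(log2(D + 1), kernel, smin, min(smax, n - 1L))
    r <- kb$r
    iu <- row(r); du <- matrix(kb$dvals[col(r)], nrow(r), ncol(r))
    ju <- iu + du
    inside <- ju <= n
    center_oe <- matrix(0, nrow(r), ncol(r))
    center_oe[inside] <- D[cbind(iu[inside], ju[inside])]
    hit <- inside & !is.na(r) & r >= score_min & center_oe > min_center_oe
    if (!any(hit)) next
    ii <- iu[hit]; jj <- ju[hit]; sc <- r[hit]
    o <- order(-sc, ii, jj)
    ii <- ii[o]; jj <- jj[o]; sc <- sc[o]
    keep <- logical(length(ii))
    ki <- integer(0); kj <- integer(0)
    for (q in seq_along(ii)) {
      if (length(ki) == 0L ||
          all(pmax(abs(ki - ii[q]), abs(kj - jj[q])) > nms_radius)) {
        keep[q] <- TRUE
        ki <- c(ki, ii[q]); kj <- c(kj, jj[q])
      }
    }
    calls[[cc]] <- data.frame(chrom = cc,
                              i = ii[keep] + offs[[cc]],
                              j = jj[keep] + offs[[cc]],
                              score = sc[keep])
  }
  out <- if (length(calls)) do.call(rbind, calls) else
    data.frame(chrom = character(), i = integer(), j = integer(),
               score = numeric())
  rownames(out) <- NULL
  if (nrow(out)) {
    out$start1 <- bins$start[out$i]
    out$start2 <- bins$start[out$j]
    out$distance <- (out$j - out$i) * binsize
    out <- out[order(-out$score, out$i, out$j),
               c("chrom", "i", "j", "start1", "start2", "distance", "score")]
    rownames(out) <- NULL
  }
  class(out) <- c("LoopCall", "data.frame")
  out
}

# mean contact value in the (2r+1)^2 box around (i, j), in-range cells only;
# absent cells count as 0, fully out-of-range boxes are an error
box_score <- function(S, bins, i, j, r) {
  n <- nrow(bins)
  ri <- (i - r):(i + r); rj <- (j - r):(j + r)
  # clip to the two bins' chromosome blocks
  offs <- bin_offsets(bins); ncs <- bin_counts(bins)
  ci <- as.character(bins$chrom[i]); cj <- as.character(bins$chrom[j])
  ri <- ri[ri > offs[[ci]] & ri <= offs[[ci]] + ncs[[ci]]]
  rj <- rj[rj > offs[[cj]] & rj <= offs[[cj]] + ncs[[cj]]]
  if (length(ri) == 0L || length(rj) == 0L)
    stop("anchor box fully outside the matrix")
  mean(as.matrix(S[ri, rj, drop = FALSE]))
}

#' Quantify loops in two conditions and classify fold changes
#'
#' The contact score of each loop in each condition is the mean balanced
#' value in the `(2 * agg_radius + 1)^2` box at the anchor; the fold change
#' is `score_iaa / score_con`, and calls are classed `up` if the fold
#' exceeds `fold_threshold`, `down` if below its reciprocal, else
#' `marginal`. Swapping conditions maps fold to 1/fold and up to down
#' exactly.
#'
#' @param loops A `LoopCall` data.frame (or any data.frame with global bin
#'   columns `i`, `j`).
#' @param M_con,M_iaa Balanced `ContactMatrix` objects on matched bin tables.
#' @param agg_radius Box radius in bins (default 1).
#' @param fold_threshold Classification threshold (default 1.5).
#' @return The input with `score_con`, `score_iaa`, `fold`, `class` added.
#' @export
quantify_loops <- function(loops, M_con, M_iaa, agg_radius = 1,
                           fold_threshold = 1.5) {
  check_same_bins(M_con, M_iaa)
  bins <- M_con$bins
  Sc <- cm_sparse(M_con); Si <- cm_sparse(M_iaa)
  sc <- numeric(nrow(loops)); si <- numeric(nrow(loops))
  for (q in seq_len(nrow(loops))) {
    sc[q] <- box_score(Sc, bins, loops$i[q], loops$j[q], agg_radius)
    si[q] <- box_score(Si, bins, loops$i[q], loops$j[q], agg_radius)
  }
  fold <- ifelse(sc > 0, si / sc, ifelse(si > 0, Inf, NA_real_))
  cls <- rep("marginal", length(fold))
  cls[!is.na(fold) & fold > fold_threshold] <- "up"
  cls[!is.na(fold) & fold < 1 / fold_threshold] <- "down"
  loops$score_con <- sc
  loops$score_iaa <- si
  loops$fold <- fold
  loops$class <- cls
  loops
}

#' Score all bin pairs of a genomic region in two conditions
#'
#' One row per bin pair inside the region (bins fully contained in
#' `[start, end)`; the diagonal is excluded unless `include_diagonal`).
#' Scores are read from the balanced matrices (absent cells are 0). Quartile
#' groups 1-4 partition rows by the score of `quantile_on` condition at its
#' 25/50/75 percentiles, boundary values going to the lower group. Arc
#' classes compare conditions: `ge2` if `score_iaa / score_con > 2` (or the
#' control score is 0 with a positive depleted score), `ge1.5` if > 1.5,
#' else `below`.
#'
#' @param M_con,M_iaa Balanced `ContactMatrix` objects on one bin table.
#' @param region List or vector `(chrom, start, end)` inside one chromosome.
#' @param include_diagonal Include self-pairs (default FALSE).
#' @param quantile_on `"iaa"` (default, mirroring grouping of the treated
#'   sample) or `"con"`.
#' @param min_score Optional filter: keep rows whose `quantile_on` score is
#'   at least this (default 0 keeps all).
#' @return `RegionInteractionTable`: data.frame with `i`, `j`, `distance`,
#'   `score_con`, `score_iaa`, `group`, `arc_class`; region in attributes.
#' @export
score_region <- function(M_con, M_iaa, region, include_diagonal = FALSE,
                         quantile_on = c("iaa", "con"), min_score = 0) {
  quantile_on <- match.arg(quantile_on)
  check_same_bins(M_con, M_iaa)
  bins <- M_con$bins
  chrom <- as.character(region[[1]])
  start <- as.numeric(region[[2]]); end <- as.numeric(region[[3]])
  sel <- which(bins$chrom == chrom & bins$start >= start & bins$end <= end)
  if (length(sel) < 2) stop("region smaller than 2 bins")
  pr <- expand.grid(i = sel, j = sel)
  pr <- pr[if (include_diagonal) pr$j >= pr$i else pr$j > pr$i, ]
  Sc <- cm_sparse(M_con); Si <- cm_sparse(M_iaa)
  idx <- cbind(pr$i, pr$j)
  tab <- data.frame(i = pr$i, j = pr$j,
                    distance = (pr$j - pr$i) * bin_binsize(bins),
                    score_con = Sc[idx], score_iaa = Si[idx])
  ref <- if (quantile_on == "iaa") tab$score_iaa else tab$score_con
  if (min_score > 0) { tab <- tab[ref >= min_score, ]; ref <- ref[ref >= min_score] }
  qs <- stats::quantile(ref, c(0.25, 0.5, 0.75), names = FALSE)
  tab$group <- 1L + (ref > qs[1]) + (ref > qs[2]) + (ref > qs[3])
  ratio <- ifelse(tab$score_con > 0, tab$score_iaa / tab$score_con,
                  ifelse(tab$score_iaa > 0, Inf, NA_real_))
  tab$arc_class <- ifelse(!is.na(ratio) & ratio > 2, "ge2",
                          ifelse(!is.na(ratio) & ratio > 1.5, "ge1.5", "below"))
  rownames(tab) <- NULL
  structure(tab, region = list(chrom = chrom, start = start, end = end),
            class = c("RegionInteractionTable", "data.frame"))
}

#' Distance histogram of a region interaction table
#'
#' Per 1-bin distance stratum: the number of rows, the summed score per
#' condition, and counts relative to the table size.
#'
#' @param table A `RegionInteractionTable`.
#' @return data.frame with `distance`, `n`, `rel_n`, `score_con`, `score_iaa`.
#' @export
distance_histogram <- function(table) {
  if (nrow(table) == 0L) stop("empty interaction table")
  d <- sort(unique(table$distance))
  out <- data.frame(
    distance = d,
    n = as.integer(rowsum(rep(1L, nrow(table)), table$distance)),
    score_con = as.numeric(rowsum(table$score_con, table$distance)),
    score_iaa = as.numeric(rowsum(table$score_iaa, table$distance))
  )
  out$rel_n <- out$n / sum(out$n)
  out[, c("distance", "n", "rel_n", "score_con", "score_iaa")]
}
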