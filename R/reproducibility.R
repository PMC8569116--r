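# box-mean smoothing of a dense block: each cell becomes the mean of its
# (2h+1)^2 neighbourhood clipped to the block (absent cells are zeros; the
# divisor is the in-range cell count), via summed-area tables
box_mean <- function(m, h) {
  if (h == 0) return(m)
  n1 <- nrow(m); n2 <- ncol(m)
  sat <- function(x) {
    x <- apply(x, 2, cumsum)
    t(apply(x, 1, cumsum))
  }
  S <- sat(m)
  Sp <- rbind(0, cbind(0, S))  # padded: Sp[i+1, j+1] = sum of m[1:i, 1:j]
  lo1 <- pmax(seq_len(n1) - h, 1L); hi1 <- pmin(seq_len(n1) + h, n1)
  lo2 <- pmax(seq_len(n2) - h, 1L); hi2 <- pmin(seq_len(n2) + h, n2)
  tot <- Sp[hi1 + 1L, hi2 + 1L, drop = FALSE] -
    Sp[lo1, hi2 + 1L, drop = FALSE] -
    Sp[hi1 + 1L, lo2, drop = FALSE] + Sp[lo1, lo2, drop = FALSE]
  cnt <- outer(hi1 - lo1 + 1L, hi2 - lo2 + 1L)
  tot / cnt
}

#' Mean-filter smoothing of a contact matrix
#'
#' Each intra-chromosomal cell is replaced by the mean of its `(2h+1)^2`
#' neighbourhood clipped to the chromosome block; absent cells count as 0
#' and the divisor is the in-range cell count. This is the 2D smoothing step
#' of the SCC reproducibility statistic. `h = 0` is the identity;
#' inter-chromosomal entries are passed through unchanged.
#'
#' @param cm A `ContactMatrix`.
#' @param h Smoothing half-width in bins (>= 0).
#' @return A `ContactMatrix`.
#' @export
mean_filter <- function(cm, h) {
  if (h < 0) stop("'h' must be >= 0")
  if (h == 0) return(cm)
  bins <- cm$bins
  g <- bin_genome_of(bins)
  offs <- bin_offsets(bins)
  intra_chrom <- {
    n <- bin_counts(bins)
    ci <- findInterval(cm$entries$i, cumsum(c(0, n)) + 1)
    cj <- findInterval(cm$entries$j, cumsum(c(0, n)) + 1)
    ci == cj
  }
  inter <- cm$entries[!intra_chrom, , drop = FALSE]
  parts <- lapply(g$chroms, function(cc) {
    sm <- box_mean(cm_dense_block(cm, cc), h)
    nz <- which(sm != 0 & row(sm) <= col(sm), arr.ind = TRUE)
    if (nrow(nz) == 0L)
      return(data.frame(i = integer(), j = integer(), value = numeric()))
    data.frame(i = nz[, 1] + offs[[cc]], j = nz[, 2] + offs[[cc]],
               value = sm[nz])
  })
  all <- rbind(do.call(rbind, parts),
               inter[, c("i", "j", "value")])
  contact_matrix(bins, all$i, all$j, all$value, kind = cm$kind)
}

#' Stratum-adjusted correlation coefficient (SCC)
#'
#' Reproducibility of two contact maps: both are smoothed with
#' [mean_filter()], intra-chromosomal cell pairs with distance
#' `0 < d <= D` are stratified by distance (pooled genome-wide), the Pearson
#' correlation `r_s` is computed per stratum, and the SCC is the weighted
#' mean `sum(w_s * r_s) / sum(w_s)` with `w_s = N_s * sd1_s * sd2_s` over
#' strata with positive variance in both maps.
#'
#' @param A,B `ContactMatrix` objects on one bin table.
#' @param h Smoothing half-width in bins (default 5).
#' @param D Maximum distance in bp (default 100 kb).
#' @return `SCCResult`: list with `scc`, per-stratum data.frame `strata`
#'   (`distance`, `r`, `N`, `sd1`, `sd2`, `weight`), `h`, `D`.
#' @export
scc <- function(A, B, h = 5, D = 100000) {
  check_same_bins(A, B)
  bins <- A$bins
  binsize <- bin_binsize(bins)
  g <- bin_genome_of(bins)
  smax <- as.integer(floor(D / binsize))
  if (smax < 1) stop("'D' smaller than one bin")
  nS <- smax
  Sx <- numeric(nS); Sy <- numeric(nS); Sxx <- numeric(nS)
  Syy <- numeric(nS); Sxy <- numeric(nS); N <- numeric(nS)
  for (cc in g$chroms) {
    da <- box_mean(cm_dense_block(A, cc), h)
    db <- box_mean(cm_dense_block(B, cc), h)
    n <- nrow(da)
    for (s in seq_len(min(smax, n - 1L))) {
      idx <- cbind(seq_len(n - s), seq_len(n - s) + s)
      x <- da[idx]; y <- db[idx]
      Sx[s] <- Sx[s] + sum(x); Sy[s] <- Sy[s] + sum(y)
      Sxx[s] <- Sxx[s] + sum(x * x); Syy[s] <- Syy[s] + sum(y * y)
      Sxy[s] <- Sxy[s] + sum(x * y); N[s] <- N[s] + length(x)
    }
  }
  ok <- N > 1
  mx <- Sx / N; my <- Sy / N
  v1 <- pmax(Sxx / N - mx^2, 0); v2 <- pmax(Syy / N - my^2, 0)
  cv <- Sxy / N - mx * my
  r <- ifelse(ok & v1 > 0 & v2 > 0, cv / sqrt(v1 * v2), NA_real_)
  sd1 <- sqrt(v1); sd2 <- sqrt(v2)
  w <- ifelse(ok & v1 > 0 & v2 > 0, N * sd1 * sd2, 0)
  if (all(w == 0)) stop("no usable strata (no varying stratum below D)")
  strata <- data.frame(distance = seq_len(nS) * binsize, r = r, N = N,
                       sd1 = sd1, sd2 = sd2, weight = w)
  structure(list(scc = sum(w * r, na.rm = TRUE) / sum(w),
                 strata = strata, h = h, D = D),
            class = "SCCResult")
}

#' @export
print.SCCResult <- function(x, ...) {
  cat("SCC =", format(x$scc, digits = 4), "over",
      sum(x$strata$weight > 0), "strata (h =", x$h, "bins, D =", x$D, "bp)\n")
  invisible(x)
}

#' Pearson correlation between two contact maps
#'
#' Computed over the union of cells that are nonzero in either matrix
#' (absent cells count as 0), intra- plus inter-chromosomal.
#'
#' @param A,B `ContactMatrix` objects on one bin table.
#' @return Pearson correlation coefficient.
#' @export
pearson_matrices <- function(A, B) {
  check_same_bins(A, B)
  n <- nrow(A$bins)
  ka <- (as.numeric(A$entries$i) - 1) * n + A$entries$j
  kb <- (as.numeric(B$entries$i) - 1) * n + B$entries$j
  keys <- union(ka, kb)
  va <- numeric(length(keys)); vb <- numeric(length(keys))
  va[match(ka, keys)] <- A$entries$value
  vb[match(kb, keys)] <- B$entries$value
  if (length(keys) < 2 || stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop("zero variance; Pearson correlation undefined")
  stats::cor(va, vb)
}
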