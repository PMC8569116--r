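#' Per-chromosome log2 ratio map of two contact matrices
#'
#' Computes `log2((A_ij + eps) / (B_ij + eps))` on the dense intra-chromosomal
#' block of each requested chromosome. By convention `A` is the depleted
#' (+IAA) condition and `B` the control, so positive values mean gained
#' contacts upon depletion. Cells where both matrices are zero are reported
#' as `NA` (missing), not 0. Swapping `A` and `B` negates every finite value.
#'
#' @param A,B `ContactMatrix` objects sharing a bin table.
#' @param chrom Chromosome name, or `NULL` for a named list over all
#'   chromosomes.
#' @param pseudocount Pseudocount `eps`; default is the minimum positive
#'   value present in the union of the two requested blocks.
#' @return A dense matrix (or named list of matrices) with attribute
#'   `pseudocount`.
#' @export
log2_ratio_map <- function(A, B, chrom = NULL, pseudocount = NULL) {
  check_same_bins(A, B)
  g <- bin_genome_of(A$bins)
  chroms <- if (is.null(chrom)) g$chroms else chrom
  blocks <- lapply(chroms, function(cc) {
    list(a = cm_dense_block(A, cc), b = cm_dense_block(B, cc))
  })
  eps <- pseudocount
  if (is.null(eps)) {
    pos <- unlist(lapply(blocks, function(bl) {
      c(min_positive(bl$a), min_positive(bl$b))
    }))
    eps <- if (all(is.na(pos))) 1 else min(pos, na.rm = TRUE)
  }
  out <- lapply(blocks, function(bl) {
    r <- log2((bl$a + eps) / (bl$b + eps))
    r[bl$a == 0 & bl$b == 0] <- NA_real_
    attr(r, "pseudocount") <- eps
    r
  })
  if (length(chroms) == 1L) out[[1]] else stats::setNames(out, chroms)
}

min_positive <- function(m) {
  p <- m[m > 0]
  if (length(p)) min(p) else NA_real_
}

check_same_bins <- function(A, B) {
  ba <- A$bins; bb <- B$bins
  if (nrow(ba) != nrow(bb) || bin_binsize(ba) != bin_binsize(bb) ||
      !all(ba$chrom == bb$chrom & ba$start == bb$start))
    stop("matrices do not share a bin table")
  invisible(TRUE)
}

#' Distance strata for contact-probability curves
#'
#' Default stratification: 1-bin granularity up to `linear_limit`, then
#' log-spaced boundaries growing by `ratio` per step.
#'
#' @param binsize Bin size (bp).
#' @param max_s Largest distance to cover (bp).
#' @param linear_limit Distance up to which strata are single bins (bp).
#' @param ratio Multiplicative step beyond `linear_limit`.
#' @return Integer vector of stratum upper boundaries in bins.
#' @export
cp_strata <- function(binsize, max_s, linear_limit = 50000, ratio = 1.12) {
  nmax <- floor(max_s / binsize)
  nlin <- min(floor(linear_limit / binsize), nmax)
  bounds <- seq_len(nlin)
  b <- nlin
  while (b < nmax) {
    b <- min(max(b + 1, ceiling(b * ratio)), nmax)
    bounds <- c(bounds, b)
  }
  unique(bounds)
}

#' Distance-decay contact probability curve
#'
#' Mean contact value per genomic-distance stratum over intra-chromosomal
#' bin pairs; absent entries count as 0 in the mean (the divisor is the full
#' number of pairs at that distance). Distance is measured in bins times the
#' bin size; the diagonal (distance 0) is excluded.
#'
#' @param cm A `ContactMatrix` (raw or balanced).
#' @param scope `"genome"` (all intra-chromosomal pairs pooled) or a
#'   chromosome name.
#' @param strata `"bin"` for 1-bin granularity, or an integer vector of
#'   stratum upper boundaries in bins (see [cp_strata()]); `NULL` uses
#'   [cp_strata()] defaults.
#' @param normalize `"raw-mean"` (stratum means) or `"probability"`
#'   (means rescaled to sum to 1).
#' @return A `DistanceDecayProfile`: data.frame with `distance` (bp, mean
#'   distance of the pairs pooled in the stratum), `value`, `n_pairs`.
#' @export
contact_probability <- function(cm, scope = "genome", strata = NULL,
                                normalize = c("raw-mean", "probability")) {
  normalize <- match.arg(normalize)
  bins <- cm$bins
  binsize <- bin_binsize(bins)
  g <- bin_genome_of(bins)
  chroms <- if (identical(scope, "genome")) g$chroms else scope
  if (!all(chroms %in% g$chroms)) stop("unknown scope: ", scope)
  ncs <- bin_counts(bins)[chroms]
  if (any(ncs < 2)) stop("chromosome shorter than 2 bins in scope")
  smax <- max(ncs) - 1L
  # per-distance totals (absent cells are zeros) and pair counts
  sums <- numeric(smax)
  intra <- cm_intra_entries(cm)
  intra <- intra[intra$chrom %in% chroms & intra$s > 0, , drop = FALSE]
  if (nrow(intra)) {
    a <- rowsum(intra$value, intra$s)
    sums[as.integer(rownames(a))] <- a
  }
  npairs <- vapply(seq_len(smax), function(s) sum(pmax(ncs - s, 0)), 0)
  bounds <- if (is.null(strata)) cp_strata(binsize, smax * binsize)
            else if (identical(strata, "bin")) seq_len(smax)
            else sort(unique(pmin(strata, smax)))
  stratum <- findInterval(seq_len(smax), bounds + 1L) + 1L  # index into bounds
  np <- rowsum(npairs, stratum)
  sv <- rowsum(sums, stratum)
  sd_ <- rowsum(seq_len(smax) * npairs, stratum)  # pair-weighted distance sum
  keep <- np[, 1] > 0
  prof <- data.frame(distance = (sd_[keep, 1] / np[keep, 1]) * binsize,
                     value = sv[keep, 1] / np[keep, 1],
                     n_pairs = np[keep, 1])
  if (normalize == "probability") prof$value <- prof$value / sum(prof$value)
  structure(prof, binsize = binsize, normalize = normalize,
            scope = scope, class = c("DistanceDecayProfile", "data.frame"))
}

#' Log2 ratio of two contact-probability curves
#'
#' @param P_iaa,P_con `DistanceDecayProfile`s on identical strata
#'   (depleted and control).
#' @return data.frame with `distance` and `log2_ratio`; strata where either
#'   curve is 0 are dropped and counted in attribute `n_dropped`.
#' @export
cp_log2_ratio <- function(P_iaa, P_con) {
  if (nrow(P_iaa) != nrow(P_con) ||
      any(abs(P_iaa$distance - P_con$distance) > 1e-9) ||
      any(P_iaa$n_pairs != P_con$n_pairs))
    stop("profiles are not on identical strata")
  ok <- P_iaa$value > 0 & P_con$value > 0
  out <- data.frame(distance = P_iaa$distance[ok],
                    log2_ratio = log2(P_iaa$value[ok] / P_con$value[ok]))
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Short-versus-long (SVL) interaction ratio per chromosome
#'
#' For each chromosome, sums intra-chromosomal contact values at distances
#' `0 < d < L` (short) and `d >= L` (long; a distance of exactly `L` counts
#' as long) and reports their ratio. Chromosomes shorter than `L` get a
#' missing ratio with a warning; a zero long sum with positive short sum
#' yields `Inf` with the `all_short` flag set.
#'
#' @param cm A `ContactMatrix`.
#' @param L Distance threshold in bp (default 100 kb).
#' @return `SVLResult`: data.frame with `chrom`, `short_sum`, `long_sum`,
#'   `ratio`, `all_short`; attribute `L`.
#' @export
svl_ratio <- function(cm, L = 100000) {
  bins <- cm$bins
  binsize <- bin_binsize(bins)
  if (L %% binsize != 0)
    stop("'L' must be a multiple of the bin size")
  g <- bin_genome_of(bins)
  intra <- cm_intra_entries(cm)
  d <- intra$s * binsize
  res <- lapply(g$chroms, function(cc) {
    if (g$lengths[[cc]] < L)
      return(data.frame(chrom = cc, short_sum = NA_real_, long_sum = NA_real_,
                        ratio = NA_real_, all_short = FALSE))
    sel <- intra$chrom == cc
    short <- sum(intra$value[sel & d > 0 & d < L])
    long <- sum(intra$value[sel & d >= L])
    data.frame(chrom = cc, short_sum = short, long_sum = long,
               ratio = if (long > 0) short / long else
                 if (short > 0) Inf else NA_real_,
               all_short = long == 0 && short > 0)
  })
  out <- do.call(rbind, res)
  if (any(is.na(out$ratio) & !out$all_short))
    warning("chromosome(s) shorter than L or without long-range mass: ",
            paste(out$chrom[is.na(out$ratio)], collapse = ", "))
  structure(out, L = L, class = c("SVLResult", "data.frame"))
}

#' One-sided Wilcoxon rank-sum test
#'
#' Exact p-value by enumeration when `n_x + n_y <= 12` and the pooled sample
#' is tie-free; otherwise the normal approximation with tie and continuity
#' correction. The method used is recorded in the result.
#'
#' @param x,y Nonempty numeric samples.
#' @param alternative `"less"` (x tends smaller than y) or `"greater"`.
#' @return List with `p.value`, `statistic` (rank-sum W of `x`), `method`
#'   (`"exact"` or `"normal-approximation"`), `alternative`.
#' @export
wilcoxon_rank_sum <- function(x, y, alternative = c("less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be nonempty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 12) && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative, exact = exact,
                       correct = TRUE)
  )
  list(p.value = unname(ht$p.value), statistic = unname(ht$statistic),
       method = if (exact) "exact" else "normal-approximation",
       alternative = alternative)
}

#' Virtual 4C profile anchored at a centromere
#'
#' Returns the contact value between the bin containing the chromosome's
#' centromere and every bin of that chromosome, in coordinate order — one
#' row of the (symmetric) contact matrix viewed as a profile.
#'
#' @param cm A `ContactMatrix` (typically 5-kb balanced, per the pericentric
#'   profile convention).
#' @param genome A `GenomeModel` with the centromere annotated; defaults to
#'   the genome carried by the bin table.
#' @param chrom Chromosome name.
#' @return data.frame with `start`, `end`, `value` and attribute `anchor_bin`.
#' @export
virtual_4c <- function(cm, chrom, genome = NULL) {
  bins <- cm$bins
  if (is.null(genome)) genome <- bin_genome_of(bins)
  cen_g <- centromere_bin(genome, bins, chrom)
  off <- bin_offsets(bins)[[chrom]]
  block <- cm_dense_block(cm, chrom)
  local <- cen_g - off
  sel <- bins$chrom == chrom
  out <- data.frame(start = bins$start[sel], end = bins$end[sel],
                    value = block[local, ])
  attr(out, "anchor_bin") <- cen_g
  out
}
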