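#' Bin containing a chromosome's point centromere
#'
#' The centromere midpoint is assigned to exactly one bin under the half-open
#' convention: a midpoint on a bin boundary belongs to the bin starting at
#' that coordinate.
#'
#' @param genome A `GenomeModel` with the centromere annotated.
#' @param bins A `BinTable`.
#' @param chrom Chromosome name.
#' @return Global (1-based) bin index of the centromere bin.
#' @export
centromere_bin <- function(genome, bins, chrom) {
  if (is.null(genome$centromeres) || !chrom %in% names(genome$centromeres))
    stop("no centromere annotated for ", chrom)
  locate_bin(bins, chrom, genome$centromeres[[chrom]])
}

#' Aggregate inter CEN-CEN pile-up
#'
#' For every unordered pair of distinct centromere-bearing chromosomes, the
#' inter-chromosomal sub-matrix centred at (centromere bin, centromere bin)
#' and spanning +/- `flank` is extracted, symmetrised by averaging with its
#' transpose, and averaged across pairs cell-wise. Cells extending past a
#' chromosome end are missing for that pair; cell-wise means divide by the
#' per-cell count of contributing pairs, and cells with no contributing pair
#' are `NA`.
#'
#' @param cm A `ContactMatrix` (1-kb balanced matrices are the convention,
#'   given the small size of point centromeres).
#' @param genome A `GenomeModel` with >= 2 centromeres; defaults to the
#'   genome carried by the bin table.
#' @param flank Flanking distance F in bp (default 50 kb).
#' @return A `PileupResult`: list with `window` (square mean-value grid with
#'   odd side `2F/binsize + 1`), `valid_count`, `n_pairs_averaged`, `flank`,
#'   `binsize`.
#' @export
cen_cen_pileup <- function(cm, genome = NULL, flank = 50000) {
  bins <- cm$bins
  if (is.null(genome)) genome <- bin_genome_of(bins)
  cen_chroms <- names(genome$centromeres)
  if (length(cen_chroms) < 2)
    stop("at least 2 annotated centromeres are required")
  binsize <- bin_binsize(bins)
  f <- as.integer(flank %/% binsize)
  side <- 2L * f + 1L
  offs <- bin_offsets(bins)
  ncs <- bin_counts(bins)
  cenbin <- vapply(cen_chroms, function(cc) centromere_bin(genome, bins, cc), 0L)
  # restrict the sparse view to window bins once; remap indices to it
  wanted <- sort(unique(unlist(lapply(cen_chroms, function(cc) {
    r <- cenbin[[cc]] + (-f:f)
    r[r > offs[[cc]] & r <= offs[[cc]] + ncs[[cc]]]
  }))))
  S <- cm_sparse(cm)[wanted, wanted, drop = FALSE]
  remap <- integer(nrow(bins)); remap[wanted] <- seq_along(wanted)
  acc <- matrix(0, side, side)
  cnt <- matrix(0L, side, side)
  pairs <- utils::combn(seq_along(cen_chroms), 2)
  for (p in seq_len(ncol(pairs))) {
    ca <- cen_chroms[pairs[1, p]]; cb <- cen_chroms[pairs[2, p]]
    ra <- cenbin[[ca]] + (-f:f)
    rb <- cenbin[[cb]] + (-f:f)
    ok_a <- ra > offs[[ca]] & ra <= offs[[ca]] + ncs[[ca]]
    ok_b <- rb > offs[[cb]] & rb <= offs[[cb]] + ncs[[cb]]
    block <- as.matrix(S[remap[ra[ok_a]], remap[rb[ok_b]], drop = FALSE])
    w <- matrix(NA_real_, side, side)
    w[ok_a, ok_b] <- block
    w <- (w + t(w)) / 2          # orientation-free estimate
    valid <- !is.na(w)
    acc[valid] <- acc[valid] + w[valid]
    cnt <- cnt + valid
  }
  window <- acc / cnt
  window[cnt == 0L] <- NA_real_
  structure(list(window = window, valid_count = cnt,
                 n_pairs_averaged = ncol(pairs),
                 flank = flank, binsize = binsize),
            class = "PileupResult")
}

#' @export
print.PileupResult <- function(x, ...) {
  cat("PileupResult: ", nrow(x$window), "x", ncol(x$window), " window (+/-",
      x$flank, " bp at ", x$binsize, " bp), ", x$n_pairs_averaged,
      " chromosome pairs averaged\n", sep = "")
  invisible(x)
}

#' Cell-wise log2 ratio of two pile-ups
#'
#' @param P_iaa,P_con `PileupResult`s with equal flank and bin size
#'   (depleted and control).
#' @return Matrix of `log2(iaa / con)`; cells missing in either are `NA`.
#' @export
pileup_log2_ratio <- function(P_iaa, P_con) {
  if (!identical(dim(P_iaa$window), dim(P_con$window)) ||
      P_iaa$flank != P_con$flank || P_iaa$binsize != P_con$binsize)
    stop("pile-ups have mismatched shape")
  log2(P_iaa$window / P_con$window)
}

#' Central window of a pile-up
#'
#' Extracts the `side x side` cells centred on the window centre — the
#' jitter-plot quantification set (25 values for the default side of 5).
#'
#' @param P A `PileupResult`.
#' @param side Odd window side (default 5), at most the pile-up side.
#' @return `CentralWindowStats`: list with `values` (length `side^2`),
#'   `side`, `mean`, `sd`.
#' @export
central_window <- function(P, side = 5) {
  side <- as.integer(side)
  if (side %% 2L == 0L) stop("'side' must be odd")
  full <- nrow(P$window)
  if (side > full) stop("'side' exceeds the pile-up window side")
  c0 <- (full + 1L) %/% 2L
  h <- (side - 1L) %/% 2L
  idx <- (c0 - h):(c0 + h)
  vals <- as.numeric(P$window[idx, idx])
  structure(list(values = vals, side = side,
                 mean = mean(vals, na.rm = TRUE),
                 sd = stats::sd(vals, na.rm = TRUE)),
            class = "CentralWindowStats")
}

#' Compare central-window statistics between conditions
#'
#' Fold change is `mean(control) / mean(depleted)` when testing a depletion
#' (the reported direction is explicit in the result); the p-value comes from
#' a one-sided Wilcoxon rank-sum test on the two value sets.
#'
#' @param S_con,S_iaa `CentralWindowStats` of equal side.
#' @param direction `"depletion"` (tests iaa < con, fold = con/iaa) or
#'   `"enrichment"` (tests iaa > con, fold = iaa/con).
#' @return List with `fold`, `log2_fold`, `p.value`, `direction`, `method`.
#' @export
compare_central_windows <- function(S_con, S_iaa,
                                    direction = c("depletion", "enrichment")) {
  direction <- match.arg(direction)
  if (S_con$side != S_iaa$side) stop("central windows have unequal side")
  if (direction == "depletion") {
    if (S_iaa$mean == 0) stop("zero mean in denominator")
    fold <- S_con$mean / S_iaa$mean
    wt <- wilcoxon_rank_sum(S_iaa$values, S_con$values, "less")
  } else {
    if (S_con$mean == 0) stop("zero mean in denominator")
    fold <- S_iaa$mean / S_con$mean
    wt <- wilcoxon_rank_sum(S_iaa$values, S_con$values, "greater")
  }
  list(fold = fold, log2_fold = log2(fold), p.value = wt$p.value,
       direction = direction, method = wt$method)
}
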