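#' Minimum sequencing depth across matrices
#'
#' Depth equalisation across conditions samples every library down to the
#' shallowest one; this returns that target.
#'
#' @param matrices List of raw `ContactMatrix` objects.
#' @return The minimum total count.
#' @export
min_depth <- function(matrices) {
  if (length(matrices) == 0L) stop("'matrices' must contain at least one matrix")
  min(vapply(matrices, cm_total, 0))
}

#' Downsample a raw contact matrix to an exact total
#'
#' Draws `target_total` read pairs without replacement from the binned counts
#' — an exact multivariate-hypergeometric draw, equivalent to sampling valid
#' pairs before binning. The output total equals `target_total` exactly and
#' no cell exceeds its input count.
#'
#' @param cm Raw `ContactMatrix` with integer values.
#' @param target_total Target total count (<= current total).
#' @param seed Integer seed; the draw is reproducible given the seed.
#' @return A raw `ContactMatrix`.
#' @export
downsample_counts <- function(cm, target_total, seed) {
  stopifnot(inherits(cm, "ContactMatrix"))
  v <- cm$entries$value
  if (any(v != round(v)))
    stop("downsampling requires integer counts (raw matrix)")
  total <- sum(v)
  if (target_total > total)
    stop("target_total (", target_total, ") exceeds the matrix total (",
         total, ")")
  if (target_total == total) return(cm)
  set.seed(seed)
  # positions 1..total partition into per-cell segments; an SRSWOR of
  # positions induces the multivariate-hypergeometric cell counts
  pos <- sample.int(total, target_total)
  cum <- cumsum(v)
  cell <- findInterval(pos - 0.5, cum) + 1L
  cnt <- tabulate(cell, nbins = length(v))
  keep <- cnt > 0L
  contact_matrix(cm$bins, cm$entries$i[keep], cm$entries$j[keep],
                 cnt[keep], kind = "raw")
}

# full-symmetric row sums: each off-diagonal entry contributes to both bins,
# the diagonal once (optionally excluded)
cm_marginals <- function(entries, n, bias = NULL, include_diagonal = TRUE) {
  v <- entries$value
  if (!is.null(bias)) v <- v / (bias[entries$i] * bias[entries$j])
  if (!include_diagonal) v[entries$i == entries$j] <- 0
  m <- numeric(n)
  a <- rowsum(v, entries$i)
  m[as.integer(rownames(a))] <- a
  off <- entries$i != entries$j
  if (any(off)) {
    b <- rowsum(v[off], entries$j[off])
    idx <- as.integer(rownames(b))
    m[idx] <- m[idx] + b
  }
  m
}

#' ICE iterative matrix balancing
#'
#' Iterative correction equalises per-bin marginals via multiplicative biases:
#' the lowest `low_coverage_fraction` share of bins by raw marginal, and any
#' zero-marginal bin, are masked; then `b_i <- b_i * m_i / mean(m)` with
#' `m_i` the current bias-corrected marginal, until the coefficient of
#' variation of unmasked marginals drops below `tol` or `max_iter` is
#' reached. Balanced values are `raw_ij / (b_i * b_j)`, rescaled so the mean
#' of stored unmasked balanced values is 1.
#'
#' @param cm Symmetric nonnegative `ContactMatrix`.
#' @param max_iter Maximum iterations (default 200).
#' @param tol Convergence tolerance on the marginal CV (default 1e-5).
#' @param low_coverage_fraction Fraction of lowest-coverage bins to mask
#'   (default 0.02).
#' @param include_diagonal Whether diagonal entries participate in marginals
#'   (default TRUE, as in HiC-Pro's ICE).
#' @return List with `matrix` (balanced `ContactMatrix`, masked bins dropped),
#'   `bias` (list `values` with NA at masked bins, `mask` of masked indices),
#'   `converged`, `n_iter`, and final `cv`. Non-convergence is reported with
#'   a warning; the result is still returned.
#' @export
ice_balance <- function(cm, max_iter = 200, tol = 1e-5,
                        low_coverage_fraction = 0.02,
                        include_diagonal = TRUE) {
  stopifnot(inherits(cm, "ContactMatrix"))
  n <- nrow(cm$bins)
  e <- cm$entries
  raw_marg <- cm_marginals(e, n, include_diagonal = include_diagonal)
  # mask the floor(frac * n) lowest-coverage bins, plus any zero-marginal bin
  k <- floor(low_coverage_fraction * n)
  mask <- raw_marg == 0
  if (k > 0) mask[order(raw_marg)[seq_len(k)]] <- TRUE
  if (all(mask)) stop("all bins masked; nothing to balance")
  keep_entry <- !(mask[e$i] | mask[e$j])
  eu <- e[keep_entry, , drop = FALSE]
  b <- rep(1, n)
  converged <- FALSE
  iter <- 0L
  cv <- Inf
  while (iter < max_iter) {
    iter <- iter + 1L
    m <- cm_marginals(eu, n, bias = b, include_diagonal = include_diagonal)
    mu <- m[!mask]
    mbar <- mean(mu)
    cv <- stats::sd(mu) / mbar
    if (is.finite(cv) && cv < tol) { converged <- TRUE; break }
    b[!mask] <- b[!mask] * mu / mbar
  }
  if (!converged)
    warning("ICE did not converge in ", max_iter, " iterations (cv = ",
            signif(cv, 3), ")")
  bal <- eu$value / (b[eu$i] * b[eu$j])
  scale <- mean(bal)
  bal <- bal / scale
  b <- b * sqrt(scale)
  b[mask] <- NA_real_
  list(matrix = contact_matrix(cm$bins, eu$i, eu$j, bal, kind = "balanced"),
       bias = structure(list(values = b, mask = which(mask)),
                        class = "BiasVector"),
       converged = converged, n_iter = iter, cv = cv)
}
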