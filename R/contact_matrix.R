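#' Construct a contact matrix
#'
#' A `ContactMatrix` is a genome-wide, symmetric-by-contract sparse contact
#' map: entries are stored on the upper triangle (`i <= j` after folding) over
#' the single global bin index space of a `BinTable`, so intra- and
#' inter-chromosomal queries use one structure. Values are raw counts or
#' balanced (ICE-corrected) reals.
#'
#' @param bins A `BinTable` from [bin_genome()].
#' @param i,j Global bin indices (1-based). Pairs with `i > j` are swapped.
#' @param value Nonnegative contact values.
#' @param kind `"raw"` (counts) or `"balanced"`.
#' @return A `ContactMatrix`.
#' @export
contact_matrix <- function(bins, i, j, value, kind = c("raw", "balanced")) {
  kind <- match.arg(kind)
  stopifnot(inherits(bins, "BinTable"))
  n <- nrow(bins)
  i <- as.integer(i); j <- as.integer(j); value <- as.numeric(value)
  if (length(i) != length(j) || length(i) != length(value))
    stop("'i', 'j' and 'value' must have equal length")
  if (length(i)) {
    if (any(is.na(i) | is.na(j)) || any(i < 1L | i > n | j < 1L | j > n))
      stop("bin index out of range 1..", n)
    if (any(!is.finite(value)) || any(value < 0))
      stop("contact values must be finite and nonnegative")
    sw <- i > j
    if (any(sw)) { tmp <- i[sw]; i[sw] <- j[sw]; j[sw] <- tmp }
    key <- (as.numeric(i) - 1) * n + as.numeric(j)
    if (anyDuplicated(key))
      stop("duplicate (i, j) coordinates after upper-triangle folding")
    o <- order(i, j)
    i <- i[o]; j <- j[o]; value <- value[o]
  }
  structure(list(bins = bins,
                 entries = data.frame(i = i, j = j, value = value),
                 kind = kind),
            class = "ContactMatrix")
}

#' @export
print.ContactMatrix <- function(x, ...) {
  cat("ContactMatrix (", x$kind, "): ", nrow(x$bins), " bins @ ",
      format(bin_binsize(x$bins), big.mark = ","), " bp, ",
      nrow(x$entries), " stored entries, total ",
      format(cm_total(x), big.mark = ","), "\n", sep = "")
  invisible(x)
}

#' Total contact mass of a matrix
#' @param cm A `ContactMatrix`.
#' @return Sum of all stored values (upper triangle, diagonal once).
#' @export
cm_total <- function(cm) sum(cm$entries$value)

# genome-wide symmetric sparse view (dgCMatrix)
cm_sparse <- function(cm) {
  n <- nrow(cm$bins)
  e <- cm$entries
  off <- e$i != e$j
  Matrix::sparseMatrix(i = c(e$i, e$j[off]), j = c(e$j, e$i[off]),
                       x = c(e$value, e$value[off]), dims = c(n, n))
}

# dense symmetric intra-chromosomal block
cm_dense_block <- function(cm, chrom) {
  bins <- cm$bins
  off <- bin_offsets(bins)[[chrom]]
  nc <- bin_counts(bins)[[chrom]]
  e <- cm$entries
  keep <- e$i > off & e$i <= off + nc & e$j > off & e$j <= off + nc
  m <- matrix(0, nc, nc)
  if (any(keep)) {
    ii <- e$i[keep] - off; jj <- e$j[keep] - off; v <- e$value[keep]
    m[cbind(ii, jj)] <- v
    lower <- ii != jj
    m[cbind(jj[lower], ii[lower])] <- v[lower]
  }
  m
}

# entries restricted to intra-chromosomal pairs, annotated with chrom and
# distance in bins
cm_intra_entries <- function(cm) {
  bins <- cm$bins
  g <- bin_genome_of(bins)
  off <- bin_offsets(bins)
  n <- bin_counts(bins)
  e <- cm$entries
  ci <- findInterval(e$i, cumsum(c(0, n)) + 1)
  cj <- findInterval(e$j, cumsum(c(0, n)) + 1)
  keep <- ci == cj
  data.frame(chrom = g$chroms[ci[keep]],
             i = e$i[keep], j = e$j[keep], value = e$value[keep],
             s = e$j[keep] - e$i[keep])
}

#' Rebin a contact matrix to a coarser resolution
#'
#' Coarse values are sums of their constituent fine values, so the total
#' contact mass is conserved exactly. `factor = 1` is the identity.
#'
#' @param cm A `ContactMatrix`.
#' @param factor Integer rebinning factor (>= 1).
#' @return A `ContactMatrix` on the coarser `BinTable`.
#' @export
rebin <- function(cm, factor) {
  stopifnot(inherits(cm, "ContactMatrix"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("'factor' must be a positive integer")
  if (factor == 1L) return(cm)
  bins <- cm$bins
  g <- bin_genome_of(bins)
  coarse <- bin_genome(g, bin_binsize(bins) * factor)
  # map each fine bin to its coarse bin
  offc <- bin_offsets(coarse)
  map <- offc[match(bins$chrom, names(offc))] +
    bins$start %/% bin_binsize(coarse) + 1
  e <- cm$entries
  ni <- map[e$i]; nj <- map[e$j]
  sw <- ni > nj
  if (any(sw)) { tmp <- ni[sw]; ni[sw] <- nj[sw]; nj[sw] <- tmp }
  nb <- nrow(coarse)
  key <- (ni - 1) * nb + nj
  agg <- rowsum(e$value, key)
  k <- as.numeric(rownames(agg))
  contact_matrix(coarse,
                 i = (k - 1) %/% nb + 1, j = (k - 1) %% nb + 1,
                 value = as.numeric(agg), kind = cm$kind)
}
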