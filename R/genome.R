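#' Build a genome model
#'
#' A `GenomeModel` is the coordinate frame for everything else in the package:
#' an ordered set of chromosomes with lengths, plus (optionally) the midpoint
#' position of each point centromere. S. cerevisiae centromeres are ~120 bp,
#' so a single midpoint per chromosome is an adequate representation at the
#' 1-kb and 5-kb resolutions used throughout.
#'
#' @param chroms Character vector of chromosome names (unique, ordered).
#' @param lengths Numeric vector of chromosome lengths in base pairs (> 0).
#' @param centromeres Optional named numeric vector of centromere midpoint
#'   positions (bp, 0-based); names must be a subset of `chroms` and each
#'   midpoint must lie in `[0, length)`.
#' @return An object of class `GenomeModel`.
#' @export
#' @examples
#' genome_model(c("chrA", "chrB"), c(200000, 150000),
#'              centromeres = c(chrA = 100000, chrB = 60000))
genome_model <- function(chroms, lengths, centromeres = NULL) {
  chroms <- as.character(chroms)
  lengths <- as.numeric(lengths)
  if (length(chroms) == 0L) stop("at least one chromosome is required")
  if (length(chroms) != length(lengths))
    stop("'chroms' and 'lengths' must have the same length")
  if (anyDuplicated(chroms)) stop("chromosome names must be unique")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("all chromosome lengths must be positive")
  if (!is.null(centromeres)) {
    centromeres <- unlist(centromeres)
    if (is.null(names(centromeres)) || any(names(centromeres) == ""))
      stop("'centromeres' must be a named vector")
    bad <- setdiff(names(centromeres), chroms)
    if (length(bad))
      stop("centromere(s) for unknown chromosome(s): ", paste(bad, collapse = ", "))
    len <- lengths[match(names(centromeres), chroms)]
    if (any(centromeres < 0 | centromeres >= len))
      stop("centromere midpoints must lie in [0, chromosome length)")
    centromeres <- centromeres[order(match(names(centromeres), chroms))]
  }
  structure(
    list(chroms = chroms, lengths = stats::setNames(lengths, chroms),
         centromeres = centromeres),
    class = "GenomeModel"
  )
}

#' @export
print.GenomeModel <- function(x, ...) {
  cat("GenomeModel:", length(x$chroms), "chromosomes,",
      format(sum(x$lengths), big.mark = ","), "bp total;",
      length(x$centromeres), "centromeres annotated\n")
  invisible(x)
}

#' Read a two-column chromosome-sizes table
#'
#' @param path Path to a TSV with columns name, length (no header).
#' @return A data.frame with columns `chrom`, `length`.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop("chrom.sizes file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  df
}

#' Read centromere midpoints from a BED file
#'
#' The midpoint of each interval (floor of the interval centre) is taken as
#' the point-centromere position.
#'
#' @param path BED file (chrom, start, end, optional name), 0-based half-open.
#' @return Named numeric vector of midpoints keyed by chromosome.
#' @export
read_centromeres_bed <- function(path) {
  bed <- read_bed(path)
  stats::setNames(floor((bed$start + bed$end) / 2), bed$chrom)
}

#' The bundled sacCer3 genome model
#'
#' Chromosome lengths and point-centromere midpoints for the 16 nuclear
#' chromosomes of the sacCer3 S. cerevisiae reference assembly, shipped as
#' plain-text fixtures and overridable everywhere a genome is accepted.
#'
#' @return A `GenomeModel` with 16 chromosomes and centromeres.
#' @export
sacCer3_genome <- function() {
  sizes <- read_chrom_sizes(system.file("extdata", "sacCer3.chrom.sizes",
                                        package = "rablhic", mustWork = TRUE))
  cen <- read_centromeres_bed(system.file("extdata", "sacCer3.centromeres.bed",
                                          package = "rablhic", mustWork = TRUE))
  genome_model(sizes$chrom, sizes$length, centromeres = cen)
}

#' A small four-chromosome demo genome
#'
#' Four chromosomes of 200-900 kb with mid-arm centromeres; used for fast
#' examples and tests where the full 16-chromosome model is unnecessary.
#'
#' @return A `GenomeModel`.
#' @export
demo_genome <- function() {
  genome_model(
    c("chrA", "chrB", "chrC", "chrD"),
    c(200000, 400000, 650000, 900000),
    centromeres = c(chrA = 100500, chrB = 150500, chrC = 300500, chrD = 450500)
  )
}

#' Partition a genome into fixed-width bins
#'
#' Each chromosome is tiled with half-open `[start, end)` intervals of width
#' `binsize`; the final partial bin is truncated at the chromosome end, so a
#' chromosome of length L yields `ceiling(L / binsize)` bins. Global bin
#' indices are 1-based and contiguous in genome order.
#'
#' @param genome A `GenomeModel`.
#' @param binsize Bin width in bp (>= 1).
#' @return A `BinTable`: data.frame with columns `chrom`, `start`, `end`,
#'   `bin` plus attributes `binsize` and `genome`.
#' @export
bin_genome <- function(genome, binsize) {
  stopifnot(inherits(genome, "GenomeModel"))
  if (!is.numeric(binsize) || length(binsize) != 1L || binsize < 1)
    stop("'binsize' must be a single positive number")
  binsize <- as.numeric(binsize)
  per <- lapply(seq_along(genome$chroms), function(k) {
    len <- genome$lengths[[k]]
    n <- ceiling(len / binsize)
    start <- (seq_len(n) - 1) * binsize
    data.frame(chrom = genome$chroms[k], start = start,
               end = pmin(start + binsize, len))
  })
  bins <- do.call(rbind, per)
  bins$bin <- seq_len(nrow(bins))
  rownames(bins) <- NULL
  structure(bins, binsize = binsize, genome = genome,
            class = c("BinTable", "data.frame"))
}

bin_binsize <- function(bins) attr(bins, "binsize", exact = TRUE)
bin_genome_of <- function(bins) attr(bins, "genome", exact = TRUE)

# first global bin index minus one, per chromosome
bin_offsets <- function(bins) {
  g <- bin_genome_of(bins)
  n <- ceiling(g$lengths / bin_binsize(bins))
  stats::setNames(cumsum(c(0, n[-length(n)])), g$chroms)
}

bin_counts <- function(bins) {
  g <- bin_genome_of(bins)
  stats::setNames(ceiling(g$lengths / bin_binsize(bins)), g$chroms)
}

#' Locate the bin containing a genomic position
#'
#' @param bins A `BinTable`.
#' @param chrom Chromosome name.
#' @param pos Position(s) in bp, `0 <= pos < chromosome length`.
#' @return Global (1-based) bin index/indices.
#' @export
locate_bin <- function(bins, chrom, pos) {
  g <- bin_genome_of(bins)
  if (!chrom %in% g$chroms) stop("unknown chromosome: ", chrom)
  len <- g$lengths[[chrom]]
  if (any(pos < 0 | pos >= len))
    stop("position out of range [0, ", len, ") on ", chrom)
  as.integer(bin_offsets(bins)[[chrom]] + pos %/% bin_binsize(bins) + 1)
}

#' Read a BED annotation file
#'
#' Intervals are kept 0-based half-open; absent name/score columns are filled
#' with NA. Used for CAR/peak annotations consumed as plain intervals.
#'
#' @param path Path to a BED3+ file (tab-separated, `#`/track lines ignored).
#' @return data.frame with columns `chrom`, `start`, `end`, `name`, `score`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      name = character(), score = numeric()))
  fields <- strsplit(lines, "\t| +")
  ncol <- min(lengths(fields))
  if (ncol < 3) stop("malformed BED: fewer than 3 columns")
  df <- data.frame(
    chrom = vapply(fields, `[[`, "", 1L),
    start = as.numeric(vapply(fields, `[[`, "", 2L)),
    end = as.numeric(vapply(fields, `[[`, "", 3L)),
    name = if (ncol >= 4) vapply(fields, `[[`, "", 4L) else NA_character_,
    score = if (ncol >= 5) as.numeric(vapply(fields, `[[`, "", 5L)) else NA_real_
  )
  if (any(is.na(df$start) | is.na(df$end)) || any(df$end < df$start))
    stop("malformed BED intervals in ", path)
  df
}

#' Write intervals as BED
#' @param x data.frame with columns chrom, start, end and optionally name, score.
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score"), names(x))
  utils::write.table(x[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
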