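#' Read a HiC-Pro-style sparse triplet matrix
#'
#' The triplet file holds whitespace-separated `(index1, index2, value)`
#' records; the companion bin BED holds `(chrom, start, end, index)` rows
#' defining the binning. Entries are folded to the upper triangle
#' (`i <= j`); duplicate coordinates after folding are an error reported with
#' their line numbers. Self-interactions (`i == j`) are retained.
#'
#' Whether triplet indices are 0- or 1-based varies between pipelines;
#' `index_base` (default 1, the HiC-Pro convention) controls the conversion
#' to the package's internal 1-based global indices.
#'
#' @param matrix_path Path to the `.matrix` triplet file.
#' @param bins_path Path to the companion bin BED; ignored if `bins` is given.
#' @param bins Optional `BinTable` to use directly.
#' @param index_base 0 or 1: base of the indices in the files.
#' @param kind `"raw"` or `"balanced"`.
#' @param genome Optional `GenomeModel`; when reconstructing the bin table
#'   from the bin BED this supplies centromeres (lengths are cross-checked).
#' @return A `ContactMatrix`.
#' @export
read_sparse_matrix <- function(matrix_path, bins_path = NULL, bins = NULL,
                               index_base = 1, kind = c("raw", "balanced"),
                               genome = NULL) {
  kind <- match.arg(kind)
  if (is.null(bins)) {
    if (is.null(bins_path)) stop("either 'bins' or 'bins_path' is required")
    bins <- read_bin_bed(bins_path, index_base = index_base, genome = genome)
  }
  if (!file.exists(matrix_path)) stop("matrix file not found: ", matrix_path)
  dt <- tryCatch(
    data.table::fread(matrix_path, header = FALSE,
                      col.names = c("i", "j", "value")),
    error = function(e) stop("malformed triplet file ", matrix_path, ": ",
                             conditionMessage(e))
  )
  if (nrow(dt) == 0L)
    return(contact_matrix(bins, integer(), integer(), numeric(), kind = kind))
  if (!is.numeric(dt$i) || !is.numeric(dt$j) || !is.numeric(dt$value))
    stop("malformed triplet file ", matrix_path, ": non-numeric fields")
  if (any(dt$value < 0)) {
    bad <- which(dt$value < 0)[1]
    stop("negative value at line ", bad, " of ", matrix_path)
  }
  n <- nrow(bins)
  i <- dt$i + (1L - as.integer(index_base))
  j <- dt$j + (1L - as.integer(index_base))
  if (any(i < 1 | i > n | j < 1 | j > n)) {
    bad <- which(i < 1 | i > n | j < 1 | j > n)[1]
    stop("bin index outside the bin table at line ", bad, " of ", matrix_path)
  }
  ii <- pmin(i, j); jj <- pmax(i, j)
  key <- (as.numeric(ii) - 1) * n + as.numeric(jj)
  if (anyDuplicated(key)) {
    d <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
    stop("duplicate coordinates after upper-triangle folding at lines ",
         paste(utils::head(d, 10), collapse = ", "), " of ", matrix_path)
  }
  contact_matrix(bins, ii, jj, dt$value, kind = kind)
}

#' Write a contact matrix as triplets plus a bin BED
#'
#' @param cm A `ContactMatrix`.
#' @param matrix_path Output triplet path.
#' @param bins_path Output bin BED path (optional).
#' @param index_base 0 or 1: base of the written indices (default 1).
#' @export
write_sparse_matrix <- function(cm, matrix_path, bins_path = NULL,
                                index_base = 1) {
  shift <- as.integer(index_base) - 1L
  e <- cm$entries
  data.table::fwrite(
    data.frame(i = e$i + shift, j = e$j + shift, value = e$value),
    matrix_path, sep = "\t", col.names = FALSE
  )
  if (!is.null(bins_path)) write_bin_bed(cm$bins, bins_path, index_base)
  invisible(matrix_path)
}

#' Read a bin BED into a BinTable
#' @param path Bin BED path (chrom, start, end, index).
#' @param index_base Base of the index column.
#' @param genome Optional `GenomeModel` supplying centromeres.
#' @return A `BinTable`.
#' @export
read_bin_bed <- function(path, index_base = 1, genome = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE)
  if (ncol(df) < 4) stop("bin BED must have 4 columns (chrom,start,end,index)")
  names(df)[1:4] <- c("chrom", "start", "end", "index")
  df <- df[order(df$index), ]
  chroms <- unique(df$chrom)
  lengths <- vapply(chroms, function(c) max(df$end[df$chrom == c]), 0)
  cen <- NULL
  if (!is.null(genome)) {
    if (!all(chroms %in% genome$chroms))
      stop("bin BED names chromosomes absent from the supplied genome")
    mism <- lengths != genome$lengths[chroms]
    if (any(mism))
      stop("bin BED chromosome length disagrees with genome for: ",
           paste(chroms[mism], collapse = ", "))
    cen <- genome$centromeres[names(genome$centromeres) %in% chroms]
  }
  g <- genome_model(chroms, lengths, centromeres = cen)
  binsize <- max(df$end - df$start)
  bins <- bin_genome(g, binsize)
  if (nrow(bins) != nrow(df) ||
      !all(bins$chrom == df$chrom & bins$start == df$start & bins$end == df$end))
    stop("bin BED does not describe a contiguous fixed-width binning")
  bins
}

write_bin_bed <- function(bins, path, index_base = 1) {
  shift <- as.integer(index_base) - 1L
  utils::write.table(
    data.frame(bins$chrom, bins$start, bins$end, bins$bin + shift),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export bin-pair interactions as BEDPE
#'
#' One record per interaction with coordinates taken from the bin table,
#' 0-based half-open. Inter-chromosomal pairs are permitted. An empty input
#' produces a valid file holding only the header comment.
#'
#' @param x data.frame with global bin index columns `i`, `j`, an optional
#'   `name`, and a score column (`score`, or the first remaining numeric
#'   column).
#' @param bins A `BinTable`.
#' @param path Output path.
#' @param score_col Name of the column written as the BEDPE score.
#' @export
export_bedpe <- function(x, bins, path, score_col = "score") {
  header <- "#chrom1\tstart1\tend1\tchrom2\tstart2\tend2\tname\tscore"
  if (nrow(x) == 0L) { writeLines(header, path); return(invisible(path)) }
  n <- nrow(bins)
  if (any(x$i < 1 | x$i > n | x$j < 1 | x$j > n))
    stop("bin index outside the bin table")
  if (!score_col %in% names(x)) stop("no '", score_col, "' column to export")
  name <- if ("name" %in% names(x)) x$name else
    paste0("interaction_", seq_len(nrow(x)))
  rec <- data.frame(
    chrom1 = bins$chrom[x$i], start1 = bins$start[x$i], end1 = bins$end[x$i],
    chrom2 = bins$chrom[x$j], start2 = bins$start[x$j], end2 = bins$end[x$j],
    name = name, score = x[[score_col]]
  )
  writeLines(header, path)
  utils::write.table(rec, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE, append = TRUE)
  invisible(path)
}

#' Read a BEDPE file
#' @param path BEDPE path (header comments ignored).
#' @param bins Optional `BinTable`; when given, global bin indices `i`, `j`
#'   are attached.
#' @return data.frame with the six coordinates, `name`, `score` (and `i`, `j`).
#' @export
read_bedpe <- function(path, bins = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L)
    return(data.frame(chrom1 = character(), start1 = numeric(), end1 = numeric(),
                      chrom2 = character(), start2 = numeric(), end2 = numeric(),
                      name = character(), score = numeric()))
  df <- utils::read.table(text = lines, sep = "\t", header = FALSE)
  names(df)[1:6] <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  df$name <- if (ncol(df) >= 7) as.character(df[[7]]) else NA_character_
  df$score <- if (ncol(df) >= 8) as.numeric(df[[8]]) else NA_real_
  df <- df[, c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
               "name", "score")]
  if (!is.null(bins)) {
    df$i <- mapply(function(c, p) locate_bin(bins, c, p), df$chrom1, df$start1)
    df$j <- mapply(function(c, p) locate_bin(bins, c, p), df$chrom2, df$start2)
  }
  df
}

#' Write a results table as TSV with a header
#' @param x data.frame.
#' @param path Output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
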