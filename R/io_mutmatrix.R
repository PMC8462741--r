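#' Read an amplicon reference sequence
#'
#' Reads the first record of a FASTA file and returns it as an uppercase
#' reference sequence. Position 1 is the first base of the amplicon; all
#' coordinates in this package are 1-based and inclusive, relative to this
#' reference.
#'
#' @param path Path to a FASTA file with at least one record.
#' @return An object of class `bar_reference`: a list with elements `id`,
#'   `bases` (uppercase DNA string) and `length`.
#' @export
read_reference <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) {
    stop("empty FASTA: no records in ", path)
  }
  bases <- toupper(as.character(seqs[[1L]]))
  if (grepl("[^ACGTN]", bases)) {
    stop("reference contains characters other than A/C/G/T/N")
  }
  if (nchar(bases) == 0L) {
    stop("empty FASTA: first record has zero length")
  }
  structure(
    list(id = sub("\\s.*$", "", names(seqs)[1L]),
         bases = bases,
         length = nchar(bases)),
    class = "bar_reference"
  )
}

#' @export
print.bar_reference <- function(x, ...) {
  cat("Amplicon reference '", x$id, "': ", x$length, " bp\n", sep = "")
  invisible(x)
}

#' Construct a binary mutation matrix
#'
#' Low-level constructor validating the core container of this package: a
#' molecules-by-sites binary matrix of conversion calls at informative sites
#' (reference C positions on the top strand, reference G positions -- i.e. C
#' on the bottom strand -- for the bottom strand), in top-strand amplicon
#' coordinates.
#'
#' @param calls Binary matrix (S sequences x N sites), values 0/1.
#' @param positions Strictly increasing 1-based amplicon coordinates of the
#'   informative sites (one per column of `calls`).
#' @param strand `"top"` or `"bottom"`.
#' @param seq_ids Optional per-row sequence identifiers.
#' @param weights Optional per-sequence duplicate counts (default 1); used to
#'   weight all downstream counts.
#' @return An object of class `mutation_matrix`.
#' @export
mutation_matrix <- function(calls, positions, strand = c("top", "bottom"),
                            seq_ids = NULL, weights = NULL) {
  strand <- match.arg(strand)
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (ncol(calls) != length(positions)) {
    stop("number of columns of 'calls' must equal length of 'positions'")
  }
  if (length(positions) > 0 && any(diff(positions) <= 0)) {
    stop("'positions' must be strictly increasing")
  }
  if (length(calls) > 0 && !all(calls %in% c(0L, 1L))) {
    stop("'calls' must be binary (0/1)")
  }
  if (is.null(seq_ids)) {
    seq_ids <- paste0("seq", seq_len(nrow(calls)), recycle0 = TRUE)
  }
  if (is.null(weights)) weights <- rep(1, nrow(calls))
  if (length(seq_ids) != nrow(calls) || length(weights) != nrow(calls)) {
    stop("'seq_ids' and 'weights' must have one entry per sequence")
  }
  if (any(weights < 1)) stop("'weights' must be >= 1")
  dimnames(calls) <- list(seq_ids, as.character(positions))
  structure(
    list(strand = strand, positions = as.integer(positions), calls = calls,
         seq_ids = as.character(seq_ids), weights = as.numeric(weights)),
    class = "mutation_matrix"
  )
}

#' @export
print.mutation_matrix <- function(x, ...) {
  cat("Mutation matrix (", x$strand, " strand): ",
      nrow(x$calls), " sequences (", sum(x$weights), " weighted) x ",
      length(x$positions), " informative sites\n", sep = "")
  invisible(x)
}

#' Build a strand-specific mutation matrix from aligned reads
#'
#' Converts equal-length, reference-aligned amplicon reads (gap-free UMI
#' consensuses) into a binary conversion-call matrix. On the top strand the
#' informative sites are reference C positions and a call is 1 iff the read
#' base is T (C>T conversion); on the bottom strand the informative sites are
#' reference G positions (C on the bottom strand) and a call is 1 iff the
#' read base is A (G>A in top-strand orientation). Any other substitution at
#' an informative site, and any N, scores 0; per-site N counts are kept in a
#' missingness report.
#'
#' Reads whose length differs from the reference are dropped with a warning;
#' reads containing characters outside A/C/G/T/N are dropped and counted.
#'
#' @param reads Path to a FASTA file of aligned reads, or a
#'   [Biostrings::DNAStringSet].
#' @param ref A `bar_reference` from [read_reference()].
#' @param strand `"top"` or `"bottom"`.
#' @param weights Optional named vector of duplicate counts, indexed by read
#'   id (default 1 per read).
#' @return A `mutation_matrix` with attributes `report` (dropped-read counts)
#'   and `n_missing` (per-site N counts).
#' @export
build_mutation_matrix <- function(reads, ref, strand = c("top", "bottom"),
                                  weights = NULL) {
  strand <- match.arg(strand)
  stopifnot(inherits(ref, "bar_reference"))
  if (is.character(reads)) reads <- Biostrings::readDNAStringSet(reads)
  if (length(reads) == 0L) stop("empty FASTA: no reads")
  ids <- sub("\\s.*$", "", names(reads))
  seq_chr <- toupper(as.character(reads))

  ref_base <- if (strand == "top") "C" else "G"
  conv_base <- if (strand == "top") "T" else "A"
  ref_chars <- strsplit(ref$bases, "")[[1L]]
  positions <- which(ref_chars == ref_base)
  if (length(positions) == 0L) {
    stop("zero informative sites: reference has no ", ref_base,
         " for the ", strand, " strand")
  }

  ok_len <- nchar(seq_chr) == ref$length
  if (!all(ok_len)) {
    warning(sum(!ok_len), " read(s) with length != ", ref$length, " dropped")
  }
  ok_alpha <- !grepl("[^ACGTN]", seq_chr)
  n_bad_alpha <- sum(ok_len & !ok_alpha)
  keep <- ok_len & ok_alpha
  if (!any(keep)) stop("no reads left after filtering")

  seq_chr <- seq_chr[keep]
  ids <- ids[keep]
  base_mat <- matrix(unlist(strsplit(seq_chr, ""), use.names = FALSE),
                     nrow = length(seq_chr), byrow = TRUE)
  at_sites <- base_mat[, positions, drop = FALSE]
  calls <- (at_sites == conv_base) + 0L

  w <- rep(1, length(ids))
  if (!is.null(weights)) {
    hit <- ids %in% names(weights)
    w[hit] <- as.numeric(weights[ids[hit]])
  }
  m <- mutation_matrix(calls, positions, strand, seq_ids = ids, weights = w)
  attr(m, "report") <- c(dropped_length = sum(!ok_len),
                         dropped_alphabet = n_bad_alpha)
  attr(m, "n_missing") <- colSums(at_sites == "N")
  m
}

#' Per-site and overall conversion frequencies
#'
#' @param matrix A `mutation_matrix`.
#' @return A list with `per_site` (weighted conversion frequency at each
#'   informative site) and `overall` (total weighted converted calls over
#'   weighted sequences times sites).
#' @export
mutation_rate <- function(matrix) {
  stopifnot(inherits(matrix, "mutation_matrix"))
  if (nrow(matrix$calls) < 1L) stop("no sequences")
  n <- sum(matrix$weights)
  x <- as.numeric(crossprod(matrix$weights, matrix$calls))
  list(per_site = stats::setNames(x / n, matrix$positions),
       overall = sum(x) / (n * length(matrix$positions)))
}

#' Collapse a mutation matrix to weighted per-site counts
#'
#' Summing the binary calls over molecules gives, at each informative site, a
#' binomial count x_t out of n (the weighted number of molecules) -- the
#' sufficient statistics consumed by the segmentation model.
#'
#' @param matrix A `mutation_matrix`.
#' @return A `site_counts` object.
#' @export
to_site_counts <- function(matrix) {
  stopifnot(inherits(matrix, "mutation_matrix"))
  if (nrow(matrix$calls) == 0L) stop("no sequences")
  x <- as.numeric(crossprod(matrix$weights, matrix$calls))
  site_counts(matrix$positions, x, sum(matrix$weights))
}

#' Per-site binomial counts
#'
#' @param positions Strictly increasing informative-site coordinates.
#' @param x Weighted converted counts per site (real-valued counts are
#'   allowed, e.g. after [scale_counts()]).
#' @param n Total weighted sequence count (scalar; the binomial size shared
#'   by all sites).
#' @return An object of class `site_counts`.
#' @export
site_counts <- function(positions, x, n) {
  if (length(x) != length(positions)) {
    stop("'x' and 'positions' must have equal length")
  }
  if (length(positions) > 1 && any(diff(positions) <= 0)) {
    stop("'positions' must be strictly increasing")
  }
  if (length(n) != 1 || n <= 0) stop("'n' must be a positive scalar")
  if (any(x < 0) || any(x > n)) stop("counts must satisfy 0 <= x <= n")
  structure(list(positions = as.numeric(positions), x = as.numeric(x),
                 n = as.numeric(n)),
            class = "site_counts")
}

#' @export
print.site_counts <- function(x, ...) {
  cat("Site counts: ", length(x$positions), " sites, n = ", x$n, "\n",
      sep = "")
  invisible(x)
}

#' Write a mutation matrix as TSV
#'
#' Format of the supplementary-style matrices: a comment header stating the
#' coordinate convention and strand, then a header row `seq_id` followed by
#' the 1-based site positions, then one 0/1 row per sequence.
#'
#' @param matrix A `mutation_matrix`.
#' @param path Output path.
#' @export
write_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "mutation_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# binary conversion-call matrix; coordinates are 1-based inclusive amplicon positions",
    paste0("# strand: ", matrix$strand)), con)
  df <- data.frame(seq_id = matrix$seq_ids, matrix$calls,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a mutation matrix from TSV
#'
#' @param path Path written by [write_matrix()] (or any TSV with a `seq_id`
#'   column, position-named columns and 0/1 cells).
#' @param weights Optional path to a two-column TSV `seq_id<TAB>count` of
#'   duplicate counts.
#' @return A `mutation_matrix`.
#' @export
read_matrix <- function(path, weights = NULL) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  strand <- "top"
  sm <- grep("^#\\s*strand:", meta, value = TRUE)
  if (length(sm)) strand <- trimws(sub("^#\\s*strand:", "", sm[1L]))
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0L) stop("no header row in ", path)
  header <- strsplit(body[1L], "\t", fixed = TRUE)[[1L]]
  if (header[1L] != "seq_id" || length(header) < 2L) {
    stop("missing header: first row must be 'seq_id' followed by positions")
  }
  positions <- suppressWarnings(as.integer(header[-1L]))
  if (anyNA(positions)) stop("non-numeric position in header of ", path)
  rows <- strsplit(body[-1L], "\t", fixed = TRUE)
  if (length(rows) == 0L) stop("no sequences in ", path)
  nfield <- lengths(rows)
  if (any(nfield != length(header))) {
    stop("ragged row ", which(nfield != length(header))[1L], " in ", path)
  }
  ids <- vapply(rows, `[[`, "", 1L)
  cells <- matrix(unlist(lapply(rows, `[`, -1L), use.names = FALSE),
                  nrow = length(rows), byrow = TRUE)
  bad <- which(matrix(!(cells %in% c("0", "1")), nrow = nrow(cells)),
               arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("non-binary cell '", cells[bad[1L, , drop = FALSE]],
         "' at row ", bad[1L, 1L], " (", ids[bad[1L, 1L]], "), column ",
         bad[1L, 2L], " (position ", positions[bad[1L, 2L]], ")")
  }
  calls <- matrix(as.integer(cells), nrow = nrow(cells))
  w <- NULL
  if (!is.null(weights)) {
    wt <- utils::read.delim(weights, header = FALSE,
                            col.names = c("seq_id", "count"),
                            stringsAsFactors = FALSE)
    w <- rep(1, length(ids))
    hit <- match(ids, wt$seq_id)
    w[!is.na(hit)] <- wt$count[hit[!is.na(hit)]]
  }
  mutation_matrix(calls, positions, strand, seq_ids = ids, weights = w)
}
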