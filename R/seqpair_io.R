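#' Read in-frame coding sequences from a FASTA file
#'
#' Sequence identifiers are the first whitespace-delimited token of each
#' header line. Every record must be a gap-free, in-frame coding sequence:
#' only `A`, `C`, `G`, `T` are accepted (IUPAC ambiguity codes are rejected)
#' and the length must be a positive multiple of 3.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped).
#' @return A named character vector of upper-case nucleotide sequences, in
#'   file order, one element per record.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">g1 some description", "ATGGCC"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  for (i in seq_along(seqs)) {
    validate_coding_sequence(seqs[[i]], ids[[i]])
  }
  seqs
}

validate_coding_sequence <- function(seq, id = "<sequence>") {
  if (!nzchar(seq) || nchar(seq) %% 3L != 0L) {
    stop("sequence '", id, "' has length ", nchar(seq),
         ", not a positive multiple of 3 (frame error)")
  }
  bad <- gsub("[ACGT]", "", seq)
  if (nzchar(bad)) {
    stop("sequence '", id, "' contains characters outside {A,C,G,T}: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ", "))
  }
  invisible(seq)
}

#' Write coding sequences to FASTA
#'
#' @param seqs Named character vector of nucleotide sequences.
#' @param path Output path.
#' @param width Line-wrap width; `Inf` writes each sequence on one line.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    if (is.finite(width) && nchar(s) > width) {
      starts <- seq(1L, nchar(s), by = width)
      s <- substring(s, starts, pmin(starts + width - 1L, nchar(s)))
    }
    writeLines(s, con)
  }
  invisible(path)
}

PAIR_NUMERIC_COLS <- c("length", "divergence", "ka", "ks", "omega",
                       "correlation", "cosine")

#' Read a gene-pair table
#'
#' Tab-separated, UTF-8, `.` decimal; one row per duplicate gene pair.
#' Required columns: `gene1`, `gene2`, `class` (`in`/`out`), `replicon1`,
#' `replicon2`. Optional numeric columns (`length`, `divergence`, `ka`, `ks`,
#' `omega`, `correlation`, `cosine`) may contain `NA` or `N/A` cells, which
#' are read as missing values -- never as zero.
#'
#' @param path Path to the TSV file.
#' @param replicons Allowed replicon labels.
#' @return A `data.frame` with class `pair_table`.
#' @export
read_pair_table <- function(path, replicons = REPLICON_LEVELS) {
  if (!file.exists(path)) stop("pair table not found: ", path)
  df <- read.table(path, header = TRUE, sep = "\t", quote = "",
                   stringsAsFactors = FALSE, check.names = FALSE,
                   na.strings = c("NA", "N/A", ""), comment.char = "")
  required <- c("gene1", "gene2", "class", "replicon1", "replicon2")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("pair table is missing required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  key <- paste(df$gene1, df$gene2, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate gene-pair rows: ",
         paste(unique(paste(df$gene1, df$gene2)[duplicated(key)]),
               collapse = "; "))
  }
  if (!all(df$class %in% c("in", "out"))) {
    stop("paralog class must be 'in' or 'out'; found: ",
         paste(setdiff(unique(df$class), c("in", "out")), collapse = ", "))
  }
  for (col in c("replicon1", "replicon2")) {
    bad <- setdiff(unique(df[[col]]), replicons)
    if (length(bad)) {
      stop("unknown replicon label(s) in column ", col, ": ",
           paste(bad, collapse = ", "))
    }
  }
  for (col in intersect(PAIR_NUMERIC_COLS, names(df))) {
    if (is.character(df[[col]])) {
      val <- suppressWarnings(as.numeric(df[[col]]))
      if (any(is.na(val) & !is.na(df[[col]]))) {
        stop("non-numeric value in column ", col)
      }
      df[[col]] <- val
    }
  }
  class(df) <- c("pair_table", "data.frame")
  df
}

fmt_full <- function(x) {
  ifelse(is.na(x), "NA",
         ifelse(x == round(x) & abs(x) < 1e15,
                sprintf("%.0f", x), sprintf("%.17g", x)))
}

#' Write a gene-pair (or any result) table as TSV with full numeric precision
#'
#' Numbers are serialised with 17 significant digits so that a write/read
#' round trip reproduces doubles bit-exactly.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pair_table <- function(df, path) {
  out <- df
  for (col in names(out)) {
    if (is.double(out[[col]])) out[[col]] <- fmt_full(out[[col]])
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read a replicated expression matrix
#'
#' Expected layout: a TSV whose first column (`gene`) holds gene identifiers
#' and whose remaining column names follow `<condition>.<replicate_index>`
#' (e.g. `aerobic.1`, `aerobic.2`, ...). Every condition must carry the same
#' number of replicates and every row the full set of values.
#'
#' @param path Path to the TSV file.
#' @return An object of class `expr_table`: a list with elements `data`
#'   (numeric matrix, genes x replicate columns, gene ids as row names),
#'   `conditions` (condition label per column), and `n_replicates`.
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) stop("expression table not found: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(unique(nf)) != 1L) {
    stop("ragged expression table: rows have ",
         paste(unique(nf), collapse = ", "), " fields")
  }
  df <- read.table(path, header = TRUE, sep = "\t", quote = "",
                   stringsAsFactors = FALSE, check.names = FALSE,
                   comment.char = "")
  if (names(df)[1] != "gene") {
    stop("first column of an expression table must be named 'gene'")
  }
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes)) stop("duplicate gene ids in expression table")
  vals <- df[, -1, drop = FALSE]
  for (col in names(vals)) {
    if (!is.numeric(vals[[col]])) {
      stop("non-numeric expression value in column ", col)
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  cond <- sub("\\.[0-9]+$", "", colnames(m))
  reps <- table(cond)
  if (length(unique(as.integer(reps))) != 1L) {
    stop("unbalanced replicate counts per condition: ",
         paste(names(reps), as.integer(reps), sep = "=", collapse = ", "))
  }
  structure(list(data = m,
                 conditions = cond,
                 n_replicates = as.integer(reps[[1]])),
            class = "expr_table")
}

#' Write a replicated expression matrix as TSV
#'
#' Inverse of [read_expression_table()]; numbers keep full precision.
#'
#' @param tab An `expr_table`, or a numeric matrix with gene row names and
#'   `<condition>.<replicate>` column names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(tab, path) {
  m <- if (inherits(tab, "expr_table")) tab$data else tab
  df <- data.frame(gene = rownames(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (j in seq_len(ncol(m))) df[[colnames(m)[j]]] <- fmt_full(m[, j])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.expr_table <- function(x, ...) {
  cat("expression table: ", nrow(x$data), " genes x ",
      length(unique(x$conditions)), " conditions x ",
      x$n_replicates, " replicates\n", sep = "")
  invisible(x)
}
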