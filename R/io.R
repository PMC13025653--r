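# Delimited-table and FASTA readers/writers. Comma is the default
# delimiter; tab is auto-detected from the header line. All numeric I/O is
# locale-independent (decimal point, no thousands separators).

sniff_delim <- function(path) {
  header <- readLines(path, n = 1)
  if (!length(header)) stop("file '", path, "' is empty", call. = FALSE)
  if (grepl("\t", header)) "\t" else ","
}

read_delim_checked <- function(path, required = character(0)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.table(path, header = TRUE, sep = sniff_delim(path),
                         stringsAsFactors = FALSE, check.names = FALSE)
  if (!nrow(d)) stop("file '", path, "' has a header but no rows", call. = FALSE)
  miss <- setdiff(required, names(d))
  if (length(miss)) {
    stop("file '", path, "' lacks required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  d
}

check_numeric_cols <- function(d, cols, path) {
  for (col in cols) {
    v <- d[[col]]
    if (is.character(v)) v <- suppressWarnings(as.numeric(v))
    bad <- which(!is.finite(v) & !is.na(d[[col]]))
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' in column '%s', row %d of %s",
                   d[[col]][bad[1]], col, bad[1], path), call. = FALSE)
    }
    d[[col]] <- v
  }
  d
}

#' Read a kinetic trace from a delimited table
#'
#' Expects a header and two columns: time and absorbance (extra columns are
#' ignored). The time unit is declared by the caller, not guessed.
#'
#' @param path File path.
#' @param time_unit `"s"` or `"min"`.
#' @return A [kinetic_trace()].
#' @export
read_kinetic_trace <- function(path, time_unit = c("s", "min")) {
  time_unit <- match.arg(time_unit)
  d <- read_delim_checked(path)
  if (ncol(d) < 2) stop("kinetic trace needs 2 columns (time, absorbance)",
                        call. = FALSE)
  d <- check_numeric_cols(d, names(d)[1:2], path)
  kinetic_trace(d[[1]], d[[2]], time_unit = time_unit)
}

#' Read a design/response table
#'
#' Reads a delimited table whose columns are the three factors in actual
#' units plus any number of response columns, matched by name. Row order is
#' irrelevant downstream.
#'
#' @param path File path.
#' @param factors A [bbd_factors()] specification naming the factor columns.
#' @param strict If `TRUE`, additionally require the runs to form a valid
#'   3-factor Box-Behnken multiset (see [validate_bbd()]).
#' @return A `bbd_design` data.frame with the factor specification attached.
#' @export
read_design_table <- function(path, factors, strict = FALSE) {
  stopifnot(inherits(factors, "bbd_factors"))
  d <- read_delim_checked(path, required = factors$name)
  num_cols <- names(d)[vapply(d, function(v)
    is.numeric(v) || all(grepl("^\\s*-?[0-9.eE+]+\\s*$", v)), logical(1))]
  d <- check_numeric_cols(d, union(factors$name, num_cols), path)
  if (strict) validate_bbd(d, factors)
  attr(d, "factors") <- factors
  class(d) <- c("bbd_design", "data.frame")
  d
}

#' Read a peptide identification table
#'
#' Requires a `sequence` column; recognises the optional columns `mass`,
#' `alc`, `rt`, `area`, `ranker`, `toxin`, `solubility` (extra columns are
#' kept but ignored by the funnel). Sequences are validated against the
#' 20-letter alphabet and normalised to upper case; an invalid letter is an
#' error naming the record.
#'
#' @param path File path.
#' @return A data.frame of peptide records.
#' @export
read_peptide_table <- function(path) {
  d <- read_delim_checked(path, required = "sequence")
  d$sequence <- toupper(trimws(d$sequence))
  for (i in seq_len(nrow(d))) {
    tryCatch(split_sequence(d$sequence[i]), error = function(e) {
      stop(sprintf("row %d of %s: %s", i, path, conditionMessage(e)),
           call. = FALSE)
    })
  }
  check_numeric_cols(d, intersect(c("mass", "alc", "rt", "area", "ranker"),
                                  names(d)), path)
}

#' Read peptide sequences from a FASTA file
#'
#' Standard FASTA via \pkg{seqinr}; headers are preserved as identifiers
#' and sequences normalised to upper case and validated against the
#' 20-letter alphabet.
#'
#' @param path File path.
#' @return Named character vector of sequences.
#' @importFrom seqinr read.fasta
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  seqs <- toupper(vapply(recs, function(r) as.character(r)[1], character(1)))
  names(seqs) <- names(recs)
  for (i in seq_along(seqs)) {
    tryCatch(split_sequence(seqs[[i]]), error = function(e) {
      stop(sprintf("FASTA record '%s': %s", names(seqs)[i],
                   conditionMessage(e)), call. = FALSE)
    })
  }
  seqs
}

#' Write an ANOVA report as a delimited table
#'
#' Emits the usual response-surface ANOVA layout (Source, SS, Df, MS, F, p)
#' as a tab-delimited table, full precision, plus the fit statistics as
#' trailing comment-free rows of the same table. Writes are deterministic:
#' the same report always yields identical bytes.
#'
#' @param x An `rsm_anova` from [anova.rsm_fit()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_anova_table <- function(x, path) {
  stopifnot(inherits(x, "rsm_anova"))
  out <- data.frame(Source = x$source, SS = x$ss, Df = x$df, MS = x$ms,
                    F = x$f, p = x$p)
  out <- rbind(out, data.frame(Source = c("R2", "R2adj", "CV%"),
                               SS = c(attr(x, "r2"), attr(x, "r2_adj"),
                                      attr(x, "cv_percent")),
                               Df = NA, MS = NA, F = NA, p = NA))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Write a screening-funnel report as a delimited table
#'
#' One row per stage in execution order (stage, records entering, records
#' surviving); an empty funnel yields a header-only file.
#'
#' @param x A `funnel_report` from [screen_peptides()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_funnel_report <- function(x, path) {
  stopifnot(inherits(x, "funnel_report"))
  utils::write.table(x$stages, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
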