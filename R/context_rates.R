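#' Trinucleotide-context substitution rate tables
#'
#' The de novo expectation model is driven by a 192-entry table giving, for
#' each trinucleotide context (64 contexts) and each alternative middle base
#' (3 per context), the per-base, per-generation haploid probability that the
#' middle base mutates to that alternative. The table is the interface: a
#' methylation-aware model can be supplied as an alternative 192-entry table
#' per stratum.
#'
#' @param df data.frame with columns `context` (3-mer over ACGT), `alt`
#'   (single base differing from the middle base) and `rate` (> 0).
#' @return A validated `context_rates` data.frame with 192 rows.
#' @export
context_rate_table <- function(df) {
  stopifnot(is.data.frame(df), all(c("context", "alt", "rate") %in% names(df)))
  df <- df[, c("context", "alt", "rate")]
  df$context <- toupper(as.character(df$context))
  df$alt <- toupper(as.character(df$alt))
  if (!all(grepl("^[ACGT]{3}$", df$context)))
    stop("contexts must be 3-mers over ACGT")
  if (!all(df$alt %in% c("A", "C", "G", "T")))
    stop("alt must be a single base in ACGT")
  if (any(substr(df$context, 2, 2) == df$alt))
    stop("alt base must differ from the context middle base")
  if (any(!is.finite(df$rate)) || any(df$rate <= 0))
    stop("all rates must be finite and > 0")
  key <- paste0(df$context, ">", df$alt)
  if (anyDuplicated(key)) stop("duplicated (context, alt) entries")
  if (nrow(df) != 192L)
    stop("a complete table has 192 rows (64 contexts x 3 alts); got ", nrow(df))
  df <- df[order(df$context, df$alt), ]
  rownames(df) <- NULL
  class(df) <- c("context_rates", "data.frame")
  df
}

#' @describeIn context_rate_table Uniform table with every entry equal to `rate`.
#' @param rate per-base per-generation rate used for every entry.
#' @export
flat_context_rates <- function(rate = 1e-8) {
  b <- c("A", "C", "G", "T")
  ctx <- as.vector(outer(as.vector(outer(b, b, paste0)), b,
                         function(xy, z) paste0(substr(xy, 1, 1), substr(xy, 2, 2), z)))
  df <- expand.grid(context = ctx, alt = b, stringsAsFactors = FALSE)
  df <- df[substr(df$context, 2, 2) != df$alt, ]
  df$rate <- rate
  context_rate_table(df)
}

#' @describeIn context_rate_table Read a table from TSV (columns context, alt, rate).
#' @param path file path.
#' @export
read_context_rates <- function(path) {
  context_rate_table(utils::read.table(path, header = TRUE, sep = "\t",
                                       stringsAsFactors = FALSE))
}

#' @describeIn context_rate_table Write a table as TSV.
#' @param rates a `context_rates` table.
#' @export
write_context_rates <- function(rates, path) {
  utils::write.table(rates, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @describeIn context_rate_table Reverse-complement a table: entry
#'   (XYZ -> b) maps to (revcomp(XYZ) -> comp(b)). Applying it twice is the
#'   identity; a strand-symmetric table equals its own complement.
#' @export
complement_context_rates <- function(rates) {
  stopifnot(inherits(rates, "context_rates"))
  df <- as.data.frame(rates)
  df$context <- revcomp(df$context)
  df$alt <- revcomp(df$alt)
  context_rate_table(df)
}

# named vector "CTX>B" -> rate, used for vectorized lookups
rate_lookup <- function(rates) {
  stopifnot(inherits(rates, "context_rates"))
  stats::setNames(rates$rate, paste0(rates$context, ">", rates$alt))
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
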