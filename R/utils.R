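# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

pgx_stop <- function(...) stop(..., call. = FALSE)

#' Path to a bundled example/fixture file
#'
#' Returns the path to one of the plain-text tables shipped with the package
#' (toy knowledge tables, printed summary tables used in examples and tests).
#'
#' @param file File name relative to the package `extdata` directory. With no
#'   argument, lists the available files.
#' @return A file path, or a character vector of available file names.
#' @export
pgx_extdata <- function(file = NULL) {
  if (is.null(file)) {
    return(list.files(system.file("extdata", package = "pgxprofiler"),
                      recursive = TRUE))
  }
  path <- system.file("extdata", file, package = "pgxprofiler")
  if (identical(path, "")) pgx_stop("no bundled file '", file, "'")
  path
}

read_tsv <- function(path, ...) {
  if (!file.exists(path)) pgx_stop("file not found: ", path)
  utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    fill = TRUE, ...)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# unordered pair key: symmetric in (a, b)
pair_key <- function(a, b) {
  ifelse(a <= b, paste(a, b, sep = "||"), paste(b, a, sep = "||"))
}

# canonical display order for a diplotype: reference allele first, then
# lexicographic star-name order
canonical_pair <- function(a, b, reference_allele) {
  swap <- (b == reference_allele & a != reference_allele) |
    (a != reference_allele & b != reference_allele & b < a)
  list(allele1 = ifelse(swap, b, a), allele2 = ifelse(swap, a, b))
}

# round half away from zero (printed-table convention), unlike base round()
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# drug names are matched case-insensitively after trimming
normalize_drug <- function(x) tolower(trimws(x))

site_id <- function(chrom, pos, ref, alt) paste(chrom, pos, ref, alt, sep = ":")
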