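#' Read and write the pipeline's tab-separated formats
#'
#' All pipeline tables are plain TSV. The genotype matrix has the locus id
#' in the first column (`locus`), one column per individual, and cells
#' `AA`/`AB`/`BB`/`NA`. Anchor tables have columns `locus`, `ref_chrom`,
#' `ref_pos` (1-based bp); haplotype-flag tables `locus`, `vesca_match`,
#' `iinumae_match`; depth tables `locus`, `depth`, `class`.
#'
#' @param x Matrix or data.frame to write.
#' @param path File path.
#' @return `read_genotype_matrix` returns a character matrix with locus
#'   rownames; the other readers return data.frames; writers return `path`
#'   invisibly.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
write_genotype_matrix <- function(x, path) {
  if (inherits(x, "sim_population")) x <- x$genotypes
  stopifnot(is.matrix(x))
  df <- data.frame(locus = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_genotype_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  stopifnot(names(df)[1L] == "locus")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$locus
  bad <- !is.na(m) & !m %in% c("AA", "AB", "BB")
  if (any(bad)) {
    stop(sprintf("invalid genotype calls in %s: %s", path,
                 paste(utils::head(unique(m[bad])), collapse = ", ")),
         call. = FALSE)
  }
  m
}

#' @rdname pipeline_io
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_anchor_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("locus", "ref_chrom", "ref_pos") %in% names(df)),
            all(df$ref_pos >= 1))
  df
}

#' @rdname pipeline_io
#' @export
read_haplosnp_flags <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("locus", "vesca_match", "iinumae_match") %in% names(df)))
  df$vesca_match <- as.logical(df$vesca_match)
  df$iinumae_match <- as.logical(df$iinumae_match)
  df
}

#' @rdname pipeline_io
#' @export
read_depth_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("locus", "depth", "class") %in% names(df)))
  df
}
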