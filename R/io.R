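# Plain-text interchange formats: BED6+ peak lists, refGene-like gene
# tables, counts/code matrices as TSV, GMT gene sets, sample sheets. All
# coordinates on disk are 0-based half-open, matching the in-memory
# convention.

#' Write peaks as BED6+ (name, fold-enrichment score, strand ".", plus
#' breadth and tag_density columns)
#'
#' @param peaks Peak data frame.
#' @param path Output file.
#' @export
write_peaks_bed <- function(peaks, path) {
  bed <- data.frame(chrom = peaks$chrom, start = peaks$start, end = peaks$end,
                    name = if (nrow(peaks))
                      sprintf("peak_%05d", seq_len(nrow(peaks))) else character(0),
                    score = peaks$fold_enrichment, strand = ".",
                    breadth = peaks$end - peaks$start,
                    tag_density = peaks$tag_density)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a BED6+ peak list written by [write_peaks_bed()]
#'
#' @param path Input file.
#' @param mark,sample_id Metadata attached to every row.
#' @return Peak data frame.
#' @export
read_peaks_bed <- function(path, mark = NA_character_, sample_id = NA_character_) {
  cols <- c("chrom", "start", "end", "name", "score", "strand",
            "breadth", "tag_density")
  bed <- read.delim(path, header = FALSE, col.names = cols,
                    stringsAsFactors = FALSE)
  data.frame(chrom = bed$chrom, start = bed$start, end = bed$end,
             breadth = bed$end - bed$start, fold_enrichment = bed$score,
             tag_density = bed$tag_density, mark = mark,
             sample_id = sample_id, stringsAsFactors = FALSE)
}

#' Write / read a refGene-like gene table (TSV)
#' @param genes Gene data frame.
#' @param path File path.
#' @export
write_gene_table <- function(genes, path) {
  write.table(genes[, c("gene_id", "chrom", "strand", "start", "end")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_table
#' @export
read_gene_table <- function(path) {
  g <- read.delim(path, stringsAsFactors = FALSE)
  g$length <- g$end - g$start
  g
}

#' Write / read a genes x samples matrix as TSV with a header row
#' @param mat Matrix with dimnames.
#' @param path File path.
#' @export
write_matrix_tsv <- function(mat, path) {
  rn <- if (is.null(rownames(mat))) sprintf("row_%05d", seq_len(nrow(mat)))
        else rownames(mat)
  df <- data.frame(gene_id = rn, mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Read a numeric genes x samples TSV matrix
#' @rdname write_matrix_tsv
#' @export
read_counts_tsv <- function(path) {
  m <- read_matrix_tsv(path)
  storage.mode(m) <- "numeric"
  m
}

#' Read a code matrix TSV (cells "00"/"10"/"01"/"11")
#' @rdname write_matrix_tsv
#' @export
read_code_matrix <- function(path) {
  m <- read_matrix_tsv(path)
  if (!all(m %in% MOD_STATES)) abort_arg("invalid modification codes in ", path)
  structure(m, class = c("code_matrix", class(m)))
}

#' Write / read gene sets in GMT format
#' @param sets Named list of gene-id vectors.
#' @param path File path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  out <- lapply(strsplit(lines, "\t"), function(f) f[-(1:2)])
  names(out) <- vapply(strsplit(lines, "\t"), `[`, "", 1)
  out
}

#' Read a sample sheet (TSV: sample_id, condition_class, ...)
#'
#' @param path File path.
#' @return Named character vector sample_id -> condition_class, suitable for
#'   [standard_rules()].
#' @export
read_sample_sheet <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "condition_class") %in% names(df)))
    abort_arg("sample sheet needs sample_id and condition_class columns")
  setNames(df$condition_class, df$sample_id)
}
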