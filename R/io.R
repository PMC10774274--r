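#' Read and write BED6 interval files
#'
#' BED6: `chrom`, `start`, `end`, `name`, `score`, `strand`, 0-based
#' half-open, tab-separated, no header.  Missing name/score/strand are
#' written as `.`/`0`/`.` and read back as `NA`/`0`/`"."`, so a write
#' followed by a read round-trips the interval content.
#'
#' @param x Interval tibble.
#' @param path File path.
#' @return `read_bed()` returns an interval tibble; `write_bed()` returns
#'   `path` invisibly.
#' @export
write_bed <- function(x, path) {
  x <- as_interval_tbl(x)
  out <- tibble(
    chrom = x$chrom,
    start = format(x$start, scientific = FALSE, trim = TRUE),
    end = format(x$end, scientific = FALSE, trim = TRUE),
    name = if ("name" %in% names(x)) dplyr::coalesce(x$name, ".") else ".",
    score = if ("score" %in% names(x)) x$score else 0,
    strand = if ("strand" %in% names(x)) x$strand else ".")
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  x <- readr::read_tsv(path,
                       col_names = c("chrom", "start", "end", "name",
                                     "score", "strand"),
                       col_types = "ciicdc", progress = FALSE)
  x$name[x$name == "."] <- NA_character_
  as_interval_tbl(x)
}

#' Read and write FASTA sequence tables
#'
#' Sequences travel as tibbles with `name` and `seq` columns; files are
#' standard FASTA handled by Biostrings.
#'
#' @param x Tibble with `name` and `seq`.
#' @param path File path.
#' @return `read_fasta()` returns a tibble; `write_fasta()` returns
#'   `path` invisibly.
#' @export
write_fasta <- function(x, path) {
  ss <- Biostrings::DNAStringSet(setNames(x$seq, x$name))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  tibble(name = names(ss), seq = unname(as.character(ss)))
}

#' Read and write toy gene annotations as TSV gene-model tables
#'
#' The internal tabular gene-model format: one feature per row
#' (`gene_id`, `chrom`, `strand`, `feature`, `start`, `end`) plus header
#' comment lines `#chrom_length <chrom> <length>` carrying the
#' chromosome sizes, so the round-trip is lossless.
#'
#' @param annotation A `clip_annotation` tibble.
#' @param path File path.
#' @return `read_gene_models()` returns a `clip_annotation`;
#'   `write_gene_models()` returns `path` invisibly.
#' @export
write_gene_models <- function(annotation, path) {
  cl <- chrom_lengths(annotation)
  header <- sprintf("#chrom_length\t%s\t%d", names(cl), cl)
  body <- capture_tsv(as_tibble(annotation)[, c("gene_id", "chrom",
                                                "strand", "feature",
                                                "start", "end")])
  writeLines(c(header, body), path)
  invisible(path)
}

capture_tsv <- function(x) {
  tc <- textConnection("out", "w", local = TRUE)
  on.exit(close(tc))
  utils::write.table(x, tc, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}

#' @rdname write_gene_models
#' @export
read_gene_models <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#chrom_length\t", lines, value = TRUE)
  parts <- strsplit(hdr, "\t")
  cl <- setNames(as.integer(vapply(parts, `[`, "", 3)),
                 vapply(parts, `[`, "", 2))
  body <- lines[!startsWith(lines, "#")]
  ann <- readr::read_tsv(I(paste(body, collapse = "\n")),
                         col_types = "ccccii", progress = FALSE)
  ann <- as_tibble(ann)
  attr(ann, "chrom_lengths") <- cl
  class(ann) <- c("clip_annotation", class(ann))
  ann
}
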