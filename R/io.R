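# Plain-text input/output for the documented formats.

#' Write a synthetic bundle to disk
#'
#' Writes chrom sizes (TSV), gene annotation (GFF3 when rtracklayer is
#' available, TSV otherwise), genome (FASTA), planted intervals (BED6),
#' probe tables, expression intensities and truth labels (TSV).
#'
#' @param bundle Output of [simulate_screen_bundle()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of file paths, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    chrom_sizes = file.path(dir, "chrom_sizes.tsv"),
    genes = file.path(dir, if (has_rtracklayer()) "genes.gff3" else "genes.tsv"),
    genome = file.path(dir, "genome.fa"),
    planted = file.path(dir, "planted.bed"),
    probes = file.path(dir, "probes.tsv"),
    expression = file.path(dir, "expression.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  readr::write_tsv(bundle$chrom_sizes, paths["chrom_sizes"],
                   col_names = FALSE)
  write_genes(bundle$genes, paths["genes"])
  Biostrings::writeXStringSet(bundle$genome, paths["genome"])
  readr::write_tsv(
    bundle$planted_intervals |>
      transmute(.data$chrom, start = as.integer(.data$start),
                end = as.integer(.data$end),
                name = paste0(.data$gene_id, "|", .data$condition),
                score = 0L, strand = "."),
    paths["planted"], col_names = FALSE
  )
  readr::write_tsv(bundle$arrays, paths["probes"])
  readr::write_tsv(bundle$expression$intensities, paths["expression"])
  readr::write_tsv(bundle$expression$truth, paths["truth"])
  invisible(paths)
}

has_rtracklayer <- function() {
  requireNamespace("rtracklayer", quietly = TRUE)
}

write_genes <- function(genes, path) {
  if (has_rtracklayer() && grepl("\\.gff3?$", path)) {
    gr <- GenomicRanges::GRanges(
      genes$chrom,
      IRanges::IRanges(genes$start + 1, genes$end),
      strand = genes$strand
    )
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      type = "gene", ID = genes$gene_id, Name = genes$symbol
    )
    rtracklayer::export(gr, path, format = "gff3")
  } else {
    readr::write_tsv(genes, path)
  }
}

#' Read a probe-signal TSV
#' @param path File written by [write_bundle()] (probes.tsv layout).
#' @return Probe-signal tibble.
#' @export
read_probe_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    probe_id = "c", chrom = "c", condition = "c"
                  )) |>
    mutate(replicate = as.integer(.data$replicate),
           across(any_of(c("start", "end", "e4c", "control")), as.numeric))
}

#' Read a FISH coordinate TSV
#' @param path TSV with nucleus_id, condition, gene, x_um, y_um, z_um.
#' @return FISH tibble.
#' @export
read_fish_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Read gene sets from one-accession-per-line text
#' @param path File path.
#' @return Character vector.
#' @export
read_gene_set <- function(path) {
  x <- trimws(readr::read_lines(path))
  x[nzchar(x)]
}
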