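# Synthetic genome, annotation, in-silico double digestion and array design.
#
# Coordinates are 0-based half-open (BED convention) throughout.

#' Simulate chromosome sizes and a non-overlapping gene annotation
#'
#' Genes are laid out in equal slots along each chromosome and jittered
#' within their slot, which guarantees non-overlap by construction.  Gene
#' lengths are drawn uniformly between 5 and 20 kb and strands at random.
#' TSS/TES are the strand-aware 5' and 3' ends of the gene body.
#'
#' @param config A [synthetic_config()].
#' @param seed Optional integer overriding the seed derived from `config`.
#' @return A list with `chrom_sizes` (tibble: `chrom`, `length`) and
#'   `genes` (tibble: `gene_id`, `symbol`, `chrom`, `start`, `end`,
#'   `strand`, `tss`, `tes`).
#' @export
#' @examples
#' g <- simulate_genome(synthetic_config(n_genes = 30, seed = 7))
#' g$genes
simulate_genome <- function(config, seed = NULL) {
  stopifnot(inherits(config, "gfap4c_synth_config"))
  withr::local_seed(seed %||% (config$seed + 101L))
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  chrom_sizes <- tibble(chrom = chroms, length = config$chrom_length_bp)
  if (config$n_genes == 0) {
    genes <- tibble(
      gene_id = character(), symbol = character(), chrom = character(),
      start = numeric(), end = numeric(), strand = character(),
      tss = numeric(), tes = numeric()
    )
    return(list(chrom_sizes = chrom_sizes, genes = genes))
  }
  # spread genes over chromosomes as evenly as possible
  n_per <- diff(round(seq(0, config$n_genes, length.out = config$n_chromosomes + 1)))
  margin <- 1000
  max_len <- 20000
  rows <- map2(chroms, n_per, function(ch, n) {
    if (n == 0) return(NULL)
    slot <- config$chrom_length_bp / n
    if (slot < max_len + 2 * margin) {
      abort(paste0("cannot place ", n, " genes of up to ", max_len,
                   " bp on a ", config$chrom_length_bp, " bp chromosome"))
    }
    len <- round(runif(n, 5000, max_len))
    slot_start <- (seq_len(n) - 1) * slot
    start <- round(slot_start + margin +
                     runif(n) * (slot - len - 2 * margin))
    tibble(chrom = ch, start = start, end = start + len,
           strand = sample(c("+", "-"), n, replace = TRUE))
  })
  genes <- list_rbind(purrr::compact(rows)) |>
    arrange(.data$chrom, .data$start) |>
    mutate(
      gene_id = sprintf("G%04d", row_number()),
      symbol = sprintf("Sg%04d", row_number()),
      tss = ifelse(.data$strand == "+", .data$start, .data$end),
      tes = ifelse(.data$strand == "+", .data$end, .data$start)
    ) |>
    select("gene_id", "symbol", "chrom", "start", "end", "strand",
           "tss", "tes")
  list(chrom_sizes = chrom_sizes, genes = genes)
}

#' Simulate a random genome sequence
#'
#' Uniform-composition DNA for each chromosome; the substrate for the
#' in-silico double digest and for promoter motif scanning.
#'
#' @inheritParams simulate_genome
#' @param chrom_sizes Tibble with `chrom` and `length` columns.
#' @return A named [Biostrings::DNAStringSet].
#' @export
simulate_genome_sequence <- function(config, chrom_sizes, seed = NULL) {
  withr::local_seed(seed %||% (config$seed + 102L))
  seqs <- map(chrom_sizes$length, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  })
  out <- Biostrings::DNAStringSet(unlist(seqs))
  names(out) <- chrom_sizes$chrom
  out
}

#' In-silico double digestion
#'
#' Enumerates every maximal fragment whose 5' boundary is a cut of
#' `enzyme_a` and whose 3' boundary is the nearest downstream cut of
#' `enzyme_b`, with no intervening cut of either enzyme, on both strands of
#' the sequence.  Overlapping site occurrences all count, the cut position
#' is the 5' coordinate of the recognition site (in the scanned
#' orientation), and fragments of length `<= min_len` are dropped.
#'
#' @param sequence A [Biostrings::DNAString], or a plain ACGT string.
#' @param enzyme_a,enzyme_b Recognition sites (plain ACGT; IUPAC ambiguity
#'   codes are rejected).
#' @param min_len Fragments must be strictly longer than this (bp).
#' @return Tibble with `start`, `end` (0-based half-open, plus-strand
#'   coordinates), `length`, `strand`, `left_site`, `right_site`.  On the
#'   minus strand, "left"/"right" refer to the scanned orientation.
#' @export
#' @examples
#' digest_double("AGATCTAAAACATG", "AGATCT", "CATG", min_len = 0)
digest_double <- function(sequence, enzyme_a = "AGATCT", enzyme_b = "CATG",
                          min_len = 100) {
  for (site in c(enzyme_a, enzyme_b)) {
    if (!nzchar(site) || grepl("[^ACGT]", site)) {
      abort("recognition sites must be nonempty plain ACGT strings")
    }
  }
  if (min_len < 0) abort("`min_len` must be >= 0")
  seq <- if (inherits(sequence, "DNAString")) sequence else {
    Biostrings::DNAString(as.character(sequence))
  }
  L <- length(seq)
  one_strand <- function(s) {
    # 0-based 5' coordinates of all (overlapping) site occurrences
    cuts_a <- Biostrings::start(Biostrings::matchPattern(enzyme_a, s)) - 1L
    cuts_b <- Biostrings::start(Biostrings::matchPattern(enzyme_b, s)) - 1L
    if (length(cuts_a) == 0 || length(cuts_b) == 0) {
      return(tibble(start = integer(), end = integer()))
    }
    cuts <- sort(unique(c(cuts_a, cuts_b)))
    is_b <- cuts %in% cuts_b & !(cuts %in% cuts_a)  # a-cut wins shared pos
    nxt <- match(cuts_a, cuts) + 1L
    ok <- nxt <= length(cuts) & is_b[pmin(nxt, length(cuts))]
    tibble(start = cuts_a[ok], end = cuts[nxt[ok]])
  }
  fwd <- one_strand(seq) |> mutate(strand = "+")
  rev <- one_strand(Biostrings::reverseComplement(seq)) |>
    mutate(s2 = L - .data$end, e2 = L - .data$start) |>
    transmute(start = .data$s2, end = .data$e2, strand = "-")
  bind_rows(fwd, rev) |>
    mutate(length = .data$end - .data$start,
           left_site = enzyme_a, right_site = enzyme_b) |>
    filter(.data$length > min_len) |>
    arrange(.data$start, .data$strand) |>
    select("start", "end", "length", "strand", "left_site", "right_site")
}

#' Digest every chromosome of a genome
#'
#' @param genome Named [Biostrings::DNAStringSet].
#' @inheritParams digest_double
#' @return Fragment tibble with a `chrom` column.
#' @export
digest_genome <- function(genome, enzyme_a = "AGATCT", enzyme_b = "CATG",
                          min_len = 100) {
  imap(as.list(genome), function(s, ch) {
    digest_double(s, enzyme_a, enzyme_b, min_len) |>
      mutate(chrom = ch, .before = 1)
  }) |>
    list_rbind()
}

#' Design one probe per qualifying fragment
#'
#' Each fragment contributes one probe anchored at its enzyme-a (BglII) end,
#' mirroring tiling arrays that carry a probe per target fragment.
#' Duplicate probe intervals (palindromic sites make plus- and minus-strand
#' fragments mirror each other) are collapsed.
#'
#' @param fragments Output of [digest_genome()].
#' @param probe_bp Probe length in bp (clipped to the fragment).
#' @return Tibble with `probe_id`, `chrom`, `start`, `end`.
#' @export
design_probes <- function(fragments, probe_bp = 60) {
  fragments |>
    mutate(
      p_start = ifelse(.data$strand == "+", .data$start,
                       pmax(.data$start, .data$end - probe_bp)),
      p_end = ifelse(.data$strand == "+",
                     pmin(.data$end, .data$start + probe_bp), .data$end)
    ) |>
    distinct(.data$chrom, p_start = .data$p_start, p_end = .data$p_end) |>
    arrange(.data$chrom, .data$p_start) |>
    transmute(probe_id = sprintf("p%06d", row_number()),
              chrom = .data$chrom, start = .data$p_start, end = .data$p_end)
}
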