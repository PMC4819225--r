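# Mapping e4C peaks to genes within a distance cut-off, distance-bin
# classification against TSS/TES, and hit-vs-array distance enrichment.

distance_bin_breaks <- c(0, 2000, 5000, 10000, 30000, Inf)
distance_bin_labels <- c("<2 kb", "2-5 kb", "5-10 kb", "10-30 kb", ">30 kb")

#' Map peaks to genes within a distance cut-off
#'
#' A gene is bait-associated when the gap between its body (TSS-TES span)
#' and any peak is at most `gene_distance_bp` (0 when they overlap).  Each
#' gene is reported once per condition with its nearest supporting peak and
#' the distance bin of that peak (see [classify_distance()]).
#'
#' @param peaks Peak tibble (`chrom`, `start`, `end`, optional `condition`).
#' @param genes Gene annotation tibble from [simulate_genome()] (or any
#'   tibble with `gene_id`, `symbol`, `chrom`, `start`, `end`, `tss`, `tes`).
#' @param gene_distance_bp Maximum peak-to-gene-body gap in bp (inclusive).
#' @return Association tibble: `gene_id`, `symbol`, `condition`,
#'   `n_supporting_peaks`, `min_distance_bp`, `peak_start`, `peak_end`,
#'   `distance_bin`.
#' @export
map_peaks_to_genes <- function(peaks, genes, gene_distance_bp = 50000) {
  has_cond <- "condition" %in% names(peaks)
  if (!has_cond) peaks <- mutate(peaks, condition = "all")
  if (nrow(peaks) == 0 || nrow(genes) == 0) {
    return(tibble(gene_id = character(), symbol = character(),
                  condition = character(), n_supporting_peaks = integer(),
                  min_distance_bp = numeric(), peak_start = numeric(),
                  peak_end = numeric(), distance_bin = character()))
  }
  pg <- GenomicRanges::GRanges(peaks$chrom,
                               IRanges::IRanges(peaks$start + 1, peaks$end))
  gg <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start + 1, genes$end))
  ov <- GenomicRanges::findOverlaps(pg, gg, maxgap = gene_distance_bp)
  if (length(ov) == 0) {
    return(map_peaks_to_genes(peaks[0, ], genes))
  }
  pi <- S4Vectors::queryHits(ov)
  gi <- S4Vectors::subjectHits(ov)
  gap <- GenomicRanges::distance(pg[pi], gg[gi])  # 0 when overlapping
  recs <- tibble(
    condition = peaks$condition[pi],
    gene_id = genes$gene_id[gi], symbol = genes$symbol[gi],
    distance_bp = as.numeric(gap),
    peak_start = peaks$start[pi], peak_end = peaks$end[pi],
    peak_mid = (peaks$start[pi] + peaks$end[pi]) / 2,
    tss = genes$tss[gi], tes = genes$tes[gi]
  ) |>
    filter(.data$distance_bp <= gene_distance_bp)
  recs |>
    group_by(.data$condition, .data$gene_id) |>
    arrange(.data$distance_bp, .data$peak_start, .by_group = TRUE) |>
    summarise(
      symbol = first(.data$symbol),
      n_supporting_peaks = n(),
      min_distance_bp = first(.data$distance_bp),
      peak_start = first(.data$peak_start),
      peak_end = first(.data$peak_end),
      distance_bin = classify_distance(first(.data$peak_mid),
                                       first(.data$tss), first(.data$tes)),
      .groups = "drop"
    ) |>
    select("gene_id", "symbol", "condition", "n_supporting_peaks",
           "min_distance_bp", "peak_start", "peak_end", "distance_bin")
}

#' Classify a peak-to-gene distance into reporting bins
#'
#' Distance is measured from the peak midpoint to the nearer of the gene's
#' TSS and TES; the reference point is whichever is closer (ties go to the
#' TSS).  Bins are lower-inclusive: `[0,2) [2,5) [5,10) [10,30) [30,Inf)` kb.
#'
#' @param peak_mid Peak midpoint coordinate(s), bp.
#' @param tss,tes Gene TSS/TES coordinates, bp.
#' @return Character vector like `"10-30 kb from TES"`.
#' @export
#' @examples
#' classify_distance(21000, tss = 100000, tes = 1000)
classify_distance <- function(peak_mid, tss, tes) {
  d_tss <- abs(peak_mid - tss)
  d_tes <- abs(peak_mid - tes)
  use_tss <- d_tss <= d_tes
  d <- ifelse(use_tss, d_tss, d_tes)
  bin <- cut(d, breaks = distance_bin_breaks, labels = distance_bin_labels,
             right = FALSE, include.lowest = FALSE)
  # cut() with right = FALSE is lower-inclusive; d = 0 falls in "<2 kb"
  bin <- as.character(bin)
  bin[d == 0] <- distance_bin_labels[1]
  paste0(bin, " from ", ifelse(use_tss, "TSS", "TES"))
}

#' Distance enrichment of hits relative to the whole array
#'
#' For hit probes and for all array probes, computes the fraction falling in
#' each distance bin (probe midpoint to the nearest TSS-or-TES anchor over
#' all genes) and the hit/array fraction ratio.
#'
#' @param hits Hit probe tibble (`chrom`, `start`, `end`).
#' @param all_probes Full array probe tibble.
#' @param genes Gene annotation tibble.
#' @param breaks Distance bin breaks in bp (must start at 0 and end at Inf).
#' @return Tibble: `bin`, `n_hits`, `n_array`, `frac_hits`, `frac_array`,
#'   `enrichment`.
#' @export
distance_enrichment <- function(hits, all_probes, genes,
                                breaks = distance_bin_breaks) {
  if (nrow(hits) == 0) abort("empty hit set: enrichment undefined")
  if (breaks[1] != 0 || !is.infinite(breaks[length(breaks)])) {
    abort("`breaks` must partition [0, Inf)")
  }
  anchor_dist <- function(probes) {
    mid <- (probes$start + probes$end) / 2
    out <- rep(Inf, nrow(probes))
    for (ch in unique(probes$chrom)) {
      idx <- which(probes$chrom == ch)
      anc <- sort(c(genes$tss[genes$chrom == ch],
                    genes$tes[genes$chrom == ch]))
      if (length(anc) == 0) next
      m <- mid[idx]
      j <- findInterval(m, anc)
      lo <- ifelse(j >= 1, m - anc[pmax(j, 1)], Inf)
      hi <- ifelse(j < length(anc), anc[pmin(j + 1, length(anc))] - m, Inf)
      out[idx] <- pmin(lo, hi)
    }
    out
  }
  lab <- function(d) {
    cut(d, breaks = breaks, right = FALSE, include.lowest = FALSE,
        labels = FALSE)
  }
  bh <- lab(anchor_dist(hits))
  ba <- lab(anchor_dist(all_probes))
  nb <- length(breaks) - 1
  tab <- tibble(
    bin = bin_labels_from_breaks(breaks),
    n_hits = tabulate(bh, nbins = nb),
    n_array = tabulate(ba, nbins = nb)
  ) |>
    mutate(frac_hits = .data$n_hits / sum(.data$n_hits),
           frac_array = .data$n_array / sum(.data$n_array),
           enrichment = .data$frac_hits / .data$frac_array)
  tab
}

bin_labels_from_breaks <- function(breaks) {
  lo <- breaks[-length(breaks)] / 1000
  hi <- breaks[-1] / 1000
  ifelse(is.infinite(hi), paste0(">", lo, " kb"),
         ifelse(lo == 0, paste0("<", hi, " kb"), paste0(lo, "-", hi, " kb")))
}
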