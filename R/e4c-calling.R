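# Hit calling on two-channel e4C probe tables: log2 ratios, sliding-window
# smoothing, cut-off calling, replicate reproducibility, peak merging and
# per-chromosome peak densities.

#' Compute per-probe log2(e4C / genomic control) ratios
#'
#' @param probes Probe-signal tibble with `e4c` and `control` intensity
#'   columns (and any identifying columns, which are preserved).
#' @param pseudocount Added to both channels before the ratio; guards zero
#'   channels on competitive-hybridisation arrays.
#' @return The input with a `log2_ratio` column, order preserved.
#' @export
#' @examples
#' compute_probe_ratios(tibble::tibble(e4c = 400, control = 100),
#'                      pseudocount = 0)
compute_probe_ratios <- function(probes, pseudocount = 1) {
  if (nrow(probes) == 0) abort("probe table is empty")
  if (any(probes$e4c < 0) || any(probes$control < 0)) {
    abort("intensities must be nonnegative")
  }
  if (pseudocount == 0 && any(probes$e4c == 0 & probes$control == 0)) {
    abort("both channels zero with pseudocount 0: ratio undefined")
  }
  mutate(probes, log2_ratio = log2((.data$e4c + pseudocount) /
                                     (.data$control + pseudocount)))
}

#' Smooth log2 ratios with a midpoint-centred sliding window
#'
#' Each probe's smoothed ratio is the mean log2 ratio over all probes (same
#' chromosome, and same replicate/condition track when those columns are
#' present) whose midpoints lie within `window_bp / 2` of its own midpoint.
#' An isolated probe keeps its own ratio.
#'
#' @param track Output of [compute_probe_ratios()] with `chrom`, `start`,
#'   `end` columns.
#' @param window_bp Window width in bp (200 by default).
#' @return The input with a `smoothed_ratio` column.
#' @export
smooth_sliding_window <- function(track, window_bp = 200) {
  hw <- window_bp / 2
  grp <- intersect(c("condition", "replicate", "chrom"), names(track))
  track |>
    group_by(across(all_of(grp))) |>
    group_modify(function(d, key) {
      mid <- (d$start + d$end) / 2
      ord <- order(mid)
      ms <- mid[ord]
      rs <- d$log2_ratio[ord]
      cs <- c(0, cumsum(rs))
      lo <- findInterval(mid - hw, ms, left.open = TRUE) + 1L
      hi <- findInterval(mid + hw, ms)
      d$smoothed_ratio <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
      d
    }) |>
    ungroup()
}

#' Call positive probes at a smoothed-ratio cut-off
#'
#' A probe is a hit when its smoothed log2 ratio is at or above the cut-off
#' (inclusive; the published operating point sets the cut-off *at* 2).
#'
#' @param track Output of [smooth_sliding_window()].
#' @param cutoff Log2-ratio cut-off.
#' @return The hit rows of `track`.
#' @export
call_positive_probes <- function(track, cutoff = 2) {
  if (!"smoothed_ratio" %in% names(track)) {
    abort("run smooth_sliding_window() first")
  }
  filter(track, .data$smoothed_ratio >= cutoff)
}

#' Intersect hits across two biological replicates
#'
#' Reproducible positive probes (present in both replicates, matched by
#' `probe_id`) are the e4C hits.  The reported smoothed ratio is the mean of
#' the two replicates.
#'
#' @param rep1,rep2 Hit tibbles from [call_positive_probes()], from the same
#'   probe universe.
#' @return Hit tibble with `replicate_support = "both"`.
#' @export
reproducible_hits <- function(rep1, rep2) {
  if (anyDuplicated(rep1$probe_id) || anyDuplicated(rep2$probe_id)) {
    abort("duplicated probe_id within a replicate")
  }
  shared <- intersect(rep1$probe_id, rep2$probe_id)
  a <- filter(rep1, .data$probe_id %in% shared) |> arrange(.data$probe_id)
  b <- filter(rep2, .data$probe_id %in% shared) |> arrange(.data$probe_id)
  if (!identical(a$chrom, b$chrom) || !identical(a$start, b$start) ||
      !identical(a$end, b$end)) {
    abort("replicates disagree on probe coordinates: mismatched probe universes")
  }
  a |>
    mutate(smoothed_ratio = (a$smoothed_ratio + b$smoothed_ratio) / 2,
           replicate_support = "both") |>
    select(-any_of("replicate"))
}

#' Merge adjacent hits into peaks
#'
#' Hits on the same chromosome (and condition, when present) whose gap is at
#' most `max_gap` bp merge into one peak interval.  `max_gap = 0` merges
#' only touching probes — the most conservative reading of a "peak".
#'
#' @param hits Hit tibble with `chrom`, `start`, `end`.
#' @param max_gap Maximum merged gap in bp.
#' @return Peak tibble: `chrom` (and `condition`), `start`, `end`,
#'   `n_probes`, `max_smoothed_ratio`.
#' @export
merge_hits_to_peaks <- function(hits, max_gap = 0) {
  grp <- intersect(c("condition", "chrom"), names(hits))
  empty <- tibble(chrom = character(), start = numeric(), end = numeric(),
                  n_probes = integer(), max_smoothed_ratio = numeric())
  if (nrow(hits) == 0) return(empty)
  hits |>
    group_by(across(all_of(grp))) |>
    arrange(.data$start, .by_group = TRUE) |>
    mutate(new_run = .data$start - cummax_shift(.data$end) > max_gap,
           peak = cumsum(.data$new_run)) |>
    group_by(.data$peak, .add = TRUE) |>
    summarise(start = min(.data$start), end = max(.data$end),
              n_probes = n(),
              max_smoothed_ratio = if ("smoothed_ratio" %in% names(hits)) {
                max(.data$smoothed_ratio)
              } else NA_real_,
              .groups = "drop") |>
    select(-"peak")
}

# running max of `end` over previous rows (first row starts a run)
cummax_shift <- function(end) {
  if (length(end) == 0) return(numeric())
  c(-Inf, cummax(end)[-length(end)])
}

#' Peak counts and densities per chromosome
#'
#' @param peaks Peak tibble from [merge_hits_to_peaks()].
#' @param chrom_sizes Tibble with `chrom` and `length` (bp).
#' @return Tibble `chrom`, `n_peaks`, `peaks_per_mb`, zero-filled over every
#'   chromosome (crossed with `condition` when present).
#' @export
peak_density_by_chromosome <- function(peaks, chrom_sizes) {
  if (!all(peaks$chrom %in% chrom_sizes$chrom)) {
    abort("peak on a chromosome absent from `chrom_sizes`")
  }
  has_cond <- "condition" %in% names(peaks)
  frame <- if (has_cond) {
    crossing(condition = unique(peaks$condition) %||% character(),
             chrom = chrom_sizes$chrom)
  } else {
    tibble(chrom = chrom_sizes$chrom)
  }
  counts <- peaks |>
    group_by(across(all_of(intersect(c("condition", "chrom"), names(peaks))))) |>
    summarise(n_peaks = n(), .groups = "drop")
  frame |>
    left_join(counts, by = intersect(names(frame), names(counts))) |>
    mutate(n_peaks = coalesce(.data$n_peaks, 0L)) |>
    left_join(chrom_sizes, by = "chrom") |>
    mutate(peaks_per_mb = .data$n_peaks / (.data$length / 1e6)) |>
    select(-"length")
}
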