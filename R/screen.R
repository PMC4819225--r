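# End-to-end composition of the screen: hit calling -> gene mapping ->
# expression quantification -> candidate integration.

#' Run the full candidate screen
#'
#' Executes, for every condition: per-replicate log2 ratios, sliding-window
#' smoothing, cut-off calling, replicate-reproducibility filtering, peak
#' merging, per-chromosome densities and peak-to-gene mapping; then
#' spike-in quantification and the expression filters; and finally the
#' intersection of the LIF+-exclusive association and expression sets into
#' the candidate table (with optional STAT3 promoter scanning).
#'
#' @param arrays Probe-signal tibble (`probe_id`, `chrom`, `start`, `end`,
#'   `e4c`, `control`, `replicate`, `condition`).
#' @param genes Gene annotation tibble.
#' @param expression_intensities Long intensity tibble with spike rows (see
#'   [percellome_quantify()]).
#' @param chrom_sizes Tibble `chrom`, `length`.
#' @param config A [pipeline_config()].
#' @param genome Optional [Biostrings::DNAStringSet] for motif scanning.
#' @param pwm Optional `gfap4c_pwm`; with `genome`, candidates are scanned
#'   for STAT3 motifs within `config$stat3_window_bp` of the TSS.
#' @param target_condition Condition whose exclusive sets define the
#'   candidates.
#' @return Object of class `gfap4c_screen`: list with `hits`, `peaks`,
#'   `peak_density`, `associations`, `assoc_sets`, `expression`,
#'   `calibrations`, `expr_sets`, `candidates` and `manifest`.
#' @export
run_screen <- function(arrays, genes, expression_intensities, chrom_sizes,
                       config = pipeline_config(), genome = NULL,
                       pwm = NULL, target_condition = "LIF+") {
  conds <- unique(arrays$condition)

  smoothed <- arrays |>
    compute_probe_ratios(pseudocount = config$pseudocount) |>
    smooth_sliding_window(window_bp = config$window_bp)
  positive <- call_positive_probes(smoothed, cutoff = config$ratio_cutoff)
  hits <- positive |>
    group_by(.data$condition) |>
    group_map(function(d, key) {
      reproducible_hits(filter(d, .data$replicate == 1),
                        filter(d, .data$replicate == 2)) |>
        mutate(condition = key$condition)
    }) |>
    list_rbind()
  peaks <- merge_hits_to_peaks(hits, max_gap = config$max_gap_bp)
  density <- peak_density_by_chromosome(peaks, chrom_sizes)
  assoc <- map_peaks_to_genes(peaks, genes,
                              gene_distance_bp = config$gene_distance_bp)
  assoc_sets <- lapply(setNames(conds, conds), function(cc) {
    sort(assoc$gene_id[assoc$condition == cc])
  })
  assoc_excl <- exclusive_association_sets(assoc_sets)

  quant <- percellome_quantify(expression_intensities)
  other <- setdiff(conds, c(target_condition, "NPC"))
  up <- lapply(setNames(c(target_condition, other),
                        c(target_condition, other)), function(cc) {
    upregulated_genes(quant$expression, cc, "NPC",
                      fold = config$expr_fold,
                      floor = config$expr_floor_copies,
                      eps = config$expr_eps)
  })
  expr_excl <- sort(setdiff(up[[target_condition]],
                            unlist(up[names(up) != target_condition])))

  bins <- assoc |>
    filter(.data$condition == target_condition) |>
    select("gene_id", "distance_bin")
  stat3 <- NULL
  candidates <- integrate_candidates(
    assoc_excl$exclusive[[target_condition]], expr_excl, quant$expression,
    distance_bins = bins,
    symbols = select(genes, "gene_id", "symbol"),
    eps = config$expr_eps
  )
  if (!is.null(genome) && !is.null(pwm) && nrow(candidates) > 0) {
    stat3 <- scan_stat3(semi_join(genes, candidates, by = "gene_id"),
                        genome, pwm,
                        window_bp = config$stat3_window_bp,
                        score_fraction = config$pwm_score_fraction)
    candidates <- left_join(candidates, stat3, by = "gene_id")
  }
  structure(
    list(
      hits = hits, peaks = peaks, peak_density = density,
      associations = assoc, assoc_sets = assoc_sets,
      assoc_exclusive = assoc_excl, expression = quant$expression,
      calibrations = quant$calibrations, upregulated = up,
      expr_exclusive = expr_excl, stat3 = stat3, candidates = candidates,
      manifest = list(
        config = unclass(config), conditions = conds,
        n_probes = length(unique(arrays$probe_id)),
        n_genes = nrow(genes), target_condition = target_condition,
        timestamp = format(Sys.time(), tz = "UTC")
      )
    ),
    class = "gfap4c_screen"
  )
}

#' @export
print.gfap4c_screen <- function(x, ...) {
  cat("<gfap4c screen>\n")
  cat("  conditions:", paste(x$manifest$conditions, collapse = ", "), "\n")
  cat("  reproducible hits:", nrow(x$hits), " peaks:", nrow(x$peaks), "\n")
  cat("  candidates:", nrow(x$candidates), "\n")
  invisible(x)
}

#' @export
glance.gfap4c_screen <- function(x, ...) {
  tibble(
    n_probes = x$manifest$n_probes,
    n_hits = nrow(x$hits),
    n_peaks = nrow(x$peaks),
    n_assoc_exclusive = length(
      x$assoc_exclusive$exclusive[[x$manifest$target_condition]]
    ),
    n_expr_exclusive = length(x$expr_exclusive),
    n_candidates = nrow(x$candidates)
  )
}

#' Validate screen input files
#'
#' Light-weight schema checks for the documented plain-text formats; never
#' mutates inputs.  Supported formats: `"chrom_sizes"`, `"bed"`,
#' `"probe_tsv"`, `"fish_tsv"`, `"expression_tsv"`.
#'
#' @param paths Named character vector or list, names giving the format of
#'   each file.
#' @param chrom_sizes Optional chrom-sizes tibble for cross-referencing
#'   chromosome names.
#' @return Tibble `file`, `format`, `ok`, `problem` (first offending line
#'   number and message, `NA` when the file passes).
#' @export
validate_inputs <- function(paths, chrom_sizes = NULL) {
  checks <- imap(as.list(paths), function(path, fmt) {
    res <- tryCatch(validate_one(path, fmt, chrom_sizes),
                    error = function(e) conditionMessage(e))
    tibble(file = path, format = fmt, ok = is.na(res) || res == "",
           problem = if (is.na(res) || res == "") NA_character_ else res)
  })
  list_rbind(checks)
}

validate_one <- function(path, fmt, chrom_sizes) {
  if (!file.exists(path)) return("file does not exist")
  check_intervals <- function(d, start, end, chrom, offset) {
    bad <- which(d[[end]] <= d[[start]])
    if (length(bad)) {
      return(paste0("line ", bad[1] + offset, ": end <= start"))
    }
    if (!is.null(chrom_sizes) && !is.null(chrom)) {
      bad <- which(!d[[chrom]] %in% chrom_sizes$chrom)
      if (length(bad)) {
        return(paste0("line ", bad[1] + offset, ": unknown chromosome ",
                      d[[chrom]][bad[1]]))
      }
    }
    NA_character_
  }
  switch(
    fmt,
    chrom_sizes = {
      d <- readr::read_tsv(path, col_names = c("chrom", "length"),
                           show_col_types = FALSE)
      if (!is.numeric(d$length) || any(d$length <= 0)) {
        "non-positive chromosome length"
      } else NA_character_
    },
    bed = {
      d <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
      if (ncol(d) < 3) return("fewer than 3 BED columns")
      names(d)[1:3] <- c("chrom", "start", "end")
      check_intervals(d, "start", "end", "chrom", offset = 0)
    },
    probe_tsv = {
      d <- readr::read_tsv(path, show_col_types = FALSE)
      need <- c("probe_id", "chrom", "start", "end", "e4c", "control",
                "replicate", "condition")
      miss <- setdiff(need, names(d))
      if (length(miss)) {
        return(paste("missing columns:", paste(miss, collapse = ", ")))
      }
      if (any(d$e4c < 0 | d$control < 0)) return("negative intensity")
      check_intervals(d, "start", "end", "chrom", offset = 1)
    },
    fish_tsv = {
      d <- readr::read_tsv(path, show_col_types = FALSE)
      need <- c("nucleus_id", "condition", "gene", "x_um", "y_um", "z_um")
      miss <- setdiff(need, names(d))
      if (length(miss)) {
        return(paste("missing columns:", paste(miss, collapse = ", ")))
      }
      if (!all(is.finite(d$x_um) & is.finite(d$y_um) & is.finite(d$z_um))) {
        return("non-finite coordinates")
      }
      NA_character_
    },
    expression_tsv = {
      d <- readr::read_tsv(path, show_col_types = FALSE)
      need <- c("feature_id", "type", "condition", "intensity")
      miss <- setdiff(need, names(d))
      if (length(miss)) {
        return(paste("missing columns:", paste(miss, collapse = ", ")))
      }
      if (any(d$intensity < 0)) return("negative intensity")
      NA_character_
    },
    paste("unknown format:", fmt)
  )
}
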