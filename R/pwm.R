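# Position weight matrices: JASPAR-format reading, log-odds scoring and
# promoter-window scanning for STAT3-like motifs.

#' Build a PWM from a count (or probability) matrix
#'
#' @param counts 4 x L numeric matrix with rownames A, C, G, T.
#' @param pseudocount Added to every cell before column normalisation.
#' @param background Background base probabilities (recycled/normalised).
#' @return Object of class `gfap4c_pwm`: list with `prob` (4 x L, columns
#'   summing to 1), `background`, `length`.
#' @export
pwm_from_counts <- function(counts, pseudocount = 0.01,
                            background = rep(0.25, 4)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) abort("PWM matrix must have 4 rows (A, C, G, T)")
  if (is.null(rownames(counts))) rownames(counts) <- c("A", "C", "G", "T")
  counts <- counts[c("A", "C", "G", "T"), , drop = FALSE]
  if (any(counts < 0)) abort("counts must be nonnegative")
  prob <- sweep(counts + pseudocount, 2, colSums(counts + pseudocount), "/")
  background <- background / sum(background)
  names(background) <- c("A", "C", "G", "T")
  structure(list(prob = prob, background = background,
                 length = ncol(prob)), class = "gfap4c_pwm")
}

#' @export
print.gfap4c_pwm <- function(x, ...) {
  cat("<gfap4c_pwm> length", x$length, "consensus", pwm_consensus(x), "\n")
  invisible(x)
}

#' Consensus sequence of a PWM
#' @param pwm A `gfap4c_pwm`.
#' @return Single string of per-column argmax bases.
#' @export
pwm_consensus <- function(pwm) {
  paste(rownames(pwm$prob)[apply(pwm$prob, 2, which.max)], collapse = "")
}

#' Read a JASPAR plain-text matrix
#'
#' Supports the standard JASPAR layout: an optional `>ID NAME` header
#' followed by four lines like `A [ 10 20 ... ]` (brackets optional).
#'
#' @param path File path.
#' @inheritParams pwm_from_counts
#' @return A `gfap4c_pwm`.
#' @export
read_jaspar <- function(path, pseudocount = 0.01,
                        background = rep(0.25, 4)) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), ">")]
  rows <- lapply(lines, function(l) {
    l <- trimws(l)
    base <- substr(l, 1, 1)
    nums <- stringr::str_extract_all(l, "[0-9.eE+-]+")[[1]]
    list(base = toupper(base), counts = as.numeric(nums))
  })
  bases <- vapply(rows, `[[`, character(1), "base")
  if (!setequal(bases, c("A", "C", "G", "T"))) {
    abort("JASPAR file must contain one row each for A, C, G, T")
  }
  counts <- do.call(rbind, lapply(rows, `[[`, "counts"))
  rownames(counts) <- bases
  pwm_from_counts(counts, pseudocount = pseudocount, background = background)
}

#' Log-odds PWM score of fixed-length windows
#'
#' `score = sum_i log2(p_i(base_i) / background(base_i))`; `N` bases score
#' 0 (background).  Maximal on the consensus sequence.
#'
#' @param windows Character vector of sequences, each of `pwm$length`.
#' @param pwm A `gfap4c_pwm`.
#' @return Numeric vector of scores.
#' @export
#' @examples
#' p <- pwm_from_counts(matrix(c(1, 0, 0, 0), 4, 1,
#'                             dimnames = list(c("A", "C", "G", "T"), NULL)),
#'                      pseudocount = 0)
#' pwm_score("A", p)
pwm_score <- function(windows, pwm) {
  L <- pwm$length
  if (any(nchar(windows) != L)) {
    abort("every window must have the PWM's length")
  }
  lom <- log2(sweep(pwm$prob, 1, pwm$background, "/"))
  lom <- rbind(lom, N = 0)
  mat <- matrix(match(
    unlist(strsplit(toupper(windows), "", fixed = TRUE)),
    c("A", "C", "G", "T", "N")
  ), nrow = L)
  if (anyNA(mat)) abort("windows must use the A/C/G/T/N alphabet")
  colSums(lom[cbind(as.vector(mat), rep(seq_len(L), length(windows)))] |>
            matrix(nrow = L))
}

#' Maximum achievable PWM score
#' @param pwm A `gfap4c_pwm`.
#' @return Sum over columns of the maximal per-base log-odds.
#' @export
pwm_max_score <- function(pwm) {
  lom <- log2(sweep(pwm$prob, 1, pwm$background, "/"))
  sum(apply(lom, 2, max))
}

#' Scan a sequence for PWM hits on both strands
#'
#' @param sequence A [Biostrings::DNAString] or plain string.
#' @param pwm A `gfap4c_pwm`.
#' @param score_fraction Hit threshold as a fraction of [pwm_max_score()].
#' @return Tibble `position` (0-based offset of the window), `strand`,
#'   `score`.
#' @export
pwm_scan <- function(sequence, pwm, score_fraction = 0.8) {
  s <- toupper(as.character(sequence))
  L <- pwm$length
  n <- nchar(s) - L + 1
  if (n < 1) {
    return(tibble(position = integer(), strand = character(),
                  score = numeric()))
  }
  thr <- score_fraction * pwm_max_score(pwm)
  wins <- substring(s, seq_len(n), seq_len(n) + L - 1)
  fwd <- pwm_score(wins, pwm)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  wins_rc <- substring(rc, seq_len(n), seq_len(n) + L - 1)
  rev <- pwm_score(wins_rc, pwm)
  bind_rows(
    tibble(position = seq_len(n) - 1L, strand = "+", score = fwd),
    # map rc window offsets back to plus-strand coordinates
    tibble(position = nchar(s) - L - (seq_len(n) - 1L), strand = "-",
           score = rev)
  ) |>
    filter(.data$score >= thr) |>
    arrange(.data$position)
}

#' Flag STAT3 motifs near gene TSSs
#'
#' Scans both strands of the window `TSS +/- window_bp` (clipped to the
#' chromosome) for PWM hits at `score_fraction` of the maximum score.
#'
#' @param genes Gene tibble (`gene_id`, `chrom`, `tss`).
#' @param genome Named [Biostrings::DNAStringSet].
#' @param pwm A `gfap4c_pwm`.
#' @param window_bp Half-width of the scanned promoter window.
#' @param score_fraction Hit threshold as fraction of the maximum score.
#' @return Tibble `gene_id`, `stat3_site` (logical), `n_hits`, `best_score`.
#' @export
scan_stat3 <- function(genes, genome, pwm, window_bp = 5000,
                       score_fraction = 0.8) {
  if (!all(genes$chrom %in% names(genome))) {
    abort("gene chromosome missing from genome")
  }
  rows <- map(seq_len(nrow(genes)), function(i) {
    ch <- genome[[genes$chrom[i]]]
    lo <- max(genes$tss[i] - window_bp, 0)
    hi <- min(genes$tss[i] + window_bp, length(ch))
    hits <- pwm_scan(Biostrings::subseq(ch, lo + 1, hi), pwm,
                     score_fraction = score_fraction)
    tibble(gene_id = genes$gene_id[i], stat3_site = nrow(hits) > 0,
           n_hits = nrow(hits),
           best_score = if (nrow(hits)) max(hits$score) else NA_real_)
  })
  list_rbind(rows)
}
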