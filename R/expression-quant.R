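# Spike-in (Percellome-style) calibration of array intensities to mRNA
# copies per cell, expression filters and Venn partitions.

#' Fit a spike-in calibration for one sample
#'
#' Ordinary least squares of log2(intensity) on log2(known copies) over the
#' external spike set.  Inverting the line converts any intensity in the
#' same sample to copies of mRNA per cell.
#'
#' @param spikes Tibble with `known_copies` and `intensity` columns (one row
#'   per spike); rows with non-positive copies are ignored for the fit.
#' @return An object of class `percellome_fit` with `slope`, `intercept`
#'   (log2-log2 scale), `sigma` (residual sd), `r_squared` and `n_spikes`.
#' @export
#' @examples
#' sp <- tibble::tibble(known_copies = c(1, 10, 100),
#'                      intensity = 10 * known_copies)
#' fit <- fit_spike_calibration(sp)
#' tidy(fit)
fit_spike_calibration <- function(spikes) {
  use <- spikes[spikes$known_copies > 0 & spikes$intensity > 0, ]
  if (nrow(use) < 2 || length(unique(use$known_copies)) < 2) {
    abort("need >= 2 spikes with distinct positive copies to calibrate")
  }
  x <- log2(use$known_copies)
  y <- log2(use$intensity)
  fit <- lm(y ~ x)
  # summary.lm warns on a zero-residual (noiseless) fit; that case is valid
  s <- suppressWarnings(summary(fit))
  structure(
    list(
      intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
      sigma = s$sigma, r_squared = s$r.squared, n_spikes = nrow(use),
      fit = fit
    ),
    class = "percellome_fit"
  )
}

#' @export
print.percellome_fit <- function(x, ...) {
  cat(sprintf(
    "<percellome_fit> log2(I) = %.4f + %.4f * log2(copies)  (n = %d, sigma = %.3g)\n",
    x$intercept, x$slope, x$n_spikes, x$sigma
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.percellome_fit <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope),
         std.error = unname(
           suppressWarnings(summary(x$fit))$coefficients[, "Std. Error"]
         ))
}

#' @export
glance.percellome_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, sigma = x$sigma, n_spikes = x$n_spikes)
}

#' Convert intensities to mRNA copies per cell
#'
#' Applies the inverse of a per-sample spike calibration:
#' `copies = 2^((log2(intensity) - intercept) / slope)`.  Zero intensities
#' map to zero copies.  Monotone in intensity.
#'
#' @param intensities Tibble with `feature_id`, `condition`, `intensity`
#'   (long format, one row per feature and sample).
#' @param calibrations Named list of [fit_spike_calibration()] objects, one
#'   per condition present in `intensities`.
#' @return The input with a `copies` column.
#' @export
percellome_normalize <- function(intensities, calibrations) {
  if (any(intensities$intensity < 0)) abort("negative intensity")
  conds <- unique(intensities$condition)
  if (!all(conds %in% names(calibrations))) {
    abort("missing calibration for some condition")
  }
  intensities |>
    group_by(.data$condition) |>
    group_modify(function(d, key) {
      cal <- calibrations[[key$condition]]
      d$copies <- ifelse(
        d$intensity == 0, 0,
        2^((log2(d$intensity) - cal$intercept) / cal$slope)
      )
      d
    }) |>
    ungroup()
}

#' Fit calibrations and normalise in one step
#'
#' Convenience wrapper: fits one spike calibration per condition from the
#' spike rows of a combined intensity table (as produced by
#' [simulate_expression()]) and converts the gene rows to copies per cell.
#'
#' @param intensities Long tibble with `feature_id`, `type`
#'   (`"gene"`/`"spike"`), `condition`, `intensity`, `known_copies`.
#' @return List with `expression` (tibble `gene_id`, `condition`, `copies`)
#'   and `calibrations` (named list of `percellome_fit`).
#' @export
percellome_quantify <- function(intensities) {
  conds <- unique(intensities$condition)
  cals <- lapply(setNames(conds, conds), function(cc) {
    sp <- filter(intensities, .data$condition == cc, .data$type == "spike")
    fit_spike_calibration(sp)
  })
  genes <- filter(intensities, .data$type == "gene")
  expr <- percellome_normalize(genes, cals) |>
    transmute(gene_id = .data$feature_id, condition = .data$condition,
              copies = .data$copies)
  list(expression = expr, calibrations = cals)
}

#' Genes upregulated in one condition over another
#'
#' A gene is upregulated when its copies in the numerator condition are at
#' least `floor` (genes below one copy per cell are not considered
#' expressed) and the numerator/denominator copies ratio is at least `fold`
#' (inclusive).  The denominator is guarded by `eps` copies.
#'
#' @param expr Long expression tibble (`gene_id`, `condition`, `copies`) or
#'   wide tibble with one column per condition.
#' @param numerator,denominator Condition names.
#' @param fold Minimum fold change (inclusive).
#' @param floor Minimum numerator copies (inclusive).
#' @param eps Denominator guard in copies.
#' @return Character vector of upregulated `gene_id`s.
#' @export
upregulated_genes <- function(expr, numerator, denominator, fold = 2,
                              floor = 1, eps = 0.01) {
  wide <- expression_wide(expr, c(numerator, denominator))
  num <- wide[[numerator]]
  den <- wide[[denominator]]
  keep <- num >= floor & num / pmax(den, eps) >= fold
  sort(wide$gene_id[keep])
}

# accept long (gene_id, condition, copies) or wide layout
expression_wide <- function(expr, conditions) {
  if (all(c("condition", "copies") %in% names(expr))) {
    expr <- pivot_wider(expr, id_cols = "gene_id",
                        names_from = "condition", values_from = "copies")
  }
  missing <- setdiff(conditions, names(expr))
  if (length(missing)) {
    abort(paste("conditions absent from expression table:",
                paste(missing, collapse = ", ")))
  }
  expr
}

#' Venn partition of 2 or 3 named gene sets
#'
#' @param sets Named list of 2 or 3 character vectors.
#' @return Tibble with one row per non-empty region pattern: `region`
#'   (set names joined by `&`), `degree`, `n`, and `genes` (list column).
#'   Region counts sum to the size of the union; every gene falls in
#'   exactly one region.
#' @export
#' @examples
#' venn_partition(list(A = c("g1", "g2"), B = c("g2", "g3")))
venn_partition <- function(sets) {
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == "") ||
      !(length(sets) %in% 2:3)) {
    abort("`sets` must be a named list of 2 or 3 character vectors")
  }
  universe <- sort(unique(unlist(sets)))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  member <- matrix(member, nrow = length(universe),
                   dimnames = list(NULL, names(sets)))
  pattern <- apply(member, 1, function(r) {
    paste(names(sets)[r], collapse = "&")
  })
  patterns <- unlist(lapply(seq_along(sets), function(k) {
    combn(names(sets), k, paste, collapse = "&")
  }))
  tibble(region = patterns) |>
    mutate(degree = stringr::str_count(.data$region, "&") + 1L,
           genes = map(.data$region, function(p) universe[pattern == p]),
           n = lengths(.data$genes)) |>
    select("region", "degree", "n", "genes")
}
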