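# Spatial association from 3D DNA-FISH coordinates and the validation
# statistics: residual analysis of chi-squared tests, Fisher's exact test,
# two-sample Kolmogorov-Smirnov and one-way ANOVA.

#' Shortest inter-locus distance per nucleus
#'
#' Minimum Euclidean distance over all allele pairs of two genes within
#' each nucleus.  Nuclei missing a signal for either gene are dropped and
#' reported in the `skipped` attribute.
#'
#' @param fish FISH signal tibble (`nucleus_id`, `condition`, `gene`,
#'   `x_um`, `y_um`, `z_um`).
#' @param gene_a,gene_b Gene symbols.
#' @return Tibble `nucleus_id`, `condition`, `distance_um`, with attribute
#'   `skipped` (tibble of dropped nuclei and the missing gene).
#' @export
min_pair_distance <- function(fish, gene_a, gene_b) {
  sub <- filter(fish, .data$gene %in% c(gene_a, gene_b))
  per_nuc <- sub |>
    group_by(.data$nucleus_id, .data$condition) |>
    group_modify(function(d, key) {
      a <- filter(d, .data$gene == gene_a)
      b <- filter(d, .data$gene == gene_b)
      if (nrow(a) == 0 || nrow(b) == 0) {
        return(tibble(distance_um = NA_real_,
                      missing = if (nrow(a) == 0) gene_a else gene_b))
      }
      dm <- outer(seq_len(nrow(a)), seq_len(nrow(b)), function(i, j) {
        sqrt((a$x_um[i] - b$x_um[j])^2 + (a$y_um[i] - b$y_um[j])^2 +
               (a$z_um[i] - b$z_um[j])^2)
      })
      tibble(distance_um = min(dm), missing = NA_character_)
    }) |>
    ungroup()
  skipped <- per_nuc |>
    filter(!is.na(.data$missing)) |>
    select("nucleus_id", "condition", "missing")
  out <- per_nuc |>
    filter(is.na(.data$missing)) |>
    select("nucleus_id", "condition", "distance_um")
  attr(out, "skipped") <- skipped
  out
}

#' Call spatial association at a distance threshold
#'
#' Two loci are associated when their shortest 3D distance is within the
#' threshold (inclusive at exactly 500 nm).
#'
#' @param distance_um Numeric distances in microns.
#' @param threshold_nm Threshold in nanometres.
#' @return Logical vector.
#' @export
call_association <- function(distance_um, threshold_nm = 500) {
  if (any(distance_um < 0, na.rm = TRUE)) abort("distances must be >= 0")
  distance_um <= threshold_nm / 1000
}

#' Per-condition association frequencies for a gene pair
#'
#' A nucleus counts as associated when its shortest inter-locus distance is
#' within the threshold.  Returns per-condition counts/fractions and the
#' 2 x k contingency table (associated / not x condition) that feeds
#' [chisq_residual_test()].
#'
#' @param fish FISH signal tibble.
#' @param gene_a,gene_b Gene symbols.
#' @param threshold_nm Association threshold.
#' @param conditions Conditions to keep (default: all present); empty
#'   conditions are dropped with a warning.
#' @return List: `frequencies` (tibble `condition`, `n_assoc`, `n_total`,
#'   `fraction`), `table` (2 x k matrix), `distances` (per-nucleus tibble).
#' @export
association_frequencies <- function(fish, gene_a, gene_b,
                                    threshold_nm = 500, conditions = NULL) {
  d <- min_pair_distance(fish, gene_a, gene_b)
  conditions <- conditions %||% unique(d$condition)
  absent <- setdiff(conditions, unique(d$condition))
  if (length(absent)) {
    warn(paste("no evaluable nuclei in condition(s):",
               paste(absent, collapse = ", ")))
    conditions <- setdiff(conditions, absent)
  }
  if (length(conditions) == 0) abort("no evaluable condition")
  d <- filter(d, .data$condition %in% conditions) |>
    mutate(associated = call_association(.data$distance_um, threshold_nm))
  freq <- d |>
    group_by(condition = factor(.data$condition, levels = conditions)) |>
    summarise(n_assoc = sum(.data$associated), n_total = n(),
              fraction = mean(.data$associated), .groups = "drop") |>
    mutate(condition = as.character(.data$condition))
  tab <- rbind(associated = freq$n_assoc,
               not_associated = freq$n_total - freq$n_assoc)
  colnames(tab) <- freq$condition
  list(frequencies = freq, table = tab, distances = d)
}

#' Chi-squared test with adjusted standardized residuals
#'
#' Pearson chi-squared test of independence on an r x c table plus
#' Haberman adjusted standardized residuals
#' `(O - E) / sqrt(E (1 - rowsum/N) (1 - colsum/N))`, flagged at
#' |z| > 1.96 (`*`, P < 0.05) and |z| > 2.58 (`**`, P < 0.01).
#'
#' @param table Matrix of nonnegative counts.
#' @return Object of class `gfap4c_chisq`: list with `statistic`, `df`,
#'   `p_value`, `expected`, `residuals` (adjusted standardized), `signif`
#'   (character matrix of significance marks).
#' @export
chisq_residual_test <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || sum(table) == 0) {
    abort("need a nonnegative table with positive total")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("degenerate table: a zero row or column margin")
  }
  ct <- suppressWarnings(chisq.test(table, correct = FALSE))
  z <- ct$stdres
  marks <- matrix("", nrow(z), ncol(z), dimnames = dimnames(z))
  marks[abs(z) > 1.96] <- "*"
  marks[abs(z) > 2.58] <- "**"
  structure(
    list(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p_value = ct$p.value, expected = ct$expected, residuals = z,
         signif = marks, observed = table),
    class = "gfap4c_chisq"
  )
}

#' @export
print.gfap4c_chisq <- function(x, ...) {
  cat(sprintf("<chi-squared residual analysis> X2 = %.4g, df = %d, p = %.3g\n",
              x$statistic, x$df, x$p_value))
  print(round(x$residuals, 2))
  invisible(x)
}

#' @export
tidy.gfap4c_chisq <- function(x, ...) {
  as_tibble(as.table(x$observed), .name_repair = "minimal") |>
    setNames(c("row", "col", "observed")) |>
    mutate(expected = as.vector(x$expected),
           adj_residual = as.vector(x$residuals),
           signif = as.vector(x$signif))
}

#' @export
glance.gfap4c_chisq <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p.value = x$p_value)
}

#' Fisher's exact test for a 2 x 2 table
#'
#' Two-sided p by hypergeometric probability ordering; the reported odds
#' ratio is the sample estimate `(ad)/(bc)`, with a 0.5 continuity
#' correction applied to every cell when any cell is zero.
#'
#' @param table 2 x 2 matrix of counts.
#' @return Tibble `odds_ratio`, `p_value`.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) abort("need a 2 x 2 table")
  p <- fisher.test(table)$p.value
  t2 <- if (any(table == 0)) table + 0.5 else table
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  tibble(odds_ratio = or, p_value = p)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D = sup |ECDF_a - ECDF_b|`; exact p-value when both samples have at
#' most `exact_n_max` observations, asymptotic otherwise.
#'
#' @param distances_a,distances_b Numeric samples.
#' @param exact_n_max Exact-p sample-size limit.
#' @return Tibble `statistic`, `p_value`, `exact`.
#' @export
ks_two_sample <- function(distances_a, distances_b, exact_n_max = 25) {
  if (length(distances_a) == 0 || length(distances_b) == 0) {
    abort("both samples must be nonempty")
  }
  exact <- length(distances_a) <= exact_n_max &&
    length(distances_b) <= exact_n_max
  kt <- suppressWarnings(ks.test(distances_a, distances_b, exact = exact))
  tibble(statistic = unname(kt$statistic), p_value = kt$p.value,
         exact = exact)
}

#' One-way ANOVA
#'
#' Classical between/within mean-square F ratio, e.g. to compare nuclear
#' diameters across culture conditions.
#'
#' @param values Numeric vector of measurements, or a named list of groups
#'   (in which case `group` is ignored).
#' @param group Grouping vector parallel to `values`.
#' @return Tibble `f_statistic`, `df1`, `df2`, `p_value`.
#' @export
anova_oneway <- function(values, group = NULL) {
  if (is.list(values)) {
    group <- rep(names(values) %||% seq_along(values), lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  group <- factor(group)
  if (nlevels(group) < 2 || any(table(group) < 2)) {
    abort("need >= 2 groups with >= 2 values each")
  }
  if (all(tapply(values, group, sd) == 0) &&
      length(unique(tapply(values, group, mean))) == 1) {
    abort("F undefined: zero variance everywhere with equal means")
  }
  ft <- oneway.test(values ~ group, var.equal = TRUE)
  tibble(f_statistic = unname(ft$statistic),
         df1 = unname(ft$parameter[1]), df2 = unname(ft$parameter[2]),
         p_value = ft$p.value)
}

#' Association of bait allele activity with partner proximity
#'
#' Per bait allele (not per nucleus): an allele is associated when its
#' nearest partner-gene signal in the same nucleus is within the threshold.
#' Crossing the call with the allele's transcriptional activity gives a
#' 2 x 2 table tested with Fisher's exact test.
#'
#' @param fish FISH tibble with `allele_active` labels on the bait gene.
#' @param bait,partner Gene symbols.
#' @param threshold_nm Association threshold.
#' @return List: `table` (activity x association matrix), `fisher`
#'   ([fisher_exact_2x2()] result), `alleles` (per-allele tibble).
#' @export
allele_activity_association <- function(fish, bait = "bait", partner,
                                        threshold_nm = 500) {
  b <- filter(fish, .data$gene == bait, !is.na(.data$allele_active))
  if (nrow(b) == 0) abort("no bait alleles with activity labels")
  p <- filter(fish, .data$gene == partner)
  alleles <- b |>
    left_join(
      p |> select("nucleus_id", px = "x_um", py = "y_um", pz = "z_um"),
      by = "nucleus_id", relationship = "many-to-many"
    ) |>
    mutate(d = sqrt((.data$x_um - .data$px)^2 + (.data$y_um - .data$py)^2 +
                      (.data$z_um - .data$pz)^2)) |>
    group_by(.data$nucleus_id, .data$allele, .data$allele_active) |>
    summarise(min_distance_um = min(.data$d), .groups = "drop") |>
    mutate(associated = call_association(.data$min_distance_um,
                                         threshold_nm))
  tab <- matrix(
    c(sum(alleles$allele_active & alleles$associated),
      sum(alleles$allele_active & !alleles$associated),
      sum(!alleles$allele_active & alleles$associated),
      sum(!alleles$allele_active & !alleles$associated)),
    nrow = 2, byrow = TRUE,
    dimnames = list(activity = c("active", "inactive"),
                    association = c("associated", "not_associated"))
  )
  list(table = tab, fisher = fisher_exact_2x2(tab), alleles = alleles)
}

#' Fraction of nuclei with three mutually proximal loci
#'
#' A nucleus is triple-colocalised when every pairwise shortest distance
#' among the three genes is within the threshold.  The triple fraction can
#' never exceed any pairwise association fraction.
#'
#' @param fish FISH tibble.
#' @param genes Character vector of three gene symbols.
#' @param threshold_nm Association threshold.
#' @return Tibble `condition`, `n_triple`, `n_total`, `fraction`.
#' @export
triple_colocalization <- function(fish, genes, threshold_nm = 500) {
  if (length(genes) != 3) abort("need exactly three genes")
  pairs <- utils::combn(genes, 2, simplify = FALSE)
  per_pair <- map(pairs, function(p) {
    min_pair_distance(fish, p[1], p[2]) |>
      mutate(pair = paste(p, collapse = ":"))
  }) |>
    list_rbind()
  per_nuc <- per_pair |>
    group_by(.data$nucleus_id, .data$condition) |>
    summarise(
      complete = n() == 3,
      triple = all(call_association(.data$distance_um, threshold_nm)),
      .groups = "drop"
    ) |>
    filter(.data$complete)
  per_nuc |>
    group_by(.data$condition) |>
    summarise(n_triple = sum(.data$triple), n_total = n(),
              fraction = mean(.data$triple), .groups = "drop")
}
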