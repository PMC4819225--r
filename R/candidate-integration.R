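# Intersection of condition-exclusive association and expression sets into
# the candidate gene table, and the packaged published-candidate fixture.

#' Per-condition exclusive association sets
#'
#' `exclusive[[c]]` contains the genes associated in condition `c` and in no
#' other condition; `overlaps` carries the three pairwise intersection
#' counts and the triple overlap.
#'
#' @param sets Named list of per-condition associated gene sets (character
#'   vectors), usually NPC / LIF+ / LIF-.
#' @return List with `exclusive` (named list), `overlaps` (tibble `pair`,
#'   `n`) and `partition` (the full [venn_partition()]).
#' @export
exclusive_association_sets <- function(sets) {
  if (!is.list(sets) || is.null(names(sets)) || length(sets) < 2) {
    abort("`sets` must be a named list of >= 2 gene sets")
  }
  exclusive <- imap(sets, function(s, nm) {
    sort(setdiff(s, unlist(sets[names(sets) != nm])))
  })
  pairs <- utils::combn(names(sets), 2, simplify = FALSE)
  overlaps <- tibble(
    pair = map_chr2(pairs, paste, collapse = " & "),
    n = map_int(pairs, function(p) length(intersect(sets[[p[1]]],
                                                    sets[[p[2]]])))
  )
  if (length(sets) == 3) {
    overlaps <- bind_rows(overlaps, tibble(
      pair = paste(names(sets), collapse = " & "),
      n = length(Reduce(intersect, sets))
    ))
  }
  part <- if (length(sets) %in% 2:3) venn_partition(sets) else NULL
  list(exclusive = exclusive, overlaps = overlaps, partition = part)
}

map_chr2 <- function(x, f, ...) vapply(x, f, character(1), ...)

#' Build the candidate gene table
#'
#' Candidates are the genes present in both the LIF+-exclusive association
#' set and the LIF+-exclusive expression set.  The two input sets are taken
#' as given (not re-derived), copies come from the expression matrix, fold
#' columns are recomputed from the copies, and rows are sorted by
#' LIF+/NPC fold, descending.
#'
#' @param assoc_exclusive Character vector: bait-associated genes exclusive
#'   to the numerator condition.
#' @param expr_exclusive Character vector: genes upregulated exclusively in
#'   the numerator condition.
#' @param expr Expression tibble, long (`gene_id`, `condition`, `copies`) or
#'   wide.
#' @param distance_bins Optional tibble `gene_id`, `distance_bin` (from
#'   [map_peaks_to_genes()]).
#' @param stat3_flags Optional tibble `gene_id`, `stat3_site` (from
#'   [scan_stat3()]).
#' @param symbols Optional tibble `gene_id`, `symbol`.
#' @param eps Denominator guard in copies for the fold columns.
#' @return Candidate tibble with copies, fold, STAT3 and distance-bin
#'   columns, one row per candidate gene.
#' @export
integrate_candidates <- function(assoc_exclusive, expr_exclusive, expr,
                                 distance_bins = NULL, stat3_flags = NULL,
                                 symbols = NULL, eps = 0.01) {
  ids <- intersect(assoc_exclusive, expr_exclusive)
  wide <- expression_wide(expr, conditions_all())
  out <- tibble(gene_id = ids) |>
    left_join(wide, by = "gene_id") |>
    mutate(
      fold_lifplus_npc = .data$`LIF+` / pmax(.data$NPC, eps),
      fold_lifminus_npc = .data$`LIF-` / pmax(.data$NPC, eps)
    ) |>
    rename(copies_npc = "NPC", copies_lifplus = "LIF+",
           copies_lifminus = "LIF-")
  if (!is.null(symbols)) {
    out <- left_join(out, symbols, by = "gene_id") |>
      relocate("symbol", .after = "gene_id")
  }
  if (!is.null(distance_bins)) {
    out <- left_join(out, select(distance_bins, "gene_id", "distance_bin"),
                     by = "gene_id")
  }
  if (!is.null(stat3_flags)) {
    out <- left_join(out, select(stat3_flags, "gene_id", "stat3_site"),
                     by = "gene_id")
  }
  arrange(out, desc(.data$fold_lifplus_npc), .data$gene_id)
}

#' Read the packaged published candidate table
#'
#' The fixture `table1.tsv` transcribes the published 18-gene candidate
#' list: mRNA copies per cell in NPC, LIF+ and LIF- cultures, printed fold
#' changes, STAT3 promoter-motif flag and peak-to-gene distance bin.
#'
#' @param path Path to a candidate TSV; defaults to the packaged fixture.
#' @return Tibble with `accession`, `symbol`, `copies_npc`,
#'   `copies_lifplus`, `copies_lifminus`, `fold_lifplus_npc`,
#'   `fold_lifminus_npc`, `stat3_site` (logical), `distance_bin`.
#' @export
read_candidate_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "table1.tsv", package = "gfap4c")
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    Accession = "c", Symbol = "c", STAT3_site = "c",
                    Distance_bin = "c", .default = "d"
                  )) |>
    transmute(
      accession = .data$Accession, symbol = .data$Symbol,
      copies_npc = .data$NPCs, copies_lifplus = .data$`LIF+`,
      copies_lifminus = .data$`LIF-`,
      fold_lifplus_npc = .data$`LIF+/NPCs`,
      fold_lifminus_npc = .data$`LIF-/NPCs`,
      stat3_site = .data$STAT3_site %in% c("yes", "TRUE", "o", "circle"),
      distance_bin = .data$Distance_bin
    )
}

#' Write a candidate table as TSV
#'
#' Copies and folds are rounded to 2 decimals at output time only.
#'
#' @param candidates Candidate tibble ([integrate_candidates()] or
#'   [read_candidate_table()] layout).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_candidate_table <- function(candidates, path) {
  out <- candidates |>
    mutate(across(where(is.numeric), ~ round(.x, 2)))
  readr::write_tsv(out, path)
  invisible(path)
}
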