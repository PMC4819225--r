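# small builders shared across test files

tiny_synth_config <- function(..., seed = 11L) {
  synthetic_config(
    n_chromosomes = 2, chrom_length_bp = 1e6, n_genes = 20,
    n_planted_assoc_genes = 3, n_planted_expr_genes = 3,
    n_planted_shared_expr_genes = 2, n_planted_other_assoc_genes = 2,
    seed = seed, ...
  )
}

probe_track <- function(mids, ratios, chrom = "chr1", width = 10) {
  tibble::tibble(
    probe_id = sprintf("p%03d", seq_along(mids)), chrom = chrom,
    start = mids - width / 2, end = mids + width / 2, log2_ratio = ratios
  )
}

unit_sphere_fish <- function(positions, gene = rep("bait", nrow(positions)),
                             nucleus_id = "n1", condition = "LIF+") {
  tibble::tibble(
    nucleus_id = nucleus_id, condition = condition, gene = gene,
    allele = stats::ave(seq_len(nrow(positions)), gene, FUN = seq_along),
    x_um = positions[, 1], y_um = positions[, 2], z_um = positions[, 3],
    allele_active = NA, nucleus_diameter_um = 10
  )
}
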