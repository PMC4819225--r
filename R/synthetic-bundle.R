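# One-call synthetic study: genome, digestion-based probe array, planted
# bait contacts, spike-calibrated expression arrays, and ground truth.

#' Simulate a complete screen input bundle with known ground truth
#'
#' Generates every input the screen consumes.  Planted LIF+-specific
#' contact regions are anchored on a real array probe 10-30 kb from the
#' TSS of each planted gene (the distance band where bait-contact probes
#' concentrate), so each contact is observable on the array by
#' construction.  Planted genes are chosen pairwise at least `min_sep_bp`
#' apart so that one gene's contact cannot fall within the mapping distance
#' of another planted gene.  A set of bait-proximal contacts shared by all
#' conditions is planted on chromosome 1 around the bait gene, reproducing
#' the expected excess of cis peaks on the bait chromosome.
#'
#' @param config A [synthetic_config()].
#' @param min_sep_bp Minimum separation between planted genes.
#' @param n_bait_contacts Bait-proximal cis contacts shared by all
#'   conditions.
#' @return List with `config`, `chrom_sizes`, `genes`, `genome`,
#'   `fragments`, `probes`, `planted_intervals`, `arrays`, `expression`
#'   (intensities + truth), and `truth` (list of gene-id sets:
#'   `assoc_lifplus`, `assoc_npc`, `assoc_lifminus`, `expr_lifplus`,
#'   `expr_shared`, `candidates`, plus `bait_gene`).
#' @export
simulate_screen_bundle <- function(config = synthetic_config(),
                                   min_sep_bp = 150000,
                                   n_bait_contacts = 5) {
  gen <- simulate_genome(config)
  genome <- simulate_genome_sequence(config, gen$chrom_sizes)
  fragments <- digest_genome(genome, config$enzyme_a, config$enzyme_b,
                             config$min_fragment_bp)
  probes <- design_probes(fragments, config$probe_bp)

  withr::local_seed(config$seed + 106L)
  genes <- gen$genes
  probe_mid <- (probes$start + probes$end) / 2

  # probes 10-30 kb from a gene's TSS, candidates for contact anchors
  anchor_for <- function(gi) {
    on_chr <- which(probes$chrom == genes$chrom[gi])
    d <- abs(probe_mid[on_chr] - genes$tss[gi])
    ok <- on_chr[d >= 10000 & d <= 30000]
    if (length(ok) == 0) return(NA_integer_)
    if (length(ok) == 1) ok else sample(ok, 1)
  }

  # greedy selection of planted genes, pairwise >= min_sep_bp apart
  eligible <- which(!is.na(vapply(seq_len(nrow(genes)), anchor_for,
                                  integer(1))))
  n_needed <- config$n_planted_assoc_genes + config$n_planted_expr_genes +
    config$n_planted_shared_expr_genes + 2 * config$n_planted_other_assoc_genes
  picked <- integer()
  for (gi in sample(eligible)) {
    if (length(picked) >= n_needed) break
    far <- all(genes$chrom[picked] != genes$chrom[gi] |
                 abs(genes$tss[picked] - genes$tss[gi]) >= min_sep_bp)
    if (far) picked <- c(picked, gi)
  }
  if (length(picked) < n_needed) {
    abort(paste0("could only place ", length(picked), " of ", n_needed,
                 " planted genes ", min_sep_bp,
                 " bp apart; enlarge the genome or reduce planting"))
  }
  n_shared_truth <- min(config$n_planted_assoc_genes,
                        config$n_planted_expr_genes)
  take <- function(n) {
    if (n == 0) return(integer())
    out <- picked[seq_len(n)]
    picked <<- picked[-seq_len(n)]
    out
  }
  both_idx <- take(n_shared_truth)
  assoc_only_idx <- take(config$n_planted_assoc_genes - n_shared_truth)
  expr_only_idx <- take(config$n_planted_expr_genes - n_shared_truth)
  shared_expr_idx <- take(config$n_planted_shared_expr_genes)
  npc_idx <- take(config$n_planted_other_assoc_genes)
  lifminus_idx <- take(config$n_planted_other_assoc_genes)

  hw <- config$contact_halfwidth_bp
  plant <- function(idx, condition) {
    if (length(idx) == 0) {
      return(tibble(chrom = character(), start = numeric(), end = numeric(),
                    condition = character(), gene_id = character()))
    }
    anchors <- vapply(idx, anchor_for, integer(1))
    tibble(
      chrom = genes$chrom[idx],
      start = pmax(probe_mid[anchors] - hw, 0),
      end = pmin(probe_mid[anchors] + hw, config$chrom_length_bp),
      condition = condition,
      gene_id = genes$gene_id[idx]
    )
  }
  assoc_lifplus_idx <- c(both_idx, assoc_only_idx)
  planted <- bind_rows(
    plant(assoc_lifplus_idx, "LIF+"),
    plant(npc_idx, "NPC"),
    plant(lifminus_idx, "LIF-")
  )

  # bait gene: first chr1 gene far from every planted gene; cis contacts
  # around it in every condition
  free_chr1 <- which(genes$chrom == "chr1" &
                       !(seq_len(nrow(genes)) %in%
                           c(both_idx, assoc_only_idx, expr_only_idx,
                             shared_expr_idx, npc_idx, lifminus_idx)))
  sep_ok <- vapply(free_chr1, function(gi) {
    others <- setdiff(c(both_idx, assoc_only_idx, expr_only_idx,
                        shared_expr_idx, npc_idx, lifminus_idx), gi)
    all(genes$chrom[others] != "chr1" |
          abs(genes$tss[others] - genes$tss[gi]) >= min_sep_bp)
  }, logical(1))
  bait_idx <- free_chr1[sep_ok][1]
  bait_contacts <- NULL
  if (!is.na(bait_idx) && n_bait_contacts > 0) {
    on_chr1 <- which(probes$chrom == "chr1")
    near <- on_chr1[abs(probe_mid[on_chr1] - genes$tss[bait_idx]) <= 1e6]
    # keep bait contacts away from all planted genes
    pl_all <- c(both_idx, assoc_only_idx, expr_only_idx, shared_expr_idx,
                npc_idx, lifminus_idx)
    pl_chr1 <- pl_all[genes$chrom[pl_all] == "chr1"]
    if (length(pl_chr1)) {
      dist_ok <- vapply(near, function(pi) {
        all(abs(probe_mid[pi] - genes$tss[pl_chr1]) >= min_sep_bp)
      }, logical(1))
      near <- near[dist_ok]
    }
    if (length(near) > 0) {
      anchors <- sample(near, min(n_bait_contacts, length(near)))
      bait_contacts <- crossing(condition = conditions_all(),
                                anchor = anchors) |>
        mutate(chrom = "chr1",
               start = pmax(probe_mid[.data$anchor] - hw, 0),
               end = pmin(probe_mid[.data$anchor] + hw,
                          config$chrom_length_bp),
               gene_id = genes$gene_id[bait_idx]) |>
        select("chrom", "start", "end", "condition", "gene_id")
    }
  }
  planted <- bind_rows(planted, bait_contacts)

  arrays <- simulate_e4c_arrays(probes, planted, config)
  expr_lifplus_ids <- genes$gene_id[c(both_idx, expr_only_idx)]
  expr_shared_ids <- genes$gene_id[shared_expr_idx]
  expression <- simulate_expression(genes, expr_lifplus_ids,
                                    expr_shared_ids,
                                    config$spike_copies, config)
  truth <- list(
    assoc_lifplus = sort(genes$gene_id[assoc_lifplus_idx]),
    assoc_npc = sort(genes$gene_id[npc_idx]),
    assoc_lifminus = sort(genes$gene_id[lifminus_idx]),
    expr_lifplus = sort(expr_lifplus_ids),
    expr_shared = sort(expr_shared_ids),
    candidates = sort(genes$gene_id[both_idx]),
    bait_gene = if (is.na(bait_idx)) NA_character_ else genes$gene_id[bait_idx]
  )
  list(config = config, chrom_sizes = gen$chrom_sizes, genes = genes,
       genome = genome, fragments = fragments, probes = probes,
       planted_intervals = planted, arrays = arrays,
       expression = expression, truth = truth)
}
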