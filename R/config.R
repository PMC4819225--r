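#' Pipeline configuration
#'
#' Bundles every numeric constant of the screen in one place so that a run is
#' fully described by its config.  Defaults are the published operating point
#' of the assay: a log2(e4C/genomic control) cut-off of 2 evaluated on a
#' 200-bp sliding window, genes mapped within 50 kb of each peak, expression
#' filters of at least two-fold induction with genes below 1 mRNA copy per
#' cell excluded, a 500-nm FISH association threshold, and STAT3 motif
#' scanning within 5 kb of the TSS.
#'
#' @param window_bp Sliding-window width in bp for ratio smoothing.
#' @param ratio_cutoff Hit cut-off on the smoothed log2 ratio (inclusive).
#' @param pseudocount Intensity pseudocount added to both channels before
#'   taking the ratio, guarding zero channels.
#' @param max_gap_bp Maximum gap between positive probes merged into one
#'   peak; 0 merges only touching probes (most conservative).
#' @param gene_distance_bp Maximum peak-to-gene-body distance for a gene to
#'   count as bait-associated.
#' @param expr_fold Minimum fold change (numerator/denominator copies) for a
#'   gene to count as upregulated (inclusive).
#' @param expr_floor_copies Genes with fewer copies per cell than this in the
#'   numerator condition are excluded.
#' @param expr_eps Denominator guard (copies) when computing fold changes.
#' @param fish_threshold_nm Inter-locus 3D distance at or below which two
#'   loci are called associated.
#' @param stat3_window_bp Half-width of the promoter window scanned for
#'   STAT3 motifs, centred on the TSS.
#' @param pwm_score_fraction A window is a motif hit when its log-odds score
#'   is at least this fraction of the maximum achievable score.
#'
#' @return A list of class `gfap4c_config`.
#' @export
#' @examples
#' pipeline_config()
#' pipeline_config(ratio_cutoff = 3)
pipeline_config <- function(window_bp = 200,
                            ratio_cutoff = 2,
                            pseudocount = 1,
                            max_gap_bp = 0,
                            gene_distance_bp = 50000,
                            expr_fold = 2,
                            expr_floor_copies = 1,
                            expr_eps = 0.01,
                            fish_threshold_nm = 500,
                            stat3_window_bp = 5000,
                            pwm_score_fraction = 0.8) {
  cfg <- list(
    window_bp = window_bp, ratio_cutoff = ratio_cutoff,
    pseudocount = pseudocount, max_gap_bp = max_gap_bp,
    gene_distance_bp = gene_distance_bp, expr_fold = expr_fold,
    expr_floor_copies = expr_floor_copies, expr_eps = expr_eps,
    fish_threshold_nm = fish_threshold_nm, stat3_window_bp = stat3_window_bp,
    pwm_score_fraction = pwm_score_fraction
  )
  num <- c("window_bp", "ratio_cutoff", "gene_distance_bp", "expr_fold",
           "expr_floor_copies", "fish_threshold_nm", "stat3_window_bp",
           "pwm_score_fraction")
  for (nm in num) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1 || cfg[[nm]] <= 0) {
      abort(paste0("`", nm, "` must be a single positive number"))
    }
  }
  if (pseudocount < 0 || max_gap_bp < 0 || expr_eps <= 0) {
    abort("`pseudocount`/`max_gap_bp` must be >= 0 and `expr_eps` > 0")
  }
  structure(cfg, class = "gfap4c_config")
}

#' Synthetic study configuration
#'
#' Describes the simulated study: a small multi-chromosome genome, gene
#' annotation, a double-digest probe array with planted bait contacts,
#' spike-calibrated expression arrays for the three culture conditions
#' (NPC, LIF+, LIF-), and 3D FISH nuclei.  Defaults emulate the study
#' conditions at desk scale: 3 chromosomes of 10 Mb, 300 genes, two
#' biological array replicates, a planted probe log-ratio of 3 with 0.5
#' log2-scale noise, a planted expression induction of at least five-fold,
#' ~10-micron nuclei and 200 nuclei per condition.
#'
#' @param n_chromosomes,chrom_length_bp Genome shape.
#' @param n_genes Number of non-overlapping genes placed on the genome.
#' @param n_planted_assoc_genes Genes given a planted bait contact in LIF+
#'   cells (the bait-associated truth set).
#' @param n_planted_expr_genes Genes planted as upregulated specifically in
#'   LIF+ cells.  By default the association and expression truth sets are
#'   the same genes, so `min(n_planted_assoc_genes, n_planted_expr_genes)`
#'   genes form the associated-and-expressed ground truth.
#' @param n_planted_shared_expr_genes Genes planted as upregulated in both
#'   LIF+ and LIF- (they populate the expression Venn overlap and must be
#'   rejected by the exclusivity filter).
#' @param n_planted_other_assoc_genes Genes given planted contacts in NPC
#'   and LIF- (non-specific associations).
#' @param interaction_signal_log2 Mean planted probe log2 ratio.
#' @param noise_sd Gaussian sd, log2 scale, applied to probe ratios and to
#'   per-sample expression intensities.
#' @param contact_halfwidth_bp Planted contact regions extend this far on
#'   either side of their anchor probe (3C-style contacts have sub-gene,
#'   multi-kb resolution).
#' @param spike_copies Known copies-per-cell doses of the external spike set.
#' @param spike_noise_sd Gaussian sd, log2 scale, on spike intensities.
#'   Spikes are a known quantity added to the sample, so they carry only
#'   array technical noise, while `noise_sd` describes the full per-gene
#'   variability (biological plus technical).
#' @param expr_fold_planted Minimum true fold induction of planted genes;
#'   actual folds are drawn log-uniformly in
#'   `[expr_fold_planted, 10 * expr_fold_planted]`, mirroring the broad fold
#'   range of real candidate tables.
#' @param expr_gain Array intensity units per mRNA copy.
#' @param n_nuclei FISH nuclei per condition.
#' @param nucleus_diameter_um Mean nuclear diameter; per-nucleus diameters
#'   are drawn around it with `nucleus_diameter_sd_um`.
#' @param nucleus_diameter_sd_um Diameter sd across nuclei.
#' @param assoc_fraction Probability that a partner allele is planted within
#'   the association threshold of a bait allele (per nucleus).
#' @param enzyme_a,enzyme_b Recognition sites of the double digest
#'   (BglII = AGATCT, NlaIII = CATG).
#' @param min_fragment_bp Fragments at or below this length are dropped from
#'   the array design.
#' @param probe_bp Probe length anchored at the enzyme-a end of a fragment.
#' @param seed Integer seed; every generator is deterministic given it.
#'
#' @return A list of class `gfap4c_synth_config`.
#' @export
#' @examples
#' synthetic_config(seed = 1)
synthetic_config <- function(n_chromosomes = 3,
                             chrom_length_bp = 1e7,
                             n_genes = 300,
                             n_planted_assoc_genes = 20,
                             n_planted_expr_genes = 20,
                             n_planted_shared_expr_genes = 15,
                             n_planted_other_assoc_genes = 10,
                             interaction_signal_log2 = 3,
                             noise_sd = 0.5,
                             contact_halfwidth_bp = 5000,
                             spike_copies = c(1, 4, 16, 64, 256),
                             spike_noise_sd = 0.2,
                             expr_fold_planted = 5,
                             expr_gain = 10,
                             n_nuclei = 200,
                             nucleus_diameter_um = 10.1,
                             nucleus_diameter_sd_um = 1.1,
                             assoc_fraction = 0.4,
                             enzyme_a = "AGATCT",
                             enzyme_b = "CATG",
                             min_fragment_bp = 100,
                             probe_bp = 60,
                             seed = 1L) {
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_bp = chrom_length_bp,
    n_genes = as.integer(n_genes),
    n_planted_assoc_genes = as.integer(n_planted_assoc_genes),
    n_planted_expr_genes = as.integer(n_planted_expr_genes),
    n_planted_shared_expr_genes = as.integer(n_planted_shared_expr_genes),
    n_planted_other_assoc_genes = as.integer(n_planted_other_assoc_genes),
    interaction_signal_log2 = interaction_signal_log2,
    noise_sd = noise_sd,
    contact_halfwidth_bp = contact_halfwidth_bp,
    spike_copies = spike_copies,
    spike_noise_sd = spike_noise_sd,
    expr_fold_planted = expr_fold_planted,
    expr_gain = expr_gain,
    n_nuclei = as.integer(n_nuclei),
    nucleus_diameter_um = nucleus_diameter_um,
    nucleus_diameter_sd_um = nucleus_diameter_sd_um,
    assoc_fraction = assoc_fraction,
    enzyme_a = enzyme_a,
    enzyme_b = enzyme_b,
    min_fragment_bp = min_fragment_bp,
    probe_bp = as.integer(probe_bp),
    seed = as.integer(seed)
  )
  if (cfg$n_chromosomes < 1 || cfg$chrom_length_bp <= 0) {
    abort("genome must have >= 1 chromosome of positive length")
  }
  if (cfg$n_genes < 0) abort("`n_genes` must be >= 0")
  planted <- c(cfg$n_planted_assoc_genes, cfg$n_planted_expr_genes,
               cfg$n_planted_shared_expr_genes, cfg$n_planted_other_assoc_genes)
  if (any(planted < 0) || any(planted > cfg$n_genes)) {
    abort("planted gene counts must lie in [0, n_genes]")
  }
  if (cfg$assoc_fraction < 0 || cfg$assoc_fraction > 1) {
    abort("`assoc_fraction` must lie in [0, 1]")
  }
  if (cfg$noise_sd < 0 || cfg$spike_noise_sd < 0) {
    abort("noise sds must be >= 0")
  }
  if (cfg$nucleus_diameter_um <= 1) {
    abort("`nucleus_diameter_um` must exceed 1 micron")
  }
  if (length(cfg$spike_copies) == 0) abort("`spike_copies` must be nonempty")
  structure(cfg, class = "gfap4c_synth_config")
}

#' @export
print.gfap4c_config <- function(x, ...) {
  cat("<gfap4c pipeline config>\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' @export
print.gfap4c_synth_config <- function(x, ...) {
  cat("<gfap4c synthetic study config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-28s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  }
  invisible(x)
}

conditions_all <- function() c("NPC", "LIF+", "LIF-")
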