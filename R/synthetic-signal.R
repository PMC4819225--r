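# Synthetic two-channel e4C arrays, spike-calibrated expression arrays and
# 3D FISH nuclei, all with retained ground-truth labels.

#' Simulate two-channel e4C probe tables
#'
#' Probes overlapping a planted contact interval (for their condition) draw
#' their log2 ratio around `interaction_signal_log2`; background probes
#' around 0.  Noise is additive Gaussian on the log2 scale, independent per
#' replicate.  The genomic-control channel is a flat reference intensity and
#' the e4C channel encodes the ratio.
#'
#' @param probes Probe tibble from [design_probes()].
#' @param planted Tibble of planted contact intervals with columns `chrom`,
#'   `start`, `end`, `condition` (and optionally `gene_id`).
#' @param config A [synthetic_config()].
#' @param conditions Conditions to simulate.
#' @param seed Optional integer overriding the config-derived seed.
#' @return Probe-signal tibble: `probe_id`, `chrom`, `start`, `end`, `e4c`,
#'   `control`, `replicate`, `condition`, plus the truth column `planted`.
#' @export
simulate_e4c_arrays <- function(probes, planted, config,
                                conditions = conditions_all(), seed = NULL) {
  stopifnot(inherits(config, "gfap4c_synth_config"))
  withr::local_seed(seed %||% (config$seed + 103L))
  control0 <- 500
  out <- crossing(condition = conditions, replicate = c(1L, 2L)) |>
    pmap(function(condition, replicate) {
      pl <- filter(planted, .data$condition == !!condition)
      hit <- probes_in_intervals(probes, pl)
      mu <- ifelse(hit, config$interaction_signal_log2, 0)
      ratio <- mu + rnorm(nrow(probes), 0, config$noise_sd)
      probes |>
        mutate(e4c = control0 * 2^ratio, control = control0,
               replicate = replicate, condition = condition, planted = hit)
    }) |>
    list_rbind()
  out
}

# logical: does each probe overlap any interval (same chrom, half-open)?
probes_in_intervals <- function(probes, intervals) {
  if (nrow(intervals) == 0 || nrow(probes) == 0) {
    return(rep(FALSE, nrow(probes)))
  }
  q <- GenomicRanges::GRanges(probes$chrom,
                              IRanges::IRanges(probes$start + 1, probes$end))
  s <- GenomicRanges::GRanges(intervals$chrom,
                              IRanges::IRanges(intervals$start + 1,
                                               intervals$end))
  IRanges::overlapsAny(q, s)
}

#' Simulate expression arrays with external spike-ins
#'
#' True copies per cell are constant across conditions for background genes.
#' Genes in `planted_lifplus` start from a low basal level (0.3-0.8 copies,
#' typical of silent astrocyte genes in precursors) and are induced in LIF+
#' only, with true folds drawn log-uniformly in
#' `[expr_fold_planted, 10 * expr_fold_planted]`; genes in `planted_shared`
#' are induced in both LIF+ and LIF-.  Intensities follow
#' `gain * copies * 2^N(0, noise_sd)` with a small additive floor, and the
#' spike set is present in every sample at its known doses.
#'
#' @param genes Gene annotation tibble (needs `gene_id`).
#' @param planted_lifplus,planted_shared Character vectors of gene ids.
#' @param spikes Numeric vector of known spike copies per cell.
#' @param config A [synthetic_config()].
#' @param seed Optional integer overriding the config-derived seed.
#' @return List with `intensities` (tibble: `feature_id`, `type`,
#'   `condition`, `intensity`, `known_copies`) and `truth` (tibble of true
#'   copies per gene and condition plus planting flags).
#' @export
simulate_expression <- function(genes, planted_lifplus = character(),
                                planted_shared = character(),
                                spikes = config$spike_copies, config,
                                seed = NULL) {
  stopifnot(inherits(config, "gfap4c_synth_config"))
  if (length(spikes) == 0) {
    abort("empty spike set: per-cell calibration is impossible without spikes")
  }
  if (!all(planted_lifplus %in% genes$gene_id) ||
      !all(planted_shared %in% genes$gene_id)) {
    abort("planted gene sets must be subsets of the annotation")
  }
  withr::local_seed(seed %||% (config$seed + 104L))
  n <- nrow(genes)
  base <- 10^runif(n, -1.5, 1.5)
  is_lp <- genes$gene_id %in% planted_lifplus
  is_sh <- genes$gene_id %in% planted_shared
  base[is_lp | is_sh] <- runif(sum(is_lp | is_sh), 0.3, 0.8)
  fold <- rep(1, n)
  npl <- sum(is_lp | is_sh)
  f0 <- config$expr_fold_planted
  fold[is_lp | is_sh] <- exp(runif(npl, log(f0), log(10 * f0)))
  truth <- tibble(
    gene_id = genes$gene_id,
    copies_NPC = base,
    `copies_LIF+` = ifelse(is_lp | is_sh, base * fold, base),
    `copies_LIF-` = ifelse(is_sh, base * fold, base),
    planted_lifplus = is_lp, planted_shared = is_sh
  )
  floor_i <- 0.1
  one_sample <- function(cond, copies) {
    # genes carry the full biological + technical noise; spike-ins are a
    # known added quantity and see only array technical noise
    noise <- 2^c(rnorm(length(copies), 0, config$noise_sd),
                 rnorm(length(spikes), 0, config$spike_noise_sd))
    tibble(
      feature_id = c(genes$gene_id, sprintf("spike%02d", seq_along(spikes))),
      type = rep(c("gene", "spike"), c(length(copies), length(spikes))),
      condition = cond,
      known_copies = c(rep(NA_real_, length(copies)), spikes),
      intensity = pmax(config$expr_gain * c(copies, spikes) * noise, floor_i)
    )
  }
  intensities <- bind_rows(
    one_sample("NPC", truth$copies_NPC),
    one_sample("LIF+", truth$`copies_LIF+`),
    one_sample("LIF-", truth$`copies_LIF-`)
  )
  list(intensities = intensities, truth = truth)
}

#' Simulate 3D DNA-FISH nuclei
#'
#' Each nucleus is a sphere (diameter drawn per nucleus) holding two bait
#' alleles and two alleles of each partner gene.  With per-condition
#' probability `assoc_fraction`, one partner allele is planted within the
#' association threshold (500 nm) of a bait allele; all other signals are
#' uniform in the sphere.  With `activity = TRUE` the bait is expressed
#' monoallelically (one active allele per nucleus) and the planted partner
#' allele targets the active or inactive bait allele with the given
#' probabilities, emulating joint RNA/DNA FISH.
#'
#' @param config A [synthetic_config()].
#' @param partners Character vector of partner gene symbols.
#' @param assoc_fraction Named per-condition planting probabilities (or one
#'   number recycled to all conditions).
#' @param conditions Conditions to simulate.
#' @param diameter_um,diameter_sd_um Per-condition mean and sd of nuclear
#'   diameter (named vectors or scalars); default from `config`.
#' @param bait Bait gene symbol used in the output.
#' @param threshold_nm Planting distance for associated alleles.
#' @param activity If `TRUE`, label bait alleles active/inactive and use
#'   `active_assoc_fraction` / `inactive_assoc_fraction` instead of
#'   `assoc_fraction`.
#' @param active_assoc_fraction,inactive_assoc_fraction Per-allele planting
#'   probabilities in activity mode.
#' @param seed Optional integer overriding the config-derived seed.
#' @return Tibble: `nucleus_id`, `condition`, `gene`, `allele`, `x_um`,
#'   `y_um`, `z_um`, `allele_active`, `nucleus_diameter_um`, `planted_assoc`.
#' @export
simulate_fish <- function(config, partners, assoc_fraction = config$assoc_fraction,
                          conditions = conditions_all(),
                          diameter_um = config$nucleus_diameter_um,
                          diameter_sd_um = config$nucleus_diameter_sd_um,
                          bait = "bait", threshold_nm = 500,
                          activity = FALSE,
                          active_assoc_fraction = 0.5,
                          inactive_assoc_fraction = 0.2,
                          seed = NULL) {
  stopifnot(inherits(config, "gfap4c_synth_config"))
  dia <- expand_by_condition(diameter_um, conditions)
  dsd <- expand_by_condition(diameter_sd_um, conditions)
  frac <- expand_by_condition(assoc_fraction, conditions)
  if (any(frac < 0 | frac > 1)) abort("`assoc_fraction` must lie in [0, 1]")
  if (any(dia <= 1)) abort("nuclear diameter must exceed 1 micron")
  withr::local_seed(seed %||% (config$seed + 105L))
  thr_um <- threshold_nm / 1000
  rows <- vector("list", length(conditions) * config$n_nuclei)
  k <- 0
  for (cond in conditions) {
    for (i in seq_len(config$n_nuclei)) {
      k <- k + 1
      d <- max(rnorm(1, dia[[cond]], dsd[[cond]]), 2)
      R <- d / 2
      id <- paste0(cond, "_n", i)
      bait_xyz <- runif_in_sphere(2, R)
      active <- if (activity) sample(c(TRUE, FALSE)) else c(NA, NA)
      nuc <- list(tibble(
        nucleus_id = id, condition = cond, gene = bait, allele = 1:2,
        x_um = bait_xyz[, 1], y_um = bait_xyz[, 2], z_um = bait_xyz[, 3],
        allele_active = active, nucleus_diameter_um = d,
        planted_assoc = NA
      ))
      for (g in partners) {
        if (activity) {
          # each bait allele attracts a partner allele independently, with a
          # probability set by its transcriptional state
          targets <- c(
            if (runif(1) < active_assoc_fraction) which(active),
            if (runif(1) < inactive_assoc_fraction) which(!active)
          )
        } else {
          targets <- if (runif(1) < frac[[cond]]) sample(1:2, 1) else integer()
        }
        a1 <- if (length(targets) >= 1) {
          point_near(bait_xyz[targets[1], ], thr_um, R)
        } else {
          runif_in_sphere(1, R)[1, ]
        }
        a2 <- if (length(targets) >= 2) {
          point_near(bait_xyz[targets[2], ], thr_um, R)
        } else {
          runif_in_sphere(1, R)[1, ]
        }
        nuc <- c(nuc, list(tibble(
          nucleus_id = id, condition = cond, gene = g, allele = 1:2,
          x_um = c(a1[1], a2[1]), y_um = c(a1[2], a2[2]),
          z_um = c(a1[3], a2[3]), allele_active = NA,
          nucleus_diameter_um = d, planted_assoc = length(targets) > 0
        )))
      }
      rows[[k]] <- list_rbind(nuc)
    }
  }
  list_rbind(rows)
}

expand_by_condition <- function(x, conditions) {
  if (is.null(names(x))) {
    return(setNames(rep(x[[1]], length(conditions)), conditions))
  }
  if (!all(conditions %in% names(x))) {
    abort("per-condition values must name every condition")
  }
  x[conditions]
}

# n uniform points in a sphere of radius R centred at the origin
runif_in_sphere <- function(n, R) {
  v <- matrix(rnorm(3 * n), ncol = 3)
  v <- v / sqrt(rowSums(v^2))
  r <- R * runif(n)^(1 / 3)
  v * r
}

# uniform point within distance d of `centre`, kept inside the nucleus
point_near <- function(centre, d, R) {
  repeat {
    p <- centre + runif_in_sphere(1, d)[1, ]
    if (sum(p^2) <= R^2) return(p)
  }
}
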