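# Independent brute-force oracles, deliberately implemented with plain
# string/loop arithmetic rather than the package's code paths.

# --- double digestion: brute-force site scan on both orientations ---------
oracle_find_sites <- function(seq, site) {
  L <- nchar(seq)
  w <- nchar(site)
  if (L < w) return(integer())
  # scan every position (overlapping occurrences included)
  i <- seq_len(L - w + 1)
  which(substring(seq, i, i + w - 1) == site) - 1L
}

oracle_revcomp <- function(seq) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", seq), "")[[1]]), collapse = "")
}

oracle_digest <- function(seq, a, b, min_len) {
  one <- function(s) {
    ca <- oracle_find_sites(s, a)
    cb <- oracle_find_sites(s, b)
    res <- list()
    for (x in ca) {
      after <- c(ca[ca > x], cb[cb > x])
      if (length(after) == 0) next
      nxt <- min(after)
      if ((nxt %in% cb) && !(nxt %in% ca) && (nxt - x) > min_len) {
        res[[length(res) + 1]] <- c(x, nxt)
      }
    }
    res
  }
  L <- nchar(seq)
  fwd <- one(seq)
  rev <- lapply(one(oracle_revcomp(seq)), function(fr) c(L - fr[2], L - fr[1]))
  fw <- if (length(fwd)) do.call(rbind, fwd) else matrix(numeric(), ncol = 2)
  rv <- if (length(rev)) do.call(rbind, rev) else matrix(numeric(), ncol = 2)
  tibble::tibble(
    start = c(fw[, 1], rv[, 1]), end = c(fw[, 2], rv[, 2]),
    strand = rep(c("+", "-"), c(nrow(fw), nrow(rv)))
  ) |>
    dplyr::arrange(start, strand)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# --- peak-to-gene mapping: all-pairs distance scan ------------------------
oracle_gene_gap <- function(ps, pe, gs, ge) {
  # gap between half-open intervals, 0 when overlapping
  if (ps < ge && gs < pe) return(0)
  if (pe <= gs) gs - pe else ps - ge
}

oracle_map <- function(peaks, genes, maxd) {
  out <- list()
  for (i in seq_len(nrow(peaks))) {
    for (j in seq_len(nrow(genes))) {
      if (peaks$chrom[i] != genes$chrom[j]) next
      gap <- oracle_gene_gap(peaks$start[i], peaks$end[i],
                             genes$start[j], genes$end[j])
      if (gap <= maxd) {
        out[[length(out) + 1]] <- tibble::tibble(
          gene_id = genes$gene_id[j], peak = i, gap = gap
        )
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(gene_id = character(), gap = numeric()))
  }
  dplyr::bind_rows(out) |>
    dplyr::group_by(gene_id) |>
    dplyr::summarise(gap = min(gap), n = dplyr::n(), .groups = "drop")
}

# --- Venn regions: per-gene bitmask enumeration ---------------------------
oracle_venn <- function(sets) {
  universe <- unique(unlist(sets))
  counts <- integer(2^length(sets) - 1)
  for (g in universe) {
    mask <- sum(2^(which(vapply(sets, function(s) g %in% s, logical(1))) - 1))
    counts[mask] <- counts[mask] + 1L
  }
  counts  # indexed by nonzero membership bitmask
}

region_to_mask <- function(region, set_names) {
  members <- strsplit(region, "&", fixed = TRUE)[[1]]
  sum(2^(match(members, set_names) - 1))
}

random_sets <- function(n_sets = 3, universe_size = 30, p = 0.4) {
  u <- paste0("g", seq_len(universe_size))
  sets <- lapply(seq_len(n_sets), function(i) u[runif(universe_size) < p])
  names(sets) <- LETTERS[seq_len(n_sets)]
  sets
}

# --- Fisher: exhaustive hypergeometric enumeration ------------------------
oracle_fisher_p <- function(m) {
  a <- m[1, 1]
  r1 <- sum(m[1, ])
  c1 <- sum(m[, 1])
  N <- sum(m)
  lo <- max(0, c1 - (N - r1))
  hi <- min(r1, c1)
  x <- lo:hi
  p <- stats::dhyper(x, c1, N - c1, r1)
  pobs <- stats::dhyper(a, c1, N - c1, r1)
  min(1, sum(p[p <= pobs * (1 + 1e-7)]))
}

# --- chi-squared and adjusted residuals: direct arithmetic ----------------
oracle_chisq <- function(m) {
  N <- sum(m)
  E <- outer(rowSums(m), colSums(m)) / N
  chi2 <- sum((m - E)^2 / E)
  adj <- (m - E) / sqrt(E * (1 - rowSums(m) / N) %o% rep(1, ncol(m)) *
                          rep(1, nrow(m)) %o% (1 - colSums(m) / N))
  list(chi2 = chi2, adj = adj)
}

random_table <- function(nr = 2, nc = 3, lambda = 15) {
  repeat {
    m <- matrix(stats::rpois(nr * nc, lambda) + 1L, nr, nc)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(m)
  }
}
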