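#' Generate the macrophage differentiation continuum
#'
#' Emulates the intrahepatic macrophage/monocyte trajectory: each cell sits
#' at a latent time `t ~ Uniform(0, 1)`. Kupffer-cell markers (VSIG4, CSF1R,
#' CD163, CD206, IL18) decrease logistically in `t`; SPP1 increases
#' logistically with midpoint 0.8; TGFBR1, IL6R and the collagen-regulation
#' genes peak mid-trajectory (Gaussian bump centered at 0.5). As in real
#' differentiation continua, the markers ride on a broad transcriptional
#' program: a third of the gene universe carries smooth logistic temporal
#' profiles with random midpoints, directions and moderate amplitudes, and
#' the remainder is i.i.d. background noise. Counts are negative binomial
#' around the time-varying means. True states are KC (`t < 0.35`), IC
#' (`0.35 <= t <= 0.7`) and SPP1 (`t > 0.7`).
#'
#' @param config A `cohort_config`; uses `traj_n_cells`, `traj_n_genes`,
#'   `nb_dispersion` and `seed`.
#' @return A list with `expr` (counts `expr_matrix`) and `truth`
#'   (`synthetic_truth` with `latent_time` and `macrophage_state` per cell).
#' @export
make_macrophage_continuum <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$traj_n_cells < 50) abort("traj_n_cells must be at least 50")
  genes <- cohort_gene_table(config$n_genes, config$reactivity_size)
  kc_genes <- genes$kc
  bump_genes <- c("TGFBR1", "IL6R", genes$collagen)
  named <- unique(c("SPP1", kc_genes, bump_genes))
  n_bg <- config$traj_n_genes - length(named)
  if (n_bg < 10) abort("traj_n_genes too small for the marker panel")
  gene_ids <- c(named, sprintf("TBG%03d", seq_len(n_bg)))

  with_seed(config$seed + 303L, {
    n <- config$traj_n_cells
    t <- runif(n)
    logmu <- matrix(rnorm(length(gene_ids), -1, 1), n, length(gene_ids),
                    byrow = TRUE, dimnames = list(sprintf("m%05d", seq_len(n)),
                                                  gene_ids))
    # broad temporal program: smooth random logistics over a third of genes
    bg <- setdiff(gene_ids, named)
    n_temporal <- round(length(gene_ids) / 3)
    temporal <- bg[seq_len(min(n_temporal, length(bg)))]
    for (g in temporal) {
      mid <- runif(1, 0.15, 0.85); width <- runif(1, 0.05, 0.15)
      amp <- runif(1, 1, 2.5) * sample(c(-1, 1), 1)
      base <- rnorm(1, -1, 0.7)
      logmu[, g] <- base + amp * stats::plogis((t - mid) / width)
    }
    logmu[, "SPP1"] <- continuum_mean("SPP1", t)
    for (g in kc_genes) logmu[, g] <- continuum_mean("KC", t)
    for (g in bump_genes) logmu[, g] <- continuum_mean("BUMP", t)
    counts <- matrix(rnbinom(length(logmu), size = 1 / config$nb_dispersion,
                             mu = exp(logmu)),
                     n, length(gene_ids), dimnames = dimnames(logmu))
    expr <- expression_matrix(counts, rownames(counts), gene_ids, "counts")
    state <- cut(t, c(-Inf, 0.35, 0.7, Inf), labels = c("KC", "IC", "SPP1"),
                 right = FALSE)
    # boundary convention: t in [0.35, 0.7] is IC
    state[t == 0.7] <- "IC"
    truth <- structure(list(
      latent_time = tibble::tibble(cell_id = rownames(counts), latent_time = t,
                                   macrophage_state = as.character(state)),
      config = config
    ), class = "synthetic_truth")
    list(expr = expr, truth = truth)
  })
}

#' Noiseless log-mean of a continuum gene program at latent time t
#'
#' Exposed so tests can check the construction (logistic floors/ceilings,
#' bump maximum at `t = 0.5`) without sampling noise.
#'
#' @param program `"SPP1"` (rising logistic, midpoint 0.8), `"KC"` (falling
#'   logistic, midpoint 0.35) or `"BUMP"` (Gaussian bump centered 0.5).
#' @param t Latent times in `[0, 1]`.
#' @return Log-mean expression values.
#' @export
continuum_mean <- function(program = c("SPP1", "KC", "BUMP"), t) {
  program <- match.arg(program)
  lo <- log(0.15)
  switch(program,
    SPP1 = lo + (log(12) - lo) * stats::plogis((t - 0.8) / 0.07),
    KC   = lo + (log(8) - lo) * stats::plogis(-(t - 0.35) / 0.08),
    BUMP = log(0.3) + (log(6) - log(0.3)) * exp(-(t - 0.5)^2 / (2 * 0.12^2))
  )
}
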