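#' Synthetic cohort configuration
#'
#' Defines the study conditions of the emulated cohort: ten patients, six
#' paired tissue compartments (metastatic intrahepatic tumor MT, surrounding
#' hepatic tissue MN, primary CRC tumor PT, surrounding colonic tissue PN,
#' blood PBMC, draining lymph node LN), negative-binomial counts, and the
#' planted effects every downstream module is tested against: a 50-gene
#' tumor-reactivity program in pTRT cells, an SPP1->CD44 ligand-receptor
#' boost in MT, an intermediate (IC) macrophage state enriched in liver,
#' per-patient cytokine -> FN1/SPP1 cross-compartment slopes, and a spatial
#' macrophage-to-CD8 attraction inside alpha-SMA+ regions.
#'
#' Planted pTRT frequencies follow the ordering MT > LN > PT > MN > PN > PBMC.
#'
#' @param n_patients Number of patients (default 10).
#' @param cells_per_tissue Cells simulated per patient and tissue (default 400).
#' @param tissues Tissue compartments to simulate.
#' @param ptrt_freq Named planted pTRT fraction per tissue.
#' @param nb_dispersion Shared negative-binomial dispersion (default 0.3).
#' @param seed Integer seed; the generator is a pure function of the config.
#' @param n_genes Size of the gene universe (default 1200, so that a
#'   500-gene random control set remains a minority of the transcriptome).
#' @param ptrt_lfc Natural-log fold change of the reactivity program in pTRT
#'   cells (default 1.5).
#' @param marker_lfc Natural-log fold change of lineage/cluster marker
#'   programs (default 2); setting it to 0 removes all cell-type structure.
#' @param lr_effect Multiplier on SPP1 in MT macrophages and CD44 on MT pTRT
#'   cells (default 4; 1 plants no ligand-receptor effect).
#' @param cytokine_pt_lfc Elevation of TGFB1/IL6/TLR2/TLR4 in primary-tumor
#'   cells (default 3, keeping the pseudobulk readout in its log-linear
#'   regime).
#' @param fn1_mt_lfc Extra FN1 elevation in MT stromal cells (default 1).
#' @param cytokine_sd Per-patient latent cytokine SD (log-mean scale, default 0.4).
#' @param corr_slope Planted cross-patient cytokine -> FN1/SPP1 slope (default 0.5).
#' @param corr_noise_sd Gaussian noise SD around that slope (default 0.15).
#' @param ic_frac_liver,ic_frac_colon Fraction of liver (MT/MN) and colon
#'   (PT/PN) macrophages/monocytes in the IC state (defaults 0.20 and 0.04).
#' @param patient_sd SD of per-patient log-mean gene effects (default 0.1).
#' @param traj_n_cells Cells on the macrophage continuum (default 300).
#' @param traj_n_genes Gene universe of the continuum (default 300).
#' @param spatial_attraction Displacement factor of alpha-SMA+ macrophages
#'   toward their nearest CD8 T cell, in `[0, 1)` (default 0.5).
#' @param n_spatial_samples Imaging samples in the spatial cohort (default 15).
#' @param field_size Imaged field side length in micrometers (default 2000).
#' @param type_mix Named coarse-type composition of every tissue.
#' @param reactivity_size Genes in the reactivity program (default 50).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 10, cells_per_tissue = 400,
                          tissues = TISSUES,
                          ptrt_freq = c(MT = 0.10, LN = 0.05, PT = 0.03,
                                        MN = 0.01, PN = 0.005, PBMC = 0.002),
                          nb_dispersion = 0.3, seed = 1, n_genes = 1200,
                          ptrt_lfc = 1.5, marker_lfc = 2, lr_effect = 4,
                          cytokine_pt_lfc = 3, fn1_mt_lfc = 1,
                          cytokine_sd = 0.4, corr_slope = 0.5,
                          corr_noise_sd = 0.15,
                          ic_frac_liver = 0.20, ic_frac_colon = 0.04,
                          patient_sd = 0.1,
                          traj_n_cells = 300, traj_n_genes = 300,
                          spatial_attraction = 0.5, n_spatial_samples = 15,
                          field_size = 2000,
                          type_mix = c(CD8T = 0.40, macrophage = 0.20,
                                       monocyte = 0.10, NK = 0.10,
                                       Treg = 0.10, other = 0.10),
                          reactivity_size = 50) {
  tissues <- match.arg(tissues, TISSUES, several.ok = TRUE)
  if (cells_per_tissue <= 0) abort("cells_per_tissue must be positive")
  if (any(ptrt_freq < 0 | ptrt_freq > 1)) abort("ptrt_freq must lie in [0, 1]")
  if (!all(tissues %in% names(ptrt_freq))) abort("ptrt_freq must cover all tissues")
  if (spatial_attraction < 0 || spatial_attraction >= 1) {
    abort("spatial_attraction must lie in [0, 1)")
  }
  if (abs(sum(type_mix) - 1) > 1e-8) abort("type_mix must sum to 1")
  cfg <- list(n_patients = n_patients, cells_per_tissue = cells_per_tissue,
              tissues = tissues, ptrt_freq = ptrt_freq,
              nb_dispersion = nb_dispersion, seed = as.integer(seed),
              n_genes = n_genes, ptrt_lfc = ptrt_lfc, marker_lfc = marker_lfc,
              lr_effect = lr_effect, cytokine_pt_lfc = cytokine_pt_lfc,
              fn1_mt_lfc = fn1_mt_lfc, cytokine_sd = cytokine_sd,
              corr_slope = corr_slope, corr_noise_sd = corr_noise_sd,
              ic_frac_liver = ic_frac_liver, ic_frac_colon = ic_frac_colon,
              patient_sd = patient_sd, traj_n_cells = traj_n_cells,
              traj_n_genes = traj_n_genes,
              spatial_attraction = spatial_attraction,
              n_spatial_samples = n_spatial_samples, field_size = field_size,
              type_mix = type_mix, reactivity_size = reactivity_size)
  structure(cfg, class = "cohort_config")
}

#' Configuration with every planted effect switched off
#'
#' All groups (tissues, cell types, patients' planted shifts) become
#' exchangeable, which is the basis of the type-I-error calibration tests.
#'
#' @param seed Integer seed.
#' @param ... Overrides forwarded to [cohort_config()].
#' @return A `cohort_config`.
#' @export
null_cohort_config <- function(seed = 1, ...) {
  cohort_config(seed = seed, ptrt_lfc = 0, marker_lfc = 0, lr_effect = 1,
                cytokine_pt_lfc = 0, fn1_mt_lfc = 0, cytokine_sd = 0,
                corr_slope = 0, corr_noise_sd = 0, ic_frac_liver = 0,
                ic_frac_colon = 0, spatial_attraction = 0, ...)
}

# fixed gene universe: named biology + numbered background genes
cohort_gene_table <- function(n_genes, reactivity_size = 50) {
  g <- list(
    trg = sprintf("TRG%03d", seq_len(reactivity_size)),
    cluster_markers = list(
      Tex_LAYN = c("LAYN", "LAG3", "PDCD1"),
      TRM = c("KLRB1", "KLRD1", "ITGAE"),
      IEL_CD160 = c("CD160", "KLRC2"),
      HSPA1A = c("HSPA1A", "HSPA6", "HSPA1B"),
      Prolif_MKI67 = c("MKI67", "TOP2A")
    ),
    lineage = list(
      CD8T = c("CD8A", "CD3E"), macrophage = "CD68", monocyte = "CD14",
      NK = c("NKG7", "GNLY"), Treg = c("FOXP3", "IL2RA")
    ),
    kc = c("VSIG4", "CSF1R", "CD163", "CD206", "IL18"),
    ic = c("SPP1", "TGFBR1", "IL6R", "CSF1R", "VSIG4", "CD163"),
    collagen = c("COL1A1", "COL4A1", "LOX", "P4HA1", "SERPINH1"),
    cytokines = c("TGFB1", "IL6", "TLR2", "TLR4"),
    lr_extra = c("CD44", "FN1", "ITGA4", "ITGB1", "ITGB7", "TGFBR2")
  )
  named <- unique(c(g$trg, unlist(g$cluster_markers), unlist(g$lineage),
                    g$kc, g$ic, g$collagen, g$cytokines, g$lr_extra))
  if (n_genes < length(named) + 10) {
    abort(sprintf("n_genes must be at least %d", length(named) + 10))
  }
  g$background <- sprintf("BG%03d", seq_len(n_genes - length(named)))
  g$all <- c(named, g$background)
  g
}

# baseline log-means of the named genes (log raw-count scale)
baseline_logmu <- function(genes, seed) {
  base <- setNames(rep(-1.2, length(genes$all)), genes$all)
  base[genes$trg] <- -1
  base[unlist(genes$cluster_markers)] <- -1.5
  base[unlist(genes$lineage)] <- -1.5
  base[c("VSIG4", "CD163", "CD206", "IL18")] <- -1
  base["CSF1R"] <- -1.5
  base[c("TGFBR1", "IL6R", "TGFBR2")] <- -0.5
  base[genes$collagen] <- -1
  base[genes$cytokines] <- -1
  base["SPP1"] <- -1
  base["CD44"] <- 0.3
  base["FN1"] <- -1
  base[c("ITGA4", "ITGB1", "ITGB7")] <- -0.5
  base[genes$background] <- with_seed(seed + 101L,
                                      rnorm(length(genes$background), -1.2, 1))
  base
}

#' Generate the synthetic multi-tissue cohort
#'
#' Draws negative-binomial counts for every cell of a paired six-compartment
#' cohort with the planted structure described in [cohort_config()]. The
#' returned truth object carries the planted pTRT labels, IC states and the
#' per-patient latent cytokine levels with their planted slope, so that each
#' downstream module's recovery test consumes only generator outputs.
#'
#' @param config A `cohort_config`.
#' @return A list with elements `expr` (counts `expr_matrix`),
#'   `annotation` (tibble: cell_id, patient, tissue, cluster, coarse_type)
#'   and `truth` (list of class `synthetic_truth`).
#' @export
make_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  genes <- cohort_gene_table(config$n_genes, config$reactivity_size)
  base <- baseline_logmu(genes, config$seed)
  patients <- sprintf("P%02d", seq_len(config$n_patients))

  with_seed(config$seed, {
    # deterministic per-tissue composition, identical across tissues
    n_type <- round(config$type_mix * config$cells_per_tissue)
    n_type[1] <- config$cells_per_tissue - sum(n_type[-1])
    ann <- tidyr::expand_grid(patient = patients, tissue = config$tissues) |>
      dplyr::rowwise() |>
      dplyr::reframe(coarse_type = rep(names(n_type), n_type),
                     patient = .data$patient, tissue = .data$tissue)
    n_cells <- nrow(ann)
    ann$cell_id <- sprintf("c%06d", seq_len(n_cells))

    # CD8 cluster mixture, shared across tissues
    cd8_mix <- c(Tex_LAYN = 0.30, TRM = 0.25, IEL_CD160 = 0.15,
                 HSPA1A = 0.15, Prolif_MKI67 = 0.15)
    ann$cluster <- ann$coarse_type
    is_cd8 <- ann$coarse_type == "CD8T"
    ann$cluster[is_cd8] <- sample(names(cd8_mix), sum(is_cd8),
                                  replace = TRUE, prob = cd8_mix)
    ann$cluster[ann$coarse_type == "other"] <- "Stromal"

    # planted pTRT labels among CD8 T cells
    ann$is_ptrt <- FALSE
    ann$is_ptrt[is_cd8] <- runif(sum(is_cd8)) <
      config$ptrt_freq[ann$tissue[is_cd8]]

    # IC state among liver/colon macrophages+monocytes
    is_macmono <- ann$coarse_type %in% c("macrophage", "monocyte")
    ic_p <- rep(0, n_cells)
    ic_p[is_macmono & ann$tissue %in% c("MT", "MN")] <- config$ic_frac_liver
    ic_p[is_macmono & ann$tissue %in% c("PT", "PN")] <- config$ic_frac_colon
    ann$is_ic <- runif(n_cells) < ic_p

    # per-patient latent effects
    c_p <- rnorm(config$n_patients, 0, config$cytokine_sd)
    eps_fn1 <- rnorm(config$n_patients, 0, config$corr_noise_sd)
    eps_spp1 <- rnorm(config$n_patients, 0, config$corr_noise_sd)
    names(c_p) <- names(eps_fn1) <- names(eps_spp1) <- patients
    pat_eff <- matrix(rnorm(config$n_patients * config$n_genes, 0,
                            config$patient_sd),
                      config$n_patients, config$n_genes,
                      dimnames = list(patients, genes$all))

    pidx <- match(ann$patient, patients)
    logmu <- matrix(base, n_cells, config$n_genes, byrow = TRUE,
                    dimnames = list(ann$cell_id, genes$all)) +
      pat_eff[pidx, , drop = FALSE]

    bump <- function(rows, gene_set, amount) {
      if (any(rows) && amount != 0) {
        logmu[rows, gene_set] <<- logmu[rows, gene_set] + amount
      }
    }
    # lineage and CD8-cluster marker programs
    for (tp in names(genes$lineage)) {
      bump(ann$coarse_type == tp, genes$lineage[[tp]], config$marker_lfc)
    }
    for (cl in names(genes$cluster_markers)) {
      bump(ann$cluster == cl, genes$cluster_markers[[cl]], config$marker_lfc)
    }
    is_mac <- ann$coarse_type == "macrophage"
    # macrophage program: constitutive SPP1/FN1 and Kupffer-like markers
    # constitutive, sub-saturating: SPP1+/FN1+ macrophages are a subset
    bump(is_mac, "SPP1", 0.4 * config$marker_lfc)
    bump(is_mac, "FN1", 0.4 * config$marker_lfc)
    bump(is_mac, c("VSIG4", "CD163", "CD206", "IL18"), 0.5 * config$marker_lfc)
    bump(is_mac, "CSF1R", config$marker_lfc)
    bump(ann$coarse_type == "monocyte", "CSF1R", 0.5 * config$marker_lfc)
    # stromal program: ECM genes
    is_stromal <- ann$coarse_type == "other"
    bump(is_stromal, "FN1", config$marker_lfc)
    bump(is_stromal, genes$collagen, 0.5 * config$marker_lfc)
    # reactivity program in pTRT cells
    bump(ann$is_ptrt, genes$trg, config$ptrt_lfc)
    # planted SPP1 -> CD44 axis in MT
    in_mt <- ann$tissue == "MT"
    bump(in_mt & is_mac, "SPP1", log(config$lr_effect))
    bump(in_mt & ann$is_ptrt, "CD44", log(config$lr_effect))
    # cytokines elevated in the primary tumor, patient-shifted; restricted
    # to the producing compartments (myeloid + stromal), so lymphocytes
    # stay exchangeable across tissues
    in_pt <- ann$tissue == "PT"
    producer <- ann$coarse_type %in% c("macrophage", "monocyte", "other")
    pt_prod <- in_pt & producer
    if (any(pt_prod)) {
      logmu[pt_prod, genes$cytokines] <- logmu[pt_prod, genes$cytokines] +
        config$cytokine_pt_lfc + c_p[ann$patient[pt_prod]]
    }
    # MT responses to the latent cytokine level: FN1 in stroma, SPP1 in macs
    mt_str <- in_mt & is_stromal
    if (any(mt_str)) {
      logmu[mt_str, "FN1"] <- logmu[mt_str, "FN1"] + config$fn1_mt_lfc +
        config$corr_slope * c_p[ann$patient[mt_str]] + eps_fn1[ann$patient[mt_str]]
    }
    mt_mac <- in_mt & is_mac
    if (any(mt_mac)) {
      logmu[mt_mac, "SPP1"] <- logmu[mt_mac, "SPP1"] +
        config$corr_slope * c_p[ann$patient[mt_mac]] + eps_spp1[ann$patient[mt_mac]]
    }
    # IC state: co-expression of the six IC markers
    bump(ann$is_ic, "SPP1", 1.5)
    bump(ann$is_ic, c("VSIG4", "CD163"), 1.5)
    bump(ann$is_ic, c("TGFBR1", "IL6R"), 2.5)
    bump(ann$is_ic, "CSF1R", 1.0)

    counts <- matrix(
      rnbinom(length(logmu), size = 1 / config$nb_dispersion, mu = exp(logmu)),
      n_cells, config$n_genes, dimnames = dimnames(logmu))
    rm(logmu)

    expr <- expression_matrix(counts, ann$cell_id, genes$all, "counts")
    annotation <- dplyr::select(ann, "cell_id", "patient", "tissue",
                                "cluster", "coarse_type")
    truth <- structure(list(
      ptrt_labels = dplyr::select(ann, "cell_id", "is_ptrt"),
      ic_state = dplyr::select(ann, "cell_id", "is_ic"),
      patient_effects = tibble::tibble(patient = patients, cytokine = c_p,
                                       fn1_noise = eps_fn1,
                                       spp1_noise = eps_spp1),
      planted_slope = config$corr_slope,
      reactivity_genes = genes$trg,
      config = config
    ), class = "synthetic_truth")
    list(expr = expr, annotation = annotation, truth = truth)
  })
}

#' Generate the signature collection used for pTRT classification
#'
#' 100 tumor-reactivity signatures (`ptrt_sig_001` ...) each sampling 15
#' genes of the planted reactivity program plus 5 decoy background genes,
#' together with the six-marker IC set (SPP1, TGFBR1, IL6R, CSF1R, VSIG4,
#' CD163), a Kupffer-cell set and a positive collagen-regulation set.
#'
#' @param config A `cohort_config`.
#' @return A `gene_set_collection`.
#' @export
make_signature_collection <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  genes <- cohort_gene_table(config$n_genes, config$reactivity_size)
  with_seed(config$seed + 202L, {
    sigs <- lapply(seq_len(100), function(i) {
      c(sample(genes$trg, 15), sample(genes$background, 5))
    })
    names(sigs) <- sprintf("ptrt_sig_%03d", seq_len(100))
    sigs$IC <- genes$ic
    sigs$KC <- genes$kc
    sigs$COLLAGEN_REG <- genes$collagen
    desc <- setNames(c(rep("tumor-reactivity signature", 100),
                       "intermediate macrophage state markers",
                       "Kupffer cell markers",
                       "positive collagen regulation"), names(sigs))
    gene_set_collection(sigs, desc)
  })
}
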