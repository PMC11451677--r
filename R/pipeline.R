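#' Default end-to-end pipeline configuration
#'
#' Nested list: a `simulate` block (forwarded to [cohort_config()]) and
#' per-stage parameter blocks with the package defaults. One global seed
#' fans out to per-stage seeds via a fixed `seed + stage index` rule so
#' stages can be rerun in isolation reproducibly.
#'
#' @param seed Global integer seed.
#' @param outdir Output directory for intermediate artifacts and the report
#'   (`NULL` skips artifact writing).
#' @param simulate Overrides for the cohort configuration.
#' @return A list of class `pipeline_config`.
#' @export
default_pipeline_config <- function(seed = 1, outdir = NULL, simulate = list()) {
  cfg <- list(
    seed = as.integer(seed),
    outdir = outdir,
    simulate = simulate,
    score = list(alpha = 0.25, cutoff_z = 2, min_sets_frac = 0.1,
                 n_control_sets = 10, control_set_size = 500),
    commnet = list(cond_a = "MT", cond_b = "PT", n_perm = 100, kh = 0.5,
                   alpha_sig = 0.05, min_cells = 10),
    trajectory = list(k = 15, n_pcs = 20, root = "max-kc", n_perm = 49),
    spatial = list(rho = 100, cutoff = 4),
    crosscorr = list(cytokines = c("TGFB1", "IL6", "TLR2", "TLR4"))
  )
  structure(cfg, class = "pipeline_config")
}

#' Read and validate a pipeline configuration from YAML
#'
#' Unknown keys (top-level or per stage) are rejected before any stage
#' runs; stage blocks override the defaults of
#' [default_pipeline_config()].
#'
#' @param path Path to a YAML file.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  validate_pipeline_config(user)
}

#' Validate and complete a pipeline configuration list
#'
#' @param user A (possibly partial) configuration list.
#' @return A `pipeline_config` with defaults filled in.
#' @export
validate_pipeline_config <- function(user) {
  base <- default_pipeline_config()
  unknown <- setdiff(names(user), names(base))
  if (length(unknown)) {
    abort(paste("unknown configuration key(s):", paste(unknown, collapse = ", ")),
          class = "trtniche_schema_error")
  }
  for (block in c("score", "commnet", "trajectory", "spatial", "crosscorr")) {
    if (!is.null(user[[block]])) {
      bad <- setdiff(names(user[[block]]), names(base[[block]]))
      if (length(bad)) {
        abort(sprintf("unknown key(s) in '%s' block: %s", block,
                      paste(bad, collapse = ", ")),
              class = "trtniche_schema_error")
      }
      base[[block]][names(user[[block]])] <- user[[block]]
    }
  }
  if (!is.null(user$simulate)) {
    bad <- setdiff(names(user$simulate), names(formals(cohort_config)))
    if (length(bad)) {
      abort(sprintf("unknown key(s) in 'simulate' block: %s",
                    paste(bad, collapse = ", ")),
            class = "trtniche_schema_error")
    }
    base$simulate <- user$simulate
  }
  if (!is.null(user$seed)) base$seed <- as.integer(user$seed)
  if (!is.null(user$outdir)) base$outdir <- user$outdir
  if (is.null(base$spatial$cutoff)) {
    abort("spatial stage requires a marker threshold ('cutoff')",
          class = "trtniche_schema_error")
  }
  structure(base, class = "pipeline_config")
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' simulate -> score -> commnet -> trajectory -> spatial -> crosscorr, each
#' stage seeded from the global seed, intermediate artifacts written in the
#' package's interchange formats when `outdir` is set, and a deterministic
#' run report assembled at the end. Any stage error aborts with the stage
#' name attached.
#'
#' @param config A `pipeline_config` (or plain list validated on entry).
#' @return A list of class `run_report`.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  if (!inherits(config, "pipeline_config")) {
    config <- validate_pipeline_config(config)
  }
  report <- list(package = "trtniche",
                 version = as.character(utils::packageVersion("trtniche")),
                 seed = config$seed, parameters = unclass(config),
                 stages = list())
  run_stage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
            class = "trtniche_stage_error")
    })
    report$stages[[name]] <<- c(list(status = "ok"), res)
  }

  sim_args <- config$simulate
  sim_args$seed <- config$seed + 1L
  cohort_cfg <- do.call(cohort_config, sim_args)
  env <- new.env()

  run_stage("simulate", function() {
    env$cohort <- make_cohort(cohort_cfg)
    env$sigs <- make_signature_collection(cohort_cfg)
    env$continuum <- make_macrophage_continuum(cohort_cfg)
    env$spatial <- make_spatial_cohort(cohort_cfg)
    env$lrdb <- default_lr_database()
    if (!is.null(config$outdir)) write_artifacts(env, config$outdir)
    list(n_cells = length(env$cohort$expr$cell_ids),
         n_genes = length(env$cohort$expr$gene_ids),
         n_signatures = length(env$sigs),
         n_spatial_samples = length(env$spatial))
  })

  run_stage("score", function() {
    p <- config$score
    ann <- env$cohort$annotation
    cd8 <- ann$cell_id[ann$coarse_type == "CD8T"]
    expr_cd8 <- normalize_expression(subset_expression(env$cohort$expr, cells = cd8))
    sig_only <- gene_set_collection(
      env$sigs$sets[grepl("^ptrt_sig_", names(env$sigs$sets))])
    sm <- suppressWarnings(
      normalize_scores(ssgsea_cell_scores(expr_cd8, sig_only, alpha = p$alpha)))
    calls <- classify_ptrt(sm, ann, cutoff_z = p$cutoff_z,
                           min_sets = ceiling(p$min_sets_frac * length(sig_only)))
    env$calls <- calls
    freq <- tissue_ptrt_frequency(calls, ann)
    comp <- cluster_composition(calls, ann)
    ctrl <- random_control_sets(env$cohort$expr,
                                min(p$control_set_size,
                                    length(env$cohort$expr$gene_ids) - 1L),
                                p$n_control_sets, seed = config$seed + 2L)
    ctrl_sm <- suppressWarnings(ssgsea_cell_scores(expr_cd8, ctrl, alpha = p$alpha))
    ctrl_df <- dplyr::inner_join(
      tibble::tibble(cell_id = ctrl_sm$cell_ids,
                     score = rowMeans(ctrl_sm$raw)), ann, by = "cell_id") |>
      dplyr::group_by(.data$patient, .data$tissue) |>
      dplyr::summarise(score = mean(.data$score), .groups = "drop")
    ctrl_p <- summary(aov(score ~ tissue, data = ctrl_df))[[1]][["Pr(>F)"]][1]
    list(n_ptrt = sum(calls$is_ptrt),
         frequency = as.data.frame(freq),
         frequency_summary = as.data.frame(summarize_ptrt_frequency(freq)),
         composition = as.data.frame(comp),
         control_anova_p = ctrl_p)
  })

  run_stage("commnet", function() {
    p <- config$commnet
    ann <- env$cohort$annotation
    grp <- ann$coarse_type
    grp[ann$cell_id %in% env$calls$cell_id[env$calls$is_ptrt]] <- "pTRT"
    grp[grp == "CD8T"] <- "CD8_nonreactive"
    ann$group <- grp
    graph_of <- function(tissue, seed) {
      sub_ann <- ann[ann$tissue == tissue, ]
      sub <- normalize_expression(subset_expression(env$cohort$expr,
                                                    cells = sub_ann$cell_id))
      suppressWarnings(permutation_pvalues(
        sub, sub_ann, env$lrdb, "group", n_perm = p$n_perm, seed = seed,
        kh = p$kh, min_cells = p$min_cells, condition_tag = tissue))
    }
    ga <- graph_of(p$cond_a, config$seed + 3L)
    gb <- graph_of(p$cond_b, config$seed + 4L)
    diff <- suppressWarnings(differential_network(ga, gb, p$alpha_sig))
    pc <- pathway_contribution(diff, sender = "macrophage", receiver = "pTRT")
    top <- diff$summary |> dplyr::arrange(dplyr::desc(.data$delta_strength))
    list(differential = as.data.frame(head(top, 10)),
         mac_to_ptrt_pathways = as.data.frame(pc))
  })

  run_stage("trajectory", function() {
    p <- config$trajectory
    expr_t <- normalize_expression(env$continuum$expr)
    graph <- build_cell_graph(expr_t, k = p$k, n_pcs = p$n_pcs,
                              seed = config$seed + 5L)
    ptime <- compute_pseudotime(graph, expr_t, root = p$root)
    env$ptime <- ptime
    moran <- rank_trajectory_genes(graph, expr_t, n_perm = p$n_perm,
                                   seed = config$seed + 6L)
    bc <- suppressWarnings(subcluster_branch(ptime, expr_t, seed = config$seed + 7L))
    icf <- ic_coexpression_frequency(env$cohort$expr, env$cohort$annotation)
    list(root_cell = attr(ptime, "root_cell_id"),
         moran_top = as.data.frame(head(moran, 10)),
         spp1_moran_rank = moran$rank[moran$gene == "SPP1"],
         state_summary = as.data.frame(attr(bc, "state_summary")),
         ic_frequency = as.data.frame(icf$frequencies),
         ic_test = as.data.frame(icf$test))
  })

  run_stage("spatial", function() {
    p <- config$spatial
    defs <- default_phenotype_definitions(p$cutoff)
    stats <- purrr::map_dfr(env$spatial, function(s) {
      pheno <- threshold_phenotypes(s$cells, defs)
      assign <- assign_regions(s$cells, s$regions)
      proximity_summary(s$cells, pheno, assign,
                        pairs = tibble::tibble(query = "macrophage",
                                               target = c("CD8T", "NK")),
                        rho = p$rho)
    })
    dens <- purrr::map_dfr(env$spatial, function(s) {
      pheno <- threshold_phenotypes(s$cells, defs)
      assign <- assign_regions(s$cells, s$regions)
      region_density(assign, pheno, s$regions, phenotypes = "macrophage")
    })
    t_cd8 <- paired_region_stats(stats, "macrophage", "CD8T")
    t_nk <- paired_region_stats(stats, "macrophage", "NK")
    t_dens <- paired_region_stats(dens, "macrophage", metric = "density_per_mm2")
    list(proximity = as.data.frame(stats),
         mac_cd8_test = as.data.frame(glance(t_cd8)),
         mac_nk_test = as.data.frame(glance(t_nk)),
         mac_density_test = as.data.frame(glance(t_dens)))
  })

  run_stage("crosscorr", function() {
    p <- config$crosscorr
    expr_n <- normalize_expression(env$cohort$expr)
    ann <- env$cohort$annotation
    grid <- purrr::map_dfr(p$cytokines, function(ck) {
      x <- suppressWarnings(pseudobulk_mean(expr_n, ann, "PT", ck))
      purrr::map_dfr(
        list(c("MT", "FN1", "all"), c("MT", "SPP1", "macrophage"),
             c("PT", "FN1", "all"), c("PT", "SPP1", "macrophage")),
        function(spec) {
          flt <- if (spec[3] == "all") NULL else spec[3]
          y <- suppressWarnings(pseudobulk_mean(expr_n, ann, spec[1], spec[2], flt))
          xc <- cross_compartment_correlation(
            x, y, x_label = paste0("PT:", ck),
            y_label = paste(spec[1], spec[2], spec[3], sep = ":"))
          glance(xc)
        })
    })
    fn1 <- paired_expression_compare(expr_n, ann, "FN1", "MT", "PT")
    list(correlation_grid = as.data.frame(grid),
         fn1_mt_vs_pt = as.data.frame(glance(fn1)))
  })

  structure(report, class = "run_report")
}

# write the simulated artifacts in the package interchange formats
write_artifacts <- function(env, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_expression(env$cohort$expr, file.path(outdir, "cohort_counts.mtx"),
                   file.path(outdir, "cohort_genes.tsv"),
                   file.path(outdir, "cohort_cells.tsv"))
  readr::write_csv(env$cohort$annotation, file.path(outdir, "cohort_annotation.csv"))
  write_gene_sets(env$sigs, file.path(outdir, "signatures.gmt"))
  write_lr_database(env$lrdb, file.path(outdir, "lr_pairs.csv"))
  s1 <- env$spatial[[1]]
  write_spatial_sample(s1$cells, s1$regions,
                       file.path(outdir, "spatial_S01_cells.csv"),
                       file.path(outdir, "spatial_S01_regions.json"))
  truth <- env$cohort$truth
  jsonlite::write_json(
    list(n_ptrt = sum(truth$ptrt_labels$is_ptrt),
         planted_slope = truth$planted_slope,
         patient_effects = truth$patient_effects),
    file.path(outdir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> trtniche %s, seed %d\n", x$version, x$seed))
  for (nm in names(x$stages)) {
    cat(sprintf("  %-10s %s\n", nm, x$stages[[nm]]$status))
  }
  invisible(x)
}

#' Write a run report to JSON plus a human-readable summary
#'
#' The JSON body is regenerable byte-identically from the same
#' configuration and seed (no timestamps or machine state are recorded).
#'
#' @param report A `run_report`.
#' @param path Output path for the JSON (`<path>.txt` gets the summary).
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  txt <- c(sprintf("trtniche %s run report (seed %d)", report$version, report$seed),
           vapply(names(report$stages), function(nm) {
             sprintf("stage %-10s: %s", nm, report$stages[[nm]]$status)
           }, ""))
  writeLines(txt, paste0(path, ".txt"))
  invisible(path)
}
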