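#' Built-in exposure signatures for the synthetic four-toxicant panel
#'
#' Per-agent fold-change signatures at the highest dose, chosen once to
#' emulate the qualitative reprogramming patterns of the four mechanistically
#' distinct stressors: the oxidant H2O2 raises m5C, Cm and m22G (t6A at high
#' dose) and lowers several others; the methylating agent MMS raises m7G;
#' NaAsO2 mostly lowers levels at high dose; NaOCl raises Am and Um inversely
#' with dose. All values lie in the 0.2-4 fold-change range typical of
#' population-level tRNA modification shifts.
#'
#' @return Named list (agent -> named fold-change vector at dose level 3).
#' @export
default_exposure_signatures <- function() {
  list(
    H2O2 = c(m5C = 2.5, Cm = 2.2, m22G = 2.0, t6A = 1.8,
             m5U = 0.6, m1G = 0.7, m2G = 0.7, mcm5s2U = 0.5, i6A = 0.5,
             yW = 0.6, m1A = 0.7),
    MMS = c(m7G = 2.8, m3C = 1.6, m1A = 1.4,
            Am = 0.6, m5C = 0.6, Cm = 0.7, mcm5s2U = 0.5, i6A = 0.5,
            yW = 0.4),
    NaAsO2 = c(mcm5U = 0.4, m3C = 0.5, m7G = 0.5, mcm5s2U = 0.4, i6A = 0.4,
               yW = 0.5, m5C = 0.6, Cm = 0.6, m2G = 1.6),
    NaOCl = c(Am = 2.4, Um = 2.2, Gm = 1.6, I = 1.5, m5C = 0.5))
}

# geometric dose interpolation: level 3 applies the full signature,
# lower levels proportionally weaker; NaOCl runs inverse to dose
dose_fold <- function(signature, level, inverse = FALSE) {
  w <- if (inverse) (4 - level) / 3 else level / 3
  signature ^ w
}

#' Simulate the four-agent x three-dose exposure panel
#'
#' Generates the full chromatogram-level dataset of the reference design:
#' one shared control group and 12 treated conditions (4 agents x 3 dose
#' levels), each with `n_replicates` biological replicates, using
#' [default_exposure_signatures()] dose-scaled geometrically (NaOCl
#' inverse-dosed).
#'
#' @param seed integer seed.
#' @param registry an `mrm_registry`.
#' @param n_replicates replicates per group (default 3).
#' @param signatures per-agent signatures, as [default_exposure_signatures()].
#' @param ... further noise / design arguments passed to
#'   [experiment_design()].
#' @return List with `samples` (named list of `chromatogram_set`; groups
#'   `control` and `<agent>_d<level>`), `truth` (design true areas), and
#'   `true_fold` (conditions x analytes matrix of the fold-changes applied).
#' @export
simulate_exposure_panel <- function(seed = 1L, registry = default_registry(),
                                    n_replicates = 3L,
                                    signatures = default_exposure_signatures(),
                                    ...) {
  samples <- list()
  truth <- list()
  true_fold <- list()
  cond_i <- 0L
  for (agent in names(signatures)) {
    for (level in 1:3) {
      cond_i <- cond_i + 1L
      cond <- sprintf("%s_d%d", agent, level)
      fc <- dose_fold(signatures[[agent]], level,
                      inverse = agent == "NaOCl")
      design <- experiment_design(
        fold_change = fc, n_replicates = n_replicates,
        seed = sample_seed(seed, cond_i), ...)
      ex <- simulate_experiment(design, registry,
                                group_labels = c("control", cond))
      if (cond_i == 1L) {
        # one shared control group across all conditions
        ctrl <- names(ex$samples)[grep("^control", names(ex$samples))]
        samples[ctrl] <- ex$samples[ctrl]
        truth[[length(truth) + 1L]] <-
          ex$truth[ex$truth$group == "control", ]
      }
      tr_ids <- names(ex$samples)[grep(paste0("^", cond), names(ex$samples))]
      samples[tr_ids] <- ex$samples[tr_ids]
      truth[[length(truth) + 1L]] <- ex$truth[ex$truth$group == cond, ]
      full_fc <- design$fold_change
      true_fold[[cond]] <- full_fc
    }
  }
  list(samples = samples,
       truth = do.call(rbind, c(truth, make.row.names = FALSE)),
       true_fold = do.call(rbind, true_fold))
}

#' Built-in enzyme-product map for the synthetic deletion-mutant panel
#'
#' True mutant/wild-type ratios per strain, chosen once from the known yeast
#' modification enzymology: each deletion abolishes (sentinel 0.00001) or
#' reduces its product; the two subunits of the m7G methyltransferase
#' (trm8, trm82) share an essentially identical profile including secondary
#' ~1.5-fold increases in other modifications; trm44, trm7 and trm13 all
#' lower Um (redundant 2'-O-methylation of U44); the trm5 heterozygote shows
#' a gene-dosage ~0.6 ratio for m1I.
#'
#' @return Named list (strain -> named true-ratio vector; unlisted analytes
#'   are 1).
#' @export
default_mutant_effects <- function() {
  m7g_secondary <- c(m3C = 1.6, mcm5U = 1.5, m1G = 1.5, m2G = 1.5, t6A = 1.5,
                     mcm5s2U = 1.6, m22G = 1.5, yW = 0.4)
  list(
    trm1 = c(m22G = 1e-05),
    trm2 = c(m5U = 1e-05),
    trm3 = c(Gm = 0.8),                       # redundant with Trm7
    trm4 = c(m5C = 1e-05),
    trm7 = c(Cm = 1e-05, ncm5Um = 1e-05, Gm = 0.5, Um = 0.50),
    trm8 = c(m7G = 0.14, m7g_secondary),
    trm82 = c(m7G = 0.15, m7g_secondary),
    trm9 = c(mcm5U = 1e-05, mcm5s2U = 1e-05),
    trm10 = c(m1G = 0.3),
    trm11 = c(m2G = 1e-05, yW = 0.5),
    trm12 = c(yW = 1e-05),
    trm13 = c(Um = 0.76, ncm5U = 0.8, mcm5U = 0.85),
    trm44 = c(Um = 0.53, ncm5U = 0.85, mcm5U = 0.9),
    trm5_het = c(m1I = 0.6, yW = 0.5),
    tad1 = c(m1I = 1e-05, I = 0.3, yW = 0.4),
    mod5 = c(i6A = 0.013, D = 0.5, yW = 0.35),
    tan1 = c(ac4C = 1e-05, yW = 0.45))
}

#' Simulate a deletion-mutant modification panel at the intensity level
#'
#' Draws replicate normalized-intensity vectors for wild type and each
#' mutant strain (log-normal replicate noise around the strain's true mean =
#' wild-type abundance x true ratio; sentinel ratios give zero intensity),
#' then computes mutant/wild-type ratio statistics per strain via
#' [fold_changes()].
#'
#' @param seed integer seed.
#' @param effects strain effect map, as [default_mutant_effects()].
#' @param registry an `mrm_registry`.
#' @param n_replicates per strain (default 3).
#' @param replicate_cv log-normal replicate CV (default 0.06).
#' @return List with `ratios` (strains x analytes matrix; undetectable cells
#'   carry the 0.00001 sentinel), `significant` (logical matrix, t-test
#'   p < 0.05), `stats` (long data.frame), `true_ratios`.
#' @export
simulate_mutant_panel <- function(seed = 1L,
                                  effects = default_mutant_effects(),
                                  registry = default_registry(),
                                  n_replicates = 3L,
                                  replicate_cv = 0.06) {
  ab <- default_abundances(registry)
  analytes <- names(ab)
  draw <- function(mu, s) {
    vals <- matrix(0, n_replicates, length(mu),
                   dimnames = list(NULL, analytes))
    pos <- mu > 0
    withr::with_seed(s, {
      vals[, pos] <- rep(mu[pos], each = n_replicates) *
        exp(stats::rnorm(n_replicates * sum(pos), 0, replicate_cv))
    })
    vals
  }
  wt <- draw(ab, sample_seed(seed, 0L))
  strains <- names(effects)
  true_ratios <- matrix(1, length(strains), length(analytes),
                        dimnames = list(strains, analytes))
  stats_l <- list()
  for (i in seq_along(strains)) {
    eff <- effects[[i]]
    eff <- eff[names(eff) %in% analytes]
    true_ratios[i, names(eff)] <- unname(eff)
    mu <- ab * true_ratios[i, ]
    mu[true_ratios[i, ] <= 1e-05] <- 0          # sentinel = undetectable
    mut <- draw(mu, sample_seed(seed, i))
    stats_l[[strains[i]]] <- fold_changes(mut, wt, condition = strains[i])
  }
  st <- do.call(rbind, c(stats_l, make.row.names = FALSE))
  ratios <- matrix(st$fold_change, nrow = length(strains), byrow = TRUE,
                   dimnames = list(strains, analytes))
  signif <- matrix(st$p_value < 0.05, nrow = length(strains), byrow = TRUE,
                   dimnames = list(strains, analytes))
  list(ratios = ratios, significant = signif, stats = st,
       true_ratios = true_ratios)
}

#' Write the bundled synthetic demo dataset
#'
#' Materializes the reference design — the 4-agent x 3-dose x 3-replicate
#' exposure panel with a shared control group, plus the deletion-mutant
#' panel — as plain-text files: chromatograms TSV, sample metadata CSV,
#' ground-truth CSVs, mutant ratio/significance CSVs, and a ready-to-run
#' pipeline config YAML.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @return Character vector of the files written, invisibly.
#' @export
make_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  panel <- simulate_exposure_panel(seed)
  write_chromatograms_tsv(panel$samples, p("chromatograms.tsv"))
  write_sample_metadata(panel$samples, p("metadata.csv"))
  utils::write.csv(panel$truth, p("truth_areas.csv"), row.names = FALSE)
  write_matrix_csv(panel$true_fold, p("truth_fold_changes.csv"),
                   label = "condition")
  mp <- simulate_mutant_panel(seed)
  write_matrix_csv(mp$ratios, p("mutant_ratios.csv"), label = "strain")
  write_matrix_csv(mp$significant * 1, p("mutant_significance.csv"),
                   label = "strain")
  yaml::write_yaml(list(
    seed = seed, registry = "default", rt_tolerance = 0.5,
    input = list(chromatograms = "chromatograms.tsv",
                 metadata = "metadata.csv",
                 mutant_ratios = "mutant_ratios.csv",
                 mutant_significance = "mutant_significance.csv"),
    control_group = "control",
    thresholds = list(undetectable = 0.02, decreased = 0.6, increased = 1.5),
    out_dir = "results"), p("config.yml"))
  invisible(list.files(dir, full.names = TRUE))
}

#' Run the full pipeline from a config
#'
#' Executes quantify -> signatures -> pathways over a config (YAML path or
#' list, as written by [make_fixtures()]): builds the intensity table,
#' fold-change matrix with t-tests, row/column centroid cluster trees on the
#' log2 matrix, correlation PCA with per-agent contributions, and — when a
#' mutant ratio matrix is configured — classification, enzyme-product links
#' and redundancy ranking. Every CSV carries a provenance header; a manifest
#' of output files with MD5 checksums is written last, so identical config
#' and seed give identical checksums.
#'
#' @param config YAML file path or an equivalent list; relative input paths
#'   resolve against the config file's directory.
#' @param out_dir overrides the config's output directory.
#' @return The manifest data.frame (`file`, `md5`), invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  base <- "."
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    base <- dirname(config)
    config <- yaml::read_yaml(config)
  }
  resolve <- function(pth) if (file.exists(pth)) pth else file.path(base, pth)
  registry <- if (identical(config$registry %||% "default", "default"))
    default_registry() else read_registry(resolve(config$registry))
  v <- validate_registry(registry)
  if (length(v)) stop("invalid registry: ", paste(unlist(v), collapse = "; "))
  out <- out_dir %||% config$out_dir %||% stop("config needs out_dir")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  rt_tol <- config$rt_tolerance %||% 0.5
  written <- character(0)
  emit <- function(name) written[[length(written) + 1L]] <<- file.path(out, name)

  # --- quantify ---------------------------------------------------------
  chrom_path <- resolve(config$input$chromatograms)
  if (!file.exists(chrom_path)) stop("chromatogram input not found: ", chrom_path)
  meta <- read_sample_metadata(resolve(config$input$metadata))
  csets <- read_chromatograms_tsv(chrom_path, metadata = meta)
  tab <- intensity_table(csets, registry, rt_tolerance = rt_tol)
  write_intensity_csv(tab, file.path(out, "intensities.csv"), seed = seed)
  emit("intensities.csv")

  # --- signatures -------------------------------------------------------
  ctrl <- config$control_group %||% "control"
  fc <- fold_change_matrix(tab, control_group = ctrl)
  utils::write.csv(as.data.frame(fc), file.path(out, "fold_changes.csv"),
                   row.names = FALSE)
  emit("fold_changes.csv")
  wide <- attr(fc, "wide")
  ok_cols <- colnames(wide)[colSums(is.na(wide) | wide <= 1e-05) == 0]
  log2m <- log2(wide[, ok_cols, drop = FALSE])
  rt <- hierarchical_cluster(log2m, axis = "rows")
  ct <- hierarchical_cluster(log2m, axis = "cols")
  write_cluster_json(rt, file.path(out, "cluster_rows.json")); emit("cluster_rows.json")
  write_cluster_json(ct, file.path(out, "cluster_cols.json")); emit("cluster_cols.json")
  write_cdt(rt, log2m, file.path(out, "clustered.cdt"))
  emit("clustered.cdt"); emit("clustered.gtr")
  pca <- pca_signature(wide[, ok_cols, drop = FALSE])
  write_matrix_csv(pca$scores, file.path(out, "pca_scores.csv"), "condition")
  emit("pca_scores.csv")
  write_matrix_csv(pca$loadings, file.path(out, "pca_loadings.csv"), "analyte")
  emit("pca_loadings.csv")
  utils::write.csv(data.frame(component = paste0("P", seq_along(pca$variance_percent)),
                              variance_percent = pca$variance_percent),
                   file.path(out, "pca_variance.csv"), row.names = FALSE)
  emit("pca_variance.csv")
  agent <- sub("_d[0-9]+$", "", rownames(pca$scores))
  contrib <- observation_contributions(pca, grouping = agent)
  write_matrix_csv(contrib, file.path(out, "pca_contributions.csv"), "agent")
  emit("pca_contributions.csv")

  # --- pathways ---------------------------------------------------------
  if (!is.null(config$input$mutant_ratios)) {
    ratios <- read_matrix_csv(resolve(config$input$mutant_ratios))
    signif <- if (!is.null(config$input$mutant_significance))
      read_matrix_csv(resolve(config$input$mutant_significance)) == 1
    else NULL
    th <- unlist(config$thresholds %||%
                   list(undetectable = 0.02, decreased = 0.6, increased = 1.5))
    cls <- classify_ratios(ratios, thresholds = th)
    write_matrix_csv(unclass(cls), file.path(out, "ratio_classification.csv"),
                     "strain")
    emit("ratio_classification.csv")
    links <- infer_enzyme_products(cls, ratios, significance = signif)
    utils::write.csv(links, file.path(out, "enzyme_product_links.csv"),
                     row.names = FALSE)
    emit("enzyme_product_links.csv")
    cm <- profile_correlation(ratios)
    red <- redundancy_candidates(cm)
    utils::write.csv(red, file.path(out, "redundancy_candidates.csv"),
                     row.names = FALSE)
    emit("redundancy_candidates.csv")
  }

  manifest <- data.frame(file = basename(unlist(written)),
                         md5 = unname(tools::md5sum(unlist(written))),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       digits = NA)
  invisible(manifest)
}
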