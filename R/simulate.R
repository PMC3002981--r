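#' Default per-analyte control abundances (counts x min)
#'
#' Synthetic true peak areas for an unexposed wild-type sample, spanning the
#' three-decade signal-intensity range seen in yeast tRNA hydrolysates: the
#' high tier (I, ac4C, m1A, m22G, Am, Y) near 1e5, the medium tier (Cm, m5C,
#' Gm, m1G, t6A, m7G, m2G, m3C, i6A) near 1e4, and the low tier (m1I, D, m5U,
#' ncm5Um, mcm5U, mcm5s2U, Um, yW, ncm5U) near 1e3. Signal intensity reflects
#' both abundance and ionization efficiency, so these are instrument-response
#' areas, not molar amounts.
#'
#' @param registry an `mrm_registry`.
#' @return Named numeric vector over the registry's analytes.
#' @export
default_abundances <- function(registry = default_registry()) {
  tiers <- c(
    I = 1.5e5, ac4C = 1.2e5, m1A = 9e4, m22G = 8e4, Am = 7e4, Y = 6e4,
    Cm = 2.5e4, m5C = 2e4, Gm = 1.6e4, m1G = 1.4e4, t6A = 1.2e4,
    m7G = 1.1e4, m2G = 1e4, m3C = 9e3, i6A = 8e3,
    m1I = 2.5e3, D = 2e3, m5U = 1.8e3, ncm5Um = 6e2, mcm5U = 1.4e3,
    mcm5s2U = 1.2e3, Um = 1.1e3, yW = 1e3, ncm5U = 9e2)
  nm <- analyte_names(registry)
  out <- tiers[nm]
  out[is.na(out)] <- 1e3
  names(out) <- nm
  out
}

#' Specification for one synthetic scheduled-MRM acquisition
#'
#' @param true_area named numeric vector of true peak areas (counts x min),
#'   one per transition to simulate; transitions absent from the vector get
#'   area 0. The internal standard is included here like any other transition.
#' @param peak_sigma Gaussian peak standard deviation, minutes. The default
#'   0.05 min resolves the closest scheduled neighbours (e.g. m7G at 5.1 min
#'   vs m1A at 5.7 min).
#' @param rt_jitter_sd per-peak retention-time jitter SD, minutes.
#' @param baseline_level constant baseline, counts.
#' @param baseline_noise_sd additive Gaussian noise SD, counts (traces are
#'   truncated at zero).
#' @param seed integer seed making the simulation a pure function of its
#'   arguments.
#' @return An object of class `mrm_sim_spec`.
#' @export
simulation_spec <- function(true_area,
                            peak_sigma = 0.05,
                            rt_jitter_sd = 0,
                            baseline_level = 0,
                            baseline_noise_sd = 0,
                            seed = 1L) {
  stopifnot(is.numeric(true_area), !is.null(names(true_area)),
            all(true_area >= 0), peak_sigma > 0,
            rt_jitter_sd >= 0, baseline_noise_sd >= 0)
  structure(list(true_area = true_area, peak_sigma = peak_sigma,
                 rt_jitter_sd = rt_jitter_sd,
                 baseline_level = baseline_level,
                 baseline_noise_sd = baseline_noise_sd,
                 seed = as.integer(seed)),
            class = "mrm_sim_spec")
}

# sampling grid for one segment: the duty cycle visits every co-scheduled
# transition once, so the cadence is dwell_time x (number of members)
segment_grid <- function(registry, i) {
  seg <- registry$segments
  dt_min <- registry$dwell_time * length(segment_members(registry, i)) / 60
  seq(seg$start_min[i], seg$end_min[i], by = dt_min)
}

#' Simulate one scheduled-MRM chromatogram set
#'
#' Each transition receives a trace sampled only within its scheduled
#' acquisition segment, at the dwell-time-derived cadence (dwell x number of
#' co-scheduled transitions). The analyte contributes a Gaussian peak of total
#' area `true_area` centred at its registry retention time plus jitter, on a
#' constant baseline with additive Gaussian noise; intensities are truncated
#' at zero. Given the same spec, registry and seed the output is bit-identical.
#'
#' @param spec an `mrm_sim_spec` from [simulation_spec()].
#' @param registry an `mrm_registry`.
#' @param sample_id sample label.
#' @param metadata list with `trna_mass` (ug), `is_amount` (pmol), `group`.
#' @return A `chromatogram_set`: list of `sample_id`, `traces` (named list of
#'   data.frames with `time`, `intensity`) and `metadata`.
#' @export
simulate_chromatograms <- function(spec, registry = default_registry(),
                                   sample_id = "sample1",
                                   metadata = list(trna_mass = 6,
                                                   is_amount = 6,
                                                   group = "control")) {
  stopifnot(inherits(spec, "mrm_sim_spec"))
  e <- registry$entries
  withr::with_seed(spec$seed, {
    traces <- vector("list", nrow(e))
    names(traces) <- e$short_name
    for (i in seq_len(nrow(e))) {
      nm <- e$short_name[i]
      seg_i <- segment_for(registry, e$retention_time[i])
      tt <- segment_grid(registry, seg_i)
      area <- if (nm %in% names(spec$true_area)) spec$true_area[[nm]] else 0
      mu <- e$retention_time[i] +
        if (spec$rt_jitter_sd > 0) stats::rnorm(1, 0, spec$rt_jitter_sd) else 0
      y <- spec$baseline_level +
        area * stats::dnorm(tt, mean = mu, sd = spec$peak_sigma)
      if (spec$baseline_noise_sd > 0)
        y <- y + stats::rnorm(length(tt), 0, spec$baseline_noise_sd)
      traces[[i]] <- data.frame(time = tt, intensity = pmax(y, 0))
    }
  })
  structure(list(sample_id = sample_id, traces = traces, metadata = metadata),
            class = "chromatogram_set")
}

#' @export
print.chromatogram_set <- function(x, ...) {
  npts <- sum(vapply(x$traces, nrow, integer(1)))
  cat(sprintf("chromatogram_set '%s' (group %s): %d traces, %d points\n",
              x$sample_id, x$metadata$group %||% "?", length(x$traces), npts))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Paired treated/control experiment design
#'
#' Describes one exposure condition: `n_replicates` control and
#' `n_replicates` treated samples, per-analyte control abundances, and the
#' per-analyte fold-change applied in the treated group. The internal
#' standard is spiked at a fixed amount per sample (6 pmol) into a fixed tRNA
#' mass (6 ug), mirroring the assay protocol; `injection_cv` applies a
#' common multiplicative per-sample scale to *all* traces (internal standard
#' included), emulating the injection-to-injection variation the internal
#' standard exists to cancel.
#'
#' @param control_abundance named numeric vector of control true areas; the
#'   default is [default_abundances()].
#' @param fold_change named numeric vector of treated/control fold-changes
#'   (> 0); analytes not named get 1.0.
#' @param n_replicates per group (default 3, the biological-replicate design).
#' @param is_amount internal standard per sample, pmol (default 6).
#' @param trna_mass tRNA per sample, ug (default 6).
#' @param is_area true internal-standard peak area, counts x min.
#' @param injection_cv per-sample global intensity scale CV (default 0.03,
#'   matching low-percent intra-day instrument variation).
#' @param biological_cv per-sample, per-analyte log-normal CV of the true
#'   analyte areas (default 0.10), emulating biological replicate-to-replicate
#'   variation in modification levels; unlike `injection_cv` it does not
#'   apply to the internal standard and therefore survives normalization.
#' @param peak_sigma,rt_jitter_sd,baseline_level,baseline_noise_sd noise
#'   parameters as in [simulation_spec()].
#' @param seed integer; per-sample substreams are derived deterministically
#'   from (seed, sample index).
#' @return An object of class `mrm_design`.
#' @export
experiment_design <- function(control_abundance = default_abundances(),
                              fold_change = numeric(0),
                              n_replicates = 3L,
                              is_amount = 6,
                              trna_mass = 6,
                              is_area = 5e4,
                              injection_cv = 0.03,
                              biological_cv = 0.10,
                              peak_sigma = 0.05,
                              rt_jitter_sd = 0.02,
                              baseline_level = 20,
                              baseline_noise_sd = 5,
                              seed = 1L) {
  stopifnot(n_replicates >= 1, all(control_abundance >= 0),
            all(fold_change > 0), is_amount > 0, trna_mass > 0, is_area > 0,
            injection_cv >= 0, biological_cv >= 0)
  fc <- rep(1, length(control_abundance))
  names(fc) <- names(control_abundance)
  fc[names(fold_change)] <- fold_change
  structure(list(control_abundance = control_abundance, fold_change = fc,
                 n_replicates = as.integer(n_replicates),
                 is_amount = is_amount, trna_mass = trna_mass,
                 is_area = is_area, injection_cv = injection_cv,
                 biological_cv = biological_cv,
                 peak_sigma = peak_sigma, rt_jitter_sd = rt_jitter_sd,
                 baseline_level = baseline_level,
                 baseline_noise_sd = baseline_noise_sd,
                 seed = as.integer(seed)),
            class = "mrm_design")
}

# deterministic per-sample substream seed, kept within 32-bit integer range
sample_seed <- function(seed, idx) {
  as.integer((as.numeric(seed) * 7919 + idx * 104729) %% 2147483647)
}

#' Simulate a paired treated/control replicate experiment
#'
#' Generates `n_replicates` control and `n_replicates` treated chromatogram
#' sets plus the ground-truth table of the true areas used. Treated true
#' areas are exactly `control_abundance * fold_change`; the internal-standard
#' true area is constant across samples up to the injection-scale jitter.
#'
#' @param design an `mrm_design` from [experiment_design()].
#' @param registry an `mrm_registry`.
#' @param group_labels length-2 character vector, control then treated.
#' @return List with `samples` (list of `chromatogram_set`), `truth`
#'   (data.frame: sample_id, group, short_name, true_area — pre-injection
#'   design areas) and `design`.
#' @export
simulate_experiment <- function(design, registry = default_registry(),
                                group_labels = c("control", "treated")) {
  stopifnot(inherits(design, "mrm_design"))
  is_name <- internal_standard(registry)$short_name
  base_control <- c(design$control_abundance,
                    stats::setNames(design$is_area, is_name))
  base_treated <- c(design$control_abundance * design$fold_change,
                    stats::setNames(design$is_area, is_name))
  samples <- list()
  truth <- list()
  idx <- 0L
  for (g in seq_along(group_labels)) {
    base <- if (g == 1L) base_control else base_treated
    for (r in seq_len(design$n_replicates)) {
      idx <- idx + 1L
      sid <- sprintf("%s_rep%d", group_labels[g], r)
      s_seed <- sample_seed(design$seed, idx)
      jitter <- withr::with_seed(s_seed + 1L, {
        scale <- if (design$injection_cv > 0)
          exp(stats::rnorm(1, 0, design$injection_cv)) else 1
        bio <- rep(1, length(base))
        names(bio) <- names(base)
        if (design$biological_cv > 0) {
          an <- setdiff(names(base), is_name)
          bio[an] <- exp(stats::rnorm(length(an), 0, design$biological_cv))
        }
        scale * bio
      })
      spec <- simulation_spec(
        true_area = base * jitter,
        peak_sigma = design$peak_sigma,
        rt_jitter_sd = design$rt_jitter_sd,
        baseline_level = design$baseline_level,
        baseline_noise_sd = design$baseline_noise_sd,
        seed = s_seed)
      samples[[sid]] <- simulate_chromatograms(
        spec, registry, sample_id = sid,
        metadata = list(trna_mass = design$trna_mass,
                        is_amount = design$is_amount,
                        group = group_labels[g]))
      truth[[sid]] <- data.frame(
        sample_id = sid, group = group_labels[g],
        short_name = names(base), true_area = unname(base),
        stringsAsFactors = FALSE)
    }
  }
  list(samples = samples, truth = do.call(rbind, c(truth, make.row.names = FALSE)),
       design = design)
}
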