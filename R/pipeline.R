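#' Pipeline configuration
#'
#' Validated bag of options for [run_analysis()].
#'
#' @param rheology a [rheology_params()].
#' @param include_viscous include the viscous term in the pressure gradient.
#' @param hdf_convention `"pressure_gradient"` or `"wall_on_blood"` (global
#'   sign flip).
#' @param normalization EL_V normalization, see [normalize_and_summarize()].
#' @param refine_peaks parabolic sub-frame peak refinement.
#' @param regions_fixed_at_ed freeze regional cut planes at end-diastole.
#' @param compute_components run the pathline subdivision (the slowest stage).
#' @param substep_frac pathline CFL bound, voxels per sub-step.
#' @param record_tracks number of pathlines to keep for geometry export.
#' @param seed stored in provenance (the analysis itself is deterministic).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(rheology = rheology_params(),
                            include_viscous = TRUE,
                            hdf_convention = c("pressure_gradient", "wall_on_blood"),
                            normalization = c("phase_mean_volume", "per_frame"),
                            refine_peaks = FALSE,
                            regions_fixed_at_ed = FALSE,
                            compute_components = TRUE,
                            substep_frac = 0.5,
                            record_tracks = 0,
                            seed = 1L) {
  stopifnot(inherits(rheology, "rheology_params"))
  hdf_convention <- match.arg(hdf_convention)
  normalization <- match.arg(normalization)
  if (substep_frac <= 0 || substep_frac > 1) stop("substep_frac must be in (0, 1]")
  structure(list(rheology = rheology, include_viscous = include_viscous,
                 hdf_convention = hdf_convention, normalization = normalization,
                 refine_peaks = refine_peaks,
                 regions_fixed_at_ed = regions_fixed_at_ed,
                 compute_components = compute_components,
                 substep_frac = substep_frac, record_tracks = record_tracks,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full LV flow analysis
#'
#' Executes geometry (volumes, regions, valve flows, phases), energetics
#' (KE_V, EL_V, peaks), hemodynamic forces (components, RMS, R_RMS, filling
#' impulse) and, optionally, the pathline flow-component subdivision, and
#' assembles a result bundle with full provenance.
#'
#' @param ds a [flow_dataset()] with landmarks.
#' @param config a [pipeline_config()].
#' @return list of class `result_bundle`: `timeseries` (one row per frame),
#'   `summary` (scalars), plus the stage objects (`phases`, `energetics`,
#'   `hdf`, `hdf_summary`, `impulse`, `components`, `volumes`).
#' @export
run_analysis <- function(ds, config = pipeline_config()) {
  stopifnot(inherits(ds, "flow_dataset"), inherits(config, "pipeline_config"))
  if (is.null(ds$landmarks)) stop("stage geometry: dataset has no landmarks")
  nt <- dim(ds$mask)[4]

  labels <- subdivide_regions(ds, fixed_at_ed = config$regions_fixed_at_ed)
  volumes <- lv_volume_series(ds, labels = labels)
  aflow <- transvalvular_flow(ds, "aortic")
  mflow <- transvalvular_flow(ds, "mitral")
  phases <- detect_phases(aflow, mflow, ds$frame_times, ds$rr_interval,
                          volume_ml = volumes$volume_ml)

  regs <- c("global", "basal", "mid", "apical")
  ke <- el <- matrix(0, nt, 4, dimnames = list(NULL, regs))
  hdf_rows <- vector("list", nt)
  for (k in seq_len(nt)) {
    grad <- velocity_gradient(ds, k)
    ke[k, ] <- kinetic_energy(ds, k, density = config$rheology$density, labels = labels)
    el[k, ] <- viscous_loss_rate(ds, k, params = config$rheology, labels = labels, grad = grad)
    bf <- pressure_gradient_field(ds, k, config$rheology,
                                  include_viscous = config$include_viscous,
                                  grad = grad)
    fr <- build_frame(ds$landmarks[[k]])
    h <- hemodynamic_force(bf, ds$spacing, fr, volumes$volume_ml[k],
                           convention = config$hdf_convention)
    hdf_rows[[k]] <- data.frame(
      frame = k, time = ds$frame_times[k],
      fx = h$vector[1], fy = h$vector[2], fz = h$vector[3],
      basal_apical = h$components[["basal_apical"]],
      septal_lateral = h$components[["septal_lateral"]],
      inferior_anterior = h$components[["inferior_anterior"]],
      basal_apical_v = h$components_v[["basal_apical"]],
      septal_lateral_v = h$components_v[["septal_lateral"]],
      inferior_anterior_v = h$components_v[["inferior_anterior"]],
      volume_ml = volumes$volume_ml[k]
    )
  }
  volmat <- as.matrix(volumes[, c("volume_ml", "basal_ml", "mid_ml", "apical_ml")])
  colnames(volmat) <- regs
  energetics <- normalize_and_summarize(ke, el, volmat, phases, ds$frame_times,
                                        ds$rr_interval,
                                        normalization = config$normalization,
                                        refine_peaks = config$refine_peaks)

  hdf <- structure(list(samples = do.call(rbind, hdf_rows),
                        frame_times = ds$frame_times,
                        rr_interval = ds$rr_interval),
                   class = "hdf_series")
  hdf_summary <- summarize_hdf(hdf, phases)
  impulse <- filling_impulse(hdf, phases)

  components <- NULL; tracks <- NULL; classes <- NULL
  if (config$compute_components) {
    components <- classify_components(ds, phases, substep_frac = config$substep_frac)
    if (config$record_tracks > 0) {
      nseed <- nrow(components$seeds)
      pick <- unique(round(seq(1, nseed, length.out = min(config$record_tracks, nseed))))
      tr <- trace_pathlines(as_grid_frame(ds), components$seeds[pick, , drop = FALSE],
                            t_start = 0, duration = phases$aortic_valve_closure,
                            direction = "forward",
                            substep_frac = config$substep_frac, record_every = 5)
      tracks <- lapply(seq_along(pick), function(i) {
        do.call(rbind, c(list(components$seeds[pick[i], , drop = FALSE]),
                         lapply(tr$track, function(s) s$positions[i, , drop = FALSE])))
      })
      classes <- components$class[pick]
    }
  }

  timeseries <- data.frame(
    frame = seq_len(nt), time = ds$frame_times,
    volume_ml = volumes$volume_ml,
    aortic_flow_ml_s = aflow, mitral_flow_ml_s = mflow,
    ke_v_global = energetics$ke_v[, "global"],
    ke_v_basal = energetics$ke_v[, "basal"],
    ke_v_mid = energetics$ke_v[, "mid"],
    ke_v_apical = energetics$ke_v[, "apical"],
    el_rate_global = el[, "global"],
    el_rate_basal = el[, "basal"],
    el_rate_mid = el[, "mid"],
    el_rate_apical = el[, "apical"],
    hdf_ba_v = hdf$samples$basal_apical_v,
    hdf_sl_v = hdf$samples$septal_lateral_v,
    hdf_ia_v = hdf$samples$inferior_anterior_v
  )

  summary <- list(
    n_frames = nt, rr_interval = ds$rr_interval,
    edv_ml = max(volumes$volume_ml), esv_ml = min(volumes$volume_ml),
    sv_ml = max(volumes$volume_ml) - min(volumes$volume_ml),
    ef = 1 - min(volumes$volume_ml) / max(volumes$volume_ml),
    aortic_valve_closure_s = phases$aortic_valve_closure,
    e_peak_s = phases$e_peak, a_peak_s = phases$a_peak,
    merged_inflow = phases$merged,
    ke_v_peaks = energetics$peaks,
    el_v = as.data.frame(energetics$el_v),
    hdf_rms = as.data.frame(hdf_summary$rms),
    r_rms_systole = unname(hdf_summary$r_rms["systole"]),
    r_rms_diastole = unname(hdf_summary$r_rms["diastole"]),
    hdf_peaks = hdf_summary$peaks,
    filling_impulse_ns_l = impulse$impulse,
    filling_impulse_defined = impulse$defined,
    flow_components_pct = if (!is.null(components)) as.list(components$fractions) else NULL,
    provenance = list(package_version = as.character(utils::packageVersion("lvflow")),
                      seed = config$seed,
                      config = config[setdiff(names(config), "rheology")],
                      rheology = unclass(config$rheology))
  )

  structure(list(timeseries = timeseries, summary = summary, phases = phases,
                 energetics = energetics, hdf = hdf, hdf_summary = hdf_summary,
                 impulse = impulse, components = components, volumes = volumes,
                 pathline_tracks = tracks, pathline_classes = classes),
            class = "result_bundle")
}

#' @export
print.result_bundle <- function(x, ...) {
  s <- x$summary
  cat("<result_bundle>\n")
  cat(sprintf("  EDV %.1f mL, SV %.1f mL, EF %.1f%%\n", s$edv_ml, s$sv_ml, 100 * s$ef))
  cat(sprintf("  R_RMS systole %.3f, diastole %.3f; impulse %.4g Ns/L\n",
              s$r_rms_systole, s$r_rms_diastole, s$filling_impulse_ns_l))
  if (!is.null(s$flow_components_pct)) {
    f <- s$flow_components_pct
    cat(sprintf("  DF %.1f%% RI %.1f%% DE %.1f%% RV %.1f%%\n", f$df, f$ri, f$de, f$rv))
  }
  invisible(x)
}

# Scalar metrics of one bundle used for group comparison.
bundle_metrics <- function(b) {
  s <- b$summary
  pk <- s$ke_v_peaks
  out <- c(
    ke_v_peak_systolic = pk$ke_v[pk$peak == "systolic" & pk$region == "global"],
    ke_v_peak_e_wave = pk$ke_v[pk$peak == "e_wave" & pk$region == "global"],
    el_v_systole = s$el_v["systole", "global"],
    el_v_diastole = s$el_v["diastole", "global"],
    r_rms_systole = s$r_rms_systole,
    r_rms_diastole = s$r_rms_diastole,
    filling_impulse_abs = abs(s$filling_impulse_ns_l),
    ef_pct = 100 * s$ef
  )
  if (!is.null(s$flow_components_pct)) {
    f <- s$flow_components_pct
    out <- c(out, df_pct = f$df, ri_pct = f$ri, de_pct = f$de, rv_pct = f$rv)
  }
  unlist(out)
}

#' Descriptive group comparison of result bundles
#'
#' Per-metric group mean, SD and percent difference against a reference
#' group. Descriptive only: no inferential statistics are computed.
#'
#' @param groups named list; each element a list of [run_analysis()] bundles.
#' @param reference name of the reference group (default: the first).
#' @return data.frame with columns `metric`, `group`, `n`, `mean`, `sd`,
#'   `pct_diff_vs_ref`.
#' @export
compare_groups <- function(groups, reference = names(groups)[1]) {
  if (is.null(names(groups)) || any(names(groups) == "")) stop("groups must be named")
  if (!reference %in% names(groups)) stop("unknown reference group")
  if (any(vapply(groups, length, integer(1)) == 0)) stop("empty group")
  mets <- lapply(groups, function(g) do.call(rbind, lapply(g, bundle_metrics)))
  metric_names <- colnames(mets[[1]])
  ref_mean <- colMeans(mets[[reference]][, metric_names, drop = FALSE])
  out <- do.call(rbind, lapply(names(groups), function(gn) {
    m <- mets[[gn]]
    data.frame(
      metric = metric_names, group = gn, n = nrow(m),
      mean = colMeans(m),
      sd = if (nrow(m) > 1) apply(m, 2, stats::sd) else NA_real_,
      pct_diff_vs_ref = 100 * (colMeans(m) - ref_mean) / ifelse(abs(ref_mean) > 1e-12, ref_mean, NA_real_),
      row.names = NULL
    )
  }))
  out
}
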