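#' Pipeline run configuration
#'
#' Collects every tunable parameter of an end-to-end run with its default.
#' `intensity_hotspots = "per-condition"` centres each intensity block's coil
#' grid on the reference muscle of that condition (the FDI/EDC/FCR hotspot
#' rule); `"shared"` centres all blocks on the first muscle's hotspot.
#'
#' @param seed master RNG seed.
#' @param n_subjects cohort size.
#' @param n_intensities,stims_per_block,n_repetitions,inter_stimulus_s,grid_extent_mm
#'   design parameters, see [experiment_design()].
#' @param patch_nx,patch_ny,patch_spacing_mm,region_halfwidth_mm template
#'   flat-patch geometry.
#' @param sigma_mm,jitter_mm,mesh_noise_mm,amplitude_noise_uv synthetic-field
#'   parameters, see [make_cohort()].
#' @param cutoff_hz,filter_order,response_window_ms,baseline_window_ms,k_sd,upper_limit_uv
#'   EMG filtering and MEP classification parameters.
#' @param radius_mm geodesic interpolation radius.
#' @param lambda_curv curvature-penalty weight of the warp.
#' @param overlap_mode `"geometric"` or `"weighted"`.
#' @param m1_mask mask stimulations to the precentral region before warping.
#' @param region atlas label of the mask.
#' @param intensity_hotspots `"per-condition"` or `"shared"`.
#' @param out_dir optional output directory; `NULL` keeps results in memory.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1, n_subjects = 20,
                       n_intensities = 3, stims_per_block = 120,
                       n_repetitions = 2, inter_stimulus_s = 5,
                       grid_extent_mm = 50,
                       patch_nx = 41, patch_ny = 41, patch_spacing_mm = 2,
                       region_halfwidth_mm = 15,
                       sigma_mm = 6, jitter_mm = 2, mesh_noise_mm = 0.2,
                       amplitude_noise_uv = 20,
                       cutoff_hz = 30, filter_order = 2,
                       response_window_ms = c(15, 50),
                       baseline_window_ms = 200, k_sd = 20,
                       upper_limit_uv = 10000,
                       radius_mm = 5, lambda_curv = 1,
                       overlap_mode = "geometric", m1_mask = TRUE,
                       region = "precentral L",
                       intensity_hotspots = "per-condition",
                       out_dir = NULL) {
  cfg <- as.list(environment())
  # YAML sequences arrive as lists; the window must be a numeric pair
  cfg$response_window_ms <- as.numeric(unlist(cfg$response_window_ms))
  if (length(cfg$response_window_ms) != 2L)
    stop("response_window_ms must be a two-element window")
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected; missing keys take the [run_config()] defaults.
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(run_config, y)
}

# per-condition grid centres for a subject, following the hotspot rule:
# "per-condition" centres each block on its reference muscle's hotspot,
# "shared" on the first muscle's, "center" on the mean of all field centres
condition_hotspots <- function(fields, design, mode) {
  ref <- sub("^105%-RMT-", "", design$intensity_labels)
  ctr <- rowMeans(vapply(fields, function(f) f$center, numeric(3)))
  vapply(seq_len(design$n_intensities), function(i) {
    if (mode == "center") return(ctr)
    m <- if (mode == "per-condition" && ref[i] %in% names(fields)) ref[i]
    else names(fields)[1]
    fields[[m]]$center
  }, numeric(3))
}

#' MEP detection over a whole cohort
#'
#' Regenerates every trial's EMG trace, high-pass filters it, and applies the
#' MEP classification rules, yielding the per-pulse MEP table.
#'
#' @param cohort a `tms_cohort`.
#' @param cfg a [run_config()].
#' @param subjects subject indices to process (default all).
#' @return data.frame with `subject`, `event_id`, `muscle`, `p2p_uv`,
#'   `baseline_sd_uv`, `is_mep`, `reason`.
#' @export
detect_cohort_meps <- function(cohort, cfg = run_config(),
                               subjects = seq_along(cohort$subjects)) {
  muscles <- names(cohort$fields)
  out <- vector("list", length(subjects))
  for (si in seq_along(subjects)) {
    s <- subjects[si]
    ev <- cohort$subjects[[s]]$events
    res <- vector("list", nrow(ev) * length(muscles))
    k <- 0L
    for (e in seq_len(nrow(ev))) {
      for (mi in seq_along(muscles)) {
        tr <- highpass_filter(cohort_trace(cohort, s, e, mi),
                              cfg$cutoff_hz, cfg$filter_order)
        r <- detect_mep(tr, cfg$response_window_ms, cfg$baseline_window_ms,
                        cfg$k_sd, cfg$upper_limit_uv)
        k <- k + 1L
        res[[k]] <- data.frame(subject = s, event_id = ev$event_id[e],
                               muscle = muscles[mi], p2p_uv = r$p2p_uv,
                               baseline_sd_uv = r$baseline_sd_uv,
                               is_mep = r$is_mep, reason = r$reason,
                               stringsAsFactors = FALSE)
      }
    }
    out[[si]] <- do.call(rbind, res)
  }
  do.call(rbind, out)
}

# project, mask and warp one subject's MEP-positive stimulations; returns a
# template-space stimulation set per muscle x intensity
subject_stim_sets <- function(cohort, mep_table, s, cfg) {
  subj <- cohort$subjects[[s]]
  ev <- subj$events
  vid <- vapply(seq_len(nrow(ev)), function(e)
    project_event_to_vertex(as.numeric(ev[e, c("x_mm", "y_mm", "z_mm")]),
                            subj$mesh), 0L)
  keep_mask <- vid %in% mask_to_region(unique(vid), subj$mesh, cfg$region,
                                       enabled = cfg$m1_mask)
  mt <- mep_table[mep_table$subject == s, ]
  sets <- list()
  for (m in names(cohort$fields)) {
    mm <- mt[mt$muscle == m & mt$is_mep, ]
    for (cond in cohort$design$intensity_labels) {
      rows <- which(ev$intensity_condition == cond & keep_mask &
                      ev$event_id %in% mm$event_id)
      stims <- data.frame(
        vertex_id = vid[rows],
        mep_uv = mm$p2p_uv[match(ev$event_id[rows], mm$event_id)])
      if (nrow(stims) > 0)
        stims <- warp_events(stims, subj$mesh, cohort$template,
                             cfg$lambda_curv)
      sets[[m]][[cond]] <- stims
    }
  }
  sets
}

#' Build excitability maps and metrics for a whole cohort
#'
#' The mapping stage of the pipeline: projects each subject's MEP-positive
#' stimulations to surface vertices, masks them to the precentral region,
#' warps them to the template, interpolates per-muscle excitability maps per
#' intensity condition, and computes the map metrics (centroid, weighted
#' area) and the 28-pair overlap tables (one per subject and intensity where
#' all eight maps exist).
#'
#' @param cohort a `tms_cohort`.
#' @param mep_table per-pulse MEP table from [detect_cohort_meps()].
#' @param cfg a [run_config()].
#' @param verbose print per-subject counters.
#' @return list with `maps` (nested subject/condition/muscle), `metrics`
#'   (data.frame), and `overlaps` (data.frame).
#' @export
map_cohort <- function(cohort, mep_table, cfg = run_config(),
                       verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  muscles <- names(cohort$fields)
  conds <- cohort$design$intensity_labels
  metrics <- NULL
  overlaps <- NULL
  maps <- list()
  for (s in seq_along(cohort$subjects)) {
    sets <- subject_stim_sets(cohort, mep_table, s, cfg)
    smaps <- list()
    for (cond in conds) {
      cmaps <- list()
      for (m in muscles) {
        stims <- sets[[m]][[cond]]
        if (is.null(stims) || nrow(stims) == 0) next
        map <- interpolate_to_vertices(stims, cohort$template, cfg$radius_mm,
                                       muscle_label = m,
                                       intensity_condition = cond)
        cmaps[[m]] <- map
        metrics <- rbind(metrics, data.frame(
          subject = s, muscle = m, intensity = cond,
          n_stims = nrow(stims),
          Cx = map_centroid(map)[1], Cy = map_centroid(map)[2],
          Cz = map_centroid(map)[3], W = area_size(map),
          stringsAsFactors = FALSE))
      }
      if (length(cmaps) == length(muscles)) {
        ot <- overlap_table(cmaps[muscles], cfg$overlap_mode)
        ot$subject <- s
        ot$intensity <- cond
        overlaps <- rbind(overlaps, ot)
      }
      smaps[[cond]] <- cmaps
    }
    maps[[s]] <- smaps
    say("subject ", s, ": ",
        sum(metrics$subject == s & !is.na(metrics$W)), " maps")
  }
  list(maps = maps, metrics = metrics, overlaps = overlaps)
}

#' Group-level repeated-measures statistics
#'
#' The inference stage: two-way RM-ANOVAs of each map metric (Cx, Cy, Cz, W)
#' over muscle x intensity; of the mean overlap over pair-group x intensity
#' (with Bonferroni post-hocs on both factors); and, within each pair group,
#' over pair x intensity.
#'
#' @param metrics map-metric table from [map_cohort()].
#' @param overlaps overlap table from [map_cohort()].
#' @return list with `anova` (named list of three tables) and `posthoc`.
#' @export
group_statistics <- function(metrics, overlaps) {
  anova <- list()
  posthoc <- list()
  if (!is.null(metrics)) {
    met_long <- lapply(c("Cx", "Cy", "Cz", "W"), function(meas) {
      lt <- long_table(metrics$subject, metrics$muscle, metrics$intensity,
                       metrics[[meas]], aggregate = TRUE)
      at <- rm_anova_2way(lt)
      at$measure <- meas
      at
    })
    anova$metrics <- do.call(rbind, met_long)
  }
  if (!is.null(overlaps)) {
    grp <- stats::aggregate(overlap ~ subject + pair_group + intensity,
                            overlaps, mean)
    lt <- long_table(grp$subject, grp$pair_group, grp$intensity, grp$overlap)
    anova$overlap_group <- rm_anova_2way(lt)
    if (length(unique(overlaps$intensity)) >= 2)
      posthoc$overlap_intensity <- bonferroni_posthoc(lt, "factor_b")
    posthoc$overlap_group <- bonferroni_posthoc(lt, "factor_a")
    within <- lapply(unique(overlaps$pair_group), function(g) {
      og <- overlaps[overlaps$pair_group == g, ]
      pair <- paste(og$muscle_k, og$muscle_l, sep = "-")
      at <- rm_anova_2way(long_table(og$subject, pair, og$intensity,
                                     og$overlap))
      at$pair_group <- g
      at
    })
    anova$overlap_within_group <- do.call(rbind, within)
  }
  list(anova = anova, posthoc = posthoc)
}

#' Run the full mapping pipeline
#'
#' End-to-end run on a synthetic cohort: EMG synthesis and MEP detection,
#' projection of stimulation sites onto the subject surface, M1 masking,
#' warping to the template, geodesic interpolation into per-muscle
#' excitability maps, map metrics (centroid, weighted area), pairwise
#' overlaps with muscle-pair grouping, and the group-level
#' repeated-measures ANOVAs (map metrics by muscle x intensity; overlap by
#' pair-group x intensity; within-group overlap by pair x intensity) with
#' Bonferroni-corrected intensity post-hocs. When `cfg$out_dir` is set, all
#' tables, the configuration echo, and a manifest are written there.
#'
#' @param cfg a [run_config()].
#' @param cohort optional pre-built `tms_cohort`; by default one is generated
#'   from `cfg`.
#' @param verbose print per-stage counters.
#' @return list with `cohort`, `mep_table`, `maps`, `metrics`, `overlaps`,
#'   `anova` (list of three tables), `posthoc`, `config`.
#' @export
run_pipeline <- function(cfg = run_config(), cohort = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  design <- experiment_design(cfg$n_intensities, cfg$stims_per_block,
                              cfg$n_repetitions, cfg$inter_stimulus_s,
                              cfg$grid_extent_mm)
  if (is.null(cohort)) {
    template <- make_flat_patch_mesh(cfg$patch_nx, cfg$patch_ny,
                                     cfg$patch_spacing_mm,
                                     region_halfwidth_mm =
                                       cfg$region_halfwidth_mm)
    cohort <- make_cohort(cfg$n_subjects, template,
                          default_fields(cfg$sigma_mm), design,
                          jitter_mm = cfg$jitter_mm,
                          mesh_noise_mm = cfg$mesh_noise_mm,
                          amplitude_noise_uv = cfg$amplitude_noise_uv,
                          hotspot_rule = cfg$intensity_hotspots,
                          seed = cfg$seed)
  }
  say("cohort: ", length(cohort$subjects), " subjects, ",
      nrow(cohort$subjects[[1]]$events), " events each")
  mep_table <- detect_cohort_meps(cohort, cfg)
  say("MEP detection: ", sum(mep_table$is_mep), " of ", nrow(mep_table),
      " trials classified as MEP")
  mapped <- map_cohort(cohort, mep_table, cfg, verbose = verbose)
  stats_out <- group_statistics(mapped$metrics, mapped$overlaps)
  result <- list(cohort = cohort, mep_table = mep_table,
                 maps = mapped$maps, metrics = mapped$metrics,
                 overlaps = mapped$overlaps, anova = stats_out$anova,
                 posthoc = stats_out$posthoc, config = cfg)
  if (!is.null(cfg$out_dir)) write_pipeline_outputs(result, cfg$out_dir)
  result
}

#' Write pipeline outputs to a directory
#'
#' Emits the MEP table, map metrics, overlap table, the three ANOVA tables,
#' post-hoc tables, the configuration echo (YAML), the synthetic ground
#' truth (JSON) and a manifest (JSON with package version, seed and config).
#'
#' @param result a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(x, f) if (!is.null(x))
    write.csv(x, file.path(dir, f), row.names = FALSE)
  wcsv(result$mep_table, "mep_table.csv")
  wcsv(result$metrics, "map_metrics.csv")
  wcsv(result$overlaps, "overlap_table.csv")
  wcsv(result$anova$metrics, "anova_metrics.csv")
  wcsv(result$anova$overlap_group, "anova_overlap_group.csv")
  wcsv(result$anova$overlap_within_group, "anova_overlap_within_group.csv")
  for (nm in names(result$posthoc))
    wcsv(result$posthoc[[nm]], paste0("posthoc_", nm, ".csv"))
  cfg <- result$config
  cfg$out_dir <- NULL
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  gt <- result$cohort$ground_truth
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       dataframe = "rows", digits = NA)
  manifest <- list(package = "tmsmap",
                   version = as.character(utils::packageVersion("tmsmap")),
                   r_version = R.version.string,
                   seed = result$config$seed,
                   config_hash = sum(utf8ToInt(paste(
                     utils::capture.output(utils::str(unclass(cfg))),
                     collapse = ""))),
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Write a synthetic cohort to disk
#'
#' Meshes in the plain-text dialect, one events CSV per subject, per-trial
#' amplitudes, and the ground truth as JSON. EMG traces can optionally be
#' materialised (one CSV per subject x muscle, columns `event_id`, `time_s`,
#' `value_uV`) — feasible for small cohorts only.
#'
#' @param cohort a `tms_cohort`.
#' @param dir output directory.
#' @param write_emg materialise EMG traces.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, write_emg = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_sphere <- function(mesh, tag) {
    if (is.null(mesh$sphere)) return(invisible(NULL))
    write.csv(data.frame(vertex_id = seq_len(nrow(mesh$sphere)) - 1L,
                         sx = mesh$sphere[, 1], sy = mesh$sphere[, 2],
                         sz = mesh$sphere[, 3]),
              file.path(dir, paste0(tag, ".sphere.csv")), row.names = FALSE)
  }
  write_mesh_txt(cohort$template, file.path(dir, "template.mesh.txt"))
  write_sphere(cohort$template, "template")
  d <- cohort$design
  jsonlite::write_json(
    list(seed = cohort$seed, n_subjects = length(cohort$subjects),
         muscles = names(cohort$fields),
         design = list(n_intensities = d$n_intensities,
                       stims_per_block = d$stims_per_block,
                       n_repetitions = d$n_repetitions,
                       inter_stimulus_s = d$inter_stimulus_s,
                       grid_extent_mm = d$grid_extent_mm,
                       intensity_labels = d$intensity_labels),
         intensity_scale = as.list(cohort$intensity_scale),
         amplitude_noise_uv = cohort$amplitude_noise_uv),
    file.path(dir, "cohort.json"), auto_unbox = TRUE, digits = NA)
  for (s in seq_along(cohort$subjects)) {
    subj <- cohort$subjects[[s]]
    tag <- sprintf("sub-%02d", s)
    write_mesh_txt(subj$mesh, file.path(dir, paste0(tag, ".mesh.txt")))
    write_sphere(subj$mesh, tag)
    ev <- subj$events
    ev$subject <- s
    write.csv(ev[, c("subject", "event_id", "time_s", "x_mm", "y_mm", "z_mm",
                     "ox", "oy", "oz", "intensity_condition")],
              file.path(dir, paste0(tag, "_events.csv")), row.names = FALSE)
    amps <- cbind(data.frame(subject = s, event_id = ev$event_id),
                  as.data.frame(subj$amplitudes))
    write.csv(amps, file.path(dir, paste0(tag, "_amplitudes.csv")),
              row.names = FALSE)
    if (write_emg) {
      for (m in names(cohort$fields)) {
        traces <- lapply(seq_len(nrow(ev)), function(e) {
          tr <- cohort_trace(cohort, s, e, m)
          data.frame(event_id = ev$event_id[e], time_s = trace_times(tr),
                     value_uV = tr$samples)
        })
        write.csv(do.call(rbind, traces),
                  file.path(dir, paste0(tag, "_emg_", m, ".csv")),
                  row.names = FALSE)
      }
    }
  }
  jsonlite::write_json(cohort$ground_truth,
                       file.path(dir, "ground_truth.json"),
                       dataframe = "rows", digits = NA)
  invisible(dir)
}

#' Read a synthetic cohort back from disk
#'
#' Reconstructs a `tms_cohort` written by [write_cohort()]: meshes (with
#' their sphere-registration sidecars), event tables, per-trial amplitudes,
#' and the ground-truth field parameters. The reloaded cohort supports the
#' full downstream pipeline, including deterministic EMG regeneration via
#' [cohort_trace()].
#'
#' @param dir directory written by [write_cohort()].
#' @return a `tms_cohort`.
#' @export
read_cohort <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "cohort.json"),
                              simplifyVector = TRUE)
  read_with_sphere <- function(tag) {
    mesh <- read_mesh_txt(file.path(dir, paste0(tag, ".mesh.txt")))
    sp <- file.path(dir, paste0(tag, ".sphere.csv"))
    if (file.exists(sp)) {
      s <- read.csv(sp)
      mesh$sphere <- as.matrix(s[order(s$vertex_id), c("sx", "sy", "sz")])
      dimnames(mesh$sphere) <- NULL
    }
    mesh
  }
  template <- read_with_sphere("template")
  d <- meta$design
  design <- experiment_design(d$n_intensities, d$stims_per_block,
                              d$n_repetitions, d$inter_stimulus_s,
                              d$grid_extent_mm, d$intensity_labels)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  centers <- gt$centers
  subjects <- lapply(seq_len(meta$n_subjects), function(s) {
    tag <- sprintf("sub-%02d", s)
    mesh <- read_with_sphere(tag)
    ev <- read.csv(file.path(dir, paste0(tag, "_events.csv")),
                   stringsAsFactors = FALSE)
    ev$subject <- NULL
    amps <- read.csv(file.path(dir, paste0(tag, "_amplitudes.csv")))
    amps <- as.matrix(amps[, meta$muscles, drop = FALSE])
    sc <- centers[centers$subject == s, ]
    fields <- lapply(meta$muscles, function(m) {
      r <- sc[sc$muscle == m, ]
      gt_field(m, c(r$cx, r$cy, r$cz), r$sigma_mm, r$peak_uv)
    })
    names(fields) <- meta$muscles
    list(mesh = mesh, fields = fields, events = ev, amplitudes = amps,
         seed = (meta$seed + s * 7919) %% 2147483647)
  })
  scale <- unlist(meta$intensity_scale)
  structure(list(template = template, fields = subjects[[1]]$fields,
                 design = design, subjects = subjects,
                 intensity_scale = scale,
                 amplitude_noise_uv = meta$amplitude_noise_uv,
                 ground_truth = gt, seed = meta$seed),
            class = "tms_cohort")
}
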