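# evaluate `code` under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE))
        rm(".Random.seed", envir = genv)
    } else assign(".Random.seed", old, envir = genv)
  })
  set.seed(seed)
  force(code)
}

#' Experiment design parameters
#'
#' The stimulation schedule of a mapping session: `n_intensities` stimulation
#' intensity conditions, delivered in blocks of `stims_per_block` pulses,
#' with the whole set of blocks repeated `n_repetitions` times. Defaults
#' reproduce the standard protocol of 3 intensities x 120 stimulations x 2
#' repetitions = 720 pulses, 5 s apart, pseudo-randomly positioned over a
#' 5 x 5 cm grid around the hotspot.
#'
#' @param n_intensities number of intensity conditions.
#' @param stims_per_block stimulations per intensity block.
#' @param n_repetitions number of repetitions of the full block set.
#' @param inter_stimulus_s inter-stimulus interval (seconds).
#' @param grid_extent_mm side length of the square coil-positioning grid (mm).
#' @param intensity_labels optional condition labels (length
#'   `n_intensities`); defaults to `105%-RMT-{FDI,EDC,FCR}` for three
#'   conditions.
#' @return a list of class `experiment_design`.
#' @export
experiment_design <- function(n_intensities = 3, stims_per_block = 120,
                              n_repetitions = 2, inter_stimulus_s = 5,
                              grid_extent_mm = 50, intensity_labels = NULL) {
  counts <- c(n_intensities, stims_per_block, n_repetitions)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("invalid design: all counts must be positive integers")
  if (inter_stimulus_s <= 0) stop("invalid design: inter_stimulus_s must be > 0")
  if (grid_extent_mm <= 0) stop("invalid design: grid_extent_mm must be > 0")
  if (is.null(intensity_labels)) {
    intensity_labels <- if (n_intensities == 3)
      paste0("105%-RMT-", c("FDI", "EDC", "FCR")) else
        paste0("intensity-", seq_len(n_intensities))
  }
  if (length(intensity_labels) != n_intensities)
    stop("need one label per intensity condition")
  structure(list(n_intensities = as.integer(n_intensities),
                 stims_per_block = as.integer(stims_per_block),
                 n_repetitions = as.integer(n_repetitions),
                 inter_stimulus_s = inter_stimulus_s,
                 grid_extent_mm = grid_extent_mm,
                 intensity_labels = intensity_labels),
            class = "experiment_design")
}

#' Generate a stimulation schedule
#'
#' Draws the pseudo-random coil positions of a full mapping session: for each
#' repetition and each intensity block, `stims_per_block` pulses uniformly
#' distributed over a `grid_extent_mm` square centred on the hotspot, with
#' timestamps spaced by the inter-stimulus interval. Coil orientation is a
#' fixed downward normal (orientation is registered but not used by the
#' analysis).
#'
#' @param design an [experiment_design()].
#' @param hotspot 3-vector (common grid centre), or an `n_intensities` x 3
#'   matrix of per-condition grid centres (each intensity block is centred on
#'   the hotspot of its reference muscle).
#' @param seed RNG seed (reproducible schedules).
#' @return data.frame with columns `event_id`, `repetition`, `block`,
#'   `intensity_condition`, `time_s`, `x_mm`, `y_mm`, `z_mm`, `ox`, `oy`,
#'   `oz`.
#' @export
design_experiment <- function(design, hotspot = c(0, 0, 0), seed = 1) {
  stopifnot(inherits(design, "experiment_design"))
  n <- design$n_intensities * design$stims_per_block * design$n_repetitions
  hs <- if (is.matrix(hotspot)) hotspot else
    matrix(hotspot, nrow = design$n_intensities, ncol = 3, byrow = TRUE)
  if (!all(dim(hs) == c(design$n_intensities, 3L)))
    stop("hotspot must be a 3-vector or an n_intensities x 3 matrix")
  with_seed(seed, {
    half <- design$grid_extent_mm / 2
    block <- rep(rep(seq_len(design$n_intensities),
                     each = design$stims_per_block),
                 times = design$n_repetitions)
    data.frame(
      event_id = seq_len(n),
      repetition = rep(seq_len(design$n_repetitions),
                       each = design$n_intensities * design$stims_per_block),
      block = block,
      intensity_condition = design$intensity_labels[block],
      time_s = (seq_len(n) - 1) * design$inter_stimulus_s,
      x_mm = hs[block, 1] + runif(n, -half, half),
      y_mm = hs[block, 2] + runif(n, -half, half),
      z_mm = hs[block, 3],
      ox = 0, oy = 0, oz = -1,
      stringsAsFactors = FALSE
    )
  })
}

#' Flat rectangular patch mesh
#'
#' Planar test surface: an `nx` x `ny` vertex grid with spacing `spacing_mm`,
#' centred on the origin in the z = 0 plane, triangulated into
#' `2(nx-1)(ny-1)` triangles. Curvature is zero everywhere. Vertices whose
#' `|y|` lies within `region_halfwidth_mm` are labelled `region` (a synthetic
#' precentral-gyrus band, so that M1 masking is exercised); the rest are
#' `"other"`. A synthetic unit-sphere registration (azimuthal mapping of the
#' patch onto a polar cap) is attached so the patch can serve in warping
#' tests.
#'
#' @param nx,ny grid dimensions (>= 2).
#' @param spacing_mm grid spacing (mm, > 0).
#' @param region band label, default `"precentral L"`.
#' @param region_halfwidth_mm half-width of the labelled band; `Inf` labels
#'   the whole patch.
#' @param cap_angle maximal polar angle (radians) of the sphere-registration
#'   cap.
#' @return a [tri_surface].
#' @export
make_flat_patch_mesh <- function(nx, ny, spacing_mm,
                                 region = "precentral L",
                                 region_halfwidth_mm = Inf,
                                 cap_angle = 0.4) {
  if (nx < 2 || ny < 2) stop("degenerate grid: nx and ny must be >= 2")
  if (spacing_mm <= 0) stop("degenerate grid: spacing_mm must be > 0")
  xs <- (seq_len(nx) - 1 - (nx - 1) / 2) * spacing_mm
  ys <- (seq_len(ny) - 1 - (ny - 1) / 2) * spacing_mm
  v <- cbind(rep(xs, times = ny), rep(ys, each = nx), 0)
  idx <- function(i, j) (j - 1L) * nx + i
  i <- rep(seq_len(nx - 1), times = ny - 1)
  j <- rep(seq_len(ny - 1), each = nx - 1)
  f <- rbind(cbind(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
             cbind(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1)))
  labels <- ifelse(abs(v[, 2]) <= region_halfwidth_mm, region, "other")
  r <- sqrt(v[, 1]^2 + v[, 2]^2)
  rmax <- max(r)
  theta <- if (rmax > 0) r / rmax * cap_angle else rep(0, length(r))
  phi <- atan2(v[, 2], v[, 1])
  sphere <- cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
  tri_surface(v, f, curvature = rep(0, nrow(v)), atlas_labels = labels,
              sphere = sphere)
}

#' Hemispheric test mesh
#'
#' Octahedron-based triangulation of the upper hemisphere of a sphere of
#' radius `radius_mm`: each subdivision splits every triangle into four and
#' re-projects new vertices onto the sphere, so the equator stays exact.
#' The analytic curvature `1/radius` is stored per vertex and the radial
#' projection provides the unit-sphere registration. Vertices with polar
#' angle inside `region_theta` (radians from the pole) are labelled
#' `region`, the rest `"other"`.
#'
#' @param n_subdiv number of subdivision levels (>= 0).
#' @param radius_mm sphere radius (mm).
#' @param region band label.
#' @param region_theta two-element polar-angle band defining the region;
#'   default covers the whole hemisphere.
#' @return a [tri_surface].
#' @export
make_hemisphere_mesh <- function(n_subdiv, radius_mm,
                                 region = "precentral L",
                                 region_theta = c(0, pi)) {
  if (n_subdiv < 0) stop("n_subdiv must be >= 0")
  v <- rbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0), c(0, -1, 0))
  f <- rbind(c(1, 2, 3), c(1, 3, 4), c(1, 4, 5), c(1, 5, 2))
  if (n_subdiv > 0) {
    for (lev in seq_len(n_subdiv)) {
      midkey <- new.env(hash = TRUE)
      vlist <- lapply(seq_len(nrow(v)), function(i) v[i, ])
      midpoint <- function(i, j) {
        key <- paste(min(i, j), max(i, j))
        hit <- mget(key, envir = midkey, ifnotfound = list(NULL))[[1]]
        if (!is.null(hit)) return(hit)
        m <- (vlist[[i]] + vlist[[j]]) / 2
        m <- m / sqrt(sum(m^2))
        vlist[[length(vlist) + 1L]] <<- m
        assign(key, length(vlist), envir = midkey)
        length(vlist)
      }
      newf <- matrix(0L, nrow = 4L * nrow(f), ncol = 3L)
      for (k in seq_len(nrow(f))) {
        a <- f[k, 1]; b <- f[k, 2]; cc <- f[k, 3]
        ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
        newf[4L * k - 3L, ] <- c(a, ab, ca)
        newf[4L * k - 2L, ] <- c(ab, b, bc)
        newf[4L * k - 1L, ] <- c(ca, bc, cc)
        newf[4L * k, ] <- c(ab, bc, ca)
      }
      v <- do.call(rbind, vlist)
      f <- newf
    }
  }
  theta <- acos(pmin(pmax(v[, 3], -1), 1))
  labels <- ifelse(theta >= region_theta[1] & theta <= region_theta[2],
                   region, "other")
  tri_surface(v * radius_mm, f, curvature = rep(1 / radius_mm, nrow(v)),
              atlas_labels = labels, sphere = v)
}

#' Ground-truth excitability field
#'
#' Isotropic Gaussian excitability blob of one muscle: amplitude
#' `peak * exp(-||p - center||^2 / (2 sigma^2))` at point `p`.
#'
#' @param muscle_label one of [muscle_labels()].
#' @param center 3-vector, field centre (mm; should lie on the target mesh).
#' @param sigma_mm spatial spread (mm, > 0).
#' @param peak_uv peak MEP amplitude at the centre (microvolts, > 0).
#' @return a list of class `gt_field`.
#' @export
gt_field <- function(muscle_label, center, sigma_mm, peak_uv) {
  if (!muscle_label %in% muscle_labels())
    stop("unknown muscle label: ", muscle_label)
  if (sigma_mm <= 0) stop("sigma_mm must be > 0")
  if (peak_uv <= 0) stop("peak_uv must be > 0")
  structure(list(muscle_label = muscle_label, center = as.numeric(center),
                 sigma_mm = sigma_mm, peak_uv = peak_uv),
            class = "gt_field")
}

# noiseless field value at one or more points (rows of a matrix)
field_value <- function(field, points) {
  points <- rbind(points)
  dimnames(points) <- NULL
  d2 <- (points[, 1] - field$center[1])^2 + (points[, 2] - field$center[2])^2 +
    (points[, 3] - field$center[3])^2
  field$peak_uv * exp(-d2 / (2 * field$sigma_mm^2))
}

#' Sample a ground-truth field at a point
#'
#' Noiseless Gaussian field value plus optional additive Gaussian noise,
#' clipped at zero (amplitudes are non-negative).
#'
#' @param field a [gt_field()].
#' @param point 3-vector (mm).
#' @param noise_sd additive noise SD (microvolts, >= 0).
#' @param seed optional RNG seed.
#' @return amplitude in microvolts.
#' @export
sample_field_amplitude <- function(field, point, noise_sd = 0, seed = NULL) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  base <- field_value(field, point)
  if (noise_sd == 0) return(base)
  with_seed(seed, pmax(0, base + rnorm(length(base), 0, noise_sd)))
}

#' Synthesise a stimulation-locked EMG trace
#'
#' Gaussian baseline noise plus, when `mep_amplitude_uv > 0`, a biphasic
#' Gabor-like wavelet (a Gaussian-windowed odd lobe pair) centred
#' `latency_ms` after the stimulus whose peak-to-peak amplitude equals
#' `mep_amplitude_uv` (within 1% at 2 kHz sampling).
#'
#' @param mep_amplitude_uv injected MEP peak-to-peak amplitude (microvolts;
#'   0 injects nothing).
#' @param latency_ms wavelet centre relative to the stimulus (ms).
#' @param baseline_sd_uv SD of the additive Gaussian noise (microvolts).
#' @param rate_hz sampling rate.
#' @param t0_ms time of the first sample relative to the stimulus (ms).
#' @param duration_ms total trace duration (ms); must cover the wavelet.
#' @param tau_ms wavelet time constant (ms); extrema sit at `latency +/- tau`.
#' @param seed optional RNG seed.
#' @return an [emg_trace].
#' @export
synth_emg <- function(mep_amplitude_uv, latency_ms = 20, baseline_sd_uv = 5,
                      rate_hz = 2000, t0_ms = -250, duration_ms = 450,
                      tau_ms = 3, seed = NULL) {
  n <- round(duration_ms / 1000 * rate_hz)
  if (n < 2) stop("trace too short")
  t_ms <- t0_ms + (seq_len(n) - 1) / rate_hz * 1000
  if (mep_amplitude_uv > 0 &&
      (latency_ms - 3 * tau_ms < t_ms[1] || latency_ms + 3 * tau_ms > t_ms[n]))
    stop("MEP latency outside the trace")
  with_seed(seed, {
    x <- rnorm(n, 0, baseline_sd_uv)
    if (mep_amplitude_uv > 0) {
      u <- (t_ms - latency_ms) / tau_ms
      # u * exp(-u^2/2) has extrema +/- exp(-1/2) at u = +/- 1
      x <- x + mep_amplitude_uv / (2 * exp(-0.5)) * u * exp(-u^2 / 2)
    }
    emg_trace(x, rate_hz, t0_ms / 1000)
  })
}

#' Default ground-truth fields for the eight muscles
#'
#' Hand-muscle fields are placed lateral (negative x), forearm fields medial
#' (positive x), along the synthetic precentral band of the template patch,
#' 4 mm apart, with a common spatial spread and muscle-specific peaks (FDI
#' largest). Spacing and spread give neighbouring representations a
#' substantial half-maximum-disc overlap and distant ones none.
#'
#' @param sigma_mm common field spread (mm).
#' @return named list of eight [gt_field()]s.
#' @export
default_fields <- function(sigma_mm = 6) {
  xs <- c(FDI = -15, ADM = -11, FPB = -7, APB = -3,
          EDC = 3, FDS = 7, ECR = 11, FCR = 15)
  peaks <- c(FDI = 800, ADM = 500, FPB = 600, APB = 650,
             EDC = 550, FDS = 500, ECR = 450, FCR = 400)
  fields <- lapply(muscle_labels(), function(m)
    gt_field(m, c(xs[[m]], 0, 0), sigma_mm, peaks[[m]]))
  names(fields) <- muscle_labels()
  fields
}

#' Analytic Jaccard overlap of two discs
#'
#' Intersection-over-union of two planar discs of radii `r1`, `r2` with
#' centre distance `d` (circular-lens formula); the analytic ground truth for
#' half-maximum-disc overlaps of Gaussian fields on a flat patch.
#'
#' @param d centre distance.
#' @param r1,r2 disc radii.
#' @return overlap in `[0, 1]`.
#' @export
disc_jaccard <- function(d, r1, r2) {
  a1 <- pi * r1^2; a2 <- pi * r2^2
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) {
    inter <- pi * min(r1, r2)^2
  } else {
    inter <- r1^2 * acos((d^2 + r1^2 - r2^2) / (2 * d * r1)) +
      r2^2 * acos((d^2 + r2^2 - r1^2) / (2 * d * r2)) -
      0.5 * sqrt((-d + r1 + r2) * (d + r1 - r2) * (d - r1 + r2) *
                   (d + r1 + r2))
  }
  inter / (a1 + a2 - inter)
}

# deterministic per-trial seed, kept below 2^31
trial_seed <- function(seed, subject, event, muscle_idx) {
  (seed + subject * 1000003 + event * 8191 + muscle_idx * 131) %% 2147483647
}

#' Generate a synthetic cohort with known ground truth
#'
#' Builds a full synthetic mapping study: a template surface, per-subject
#' perturbed meshes (vertex jitter, shared sphere registration and labels),
#' per-subject excitability fields with tangentially jittered centres,
#' complete stimulation schedules, and per-trial MEP amplitudes (intensity
#' conditions scale the field peaks). EMG traces are generated on demand by
#' [cohort_trace()] with deterministic per-trial seeds. Ground truth
#' (per-subject field centres, peaks, and analytic half-maximum-disc pair
#' overlaps) is recorded for recovery tests.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param template template [tri_surface]; default a 41 x 41 flat patch at
#'   2 mm spacing with a 30 mm wide precentral band.
#' @param fields named list of [gt_field()]s (template-space ground truth).
#' @param design an [experiment_design()].
#' @param jitter_mm SD of the tangential Gaussian jitter of per-subject field
#'   centres (mm).
#' @param mesh_noise_mm SD of per-subject vertex position noise (mm).
#' @param amplitude_noise_uv SD of the additive per-trial amplitude noise
#'   (microvolts).
#' @param intensity_scale named or unnamed numeric vector, one multiplicative
#'   peak scaling per intensity condition.
#' @param hotspot_rule `"per-condition"` centres each intensity block's coil
#'   grid on the reference muscle of that condition's label
#'   (`105%-RMT-X` -> muscle X); `"shared"` centres all blocks on the first
#'   muscle's hotspot.
#' @param seed RNG seed.
#' @return a list of class `tms_cohort` with elements `template`, `fields`,
#'   `design`, `subjects` (each with `mesh`, `fields`, `events`,
#'   `amplitudes` [events x muscles], `seed`), `ground_truth` (`centers`,
#'   `overlaps`), and `seed`.
#' @export
make_cohort <- function(n_subjects = 20,
                        template = make_flat_patch_mesh(41, 41, 2,
                                                        region_halfwidth_mm = 15),
                        fields = default_fields(),
                        design = experiment_design(),
                        jitter_mm = 2, mesh_noise_mm = 0.2,
                        amplitude_noise_uv = 20,
                        intensity_scale = NULL,
                        hotspot_rule = c("per-condition", "shared", "center"),
                        seed = 1) {
  hotspot_rule <- match.arg(hotspot_rule)
  if (n_subjects < 2) stop("n_subjects must be >= 2")
  if (is.null(intensity_scale))
    intensity_scale <- seq(1, by = 0.15,
                           length.out = design$n_intensities)
  if (length(intensity_scale) != design$n_intensities)
    stop("need one intensity_scale per intensity condition")
  names(intensity_scale) <- design$intensity_labels
  muscles <- names(fields)
  subjects <- vector("list", n_subjects)
  centers <- NULL
  for (s in seq_len(n_subjects)) {
    sseed <- (seed + s * 7919) %% 2147483647
    subj <- with_seed(sseed, {
      mesh <- template
      if (mesh_noise_mm > 0)
        mesh$vertices <- mesh$vertices +
          matrix(rnorm(length(mesh$vertices), 0, mesh_noise_mm),
                 ncol = 3)
      sfields <- lapply(fields, function(f) {
        if (jitter_mm > 0)
          f$center <- f$center + c(rnorm(2, 0, jitter_mm), 0)
        f
      })
      hotspots <- t(condition_hotspots(sfields, design, hotspot_rule))
      events <- design_experiment(design, hotspot = hotspots,
                                  seed = (sseed + 17) %% 2147483647)
      pts <- as.matrix(events[, c("x_mm", "y_mm", "z_mm")])
      scale <- intensity_scale[events$intensity_condition]
      amps <- vapply(sfields, function(f) {
        a <- scale * field_value(f, pts)
        if (amplitude_noise_uv > 0)
          a <- pmax(0, a + rnorm(length(a), 0, amplitude_noise_uv))
        a
      }, numeric(nrow(events)))
      colnames(amps) <- muscles
      list(mesh = mesh, fields = sfields, events = events,
           amplitudes = amps, seed = sseed)
    })
    subjects[[s]] <- subj
    centers <- rbind(centers, data.frame(
      subject = s, muscle = muscles,
      cx = vapply(subj$fields, function(f) f$center[1], 0),
      cy = vapply(subj$fields, function(f) f$center[2], 0),
      cz = vapply(subj$fields, function(f) f$center[3], 0),
      sigma_mm = vapply(subj$fields, function(f) f$sigma_mm, 0),
      peak_uv = vapply(subj$fields, function(f) f$peak_uv, 0),
      row.names = NULL))
  }
  pairs <- utils::combn(muscles, 2)
  overlaps <- do.call(rbind, lapply(seq_len(n_subjects), function(s) {
    sf <- subjects[[s]]$fields
    data.frame(
      subject = s, muscle_k = pairs[1, ], muscle_l = pairs[2, ],
      overlap = vapply(seq_len(ncol(pairs)), function(j) {
        f1 <- sf[[pairs[1, j]]]; f2 <- sf[[pairs[2, j]]]
        disc_jaccard(sqrt(sum((f1$center - f2$center)^2)),
                     f1$sigma_mm * sqrt(2 * log(2)),
                     f2$sigma_mm * sqrt(2 * log(2)))
      }, 0),
      row.names = NULL)
  }))
  structure(list(template = template, fields = fields, design = design,
                 subjects = subjects,
                 intensity_scale = intensity_scale,
                 amplitude_noise_uv = amplitude_noise_uv,
                 ground_truth = list(centers = centers, overlaps = overlaps),
                 seed = seed),
            class = "tms_cohort")
}

#' @export
print.tms_cohort <- function(x, ...) {
  cat("tms_cohort:", length(x$subjects), "subjects,",
      length(x$fields), "muscles,",
      nrow(x$subjects[[1]]$events), "events/subject\n")
  invisible(x)
}

#' Regenerate the EMG trace of one trial
#'
#' Traces are not materialised by [make_cohort()] (a full cohort holds
#' hundreds of thousands of them); this reconstructs any single trial's trace
#' deterministically from the cohort seed.
#'
#' @param cohort a `tms_cohort`.
#' @param subject subject index.
#' @param event event index (row of the subject's event table).
#' @param muscle muscle label or column index.
#' @param ... passed to [synth_emg()] (latency, rate, windows).
#' @return an [emg_trace].
#' @export
cohort_trace <- function(cohort, subject, event, muscle, ...) {
  subj <- cohort$subjects[[subject]]
  mi <- if (is.character(muscle)) match(muscle, colnames(subj$amplitudes))
  else as.integer(muscle)
  if (is.na(mi)) stop("unknown muscle: ", muscle)
  amp <- subj$amplitudes[event, mi]
  synth_emg(amp, seed = trial_seed(cohort$seed, subject, event, mi), ...)
}
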