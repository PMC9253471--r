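#' Fiber bundle specification
#'
#' Describes one synthetic white-matter bundle as a polyline centerline in
#' world mm with parallel streamlines scattered transversally around it.
#'
#' @param centerline Numeric k x 3 matrix (k >= 2) of world-mm points.
#' @param n_streamlines Number of streamlines in the bundle (>= 1).
#' @param radial_spread SD (mm) of the transverse offset of each streamline
#'   from the centerline (>= 0).
#' @param step Spacing (mm) between consecutive points along each
#'   streamline (> 0).
#' @return A `bundle_spec` object.
#' @export
bundle_spec <- function(centerline, n_streamlines = 20L, radial_spread = 0.5,
                        step = 0.5) {
  centerline <- matrix(as.numeric(centerline), ncol = 3L)
  if (nrow(centerline) < 2L) stop("centerline needs >= 2 points")
  if (n_streamlines < 1L) stop("`n_streamlines` must be >= 1")
  if (radial_spread < 0) stop("`radial_spread` must be >= 0")
  if (step <= 0) stop("`step` must be > 0")
  structure(list(centerline = centerline,
                 n_streamlines = as.integer(n_streamlines),
                 radial_spread = radial_spread, step = step),
            class = "bundle_spec")
}

# two unit vectors spanning the plane transverse to the bundle's overall
# direction
transverse_basis <- function(centerline) {
  d <- centerline[nrow(centerline), ] - centerline[1, ]
  d <- d / sqrt(sum(d^2))
  ref <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * d) * d
  u <- u / sqrt(sum(u^2))
  v <- c(d[2] * u[3] - d[3] * u[2],
         d[3] * u[1] - d[1] * u[3],
         d[1] * u[2] - d[2] * u[1])
  rbind(u, v)
}

#' Generate normative control tractograms
#'
#' Emulates a set of healthy-control whole-brain streamline reconstructions
#' sharing one bundle geometry. Per-bundle transverse streamline offsets are
#' drawn once (so the bundle population is the same anatomy in every
#' control), and each control receives an independent rigid translation
#' jitter standing in for residual inter-individual/registration
#' variability. With `jitter = 0` all controls are identical.
#'
#' @param grid A [template_grid()]; all centerlines must lie inside its
#'   world bounds.
#' @param bundles List of [bundle_spec()] objects.
#' @param n_controls Number of controls (>= 1).
#' @param jitter SD (mm) of the per-control rigid translation (>= 0).
#' @param seed Integer seed; identical inputs give identical output.
#' @return List of `n_controls` [tractogram()] objects.
#' @export
generate_controls <- function(grid, bundles, n_controls = 10L, jitter = 0,
                              seed = 1L) {
  if (n_controls < 1L) stop("`n_controls` must be >= 1")
  if (jitter < 0) stop("`jitter` must be >= 0")
  if (inherits(bundles, "bundle_spec")) bundles <- list(bundles)
  bounds <- grid_world_bounds(grid)
  for (b in bundles) {
    cl <- b$centerline
    if (any(cl < matrix(bounds[1, ], nrow(cl), 3, byrow = TRUE)) ||
        any(cl > matrix(bounds[2, ], nrow(cl), 3, byrow = TRUE)))
      stop("bundle centerline exits the grid world bounds")
  }
  set.seed(seed)
  # fixed per-bundle anatomy: transverse offsets per streamline
  offsets <- lapply(bundles, function(b) {
    tb <- transverse_basis(b$centerline)
    o <- matrix(stats::rnorm(2L * b$n_streamlines, 0, b$radial_spread),
                ncol = 2L)
    o %*% tb
  })
  lapply(seq_len(n_controls), function(ci) {
    shift <- if (jitter > 0) stats::rnorm(3L, 0, jitter) else c(0, 0, 0)
    streams <- list()
    for (bi in seq_along(bundles)) {
      b <- bundles[[bi]]
      base <- unclass(resample_streamline(streamline(b$centerline), b$step))
      for (si in seq_len(b$n_streamlines)) {
        off <- offsets[[bi]][si, ] + shift
        streams[[length(streams) + 1L]] <-
          sweep(base, 2L, off, "+")
      }
    }
    tractogram(streams, space = "template")
  })
}

#' Generate a spherical lesion mask
#'
#' A voxel belongs to the lesion iff its centre lies within `radius` mm of
#' `center` (non-strict); this membership rule is orientation-free and
#' unambiguous on any grid.
#'
#' @param grid A [template_grid()].
#' @param center World-mm triple inside the grid bounds.
#' @param radius Sphere radius in mm (> 0).
#' @return Binary 3-D array (`integer`, 0/1) on `grid`.
#' @export
generate_lesion <- function(grid, center, radius) {
  if (radius <= 0) stop("`radius` must be > 0")
  bounds <- grid_world_bounds(grid)
  if (any(center < bounds[1, ]) || any(center > bounds[2, ]))
    stop("lesion `center` is outside the grid world bounds")
  # bounding box of candidate voxels, then exact centre-in-sphere test
  ijk0 <- world_to_voxel(grid, matrix(center - radius - max(grid$voxel_size),
                                      1L))
  ijk1 <- world_to_voxel(grid, matrix(center + radius + max(grid$voxel_size),
                                      1L))
  lo <- pmax(ijk0[1, ], 0L); hi <- pmin(ijk1[1, ], grid$shape - 1L)
  cand <- as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]))
  w <- voxel_to_world(grid, cand)
  d2 <- (w[, 1] - center[1])^2 + (w[, 2] - center[2])^2 +
    (w[, 3] - center[3])^2
  inside <- d2 <= radius^2 + 1e-12
  if (!any(inside))
    stop("lesion sphere contains no voxel centres (empty mask)")
  mask <- empty_volume(grid)
  mask[grid_linear_index(grid, cand[inside, , drop = FALSE])] <- 1
  storage.mode(mask) <- "integer"
  mask
}

#' Cohort simulation configuration
#'
#' Defaults plant the fixed-effect structure reported for the standardized
#' GD mixed model: NfL slope +0.03, follow-up (timepoint) shift -0.04,
#' NfL-by-timepoint interaction -0.01, center intercept shifts
#' (Barcelona reference) Oslo -0.29, Berlin -0.41, Genoa +0.44, a
#' subject-level random-intercept SD of 0.92 and a small residual SD so the
#' total variance of the standardized response is close to 1.
#'
#' @param n_subjects Number of subjects.
#' @param n_centers Number of centers (default 4, named
#'   Barcelona/Oslo/Berlin/Genoa; other counts get generic names).
#' @param timepoints Number of visits (1 or 2).
#' @param beta_nfl_gd Standardized effect of serum NfL on GD.
#' @param beta_time Timepoint (0/1) effect.
#' @param beta_interaction NfL x timepoint effect.
#' @param center_shifts Per-center fixed intercept offsets (length
#'   `n_centers`, first entry the reference, conventionally 0).
#' @param subject_sd,center_sd,noise_sd Random-intercept and residual SDs
#'   (>= 0). `center_sd > 0` adds a random center intercept on top of the
#'   fixed shifts (for the random-center model variant).
#' @param outlier_rate Fraction of records given a grossly inflated NfL
#'   value (to exercise the outlier rule); default 0.
#' @param seed Integer seed (mandatory; the generator is a pure function of
#'   config and seed).
#' @return A `cohort_sim_config` object (validated list).
#' @export
cohort_sim_config <- function(n_subjects = 300L, n_centers = 4L,
                              timepoints = 2L,
                              beta_nfl_gd = 0.03, beta_time = -0.04,
                              beta_interaction = -0.01,
                              center_shifts = c(0, -0.29, -0.41, 0.44),
                              subject_sd = 0.92, center_sd = 0,
                              noise_sd = 0.05, outlier_rate = 0,
                              seed = 1L) {
  if (any(c(subject_sd, center_sd, noise_sd) < 0))
    stop("all SDs must be >= 0")
  if (n_centers < 1L) stop("`n_centers` must be >= 1")
  if (timepoints < 1L) stop("`timepoints` must be >= 1")
  if (timepoints > 2L)
    stop("only 1 or 2 timepoints are supported (baseline / follow-up design)")
  if (length(center_shifts) != n_centers)
    stop("`center_shifts` must have one entry per center")
  if (is.null(seed) || is.na(seed)) stop("`seed` is mandatory")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_centers = as.integer(n_centers),
                 timepoints = as.integer(timepoints),
                 beta_nfl_gd = beta_nfl_gd, beta_time = beta_time,
                 beta_interaction = beta_interaction,
                 center_shifts = as.numeric(center_shifts),
                 subject_sd = subject_sd, center_sd = center_sd,
                 noise_sd = noise_sd, outlier_rate = outlier_rate,
                 seed = as.integer(seed)),
            class = "cohort_sim_config")
}

center_names <- function(n) {
  if (n == 4L) c("Barcelona", "Oslo", "Berlin", "Genoa")
  else paste0("Center", seq_len(n))
}

edss_grid <- seq(0, 10, by = 0.5)

#' Generate a longitudinal multicenter cohort
#'
#' Simulates a two-visit multicenter MS-like cohort: demographics and
#' treatment/phenotype frequencies follow the study-population margins
#' (71% female, mean age 42.9 (SD 9.9), disease duration mean 11 (SD 8.2),
#' phenotypes CIS/RRMS/PMS at 1.6/81.4/17%, treatment none/effective/
#' highly-effective at 30/44/26%, centers at 18/30/22/28%), serum NfL is
#' right-skewed lognormal (mean ~8.9, SD ~7 pg/ml) with optional injected
#' outliers, and the standardized GD response follows
#' `y = b0 + b_nfl z(NfL) + b_t t + b_int z(NfL) t + center shift +
#' b_subject + b_center + eps` with the configured SDs. T2LV is a lognormal
#' monotone transform of the subject intercept (mean ~8.5, SD ~11 ml), which
#' induces a strong, slightly curved GD-T2LV association. EDSS trajectories
#' mix improving/stable/worsening cases (roughly 19/65/16%).
#'
#' @param cfg A [cohort_sim_config()].
#' @param grid Optional [template_grid()]; if supplied (with `controls`),
#'   per-subject-visit spherical lesion masks are generated inside the
#'   central region of the grid, with radius increasing with disease
#'   severity (the subject intercept).
#' @param controls Optional list of control [tractogram()]s (used only to
#'   anchor lesion placement near the bundle corridors via their bounding
#'   box).
#' @return A list with `cohort` (data.frame, one row per subject-visit:
#'   subject_id, center, timepoint, age, sex, disease_duration, phenotype,
#'   treatment, snfl, edss, gd, t2lv) and `lesions` (named list of binary
#'   masks keyed `subjectID_timepoint`, or NULL when no grid is given).
#' @export
generate_cohort <- function(cfg, grid = NULL, controls = NULL) {
  stopifnot(inherits(cfg, "cohort_sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_subjects
  cn <- center_names(cfg$n_centers)
  cprob <- if (cfg$n_centers == 4L) c(0.18, 0.30, 0.22, 0.28)
           else rep(1 / cfg$n_centers, cfg$n_centers)
  center <- sample(cn, n, replace = TRUE, prob = cprob)
  age <- pmin(pmax(round(stats::rnorm(n, 42.9, 9.9)), 19), 68)
  sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.705, 0.295))
  duration <- round(pmin(pmax(stats::rnorm(n, 11, 8.2), 0), 43), 1)
  phenotype <- sample(c("CIS", "RRMS", "PMS"), n, replace = TRUE,
                      prob = c(0.016, 0.814, 0.17))
  treatment <- sample(c("none", "effective", "highly-effective"), n,
                      replace = TRUE, prob = c(0.30, 0.44, 0.26))
  b_subject <- stats::rnorm(n, 0, cfg$subject_sd)
  b_center <- if (cfg$center_sd > 0) stats::rnorm(cfg$n_centers, 0,
                                                  cfg$center_sd)
              else rep(0, cfg$n_centers)

  # serum NfL, right-skewed; follow-up correlated with baseline
  sdlog <- sqrt(log(1 + (7.0 / 8.9)^2))
  meanlog <- log(8.9) - sdlog^2 / 2
  nfl0 <- stats::rlnorm(n, meanlog, sdlog)
  nfl1 <- nfl0 * exp(stats::rnorm(n, -0.02, 0.25))
  n_out <- stats::rbinom(1L, n * cfg$timepoints, cfg$outlier_rate)
  # EDSS: baseline from the clinical grid, then a labelled trajectory
  eb <- sample(edss_grid[1:17], n, replace = TRUE,
               prob = stats::dlnorm(seq_along(edss_grid[1:17]), log(5), 0.6))
  traj <- sample(c("improving", "stable", "worsening"), n, replace = TRUE,
                 prob = c(0.19, 0.65, 0.16))
  delta <- numeric(n)
  delta[traj == "improving"] <- sample(c(-1, -1.5), sum(traj == "improving"),
                                       TRUE, prob = c(0.8, 0.2))
  delta[traj == "stable"] <- sample(c(-0.5, 0, 0.5), sum(traj == "stable"),
                                    TRUE, prob = c(0.2, 0.6, 0.2))
  delta[traj == "worsening"] <- sample(c(1, 1.5), sum(traj == "worsening"),
                                       TRUE, prob = c(0.8, 0.2))
  ef <- pmin(pmax(eb + delta, 0), 10)

  tps <- c("baseline", "followup")[seq_len(cfg$timepoints)]
  rows <- expand.grid(subject = seq_len(n), timepoint = tps,
                      stringsAsFactors = FALSE)
  rows <- rows[order(rows$subject), ]
  tnum <- as.integer(rows$timepoint == "followup")
  snfl <- ifelse(tnum == 0L, nfl0[rows$subject], nfl1[rows$subject])
  if (n_out > 0L) {
    idx <- sample(length(snfl), n_out)
    snfl[idx] <- snfl[idx] * stats::runif(n_out, 5, 9)
  }
  nfl_z <- as.numeric(scale(snfl))
  ci <- match(center[rows$subject], cn)
  gd <- cfg$beta_nfl_gd * nfl_z + cfg$beta_time * tnum +
    cfg$beta_interaction * nfl_z * tnum +
    cfg$center_shifts[ci] + b_center[ci] + b_subject[rows$subject] +
    stats::rnorm(nrow(rows), 0, cfg$noise_sd)

  t2_sdlog <- sqrt(log(1 + (10.9 / 8.5)^2))
  t2_meanlog <- log(8.5) - t2_sdlog^2 / 2
  u <- stats::pnorm(b_subject, 0, max(cfg$subject_sd, 1e-8))
  t2lv0 <- stats::qlnorm(pmin(pmax(u, 1e-6), 1 - 1e-6), t2_meanlog, t2_sdlog)
  t2lv <- t2lv0[rows$subject] * exp(stats::rnorm(nrow(rows), 0, 0.05) +
                                    0.03 * tnum)

  cohort <- data.frame(
    subject_id = sprintf("S%03d", rows$subject),
    center = center[rows$subject],
    timepoint = rows$timepoint,
    age = age[rows$subject],
    sex = sex[rows$subject],
    disease_duration = duration[rows$subject],
    phenotype = phenotype[rows$subject],
    treatment = treatment[rows$subject],
    snfl = snfl,
    edss = ifelse(tnum == 0L, eb[rows$subject], ef[rows$subject]),
    gd = gd,
    t2lv = t2lv,
    stringsAsFactors = FALSE)

  lesions <- NULL
  if (!is.null(grid)) {
    bounds <- grid_world_bounds(grid)
    span <- bounds[2, ] - bounds[1, ]
    lo <- bounds[1, ] + 0.3 * span
    hi <- bounds[1, ] + 0.7 * span
    lesions <- list()
    for (r in seq_len(nrow(cohort))) {
      sev <- stats::pnorm(b_subject[rows$subject[r]], 0,
                          max(cfg$subject_sd, 1e-8))
      ctr <- lo + stats::runif(3) * (hi - lo)
      rad <- (1.2 + 2.5 * sev) * min(grid$voxel_size)
      lesions[[paste0(cohort$subject_id[r], "_", cohort$timepoint[r])]] <-
        generate_lesion(grid, ctr, rad)
    }
  }
  list(cohort = cohort, lesions = lesions)
}

#' Write / read a cohort table as TSV
#'
#' Column layout: subject_id, center, timepoint, age, sex, disease_duration,
#' phenotype, treatment, snfl, edss, gd, t2lv (gd/t2lv optional on read).
#'
#' @param cohort Cohort data.frame.
#' @param path TSV path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "center", "timepoint", "age", "sex",
            "disease_duration", "phenotype", "treatment", "snfl", "edss")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("cohort table is missing columns: ", paste(miss, collapse = ", "))
  df
}
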