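# Synthetic face-like mesh populations with known ground truth.
#
# The generator emulates the statistical structure of a large 3D facial scan
# cohort: an analytic face-like base surface (half-ellipsoid with nose ridge,
# eye depressions, brow ridge and mouth groove built from smooth bumps),
# Gaussian low-frequency shape modes, demographic groups with their own mean
# offsets and age distributions, capture noise, holes, independent
# re-triangulation of every raw scan, and rigid pose jitter. Because the
# surface and all displacement fields are analytic in the (x, y) face
# parameterization, every quantity a test needs — dense correspondence, true
# mode coefficients, landmark positions — is known exactly.

face_domain <- list(x = c(-80, 80), y = c(-96, 96))  # mm

# Height field of the neutral base face (mm), symmetric in x.
face_height <- function(x, y) {
  # cranial dome curved over the whole (expanded) domain: no flat regions,
  # so surface geometry constrains correspondence everywhere
  z <- 60 * sqrt(pmax(0.02, 1 - (x / 135)^2 - (y / 155)^2))
  z <- z + 16 * exp(-((x / 11)^2 + (y / 16)^2))                 # nose ridge/tip
  z <- z - 5 * exp(-(((x - 30) / 10)^2 + ((y - 36) / 8)^2))     # eye sockets
  z <- z - 5 * exp(-(((x + 30) / 10)^2 + ((y - 36) / 8)^2))
  z <- z + 3 * exp(-(((x - 30) / 14)^2 + ((y - 58) / 7)^2))     # brow ridges
  z <- z + 3 * exp(-(((x + 30) / 14)^2 + ((y - 58) / 7)^2))
  z - 3.5 * exp(-((x / 22)^2 + ((y + 48) / 7)^2))               # mouth groove
}

# Outward (+z biased) unit normal of the base surface, by central differences.
face_normal <- function(x, y, h = 1e-3) {
  hx <- (face_height(x + h, y) - face_height(x - h, y)) / (2 * h)
  hy <- (face_height(x, y + h) - face_height(x, y - h)) / (2 * h)
  n <- cbind(-hx, -hy, 1)
  n / sqrt(rowSums(n^2))
}

# Deterministic skin-like vertex colors: base tone, redder lips, darker brows.
face_colors <- function(x, y) {
  base <- cbind(0.80 + 0.05 * cos(pi * y / 192),
                0.60 + 0.04 * sin(pi * x / 160),
                rep(0.50, length(x)))
  lips <- exp(-((x / 22)^2 + ((y + 48) / 7)^2))
  base[, 1L] <- base[, 1L] + 0.1 * lips
  base[, 2L] <- base[, 2L] - 0.2 * lips
  base[, 3L] <- base[, 3L] - 0.15 * lips
  pmin(pmax(base, 0), 1)
}

# Named landmark sites in the (x, y) face parameterization: 13 primary
# anatomical points plus arcs over the jaw, brows, nose, eyes, mouth rim,
# cheeks and forehead — mirroring the density of the standard 68-point 2D
# facial annotation a landmark detector emits.
face_landmark_sites <- function() {
  primary <- rbind(
    nose_tip = c(0, 0), nose_bridge = c(0, 24), nasal_base = c(0, -24),
    chin = c(0, -72), mouth_center = c(0, -48),
    mouth_l = c(-20, -48), mouth_r = c(20, -48),
    eye_inner_l = c(-20, 36), eye_outer_l = c(-40, 36),
    eye_inner_r = c(20, 36), eye_outer_r = c(40, 36),
    brow_l = c(-30, 58), brow_r = c(30, 58))
  # ear-to-ear jawline arc, as in the standard 68-point annotation
  jaw_t <- seq(-1, 1, length.out = 9L)
  jaw <- cbind(64 * sin(jaw_t * pi / 2), -72 + 88 * (1 - cos(jaw_t * pi / 2)))
  rownames(jaw) <- sprintf("jaw_%d", seq_len(nrow(jaw)))
  brows <- rbind(brow_inner_l = c(-14, 56), brow_outer_l = c(-46, 54),
                 brow_inner_r = c(14, 56), brow_outer_r = c(46, 54))
  nose <- rbind(nose_side_l = c(-12, -12), nose_side_r = c(12, -12),
                nose_mid = c(0, 12))
  eyes <- rbind(eye_top_l = c(-30, 42), eye_bot_l = c(-30, 30),
                eye_top_r = c(30, 42), eye_bot_r = c(30, 30))
  mouth <- rbind(mouth_top = c(0, -40), mouth_bot = c(0, -56),
                 mouth_tl = c(-10, -42), mouth_tr = c(10, -42))
  cheeks <- rbind(cheek_l = c(-44, -8), cheek_r = c(44, -8),
                  cheek_low_l = c(-34, -34), cheek_low_r = c(34, -34))
  forehead <- rbind(forehead_c = c(0, 76), forehead_l = c(-32, 74),
                    forehead_r = c(32, 74))
  rbind(primary, jaw, brows, nose, eyes, mouth, cheeks, forehead)
}

# Regular parameter grid and its triangulation. `expand` > 1 widens the
# sampled domain: raw scans capture more surface than the template's face
# crop (as real captures include neck/ears), so template rim vertices find
# interior — not boundary — correspondences on the target.
face_grid <- function(n_side, expand = 1) {
  xs <- seq(face_domain$x[1L] * expand, face_domain$x[2L] * expand,
            length.out = n_side)
  ys <- seq(face_domain$y[1L] * expand, face_domain$y[2L] * expand,
            length.out = n_side)
  g <- expand.grid(x = xs, y = ys)  # x fastest
  idx <- function(i, j) (j - 1L) * n_side + i
  quads <- expand.grid(i = seq_len(n_side - 1L), j = seq_len(n_side - 1L))
  # winding chosen so triangle normals point towards +z (out of the face)
  tri <- rbind(
    cbind(idx(quads$i, quads$j), idx(quads$i + 1L, quads$j),
          idx(quads$i + 1L, quads$j + 1L)),
    cbind(idx(quads$i, quads$j), idx(quads$i + 1L, quads$j + 1L),
          idx(quads$i, quads$j + 1L)))
  list(params = as.matrix(g), trilist = tri, n_side = n_side)
}

#' Analytic face-like template mesh with named landmarks
#'
#' Builds the deformable template: a face-like height-field surface sampled
#' on a regular grid at subdivision level `resolution` (grid side
#' `8 * 2^resolution + 1`), with per-vertex skin-like colors and 13 named
#' landmark vertices (nose tip, eye corners, mouth corners, chin, brows...).
#' Fully deterministic.
#'
#' @param resolution non-negative integer subdivision level.
#' @return list with `mesh` (a `triangle_mesh`), `landmarks` (a
#'   [landmark_set()] with `template_indices`), and `params` (the `(x, y)`
#'   parameter of every vertex).
#' @export
make_template <- function(resolution = 1L) {
  if (resolution < 0) stop("make_template: resolution must be >= 0")
  g <- face_grid(8L * 2L^resolution + 1L)
  x <- g$params[, 1L]; y <- g$params[, 2L]
  pts <- cbind(x, y, face_height(x, y))
  mesh <- triangle_mesh(pts, g$trilist, colors = face_colors(x, y))
  sites <- face_landmark_sites()
  # snap each site to the nearest grid vertex
  idx <- vapply(seq_len(nrow(sites)), function(i)
    which.min((x - sites[i, 1L])^2 + (y - sites[i, 2L])^2), integer(1L))
  lms <- landmark_set(rownames(sites), pts[idx, , drop = FALSE],
                      template_indices = idx)
  list(mesh = mesh, landmarks = lms, params = g$params)
}

# Low-frequency analytic displacement fields: mode j displaces the surface
# along its normal with a distinct smooth pattern, normalized so a unit
# coefficient produces 1 mm RMS per-vertex displacement at the template
# resolution.
mode_patterns <- list(
  function(x, y) cos(pi * x / 160) * cos(pi * y / 192),
  function(x, y) sin(pi * x / 80) * cos(pi * y / 192),
  function(x, y) cos(pi * x / 160) * sin(pi * y / 96),
  function(x, y) sin(pi * x / 80) * sin(pi * y / 96),
  function(x, y) cos(3 * pi * x / 160) * cos(pi * y / 192),
  function(x, y) cos(pi * x / 160) * cos(3 * pi * y / 192),
  function(x, y) sin(3 * pi * x / 160) * sin(pi * y / 96),
  function(x, y) cos(3 * pi * x / 160) * sin(3 * pi * y / 192))

make_mode_fields <- function(n_modes, template_params) {
  if (n_modes > length(mode_patterns))
    stop("make_mode_fields: at most ", length(mode_patterns), " modes available")
  lapply(seq_len(n_modes), function(j) {
    pat <- mode_patterns[[j]]
    tx <- template_params[, 1L]; ty <- template_params[, 2L]
    d0 <- pat(tx, ty) * face_normal(tx, ty)
    scale <- 1 / sqrt(mean(rowSums(d0^2)))
    function(x, y) (pat(x, y) * face_normal(x, y)) * scale
  })
}

# Per-group mean-offset fields (same normalization convention as the modes).
make_offset_field <- function(group_index, template_params) {
  gi <- group_index
  pat <- function(x, y)
    cos(pi * x / 160 + 0.9 * gi) * cos(pi * y / 192 + 0.5 * gi) +
    0.5 * sin(pi * x / 80 - 0.4 * gi)
  tx <- template_params[, 1L]; ty <- template_params[, 2L]
  d0 <- pat(tx, ty) * face_normal(tx, ty)
  scale <- 1 / sqrt(mean(rowSums(d0^2)))
  function(x, y) (pat(x, y) * face_normal(x, y)) * scale
}

#' Specification of a synthetic study population
#'
#' Declares the conditions of a synthetic cohort: its size, template
#' resolution, the number and scale of Gaussian shape modes, the demographic
#' profile (group proportions, per-group mean-offset scales and age
#' distributions), capture noise, hole corruption, remeshing and rigid pose
#' jitter. One seed fixes every downstream draw.
#'
#' @param n_subjects cohort size.
#' @param resolution template subdivision level (see [make_template()]).
#' @param n_modes number of true shape modes.
#' @param mode_sd per-mode standard deviations (mm RMS per vertex).
#' @param demographics data frame with columns `ethnicity`, `proportion`
#'   (summing to 1), `offset_scale` (mm), `age_shape`, `age_scale`
#'   (gamma age distribution).
#' @param gender_split probability of "male".
#' @param noise_sd capture noise standard deviation (mm, per coordinate).
#' @param hole_probability per-subject probability of a punched hole.
#' @param hole_radius hole radius (mm).
#' @param remesh re-triangulate every raw scan on its own jittered parameter
#'   grid so target topologies genuinely differ from the template.
#' @param raw_resolution grid side of raw scans; default `1.25x` template.
#' @param jitter_angle_deg,jitter_translation rigid pose jitter ranges.
#' @param age_coupling mm of mode-1 displacement per year of age offset from
#'   40 (ties shape to age; 0 disables).
#' @param seed integer seed fixing the population.
#' @return a `fixture_spec`.
#' @export
fixture_spec <- function(n_subjects = 50L,
                         resolution = 1L,
                         n_modes = 5L,
                         mode_sd = c(3, 2.5, 2, 1.5, 1),
                         demographics = default_fixture_demographics(),
                         gender_split = 0.48,
                         noise_sd = 0.15,
                         hole_probability = 0.3,
                         hole_radius = 15,
                         remesh = TRUE,
                         raw_resolution = NULL,
                         jitter_angle_deg = 10,
                         jitter_translation = 20,
                         age_coupling = 0,
                         seed = 1L) {
  if (abs(sum(demographics$proportion) - 1) > 1e-8)
    stop("fixture_spec: demographic proportions must sum to 1")
  if (length(mode_sd) != n_modes)
    stop("fixture_spec: mode_sd length must equal n_modes")
  if (any(mode_sd < 0) || noise_sd < 0 || hole_radius < 0)
    stop("fixture_spec: scales must be >= 0")
  if (is.null(raw_resolution))
    raw_resolution <- round(1.25 * (8L * 2L^resolution + 1L))
  structure(list(n_subjects = as.integer(n_subjects),
                 resolution = as.integer(resolution),
                 n_modes = as.integer(n_modes), mode_sd = as.numeric(mode_sd),
                 demographics = demographics, gender_split = gender_split,
                 noise_sd = noise_sd, hole_probability = hole_probability,
                 hole_radius = hole_radius, remesh = remesh,
                 raw_resolution = as.integer(raw_resolution),
                 jitter_angle_deg = jitter_angle_deg,
                 jitter_translation = jitter_translation,
                 age_coupling = age_coupling, seed = as.integer(seed)),
            class = "fixture_spec")
}

#' @rdname fixture_spec
#' @export
default_fixture_demographics <- function() {
  data.frame(
    ethnicity = c("White", "Asian", "Mixed", "Black", "Other"),
    proportion = c(0.82, 0.09, 0.05, 0.03, 0.01),
    offset_scale = c(2, 3, 2.5, 3, 2.5),
    age_shape = 2, age_scale = 16,
    stringsAsFactors = FALSE)
}

random_rotation <- function(max_angle_deg) {
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, -1, 1) * max_angle_deg * pi / 180
  K <- matrix(c(0, ax[3L], -ax[2L], -ax[3L], 0, ax[1L], ax[2L], -ax[1L], 0),
              3L, 3L)
  diag(3L) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Generate a synthetic population with full ground truth
#'
#' Draws `n_subjects` subjects under the conditions in `spec`. Every subject
#' carries: the raw scan as a registration target (independently remeshed,
#' noised, possibly holed, rigidly jittered), the ground-truth corresponded
#' mesh on the template topology (noise-free, template frame), the true mode
#' coefficients, the demographic record, ground-truth landmarks in the raw
#' scan's frame, the rigid jitter transform, and an outlier flag (see
#' [plant_outliers()]). Bit-identical for identical specs.
#'
#' @param spec a [fixture_spec()].
#' @return a `fixture_population`: list with `template` (as from
#'   [make_template()]), `mode_fields`, `spec`, and `subjects` (list of
#'   `fixture_subject`s).
#' @export
generate_population <- function(spec) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)

  tmpl <- make_template(spec$resolution)
  fields <- make_mode_fields(spec$n_modes, tmpl$params)
  groups <- spec$demographics
  offset_fields <- lapply(seq_len(nrow(groups)), function(g)
    make_offset_field(g, tmpl$params))

  lm_sites <- face_landmark_sites()
  lm_idx <- tmpl$landmarks$template_indices

  subjects <- lapply(seq_len(spec$n_subjects), function(si) {
    gi <- sample.int(nrow(groups), 1L, prob = groups$proportion)
    age <- stats::rgamma(1L, shape = groups$age_shape[gi],
                         scale = groups$age_scale[gi])
    gender <- if (stats::runif(1) < spec$gender_split) "male" else "female"
    coeffs <- stats::rnorm(spec$n_modes, 0, spec$mode_sd)
    eff <- coeffs
    if (spec$age_coupling != 0 && spec$n_modes >= 1L)
      eff[1L] <- eff[1L] + spec$age_coupling * (age - 40)

    # analytic subject surface: base + group offset + sum of mode fields
    surface <- function(x, y) {
      p <- cbind(x, y, face_height(x, y))
      p <- p + groups$offset_scale[gi] * offset_fields[[gi]](x, y)
      for (j in seq_len(spec$n_modes))
        p <- p + eff[j] * fields[[j]](x, y)
      p
    }

    gt_pts <- surface(tmpl$params[, 1L], tmpl$params[, 2L])
    gt_mesh <- triangle_mesh(gt_pts, tmpl$mesh$trilist,
                             colors = tmpl$mesh$colors, validate = FALSE)

    if (spec$remesh) {
      g <- face_grid(spec$raw_resolution, expand = 1.12)
      prm <- g$params
      dx <- diff(range(prm[, 1L])) / (spec$raw_resolution - 1L)
      dy <- diff(range(prm[, 2L])) / (spec$raw_resolution - 1L)
      interior <- prm[, 1L] > min(prm[, 1L]) & prm[, 1L] < max(prm[, 1L]) &
        prm[, 2L] > min(prm[, 2L]) & prm[, 2L] < max(prm[, 2L])
      prm[interior, 1L] <- prm[interior, 1L] +
        stats::runif(sum(interior), -0.35, 0.35) * dx
      prm[interior, 2L] <- prm[interior, 2L] +
        stats::runif(sum(interior), -0.35, 0.35) * dy
      raw_pts <- surface(prm[, 1L], prm[, 2L])
      raw_tri <- g$trilist
      raw_params <- prm
    } else {
      raw_pts <- gt_pts
      raw_tri <- tmpl$mesh$trilist
      raw_params <- tmpl$params
    }
    raw_pts <- raw_pts + matrix(stats::rnorm(length(raw_pts), 0, spec$noise_sd),
                                ncol = 3L)

    hole_center <- NULL
    if (stats::runif(1) < spec$hole_probability) {
      # punch the hole inside the face area proper (not the outer margin),
      # where the template actually needs to interpolate across it
      inner <- which(abs(raw_params[, 1L]) < 0.8 * face_domain$x[2L] &
                       abs(raw_params[, 2L]) < 0.8 * face_domain$y[2L])
      ci <- inner[sample.int(length(inner), 1L)]
      hole_center <- raw_pts[ci, ]
      cent <- (raw_pts[raw_tri[, 1L], ] + raw_pts[raw_tri[, 2L], ] +
                 raw_pts[raw_tri[, 3L], ]) / 3
      keep <- sqrt(rowSums(sweep(cent, 2L, hole_center)^2)) > spec$hole_radius
      if (sum(keep) >= 3L) raw_tri <- raw_tri[keep, , drop = FALSE]
    }

    R <- random_rotation(spec$jitter_angle_deg)
    tv <- stats::runif(3, -1, 1) * spec$jitter_translation
    rigid <- list(s = 1, R = R, t = tv)
    if (!is.null(hole_center))
      hole_center <- as.numeric(apply_similarity(rbind(hole_center), rigid))
    raw_mesh <- triangle_mesh(apply_similarity(raw_pts, rigid), raw_tri,
                              colors = face_colors(raw_params[, 1L],
                                                   raw_params[, 2L]),
                              validate = FALSE)
    lm_pts <- apply_similarity(gt_pts[lm_idx, , drop = FALSE], rigid)
    landmarks_raw <- landmark_set(rownames(lm_sites), lm_pts)

    structure(list(subject_id = sprintf("subj_%03d", si),
                   raw_mesh = raw_mesh, gt_mesh = gt_mesh,
                   coeffs = coeffs, effective_coeffs = eff,
                   record = data.frame(subject_id = sprintf("subj_%03d", si),
                                       age = age, gender = gender,
                                       ethnicity = groups$ethnicity[gi],
                                       stringsAsFactors = FALSE),
                   landmarks_raw = landmarks_raw,
                   rigid = rigid, raw_params = raw_params,
                   group_index = gi, hole_center = hole_center,
                   is_planted_outlier = FALSE),
              class = "fixture_subject")
  })
  structure(list(template = tmpl, mode_fields = fields,
                 offset_fields = offset_fields, spec = spec,
                 subjects = subjects),
            class = "fixture_population")
}

#' @export
print.fixture_population <- function(x, ...) {
  cat(sprintf("fixture_population: %d subjects (%d planted outliers), template %d vertices\n",
              length(x$subjects),
              sum(vapply(x$subjects, `[[`, logical(1L), "is_planted_outlier")),
              nrow(x$template$mesh$points)))
  invisible(x)
}

#' Plant gross registration-style outliers in a population
#'
#' Displaces `k` subjects by `magnitude_sd` standard deviations of mode 1
#' along the mode-1 field (ground truth, raw scan and landmarks all move
#' consistently) and flags them — the ground truth for pruning experiments.
#'
#' @param population a `fixture_population`.
#' @param k number of outliers, `k <= n`.
#' @param magnitude_sd displacement in units of the mode-1 standard
#'   deviation.
#' @param seed seed for choosing which subjects are displaced.
#' @return the modified population.
#' @export
plant_outliers <- function(population, k, magnitude_sd, seed = 1L) {
  n <- length(population$subjects)
  if (k > n) stop("plant_outliers: k exceeds population size")
  if (k == 0L) return(population)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  chosen <- sample.int(n, k)
  field1 <- population$mode_fields[[1L]]
  mag <- magnitude_sd * population$spec$mode_sd[1L]
  tp <- population$template$params
  lm_idx <- population$template$landmarks$template_indices
  for (si in chosen) {
    s <- population$subjects[[si]]
    d_t <- mag * field1(tp[, 1L], tp[, 2L])
    s$gt_mesh$points <- s$gt_mesh$points + d_t
    d_raw <- mag * field1(s$raw_params[, 1L], s$raw_params[, 2L])
    s$raw_mesh$points <- s$raw_mesh$points + d_raw %*% t(s$rigid$R)
    s$landmarks_raw$points <- s$landmarks_raw$points +
      (d_t[lm_idx, , drop = FALSE] %*% t(s$rigid$R))
    s$effective_coeffs[1L] <- s$effective_coeffs[1L] + mag
    s$coeffs[1L] <- s$coeffs[1L] + mag
    s$is_planted_outlier <- TRUE
    population$subjects[[si]] <- s
  }
  population
}

#' Oracle 2D landmark detector for a fixture subject
#'
#' The test seam for the landmarking stage: returns a detector that, given a
#' rendered view, projects the subject's ground-truth 3D landmarks through
#' the view's camera. Confidence is 1 when the landmark's surface point is
#' visible in the view's z-buffer (depth agrees within `depth_tol`), 0 when
#' occluded or off-image — mirroring how a real detector degrades on
#' invisible features.
#'
#' @param subject a `fixture_subject`, or a [landmark_set()] of ground-truth
#'   3D points in the mesh's frame.
#' @param depth_tol visibility tolerance (mm) between the landmark's camera
#'   depth and the rendered depth buffer.
#' @return a detector function (see [auto_landmark()]).
#' @export
oracle_detector <- function(subject, depth_tol = 5) {
  lms <- if (inherits(subject, "landmark_set")) subject else
    subject$landmarks_raw
  function(view) {
    cam <- view$camera
    pr <- project_points(cam, lms$points)
    H <- nrow(view$mask); W <- ncol(view$mask)
    conf <- numeric(nrow(pr))
    for (i in seq_len(nrow(pr))) {
      if (!lms$valid[i] || pr[i, 3L] <= 0) next
      r <- round(pr[i, 2L]); c <- round(pr[i, 1L])
      if (r < 1 || r > H || c < 1 || c > W || !view$mask[r, c]) next
      if (abs(view$depth[r, c] - pr[i, 3L]) <= depth_tol) conf[i] <- 1
    }
    list(points = pr[, 1:2, drop = FALSE], confidence = conf,
         labels = lms$labels)
  }
}

#' Write a population to disk (PLY + landmark JSON + demographics CSV)
#'
#' Materializes a population the way a scan archive would arrive: one PLY
#' raw mesh and one ground-truth landmark JSON per subject, a demographics
#' CSV, and a ground-truth archive (`ground_truth.rds`: true coefficients,
#' correspondence meshes, rigid transforms, outlier flags).
#'
#' @param population a `fixture_population`.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_population <- function(population, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mesh_dir <- file.path(dir, "meshes")
  lm_dir <- file.path(dir, "landmarks")
  dir.create(mesh_dir, showWarnings = FALSE)
  dir.create(lm_dir, showWarnings = FALSE)
  recs <- list()
  for (s in population$subjects) {
    write_mesh(s$raw_mesh, file.path(mesh_dir, paste0(s$subject_id, ".ply")))
    write_landmarks(s$landmarks_raw,
                    file.path(lm_dir, paste0(s$subject_id, ".json")))
    recs[[length(recs) + 1L]] <- s$record
  }
  utils::write.csv(do.call(rbind, recs), file.path(dir, "demographics.csv"),
                   row.names = FALSE)
  write_mesh(population$template$mesh, file.path(dir, "template.ply"))
  write_landmarks(population$template$landmarks,
                  file.path(dir, "template_landmarks.json"))
  gt <- list(spec = population$spec,
             coeffs = t(vapply(population$subjects, `[[`,
                               numeric(population$spec$n_modes), "coeffs")),
             is_planted_outlier = vapply(population$subjects, `[[`,
                                         logical(1L), "is_planted_outlier"),
             gt_meshes = lapply(population$subjects, `[[`, "gt_mesh"),
             rigid = lapply(population$subjects, `[[`, "rigid"))
  saveRDS(gt, file.path(dir, "ground_truth.rds"))
  invisible(dir)
}
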