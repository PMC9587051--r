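# Seeded generator of stage-labelled synthetic cytology images and multi-day
# cycle sequences.
#
# Cells are parametric-geometric, not photorealistic: leukocytes are small
# dark discs, nucleated epithelial cells are mid-sized discs with a darker
# nucleus, cornified epithelial cells are large irregular polygons without a
# nucleus. The discriminative signal of real cytology — cell-type proportion
# and size — is what the four classes differ in, so this is sufficient to
# exercise preprocessing, training and evaluation end to end. Each cell type
# occupies a disjoint intensity band and cells are placed without overlap,
# which makes the rendered image exactly countable by a threshold counter
# ([count_cells_reference()]) — the generator's self-consistency oracle.

#' Cell rendering parameters
#'
#' Geometry and photometry of the synthetic cytology renderer. Size ranges
#' are radii in pixels and must be ordered leukocyte < nucleated < cornified.
#' Each cell type draws its (minimum) intensity from a disjoint band so a
#' noise-free rendering can be counted back exactly.
#'
#' @param image_size Side of the square image in pixels (default 448, min 64).
#' @param background_level Background gray level in `[0,1]`.
#' @param leukocyte_radius,nucleated_radius,cornified_radius Length-2 radius
#'   ranges in pixels.
#' @param leukocyte_intensity,nucleated_intensity,cornified_intensity Length-2
#'   intensity ranges in `[0,1]` (the nucleated range is the nucleus level;
#'   the cell body is drawn lighter).
#' @param clumping_strength In `[0,1]`: probability that a cornified cell is
#'   placed near a clump centre rather than uniformly.
#' @param stain_tints Named list of RGB multipliers per stain.
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @return A `cell_render_params` list.
#' @export
cell_render_params <- function(image_size = 448,
                               background_level = 0.92,
                               leukocyte_radius = c(2, 3.5),
                               nucleated_radius = c(6, 9),
                               cornified_radius = c(12, 17),
                               leukocyte_intensity = c(0.05, 0.15),
                               nucleated_intensity = c(0.22, 0.32),
                               cornified_intensity = c(0.62, 0.75),
                               clumping_strength = 0.7,
                               stain_tints = default_stain_tints(),
                               noise_sd = 0.02) {
  if (image_size < 64) stopf("image_size must be at least 64")
  if (!(max(leukocyte_radius) < min(nucleated_radius) &&
        max(nucleated_radius) < min(cornified_radius))) {
    stopf("size ranges must be ordered leukocyte < nucleated < cornified")
  }
  vals <- c(background_level, leukocyte_intensity, nucleated_intensity,
            cornified_intensity)
  if (any(vals < 0 | vals > 1)) stopf("intensities must lie in [0,1]")
  structure(list(image_size = image_size, background_level = background_level,
                 leukocyte_radius = leukocyte_radius,
                 nucleated_radius = nucleated_radius,
                 cornified_radius = cornified_radius,
                 leukocyte_intensity = leukocyte_intensity,
                 nucleated_intensity = nucleated_intensity,
                 cornified_intensity = cornified_intensity,
                 clumping_strength = clumping_strength,
                 stain_tints = stain_tints, noise_sd = noise_sd),
            class = "cell_render_params")
}

#' Default stain tints
#'
#' RGB multipliers emulating the overall hue of common cytology stains.
#'
#' @return Named list of length-3 RGB multipliers.
#' @export
default_stain_tints <- function() {
  list(HE = c(1.00, 0.80, 0.88),
       Shorr = c(1.00, 0.86, 0.74),
       Giemsa = c(0.80, 0.84, 1.00),
       CresylViolet = c(0.90, 0.80, 1.00),
       CrystalViolet = c(0.84, 0.76, 1.00),
       other = c(1, 1, 1))
}

#' Stage-specific cell mixtures
#'
#' Mean proportions of (leukocyte, cornified, nucleated) cells per canonical
#' stage, the Dirichlet concentration controlling spread around the mean, and
#' the per-stage total-cell-count range. Defaults respect the qualitative
#' cytology of each stage — diestrus leukocyte-dominant, proestrus
#' nucleated-dominant, estrus cornified-dominant, metestrus mixed with
#' leukocytes present; they are not literature point estimates and are
#' configurable.
#'
#' @param means 4 x 3 matrix of per-stage mean proportions (rows D, P, E, M;
#'   columns leukocyte, cornified, nucleated), each row summing to 1.
#' @param concentration Dirichlet concentration (larger = tighter around the
#'   mean; `Inf` degenerates to the mean exactly).
#' @param total_cells 4 x 2 matrix of per-stage total-cell-count ranges.
#' @return A `stage_mixture` object.
#' @export
stage_mixture <- function(means = NULL, concentration = 150,
                          total_cells = NULL) {
  if (is.null(means)) {
    means <- rbind(diestrus = c(0.85, 0.05, 0.10),
                   proestrus = c(0.10, 0.10, 0.80),
                   estrus = c(0.05, 0.90, 0.05),
                   metestrus = c(0.40, 0.30, 0.30))
  }
  colnames(means) <- c("leukocyte", "cornified", "nucleated")
  if (any(abs(rowSums(means) - 1) > 1e-6)) stopf("mixture means must sum to 1")
  if (is.null(total_cells)) {
    total_cells <- rbind(diestrus = c(60, 100), proestrus = c(40, 80),
                         estrus = c(25, 50), metestrus = c(40, 80))
  }
  structure(list(means = means, concentration = concentration,
                 total_cells = total_cells),
            class = "stage_mixture")
}

#' Sample cell-type proportions for a stage
#'
#' Draws (leukocyte, cornified, nucleated) proportions from a Dirichlet
#' distribution centred on the stage's configured mean, plus a total cell
#' count uniform on the stage's range. A transition label draws around the
#' mean of the two flanking stages' means (documented behaviour, not an
#' error). Infinite concentration returns the mean exactly.
#'
#' @param stage Canonical or transition stage label.
#' @param mix A [stage_mixture()].
#' @param seed Integer seed.
#' @return List with `proportions` (named, summing to 1) and `total_cells`.
#' @export
sample_stage_proportions <- function(stage, mix = stage_mixture(), seed = NULL) {
  stage <- normalize_stage(stage, allow_na = FALSE)
  if (is_canonical_stage(stage)) {
    mean_p <- mix$means[stage, ]
    range_n <- mix$total_cells[stage, ]
  } else {
    parts <- strsplit(stage, "/", fixed = TRUE)[[1]]
    mean_p <- colMeans(mix$means[parts, ])
    range_n <- round(colMeans(mix$total_cells[parts, ]))
  }
  with_seed(seed, {
    p <- if (is.finite(mix$concentration)) {
      g <- rgamma(3, shape = mean_p * mix$concentration, rate = 1)
      if (sum(g) == 0) mean_p else g / sum(g)
    } else mean_p
    names(p) <- colnames(mix$means)
    n <- if (range_n[2] > range_n[1]) {
      sample(seq(range_n[1], range_n[2]), 1)
    } else range_n[1]
    list(proportions = p, total_cells = as.integer(n))
  })
}

# --- rendering primitives ---------------------------------------------------

draw_disc <- function(canvas, cy, cx, r, value) {
  n <- nrow(canvas)
  ys <- max(1, floor(cy - r)):min(n, ceiling(cy + r))
  xs <- max(1, floor(cx - r)):min(ncol(canvas), ceiling(cx + r))
  yy <- matrix(ys, length(ys), length(xs))
  xx <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  inside <- (yy - cy)^2 + (xx - cx)^2 <= r^2
  canvas[ys, xs][inside] <- value
  canvas
}

# Irregular polygon fill: vertices at jittered angles and radii around the
# centre, rasterised by even-odd scanline. Angle jitter is bounded so spikes
# cannot pinch off and disconnect the rasterised shape.
draw_polygon_blob <- function(canvas, cy, cx, r, value, n_vertices = 12) {
  base_ang <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  ang <- base_ang + runif(n_vertices, -0.3, 0.3) * 2 * pi / n_vertices
  rad <- r * runif(n_vertices, 0.78, 1.18)
  vy <- cy + rad * sin(ang)
  vx <- cx + rad * cos(ang)
  h <- nrow(canvas); w <- ncol(canvas)
  ys <- max(1, floor(min(vy))):min(h, ceiling(max(vy)))
  nv <- length(vy)
  for (y in ys) {
    xints <- numeric(0)
    j <- nv
    for (i in seq_len(nv)) {
      if ((vy[i] > y) != (vy[j] > y)) {
        xints <- c(xints, vx[i] + (y - vy[i]) / (vy[j] - vy[i]) * (vx[j] - vx[i]))
      }
      j <- i
    }
    xints <- sort(xints)
    k <- 1
    while (k + 1 <= length(xints)) {
      x0 <- max(1, ceiling(xints[k])); x1 <- min(w, floor(xints[k + 1]))
      if (x0 <= x1) canvas[y, x0:x1] <- value
      k <- k + 2
    }
  }
  canvas
}

# Rejection-sample non-overlapping cell centres; clump centres attract
# cornified cells. Returns placements or fewer if the canvas saturates.
place_cells <- function(n_by_type, params) {
  size <- params$image_size
  radii <- list(
    leukocyte = params$leukocyte_radius,
    cornified = params$cornified_radius,
    nucleated = params$nucleated_radius
  )
  n_clumps <- max(1, sample(1:3, 1))
  clump_y <- runif(n_clumps, size * 0.2, size * 0.8)
  clump_x <- runif(n_clumps, size * 0.2, size * 0.8)
  placed <- list(y = numeric(0), x = numeric(0), r = numeric(0),
                 r_eff = numeric(0), type = character(0))
  for (type in c("cornified", "nucleated", "leukocyte")) {  # big cells first
    n <- n_by_type[[type]]
    if (is.null(n) || n == 0) next
    for (i in seq_len(n)) {
      r_draw <- runif(1, radii[[type]][1], radii[[type]][2])
      # polygon vertices reach 1.18x the nominal radius
      r <- if (type == "cornified") 1.25 * r_draw else r_draw
      ok <- FALSE
      for (try in 1:300) {
        if (type == "cornified" && runif(1) < params$clumping_strength) {
          k <- sample.int(n_clumps, 1)
          cy <- clump_y[k] + rnorm(1, sd = size * 0.08)
          cx <- clump_x[k] + rnorm(1, sd = size * 0.08)
        } else {
          cy <- runif(1, 1 + r, size - r)
          cx <- runif(1, 1 + r, size - r)
        }
        if (cy < 1 + r || cy > size - r || cx < 1 + r || cx > size - r) next
        if (length(placed$y) == 0 ||
            all((placed$y - cy)^2 + (placed$x - cx)^2 >
                (placed$r_eff + r + 2)^2)) {
          ok <- TRUE
          break
        }
      }
      if (!ok) next  # canvas saturated for this cell; caller rechecks counts
      placed$y <- c(placed$y, cy); placed$x <- c(placed$x, cx)
      placed$r <- c(placed$r, r_draw); placed$r_eff <- c(placed$r_eff, r)
      placed$type <- c(placed$type, type)
    }
  }
  placed
}

#' Render a synthetic cytology image
#'
#' Renders a stage-labelled brightfield-like cytology image: cell-type counts
#' are drawn via [sample_stage_proportions()], cells are placed without
#' overlap (cornified cells cluster around clump centres when
#' `clumping_strength > 0`), the stain tint is applied uniformly, and optional
#' Gaussian noise is added. The returned cell counts are exactly the rendered
#' counts.
#'
#' @param stage Canonical or transition stage label.
#' @param params A [cell_render_params()].
#' @param mix A [stage_mixture()].
#' @param seed Integer seed; identical seeds give bit-identical images.
#' @param stain Stain name selecting the tint (see [default_stain_tints()]).
#' @param path Optional PNG output path; when given the image is written.
#' @param proportions,total_cells Optional overrides: render exactly this
#'   mixture instead of drawing one from `mix` (used by the sequence
#'   generator so rendered images match recorded proportions).
#' @return List with `image` (height x width x 3 array), `counts` (named
#'   integer counts per cell type), `proportions` (rendered fractions summing
#'   to 1), `total_cells`, `stage` and `path`.
#' @export
render_cytology_image <- function(stage, params = cell_render_params(),
                                  mix = stage_mixture(), seed = NULL,
                                  stain = "HE", path = NULL,
                                  proportions = NULL, total_cells = NULL) {
  stage <- normalize_stage(stage, allow_na = FALSE)
  draw <- if (!is.null(proportions)) {
    list(proportions = proportions, total_cells = as.integer(total_cells %||% 60))
  } else {
    sample_stage_proportions(stage, mix, seed = seed)
  }
  if (draw$total_cells < 1) stopf("zero total cells requested")
  with_seed(if (is.null(seed)) NULL else seed + 1L, {
    counts <- as.vector(rmultinom(1, draw$total_cells, draw$proportions))
    names(counts) <- names(draw$proportions)
    placed <- place_cells(as.list(counts), params)
    # rendered counts are whatever was actually placed (saturation-safe)
    counts <- vapply(names(counts), function(tp) sum(placed$type == tp),
                     integer(1))
    if (sum(counts) < 1) stopf("zero total cells rendered")
    canvas <- matrix(params$background_level, params$image_size,
                     params$image_size)
    for (i in seq_along(placed$y)) {
      tp <- placed$type[i]
      if (tp == "leukocyte") {
        val <- runif(1, params$leukocyte_intensity[1], params$leukocyte_intensity[2])
        canvas <- draw_disc(canvas, placed$y[i], placed$x[i], placed$r[i], val)
      } else if (tp == "nucleated") {
        body <- runif(1, 0.45, 0.55)
        nuc <- runif(1, params$nucleated_intensity[1], params$nucleated_intensity[2])
        canvas <- draw_disc(canvas, placed$y[i], placed$x[i], placed$r[i], body)
        canvas <- draw_disc(canvas, placed$y[i], placed$x[i],
                            0.4 * placed$r[i], nuc)
      } else {
        val <- runif(1, params$cornified_intensity[1], params$cornified_intensity[2])
        canvas <- draw_polygon_blob(canvas, placed$y[i], placed$x[i],
                                    placed$r[i], val)
      }
    }
    tint <- params$stain_tints[[stain]] %||% params$stain_tints[["other"]]
    img <- array(0, c(params$image_size, params$image_size, 3))
    for (k in 1:3) img[, , k] <- canvas * tint[k]
    if (params$noise_sd > 0) {
      img <- clip01(img + array(rnorm(length(img), sd = params$noise_sd),
                                dim(img)))
    }
    if (!is.null(path)) png::writePNG(img, path)
    list(image = img, counts = counts,
         proportions = counts / sum(counts),
         total_cells = sum(counts), stage = stage, path = path)
  })
}

#' Count cells in a noise-free synthetic rendering
#'
#' Independent threshold counter used as the generator's self-consistency
#' oracle: thresholds the un-tinted luminance into the three disjoint
#' intensity bands the renderer assigns to leukocyte nuclei, nucleated-cell
#' nuclei and cornified cytoplasm, labels connected components within each
#' band, and counts them. On a noise-free rendering the counts equal the
#' generator's bookkeeping exactly.
#'
#' @param img Image returned by [render_cytology_image()] (rendered with
#'   `noise_sd = 0`).
#' @param params The [cell_render_params()] used for rendering.
#' @param stain Stain name used at render time (to undo the tint).
#' @return Named integer vector of counts (leukocyte, cornified, nucleated).
#' @export
count_cells_reference <- function(img, params = cell_render_params(),
                                  stain = "HE") {
  tint <- params$stain_tints[[stain]] %||% params$stain_tints[["other"]]
  gray <- img[, , 1] / tint[1]  # undo tint on the red channel
  bands <- list(
    leukocyte = params$leukocyte_intensity,
    nucleated = params$nucleated_intensity,
    cornified = params$cornified_intensity
  )
  out <- vapply(names(bands), function(tp) {
    b <- bands[[tp]]
    mask <- gray >= b[1] - 0.02 & gray <= b[2] + 0.02
    lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
    max(lab)
  }, numeric(1))
  out <- as.integer(out)
  names(out) <- names(bands)
  out[c("leukocyte", "cornified", "nucleated")]
}

#' Generate a balanced synthetic dataset
#'
#' Renders `n_per_stage` images for each canonical stage, cycling stains
#' deterministically across records and assigning subjects round-robin, and
#' returns the manifest. The manifest records image dimensions, stage label,
#' rendered cell proportions and total counts, so it passes
#' [apply_exclusion_filters()] unchanged.
#'
#' @param n_per_stage Images per canonical stage (>= 1).
#' @param dir Output directory for PNGs (created if needed).
#' @param params A [cell_render_params()].
#' @param mix A [stage_mixture()].
#' @param stains Character vector of stains, cycled over records.
#' @param n_subjects Number of synthetic subjects assigned round-robin.
#' @param seed Integer seed; identical seeds give identical manifests.
#' @return An `estrous_manifest` of `4 * n_per_stage` records.
#' @export
generate_dataset <- function(n_per_stage, dir = tempfile("estroset"),
                             params = cell_render_params(),
                             mix = stage_mixture(),
                             stains = c("HE", "Shorr"),
                             n_subjects = 6, seed = 1) {
  if (n_per_stage < 1) stopf("n_per_stage must be >= 1")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  idx <- 0
  for (stage in canonical_stages()) {
    for (j in seq_len(n_per_stage)) {
      idx <- idx + 1
      stain <- stains[((idx - 1) %% length(stains)) + 1]
      img_seed <- (seed * 7919L + idx * 131L) %% .Machine$integer.max
      path <- file.path(dir, sprintf("%s_%04d.png", stage, idx))
      r <- render_cytology_image(stage, params, mix, seed = img_seed,
                                 stain = stain, path = path)
      rows[[idx]] <- data.frame(
        image_path = path,
        subject_id = sprintf("subj%02d", ((idx - 1) %% n_subjects) + 1),
        species = if (((idx - 1) %% n_subjects) %% 2 == 0) "mouse" else "rat",
        strain = "synthetic",
        stain = stain,
        magnification = "20x",
        lab = "synthetic",
        stage = stage,
        leukocyte_frac = r$proportions[["leukocyte"]],
        cornified_frac = r$proportions[["cornified"]],
        nucleated_frac = r$proportions[["nucleated"]],
        total_cells = r$total_cells,
        width = params$image_size,
        height = params$image_size,
        stringsAsFactors = FALSE
      )
    }
  }
  as_manifest(do.call(rbind, rows),
              provenance = sprintf("synthetic dataset (seed %d)", seed))
}

#' Sequence specification for multi-day synthetic sampling
#'
#' @param n_days Number of days sampled (>= 1).
#' @param samples_per_day Sampling frequency per day.
#' @param true_phase Ground-truth cycle phase in `[0, 1)` cycle units.
#' @param label_noise Probability that a stored benchmark label is replaced
#'   by a uniformly random other canonical stage (the rendered image keeps the
#'   true stage's mixture).
#' @param pseudopregnancy_onset_day Optional day after which the true stage is
#'   forced to diestrus with leukocyte fraction at least 0.9.
#' @param seed Integer seed.
#' @return A `sequence_spec` list.
#' @export
sequence_spec <- function(n_days, samples_per_day = 1, true_phase = 0,
                          label_noise = 0, pseudopregnancy_onset_day = NULL,
                          seed = 1) {
  if (n_days < 1) stopf("n_days must be >= 1")
  if (label_noise < 0 || label_noise > 1) stopf("label_noise must lie in [0,1]")
  if (true_phase < 0 || true_phase >= 1) stopf("true_phase must lie in [0,1)")
  structure(list(n_days = n_days, samples_per_day = samples_per_day,
                 true_phase = true_phase, label_noise = label_noise,
                 pseudopregnancy_onset_day = pseudopregnancy_onset_day,
                 seed = seed),
            class = "sequence_spec")
}

#' Generate a multi-day cycle sequence
#'
#' Samples a subject at `samples_per_day` regular intervals for `n_days`
#' days. The true stage at time `t` (days) is the archetypal cycle's stage at
#' `t` shifted by `true_phase` cycles; after `pseudopregnancy_onset_day` all
#' true stages are diestrus with leukocyte fraction drawn at or above 0.9.
#' `label_noise` corrupts the stored benchmark label only — the rendered
#' image (and the recorded cell proportions) always follow the true stage.
#'
#' @param spec A [sequence_spec()].
#' @param cycle An [build_archetypal_cycle()] result (defaults to the
#'   standard 4.8-day cycle).
#' @param params A [cell_render_params()].
#' @param mix A [stage_mixture()].
#' @param dir Output directory for PNGs when `render = TRUE`.
#' @param render Logical; when `FALSE` no images are written (fast path for
#'   cycle-fitting work, where only labels, times and proportions are needed).
#' @return An `estrous_manifest` ordered by time with columns
#'   `collected_at_days`, `stage` (possibly noise-corrupted benchmark label)
#'   and `true_stage` (generator ground truth).
#' @export
generate_cycle_sequence <- function(spec, cycle = build_archetypal_cycle(),
                                    params = cell_render_params(),
                                    mix = stage_mixture(),
                                    dir = tempfile("estroseq"),
                                    render = FALSE) {
  stopifnot(inherits(spec, "sequence_spec"))
  times <- seq(0, by = 1 / spec$samples_per_day,
               length.out = spec$n_days * spec$samples_per_day)
  if (render) dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- with_seed(spec$seed, {
    lapply(seq_along(times), function(i) {
      t <- times[i]
      pseudo <- !is.null(spec$pseudopregnancy_onset_day) &&
        t >= spec$pseudopregnancy_onset_day
      true_stage <- if (pseudo) "diestrus" else {
        number_to_stage(eval_waveform(cycle, t + spec$true_phase * cycle$period_days))
      }
      label <- true_stage
      if (spec$label_noise > 0 && runif(1) < spec$label_noise) {
        label <- sample(setdiff(canonical_stages(), true_stage), 1)
      }
      if (pseudo) {
        leuk <- runif(1, 0.9, 0.98)
        rest <- runif(1, 0.3, 0.7)
        props <- c(leukocyte = leuk, cornified = (1 - leuk) * rest,
                   nucleated = (1 - leuk) * (1 - rest))
        total <- sample(60:100, 1)
      } else {
        d <- sample_stage_proportions(true_stage, mix)
        props <- d$proportions
        total <- d$total_cells
      }
      path <- file.path(dir, sprintf("seq_%03d.png", i))
      if (render) {
        img_seed <- (spec$seed * 104729L + i * 17L) %% .Machine$integer.max
        render_cytology_image(true_stage, params, mix, seed = img_seed,
                              path = path, proportions = props,
                              total_cells = total)
      }
      data.frame(image_path = path, subject_id = "seq01", species = "mouse",
                 strain = "synthetic", stain = "HE", magnification = "20x",
                 lab = "synthetic", collected_at_days = t, stage = label,
                 true_stage = true_stage,
                 leukocyte_frac = props[["leukocyte"]],
                 cornified_frac = props[["cornified"]],
                 nucleated_frac = props[["nucleated"]],
                 total_cells = total,
                 width = params$image_size, height = params$image_size,
                 stringsAsFactors = FALSE)
    })
  })
  as_manifest(do.call(rbind, rows),
              provenance = sprintf("synthetic sequence (phase %.2f, seed %d)",
                                   spec$true_phase, spec$seed))
}
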