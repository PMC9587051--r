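# Shared fixtures, built in code at test time.

# Manifest of n_per_stage records per canonical stage with plausible metadata
# and no image files behind the paths (manifest-level machinery does not need
# pixels). Proportions are each stage's mixture mean plus small deterministic
# jitter.
make_test_manifest <- function(n_per_stage = 5, stains = c("HE", "Shorr"),
                               width = 448, height = 448) {
  mix <- stage_mixture()
  rows <- do.call(rbind, lapply(canonical_stages(), function(st) {
    idx <- seq_len(n_per_stage)
    props <- unname(mix$means[st, ])
    data.frame(
      image_path = sprintf("img_%s_%03d.png", st, idx),
      subject_id = sprintf("subj%02d", ((idx - 1) %% 4) + 1),
      species = ifelse(idx %% 2 == 0, "mouse", "rat"),
      strain = "wt",
      stain = stains[((idx - 1) %% length(stains)) + 1],
      magnification = "20x",
      lab = "labA",
      stage = st,
      leukocyte_frac = props[1], cornified_frac = props[2],
      nucleated_frac = props[3],
      total_cells = 50L,
      width = width, height = height,
      stringsAsFactors = FALSE
    )
  }))
  as_manifest(rows, provenance = "test fixture")
}

# Fast rendering settings for image-level tests: small canvas, few cells,
# cell radii scaled down so placement never saturates.
small_render_params <- function(noise_sd = 0) {
  cell_render_params(image_size = 192, noise_sd = noise_sd,
                     leukocyte_radius = c(2, 3),
                     nucleated_radius = c(4.5, 6.5),
                     cornified_radius = c(8, 11))
}

small_mix <- function() {
  stage_mixture(total_cells = rbind(diestrus = c(14, 20), proestrus = c(12, 18),
                                    estrus = c(10, 14), metestrus = c(12, 18)))
}

# Trainer callback for grouped k-fold tests: nearest-mean classifier on the
# cell-proportion columns, with stage means estimated from the training fold.
proportion_trainer <- function(train_m, test_m) {
  cols <- c("leukocyte_frac", "cornified_frac", "nucleated_frac")
  tr <- as.data.frame(train_m)
  means <- sapply(canonical_stages(), function(st) {
    colMeans(tr[tr$stage == st, cols, drop = FALSE])
  })
  te <- as.matrix(as.data.frame(test_m)[, cols])
  vapply(seq_len(nrow(te)), function(i) {
    canonical_stages()[which.min(colSums((means - te[i, ])^2))]
  }, character(1))
}
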