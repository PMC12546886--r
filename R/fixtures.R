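# Deterministic fixture generation: the 5 x 6 x 4 factorial treatment
# design, dataset skeletons with simulated phenotypes, synthetic 64x64x3
# seed images with a recoverable morphology latent, and 50x128 treatment
# sensor sequences with a documented channel map.

#' Factorial treatment design
#'
#' Five field levels x six frequencies x four durations = 120 treatment
#' cells, 50 seeds per cell, 3 replicates, plus an optional untreated
#' control arm.
#'
#' @param field_levels_mT,frequency_levels_Hz,duration_levels_s factor
#'   levels.
#' @param seeds_per_cell,replicates cell size and replication.
#' @param control include a control cell.
#' @return An object of class `factorial_design`.
#' @export
factorial_design <- function(field_levels_mT = c(0.5, 1.5, 2.5, 3.5, 5.0),
                             frequency_levels_Hz = c(50, 150, 300, 500, 750, 1000),
                             duration_levels_s = c(60, 120, 180, 300),
                             seeds_per_cell = 50, replicates = 3,
                             control = TRUE) {
  if (length(field_levels_mT) == 0 || length(frequency_levels_Hz) == 0 ||
      length(duration_levels_s) == 0) {
    stop("factor level lists must be nonempty")
  }
  b <- protocol_bounds()
  stopifnot(all(field_levels_mT >= b$lower[1] & field_levels_mT <= b$upper[1]),
            all(frequency_levels_Hz >= b$lower[2] &
                  frequency_levels_Hz <= b$upper[2]),
            all(duration_levels_s >= b$lower[3] &
                  duration_levels_s <= b$upper[3]))
  structure(list(field_levels_mT = field_levels_mT,
                 frequency_levels_Hz = frequency_levels_Hz,
                 duration_levels_s = duration_levels_s,
                 seeds_per_cell = seeds_per_cell, replicates = replicates,
                 control = control),
            class = "factorial_design")
}

#' Enumerate the treatment cells of a factorial design
#'
#' Cartesian product in deterministic field-major order (field varies
#' slowest, duration fastest), plus one control cell (`field = 0`) if the
#' design carries a control arm.
#'
#' @param design a [factorial_design()].
#' @return Data frame with `cell_id`, `field_strength_mT`, `frequency_Hz`,
#'   `duration_s`, `is_control`.
#' @export
enumerate_design <- function(design) {
  stopifnot(inherits(design, "factorial_design"))
  grid <- expand.grid(duration_s = design$duration_levels_s,
                      frequency_Hz = design$frequency_levels_Hz,
                      field_strength_mT = design$field_levels_mT,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("field_strength_mT", "frequency_Hz", "duration_s")]
  grid$is_control <- FALSE
  if (design$control) {
    grid <- rbind(grid, data.frame(field_strength_mT = 0, frequency_Hz = 0,
                                   duration_s = 0, is_control = TRUE))
  }
  grid$cell_id <- ifelse(grid$is_control, "control",
                         sprintf("B%g_f%g_t%g", grid$field_strength_mT,
                                 grid$frequency_Hz, grid$duration_s))
  rownames(grid) <- NULL
  grid[, c("cell_id", "field_strength_mT", "frequency_Hz", "duration_s",
           "is_control")]
}

# Protocol for a treatment cell (nominal drive settings).
cell_protocol <- function(cell) {
  if (cell$is_control) return(NULL)
  treatment_protocol(cell$field_strength_mT, cell$frequency_Hz,
                     cell$duration_s)
}

#' Synthetic seed image specification
#'
#' @param height,width,channels image dimensions (64 x 64 x 3).
#' @param noise_level Gaussian pixel-noise standard deviation.
#' @return An object of class `image_spec`.
#' @export
image_spec <- function(height = 64, width = 64, channels = 3,
                       noise_level = 0.02) {
  structure(list(height = height, width = width, channels = channels,
                 noise_level = noise_level),
            class = "image_spec")
}

#' Render a synthetic seed image
#'
#' A rotated ellipse (axis lengths from the morphology latent) filled with
#' a hue-dependent kernel colour, speckle texture, Poisson-count dark
#' defects and Gaussian pixel noise, clipped to \[0, 1\]. The latent is
#' recoverable: a moment-based ellipse fit retrieves the axes to within a
#' few percent at the default noise level.
#'
#' @param spec an [image_spec()].
#' @param latent named list/vector: `length_px` (major axis, pixels),
#'   `width_px` (minor axis), `hue` in \[0, 1\], `defect_density`
#'   (expected defect count), optional `angle` (rad; drawn at random if
#'   missing).
#' @return Array of dim `c(height, width, 3)` with values in \[0, 1\].
#'   Uses the current RNG stream (seed at the caller).
#' @export
render_seed_image <- function(spec = image_spec(), latent) {
  latent <- as.list(latent)
  stopifnot(latent$length_px > 0, latent$width_px > 0,
            latent$length_px <= spec$height, latent$hue >= 0, latent$hue <= 1)
  h <- spec$height; w <- spec$width
  angle <- if (!is.null(latent$angle)) latent$angle else stats::runif(1, 0, pi)
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  xs <- matrix(rep(seq_len(w), each = h), h, w) - cx
  ys <- matrix(rep(seq_len(h), times = w), h, w) - cy
  a <- latent$length_px / 2; b <- latent$width_px / 2
  u <- (xs * cos(angle) + ys * sin(angle)) / a
  v <- (-xs * sin(angle) + ys * cos(angle)) / b
  mask <- u^2 + v^2 <= 1
  base_col <- c(0.90, 0.55 + 0.35 * latent$hue, 0.15)
  img <- array(0.05, dim = c(h, w, 3))
  speckle <- if (spec$noise_level > 0) {
    1 + stats::rnorm(sum(mask), 0, 0.05)
  } else 1
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[mask] <- base_col[ch] * speckle
    img[, , ch] <- plane
  }
  dd <- latent$defect_density %||% 0
  n_def <- if (dd > 0) stats::rpois(1, dd) else 0
  if (n_def > 0) {
    inside <- which(mask, arr.ind = TRUE)
    pick <- inside[sample.int(nrow(inside), min(n_def, nrow(inside))), ,
                   drop = FALSE]
    for (i in seq_len(nrow(pick))) {
      r0 <- max(pick[i, 1] - 1, 1):min(pick[i, 1] + 1, h)
      c0 <- max(pick[i, 2] - 1, 1):min(pick[i, 2] + 1, w)
      img[r0, c0, ] <- 0.02
    }
  }
  if (spec$noise_level > 0) {
    img <- img + array(stats::rnorm(length(img), 0, spec$noise_level),
                       dim = dim(img))
  }
  img[img < 0] <- 0; img[img > 1] <- 1
  img
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Treatment sensor-sequence specification
#'
#' 50 timesteps x 128 channels. Channel map: 1 rectified field envelope
#' (mT), 2 induced vibration amplitude (nm), 3 chamber temperature
#' (bounded walk, 22 +/- 2 C), 4 relative humidity (bounded walk,
#' 60 +/- 5%), 5 action time (normalized), 6 voltage amplitude
#' (normalized), 7 pulse width (normalized), 8 duty cycle (normalized),
#' 9 cumulative delivered-dose trace (normalized J-equivalent), 10 null
#' channel (pure noise, wired to have no effect on any target), 11-128
#' lagged noisy mixtures of channels 1-9.
#'
#' @param timesteps,channels sequence dimensions.
#' @param noise_level channel noise standard deviation (0 = noiseless).
#' @return An object of class `sequence_spec`.
#' @export
sequence_spec <- function(timesteps = 50, channels = 128,
                          noise_level = 0.02) {
  structure(list(timesteps = timesteps, channels = channels,
                 noise_level = noise_level),
            class = "sequence_spec")
}

# Bounded random walk within [lo, hi] starting at the midpoint.
bounded_walk <- function(n, lo, hi, step) {
  if (step == 0) return(rep((lo + hi) / 2, n))
  x <- numeric(n)
  x[1] <- (lo + hi) / 2
  for (i in seq_len(n - 1)) {
    x[i + 1] <- min(max(x[i] + stats::rnorm(1, 0, step), lo), hi)
  }
  x
}

#' Render a treatment sensor sequence
#'
#' @param spec a [sequence_spec()] (see its channel map).
#' @param protocol a [treatment_protocol()] or `NULL` for control (zero
#'   field).
#' @param profile a [variety_profile()] supplying the resonance model for
#'   the amplitude and dose channels.
#' @return Matrix of dim `(timesteps, channels)`. Uses the current RNG
#'   stream.
#' @export
render_sequence <- function(spec = sequence_spec(), protocol, profile) {
  nt <- spec$timesteps
  mech <- profile_mechanics(profile)
  base <- matrix(0, nt, 9)
  if (!is.null(protocol)) {
    tt <- seq(0, protocol$duration_s, length.out = nt)
    B0 <- protocol$field_strength_mT
    base[, 1] <- B0 * abs(cos(2 * pi * protocol$frequency_Hz * tt)) *
      protocol$duty_cycle_pct / 100
    base[, 2] <- vibration_amplitude(B0 * 1e-3, protocol$frequency_Hz,
                                     mech) * 1e9
    base[, 5] <- protocol$duration_s / 300
    base[, 6] <- protocol$voltage_amplitude_V / 50
    base[, 7] <- protocol$pulse_width_ms / 10
    base[, 8] <- protocol$duty_cycle_pct / 100
    dose <- effective_dose(protocol, profile, mech)
    base[, 9] <- dose / profile$d_opt * seq(0, 1, length.out = nt)
  }
  base[, 3] <- bounded_walk(nt, 20, 24, if (spec$noise_level > 0) 0.2 else 0)
  base[, 4] <- bounded_walk(nt, 55, 65, if (spec$noise_level > 0) 0.5 else 0)
  seq_mat <- matrix(0, nt, spec$channels)
  seq_mat[, 1:9] <- base
  if (spec$channels >= 10) {
    seq_mat[, 10] <- if (spec$noise_level > 0) {
      stats::rnorm(nt, 0, 1)
    } else 0
  }
  if (spec$channels > 10) {
    for (j in 11:spec$channels) {
      src <- (j - 11) %% 9 + 1
      lag <- (j - 11) %% 7
      x <- base[, src]
      if (lag > 0) x <- c(rep(x[1], lag), x[seq_len(nt - lag)])
      if (spec$noise_level > 0) x <- x + stats::rnorm(nt, 0, spec$noise_level)
      seq_mat[, j] <- x
    }
  }
  seq_mat
}

# Morphology latents per variety (pixels / hue); small per-seed jitter.
variety_latent <- function(variety_index, jitter = TRUE) {
  base <- list(
    list(length_px = 40, width_px = 26, hue = 0.20, defect_density = 1),
    list(length_px = 46, width_px = 24, hue = 0.55, defect_density = 1),
    list(length_px = 36, width_px = 30, hue = 0.85, defect_density = 1)
  )[[variety_index]]
  if (jitter) {
    base$length_px <- base$length_px * stats::runif(1, 0.95, 1.05)
    base$width_px <- base$width_px * stats::runif(1, 0.95, 1.05)
    base$hue <- min(max(base$hue + stats::rnorm(1, 0, 0.02), 0), 1)
  }
  base
}

# Expected (noiseless) 8-target vector for a variety at a given dose.
expected_targets <- function(profile, dose) {
  dr <- dose_response(dose, profile)
  frac <- if (profile$delta_g_max > 0) dr$delta_g / profile$delta_g_max else 0
  g <- min(profile$control_germination_pct + dr$delta_g, 100)
  vi <- profile$control_vigor_index + dr$delta_vi
  len <- 100 * vi / max(g, 1e-9)
  u <- dose / profile$d_opt
  c(germination_pct = g,
    vigor_index = vi,
    t50 = profile$t50 * (1 - 0.15 * frac),
    k = profile$k_germ * (1 + 0.2 * frac),
    seedling_cm = len,
    root_cm = 0.75 * len,
    moisture_pct = 10 + 2 * u / (1 + u),
    conductivity_uS = 28 - 0.6 * dr$delta_g)
}

#' Generate a simulated seed dataset
#'
#' Builds the per-seed record table (and optionally paired image/sequence
#' arrays) for the given varieties over the factorial design. In
#' `mode = "dataset"` each variety contributes `n_per_variety` seeds
#' grouped into batches of `seeds_per_batch`, batches cycling through the
#' design cells (treatment cells plus control) and replicates — the
#' 3 x 2,000 = 6,000-record skeleton at defaults. In `mode = "factorial"`
#' every cell x replicate is a batch of `seeds_per_cell` seeds.
#' Phenotypes come from [simulate_batch()]; per-record 8-target vectors
#' are replicate-level expectations (`noiseless = TRUE`) or simulated
#' replicate summaries.
#'
#' @param design a [factorial_design()].
#' @param varieties list of [variety_profile()]s (default
#'   [default_varieties()]).
#' @param rng_seed root seed (substreams: phenotypes, images, sequences).
#' @param mode `"dataset"` or `"factorial"`.
#' @param n_per_variety seeds per variety in dataset mode.
#' @param seeds_per_batch batch size in dataset mode.
#' @param include_arrays also render image and sequence arrays (memory:
#'   about 150 MB per 1,000 records).
#' @param noiseless render arrays without noise and attach expected
#'   rather than simulated targets.
#' @param out_dir optional output directory; writes `records.csv`,
#'   `arrays.rds` (if arrays are included) and `manifest.json`.
#' @return A list with `records` (data frame), `targets` (matrix n x 8),
#'   `images`, `sequences` (arrays or `NULL`), `batches` (data frame).
#' @export
generate_dataset <- function(design = factorial_design(),
                             varieties = default_varieties(),
                             rng_seed = 1, mode = c("dataset", "factorial"),
                             n_per_variety = 2000, seeds_per_batch = 10,
                             include_arrays = FALSE, noiseless = FALSE,
                             out_dir = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(varieties) >= 1)
  cells <- enumerate_design(design)
  img_spec <- image_spec(noise_level = if (noiseless) 0 else 0.02)
  seq_spec <- sequence_spec(noise_level = if (noiseless) 0 else 0.02)

  # batch plan: one row per (variety, batch) with cell + replicate
  plan <- list()
  for (vi in seq_along(varieties)) {
    if (mode == "factorial") {
      n_batches <- nrow(cells) * design$replicates
      cell_idx <- rep(seq_len(nrow(cells)), each = design$replicates)
      repl <- rep(seq_len(design$replicates), times = nrow(cells))
      n_seeds <- rep(design$seeds_per_cell, n_batches)
    } else {
      n_batches <- ceiling(n_per_variety / seeds_per_batch)
      cell_idx <- (seq_len(n_batches) - 1) %% nrow(cells) + 1
      repl <- ((seq_len(n_batches) - 1) %/% nrow(cells)) %%
        design$replicates + 1
      n_seeds <- rep(seeds_per_batch, n_batches)
      extra <- n_batches * seeds_per_batch - n_per_variety
      if (extra > 0) n_seeds[n_batches] <- seeds_per_batch - extra
    }
    plan[[vi]] <- data.frame(variety_index = vi, batch = seq_along(cell_idx),
                             cell_index = cell_idx, replicate = repl,
                             n_seeds = n_seeds)
  }
  plan <- do.call(rbind, plan)
  plan$batch_id <- sprintf("v%d_r%d_%s", plan$variety_index, plan$replicate,
                           cells$cell_id[plan$cell_index])
  plan$batch_id <- make.unique(plan$batch_id, sep = "_b")

  pheno_seed <- substream_seed(rng_seed, "phenotypes")
  rec_list <- vector("list", nrow(plan))
  tgt_list <- vector("list", nrow(plan))
  for (b in seq_len(nrow(plan))) {
    row <- plan[b, ]
    profile <- varieties[[row$variety_index]]
    cell <- cells[row$cell_index, ]
    protocol <- cell_protocol(cell)
    if (noiseless) {
      profile_b <- profile
      profile_b$dispersion[] <- 0
    } else {
      profile_b <- profile
    }
    sim <- simulate_batch(profile_b, protocol, n_seeds = row$n_seeds,
                          n_replicates = 1,
                          rng_seed = (pheno_seed + b) %% 2147483647)
    recs <- sim$records
    recs$replicate <- row$replicate
    recs$batch_id <- row$batch_id
    recs$cell_id <- cell$cell_id
    rec_list[[b]] <- recs
    tgt <- if (noiseless) {
      expected_targets(profile, sim$dose)
    } else {
      oc <- sim$outcomes[[1]]
      u <- sim$dose / profile$d_opt
      c(germination_pct = oc$germination_pct, vigor_index = oc$vigor_index,
        t50 = oc$kinetics$t50, k = oc$kinetics$k,
        seedling_cm = oc$mean_seedling_length_cm,
        root_cm = oc$mean_root_length_cm,
        moisture_pct = 10 + 2 * u / (1 + u),
        conductivity_uS = 28 - 0.6 * (oc$germination_pct -
                                        profile$control_germination_pct))
    }
    tgt_list[[b]] <- matrix(tgt, nrow = row$n_seeds, ncol = 8, byrow = TRUE)
  }
  records <- do.call(rbind, rec_list)
  targets <- do.call(rbind, tgt_list)
  colnames(targets) <- c("germination_pct", "vigor_index", "t50", "k",
                         "seedling_cm", "root_cm", "moisture_pct",
                         "conductivity_uS")
  n <- nrow(records)

  images <- NULL; sequences <- NULL
  if (include_arrays) {
    img_seed <- substream_seed(rng_seed, "images")
    seq_seed <- substream_seed(rng_seed, "sequences")
    images <- array(0, dim = c(n, img_spec$height, img_spec$width, 3))
    sequences <- array(0, dim = c(n, seq_spec$timesteps, seq_spec$channels))
    vidx_of <- match(records$variety,
                     vapply(varieties, `[[`, "", "name"))
    old <- local_seed(img_seed)
    for (i in seq_len(n)) {
      lat <- variety_latent(vidx_of[i])
      images[i, , , ] <- render_seed_image(img_spec, lat)
    }
    restore_seed(old)
    old <- local_seed(seq_seed)
    # sequences are identical within a batch cell; render per record so
    # per-record noise stays independent
    for (i in seq_len(n)) {
      prof <- varieties[[vidx_of[i]]]
      prot <- if (records$field_strength_mT[i] > 0) {
        treatment_protocol(records$field_strength_mT[i],
                           records$frequency_Hz[i], records$duration_s[i],
                           records$voltage_amplitude_V[i],
                           records$pulse_width_ms[i],
                           records$duty_cycle_pct[i])
      } else NULL
      sequences[i, , ] <- render_sequence(seq_spec, prot, prof)
    }
    restore_seed(old)
  }

  out <- list(records = records, targets = targets, images = images,
              sequences = sequences, batches = plan)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(records, file.path(out_dir, "records.csv"),
                     row.names = FALSE)
    if (include_arrays) {
      saveRDS(list(images = images, sequences = sequences,
                   targets = targets),
              file.path(out_dir, "arrays.rds"))
    }
    manifest <- list(
      n_records = n, mode = mode, rng_seed = rng_seed,
      noiseless = noiseless,
      varieties = vapply(varieties, `[[`, "", "name"),
      files = list(records = "records.csv",
                   arrays = if (include_arrays) "arrays.rds" else NULL)
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}
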