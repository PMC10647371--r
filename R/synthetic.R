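# Synthetic study conditions: scenes of fish-shaped objects on a uniform
# board, each species carrying a distinct smooth reflectance curve
# (peaks/valleys/plateaus on 400-1000 nm) and a species-specific silhouette.
# Raw counts are constructed as reflectance x reference, so white-reference
# calibration inverts the construction exactly up to the injected noise.

#' Construct a species template
#'
#' A template couples a spectral model (shared smooth baseline plus a set of
#' species-specific Gaussian bumps/dips, scaled by the scene's spectral
#' separation knob delta) with an ellipse-based silhouette (length, aspect
#' ratio, tail taper).
#'
#' @param name species name.
#' @param bumps data frame with columns `center` (nm), `width` (nm),
#'   `amplitude` (signed reflectance units).
#' @param length_px body length in pixels (before scene scaling).
#' @param aspect length over maximum height.
#' @param taper tail-taper coefficient in `[0, 1)`: 0 keeps the ellipse,
#'   larger values thin the tail end.
#' @param size_jitter relative (lognormal) s.d. of the per-individual size.
#' @return Object of class `"species_template"`.
#' @export
species_template <- function(name, bumps, length_px = 150, aspect = 3.2,
                             taper = 0.4, size_jitter = 0.08) {
  stopifnot(is.data.frame(bumps),
            all(c("center", "width", "amplitude") %in% names(bumps)),
            length_px >= 20)
  structure(list(name = name, bumps = bumps, length_px = length_px,
                 aspect = aspect, taper = taper, size_jitter = size_jitter),
            class = "species_template")
}

# Shared smooth baseline: gentle NIR plateau, everything well inside (0, 1).
.base_curve <- function(wl) {
  0.35 + 0.1 * exp(-((wl - 850) / 260)^2)
}

#' Species reflectance curve
#'
#' `base(lambda) + delta * sum(bumps)`: at `delta = 1` the species are
#' maximally separated, at `delta = 0` all species share the baseline.
#'
#' @param template a [species_template()].
#' @param wavelengths nm vector.
#' @param delta spectral separation in `[0, 1]`.
#' @return Reflectance vector in (0, 1).
#' @export
template_curve <- function(template, wavelengths, delta = 1) {
  stopifnot(inherits(template, "species_template"), delta >= 0, delta <= 1)
  d <- numeric(length(wavelengths))
  for (i in seq_len(nrow(template$bumps))) {
    b <- template$bumps[i, ]
    d <- d + b$amplitude * exp(-((wavelengths - b$center) / b$width)^2)
  }
  .base_curve(wavelengths) + delta * d
}

#' The five default species templates
#'
#' Two species get distinctive silhouettes (one slender, one large); the
#' remaining three share a nearly identical body shape, so silhouette alone
#' cannot separate them while their spectra can — the regime in which the
#' spectral channel carries the classification. One template has a
#' pronounced spectral feature near 600 nm.
#'
#' @return Named list of five [species_template()] objects.
#' @export
default_templates <- function() {
  b <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    data.frame(center = m[, 1], width = m[, 2], amplitude = m[, 3])
  }
  list(
    `Engraulis ringens` = species_template(
      "Engraulis ringens", b(480, 30, 0.18, 650, 40, -0.12, 900, 60, 0.10),
      length_px = 160, aspect = 4.5, taper = 0.45),
    `Merluccius gayi` = species_template(
      "Merluccius gayi", b(600, 25, 0.25, 450, 30, -0.10),
      length_px = 220, aspect = 3.0, taper = 0.30),
    `Normanichthys crockeri` = species_template(
      "Normanichthys crockeri", b(520, 30, 0.15, 750, 50, 0.12,
                                  430, 25, -0.08),
      length_px = 150, aspect = 3.2, taper = 0.40),
    `Stromateus stellatus` = species_template(
      "Stromateus stellatus", b(550, 35, -0.15, 820, 60, 0.18),
      length_px = 152, aspect = 3.2, taper = 0.40),
    `Strangomera bentincki` = species_template(
      "Strangomera bentincki", b(460, 25, 0.12, 700, 45, -0.14,
                                 950, 60, 0.15),
      length_px = 148, aspect = 3.2, taper = 0.40))
}

#' Scene specification
#'
#' @param species_counts named integer vector (template name -> number of
#'   fish); default one of each default species.
#' @param dims scene raster `c(lines, pixels)`.
#' @param bands number of spectral bands.
#' @param range wavelength range in nm.
#' @param board_reflectance flat board reflectance.
#' @param noise_sd multiplicative lognormal pixel-noise sigma.
#' @param texture smooth low-frequency surface texture on each fish body
#'   (in body-normalized coordinates, so its statistics are independent of
#'   body size); the board itself stays flat.
#' @param texture_range gain-field range.
#' @param delta spectral separation in `[0, 1]`.
#' @param fish_scale global silhouette scale factor.
#' @param seed integer seed.
#' @return Object of class `"scene_spec"`.
#' @export
scene_spec <- function(species_counts = NULL, dims = c(400L, 600L),
                       bands = 281L, range = c(400, 1000),
                       board_reflectance = 0.15, noise_sd = 0.02,
                       texture = TRUE, texture_range = c(0.8, 1.2),
                       delta = 1, fish_scale = 1, seed = 1L) {
  if (is.null(species_counts)) {
    species_counts <- stats::setNames(rep(1L, 5), names(default_templates()))
  }
  stopifnot(all(species_counts >= 0), delta >= 0, delta <= 1)
  structure(list(species_counts = species_counts, dims = as.integer(dims),
                 bands = as.integer(bands), range = range,
                 board_reflectance = board_reflectance, noise_sd = noise_sd,
                 texture = texture, texture_range = texture_range,
                 delta = delta, fish_scale = fish_scale,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# Tapered-ellipse silhouette on the scene grid. Returns the mask plus the
# body-normalized coordinates of the mask pixels (for surface texture).
.silhouette <- function(dims, center, length_px, aspect, taper, angle_deg) {
  a <- length_px / 2
  bb <- length_px / (2 * aspect)
  th <- angle_deg * pi / 180
  r <- matrix(seq_len(dims[1]), dims[1], dims[2]) - center[1]
  cc <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE) - center[2]
  u <- cos(th) * cc + sin(th) * r
  v <- -sin(th) * cc + cos(th) * r
  h <- bb * (1 - taper * (u + a) / (2 * a)) # tail (u = +a) thinner than head
  ok <- h > 0 & abs(u) <= a
  m <- matrix(FALSE, dims[1], dims[2])
  m[ok] <- (u[ok] / a)^2 + (v[ok] / h[ok])^2 <= 1
  list(mask = m, un = u[m] / a, vn = v[m] / bb)
}

# Smooth low-frequency surface texture in body coordinates: every fish sees
# the same statistical structure relative to its own body, whatever its
# absolute size, so region-of-interest means carry no silhouette (and hence
# no species) information.
.fish_texture <- function(un, vn, lo, hi) {
  g <- numeric(length(un))
  for (k in 1:3) {
    f <- stats::runif(2, 0.5, 2)
    ph <- stats::runif(1, 0, 2 * pi)
    g <- g + stats::runif(1, 0.5, 1) * cos(pi * (f[1] * un + f[2] * vn) + ph)
  }
  rg <- range(g)
  if (diff(rg) < 1e-12) return(rep((lo + hi) / 2, length(un)))
  lo + (hi - lo) * (g - rg[1]) / diff(rg)
}

#' Generate a raw scene, its reference frame and ground truth
#'
#' Places the requested fish at random non-overlapping poses on the flat
#' board, assigns each its species reflectance curve modulated by a smooth
#' per-fish surface texture, adds per-pixel lognormal noise, and converts
#' reflectance to raw counts through a synthetic lamp-plus-vignetting
#' reference frame — so [calibrate_reflectance()] recovers the reflectance
#' field exactly up to the injected noise.
#'
#' @param spec a [scene_spec()].
#' @param templates named list of [species_template()] objects.
#' @return List with `raw` (uncalibrated [hypercube()]), `reference`
#'   (a [reference_frame()]) and `truth` (list of `list(mask, label)` with
#'   exact [fish_mask()]s).
#' @export
generate_scene <- function(spec, templates = default_templates()) {
  stopifnot(inherits(spec, "scene_spec"))
  miss <- setdiff(names(spec$species_counts), names(templates))
  if (length(miss)) stop("no template for: ", paste(miss, collapse = ", "))
  with_seed(spec$seed, {
    N <- spec$dims[1]; M <- spec$dims[2]; Lc <- spec$bands
    wl <- seq(spec$range[1], spec$range[2], length.out = Lc)
    occupied <- matrix(FALSE, N, M)
    truth <- list()
    # wide dilation keeps placed fish far enough apart that morphological
    # closing during segmentation cannot bridge them
    brush <- EBImage::makeBrush(9L, "box")
    for (sp in names(spec$species_counts)) {
      tmpl <- templates[[sp]]
      for (rep_i in seq_len(spec$species_counts[[sp]])) {
        len <- tmpl$length_px * spec$fish_scale *
          exp(stats::rnorm(1, 0, tmpl$size_jitter))
        placed <- FALSE
        for (try_i in 1:200) {
          margin <- len / 2 + 4
          if (2 * margin >= min(N, M)) break
          ctr <- c(stats::runif(1, margin, N - margin),
                   stats::runif(1, margin, M - margin))
          ang <- stats::runif(1, -20, 20)
          sil <- .silhouette(c(N, M), ctr, len, tmpl$aspect, tmpl$taper, ang)
          m <- sil$mask
          if (!any(m)) next
          grown <- EBImage::dilate(matrix(as.numeric(m), N), brush) > 0.5
          if (!any(grown & occupied)) {
            occupied <- occupied | m
            gain <- if (spec$texture)
              .fish_texture(sil$un, sil$vn, spec$texture_range[1],
                            spec$texture_range[2])
            else rep(1, sum(m))
            truth[[length(truth) + 1]] <- list(mask = fish_mask(m),
                                               label = tmpl$name,
                                               gain = gain)
            placed <- TRUE
            break
          }
        }
        if (!placed) stop("cannot place fish without overlap; enlarge the ",
                          "scene or reduce fish_scale")
      }
    }
    refl <- matrix(spec$board_reflectance, N * M, Lc) # board is flat
    for (tr in truth) {
      curve <- template_curve(templates[[tr$label]], wl, spec$delta)
      n_px <- sum(tr$mask$mask)
      refl[as.vector(tr$mask$mask), ] <-
        matrix(curve, n_px, Lc, byrow = TRUE) * tr$gain
    }
    lamp <- 2000 * (0.6 + 0.4 * exp(-((wl - 780) / 260)^2))
    vign <- 0.92 + 0.08 * cos((seq_len(M) - (M + 1) / 2) / M * pi)
    ref <- outer(vign, lamp) # M x Lc
    col_of <- rep(seq_len(M), each = N)
    counts <- matrix(0, N * M, Lc)
    for (c in seq_len(Lc)) {
      noise <- if (spec$noise_sd > 0)
        stats::rlnorm(N * M, 0, spec$noise_sd) else 1
      counts[, c] <- refl[, c] * noise * ref[col_of, c]
    }
    truth <- lapply(truth, function(tr) tr[c("mask", "label")])
    list(raw = hypercube(array(counts, c(N, M, Lc)), wl, calibrated = FALSE),
         reference = reference_frame(ref, wl),
         truth = truth)
  })
}

# Resample the rows of a spectra matrix onto lc_prime even wavelengths.
.resample_rows <- function(mat, wl, lc_prime) {
  if (lc_prime == length(wl)) return(mat)
  xout <- seq(min(wl), max(wl), length.out = lc_prime)
  lo <- pmin(findInterval(xout, wl), length(wl) - 1L)
  f <- (xout - wl[lo]) / (wl[lo + 1L] - wl[lo])
  mat[, lo, drop = FALSE] * rep(1 - f, each = nrow(mat)) +
    mat[, lo + 1L, drop = FALSE] * rep(f, each = nrow(mat))
}

#' Generate provided (unaugmented) samples through the full chain
#'
#' Generates as many scenes as needed to yield the requested number of
#' physical fish per species (at most `max_fish_per_scene` per scene),
#' calibrates each scene, segments the fish (falling back to the exact
#' ground-truth mask when a detection overlaps poorly), and extracts per
#' fish an RoI signature, a masked-pixel bank for later signature redraws,
#' and a standardized RGB image.
#'
#' @param provided_counts named integer vector: physical fish per species.
#' @param scene a [scene_spec()] blueprint (its species counts and seed are
#'   overridden per generated scene).
#' @param templates named list of [species_template()]s.
#' @param lc_prime signature length `Lc'`.
#' @param P pixels per RoI.
#' @param bank_px masked-pixel bank size kept per fish.
#' @param seed master seed.
#' @param size standardized image side.
#' @param max_fish_per_scene packing limit per scene.
#' @return An unbalanced [fish_dataset()] of provided samples with banks.
#' @export
generate_originals <- function(provided_counts, scene = scene_spec(),
                               templates = default_templates(),
                               lc_prime = 200L, P = 256L, bank_px = 1024L,
                               seed = 1L, size = 256L,
                               max_fish_per_scene = 6L) {
  species <- names(templates)
  stopifnot(all(names(provided_counts) %in% species))
  wl <- seq(scene$range[1], scene$range[2], length.out = scene$bands)
  sens <- .sensitivity_from_table(default_sensitivity_table())
  # coarse test grids can leave some 10-nm camera channels empty; the zero
  # columns are harmless here
  proj <- suppressWarnings(build_projection_matrix(wl, sens$wavelengths))
  # plan scenes: deal remaining fish round-robin across species
  remaining <- provided_counts
  plans <- list()
  while (sum(remaining) > 0) {
    take <- stats::setNames(integer(length(remaining)), names(remaining))
    budget <- max_fish_per_scene
    while (budget > 0 && sum(remaining - take) > 0) {
      for (sp in names(remaining)) {
        if (budget == 0) break
        if (take[[sp]] < remaining[[sp]]) {
          take[[sp]] <- take[[sp]] + 1L
          budget <- budget - 1L
        }
      }
    }
    plans[[length(plans) + 1]] <- take[take > 0]
    remaining <- remaining - take
  }
  n_scenes <- length(plans)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, 2L * n_scenes))
  meta <- list(); images <- list(); sigs <- list(); banks <- list()
  k <- 0L
  for (s in seq_len(n_scenes)) {
    sc <- scene
    sc$species_counts <- plans[[s]]
    sc$seed <- seeds[s]
    gen <- generate_scene(sc, templates)
    cal <- calibrate_reflectance(gen$raw, gen$reference)
    dets <- tryCatch(segment_fish(cal), error = function(e) list())
    roi_seeds <- with_seed(seeds[n_scenes + s],
                           sample.int(.Machine$integer.max,
                                      2L * length(gen$truth)))
    for (fi in seq_along(gen$truth)) {
      tr <- gen$truth[[fi]]
      m <- .best_mask(tr$mask, dets)
      cr <- crop_fish(cal, m)
      area <- sum(cr$mask$mask)
      rois <- sample_rois(cr$mask, R = 1L, P = min(P, area),
                          seed = roi_seeds[fi])
      sig <- roi_signatures(cr$cube, rois, lc_prime = lc_prime)$signatures[1, ]
      img <- standardize_image(render_rgb(cr$cube, proj, sens), cr$mask,
                               size = size)
      k <- k + 1L
      id <- sprintf("sc%03d_f%d", s, fi)
      meta[[k]] <- data.frame(id = id, label = tr$label, kind = "provided",
                              source_id = id, aug_seed = NA_integer_,
                              roi_seed = roi_seeds[fi],
                              stringsAsFactors = FALSE)
      images[[k]] <- .img_encode(img$pixels)
      sigs[[k]] <- sig
      d <- dim(cr$cube$data)
      px_mat <- matrix(cr$cube$data, d[1] * d[2],
                       d[3])[as.vector(cr$mask$mask), , drop = FALSE]
      take <- with_seed(roi_seeds[length(gen$truth) + fi],
                        sample.int(nrow(px_mat), min(bank_px, nrow(px_mat))))
      banks[[id]] <- .resample_rows(px_mat[take, , drop = FALSE], wl, lc_prime)
    }
  }
  wl_out <- if (lc_prime == scene$bands) wl
  else seq(min(wl), max(wl), length.out = lc_prime)
  fish_dataset(do.call(rbind, meta), images, do.call(rbind, sigs), wl_out,
               classes = sort(names(provided_counts)), banks = banks,
               size = size)
}

#' Run the full synthetic experiment chain to a balanced dataset
#'
#' [generate_originals()] (equal provided counts per species) followed by
#' [balance_dataset()] up to `n_per_class`.
#'
#' @param n_per_class target samples per class after balancing.
#' @param originals_per_class provided (physical) fish per class.
#' @param scene a [scene_spec()] blueprint.
#' @param templates named list of [species_template()]s.
#' @param lc_prime signature length `Lc'`.
#' @param P pixels per RoI.
#' @param bank_px masked-pixel bank size kept per fish.
#' @param seed master seed; the whole dataset is reproducible from it.
#' @param materialize_images build all augmented images now.
#' @param ranges [aug_ranges()] for image augmentation.
#' @param size standardized image side.
#' @param max_fish_per_scene packing limit per scene.
#' @return A balanced [fish_dataset()].
#' @export
generate_experiment <- function(n_per_class, originals_per_class = 20L,
                                scene = scene_spec(),
                                templates = default_templates(),
                                lc_prime = 200L, P = 256L, bank_px = 1024L,
                                seed = 1L, materialize_images = TRUE,
                                ranges = aug_ranges(), size = 256L,
                                max_fish_per_scene = length(templates)) {
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, 2L))
  counts <- stats::setNames(rep(as.integer(originals_per_class),
                                length(templates)), names(templates))
  originals <- generate_originals(counts, scene = scene,
                                  templates = templates, lc_prime = lc_prime,
                                  P = P, bank_px = bank_px, seed = seeds[1],
                                  size = size,
                                  max_fish_per_scene = max_fish_per_scene)
  balance_dataset(originals, n_per_class, seed = seeds[2],
                  materialize_images = materialize_images, ranges = ranges,
                  P = P)
}

# Match a ground-truth mask to the best-overlapping detection (Jaccard >=
# 0.5), falling back to the truth mask itself.
.best_mask <- function(truth_mask, detections) {
  best <- NULL; best_j <- 0
  for (d in detections) {
    inter <- sum(truth_mask$mask & d$mask)
    if (inter == 0) next
    j <- inter / sum(truth_mask$mask | d$mask)
    if (j > best_j) { best_j <- j; best <- d }
  }
  if (best_j >= 0.5) best else truth_mask
}

.sensitivity_from_table <- function(df) {
  structure(list(response = as.matrix(df[, c("R", "G", "B")]),
                 wavelengths = df$wavelength_nm),
            class = "sensitivity_matrix")
}
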