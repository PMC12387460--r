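# Seeded generator of three-class CT-like phantom slices: a dark background,
# two bright elliptical lung fields, and class-conditional nodule content
# (none / smooth disc / irregular star-convex blob with internal texture).
# Visual separability is by construction; the generator is the test bed for
# every pipeline stage, not a radiological simulation.

PHANTOM_CLASSES <- c("benign", "malignant", "normal")

#' Specification of one phantom image
#'
#' Class-conditional defaults: a benign nodule is a smooth disc
#' (irregularity forced to 0, low texture contrast, radius 0.055 * size); a
#' malignant nodule is a star-convex blob (irregularity 0.6, texture
#' contrast 0.5, radius 0.075 * size); the normal class has no nodule.
#' Intensities: background 0.03, lung fields 0.35, nodule core 0.9.
#'
#' @param class_label one of `"benign"`, `"malignant"`, `"normal"`
#' @param size square image size in pixels (default 224)
#' @param nodule_radius_px nodule radius; default scales with size
#' @param irregularity boundary irregularity in \[0, 1\]; 0 is a perfect disc
#' @param texture_contrast amplitude of internal high-frequency texture
#' @param noise_sigma additive Gaussian noise level (default 0.01)
#' @param seed integer seed; generation is bit-identical for identical specs
#' @return object of class `phantom_spec`
#' @export
phantom_spec <- function(class_label, size = 224, nodule_radius_px = NULL,
                         irregularity = NULL, texture_contrast = NULL,
                         noise_sigma = 0.01, seed = 1) {
  class_label <- match.arg(class_label, PHANTOM_CLASSES)
  if (is.null(nodule_radius_px)) {
    nodule_radius_px <- switch(class_label,
      benign = 0.055 * size, malignant = 0.075 * size, normal = 0)
  }
  if (is.null(irregularity)) {
    irregularity <- if (class_label == "malignant") 0.6 else 0
  }
  if (class_label == "benign") irregularity <- 0 # smooth by definition
  if (is.null(texture_contrast)) {
    texture_contrast <- switch(class_label,
      benign = 0.1, malignant = 0.5, normal = 0)
  }
  structure(list(class_label = class_label, size = size,
                 nodule_radius_px = nodule_radius_px,
                 irregularity = irregularity,
                 texture_contrast = texture_contrast,
                 noise_sigma = noise_sigma, seed = seed),
            class = "phantom_spec")
}

# the two elliptical lung fields as a logical mask
lung_field_mask <- function(size) {
  yy <- matrix(seq_len(size), size, size)
  xx <- t(yy)
  cy <- 0.52 * size
  ax <- 0.16 * size
  ay <- 0.30 * size
  left <- ((xx - 0.30 * size) / ax)^2 + ((yy - cy) / ay)^2 <= 1
  right <- ((xx - 0.70 * size) / ax)^2 + ((yy - cy) / ay)^2 <= 1
  left | right
}

#' Generate one phantom image
#'
#' The random stream is consumed in a fixed order (noise field, nodule
#' placement, boundary profile, texture phases) regardless of class, so two
#' specs differing only in `class_label` share background and noise and
#' differ only inside the nodule support. The support mask is attached as
#' attribute `"nodule_mask"` (the generator's own geometry oracle).
#'
#' @param spec a [phantom_spec()]
#' @return a `labeled_image` whose `pixels` are an `[size, size]` matrix in
#'   \[0, 1\]
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  s <- spec$size
  with_seed(spec$seed, {
    noise <- matrix(rnorm(s * s, 0, 1), s, s)
    side <- sample(c(0.30, 0.70), 1)
    jitter <- runif(2, -0.05, 0.05)
    n_harm <- 6
    harm_amp <- runif(n_harm, 0, 1)
    harm_phase <- runif(n_harm, 0, 2 * pi)
    tex_freq <- runif(1, 0.25, 0.45)
    tex_phase <- runif(2, 0, 2 * pi)

    img <- matrix(0.03, s, s)
    lungs <- lung_field_mask(s)
    img[lungs] <- 0.35
    mask <- matrix(FALSE, s, s)
    if (spec$class_label != "normal" && spec$nodule_radius_px > 0) {
      cx <- (side + jitter[1]) * s
      cy <- (0.52 + jitter[2]) * s
      yy <- matrix(seq_len(s), s, s)
      xx <- t(yy)
      dx <- xx - cx
      dy <- yy - cy
      dist <- sqrt(dx^2 + dy^2)
      theta <- atan2(dy, dx)
      # star-convex radial profile; irregularity 0 gives a perfect disc
      rad <- spec$nodule_radius_px
      prof <- rep(1, length(theta))
      if (spec$irregularity > 0) {
        prof <- 1 + spec$irregularity * 0.45 *
          Reduce(`+`, lapply(seq_len(n_harm), function(k) {
            harm_amp[k] / n_harm * cos(k * as.vector(theta) + harm_phase[k]) * 2
          }))
      }
      rmap <- matrix(rad * prof, s, s)
      mask <- dist <= rmap
      core <- 0.9 * clip01(1.15 - (dist / pmax(rmap, 1e-9))^2)
      if (spec$texture_contrast > 0) {
        tex <- 0.5 * spec$texture_contrast *
          (0.5 + 0.5 * sin(2 * pi * tex_freq * xx + tex_phase[1]) *
             sin(2 * pi * tex_freq * yy + tex_phase[2]))
        core <- core + tex
      }
      img[mask] <- pmax(img[mask], core[mask])
    }
    if (spec$noise_sigma > 0) img <- img + spec$noise_sigma * noise
    img <- clip01(img)
    structure(list(pixels = structure(img, nodule_mask = mask),
                   label = spec$class_label,
                   id = sprintf("phantom-%s-s%d-seed%d", spec$class_label,
                                s, spec$seed),
                   provenance = "raw"),
              class = "labeled_image")
  })
}

#' Generate a labeled phantom dataset
#'
#' Per-image seeds are derived from the master seed by a documented counter
#' scheme (`derive_seed(master, counter)` with a global image counter), so
#' the dataset is reproducible and images are pairwise distinct.
#'
#' @param n_per_class named vector/list of counts, names among the three
#'   class labels (e.g. `c(benign = 5, malignant = 5, normal = 5)`)
#' @param seed master seed
#' @param size image size in pixels (default 224; tests use 64)
#' @param noise_sigma noise level forwarded to every spec
#' @return list of `labeled_image` objects
#' @export
generate_dataset <- function(n_per_class, seed = 1, size = 224,
                             noise_sigma = 0.01) {
  n_per_class <- unlist(n_per_class)
  stopifnot(all(names(n_per_class) %in% PHANTOM_CLASSES),
            all(n_per_class >= 1))
  out <- list()
  counter <- 0L
  for (cl in names(n_per_class)) {
    for (i in seq_len(n_per_class[[cl]])) {
      counter <- counter + 1L
      sp <- phantom_spec(cl, size = size, noise_sigma = noise_sigma,
                         seed = derive_seed(seed, counter))
      im <- generate_phantom(sp)
      im$id <- sprintf("%s-%04d", im$id, counter)
      out[[length(out) + 1]] <- im
    }
  }
  out
}

#' Write a dataset as a class-folder tree of PNG files
#'
#' Produces the one-folder-per-class layout that
#' [load_class_folder_dataset()] reads, plus a `manifest.csv` with columns
#' id, path, label, provenance.
#'
#' @param items list of `labeled_image` objects
#' @param dir output directory (created if needed)
#' @return invisibly, the manifest data frame
#' @export
write_image_dataset <- function(items, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(items), function(i) {
    im <- items[[i]]
    cls_dir <- file.path(dir, im$label)
    dir.create(cls_dir, showWarnings = FALSE)
    fname <- sprintf("%05d.png", i)
    path <- file.path(cls_dir, fname)
    px <- clip01(im$pixels)
    attributes(px) <- list(dim = dim(px))
    png::writePNG(px, path)
    data.frame(id = im$id, path = file.path(im$label, fname),
               label = im$label, provenance = im$provenance,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
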