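# Image ingestion, stratified splitting, augmentation and class balancing.
#
# The pipeline default is split-then-augment: raw slices are partitioned
# first and only the training partition is balanced/augmented, so augmented
# descendants can never leak across the split. A "paper-protocol" flag
# balances the full set before splitting, reproducing the published counts
# at the cost of near-duplicate leakage (kept only for comparability).

#' Construct a labeled image
#'
#' @param pixels numeric `[H, W]` matrix (or `[H, W, 3]` array) in \[0, 1\]
#' @param label class label string
#' @param id opaque identifier
#' @param provenance `"raw"` or `"augmented"`
#' @return object of class `labeled_image`
#' @export
labeled_image <- function(pixels, label, id, provenance = "raw") {
  structure(list(pixels = pixels, label = label, id = id,
                 provenance = provenance), class = "labeled_image")
}

to_gray <- function(px) {
  if (length(dim(px)) == 3) {
    if (dim(px)[3] >= 3) {
      # ITU-R 601 luminance
      px <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
    } else {
      px <- px[, , 1]
    }
  }
  px
}

read_image_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE)) {
        stop_lungsop("lungsop_unreadable_file", "jpeg reader not available")
      }
      jpeg::readJPEG(path)
    },
    pgm = ,
    pnm = read_pnm(path),
    stop_lungsop("lungsop_unreadable_file",
                 sprintf("unsupported image extension '%s'", ext))
  )
  clip01(to_gray(px))
}

#' Load a one-folder-per-class image dataset
#'
#' Reads every image below `root/<class>/`, converts to grayscale, resizes
#' to `size x size` (bilinear) and normalizes to \[0, 1\]. Ordering is
#' deterministic (lexicographic by class then filename). Unreadable files
#' are skipped with a warning; the skip count is attached as attribute
#' `"n_skipped"`.
#'
#' @param root dataset root containing one subdirectory per class
#' @param size output size (default 224)
#' @return list of `labeled_image` objects
#' @export
load_class_folder_dataset <- function(root, size = 224) {
  dirs <- sort(list.dirs(root, recursive = FALSE))
  if (length(dirs) == 0) {
    stop_lungsop("lungsop_empty_class", "no class folders found")
  }
  out <- list()
  n_skipped <- 0L
  for (d in dirs) {
    cls <- basename(d)
    files <- sort(list.files(d, pattern = "\\.(png|jpg|jpeg|pgm|pnm)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0) {
      stop_lungsop("lungsop_empty_class",
                   sprintf("class folder '%s' has no readable images", cls))
    }
    for (f in files) {
      px <- tryCatch(read_image_file(f), error = function(e) NULL)
      if (is.null(px)) {
        warn_lungsop("lungsop_unreadable_file", sprintf("skipping '%s'", f))
        n_skipped <- n_skipped + 1L
        next
      }
      if (!all(dim(px)[1:2] == c(size, size))) {
        px <- resize_bilinear(px, size, size)
      }
      out[[length(out) + 1]] <- labeled_image(clip01(px), cls,
                                              paste(cls, basename(f), sep = "/"))
    }
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Split specification
#'
#' @param fractions named fractions summing to 1 (default 0.70/0.15/0.15)
#' @param seed shuffle seed
#' @param level `"slice"` (each image independent) or `"group"` (items
#'   sharing a group key stay together)
#' @return object of class `split_spec`
#' @export
split_spec <- function(fractions = c(train = 0.70, val = 0.15, test = 0.15),
                       seed = 1, level = c("slice", "group")) {
  level <- match.arg(level)
  if (abs(sum(fractions) - 1) > 1e-9 || length(fractions) != 3) {
    stop_lungsop("lungsop_config_error", "fractions must be three values summing to 1")
  }
  structure(list(fractions = fractions, seed = seed, level = level),
            class = "split_spec")
}

# largest-remainder apportionment of n items into the given fractions;
# ties go to the earlier partition (train, then val, then test)
apportion <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- raw - base
    ord <- order(-frac, seq_along(frac)) # stable: earlier partition wins ties
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  base
}

#' Stratified train/validation/test split
#'
#' Partitions per class using largest-remainder apportionment (within one
#' item of the exact fractions), deterministic given the seed. At group
#' level, all items sharing `$group` (falling back to `$id`) are kept in one
#' partition.
#'
#' @param items list of `labeled_image` objects
#' @param spec a [split_spec()]
#' @return named list of three disjoint item lists (`train`, `val`, `test`)
#' @export
stratified_split <- function(items, spec = split_spec()) {
  stopifnot(inherits(spec, "split_spec"))
  labels <- vapply(items, function(x) x$label, character(1))
  keys <- if (spec$level == "group") {
    vapply(items, function(x) if (!is.null(x$group)) x$group else x$id,
           character(1))
  } else {
    as.character(seq_along(items))
  }
  parts <- list(train = integer(0), val = integer(0), test = integer(0))
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    units <- split(idx, keys[idx])
    if (length(units) < 3) {
      stop_lungsop("lungsop_insufficient_class",
                   sprintf("class '%s' has fewer than 3 units", cl))
    }
    units <- units[order(names(units))]
    perm <- with_seed(spec$seed + match(cl, sort(unique(labels))),
                      sample.int(length(units)))
    units <- units[perm]
    counts <- apportion(length(units), spec$fractions)
    bounds <- cumsum(counts)
    parts$train <- c(parts$train, unlist(units[seq_len(bounds[1])]))
    if (counts[2] > 0) {
      parts$val <- c(parts$val, unlist(units[(bounds[1] + 1):bounds[2]]))
    }
    if (counts[3] > 0) {
      parts$test <- c(parts$test, unlist(units[(bounds[2] + 1):bounds[3]]))
    }
  }
  lapply(parts, function(ix) items[sort(ix)])
}

# ---- augmentation ops --------------------------------------------------------

reflect_index <- function(i, n) {
  # mirror boundary: ... 3 2 1 | 1 2 3 ... n | n n-1 ...
  p <- 2 * n
  j <- ((i - 1) %% p + p) %% p + 1
  ifelse(j > n, p - j + 1, j)
}

aug_rotation <- function(px, angle_deg) {
  th <- angle_deg * pi / 180
  h <- nrow(px); w <- ncol(px)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  yy <- rep(seq_len(h), times = w) - cy
  xx <- rep(seq_len(w), each = h) - cx
  sy <- cy + (-sin(-th) * xx + cos(-th) * yy)
  sx <- cx + (cos(-th) * xx + sin(-th) * yy)
  matrix(interp_bilinear(px, sy, sx, fill = 0), h, w)
}

aug_zoom <- function(px, factor) {
  h <- nrow(px); w <- ncol(px)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  yy <- (rep(seq_len(h), times = w) - cy) / factor + cy
  xx <- (rep(seq_len(w), each = h) - cx) / factor + cx
  matrix(interp_bilinear(px, yy, xx, fill = 0), h, w)
}

aug_shift <- function(px, dx_frac = 0, dy_frac = 0) {
  h <- nrow(px); w <- ncol(px)
  dy <- round(dy_frac * h); dx <- round(dx_frac * w)
  rows <- reflect_index(seq_len(h) - dy, h)
  cols <- reflect_index(seq_len(w) - dx, w)
  px[rows, cols, drop = FALSE]
}

aug_shear <- function(px, shear_frac) {
  h <- nrow(px); w <- ncol(px)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  yy <- rep(seq_len(h), times = w)
  xx <- rep(seq_len(w), each = h) - shear_frac * (yy - cy)
  matrix(interp_bilinear(px, yy, xx, fill = 0), h, w)
}

aug_crop <- function(px, crop_frac) {
  h <- nrow(px); w <- ncol(px)
  mh <- max(1L, round(crop_frac * h)); mw <- max(1L, round(crop_frac * w))
  inner <- px[(mh + 1):(h - mh), (mw + 1):(w - mw), drop = FALSE]
  resize_bilinear(inner, h, w)
}

#' Apply one augmentation operation
#'
#' Geometric ops use bilinear interpolation (rotation/zoom fill with 0,
#' shifts use reflection padding); photometric ops clip back to \[0, 1\].
#' The output id records parent, op and parameters; provenance is
#' `"augmented"`.
#'
#' @param img a `labeled_image`
#' @param op one of `"rotation"`, `"brightness"`, `"zoom"`, `"width_shift"`,
#'   `"height_shift"`, `"horizontal_flip"`, `"gaussian_noise"`,
#'   `"salt_pepper_noise"`, `"shear"`, `"crop"`
#' @param params named list of op parameters (e.g. `list(angle = 10)`)
#' @param rng_seed seed for the stochastic noise ops
#' @return augmented `labeled_image`
#' @export
augment_one <- function(img, op, params = list(), rng_seed = 1) {
  px <- unclass_pixels(img$pixels)
  out <- switch(op,
    rotation = aug_rotation(px, params$angle %||% 0),
    brightness = px * (1 + (params$delta %||% 0)),
    zoom = aug_zoom(px, params$factor %||% 1),
    width_shift = aug_shift(px, dx_frac = params$frac %||% 0),
    height_shift = aug_shift(px, dy_frac = params$frac %||% 0),
    horizontal_flip = px[, rev(seq_len(ncol(px))), drop = FALSE],
    gaussian_noise = {
      sg <- params$sigma %||% 0
      if (sg > 0) px + with_seed(rng_seed, matrix(rnorm(length(px), 0, sg),
                                                  nrow(px), ncol(px)))
      else px
    },
    salt_pepper_noise = {
      dens <- params$density %||% 0
      if (dens > 0) {
        with_seed(rng_seed, {
          n <- length(px)
          k <- round(dens * n)
          pos <- sample.int(n, min(2 * k, n))
          px[pos[seq_len(k)]] <- 1
          if (length(pos) > k) px[pos[(k + 1):length(pos)]] <- 0
          px
        })
      } else px
    },
    shear = aug_shear(px, params$frac %||% 0),
    crop = aug_crop(px, params$frac %||% 0.05),
    stop_lungsop("lungsop_config_error", sprintf("unknown augmentation op '%s'", op))
  )
  par_str <- paste(vapply(params, function(v) format(v, digits = 4),
                          character(1)), collapse = ",")
  labeled_image(clip01(out), img$label,
                sprintf("%s|%s(%s)", img$id, op, par_str), "augmented")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

unclass_pixels <- function(px) {
  attributes(px) <- list(dim = dim(px))
  px
}

#' Augmentation plan
#'
#' The six applied techniques (rotation, brightness, zoom, width shift,
#' height shift, horizontal flip) plus the two noise resampling ops, with
#' configurable parameter ranges. Defaults: rotation +/-15 degrees,
#' brightness +/-20%, zoom 0.9-1.1, shifts +/-10%, Gaussian sigma 0.01,
#' salt-and-pepper density 0.002. Shearing and cropping are implemented but
#' disabled by default.
#'
#' @param target_counts named vector, class -> target item count
#' @param seed plan seed (drives all op/parameter sampling)
#' @param ops character vector of enabled op names
#' @param ranges named list of per-op parameter ranges
#' @return object of class `augment_plan`
#' @export
augment_plan <- function(target_counts, seed = 1,
                         ops = c("rotation", "brightness", "zoom",
                                 "width_shift", "height_shift",
                                 "horizontal_flip", "gaussian_noise",
                                 "salt_pepper_noise"),
                         ranges = NULL) {
  defaults <- list(
    rotation = c(-15, 15), brightness = c(-0.2, 0.2), zoom = c(0.9, 1.1),
    width_shift = c(-0.1, 0.1), height_shift = c(-0.1, 0.1),
    horizontal_flip = c(0.5, 0.5), gaussian_noise = c(0.01, 0.01),
    salt_pepper_noise = c(0.002, 0.002), shear = c(-0.1, 0.1),
    crop = c(0.02, 0.08)
  )
  if (!is.null(ranges)) defaults[names(ranges)] <- ranges
  missing_range <- setdiff(ops, names(defaults))
  if (length(missing_range)) {
    stop_lungsop("lungsop_config_error",
                 sprintf("no range for op(s): %s", paste(missing_range, collapse = ", ")))
  }
  structure(list(ops = ops, ranges = defaults[ops],
                 target_counts = unlist(target_counts), seed = seed),
            class = "augment_plan")
}

sample_op_params <- function(op, range) {
  switch(op,
    rotation = list(angle = runif(1, range[1], range[2])),
    brightness = list(delta = runif(1, range[1], range[2])),
    zoom = list(factor = runif(1, range[1], range[2])),
    width_shift = ,
    height_shift = list(frac = runif(1, range[1], range[2])),
    horizontal_flip = list(),
    gaussian_noise = list(sigma = runif(1, range[1], range[2])),
    salt_pepper_noise = list(density = runif(1, range[1], range[2])),
    shear = list(frac = runif(1, range[1], range[2])),
    crop = list(frac = runif(1, range[1], range[2]))
  )
}

#' Balance classes by augmentation up to exact target counts
#'
#' Raw images are always retained; each class is topped up to exactly its
#' target count by cycling through its source images and drawing an enabled
#' op with parameters from the plan's seeded stream.
#'
#' @param items list of `labeled_image` objects
#' @param plan an [augment_plan()]
#' @return list of exactly `sum(target_counts)` items
#' @export
balance_classes <- function(items, plan) {
  stopifnot(inherits(plan, "augment_plan"))
  labels <- vapply(items, function(x) x$label, character(1))
  out <- list()
  counter <- 0L
  for (cl in names(plan$target_counts)) {
    src <- items[labels == cl]
    target <- plan$target_counts[[cl]]
    if (length(src) > target) {
      stop_lungsop("lungsop_target_below_current",
                   sprintf("class '%s' already has %d > target %d items",
                           cl, length(src), target))
    }
    out <- c(out, src)
    need <- target - length(src)
    if (need > 0) {
      for (j in seq_len(need)) {
        counter <- counter + 1L
        sd <- derive_seed(plan$seed, counter)
        parent <- src[[(j - 1L) %% length(src) + 1L]]
        aug <- with_seed(sd, {
          op <- plan$ops[sample.int(length(plan$ops), 1)]
          params <- sample_op_params(op, plan$ranges[[op]])
          list(op = op, params = params)
        })
        out[[length(out) + 1]] <- augment_one(parent, aug$op, aug$params,
                                              rng_seed = sd + 1L)
      }
    }
  }
  out
}

#' Check split/augmentation lineage for leakage
#'
#' Every augmented item's parent (the id prefix before the first `"|"`)
#' must belong to the same partition.
#'
#' @param splits named list of item lists (as from [stratified_split()])
#' @return TRUE if no augmented item crosses partitions
#' @export
check_no_leakage <- function(splits) {
  parent_of <- function(id) sub("\\|.*$", "", id)
  owner <- new.env(parent = emptyenv())
  for (pn in names(splits)) {
    for (im in splits[[pn]]) {
      if (im$provenance == "raw") assign(parent_of(im$id), pn, envir = owner)
    }
  }
  for (pn in names(splits)) {
    for (im in splits[[pn]]) {
      if (im$provenance == "augmented") {
        p <- parent_of(im$id)
        if (exists(p, envir = owner) && get(p, envir = owner) != pn) {
          return(FALSE)
        }
      }
    }
  }
  TRUE
}
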