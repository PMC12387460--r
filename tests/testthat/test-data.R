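# Ingestion, stratified splitting, augmentation ops, balancing, leakage.

test_that("load_class_folder_dataset loads, resizes and orders deterministically", {
  root <- file.path(tempdir(), "folders-load")
  unlink(root, recursive = TRUE)
  d <- c(generate_dataset(c(benign = 2, malignant = 3), seed = 2, size = 40),
         generate_dataset(c(normal = 1), seed = 3, size = 96))
  write_image_dataset(d, root)
  items <- load_class_folder_dataset(root, size = 32)
  expect_length(items, 6)
  expect_true(all(vapply(items, function(x) all(dim(x$pixels) == c(32, 32)),
                         logical(1))))
  expect_true(all(vapply(items, function(x) {
    all(x$pixels >= 0 & x$pixels <= 1)
  }, logical(1))))
  # deterministic re-load
  items2 <- load_class_folder_dataset(root, size = 32)
  expect_identical(vapply(items, `[[`, character(1), "id"),
                   vapply(items2, `[[`, character(1), "id"))
  expect_identical(lapply(items, `[[`, "pixels"), lapply(items2, `[[`, "pixels"))
  # empty class folder errors
  dir.create(file.path(root, "empty_class"))
  expect_error(load_class_folder_dataset(root, size = 32),
               class = "lungsop_empty_class")
  unlink(root, recursive = TRUE)
})

test_that("stratified_split follows largest-remainder apportionment", {
  # oracle agreement across class sizes
  fr <- c(train = 0.70, val = 0.15, test = 0.15)
  for (n in c(3, 10, 100, 251, 392, 547)) {
    expect_equal(lungsop:::apportion(n, fr), largest_remainder_oracle(n, fr))
  }
  expect_equal(lungsop:::apportion(100, fr), c(train = 70, val = 15, test = 15))
  # n = 10: 7/1.5/1.5 -> remainder goes to val by the tie rule => 7/2/1
  expect_equal(unname(lungsop:::apportion(10, fr)), c(7, 2, 1))

  mk_items <- function(label, n) {
    lapply(seq_len(n), function(i) {
      labeled_image(matrix(0, 2, 2), label, sprintf("%s-%03d", label, i))
    })
  }
  items <- c(mk_items("a", 100), mk_items("b", 10), mk_items("c", 7))
  sp <- split_spec(seed = 5)
  parts <- stratified_split(items, sp)
  ids <- lapply(parts, function(p) vapply(p, `[[`, character(1), "id"))
  # disjoint partitions whose union is the input
  expect_length(Reduce(intersect, ids), 0)
  expect_setequal(unlist(ids), vapply(items, `[[`, character(1), "id"))
  # per-class counts within the documented rule
  for (cl in c("a", "b", "c")) {
    n_cl <- c(a = 100, b = 10, c = 7)[[cl]]
    got <- vapply(ids, function(v) sum(startsWith(v, cl)), numeric(1))
    expect_equal(unname(got), unname(largest_remainder_oracle(n_cl, fr)))
  }
  # determinism
  parts2 <- stratified_split(items, sp)
  expect_identical(ids, lapply(parts2, function(p) {
    vapply(p, `[[`, character(1), "id")
  }))
  # different seed shuffles membership
  parts3 <- stratified_split(items, split_spec(seed = 6))
  expect_false(identical(ids$train,
                         vapply(parts3$train, `[[`, character(1), "id")))
  expect_error(stratified_split(mk_items("a", 2), sp),
               class = "lungsop_insufficient_class")
})

test_that("group-level splitting keeps groups together", {
  items <- unlist(lapply(1:9, function(g) {
    lapply(1:3, function(i) {
      im <- labeled_image(matrix(0, 2, 2), "a", sprintf("g%02d-i%d", g, i))
      im$group <- sprintf("g%02d", g)
      im
    })
  }), recursive = FALSE)
  parts <- stratified_split(items, split_spec(seed = 1, level = "group"))
  for (p in parts) {
    gs <- vapply(p, function(x) x$group, character(1))
    # every present group is complete (3 members)
    expect_true(all(table(gs) == 3))
  }
})

test_that("augmentation ops respect their exact identities", {
  img <- generate_dataset(c(benign = 1), seed = 11, size = 32)[[1]]
  # flip twice restores bit-exactly
  f2 <- augment_one(augment_one(img, "horizontal_flip"), "horizontal_flip")
  expect_equal(unclass(f2$pixels), unclass(lungsop:::unclass_pixels(img$pixels)))
  expect_equal(f2$provenance, "augmented")
  expect_match(f2$id, "horizontal_flip")
  # rotation by 0 and noise with sigma 0 are identities
  r0 <- augment_one(img, "rotation", list(angle = 0))
  expect_lt(max(abs(unclass(r0$pixels) -
                    unclass(lungsop:::unclass_pixels(img$pixels)))), 1e-12)
  g0 <- augment_one(img, "gaussian_noise", list(sigma = 0))
  expect_equal(unclass(g0$pixels), unclass(lungsop:::unclass_pixels(img$pixels)))
  z1 <- augment_one(img, "zoom", list(factor = 1))
  expect_lt(max(abs(unclass(z1$pixels) -
                    unclass(lungsop:::unclass_pixels(img$pixels)))), 1e-12)
  # every op keeps the pixel range
  plan_ops <- c("rotation", "brightness", "zoom", "width_shift",
                "height_shift", "horizontal_flip", "gaussian_noise",
                "salt_pepper_noise", "shear", "crop")
  params <- list(rotation = list(angle = 13), brightness = list(delta = 0.2),
                 zoom = list(factor = 0.9), width_shift = list(frac = 0.1),
                 height_shift = list(frac = -0.1), horizontal_flip = list(),
                 gaussian_noise = list(sigma = 0.05),
                 salt_pepper_noise = list(density = 0.01),
                 shear = list(frac = 0.1), crop = list(frac = 0.05))
  for (op in plan_ops) {
    out <- augment_one(img, op, params[[op]], rng_seed = 3)
    expect_true(all(out$pixels >= 0 & out$pixels <= 1), label = op)
    expect_identical(dim(out$pixels), dim(img$pixels))
  }
})

test_that("balance_classes reaches exact targets, keeps raws, is seeded", {
  items <- generate_dataset(c(benign = 5, malignant = 8, normal = 6),
                            seed = 21, size = 24)
  plan <- augment_plan(c(benign = 12, malignant = 12, normal = 11), seed = 9)
  out <- balance_classes(items, plan)
  labs <- vapply(out, function(x) x$label, character(1))
  expect_equal(as.numeric(table(labs)[c("benign", "malignant", "normal")]),
               c(12, 12, 11))
  prov <- vapply(out, function(x) x$provenance, character(1))
  expect_equal(sum(prov == "raw"), length(items))
  # determinism
  out2 <- balance_classes(items, plan)
  expect_identical(lapply(out, `[[`, "pixels"), lapply(out2, `[[`, "pixels"))
  # target equal to current: nothing added
  plan0 <- augment_plan(c(benign = 5, malignant = 8, normal = 6), seed = 9)
  expect_length(balance_classes(items, plan0), length(items))
  # target below current errors
  expect_error(balance_classes(items,
                               augment_plan(c(benign = 4, malignant = 8,
                                              normal = 6), seed = 9)),
               class = "lungsop_target_below_current")
})

test_that("split-then-augment never leaks lineage across partitions", {
  items <- generate_dataset(c(benign = 8, malignant = 8, normal = 8),
                            seed = 31, size = 24)
  parts <- stratified_split(items, split_spec(seed = 2))
  plan <- augment_plan(c(benign = 10, malignant = 10, normal = 10), seed = 3)
  train_aug <- balance_classes(parts$train, plan)
  splits <- list(train = train_aug, val = parts$val, test = parts$test)
  expect_true(check_no_leakage(splits))
  # a deliberately leaked augmented item is caught
  leaked <- augment_one(parts$test[[1]], "horizontal_flip")
  splits$train <- c(splits$train, list(leaked))
  expect_false(check_no_leakage(splits))
})
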