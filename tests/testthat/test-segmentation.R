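make_training_pair <- function(seed = 1L, n_slices = 5L) {
  ph <- generate_liver_phantom(tiny_spec(seed = seed))
  vol <- fuse_phantom(ph)
  nz <- dim(ph$truth$labels)[1]
  ann <- sparse_annot(ph, round(seq(2, nz - 1, length.out = n_slices)),
                      n = 120L, seed = seed + 100L)
  list(ph = ph, vol = vol, ann = ann)
}

test_that("training records the five-slices-from-two-samples provenance", {
  a <- make_training_pair(1); b <- make_training_pair(2)
  clf <- train_classifier(list(a$vol, b$vol), list(a$ann, b$ann),
                          config = small_config(), n_trees = 50, seed = 7)
  expect_s3_class(clf, "pixel_classifier")
  expect_equal(clf$provenance$n_annotated_slices, 10)
  expect_equal(clf$provenance$n_source_volumes, 2)
  expect_setequal(names(clf$provenance$n_labeled_pixels),
                  c("background", "lumen", "low_AF", "high_AF"))
  expect_gt(clf$training_accuracy, 0.95)
})

test_that("a class with no labeled pixels raises a named error", {
  a <- make_training_pair(3)
  ann <- a$ann
  ann$labels[ann$labels == 2L] <- 0L  # erase all lumen annotations
  ann <- region_label_volume(ann$labels, a$ann$class_names)
  expect_error(train_classifier(list(a$vol), list(ann),
                                config = small_config(), n_trees = 20),
               "lumen")
})

test_that("perfectly separable two-class intensities reach accuracy 1", {
  # two constant plateaus, labels on half the slices, held-out on the rest
  vol <- array(0.1, dim = c(6, 24, 24)); vol[, , 13:24] <- 0.9
  lab <- array(0L, dim = dim(vol))
  lab[1:3, , 1:12] <- 1L; lab[1:3, , 13:24] <- 2L
  ann <- region_label_volume(lab, c("1" = "dark", "2" = "bright"))
  clf <- train_classifier(vol, ann, config = small_config(),
                          n_trees = 30, seed = 2)
  expect_equal(clf$training_accuracy, 1)
  maps <- predict_probabilities(clf, vol)
  pred <- probability_to_mask(maps)
  truth_all <- region_label_volume(
    array(rep(c(1L, 2L), each = 6 * 24 * 12), dim = dim(vol)),
    c("1" = "dark", "2" = "bright"))
  held_out <- pred$labels[4:6, , ] == truth_all$labels[4:6, , ]
  expect_true(all(held_out))
})

test_that("the train/predict chain is deterministic under a fixed seed", {
  a <- make_training_pair(4)
  run <- function() {
    clf <- train_classifier(list(a$vol), list(a$ann),
                            config = small_config(), n_trees = 40, seed = 99)
    predict_probabilities(clf, a$vol)$P
  }
  expect_identical(run(), run())
})

test_that("raw probability maps form a simplex at every voxel", {
  a <- make_training_pair(5)
  clf <- train_classifier(list(a$vol), list(a$ann),
                          config = small_config(), n_trees = 30, seed = 3)
  maps <- predict_probabilities(clf, a$vol)
  expect_equal(maps$stage, "raw")
  tot <- Reduce(`+`, maps$P)
  expect_lt(max(abs(tot - 1)), 1e-6)
  expect_gte(min(vapply(maps$P, min, numeric(1))), 0)
})

test_that("argmax prediction matches truth away from class borders", {
  ph <- generate_liver_phantom(noiseless_spec(seed = 6))
  vol <- ph$clean
  nz <- dim(ph$truth$labels)[1]
  ann <- sparse_annot(ph, round(seq(2, nz - 1, length.out = 5)), n = 120L,
                      seed = 61)
  clf <- train_classifier(list(vol), list(ann), config = small_config(),
                          n_trees = 50, seed = 6)
  pred <- probability_to_mask(predict_probabilities(clf, vol))
  # border = one-voxel dilation of class boundaries (6-neighborhood shifts)
  lab <- ph$truth$labels
  interior <- array(TRUE, dim = dim(lab))
  d <- dim(lab)
  shift_eq <- function(ax, by) {
    idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    src <- idx; src[[ax]] <- pmin(pmax(idx[[ax]] + by, 1), d[ax])
    lab[src[[1]], src[[2]], src[[3]]] == lab
  }
  for (ax in 1:3) for (by in c(-1, 1)) interior <- interior & shift_eq(ax, by)
  acc <- mean(pred$labels[interior] == lab[interior])
  expect_gte(acc, 0.99)
})

test_that("background subtraction postprocessing follows the rule", {
  P <- list(background = array(0.2, c(1, 2, 2)),
            lumen = array(0.6, c(1, 2, 2)),
            low_AF = array(0.15, c(1, 2, 2)),
            high_AF = array(0.05, c(1, 2, 2)))
  maps <- structure(list(P = P, stage = "raw",
                         class_names = stats::setNames(names(P), 1:4)),
                    class = "probability_map_set")
  post <- postprocess_background_subtraction(maps)
  expect_equal(post$stage, "background_subtracted")
  expect_equal(post$P$lumen[1], 0.4)        # 0.6 - 0.2
  expect_equal(post$P$high_AF[1], 0)        # clipped at zero
  expect_equal(post$P$background[1], 0.8)   # inversion 1 - P[bg]
  # pure-background voxel: all non-background maps zero, inversion zero
  P1 <- lapply(P, function(x) array(0, dim(x))); P1$background[] <- 1
  maps1 <- structure(list(P = P1, stage = "raw", class_names = maps$class_names),
                     class = "probability_map_set")
  post1 <- postprocess_background_subtraction(maps1)
  expect_true(all(vapply(post1$P, max, numeric(1)) == 0))
  # random simplex inputs stay within [0,1]
  set.seed(14)
  r <- matrix(rexp(4 * 50), 4); r <- sweep(r, 2, colSums(r), "/")
  Pr <- lapply(1:4, function(i) array(r[i, ], c(1, 5, 10)))
  names(Pr) <- names(P)
  mr <- structure(list(P = Pr, stage = "raw", class_names = maps$class_names),
                  class = "probability_map_set")
  pr <- postprocess_background_subtraction(mr)
  expect_true(all(vapply(pr$P, min, numeric(1)) >= 0))
  expect_true(all(vapply(pr$P, max, numeric(1)) <= 1))
  expect_error(postprocess_background_subtraction(pr), "raw")
})

test_that("probability thresholding and argmax behave as documented", {
  P <- list(background = array(0.6, c(1, 2, 2)), lumen = array(0.4, c(1, 2, 2)))
  maps <- structure(list(P = P, stage = "raw",
                         class_names = stats::setNames(names(P), 1:2)),
                    class = "probability_map_set")
  mask <- probability_to_mask(maps, "background", 0.5)
  expect_true(all(mask$labels == 1L))
  expect_error(probability_to_mask(maps, "vessel"), "unknown class")
  expect_error(probability_to_mask(maps, "lumen", threshold = 1.5), "threshold")
  # argmax partitions every voxel
  am <- probability_to_mask(maps)
  expect_true(all(am$labels %in% 1:2))
  # mask voxel count is nonincreasing in threshold (sweep oracle)
  set.seed(15)
  Pv <- array(runif(4 * 6 * 6), c(4, 6, 6))
  mv <- structure(list(P = list(a = Pv, b = 1 - Pv), stage = "raw",
                       class_names = c("1" = "a", "2" = "b")),
                  class = "probability_map_set")
  counts <- vapply(seq(0.1, 0.9, by = 0.1), function(th)
    sum(probability_to_mask(mv, "a", th)$labels), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("per-class evaluation matches brute force and handles edge cases", {
  cn <- c("1" = "background", "2" = "lumen", "3" = "low_AF")
  set.seed(16)
  mk <- function() region_label_volume(
    array(sample(1:3, 16^3, replace = TRUE), dim = c(16, 16, 16)), cn)
  pred <- mk(); truth <- mk()
  ev <- evaluate_segmentation(pred, truth)
  for (k in seq_along(cn)) {
    a <- pred$labels == k; b <- truth$labels == k
    expect_equal(ev$dice[ev$class == cn[k]],
                 2 * sum(a & b) / (sum(a) + sum(b)))
  }
  expect_equal(attr(ev, "macro_dice"), mean(ev$dice))
  # identity scores 1 everywhere
  ev1 <- evaluate_segmentation(truth, truth)
  expect_true(all(ev1$dice == 1))
  # class absent from both: 1.0 with flag
  cn4 <- c(cn, "4" = "high_AF")
  p4 <- region_label_volume(pred$labels, cn4)
  t4 <- region_label_volume(truth$labels, cn4)
  ev4 <- evaluate_segmentation(p4, t4)
  expect_equal(ev4$dice[ev4$class == "high_AF"], 1)
  expect_true(ev4$flagged[ev4$class == "high_AF"])
  # disjoint class names error
  other <- region_label_volume(array(1L, c(16, 16, 16)), c("1" = "x"))
  expect_error(evaluate_segmentation(other, truth), "class-name mismatch")
})
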