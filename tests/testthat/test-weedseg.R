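test_that("NDVI uses the bands nearest the red and near-infrared anchors", {
  lam <- seq(475.1, 901.7, length.out = 8)
  vals <- array(0.1, dim = c(2, 2, 8))
  red_i <- which.min(abs(lam - 678.2)); nir_i <- which.min(abs(lam - 899.2))
  vals[1, 1, red_i] <- 0.05; vals[1, 1, nir_i] <- 0.5
  vals[2, 1, red_i] <- 0.25; vals[2, 1, nir_i] <- 0.3
  vals[1, 2, red_i] <- 0.2;  vals[1, 2, nir_i] <- 0.2
  vals[2, 2, red_i] <- 0;    vals[2, 2, nir_i] <- 0
  cube <- reflectance_cube(vals, lam, method = "rw")
  nd <- ndvi(cube)
  expect_equal(nd[1, 1], 0.45 / 0.55)
  expect_equal(nd[2, 1], 0.05 / 0.55)
  expect_equal(nd[1, 2], 0)
  expect_equal(nd[2, 2], 0)     # zero denominator guard
  short <- reflectance_cube(vals[, , 1:4], lam[1:4], method = "rw")
  expect_error(ndvi(short), "cover")
})

test_that("vegetation masking thresholds NDVI and opens away isolated pixels", {
  cfg <- t_cfg()
  # soil-only scene: no pixel passes the threshold
  soil <- make_vegetation_scene(40, 64, cfg, classes = 2, seed = 4)
  soil_only <- soil
  soil_only$reflectance <- array(rep(soil$soil_spectrum,
                                     each = 40 * 64), c(40, 64, cfg$B))
  rc <- reflectance_cube(soil_only$reflectance, cfg$band_centers, "rw")
  expect_false(any(vegetation_mask(ndvi(rc), gamma = 0.45)))
  # a 4x4 blob survives opening, an isolated pixel does not
  nd <- matrix(0, 20, 20)
  nd[5:8, 5:8] <- 0.8
  nd[15, 15] <- 0.8
  mask <- vegetation_mask(nd, gamma = 0.45)
  expect_true(all(mask[5:8, 5:8]))
  expect_false(mask[15, 15])
  # an impossible threshold empties the mask
  expect_false(any(vegetation_mask(nd, gamma = 1.1)))
})

test_that("windowed features average 5x5 neighborhoods at masked pixels", {
  vals <- array(0.2, dim = c(9, 9, 2))
  cube <- reflectance_cube(vals, c(600, 900), "rw")
  mask <- matrix(FALSE, 9, 9); mask[3:7, 3:7] <- TRUE
  ds <- extract_features(cube, mask)
  expect_equal(nrow(ds$features), sum(mask))      # one feature per pixel
  expect_true(all(ds$features == 0.2))            # uniform cube
  # one bright pixel contributes 1/25 of its excess to in-window neighbors
  vals[5, 5, 1] <- 0.2 + 25 * 0.01
  cube2 <- reflectance_cube(vals, c(600, 900), "rw")
  ds2 <- extract_features(cube2, mask)
  i_center <- which(ds$provenance$row == 5 & ds$provenance$col == 5)
  i_near <- which(ds2$provenance$row == 3 & ds2$provenance$col == 5)
  i_far <- which(ds2$provenance$row == 3 & ds2$provenance$col == 3)
  expect_equal(ds2$features[i_center, 1], 0.2 + 0.01)
  expect_equal(ds2$features[i_near, 1], 0.2 + 0.01)
  expect_equal(ds2$features[i_far, 1], 0.2 + 0.01)  # corner still in window
  i_out <- which(ds2$provenance$row == 3 & ds2$provenance$col == 8)
  expect_length(i_out, 0)                            # outside the mask
  expect_error(extract_features(cube, mask & FALSE), "empty")
})

fake_dataset <- function(n_per_class, classes, image, K = 4, seed = 1) {
  set.seed(seed * 1000 + image)
  n <- n_per_class * length(classes)
  structure(list(
    features = matrix(rnorm(n * K), n, K),
    labels = rep(classes, each = n_per_class),
    provenance = data.frame(image = image, row = seq_len(n), col = 1L)),
    class = "classification_dataset")
}

test_that("learning-pixel sampling divides quotas by class occurrence", {
  # identification: a class present in 4 images with N = 400 -> 100 each
  ds <- lapply(1:4, function(i) fake_dataset(150, c(1L, 2L), image = i))
  out <- sample_learning_pixels(ds, n_total = 400, task = "identification",
                                seed = 3)
  counts <- table(out$labels, out$provenance$image)
  expect_true(all(counts == 100))
  # detection with N = 200 and two weed species in one image each:
  # crop 200, each weed species 100, weeds merged into one class
  ds2 <- list(fake_dataset(250, c(1L), image = 1),
              fake_dataset(250, c(2L), image = 2),
              fake_dataset(250, c(3L), image = 3))
  out2 <- sample_learning_pixels(ds2, n_total = 200, task = "detection",
                                 crop_class = 1L, seed = 3)
  expect_equal(sum(out2$labels == 1L), 200)   # crop
  expect_equal(sum(out2$labels == 2L), 200)   # two weed species, 100 + 100
  # determinism
  outa <- sample_learning_pixels(ds, 400, "identification", seed = 7)
  outb <- sample_learning_pixels(ds, 400, "identification", seed = 7)
  expect_identical(outa$features, outb$features)
  # shortage: takes all available with a warning
  small <- list(fake_dataset(30, c(1L, 2L), image = 1),
                fake_dataset(200, c(1L, 2L), image = 2))
  w <- capture_warnings(sample_learning_pixels(small, 200, "identification"))
  expect_true(all(grepl("taking all", w)) && length(w) >= 1)
})

test_that("both classifiers separate well-separated classes and not chance labels", {
  set.seed(6)
  make_blobs <- function(n, shift, seed) {
    set.seed(seed)
    X <- rbind(matrix(rnorm(n * 4, 0), n, 4),
               matrix(rnorm(n * 4, shift), n, 4))
    structure(list(features = X, labels = rep(c(1L, 2L), each = n),
                   provenance = data.frame(image = 1, row = 1, col = 1)),
              class = "classification_dataset")
  }
  train <- make_blobs(150, 4, seed = 11)
  test <- make_blobs(150, 4, seed = 12)
  for (model in c("qda", "gbdt")) {
    pred <- train_and_predict(train, test, model, seed = 5)
    acc <- mean(pred == test$labels)
    expect_gte(acc, 0.99)
    # deterministic given seed
    expect_identical(pred, train_and_predict(train, test, model, seed = 5))
  }
  # permuted labels (train and test) carry no signal: weighted accuracy
  # sits at chance 1/n_classes
  accs <- vapply(1:6, function(s) {
    shuf <- train
    set.seed(s)
    shuf$labels <- sample(shuf$labels)
    test_labels <- sample(test$labels)
    pred <- train_and_predict(shuf, test, "qda", seed = s)
    classification_metrics(test_labels, pred)$weighted_accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.05)
  # degenerate single-class training set
  one <- train; one$labels <- rep(1L, length(one$labels))
  expect_error(train_and_predict(one, test, "qda"), "2 classes")
})

test_that("in-package QDA matches MASS::qda on a well-conditioned problem", {
  set.seed(13)
  n <- 120
  X <- rbind(matrix(rnorm(n * 3, 0, 1), n, 3),
             matrix(rnorm(n * 3, 2, 1.6), n, 3))
  y <- rep(c(1L, 2L), each = n)
  Xt <- rbind(matrix(rnorm(60 * 3, 0, 1), 60, 3),
              matrix(rnorm(60 * 3, 2, 1.6), 60, 3))
  train <- structure(list(features = X, labels = y,
                          provenance = data.frame(image = 1, row = 1, col = 1)),
                     class = "classification_dataset")
  test <- structure(list(features = Xt, labels = rep(c(1L, 2L), each = 60),
                         provenance = data.frame(image = 1, row = 1, col = 1)),
                    class = "classification_dataset")
  ours <- train_and_predict(train, test, "qda")
  fit <- MASS::qda(X, grouping = factor(y))
  theirs <- as.integer(as.character(predict(fit, Xt)$class))
  expect_gte(mean(ours == theirs), 0.99)
})

test_that("class-weighted metrics follow the inverse-size weighting", {
  # perfect prediction
  m <- classification_metrics(c(1, 1, 2, 2), c(1, 1, 2, 2))
  expect_equal(m$weighted_accuracy, 1)
  expect_equal(m$weighted_f1, 1)
  expect_true(all(m$per_class$precision == 1 & m$per_class$recall == 1))
  # hand example: accuracies 0.8 (n=100) and 0.6 (n=400) -> 0.76
  y <- c(rep(1, 100), rep(2, 400))
  yhat <- c(rep(1, 80), rep(2, 20), rep(2, 240), rep(1, 160))
  m2 <- classification_metrics(y, yhat)
  expect_equal(m2$per_class$accuracy, c(0.8, 0.6))
  expect_equal(m2$weighted_accuracy, 0.76)
  # equal class sizes: weighted accuracy is the plain per-class mean
  y3 <- rep(c(1, 2), each = 50)
  yh3 <- y3; yh3[c(1:10, 51:60)] <- 3 - y3[c(1:10, 51:60)]
  m3 <- classification_metrics(y3, yh3)
  expect_equal(m3$weighted_accuracy, mean(m3$per_class$accuracy))
  # precision == recall -> F1 equals them
  expect_equal(m3$per_class$f1[1],
               m3$per_class$precision[1], tolerance = 1e-12)
  # a never-predicted class warns and gets precision 0
  expect_warning(m4 <- classification_metrics(c(1, 1, 2), c(1, 1, 1)),
                 "never predicted")
  expect_equal(m4$per_class$precision[2], 0)
  expect_error(classification_metrics(1:3, 1:2), "length")
})
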