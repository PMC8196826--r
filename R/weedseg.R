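# Vegetation extraction and the supervised crop/weed classification
# harness: NDVI segmentation with morphological cleanup, windowed spectral
# features, occurrence-balanced pixel sampling, QDA / gradient-boosted-tree
# classifiers, and class-weighted metrics for imbalanced test sets.

#' Normalized difference vegetation index map
#'
#' `(R_nir - R_red) / (R_nir + R_red)` using the bands nearest 678.2 nm
#' (chlorophyll absorption) and 899.2 nm (near-infrared plateau); 0 where
#' the denominator vanishes.
#'
#' @param cube A [reflectance_cube()].
#' @param red_nm,nir_nm Target wavelengths (nm).
#' @return `H x W` numeric NDVI matrix.
#' @export
ndvi <- function(cube, red_nm = 678.2, nir_nm = 899.2) {
  lam <- cube$band_centers
  for (target in c(red_nm, nir_nm))
    if (target < min(lam) || target > max(lam))
      stop("band centers do not cover ", target, " nm")
  red <- cube$values[, , which.min(abs(lam - red_nm))]
  nir <- cube$values[, , which.min(abs(lam - nir_nm))]
  den <- nir + red
  out <- (nir - red) / den
  out[den == 0] <- 0
  out
}

#' Threshold an NDVI map into a vegetation mask
#'
#' Pixels with NDVI >= `gamma` are kept, then isolated noise is filtered by
#' one morphological opening with a 3 x 3 square structuring element.
#'
#' @param ndvi_map `H x W` NDVI matrix.
#' @param gamma Threshold (default 0.45).
#' @return Logical `H x W` vegetation mask.
#' @export
vegetation_mask <- function(ndvi_map, gamma = 0.45) {
  raw <- ndvi_map >= gamma
  if (!any(raw)) return(raw)
  opened <- EBImage::opening(raw * 1, EBImage::makeBrush(3, shape = "box"))
  matrix(as.logical(opened > 0.5), nrow = nrow(raw))
}

#' Extract windowed spectral features at masked pixels
#'
#' Each masked pixel's feature vector is the channel-wise mean of the
#' reflectance (or radiance) over a `window x window` neighborhood
#' (reflect padding), reducing noise and within-class variability.
#'
#' @param cube A spectral cube.
#' @param mask Logical `H x W` mask of pixels to sample.
#' @param labels Optional integer `H x W` class-label map.
#' @param image_id Provenance tag stored per sample.
#' @param window Averaging window side (odd; default 5).
#' @return Object of class `classification_dataset`: `features`
#'   (`n x K` matrix), `labels` (length `n` or `NULL`), `provenance`
#'   (data frame with image, row, col).
#' @export
extract_features <- function(cube, mask, labels = NULL, image_id = 1L,
                             window = 5L) {
  if (!any(mask)) stop("mask is empty")
  d <- dim(cube$values)
  idx <- which(mask)
  feats <- matrix(0, length(idx), d[3])
  for (b in seq_len(d[3]))
    feats[, b] <- .box_filter(cube$values[, , b], window)[idx]
  rc <- arrayInd(idx, d[1:2])
  lab <- if (is.null(labels)) NULL else as.integer(labels[idx])
  structure(list(features = feats,
                 labels = lab,
                 provenance = data.frame(image = image_id,
                                         row = rc[, 1], col = rc[, 2])),
            class = "classification_dataset")
}

# Concatenate classification datasets.
.bind_datasets <- function(ds_list) {
  structure(list(
    features = do.call(rbind, lapply(ds_list, `[[`, "features")),
    labels = unlist(lapply(ds_list, `[[`, "labels")),
    provenance = do.call(rbind, lapply(ds_list, `[[`, "provenance"))),
    class = "classification_dataset")
}

.take_dataset <- function(ds, rows) {
  structure(list(features = ds$features[rows, , drop = FALSE],
                 labels = ds$labels[rows],
                 provenance = ds$provenance[rows, , drop = FALSE]),
            class = "classification_dataset")
}

#' Sample learning pixels across images, balanced by class occurrence
#'
#' For the identification task each class `Ci` contributes
#' `n_total / occurrences(Ci)` pixels from every image where it appears.
#' For the detection task the crop class contributes `n_total` pixels in
#' total while each weed species contributes `n_total / 2` (the species are
#' later merged into a single weed class), again divided by their
#' occurrence counts per image. Sampling is uniform without replacement and
#' seeded; an image holding fewer pixels than requested contributes all of
#' them with a warning.
#'
#' @param datasets List of `classification_dataset` objects, one per
#'   learning image, with labels set.
#' @param n_total Target learning-pixel count per class (`N`).
#' @param task `"identification"` or `"detection"`.
#' @param crop_class Integer label of the crop class (detection task).
#' @param seed Integer seed.
#' @param merge_weeds Logical; for detection, relabel all non-crop classes
#'   as `2L` (weed) with crop as `1L`.
#' @return A pooled `classification_dataset`.
#' @export
sample_learning_pixels <- function(datasets, n_total,
                                   task = c("identification", "detection"),
                                   crop_class = 1L, seed = 1L,
                                   merge_weeds = TRUE) {
  task <- match.arg(task)
  set.seed(seed)
  classes <- sort(unique(unlist(lapply(datasets, `[[`, "labels"))))
  classes <- classes[classes > 0]
  occ <- vapply(classes, function(cl)
    sum(vapply(datasets, function(d) any(d$labels == cl), logical(1))),
    integer(1))
  if (any(occ == 0)) stop("every class must occur in at least one image")
  names(occ) <- classes
  quota <- vapply(classes, function(cl) {
    per_class <- if (task == "identification") n_total
                 else if (cl == crop_class) n_total else n_total / 2
    per_class / occ[as.character(cl)]
  }, numeric(1))
  names(quota) <- classes
  picked <- list()
  for (d in datasets) {
    for (cl in classes) {
      rows <- which(d$labels == cl)
      if (length(rows) == 0) next
      want <- max(1L, floor(quota[as.character(cl)]))
      if (length(rows) < want) {
        warning("image has only ", length(rows), " pixels of class ", cl,
                " (", want, " requested); taking all")
        take <- rows
      } else take <- sample(rows, want)
      picked[[length(picked) + 1L]] <- .take_dataset(d, take)
    }
  }
  out <- .bind_datasets(picked)
  if (task == "detection" && merge_weeds)
    out$labels <- ifelse(out$labels == crop_class, 1L, 2L)
  out
}

# Regularized quadratic discriminant: class-wise Gaussian with unequal
# covariances, a 1e-6 diagonal ridge keeping them invertible.
.qda_fit <- function(X, y, reg = 1e-6) {
  classes <- sort(unique(y))
  models <- lapply(classes, function(cl) {
    Xi <- X[y == cl, , drop = FALSE]
    S <- stats::cov(Xi) + diag(reg, ncol(X))
    R <- chol(S)
    list(mu = colMeans(Xi), R = R,
         logdet = 2 * sum(log(diag(R))),
         logprior = log(nrow(Xi) / nrow(X)))
  })
  list(classes = classes, models = models)
}

.qda_predict <- function(fit, X) {
  scores <- vapply(fit$models, function(m) {
    Z <- backsolve(m$R, t(sweep(X, 2, m$mu)), transpose = TRUE)
    -0.5 * colSums(Z^2) - 0.5 * m$logdet + m$logprior
  }, numeric(nrow(X)))
  if (nrow(X) == 1L) scores <- matrix(scores, nrow = 1)
  fit$classes[max.col(scores, ties.method = "first")]
}

#' Train a pixel classifier and predict test labels
#'
#' `"qda"` fits a quadratic discriminant rule (class-wise Gaussian,
#' unequal covariances, 1e-6 diagonal covariance regularization).
#' `"gbdt"` fits histogram-based gradient-boosted trees with learning rate
#' 0.05, 150 leaves, 255 histogram bins, 100 boosting rounds, feature
#' fraction 0.8, bagging fraction 0.8 and the log-loss objective.
#' Both are deterministic for a fixed seed.
#'
#' @param train,test `classification_dataset` objects; `train$labels` must
#'   contain at least two classes.
#' @param model `"qda"` or `"gbdt"`.
#' @param seed Integer seed.
#' @return Integer vector of predicted labels for the test samples.
#' @export
train_and_predict <- function(train, test, model = c("qda", "gbdt"),
                              seed = 1L) {
  model <- match.arg(model)
  classes <- sort(unique(train$labels))
  if (length(classes) < 2L) stop("training set must contain >= 2 classes")
  if (model == "qda") {
    fit <- .qda_fit(train$features, train$labels)
    return(.qda_predict(fit, test$features))
  }
  set.seed(seed)
  y <- match(train$labels, classes) - 1L
  nc <- length(classes)
  params <- list(tree_method = "hist", grow_policy = "lossguide",
                 max_depth = 0L, max_leaves = 150L, max_bin = 255L,
                 eta = 0.05, subsample = 0.8, colsample_bytree = 0.8,
                 nthread = 1L, seed = seed)
  if (nc == 2L) {
    params$objective <- "binary:logistic"
    params$eval_metric <- "logloss"
  } else {
    params$objective <- "multi:softprob"
    params$eval_metric <- "mlogloss"
    params$num_class <- nc
  }
  dtrain <- xgboost::xgb.DMatrix(train$features, label = y)
  booster <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = 100L, verbose = 0)
  pred <- predict(booster, xgboost::xgb.DMatrix(test$features))
  if (nc == 2L) classes[ifelse(pred > 0.5, 2L, 1L)]
  else {
    P <- if (is.matrix(pred)) pred else matrix(pred, ncol = nc, byrow = TRUE)
    classes[max.col(P, ties.method = "first")]
  }
}

#' Class-weighted classification metrics for imbalanced test sets
#'
#' Per-class accuracy (the fraction of a class's pixels predicted
#' correctly), precision, recall and F1, plus overall scores weighted by
#' `omega_Ci = 1 / |y_Ci|` (the inverse class size), so minority classes
#' count as much as majority ones.
#'
#' @param y_true,y_pred Equal-length label vectors; every true class must
#'   be nonempty.
#' @return A list of class `class_metrics`: `per_class` data frame
#'   (class, n, accuracy, precision, recall, f1, weight), plus
#'   `weighted_accuracy` and `weighted_f1`.
#' @export
classification_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("label vectors differ in length")
  classes <- sort(unique(y_true))
  per <- lapply(classes, function(cl) {
    in_cl <- y_true == cl
    n <- sum(in_cl)
    correct <- sum(in_cl & y_pred == cl)
    predicted <- sum(y_pred == cl)
    precision <- if (predicted == 0) {
      warning("class ", cl, " never predicted; precision set to 0")
      0
    } else correct / predicted
    recall <- correct / n
    f1 <- if (precision + recall == 0) 0 else
      2 * precision * recall / (precision + recall)
    data.frame(class = cl, n = n, accuracy = correct / n,
               precision = precision, recall = recall, f1 = f1,
               weight = 1 / n)
  })
  per <- do.call(rbind, per)
  structure(list(per_class = per,
                 weighted_accuracy =
                   sum(per$weight * per$accuracy) / sum(per$weight),
                 weighted_f1 = sum(per$weight * per$f1) / sum(per$weight)),
            class = "class_metrics")
}

#' @export
print.class_metrics <- function(x, ...) {
  cat("<class_metrics>\n")
  print(x$per_class, row.names = FALSE)
  cat(sprintf("weighted accuracy = %.4f, weighted F1 = %.4f\n",
              x$weighted_accuracy, x$weighted_f1))
  invisible(x)
}
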