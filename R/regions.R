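## Region models: mean-shift fixation clustering, k-means image segmentation,
## external label maps, and the encoding of fixations as visual units.

#' Construct a region model
#'
#' A region model is the common interface the rest of the pipeline uses to map
#' fixations onto region labels. It is produced by [mean_shift_cluster()]
#' (gaze-driven), [kmeans_segment()] (image-feature-driven) or
#' [external_region_model()] (precomputed per-pixel labels).
#'
#' @param method `"msfc"`, `"kmeans"` or `"external"`.
#' @param labels Character vector of region labels.
#' @param assignment For `"msfc"`: data frame `(observer, image, fix, label)`
#'   mapping retained fixations (by index within their trial) to labels.
#' @param label_map For `"kmeans"`/`"external"`: integer matrix
#'   (`image_h` x `image_w`) of label indices into `labels`; pixel (x, y) in
#'   0-based image coordinates is `label_map[y + 1, x + 1]`.
#' @param centroids Data frame `(label, x, y)`.
#' @export
region_model <- function(method, labels, assignment = NULL, label_map = NULL,
                         centroids = NULL) {
  method <- match.arg(method, c("msfc", "kmeans", "external"))
  structure(list(method = method, labels = as.character(labels),
                 assignment = assignment, label_map = label_map,
                 centroids = centroids),
            class = "region_model")
}

#' @export
print.region_model <- function(x, ...) {
  cat(sprintf("<region_model> method %s, %d region(s): %s\n", x$method,
              length(x$labels),
              paste(utils::head(x$labels, 8), collapse = ", ")))
  invisible(x)
}

#' Mean-shift fixation clustering (MSFC)
#'
#' Clusters the pooled fixation coordinates of all trials for one image with a
#' flat-kernel mean shift. The number of clusters is data-driven: each
#' fixation ascends to the mode of its local density, and modes closer than
#' half the bandwidth are merged. The procedure is deterministic and
#' independent of input order; clusters are labelled `cluster1..clusterN` in
#' order of centroid position (x, then y).
#'
#' @param trials List of [scanpath_trial()] for a single image.
#' @param bandwidth Kernel radius in pixels. The default corresponds to 2
#'   degrees of visual angle at `px_per_deg` pixels per degree (a 1680x1050
#'   display subtending 38 x 22 degrees gives about 44 px/deg).
#' @param px_per_deg Pixels per degree used for the default bandwidth.
#' @param tol,max_iter Convergence controls for the mode ascent.
#' @return A `"msfc"` [region_model()] whose `assignment` maps every pooled
#'   fixation to a cluster.
#' @export
mean_shift_cluster <- function(trials, bandwidth = 2 * px_per_deg,
                               px_per_deg = 44, tol = 1e-3, max_iter = 200) {
  stopifnot(bandwidth > 0)
  pooled <- pooled_fixations(trials)
  if (nrow(pooled) == 0L) stop_fmt("no fixations to cluster")
  pts <- cbind(pooled$x, pooled$y)
  modes <- pts
  for (it in seq_len(max_iter)) {
    d2 <- outer(rowSums(modes^2), rowSums(pts^2), "+") - 2 * modes %*% t(pts)
    w <- d2 <= bandwidth^2
    nw <- rowSums(w)
    new_modes <- cbind((w %*% pts[, 1]) / nw, (w %*% pts[, 2]) / nw)
    shift <- sqrt(rowSums((new_modes - modes)^2))
    modes <- new_modes
    if (max(shift) < tol) break
  }
  ## merge modes within bandwidth/2 (single linkage on the converged modes)
  n <- nrow(modes)
  cl <- integer(n)
  centers <- NULL
  for (i in order(modes[, 1], modes[, 2])) {
    if (is.null(centers)) {
      centers <- modes[i, , drop = FALSE]; cl[i] <- 1L; next
    }
    d <- sqrt(rowSums((centers - matrix(modes[i, ], nrow(centers), 2,
                                        byrow = TRUE))^2))
    j <- which.min(d)
    if (d[j] <= bandwidth / 2) cl[i] <- j
    else { centers <- rbind(centers, modes[i, ]); cl[i] <- nrow(centers) }
  }
  cent <- do.call(rbind, lapply(seq_len(max(cl)), function(j)
    colMeans(pts[cl == j, , drop = FALSE])))
  ord <- order(cent[, 1], cent[, 2])
  relab <- match(seq_len(max(cl)), ord)
  cl <- relab[cl]
  cent <- cent[ord, , drop = FALSE]
  labels <- paste0("cluster", seq_len(nrow(cent)))
  region_model("msfc", labels,
               assignment = data.frame(observer = pooled$observer,
                                       image = pooled$image,
                                       fix = pooled$fix,
                                       label = labels[cl],
                                       stringsAsFactors = FALSE),
               centroids = data.frame(label = labels, x = cent[, 1],
                                      y = cent[, 2],
                                      stringsAsFactors = FALSE))
}

pooled_fixations <- function(trials) {
  do.call(rbind, lapply(trials, function(tr) {
    f <- tr$fixations
    if (nrow(f) == 0L) return(NULL)
    data.frame(observer = tr$observer, image = tr$image,
               fix = seq_len(nrow(f)), x = f$x, y = f$y,
               stringsAsFactors = FALSE)
  })) %||% data.frame(observer = character(), image = character(),
                      fix = integer(), x = numeric(), y = numeric())
}

#' Discard clusters whose centroid lies outside the image
#'
#' Blinks and track losses produce fixations (and hence mean-shift clusters)
#' outside the stimulus; such clusters are removed and their fixations drop
#' out of all downstream visual-unit sequences.
#'
#' @param model A `"msfc"` [region_model()].
#' @param image_w,image_h Image size in pixels.
#' @return The pruned model (possibly with no clusters left, in which case a
#'   message is emitted and downstream operations will reject it).
#' @export
discard_offimage_clusters <- function(model, image_w, image_h) {
  stopifnot(inherits(model, "region_model"), model$method == "msfc")
  cen <- model$centroids
  keep <- cen$x >= 0 & cen$x < image_w & cen$y >= 0 & cen$y < image_h
  if (all(keep)) return(model)
  dropped <- cen$label[!keep]
  model$labels <- cen$label[keep]
  model$centroids <- cen[keep, , drop = FALSE]
  model$assignment <- model$assignment[model$assignment$label %in% model$labels, ,
                                       drop = FALSE]
  if (!length(model$labels))
    message("all clusters lie off-image; empty region model returned")
  else
    message(sprintf("discarded %d off-image cluster(s): %s", length(dropped),
                    paste(dropped, collapse = ", ")))
  model
}

#' Segment an image with k-means on RGB + spatial features
#'
#' Every pixel is described by its standardized RGB values plus its (x, y)
#' position weighted by `spatial_weight`, and Lloyd's k-means partitions the
#' pixels into `k` segments labelled `segment1..segmentk`. When pairing
#' k-means with mean-shift fixation clustering, pass
#' `k = length(msfc_model$labels)` so both region models have the same
#' granularity.
#'
#' @param raster Numeric array `image_h x image_w x 3` (RGB, any linear scale).
#' @param k Number of segments (>= 1).
#' @param spatial_weight Weight of the standardized x/y features (default 1);
#'   0 segments on colour alone.
#' @param seed Seed for the k-means++-style initialization.
#' @param iter_max,tol Lloyd iteration controls.
#' @return A `"kmeans"` [region_model()] with a per-pixel `label_map`.
#' @export
kmeans_segment <- function(raster, k, spatial_weight = 1, seed = 1,
                           iter_max = 300, tol = 1e-4) {
  if (!is_count(k)) stop_fmt("k must be a positive integer")
  stopifnot(length(dim(raster)) == 3L, dim(raster)[3] >= 3L)
  h <- dim(raster)[1]; w <- dim(raster)[2]
  xy <- expand.grid(row = seq_len(h), col = seq_len(w))
  feat <- cbind(R = as.vector(raster[, , 1]), G = as.vector(raster[, , 2]),
                B = as.vector(raster[, , 3]),
                x = spatial_weight * (xy$col - 1),
                y = spatial_weight * (xy$row - 1))
  sds <- apply(feat, 2, stats::sd)
  feat <- sweep(feat, 2, colMeans(feat), "-")
  nz <- sds > 0
  feat[, nz] <- sweep(feat[, nz, drop = FALSE], 2, sds[nz], "/")
  n_distinct <- nrow(unique(feat))
  if (k > n_distinct) {
    warning(sprintf("k = %d exceeds the %d distinct feature vectors; using k = %d",
                    k, n_distinct, n_distinct))
    k <- n_distinct
  }
  if (k == 1L) {
    assign <- rep(1L, nrow(feat))
  } else {
    centers <- with_seed(seed, kmeanspp_init(feat, k))
    assign <- stats::kmeans(feat, centers = centers, iter.max = iter_max,
                            algorithm = "Lloyd")$cluster
  }
  keep <- sort(unique(assign))
  assign <- match(assign, keep)
  labels <- paste0("segment", seq_along(keep))
  map <- matrix(assign, nrow = h, ncol = w)
  cent <- label_map_centroids(map, labels)
  region_model("kmeans", labels, label_map = map, centroids = cent)
}

kmeanspp_init <- function(feat, k) {
  n <- nrow(feat)
  centers <- matrix(NA_real_, k, ncol(feat))
  centers[1, ] <- feat[sample.int(n, 1), ]
  d2 <- rowSums(sweep(feat, 2, centers[1, ])^2)
  for (j in seq_len(k - 1L)) {
    p <- d2 / sum(d2)
    pick <- if (all(p == 0)) sample.int(n, 1) else sample.int(n, 1, prob = p)
    centers[j + 1L, ] <- feat[pick, ]
    d2 <- pmin(d2, rowSums(sweep(feat, 2, centers[j + 1L, ])^2))
  }
  ## de-duplicate degenerate draws by a microscopic jitter
  while (anyDuplicated(centers)) {
    dup <- which(duplicated(centers))
    centers[dup, ] <- centers[dup, , drop = FALSE] +
      matrix(stats::rnorm(length(dup) * ncol(feat), 0, 1e-8), length(dup))
  }
  centers
}

label_map_centroids <- function(map, labels) {
  xs <- col(map) - 1; ys <- row(map) - 1
  do.call(rbind, lapply(seq_along(labels), function(j) {
    m <- map == j
    data.frame(label = labels[j], x = mean(xs[m]), y = mean(ys[m]),
               stringsAsFactors = FALSE)
  }))
}

#' Wrap an externally produced per-pixel label map
#'
#' @param label_map Integer matrix (`image_h` x `image_w`); values are mapped
#'   to labels `region<value>`.
#' @return An `"external"` [region_model()].
#' @export
external_region_model <- function(label_map) {
  stopifnot(is.matrix(label_map))
  vals <- sort(unique(as.vector(label_map)))
  map <- matrix(match(label_map, vals), nrow(label_map), ncol(label_map))
  labels <- paste0("region", vals)
  region_model("external", labels, label_map = map,
               centroids = label_map_centroids(map, labels))
}

#' Encode a trial's fixations as visual units
#'
#' Each retained fixation becomes one visual unit carrying the fixation's
#' onset and duration and the label of the region it falls in: its assigned
#' cluster under a mean-shift model, or the label-map value at its pixel under
#' a segmentation model. The linear order of the fixations is preserved.
#' Fixations outside the image bounds of a label-map model are dropped (with a
#' message); under a mean-shift model, fixations of discarded clusters drop out.
#'
#' @param trial A [scanpath_trial()].
#' @param model A [region_model()] covering the trial's image.
#' @return Data frame `(label, t_on, dur)`, one row per retained fixation.
#' @export
encode_visual_units <- function(trial, model) {
  stopifnot(inherits(trial, "scanpath_trial"), inherits(model, "region_model"))
  f <- trial$fixations
  empty <- data.frame(label = character(), t_on = numeric(), dur = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(f) == 0L) return(empty)
  if (model$method == "msfc") {
    a <- model$assignment
    a <- a[a$observer == trial$observer & a$image == trial$image, , drop = FALSE]
    lab <- a$label[match(seq_len(nrow(f)), a$fix)]
  } else {
    h <- nrow(model$label_map); w <- ncol(model$label_map)
    row_i <- floor(f$y) + 1; col_i <- floor(f$x) + 1
    inb <- row_i >= 1 & row_i <= h & col_i >= 1 & col_i <= w
    lab <- rep(NA_character_, nrow(f))
    lab[inb] <- model$labels[model$label_map[cbind(row_i[inb], col_i[inb])]]
    if (any(!inb))
      message(sprintf("dropped %d fixation(s) outside the %dx%d label map",
                      sum(!inb), w, h))
  }
  keep <- !is.na(lab)
  data.frame(label = lab[keep], t_on = f$t_on[keep], dur = f$dur[keep],
             stringsAsFactors = FALSE)
}
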