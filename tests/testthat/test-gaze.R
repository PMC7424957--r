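test_that("fixation log parsing groups samples into fixations", {
  txt <- fixation_log_text(c(
    log_row("p1", "im1", 7456470899, 550.0, 406.07),
    log_row("p1", "im1", 7456570899, 550.0, 406.07),   # same fixation, 100 ms on
    log_row("p1", "im1", 7456670899, 300.0, 200.0, "Saccade", "Saccade"),
    log_row("p1", "im1", 7456770899, 612.5, 380.2),
    log_row("p1", "im1", 7456990899, 612.5, 380.2)))
  trials <- read_fixation_log(textConnection(txt),
                              fixation_dialect(time_unit = "us"))
  expect_length(trials, 1L)
  f <- trials[[1]]$fixations
  expect_equal(nrow(f), 2L)
  expect_equal(f$x[1], 550.0)
  expect_equal(f$y[1], 406.07)
  expect_equal(f$t_on[1], 0)
  expect_equal(f$dur[1], 0.1)          # two samples 100 ms apart collapse
  expect_equal(f$t_on[2], 0.3)         # rebased to trial start, saccade row skipped
  expect_equal(f$dur[2], 0.22)
})

test_that("fixation log parsing averages binocular samples and honours one-eyed rows", {
  hdr <- paste("observer", "image", "time", "l_x", "l_y", "r_x", "r_y",
               "l_event", "r_event", sep = "\t")
  rows <- c(paste("p1", "im1", 0, 100, 100, 110, 104, "Fixation", "Fixation", sep = "\t"),
            paste("p1", "im1", 50000, 100, 100, 110, 104, "Fixation", "Fixation", sep = "\t"),
            paste("p1", "im1", 100000, 400, 300, 0, 0, "Fixation", "Blink", sep = "\t"),
            paste("p1", "im1", 150000, 400, 300, 0, 0, "Fixation", "Blink", sep = "\t"))
  trials <- read_fixation_log(textConnection(paste(c(hdr, rows), collapse = "\n")),
                              fixation_dialect(time_unit = "us"))
  f <- trials[[1]]$fixations
  expect_equal(f$x, c(105, 400))       # binocular average, then left eye only
  expect_equal(f$y, c(102, 300))
})

test_that("fixation log parsing rejects malformed input", {
  expect_length(read_fixation_log(textConnection(fixation_log_text(character()))), 0L)
  bad_cols <- "observer\timage\ttime\tl_x\np1\tim1\t0\t1"
  expect_error(read_fixation_log(textConnection(bad_cols)), "l_y")
  non_mono <- fixation_log_text(c(log_row("p1", "im1", 100, 1, 1),
                                  log_row("p1", "im1", 50, 1, 1)))
  expect_error(read_fixation_log(textConnection(non_mono),
                                 fixation_dialect(time_unit = "us")),
               "non-monotone.*row 2")
})

test_that("observer quality control keeps errors within k standard deviations", {
  rec <- data.frame(observer = c("a", "b", "c", "d"),
                    err_x = c(0.5, 0.5, 0.5, 5.0),
                    err_y = c(0.7, 0.7, 0.7, 0.7))
  # direct oracle: |e - mean| <= k sd. With one outlier among four, the
  # outlier inflates the SD enough to sit inside two of them (3.375 <= 4.5),
  # so exclusion kicks in at the tighter k = 1 (3.375 > 2.25).
  for (k in c(1, 2)) {
    keep <- abs(rec$err_x - mean(rec$err_x)) <= k * sd(rec$err_x)
    expect_equal(qc_filter_observers(rec, k_sd = k), rec$observer[keep])
  }
  expect_false("d" %in% qc_filter_observers(rec, k_sd = 1))

  # bad in one direction only is enough for exclusion
  rec2 <- data.frame(observer = c("a", "b", "c", "d"),
                     err_x = c(0.5, 0.5, 0.5, 0.5),
                     err_y = c(0.5, 0.5, 0.5, 9.0))
  expect_false("d" %in% qc_filter_observers(rec2, k_sd = 1))
  expect_setequal(qc_filter_observers(rec2, k_sd = 1), c("a", "b", "c"))

  # zero-spread edge: identical records all pass
  rec3 <- data.frame(observer = c("a", "b"), err_x = c(1, 1), err_y = c(1, 1))
  expect_equal(qc_filter_observers(rec3), c("a", "b"))

  expect_error(qc_filter_observers(rec3[1, ]), "two")
})

test_that("observer quality control output shrinks as k_sd shrinks", {
  set.seed(11)
  rec <- data.frame(observer = paste0("o", 1:20),
                    err_x = rgamma(20, 2, 4), err_y = rgamma(20, 2, 4))
  prev <- character(0)
  for (k in c(0.5, 1, 2, 3)) {
    cur <- qc_filter_observers(rec, k_sd = k)
    expect_true(all(prev %in% cur))
    prev <- cur
  }
  expect_true(all(prev %in% rec$observer))
})

test_that("mean-shift clustering recovers well-separated fixation groups", {
  set.seed(3)
  blob <- function(n, cx, cy) data.frame(
    x = rnorm(n, cx, 20), y = rnorm(n, cy, 20), dur = 0.2)
  fix <- rbind(blob(40, 400, 500), blob(40, 1000, 500))
  fix$t_on <- seq(0, by = 0.25, length.out = nrow(fix))
  tr <- trial_from_fix(fix)
  m <- mean_shift_cluster(list(tr), bandwidth = 80)
  expect_length(m$labels, 2L)
  cen <- m$centroids[order(m$centroids$x), ]
  expect_lt(abs(cen$x[1] - 400), 10)
  expect_lt(abs(cen$x[2] - 1000), 10)
  expect_lt(max(abs(cen$y - 500)), 10)

  # one point: a single cluster at that point
  one <- trial_from_fix(data.frame(x = rep(33, 5), y = rep(44, 5),
                                   t_on = 0:4, dur = 0.2))
  m1 <- mean_shift_cluster(list(one), bandwidth = 80)
  expect_length(m1$labels, 1L)
  expect_equal(unname(unlist(m1$centroids[, c("x", "y")])), c(33, 44))

  # bandwidth >= image diagonal: everything one basin
  mall <- mean_shift_cluster(list(tr), bandwidth = 2000)
  expect_length(mall$labels, 1L)

  expect_error(mean_shift_cluster(list(trial_from_fix(
    data.frame(x = numeric(), y = numeric(), t_on = numeric(), dur = numeric())))),
    "no fixations")
})

test_that("mean-shift clustering is deterministic and input-order invariant", {
  set.seed(5)
  fix <- data.frame(x = c(rnorm(30, 300, 25), rnorm(30, 900, 25)),
                    y = c(rnorm(30, 300, 25), rnorm(30, 700, 25)),
                    t_on = seq(0, by = 0.25, length.out = 60), dur = 0.2)
  tr <- trial_from_fix(fix)
  m1 <- mean_shift_cluster(list(tr), bandwidth = 80)
  m2 <- mean_shift_cluster(list(tr), bandwidth = 80)
  expect_identical(m1, m2)
  perm <- sample.int(nrow(fix))
  fixp <- fix[perm, ]
  fixp$t_on <- fix$t_on  # keep onsets sorted; shuffle positions only
  mp <- mean_shift_cluster(list(trial_from_fix(fixp)), bandwidth = 80)
  expect_equal(mp$centroids, m1$centroids, tolerance = 1e-6)
  expect_equal(mp$assignment$label[order(perm)], m1$assignment$label)
})

test_that("off-image clusters are discarded with their fixations", {
  fix <- data.frame(x = c(rep(200, 10), rep(-15, 4)),
                    y = c(rep(200, 10), rep(200, 4)),
                    t_on = seq(0, by = 0.25, length.out = 14), dur = 0.2)
  tr <- trial_from_fix(fix)
  m <- mean_shift_cluster(list(tr), bandwidth = 80)
  expect_length(m$labels, 2L)
  expect_message(m2 <- discard_offimage_clusters(m, 1680, 1050), "discarded")
  expect_length(m2$labels, 1L)
  expect_equal(nrow(m2$assignment), 10L)

  # all centroids inside: unchanged
  inside <- mean_shift_cluster(list(trial_from_fix(fix[1:10, ])), bandwidth = 80)
  expect_identical(discard_offimage_clusters(inside, 1680, 1050), inside)

  # everything off-image: empty model, flagged
  off <- mean_shift_cluster(list(trial_from_fix(fix[11:14, ])), bandwidth = 80)
  expect_message(m0 <- discard_offimage_clusters(off, 1680, 1050), "empty")
  expect_length(m0$labels, 0L)
})

test_that("k-means segmentation splits a two-colour image exactly", {
  ras <- array(0, c(4, 4, 3))
  ras[, 1:2, 1] <- 1           # left half red, right half black
  m <- kmeans_segment(ras, k = 2, spatial_weight = 0, seed = 1)
  expect_length(m$labels, 2L)
  expect_length(unique(as.vector(m$label_map[, 1:2])), 1L)
  expect_length(unique(as.vector(m$label_map[, 3:4])), 1L)
  expect_false(m$label_map[1, 1] == m$label_map[1, 3])
  expect_true(all(m$label_map %in% 1:2))   # every pixel labelled

  # reproducibility under a fixed seed
  expect_identical(m$label_map, kmeans_segment(ras, 2, 0, seed = 1)$label_map)

  expect_length(kmeans_segment(ras, k = 1)$labels, 1L)
  # uniform colour with colour-only features: a single distinct vector
  uni <- array(0.5, c(3, 3, 3))
  expect_warning(mu <- kmeans_segment(uni, k = 2, spatial_weight = 0),
                 "distinct")
  expect_length(mu$labels, 1L)
  expect_error(kmeans_segment(ras, k = 0), "positive integer")
})

test_that("visual-unit encoding preserves order and drops out-of-bounds fixations", {
  # msfc-style: assignment by fixation index, pattern 3 2 2 3
  fix <- data.frame(x = c(10, 500, 510, 20), y = rep(100, 4),
                    t_on = c(0, 0.3, 0.6, 0.9), dur = rep(0.25, 4))
  tr <- trial_from_fix(fix)
  model <- region_model("msfc", c("cluster2", "cluster3"),
                        assignment = data.frame(
                          observer = "o1", image = "i1", fix = 1:4,
                          label = c("cluster3", "cluster2", "cluster2", "cluster3")),
                        centroids = data.frame(label = c("cluster2", "cluster3"),
                                               x = c(505, 15), y = c(100, 100)))
  vu <- encode_visual_units(tr, model)
  expect_equal(vu$label, c("cluster3", "cluster2", "cluster2", "cluster3"))
  expect_equal(vu$t_on, fix$t_on)
  expect_equal(vu$dur, fix$dur)
  expect_false(is.unsorted(vu$t_on))

  # label-map model: out-of-bounds fixation dropped, order intact
  map <- matrix(1L, 100, 100); map[, 51:100] <- 2L
  ext <- external_region_model(map)
  fix2 <- data.frame(x = c(10, 2000, 80), y = c(10, 50, 50),
                     t_on = c(0, 0.3, 0.6), dur = 0.25)
  expect_message(vu2 <- encode_visual_units(trial_from_fix(fix2, w = 100, h = 100), ext),
                 "dropped 1")
  expect_equal(vu2$label, c("region1", "region2"))

  # empty trial: empty sequence
  empty <- trial_from_fix(data.frame(x = numeric(), y = numeric(),
                                     t_on = numeric(), dur = numeric()))
  expect_equal(nrow(encode_visual_units(empty, model)), 0L)
})
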