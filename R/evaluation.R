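## Reference alignments, temporal baselines, and precision / recall / AER.

#' Construct a reference alignment
#'
#' Sure links (S) are unambiguous word-region correspondences; possible links
#' (P) are plausible but uncertain ones. Evaluation uses P* = S `union` P, so
#' sure links are never penalized for being missing from P.
#'
#' @param S,P Data frames `(word, region)`.
#' @export
reference_alignment <- function(S, P = S[0, , drop = FALSE]) {
  norm <- function(d) {
    d <- unique(data.frame(word = tolower(as.character(d$word)),
                           region = as.character(d$region),
                           stringsAsFactors = FALSE))
    d[order(d$word, d$region), , drop = FALSE]
  }
  S <- norm(S); P <- norm(P)
  structure(list(S = S, P = P, P_star = norm(rbind(S, P))),
            class = "reference_alignment")
}

#' @export
print.reference_alignment <- function(x, ...) {
  cat(sprintf("<reference_alignment> %d sure, %d possible (P* = %d)\n",
              nrow(x$S), nrow(x$P), nrow(x$P_star)))
  invisible(x)
}

#' Describe a manually annotated reference region
#'
#' @param id Region identifier.
#' @param polygon Optional matrix/data frame of (x, y) vertices in 0-based
#'   pixel coordinates.
#' @param pixels Optional data frame `(x, y)` of member pixels (alternative to
#'   a polygon).
#' @param sure_words,possible_words Word lists attached by the annotator.
#' @export
reference_region <- function(id, polygon = NULL, pixels = NULL,
                             sure_words = character(),
                             possible_words = character()) {
  if (is.null(polygon) && is.null(pixels))
    stop_fmt("reference region '%s' needs a polygon or a pixel set", id)
  structure(list(id = as.character(id),
                 polygon = if (!is.null(polygon)) as.matrix(polygon),
                 pixels = pixels,
                 sure_words = tolower(sure_words),
                 possible_words = tolower(possible_words)),
            class = "reference_region")
}

points_in_region <- function(region, x, y) {
  if (!length(x)) return(logical(0))
  if (!is.null(region$polygon))
    mgcv::in.out(rbind(region$polygon, region$polygon[1, ]), cbind(x, y))
  else
    paste(floor(x), floor(y)) %in% paste(floor(region$pixels$x),
                                         floor(region$pixels$y))
}

#' Project pixel-level reference regions onto a region model's labels
#'
#' The annotator labels pixel regions with sure/possible words; the pipeline's
#' alignments use cluster or segment labels. A mean-shift cluster maps to a
#' reference region when a strict majority of the cluster's fixations fall
#' inside the region; a label-map segment maps to the reference region with
#' which it shares the most pixels, provided the overlap covers at least half
#' the segment and strictly beats every other region. Reference regions with
#' no mapped label are reported as uncovered (they bound attainable recall).
#'
#' @param regions List of [reference_region()].
#' @param model A [region_model()].
#' @param trials For `"msfc"` models, the trials whose fixations the model
#'   assigned (used to locate each cluster's fixations).
#' @return A [reference_alignment()] in label space, with attribute
#'   `"coverage"`: data frame `(id, labels, covered)`.
#' @export
project_reference <- function(regions, model, trials = NULL) {
  stopifnot(inherits(model, "region_model"))
  label_to_region <- character(0)
  if (model$method == "msfc") {
    if (is.null(trials)) stop_fmt("msfc projection needs the clustered trials")
    pooled <- pooled_fixations(trials)
    a <- model$assignment
    key <- paste(pooled$observer, pooled$image, pooled$fix)
    akey <- paste(a$observer, a$image, a$fix)
    pooled$label <- a$label[match(key, akey)]
    pooled <- pooled[!is.na(pooled$label), , drop = FALSE]
    for (lab in model$labels) {
      pts <- pooled[pooled$label == lab, , drop = FALSE]
      if (!nrow(pts)) next
      frac <- vapply(regions, function(r)
        mean(points_in_region(r, pts$x, pts$y)), numeric(1))
      hit <- which(frac > 0.5)
      if (length(hit) == 1L)
        label_to_region[lab] <- regions[[hit]]$id
      else if (length(hit) > 1L) {
        best <- which(frac == max(frac))
        if (length(best) == 1L) label_to_region[lab] <- regions[[best]]$id
      }
    }
  } else {
    map <- model$label_map
    xs <- col(map) - 1; ys <- row(map) - 1
    for (li in seq_along(model$labels)) {
      m <- map == li
      frac <- vapply(regions, function(r)
        mean(points_in_region(r, xs[m], ys[m])), numeric(1))
      best <- which.max(frac)
      if (frac[best] >= 0.5 && sum(frac == frac[best]) == 1L)
        label_to_region[model$labels[li]] <- regions[[best]]$id
    }
  }
  region_ids <- vapply(regions, `[[`, character(1), "id")
  mk <- function(field) {
    rows <- list()
    for (lab in names(label_to_region)) {
      r <- regions[[match(label_to_region[lab], region_ids)]]
      ws <- r[[field]]
      if (length(ws))
        rows[[length(rows) + 1L]] <- data.frame(word = ws, region = lab,
                                                stringsAsFactors = FALSE)
    }
    if (length(rows)) do.call(rbind, rows)
    else data.frame(word = character(), region = character())
  }
  ref <- reference_alignment(mk("sure_words"), mk("possible_words"))
  cov <- data.frame(
    id = region_ids,
    labels = vapply(region_ids, function(id)
      paste(names(label_to_region)[label_to_region == id], collapse = ","),
      character(1)),
    covered = region_ids %in% label_to_region,
    stringsAsFactors = FALSE)
  if (any(!cov$covered))
    message(sprintf("%d reference region(s) uncovered by any label",
                    sum(!cov$covered)))
  attr(ref, "coverage") <- cov
  ref
}

## visual unit active at time t: the unit whose [t_on, t_on + dur) covers t,
## else (under the "preceding" gap rule) the most recent earlier unit.
active_unit <- function(vunits, t, gap = c("preceding", "strict")) {
  gap <- match.arg(gap)
  k <- findInterval(t, vunits$t_on)
  if (k == 0L) return(NA_character_)
  if (gap == "strict" && t >= vunits$t_on[k] + vunits$dur[k])
    return(NA_character_)
  vunits$label[k]
}

#' Simultaneous temporal baseline for one trial
#'
#' Assumes the observer utters a region's word at the exact moment of fixating
#' it: each linguistic unit links to the visual unit active at its onset
#' (falling back to the most recent preceding unit in fixation gaps); words
#' before the first fixation stay unaligned.
#'
#' @param vunits,lunits Unit data frames for one trial.
#' @param gap `"preceding"` (default) or `"strict"` (unaligned in gaps).
#' @return Data frame `(word, region)`.
#' @export
baseline_simultaneous <- function(vunits, lunits, gap = "preceding") {
  baseline_delayed(vunits, lunits, delay = 0, gap = gap)
}

#' Fixed-delay temporal baseline for one trial
#'
#' Like [baseline_simultaneous()] but assumes a fixed eye-voice delay: the
#' word at time t is matched to the visual unit active at t - delay.
#'
#' @inheritParams baseline_simultaneous
#' @param delay Delay in seconds (default 1).
#' @export
baseline_delayed <- function(vunits, lunits, delay = 1, gap = "preceding") {
  stopifnot(delay >= 0)
  if (!nrow(lunits) || !nrow(vunits))
    return(data.frame(word = character(), region = character(),
                      stringsAsFactors = FALSE))
  region <- vapply(lunits$t_on, function(t)
    active_unit(vunits, t - delay, gap), character(1))
  keep <- !is.na(region)
  data.frame(word = lunits$surface[keep], region = region[keep],
             stringsAsFactors = FALSE)
}

#' Pooled baseline alignment set for one image
#'
#' Applies a temporal baseline per observer and pools the links into a set of
#' distinct (word, region) pairs, mirroring [align_image()] so that framework
#' and baselines are scored identically.
#'
#' @param vunit_seqs,lunit_seqs Named lists (by observer) of unit data frames.
#' @param delay Baseline delay in seconds (0 = simultaneous).
#' @param gap Gap rule, see [baseline_simultaneous()].
#' @export
baseline_image <- function(vunit_seqs, lunit_seqs, delay = 1,
                           gap = "preceding") {
  observers <- intersect(names(vunit_seqs), names(lunit_seqs))
  links <- do.call(rbind, lapply(observers, function(obs)
    baseline_delayed(vunit_seqs[[obs]], lunit_seqs[[obs]], delay, gap)))
  if (is.null(links))
    return(data.frame(word = character(), region = character()))
  u <- unique(links)
  u[order(u$word, u$region), , drop = FALSE]
}

#' Precision, recall, and alignment error rate against a reference
#'
#' precision = |A `intersect` P*| / |A|, recall = |A `intersect` S| / |S|,
#' AER = 1 - (|A `intersect` S| + |A `intersect` P*|) / (|A| + |S|), with
#' P* = S `union` P. An empty A yields vacuous precision 1, recall 0, and
#' AER = 1 - 0 / |S|; an empty S makes recall undefined (`NA`, with warning).
#'
#' @param A Alignment set: data frame `(word, region)`.
#' @param reference A [reference_alignment()].
#' @return List of class `alignment_metrics`.
#' @export
compute_metrics <- function(A, reference) {
  stopifnot(inherits(reference, "reference_alignment"))
  keyify <- function(d) paste(tolower(d$word), d$region, sep = "\r")
  a <- unique(keyify(A))
  s <- keyify(reference$S); ps <- keyify(reference$P_star)
  n_a <- length(a); n_s <- length(s)
  a_s <- sum(a %in% s); a_ps <- sum(a %in% ps)
  if (n_s == 0L) warning("empty sure set: recall undefined")
  structure(list(
    precision = if (n_a > 0) a_ps / n_a else 1,
    recall = if (n_s > 0) a_s / n_s else NA_real_,
    aer = 1 - (a_s + a_ps) / (n_a + n_s),
    n_A = n_a, n_S = n_s, n_A_S = a_s, n_A_Pstar = a_ps),
    class = "alignment_metrics")
}

#' @export
print.alignment_metrics <- function(x, ...) {
  cat(sprintf("precision %.3f  recall %.3f  AER %.3f  (|A|=%d |S|=%d)\n",
              x$precision, x$recall, x$aer, x$n_A, x$n_S))
  invisible(x)
}

#' Macro-averaged summary and per-image improvement counts
#'
#' Averages precision, recall, and AER per method over images and counts, for
#' each baseline, the images where the framework strictly improves each
#' metric (higher precision/recall, lower AER).
#'
#' @param per_image Data frame with columns `image`, `method`, `precision`,
#'   `recall`, `aer`; one row per image and method, with the framework rows
#'   labelled by `framework_method`.
#' @param framework_method Name of the framework's method in `method`.
#' @return List with `summary` (macro averages per method) and `improvement`
#'   (counts and absolute percentage-point improvements vs each baseline).
#' @export
summarize_metrics <- function(per_image, framework_method = "framework") {
  stopifnot(nrow(per_image) > 0)
  methods <- unique(per_image$method)
  stopifnot(framework_method %in% methods)
  avg <- do.call(rbind, lapply(methods, function(m) {
    d <- per_image[per_image$method == m, , drop = FALSE]
    data.frame(method = m, precision = mean(d$precision),
               recall = mean(d$recall), aer = mean(d$aer),
               n_images = nrow(d), stringsAsFactors = FALSE)
  }))
  fw <- per_image[per_image$method == framework_method, , drop = FALSE]
  fw <- fw[order(fw$image), , drop = FALSE]
  imp <- do.call(rbind, lapply(setdiff(methods, framework_method), function(m) {
    b <- per_image[per_image$method == m, , drop = FALSE]
    b <- b[order(b$image), , drop = FALSE]
    stopifnot(identical(b$image, fw$image))
    data.frame(baseline = m,
               images = nrow(b),
               n_precision = sum(fw$precision > b$precision),
               n_recall = sum(fw$recall > b$recall),
               n_aer = sum(fw$aer < b$aer),
               d_precision = 100 * (mean(fw$precision) - mean(b$precision)),
               d_recall = 100 * (mean(fw$recall) - mean(b$recall)),
               d_aer = 100 * (mean(b$aer) - mean(fw$aer)),
               stringsAsFactors = FALSE)
  }))
  list(summary = avg, improvement = imp)
}

#' Write reference regions for one image as JSON
#' @param regions List of [reference_region()].
#' @param path Output file.
#' @export
write_reference_regions <- function(regions, path) {
  jsonlite::write_json(lapply(regions, function(r) list(
    id = r$id,
    polygon = if (!is.null(r$polygon)) unname(apply(r$polygon, 1, as.list)),
    pixels = r$pixels,
    sure_words = r$sure_words, possible_words = r$possible_words)),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read reference regions written by [write_reference_regions()]
#' @param path JSON file.
#' @export
read_reference_regions <- function(path) {
  obj <- jsonlite::read_json(path)
  lapply(obj, function(o) reference_region(
    id = o$id,
    polygon = if (!is.null(o$polygon))
      do.call(rbind, lapply(o$polygon, function(v) c(v[[1]], v[[2]]))),
    pixels = if (!is.null(o$pixels))
      data.frame(x = vapply(o$pixels$x, as.numeric, numeric(1)),
                 y = vapply(o$pixels$y, as.numeric, numeric(1))),
    sure_words = unlist(o$sure_words) %||% character(),
    possible_words = unlist(o$possible_words) %||% character()))
}
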