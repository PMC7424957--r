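## Aggregation of alignment links into ranked word labels per image region.

#' Aggregate decoded links into ranked region annotations
#'
#' For each region, the words linked to it across observers are ranked by
#' frequency of utterance in the image's narratives (descending by default;
#' the ascending variant is available via `order`), with ties broken by
#' maximum link posterior and then lexicographically. Regions without links
#' appear with empty annotations.
#'
#' @param links Data frame `(word, region, posterior)` of decoded links
#'   (e.g. the `"links"` attribute of [align_image()], or the pooled set).
#' @param word_freq Named integer vector: utterance counts of each word in the
#'   image's narratives.
#' @param regions Region labels to report (default: those present in `links`).
#' @param order `"decreasing"` (default) or `"increasing"` frequency.
#' @return Data frame `(region, rank, word, count, posterior)` of class
#'   `region_annotation`.
#' @export
aggregate_labels <- function(links, word_freq, regions = NULL,
                             order = c("decreasing", "increasing")) {
  order <- match.arg(order)
  regions <- regions %||% sort(unique(links$region))
  out <- list()
  for (reg in regions) {
    d <- links[links$region == reg, , drop = FALSE]
    if (!nrow(d)) {
      out[[length(out) + 1L]] <- data.frame(
        region = character(0), rank = integer(0), word = character(0),
        count = integer(0), posterior = numeric(0), stringsAsFactors = FALSE)
      next
    }
    post <- tapply(d$posterior, d$word, max)
    words <- names(post)
    cnt <- unname(word_freq[words])
    cnt[is.na(cnt)] <- 0L
    ord <- order(if (order == "decreasing") -cnt else cnt,
                 -unname(post), words)
    out[[length(out) + 1L]] <- data.frame(
      region = reg, rank = seq_along(ord), word = words[ord],
      count = as.integer(cnt[ord]), posterior = as.numeric(post[ord]),
      stringsAsFactors = FALSE)
  }
  ann <- if (length(out)) do.call(rbind, out) else
    data.frame(region = character(0), rank = integer(0), word = character(0),
               count = integer(0), posterior = numeric(0),
               stringsAsFactors = FALSE)
  rownames(ann) <- NULL
  class(ann) <- c("region_annotation", class(ann))
  ann
}

#' Export region annotations as a TSV plus an overlay JSON
#'
#' The TSV holds one row per (region, rank, word); the overlay JSON maps each
#' region to its centroid (the anchor where a visualizer would place the top
#' `W` labels) and its ranked words.
#'
#' @param annotations A `region_annotation` from [aggregate_labels()].
#' @param model The [region_model()] providing centroids.
#' @param dir Output directory.
#' @param W Number of words per region in the overlay (default 3).
#' @export
export_annotations <- function(annotations, model, dir, W = 3) {
  stopifnot(W >= 1)
  unknown <- setdiff(unique(annotations$region), model$labels)
  if (length(unknown))
    stop_fmt("unknown region label(s): %s", paste(unknown, collapse = ", "))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(as.data.frame(annotations),
                     file.path(dir, "annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cen <- model$centroids
  overlay <- lapply(unique(annotations$region), function(reg) {
    d <- annotations[annotations$region == reg, , drop = FALSE]
    i <- match(reg, cen$label)
    list(region = reg,
         centroid = c(cen$x[i], cen$y[i]),
         words = utils::head(d$word, W))
  })
  jsonlite::write_json(overlay, file.path(dir, "overlay.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
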