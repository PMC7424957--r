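## Parallel "bitext" corpus construction: sliding windows over the two unit
## streams, contiguous-unit merging, duration-based selection under the
## visual-linguistic ratio, and the corpus file format.

#' Corpus construction parameters
#'
#' @param T_window Sliding-window length in seconds (default 5).
#' @param stride Window stride in seconds (default 0.5); windows overlap when
#'   `stride < T_window`.
#' @param alpha Visual-unit selection method when a window holds more visual
#'   than linguistic units: `"longest"` keeps the longest-duration units
#'   (default; ties favour the earlier unit), `"earliest"` keeps the first
#'   ones, `"random"` samples without replacement.
#' @param beta Visual-linguistic ratio: the visual side of each pair is
#'   truncated to `round(beta * n_linguistic)` units (at least 1, capped at
#'   availability). `beta = 1` balances the two sides.
#' @param full_pair_balance Whether the whole-trial pair appended to the
#'   corpus also receives beta-balancing. Balancing is defined per sliding
#'   window; the whole-trial pair is included as-is (after contiguous-unit
#'   merging) by default, so that decoding sees every region the observer
#'   visited.
#' @param seed Seed used only by `alpha = "random"`.
#' @export
corpus_config <- function(T_window = 5, stride = 0.5,
                          alpha = c("longest", "earliest", "random"),
                          beta = 1, full_pair_balance = FALSE, seed = 1) {
  alpha <- match.arg(alpha)
  stopifnot(T_window > 0, stride > 0, stride <= T_window, beta > 0)
  structure(list(T_window = T_window, stride = stride, alpha = alpha,
                 beta = beta, full_pair_balance = full_pair_balance,
                 seed = seed),
            class = "corpus_config")
}

#' Extract sliding-window sub-sequences of the two unit streams
#'
#' Windows `[w, w + T)` start at `w = 0, stride, 2 stride, ...` while
#' `w < D`, where `D` is the trial duration (the maximum unit end time). A
#' unit belongs to a window iff its onset lies in the half-open interval.
#' Windows with an empty side are dropped.
#'
#' @param vunits Visual-unit data frame `(label, t_on, dur)`.
#' @param lunits Linguistic-unit data frame `(surface, t_on)`.
#' @param config A [corpus_config()].
#' @return List of `list(visual =, linguistic =, window_start =)`.
#' @export
slide_windows <- function(vunits, lunits, config = corpus_config()) {
  d_candidates <- c(if (nrow(vunits)) vunits$t_on + vunits$dur,
                    if (nrow(lunits)) lunits$t_on)
  if (!length(d_candidates)) return(list())
  D <- max(d_candidates)
  starts <- seq(0, D, by = config$stride)
  starts <- starts[starts < D]
  out <- list()
  for (w in starts) {
    vs <- vunits[vunits$t_on >= w & vunits$t_on < w + config$T_window, , drop = FALSE]
    ls <- lunits[lunits$t_on >= w & lunits$t_on < w + config$T_window, , drop = FALSE]
    if (nrow(vs) == 0L || nrow(ls) == 0L) next
    out[[length(out) + 1L]] <- list(visual = vs, linguistic = ls,
                                    window_start = w)
  }
  out
}

#' Merge contiguous identical visual units
#'
#' Maximal runs of equal labels collapse to a single unit whose duration is
#' the summed duration of the run and whose onset is the first unit's onset;
#' e.g. `cluster3, cluster2, cluster2, cluster3` becomes
#' `cluster3, cluster2, cluster3`.
#'
#' @param vunits Visual-unit data frame `(label, t_on, dur)`.
#' @export
merge_contiguous <- function(vunits) {
  if (nrow(vunits) == 0L) return(vunits)
  run <- cumsum(c(TRUE, vunits$label[-1] != vunits$label[-nrow(vunits)]))
  out <- data.frame(
    label = vunits$label[!duplicated(run)],
    t_on = vunits$t_on[!duplicated(run)],
    dur = as.numeric(tapply(vunits$dur, run, sum)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Select a fixed number of visual units
#'
#' Keeps `n_target` of the units while preserving their linear order. With
#' `alpha = "longest"` the greatest-duration units are kept (duration ties go
#' to the earlier unit); `"earliest"` keeps the first `n_target`; `"random"`
#' samples without replacement under `seed`.
#'
#' @param vunits Merged visual-unit data frame.
#' @param n_target Number of units to keep (>= 1).
#' @param alpha Selection method.
#' @param seed Seed for `alpha = "random"`.
#' @export
select_units <- function(vunits, n_target, alpha = "longest", seed = 1) {
  if (!is_count(n_target)) stop_fmt("n_target must be a positive integer")
  n <- nrow(vunits)
  if (n <= n_target) return(vunits)
  keep <- switch(alpha,
    longest = sort(order(-vunits$dur, vunits$t_on)[seq_len(n_target)]),
    earliest = seq_len(n_target),
    random = sort(with_seed(seed, sample.int(n, n_target))),
    stop_fmt("unknown selection method '%s'", alpha))
  vunits[keep, , drop = FALSE]
}

#' Balance one visual/linguistic pair under the visual-linguistic ratio
#'
#' The target visual length is `max(1, round(beta * n_linguistic))` (round
#' half away from zero); the visual side is truncated to it with
#' [select_units()]. Nothing is ever padded.
#'
#' @param vmerged Merged visual units.
#' @param lsub Linguistic units (nonempty).
#' @param config A [corpus_config()].
#' @return `list(visual =, linguistic =)` or `NULL` when the visual side is
#'   empty (the pair is dropped with a message).
#' @export
balance_pair <- function(vmerged, lsub, config = corpus_config()) {
  stopifnot(nrow(lsub) > 0L)
  if (nrow(vmerged) == 0L) {
    message("pair dropped: no visual units after merging")
    return(NULL)
  }
  n_target <- max(1, round_half_up(config$beta * nrow(lsub)))
  list(visual = select_units(vmerged, n_target, config$alpha, config$seed),
       linguistic = lsub)
}

#' Build the parallel corpus for one image
#'
#' For every observer, each sliding window contributes one pair (after
#' contiguous-unit merging and beta-balancing of its visual side), and the
#' whole-trial sequence pair is appended as well. Observers with an empty
#' linguistic or visual sequence contribute no pairs.
#'
#' @param vunit_seqs,lunit_seqs Named lists (by observer) of visual- and
#'   linguistic-unit data frames for a single image.
#' @param config A [corpus_config()].
#' @return A `parallel_corpus`: list of pairs, each
#'   `list(visual = chr, linguistic = chr, observer, origin, window_start)`.
#' @export
build_corpus <- function(vunit_seqs, lunit_seqs, config = corpus_config()) {
  observers <- intersect(names(vunit_seqs), names(lunit_seqs))
  pairs <- list()
  add_pair <- function(bal, obs, origin, wstart) {
    if (is.null(bal)) return()
    pairs[[length(pairs) + 1L]] <<- list(visual = bal$visual$label,
                                         linguistic = bal$linguistic$surface,
                                         observer = obs, origin = origin,
                                         window_start = wstart)
  }
  for (obs in observers) {
    vu <- vunit_seqs[[obs]]; lu <- lunit_seqs[[obs]]
    if (is.null(vu) || is.null(lu) || nrow(vu) == 0L || nrow(lu) == 0L) {
      message(sprintf("observer %s contributes no pairs (empty unit sequence)", obs))
      next
    }
    for (win in slide_windows(vu, lu, config))
      add_pair(balance_pair(merge_contiguous(win$visual), win$linguistic, config),
               obs, "window", win$window_start)
    full_v <- merge_contiguous(vu)
    if (config$full_pair_balance)
      add_pair(balance_pair(full_v, lu, config), obs, "full", NA_real_)
    else if (nrow(full_v))
      add_pair(list(visual = full_v, linguistic = lu), obs, "full", NA_real_)
  }
  structure(pairs, class = "parallel_corpus")
}

#' @export
print.parallel_corpus <- function(x, ...) {
  cat(sprintf("<parallel_corpus> %d pairs (%d full, %d windowed)\n", length(x),
              sum(vapply(x, function(p) p$origin == "full", logical(1))),
              sum(vapply(x, function(p) p$origin == "window", logical(1)))))
  invisible(x)
}

#' Write a parallel corpus in the two-file bitext convention
#'
#' `visual.txt` and `linguistic.txt` hold one space-separated sentence per
#' line; `manifest.tsv` records observer, origin, and window start per line.
#'
#' @param corpus A `parallel_corpus`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(vapply(corpus, function(p) paste(p$visual, collapse = " "),
                    character(1)), file.path(dir, "visual.txt"))
  writeLines(vapply(corpus, function(p) paste(p$linguistic, collapse = " "),
                    character(1)), file.path(dir, "linguistic.txt"))
  man <- data.frame(
    line = seq_along(corpus),
    observer = vapply(corpus, `[[`, character(1), "observer"),
    origin = vapply(corpus, `[[`, character(1), "origin"),
    window_start = vapply(corpus, `[[`, numeric(1), "window_start"))
  utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a parallel corpus written by [write_corpus()]
#' @param dir Directory holding `visual.txt`, `linguistic.txt`, `manifest.tsv`.
#' @export
read_corpus <- function(dir) {
  vis <- strsplit(readLines(file.path(dir, "visual.txt")), " ", fixed = TRUE)
  lin <- strsplit(readLines(file.path(dir, "linguistic.txt")), " ", fixed = TRUE)
  man <- utils::read.delim(file.path(dir, "manifest.tsv"), stringsAsFactors = FALSE)
  stopifnot(length(vis) == length(lin), nrow(man) == length(vis))
  structure(lapply(seq_along(vis), function(i)
    list(visual = vis[[i]], linguistic = lin[[i]],
         observer = as.character(man$observer[i]), origin = man$origin[i],
         window_start = man$window_start[i])),
    class = "parallel_corpus")
}
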