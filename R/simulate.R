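## Synthetic co-registered scanpaths and narratives with known word-region
## ground truth, for end-to-end validation of the alignment pipeline.

#' Specify a synthetic scene
#'
#' A scene is a set of spatially separated regions of interest, each with a
#' Gaussian fixation footprint, a salience weight, and a small name lexicon
#' (a dominant name plus an optional shared synonym, with sampling
#' probabilities that sum to 1).
#'
#' @param n_regions Number of regions (default 14, the upper range of the
#'   roughly a-dozen gaze clusters a complex everyday scene yields).
#' @param image_w,image_h Image size in pixels (defaults match a 1680 x 1050
#'   display).
#' @param sigma Per-region fixation scatter in pixels.
#' @param n_synonyms Shared synonyms per region (0 or 1).
#' @param synonym_p Lexicon probability of the synonym (dominant gets the
#'   rest).
#' @param seed Optional seed.
#' @return A `scene_spec`.
#' @export
make_scene <- function(n_regions = 14, image_w = 1680, image_h = 1050,
                       sigma = 30, n_synonyms = 1, synonym_p = 0.15,
                       seed = NULL) {
  stopifnot(n_regions >= 1, n_synonyms %in% 0:1, synonym_p >= 0, synonym_p < 1)
  with_seed(seed, {
    margin <- 140
    nc <- ceiling(sqrt(n_regions * image_w / image_h))
    nr <- ceiling(n_regions / nc)
    cw <- (image_w - 2 * margin) / nc
    ch <- (image_h - 2 * margin) / nr
    cells <- expand.grid(cx = seq_len(nc), cy = seq_len(nr))
    cells <- cells[sample.int(nrow(cells), n_regions), , drop = FALSE]
    cx <- margin + (cells$cx - 0.5) * cw + stats::runif(n_regions, -.15, .15) * cw
    cy <- margin + (cells$cy - 0.5) * ch + stats::runif(n_regions, -.15, .15) * ch
    need <- n_regions * (1 + n_synonyms)
    words <- sample(concrete_noun_bank(), need)
    regions <- lapply(seq_len(n_regions), function(i) {
      names_i <- words[i]
      probs_i <- 1
      if (n_synonyms == 1) {
        names_i <- c(words[i], words[n_regions + i])
        probs_i <- c(1 - synonym_p, synonym_p)
      }
      list(id = sprintf("r%02d", i), centroid = c(cx[i], cy[i]),
           sigma = sigma, names = names_i, probs = probs_i)
    })
    ## every region is a primary object: uneven interest, but none ignored
    salience <- stats::rgamma(n_regions, shape = 2, rate = 1)
    salience <- 0.6 / n_regions + 0.4 * salience / sum(salience)
    structure(list(image_w = image_w, image_h = image_h, regions = regions,
                   salience = salience),
              class = "scene_spec")
  })
}

concrete_noun_bank <- function() c(
  "bear", "log", "giraffe", "tree", "man", "woman", "dog", "cat", "table",
  "chair", "car", "boat", "bird", "fish", "flower", "rock", "house", "door",
  "window", "ball", "book", "cup", "plate", "bottle", "horse", "cow", "sheep",
  "goat", "duck", "chicken", "child", "baby", "hat", "coat", "shoe", "bag",
  "lamp", "fence", "road", "river", "bridge", "cloud", "mountain", "field",
  "grass", "bench", "sign", "pole", "wheel", "train", "plane", "bike",
  "truck", "bus", "kite", "banana", "apple", "orange", "egg", "bread",
  "cake", "pizza", "knife", "fork", "spoon", "bowl", "towel", "mirror",
  "clock", "phone", "laptop", "camera", "scissors", "tie", "suit", "dress",
  "shirt", "glove", "umbrella", "basket")

## scene-level commentary vocabulary: few types, each uttered often, so their
## lack of grounding is statistically visible
abstract_noun_bank <- function() c(
  "picture", "scene", "thing", "side", "part", "area", "middle",
  "background", "image", "spot")

filler_word_bank <- function() c(
  "okay", "um", "uh", "the", "and", "a", "so", "like", "there", "is", "it",
  "of", "well", "just", "really")

## deterministic pronounceable pseudo-word for observer-idiosyncratic naming
pseudo_word <- function(i) {
  syl <- c("ba", "do", "fi", "gu", "ka", "lo", "mi", "na", "po", "ri",
           "su", "ta", "ve", "wo", "zu")
  n <- length(syl)
  paste0(syl[(i %% n) + 1], syl[((i %/% n) %% n) + 1],
         syl[((i %/% (n * n)) %% n) + 1])
}

#' Behavioral parameters of a simulated observer
#'
#' Defaults reproduce the regularities of observers describing everyday
#' scenes: 250 ms mean fixation durations, roughly 22 s narratives at about
#' 2.5 words per second, a 0.58 s silent preview before speech begins, and a
#' variable sub-second eye-voice lag (word onset follows the onset of the
#' generating fixation by N(0.9 s, 0.3 s)).
#'
#' @param fix_dur_mean Mean fixation duration in seconds (lognormal).
#' @param fix_dur_sdlog Lognormal log-scale SD of fixation durations.
#' @param speech_rate Words per second.
#' @param narrative_len Target narrative duration in seconds.
#' @param lag_mean,lag_sd Eye-voice lag (seconds) from fixation onset to word
#'   onset; negative draws are clamped at 0.
#' @param preview Silent viewing before the first filler word (seconds).
#' @param filler_rate Fraction of the speech-rate slot grid filled with
#'   non-groundable filler words (stopwords).
#' @param abstract_rate Probability per visit of uttering an abstract,
#'   non-groundable content noun ("picture", "thing", ...) at an arbitrary
#'   time in the narrative. Default 0: such words survive the linguistic
#'   filters yet have no generating region, breaking the simulator's
#'   one-region-per-content-word ground-truth contract, so they are an
#'   opt-in robustness stressor rather than part of the default conditions.
#' @param name_prob Probability of naming a region on its first visit.
#' @param idio_rate Probability that a naming uses an observer-idiosyncratic
#'   word instead of the scene lexicon; such words occur once per image and
#'   model the lexical diversity that per-image singleton filtering removes.
#' @param synonym_use Sample region names from the full lexicon (`TRUE`) or
#'   always use the dominant name (`FALSE`).
#' @param offimage_rate Probability a fixation is replaced by an off-image
#'   blink/track-loss point.
#' @param saccade_gap Gap between consecutive fixations (seconds).
#' @param named_extra_fix Extra fixations spent on a region while naming it
#'   (longer dwell on described regions).
#' @export
observer_params <- function(fix_dur_mean = 0.25, fix_dur_sdlog = 0.4,
                            speech_rate = 2.5, narrative_len = 22,
                            lag_mean = 0.9, lag_sd = 0.3, preview = 0.58,
                            filler_rate = 0.75, abstract_rate = 0,
                            name_prob = 0.5, idio_rate = 0.43,
                            synonym_use = TRUE, offimage_rate = 0.005,
                            saccade_gap = 0.035, named_extra_fix = 3) {
  stopifnot(fix_dur_mean > 0, fix_dur_sdlog >= 0, speech_rate > 0,
            narrative_len > 0, lag_mean >= 0, lag_sd >= 0, preview >= 0,
            filler_rate >= 0, filler_rate <= 1,
            abstract_rate >= 0, abstract_rate <= 1,
            name_prob >= 0, name_prob <= 1, idio_rate >= 0, idio_rate <= 1,
            offimage_rate >= 0, offimage_rate <= 1, saccade_gap >= 0,
            named_extra_fix >= 0)
  structure(as.list(environment()), class = "observer_params")
}

rlag <- function(n, params) pmax(0, stats::rnorm(n, params$lag_mean, params$lag_sd))

#' Simulate one observer's trial over a scene
#'
#' The observer's gaze follows a salience-weighted visit chain over the scene
#' regions (no immediate self-transitions, revisits allowed); fixations are
#' drawn around region centroids; a region is named (lexicon-sampled) on its
#' first visit with probability `name_prob`, the word onset following the
#' visit onset by the eye-voice lag; abstract nouns and filler words are
#' interleaved to reach the target speech rate.
#'
#' @param scene A [make_scene()] spec.
#' @param params [observer_params()].
#' @param observer,image Identifiers.
#' @param seed Optional seed (deterministic trial for a fixed seed).
#' @return A `simulated_trial`: list with `trial` ([scanpath_trial()]),
#'   `narr` ([narrative()]), `visits`, `fix_region` (generating region per
#'   fixation, `NA` for blinks), and `truth` (word-region naming events).
#' @export
simulate_trial <- function(scene, params = observer_params(),
                           observer = "obs01", image = "img01", seed = NULL) {
  stopifnot(inherits(scene, "scene_spec"), inherits(params, "observer_params"))
  with_seed(seed, {
    n_reg <- length(scene$regions)
    visits <- list(); t <- 0; prev <- 0L; visited <- logical(n_reg)
    fix <- list(); fix_region <- character(0)
    words <- list(); truth <- list()
    idio_counter <- as.integer(stats::runif(1, 1, 3000))
    while (t < params$narrative_len) {
      w <- scene$salience
      if (prev > 0L && n_reg > 1L) w[prev] <- 0
      r <- sample.int(n_reg, 1, prob = w / sum(w))
      reg <- scene$regions[[r]]
      named <- !visited[r] && stats::runif(1) < params$name_prob
      visited[r] <- TRUE
      n_fix <- 1L + stats::rpois(1, 0.6) +
        if (named) params$named_extra_fix + stats::rpois(1, 1) else 0L
      v_on <- t
      for (f in seq_len(n_fix)) {
        dur <- stats::rlnorm(1, log(params$fix_dur_mean) -
                               params$fix_dur_sdlog^2 / 2, params$fix_dur_sdlog)
        if (stats::runif(1) < params$offimage_rate) {
          pos <- c(-80, -80) + stats::rnorm(2, 0, 15)
          fix_region <- c(fix_region, NA_character_)
        } else {
          pos <- reg$centroid + stats::rnorm(2, 0, reg$sigma)
          fix_region <- c(fix_region, reg$id)
        }
        fix[[length(fix) + 1L]] <- c(pos[1], pos[2], t, dur)
        t <- t + dur + params$saccade_gap
      }
      if (named) {
        if (!params$synonym_use) {
          surface <- reg$names[1]; kind <- "dominant"
        } else if (stats::runif(1) < params$idio_rate) {
          ## observer-tagged so idiosyncratic words never collide across
          ## observers (each occurs once per image and is singleton-filtered)
          surface <- paste0(pseudo_word(idio_counter),
                            gsub("[^a-z0-9]", "", tolower(observer)))
          idio_counter <- idio_counter + 1L
          kind <- "idiosyncratic"
        } else {
          pick <- sample.int(length(reg$names), 1, prob = reg$probs)
          surface <- reg$names[pick]
          kind <- if (pick == 1L) "dominant" else "synonym"
        }
        w_on <- v_on + rlag(1, params)
        words[[length(words) + 1L]] <- list(surface = surface, pos = "NN",
                                            t_on = w_on)
        truth[[length(truth) + 1L]] <- list(word = surface, region = reg$id,
                                            kind = kind, t_on = w_on)
      }
      if (stats::runif(1) < params$abstract_rate)
        ## scene-level commentary is not gaze-locked to any object: its
        ## timing is arbitrary within the narrative
        words[[length(words) + 1L]] <- list(
          surface = sample(abstract_noun_bank(), 1), pos = "NN",
          t_on = stats::runif(1, params$preview, params$narrative_len))
      visits[[length(visits) + 1L]] <- list(region = reg$id, t_on = v_on,
                                            t_off = t, named = named)
      prev <- r
    }
    if (params$filler_rate > 0) {
      slots <- seq(params$preview, params$narrative_len, by = 1 / params$speech_rate)
      keep <- stats::runif(length(slots)) < params$filler_rate
      for (s in slots[keep])
        words[[length(words) + 1L]] <- list(
          surface = sample(filler_word_bank(), 1), pos = "UH", t_on = s)
    }
    fixdf <- as.data.frame(do.call(rbind, fix))
    names(fixdf) <- c("x", "y", "t_on", "dur")
    tokens <- sim_tokens_df(words, params)
    visitsdf <- do.call(rbind, lapply(visits, as.data.frame))
    truthdf <- if (length(truth)) do.call(rbind, lapply(truth, as.data.frame))
      else data.frame(word = character(), region = character(),
                      kind = character(), t_on = numeric())
    structure(list(
      trial = scanpath_trial(observer, image, fixdf, scene$image_w, scene$image_h),
      narr = narrative(observer, image, tokens),
      visits = visitsdf, fix_region = fix_region, truth = truthdf),
      class = "simulated_trial")
  })
}

sim_tokens_df <- function(words, params) {
  if (!length(words))
    return(data.frame(surface = character(), pos = character(),
                      t_on = numeric(), t_off = numeric()))
  d <- data.frame(surface = vapply(words, `[[`, character(1), "surface"),
                  pos = vapply(words, `[[`, character(1), "pos"),
                  t_on = vapply(words, `[[`, numeric(1), "t_on"),
                  stringsAsFactors = FALSE)
  d <- d[order(d$t_on), , drop = FALSE]
  d$t_off <- d$t_on + 0.9 / params$speech_rate
  rownames(d) <- NULL
  d
}

## Guarantee that every region's dominant name is uttered by at least two
## observers (>= 2 utterances), so per-image singleton filtering cannot erase
## the ground truth. Added namings are attached to the observer's longest
## visit to the region with a fresh eye-voice lag, and that visit's dwell is
## extended (speakers keep fixating an object while naming it): the visit's
## last fixation grows and everything after it shifts later in time, keeping
## all onsets monotone.
enforce_dominant_floor <- function(sims, scene, params) {
  for (reg in scene$regions) {
    namers <- vapply(sims, function(s)
      any(s$truth$region == reg$id & s$truth$kind == "dominant"), logical(1))
    need <- 2L - sum(namers)
    if (need <= 0L) next
    cand <- which(!namers & vapply(sims, function(s)
      any(s$visits$region == reg$id), logical(1)))
    if (length(cand) < need) {
      message(sprintf("region %s visited by too few observers to enforce the dominant floor",
                      reg$id))
      cand <- c(cand, which(!namers))[seq_len(min(need, sum(!namers)))]
      cand <- cand[vapply(sims[cand], function(s)
        any(s$visits$region == reg$id), logical(1))]
    }
    for (k in utils::head(cand, need))
      sims[[k]] <- add_enforced_naming(sims[[k]], reg, params)
  }
  sims
}

add_enforced_naming <- function(sim, reg, params) {
  v_all <- sim$visits
  vi <- which(v_all$region == reg$id)
  if (!length(vi)) return(sim)
  vi <- vi[which.max(v_all$t_off[vi] - v_all$t_on[vi])]
  v_on <- v_all$t_on[vi]; v_off <- v_all$t_off[vi]
  delta <- params$named_extra_fix * params$fix_dur_mean

  # dwell extension: stretch the visit's last fixation, shift the rest
  f <- sim$trial$fixations
  in_visit <- which(f$t_on >= v_on & f$t_on < v_off)
  if (length(in_visit)) {
    last <- max(in_visit)
    f$dur[last] <- f$dur[last] + delta
    later <- f$t_on >= v_off
    f$t_on[later] <- f$t_on[later] + delta
    sim$trial$fixations <- f
  } else delta <- 0
  sim$visits$t_off[vi] <- v_off + delta
  later_v <- sim$visits$t_on >= v_off
  sim$visits$t_on[later_v] <- sim$visits$t_on[later_v] + delta
  sim$visits$t_off[later_v] <- sim$visits$t_off[later_v] + delta

  # the naming itself, plus the time shift for everything spoken afterwards
  w_on <- v_on + rlag(1, params)
  tok <- sim$narr$tokens
  tok$t_on[tok$t_on >= v_off] <- tok$t_on[tok$t_on >= v_off] + delta
  tok$t_off <- tok$t_on + 0.9 / params$speech_rate
  tok <- rbind(tok, data.frame(surface = reg$names[1], pos = "NN", t_on = w_on,
                               t_off = w_on + 0.9 / params$speech_rate))
  tok <- tok[order(tok$t_on), , drop = FALSE]
  rownames(tok) <- NULL
  sim$narr <- narrative(sim$narr$observer, sim$narr$image, tok)
  sim$truth$t_on[sim$truth$t_on >= v_off] <-
    sim$truth$t_on[sim$truth$t_on >= v_off] + delta
  sim$truth <- rbind(sim$truth,
                     data.frame(word = reg$names[1], region = reg$id,
                                kind = "dominant", t_on = w_on))
  sim
}

#' Simulate a full multi-image, multi-observer dataset
#'
#' For each image a scene is drawn and `n_observers` trials simulated; the
#' pooled fixations are clustered with [mean_shift_cluster()] (off-image
#' clusters discarded), each generating region is mapped to the cluster label
#' that holds the majority of its fixations, and the ground-truth reference is
#' expressed in that label space (dominant names as sure links, shared
#' synonyms as possible links), so references and pipeline output share a
#' label space.
#'
#' @param n_images,n_observers Dataset size.
#' @param params [observer_params()].
#' @param scene_args Arguments passed to [make_scene()].
#' @param seed Seed; the whole dataset is deterministic given it.
#' @param bandwidth Mean-shift bandwidth in pixels.
#' @return List of per-image lists `(image, scene, trials, narratives, model,
#'   reference, region_labels, sims)` of class `simulated_dataset`.
#' @export
simulate_dataset <- function(n_images = 20, n_observers = 10,
                             params = observer_params(), scene_args = list(),
                             seed = 1, bandwidth = 88) {
  stopifnot(n_images >= 1, n_observers >= 1)
  with_seed(seed, {
    lapply(seq_len(n_images), function(i) {
      img <- sprintf("img%02d", i)
      scene <- do.call(make_scene, scene_args)
      sims <- lapply(seq_len(n_observers), function(j)
        simulate_trial(scene, params, sprintf("obs%02d", j), img))
      sims <- enforce_dominant_floor(sims, scene, params)
      trials <- lapply(sims, `[[`, "trial")
      model <- discard_offimage_clusters(
        mean_shift_cluster(trials, bandwidth = bandwidth),
        scene$image_w, scene$image_h)
      region_labels <- map_regions_to_labels(sims, model)
      reference <- truth_reference(scene, region_labels)
      structure(list(image = img, scene = scene, trials = trials,
                     narratives = lapply(sims, `[[`, "narr"),
                     model = model, reference = reference,
                     region_labels = region_labels, sims = sims),
                class = "simulated_image")
    }) -> dataset
    structure(dataset, class = "simulated_dataset")
  })
}

## majority cluster label of each generating region's fixations
map_regions_to_labels <- function(sims, model) {
  a <- model$assignment
  akey <- paste(a$observer, a$image, a$fix)
  prov <- do.call(rbind, lapply(sims, function(s)
    data.frame(observer = s$trial$observer, image = s$trial$image,
               fix = seq_along(s$fix_region), region = s$fix_region,
               stringsAsFactors = FALSE)))
  prov$label <- a$label[match(paste(prov$observer, prov$image, prov$fix), akey)]
  prov <- prov[!is.na(prov$region) & !is.na(prov$label), , drop = FALSE]
  out <- character(0)
  for (r in unique(prov$region)) {
    tab <- table(prov$label[prov$region == r])
    out[r] <- names(tab)[which.max(tab)]
  }
  out
}

truth_reference <- function(scene, region_labels) {
  S <- list(); P <- list()
  for (reg in scene$regions) {
    lab <- region_labels[reg$id]
    if (is.na(lab)) next
    S[[length(S) + 1L]] <- data.frame(word = reg$names[1], region = unname(lab))
    if (length(reg$names) > 1L)
      P[[length(P) + 1L]] <- data.frame(word = reg$names[-1], region = unname(lab))
  }
  reference_alignment(
    if (length(S)) do.call(rbind, S) else data.frame(word = character(), region = character()),
    if (length(P)) do.call(rbind, P) else data.frame(word = character(), region = character()))
}

#' Scene regions as annotatable reference regions
#'
#' Renders each scene region's fixation footprint (a disc of radius
#' `2.5 sigma`) as a polygonal [reference_region()] carrying the dominant name
#' as sure word and any synonyms as possible words - the format a human
#' annotator would produce.
#'
#' @param scene A [make_scene()] spec.
#' @param radius_mult Disc radius in units of the region sigma.
#' @export
scene_reference_regions <- function(scene, radius_mult = 2.5) {
  lapply(scene$regions, function(r) {
    th <- seq(0, 2 * pi, length.out = 17)[-17]
    reference_region(r$id,
                     polygon = cbind(r$centroid[1] + radius_mult * r$sigma * cos(th),
                                     r$centroid[2] + radius_mult * r$sigma * sin(th)),
                     sure_words = r$names[1],
                     possible_words = if (length(r$names) > 1) r$names[-1]
                                      else character())
  })
}

## ---- simulator output in the production file formats -----------------------

#' Write trials as a delimited fixation log
#'
#' Emits the raw-sample format [read_fixation_log()] consumes (two samples per
#' fixation, both eyes fixating at the same coordinates), with seconds as the
#' time unit. Reading the file back reproduces the trials.
#'
#' @param trials List of [scanpath_trial()].
#' @param path Output file.
#' @export
write_fixation_log <- function(trials, path) {
  rows <- do.call(rbind, lapply(trials, function(tr) {
    f <- tr$fixations
    if (!nrow(f)) return(NULL)
    data.frame(observer = tr$observer, image = tr$image,
               time = as.vector(rbind(f$t_on, f$t_on + f$dur)),
               l_x = rep(f$x, each = 2), l_y = rep(f$y, each = 2),
               r_x = rep(f$x, each = 2), r_y = rep(f$y, each = 2),
               l_event = "Fixation", r_event = "Fixation",
               stringsAsFactors = FALSE)
  }))
  utils::write.table(format(rows, digits = 15, scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write narratives as a word-level transcript TSV
#' @param narratives List of [narrative()].
#' @param path Output file.
#' @export
write_transcripts <- function(narratives, path) {
  rows <- do.call(rbind, lapply(narratives, function(n) {
    if (!nrow(n$tokens)) return(NULL)
    cbind(observer = n$observer, image = n$image, n$tokens,
          stringsAsFactors = FALSE)
  }))
  utils::write.table(format(rows, digits = 15, scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a transcript TSV written by [write_transcripts()]
#' @param path Transcript file with columns observer, image, surface, pos,
#'   t_on, t_off.
#' @return List of [narrative()].
#' @export
read_transcripts <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("observer", "image", "surface", "pos", "t_on", "t_off")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop_fmt("transcript file is missing column(s): %s",
                             paste(miss, collapse = ", "))
  key <- paste(d$observer, d$image, sep = "\r")
  lapply(unique(key), function(k) {
    g <- d[key == k, , drop = FALSE]
    narrative(g$observer[1], g$image[1],
              data.frame(surface = g$surface, pos = g$pos,
                         t_on = g$t_on, t_off = g$t_off,
                         stringsAsFactors = FALSE))
  })
}
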