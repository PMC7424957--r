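# Small programmatic fixtures shared across test files.

vunits_df <- function(labels, t_on = seq_along(labels) - 1,
                      dur = rep(0.25, length(labels))) {
  data.frame(label = labels, t_on = t_on, dur = dur, stringsAsFactors = FALSE)
}

lunits_df <- function(surfaces, t_on = seq_along(surfaces) - 1) {
  data.frame(surface = surfaces, t_on = t_on, stringsAsFactors = FALSE)
}

tokens_df <- function(surfaces, pos, t_on = seq_along(surfaces) - 1) {
  data.frame(surface = surfaces, pos = pos, t_on = t_on, t_off = t_on + 0.3,
              stringsAsFactors = FALSE)
}

# a fixation log in the SMI-style raw-sample layout
fixation_log_text <- function(rows) {
  paste(c(paste("observer", "image", "time", "l_x", "l_y", "r_x", "r_y",
                "l_event", "r_event", sep = "\t"),
          rows), collapse = "\n")
}

log_row <- function(observer, image, time, x, y,
                    l_event = "Fixation", r_event = "Fixation") {
  paste(observer, image, format(time, scientific = FALSE), x, y, x, y,
        l_event, r_event, sep = "\t")
}

trial_from_fix <- function(fix, observer = "o1", image = "i1",
                           w = 1680, h = 1050) {
  scanpath_trial(observer, image, fix, w, h)
}

# degenerate-noise observer parameters (zero lag, groundable words only)
noiseless_params <- function() {
  observer_params(lag_mean = 0, lag_sd = 0, filler_rate = 0,
                  abstract_rate = 0, idio_rate = 0, synonym_use = FALSE,
                  offimage_rate = 0)
}
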