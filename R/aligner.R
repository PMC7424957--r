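## Unsupervised bitext alignment of visual and linguistic unit sequences:
## IBM Model 1 EM, an HMM aligner trained with Baum-Welch, two-direction
## agreement training, and posterior-threshold decoding.
##
## Conventions. A "direction" fixes which side is the source: "forward" uses
## the visual side as source (regions generate words), "reverse" the
## linguistic side. Every source sentence carries an implicit NULL token so
## that non-grounded target tokens can stay unaligned. Posterior matrices are
## oriented target-rows x source-columns with the NULL column last, and every
## row sums to 1.

#' Aligner configuration
#'
#' @param m1_iters,hmm_iters EM iterations for IBM Model 1 and for the HMM
#'   stage (defaults 2 and 2; the HMM emission table is initialized from the
#'   Model 1 result).
#' @param joint Agreement training: at every E-step the two directional
#'   posteriors are multiplied elementwise (one of them transposed) and
#'   renormalized per row before count collection in both models.
#' @param delta Posterior decoding threshold (default 0.1).
#' @param max_jump HMM jumps are bucketed at `-max_jump..max_jump`, larger
#'   jumps sharing the boundary buckets.
#' @param p_null Initial probability of transitioning into a NULL state
#'   (re-estimated during HMM training).
#' @param seed Seed echoed into serialized output (training itself is
#'   deterministic given the corpus order).
#' @export
aligner_config <- function(m1_iters = 2, hmm_iters = 2, joint = TRUE,
                           delta = 0.1, max_jump = 5, p_null = 0.2, seed = 1) {
  stopifnot(m1_iters >= 1, hmm_iters >= 0, delta >= 0, delta <= 1,
            max_jump >= 1, p_null >= 0, p_null < 1)
  structure(list(m1_iters = m1_iters, hmm_iters = hmm_iters, joint = joint,
                 delta = delta, max_jump = max_jump, p_null = p_null,
                 seed = seed),
            class = "aligner_config")
}

NULL_TOKEN <- "<NULL>"

## ---- internal direction plumbing -------------------------------------------

direction_sides <- function(direction) {
  switch(match.arg(direction, c("forward", "reverse")),
         forward = c(src = "visual", tgt = "linguistic"),
         reverse = c(src = "linguistic", tgt = "visual"))
}

prep_direction <- function(corpus, direction) {
  sides <- direction_sides(direction)
  src_vocab <- sort(unique(unlist(lapply(corpus, `[[`, sides[["src"]]))))
  tgt_vocab <- sort(unique(unlist(lapply(corpus, `[[`, sides[["tgt"]]))))
  pairs <- lapply(corpus, function(p)
    list(src = match(p[[sides[["src"]]]], src_vocab),
         tgt = match(p[[sides[["tgt"]]]], tgt_vocab)))
  list(pairs = pairs, src_vocab = src_vocab, tgt_vocab = tgt_vocab,
       null_row = length(src_vocab) + 1L)
}

uniform_table <- function(n_src, n_tgt) {
  matrix(1 / n_tgt, nrow = n_src + 1L, ncol = n_tgt)
}

normalize_rows <- function(counts, eps = 1e-12) {
  counts <- counts + eps
  sweep(counts, 1, rowSums(counts), "/")
}

## Add a pair's expected counts into the global count table, aggregating over
## repeated tokens on either side. `post` is (I + 1) x J (sources + NULL by
## targets); `rows` is c(src ids, null row id); `cols` the target ids.
accumulate_counts <- function(counts, rows, cols, post) {
  cagg <- t(rowsum(t(post), cols))
  ragg <- rowsum(cagg, rows)
  ur <- as.integer(rownames(ragg)); uc <- as.integer(colnames(cagg))
  counts[ur, uc] <- counts[ur, uc] + ragg
  counts
}

## Model 1 E-step for one pair: returns the (I+1) x J source-given-target
## posterior and the pair's log-likelihood under the uniform alignment prior.
m1_pair_post <- function(src, tgt, tmat, null_row) {
  M <- tmat[c(src, null_row), tgt, drop = FALSE]
  cs <- colSums(M)
  list(post = sweep(M, 2, cs, "/"),
       ll = sum(log(cs / (length(src) + 1L))))
}

## ---- HMM machinery ---------------------------------------------------------

clamp_jump <- function(d, max_jump) pmax(-max_jump, pmin(max_jump, d))

## Transition matrix over 2I states: 1..I real source positions, I+1..2I their
## NULL shadows (a shadow remembers the last real position).
hmm_transitions <- function(I, jump, p_null, max_jump) {
  A <- matrix(0, 2 * I, 2 * I)
  for (i in seq_len(I)) {
    jp <- jump[as.character(clamp_jump(seq_len(I) - i, max_jump))]
    row <- (1 - p_null) * jp / sum(jp)
    A[i, seq_len(I)] <- row
    A[I + i, seq_len(I)] <- row
    A[i, I + i] <- p_null
    A[I + i, I + i] <- p_null
  }
  A
}

hmm_emissions <- function(src, tgt, tmat, null_row) {
  I <- length(src); J <- length(tgt)
  em <- matrix(0, 2 * I, J)
  em[seq_len(I), ] <- tmat[src, tgt, drop = FALSE]
  em[I + seq_len(I), ] <- matrix(tmat[null_row, tgt], I, J, byrow = TRUE)
  em
}

## Scaled forward-backward for one pair. Returns state posteriors (gamma),
## expected transition statistics, and the log-likelihood.
hmm_forward_backward <- function(src, tgt, tmat, hmm, null_row) {
  I <- length(src); J <- length(tgt)
  em <- hmm_emissions(src, tgt, tmat, null_row)
  A <- hmm_transitions(I, hmm$jump, hmm$p_null, hmm$max_jump)
  pi0 <- c(rep((1 - hmm$p_null) / I, I), rep(hmm$p_null / I, I))
  alpha <- matrix(0, 2 * I, J); beta <- matrix(0, 2 * I, J)
  cs <- numeric(J)
  a <- pi0 * em[, 1]
  cs[1] <- sum(a)
  alpha[, 1] <- a / cs[1]
  if (J > 1) for (j in 2:J) {
    a <- as.vector(crossprod(A, alpha[, j - 1])) * em[, j]
    cs[j] <- sum(a)
    alpha[, j] <- a / cs[j]
  }
  beta[, J] <- 1
  if (J > 1) for (j in (J - 1):1)
    beta[, j] <- as.vector(A %*% (beta[, j + 1] * em[, j + 1])) / cs[j + 1]
  gamma <- alpha * beta
  gamma <- sweep(gamma, 2, colSums(gamma), "/")
  ## expected transition counts summed over j (2I x 2I)
  xi <- matrix(0, 2 * I, 2 * I)
  if (J > 1) for (j in seq_len(J - 1))
    xi <- xi + A * (alpha[, j] %o% (beta[, j + 1] * em[, j + 1])) / cs[j + 1]
  list(gamma = gamma, xi = xi, ll = sum(log(cs)), I = I, J = J)
}

## Target x (source + NULL) posterior matrix from HMM state posteriors.
hmm_pair_posterior <- function(fb) {
  I <- fb$I
  P <- t(rbind(fb$gamma[seq_len(I), , drop = FALSE],
               colSums(fb$gamma[I + seq_len(I), , drop = FALSE])))
  colnames(P) <- NULL
  P
}

## Exact jump M-step. The per-position normalizer of the bucketed jump
## distribution depends on the sequence edge, so the count-ratio update is not
## an exact M-step; instead the expected complete log-likelihood (concave in
## log-parameters) is maximized directly, which preserves EM monotonicity.
update_jump <- function(jump, bucket_counts, ctx_counts, max_jump) {
  if (sum(bucket_counts) <= 0) return(jump)
  dvals <- as.integer(names(jump))
  mult <- lapply(ctx_counts, function(ctx) {
    tab <- table(clamp_jump(seq_len(ctx$I) - ctx$i, max_jump))
    m <- numeric(length(dvals)); names(m) <- names(jump)
    m[names(tab)] <- as.numeric(tab)
    m
  })
  N <- vapply(ctx_counts, `[[`, numeric(1), "n")
  cc <- bucket_counts + 1e-12
  qfun <- function(theta) {
    e <- exp(theta)
    sum(cc * theta) - sum(N * vapply(mult, function(m) log(sum(m * e)), numeric(1)))
  }
  qgrad <- function(theta) {
    e <- exp(theta)
    g <- cc
    for (k in seq_along(mult)) {
      z <- sum(mult[[k]] * e)
      g <- g - N[k] * mult[[k]] * e / z
    }
    g
  }
  fit <- stats::optim(log(jump), qfun, qgrad, method = "L-BFGS-B",
                      lower = -30, upper = 30,
                      control = list(fnscale = -1, maxit = 200,
                                     factr = 1e4))
  jp <- exp(fit$par)
  jp / sum(jp)
}

uniform_jump <- function(max_jump) {
  d <- (-max_jump):max_jump
  stats::setNames(rep(1 / length(d), length(d)), as.character(d))
}

## ---- training --------------------------------------------------------------

new_alignment_model <- function(prep, tmat, hmm = NULL) {
  structure(list(t = tmat, src_vocab = prep$src_vocab,
                 tgt_vocab = prep$tgt_vocab, hmm = hmm),
            class = "alignment_model")
}

#' Train IBM Model 1 by expectation maximization
#'
#' Standard Model 1 with a NULL source token and uniform initialization: the
#' E-step computes, for each target token, the posterior over the source
#' tokens that could have generated it; the M-step renormalizes the expected
#' co-occurrence counts. The corpus log-likelihood is non-decreasing across
#' iterations.
#'
#' @param corpus A `parallel_corpus` (see [build_corpus()]).
#' @param direction `"forward"` (visual side as source) or `"reverse"`.
#' @param iters Number of EM iterations.
#' @return An `alignment_model` with the translation table `t` (rows: source
#'   vocabulary plus NULL; columns: target vocabulary; rows sum to 1) and a
#'   `loglik` attribute with the per-iteration corpus log-likelihood.
#' @export
train_model1 <- function(corpus, direction = "forward", iters = 2) {
  if (!length(corpus)) stop_fmt("empty corpus")
  prep <- prep_direction(corpus, direction)
  tmat <- uniform_table(length(prep$src_vocab), length(prep$tgt_vocab))
  lls <- numeric(iters)
  for (it in seq_len(iters)) {
    counts <- matrix(0, nrow(tmat), ncol(tmat))
    ll <- 0
    for (p in prep$pairs) {
      est <- m1_pair_post(p$src, p$tgt, tmat, prep$null_row)
      ll <- ll + est$ll
      counts <- accumulate_counts(counts, c(p$src, prep$null_row), p$tgt,
                                  est$post)
    }
    tmat <- normalize_rows(counts)
    lls[it] <- ll
  }
  m <- new_alignment_model(prep, tmat)
  attr(m, "loglik") <- lls
  m
}

#' Model 1 posterior alignment matrix for one pair
#'
#' @param pair A corpus pair (`list(visual =, linguistic =)`).
#' @param model An `alignment_model` (Model 1 table suffices).
#' @param direction Direction the model was trained in.
#' @return Matrix (targets x sources + NULL, NULL last); rows sum to 1. A
#'   target token outside the model vocabulary gets all mass on NULL.
#' @export
model1_posteriors <- function(pair, model, direction = "forward") {
  sides <- direction_sides(direction)
  src <- match(pair[[sides[["src"]]]], model$src_vocab)
  tgt <- match(pair[[sides[["tgt"]]]], model$tgt_vocab)
  I <- length(src); J <- length(tgt)
  null_row <- length(model$src_vocab) + 1L
  P <- matrix(0, J, I + 1L)
  for (j in seq_len(J)) {
    if (is.na(tgt[j])) { P[j, I + 1L] <- 1; next }
    v <- c(ifelse(is.na(src), 0, model$t[cbind(src, tgt[j])]),
           model$t[null_row, tgt[j]])
    P[j, ] <- v / sum(v)
  }
  P
}

#' Train the HMM aligner with Baum-Welch
#'
#' Hidden states are the source positions (plus interleaved NULL states that
#' remember the last real position); transition probabilities depend on the
#' signed jump width, bucketed at `max_jump`; emissions are the translation
#' table, initialized from a Model 1 model. Emissions, the jump distribution,
#' and the NULL transition probability are re-estimated each iteration; the
#' corpus log-likelihood is non-decreasing.
#'
#' @param corpus A `parallel_corpus`.
#' @param direction `"forward"` or `"reverse"`.
#' @param init `alignment_model` providing the initial translation table.
#' @param iters Baum-Welch iterations.
#' @param config [aligner_config()] (for `max_jump` and initial `p_null`).
#' @return `alignment_model` with `hmm = list(jump, p_null, max_jump)` and a
#'   `loglik` attribute.
#' @export
train_hmm <- function(corpus, direction = "forward", init, iters = 2,
                      config = aligner_config()) {
  if (!length(corpus)) stop_fmt("empty corpus")
  prep <- prep_direction(corpus, direction)
  stopifnot(identical(prep$src_vocab, init$src_vocab),
            identical(prep$tgt_vocab, init$tgt_vocab))
  tmat <- init$t
  hmm <- list(jump = uniform_jump(config$max_jump), p_null = config$p_null,
              max_jump = config$max_jump)
  lls <- numeric(iters)
  for (it in seq_len(iters)) {
    st <- hmm_estep(prep, tmat, hmm)
    tmat <- normalize_rows(st$counts)
    hmm <- hmm_mstep(hmm, st)
    lls[it] <- st$ll
  }
  m <- new_alignment_model(prep, tmat, hmm)
  attr(m, "loglik") <- lls
  m
}

hmm_estep <- function(prep, tmat, hmm, combine = NULL) {
  counts <- matrix(0, nrow(tmat), ncol(tmat))
  bucket_counts <- stats::setNames(numeric(length(hmm$jump)), names(hmm$jump))
  ctx <- new.env(parent = emptyenv())
  ## p_null governs the initial distribution as well as every transition, so
  ## both kinds of occupancy enter its expected counts (an exact M-step)
  null_trans <- 0; tot_trans <- 0; ll <- 0
  for (k in seq_along(prep$pairs)) {
    p <- prep$pairs[[k]]
    fb <- hmm_forward_backward(p$src, p$tgt, tmat, hmm, prep$null_row)
    ll <- ll + fb$ll
    I <- fb$I
    null_trans <- null_trans + sum(fb$gamma[I + seq_len(I), 1])
    tot_trans <- tot_trans + 1
    P <- hmm_pair_posterior(fb)            # J x (I + 1)
    if (!is.null(combine)) P <- combine(k, P)
    counts <- accumulate_counts(counts, c(p$src, prep$null_row), p$tgt, t(P))
    if (fb$J > 1) {
      xi <- fb$xi
      pos <- rep(seq_len(I), 2)
      to_real <- xi[, seq_len(I), drop = FALSE]
      for (i in seq_len(I)) {
        from_i <- colSums(to_real[pos == i, , drop = FALSE])
        n_i <- sum(from_i)
        if (n_i <= 0) next
        d <- as.character(clamp_jump(seq_len(I) - i, hmm$max_jump))
        for (dd in unique(d))
          bucket_counts[dd] <- bucket_counts[dd] + sum(from_i[d == dd])
        key <- paste(I, i)
        prev <- if (exists(key, ctx)) get(key, ctx)$n else 0
        assign(key, list(I = I, i = i, n = prev + n_i), ctx)
      }
      null_trans <- null_trans + sum(xi[, I + seq_len(I)])
      tot_trans <- tot_trans + sum(xi)
    }
  }
  list(counts = counts, bucket_counts = bucket_counts,
       ctx = as.list(ctx), null_trans = null_trans, tot_trans = tot_trans,
       ll = ll)
}

hmm_mstep <- function(hmm, st) {
  if (st$tot_trans > 0) {
    hmm$p_null <- st$null_trans / st$tot_trans
    hmm$jump <- update_jump(hmm$jump, st$bucket_counts, st$ctx, hmm$max_jump)
  }
  hmm
}

#' HMM posterior alignment matrix for one pair
#'
#' @inheritParams model1_posteriors
#' @export
hmm_posteriors <- function(pair, model, direction = "forward") {
  if (is.null(model$hmm)) return(model1_posteriors(pair, model, direction))
  sides <- direction_sides(direction)
  src <- match(pair[[sides[["src"]]]], model$src_vocab)
  tgt <- match(pair[[sides[["tgt"]]]], model$tgt_vocab)
  null_row <- length(model$src_vocab) + 1L
  I <- length(src); J <- length(tgt)
  ## out-of-vocabulary handling: unseen source emits nothing; unseen target is
  ## forced through NULL
  tmat <- rbind(model$t, 0)
  src2 <- ifelse(is.na(src), nrow(tmat), src)
  oov_tgt <- is.na(tgt)
  tgt2 <- ifelse(oov_tgt, 1L, tgt)
  em_fix <- function(em) {
    if (any(oov_tgt)) {
      em[, oov_tgt] <- 0
      em[I + seq_len(I), oov_tgt] <- 1
    }
    em
  }
  em <- em_fix(hmm_emissions(src2, tgt2, tmat, null_row))
  fb <- hmm_fb_custom(em, I, J, model$hmm)
  hmm_pair_posterior(fb)
}

## forward-backward on a precomputed emission matrix (used for OOV handling)
hmm_fb_custom <- function(em, I, J, hmm) {
  A <- hmm_transitions(I, hmm$jump, hmm$p_null, hmm$max_jump)
  pi0 <- c(rep((1 - hmm$p_null) / I, I), rep(hmm$p_null / I, I))
  alpha <- matrix(0, 2 * I, J); beta <- matrix(0, 2 * I, J); cs <- numeric(J)
  a <- pi0 * em[, 1]; cs[1] <- sum(a); alpha[, 1] <- a / cs[1]
  if (J > 1) for (j in 2:J) {
    a <- as.vector(crossprod(A, alpha[, j - 1])) * em[, j]
    cs[j] <- sum(a); alpha[, j] <- a / cs[j]
  }
  beta[, J] <- 1
  if (J > 1) for (j in (J - 1):1)
    beta[, j] <- as.vector(A %*% (beta[, j + 1] * em[, j + 1])) / cs[j + 1]
  gamma <- alpha * beta
  gamma <- sweep(gamma, 2, colSums(gamma), "/")
  list(gamma = gamma, xi = NULL, ll = sum(log(cs)), I = I, J = J)
}

## Agreement combination: elementwise product of the two directional
## posteriors for real links; the NULL column (which has no transposed
## counterpart) keeps the directional posterior; rows renormalized.
combine_agreement <- function(P_dir, P_other) {
  J <- nrow(P_dir); I <- ncol(P_dir) - 1L
  C <- P_dir
  C[, seq_len(I)] <- P_dir[, seq_len(I), drop = FALSE] *
    t(P_other[seq_len(I), seq_len(J), drop = FALSE])
  s <- rowSums(C)
  bad <- s <= 0
  C[!bad, ] <- C[!bad, , drop = FALSE] / s[!bad]
  if (any(bad)) C[bad, ] <- P_dir[bad, , drop = FALSE]
  C
}

#' Train both directional aligners, optionally with agreement
#'
#' Runs the staged schedule - `m1_iters` of IBM Model 1 followed by
#' `hmm_iters` of the HMM aligner - in both directions. With
#' `config$joint = TRUE` the two models are trained jointly: at every E-step
#' each direction's per-pair posterior matrix is multiplied elementwise with
#' the transposed posterior of the other direction and renormalized per row
#' before the expected counts are collected.
#'
#' @param corpus A `parallel_corpus`.
#' @param config An [aligner_config()].
#' @return `alignment_models`: list with `forward`, `reverse`
#'   (`alignment_model`s), `config`, and `loglik` (per-direction traces).
#' @export
train_joint <- function(corpus, config = aligner_config()) {
  if (!length(corpus)) stop_fmt("empty corpus")
  prep_f <- prep_direction(corpus, "forward")
  prep_r <- prep_direction(corpus, "reverse")
  t_f <- uniform_table(length(prep_f$src_vocab), length(prep_f$tgt_vocab))
  t_r <- uniform_table(length(prep_r$src_vocab), length(prep_r$tgt_vocab))
  ll_f <- numeric(0); ll_r <- numeric(0)

  m1_joint_iter <- function(t_f, t_r) {
    c_f <- matrix(0, nrow(t_f), ncol(t_f)); c_r <- matrix(0, nrow(t_r), ncol(t_r))
    llf <- 0; llr <- 0
    for (k in seq_along(prep_f$pairs)) {
      pf <- prep_f$pairs[[k]]; pr <- prep_r$pairs[[k]]
      ef <- m1_pair_post(pf$src, pf$tgt, t_f, prep_f$null_row)
      er <- m1_pair_post(pr$src, pr$tgt, t_r, prep_r$null_row)
      llf <- llf + ef$ll; llr <- llr + er$ll
      P_f <- t(ef$post)                     # J x (I+1)
      P_r <- t(er$post)                     # I x (J+1)
      if (config$joint) {
        C_f <- combine_agreement(P_f, P_r)
        C_r <- combine_agreement(P_r, P_f)
      } else { C_f <- P_f; C_r <- P_r }
      c_f <- accumulate_counts(c_f, c(pf$src, prep_f$null_row), pf$tgt, t(C_f))
      c_r <- accumulate_counts(c_r, c(pr$src, prep_r$null_row), pr$tgt, t(C_r))
    }
    list(t_f = normalize_rows(c_f), t_r = normalize_rows(c_r),
         llf = llf, llr = llr)
  }

  for (it in seq_len(config$m1_iters)) {
    step <- m1_joint_iter(t_f, t_r)
    t_f <- step$t_f; t_r <- step$t_r
    ll_f <- c(ll_f, step$llf); ll_r <- c(ll_r, step$llr)
  }

  hmm_f <- list(jump = uniform_jump(config$max_jump), p_null = config$p_null,
                max_jump = config$max_jump)
  hmm_r <- hmm_f
  if (config$hmm_iters > 0) {
    for (it in seq_len(config$hmm_iters)) {
      ## per-pair posteriors of the other direction, for agreement
      post_f <- vector("list", length(prep_f$pairs))
      post_r <- vector("list", length(prep_r$pairs))
      if (config$joint) {
        for (k in seq_along(prep_f$pairs)) {
          pf <- prep_f$pairs[[k]]; pr <- prep_r$pairs[[k]]
          post_f[[k]] <- hmm_pair_posterior(
            hmm_forward_backward(pf$src, pf$tgt, t_f, hmm_f, prep_f$null_row))
          post_r[[k]] <- hmm_pair_posterior(
            hmm_forward_backward(pr$src, pr$tgt, t_r, hmm_r, prep_r$null_row))
        }
      }
      st_f <- hmm_estep(prep_f, t_f, hmm_f,
                        combine = if (config$joint)
                          function(k, P) combine_agreement(P, post_r[[k]]))
      st_r <- hmm_estep(prep_r, t_r, hmm_r,
                        combine = if (config$joint)
                          function(k, P) combine_agreement(P, post_f[[k]]))
      t_f <- normalize_rows(st_f$counts); t_r <- normalize_rows(st_r$counts)
      hmm_f <- hmm_mstep(hmm_f, st_f); hmm_r <- hmm_mstep(hmm_r, st_r)
      ll_f <- c(ll_f, st_f$ll); ll_r <- c(ll_r, st_r$ll)
    }
  }
  structure(list(
    forward = new_alignment_model(prep_f, t_f,
                                  if (config$hmm_iters > 0) hmm_f),
    reverse = new_alignment_model(prep_r, t_r,
                                  if (config$hmm_iters > 0) hmm_r),
    config = config,
    loglik = list(forward = ll_f, reverse = ll_r)),
    class = "alignment_models")
}

#' @export
print.alignment_models <- function(x, ...) {
  cat(sprintf("<alignment_models> %d regions x %d words; m1 %d + hmm %d iters, joint %s\n",
              length(x$forward$src_vocab), length(x$forward$tgt_vocab),
              x$config$m1_iters, x$config$hmm_iters, x$config$joint))
  invisible(x)
}

#' Decode one pair by posterior thresholding
#'
#' The combined posterior (agreement product of the two directional
#' posteriors, renormalized per row) is computed for the pair; every
#' (word, region) cell with posterior `>= delta` and a non-NULL region becomes
#' a link. One-to-many links in both directions are allowed.
#'
#' @param pair `list(visual =, linguistic =)`.
#' @param models `alignment_models` from [train_joint()].
#' @param delta Posterior threshold (default from the training config).
#' @return Data frame `(word, region, posterior, j, i)`.
#' @export
decode <- function(pair, models, delta = models$config$delta) {
  P <- decode_posteriors(pair, models)
  I <- length(pair$visual)
  hits <- which(P[, seq_len(I), drop = FALSE] >= delta, arr.ind = TRUE)
  out <- data.frame(word = pair$linguistic[hits[, 1]],
                    region = pair$visual[hits[, 2]],
                    posterior = P[, seq_len(I), drop = FALSE][hits],
                    j = as.integer(hits[, 1]), i = as.integer(hits[, 2]),
                    stringsAsFactors = FALSE)
  out[order(out$j, out$i), , drop = FALSE]
}

#' Combined (agreement) posterior matrix for one pair
#' @inheritParams decode
#' @return Matrix words x (regions + NULL); rows sum to 1.
#' @export
decode_posteriors <- function(pair, models) {
  P_f <- hmm_posteriors(pair, models$forward, "forward")
  P_r <- hmm_posteriors(pair, models$reverse, "reverse")
  combine_agreement(P_f, P_r)
}

#' Image-level alignment set from per-observer full-sequence pairs
#'
#' Decodes every observer's whole-trial pair and pools the links into a set of
#' distinct (word, region) pairs, keeping the maximum posterior seen for each.
#'
#' @param corpus The image's `parallel_corpus` (its `origin == "full"` pairs
#'   are decoded).
#' @param models `alignment_models`.
#' @param delta Posterior threshold.
#' @return Data frame `(word, region, posterior)`; also returns the
#'   per-observer links as attribute `"links"`.
#' @export
align_image <- function(corpus, models, delta = models$config$delta) {
  full <- Filter(function(p) identical(p$origin, "full"), corpus)
  if (!length(full)) full <- corpus
  links <- do.call(rbind, lapply(full, function(p) {
    d <- decode(p, models, delta)
    if (nrow(d)) cbind(observer = p$observer, d, stringsAsFactors = FALSE)
  }))
  if (is.null(links) || nrow(links) == 0L) {
    A <- data.frame(word = character(), region = character(),
                    posterior = numeric(), stringsAsFactors = FALSE)
    attr(A, "links") <- links
    return(A)
  }
  key <- paste(links$word, links$region, sep = "\r")
  best <- tapply(links$posterior, key, max)
  parts <- do.call(rbind, strsplit(names(best), "\r", fixed = TRUE))
  A <- data.frame(word = parts[, 1], region = parts[, 2],
                  posterior = as.numeric(best), stringsAsFactors = FALSE)
  A <- A[order(A$word, A$region), , drop = FALSE]
  rownames(A) <- NULL
  attr(A, "links") <- links
  A
}

## ---- serialization ---------------------------------------------------------

#' Write decoded alignments (Pharaoh format plus a TSV of links)
#'
#' @param corpus Corpus whose `full` pairs were decoded.
#' @param models `alignment_models`.
#' @param dir Output directory.
#' @param delta Posterior threshold.
#' @export
write_alignments <- function(corpus, models, dir,
                             delta = models$config$delta) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  full <- Filter(function(p) identical(p$origin, "full"), corpus)
  if (!length(full)) full <- corpus
  lines <- character(length(full))
  rows <- list()
  for (k in seq_along(full)) {
    d <- decode(full[[k]], models, delta)
    lines[k] <- paste(sprintf("%d-%d", d$j, d$i), collapse = " ")
    if (nrow(d))
      rows[[length(rows) + 1L]] <- cbind(observer = full[[k]]$observer, d,
                                         stringsAsFactors = FALSE)
  }
  writeLines(lines, file.path(dir, "alignments.pharaoh"))
  tsv <- if (length(rows)) do.call(rbind, rows) else
    data.frame(observer = character(), word = character(), region = character(),
               posterior = numeric(), j = integer(), i = integer())
  utils::write.table(tsv[, c("observer", "word", "region", "posterior")],
                     file.path(dir, "links.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(dir)
}

#' Serialize trained aligner models to JSON
#' @param models `alignment_models`.
#' @param path Output file.
#' @export
write_models <- function(models, path) {
  ser_one <- function(m) list(
    src_vocab = m$src_vocab, tgt_vocab = m$tgt_vocab,
    t = unname(as.data.frame(m$t)),
    hmm = if (!is.null(m$hmm)) list(jump = as.list(m$hmm$jump),
                                    p_null = m$hmm$p_null,
                                    max_jump = m$hmm$max_jump))
  jsonlite::write_json(list(forward = ser_one(models$forward),
                            reverse = ser_one(models$reverse),
                            config = unclass(models$config)),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read aligner models serialized by [write_models()]
#' @param path JSON file.
#' @export
read_models <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  de_one <- function(o) {
    tmat <- as.matrix(o$t)
    dimnames(tmat) <- NULL
    hmm <- if (!is.null(o$hmm) && length(o$hmm))
      list(jump = unlist(o$hmm$jump), p_null = o$hmm$p_null,
           max_jump = o$hmm$max_jump)
    structure(list(t = tmat, src_vocab = o$src_vocab, tgt_vocab = o$tgt_vocab,
                   hmm = hmm), class = "alignment_model")
  }
  cfg <- do.call(aligner_config, obj$config[names(obj$config) %in%
    names(formals(aligner_config))])
  structure(list(forward = de_one(obj$forward), reverse = de_one(obj$reverse),
                 config = cfg, loglik = NULL),
            class = "alignment_models")
}
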