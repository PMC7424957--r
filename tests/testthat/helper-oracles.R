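# Independent brute-force oracles for the alignment models. These enumerate
# every alignment function / state path explicitly from the model definitions
# and share no code with the package's E-step implementations.

# Model 1 with a NULL source token: alignments a map each target position j to
# a source position 1..I or NULL (0), each a_j uniform over I+1 choices.
# Returns the J x (I + 1) posterior matrix (NULL last).
oracle_model1_posteriors <- function(t_lookup, src, tgt) {
  I <- length(src); J <- length(tgt)
  choices <- 0:I
  grids <- do.call(expand.grid, rep(list(choices), J))
  post <- matrix(0, J, I + 1)
  total <- 0
  for (g in seq_len(nrow(grids))) {
    a <- as.integer(grids[g, ])
    p <- prod(vapply(seq_len(J), function(j) {
      s <- if (a[j] == 0) "<NULL>" else src[a[j]]
      t_lookup(s, tgt[j]) / (I + 1)
    }, numeric(1)))
    total <- total + p
    for (j in seq_len(J)) {
      col <- if (a[j] == 0) I + 1 else a[j]
      post[j, col] <- post[j, col] + p
    }
  }
  post / total
}

# HMM aligner oracle: states 1..I are source positions, I+1..2I NULL shadows
# remembering position i. Initial distribution (1-p_null)/I over real states,
# p_null/I over shadows. Transition from a state with memory i: to real i'
# with (1-p_null) * jump(clamp(i'-i)) / sum over i'' jump(clamp(i''-i)); to
# the shadow of i with p_null. Real state i emits t(tgt | src[i]), shadows
# emit t(tgt | NULL). Enumerates all (2I)^J paths.
oracle_hmm_posteriors <- function(t_lookup, src, tgt, jump, p_null, max_jump) {
  I <- length(src); J <- length(tgt)
  nstate <- 2L * I
  clamp <- function(d) pmax(-max_jump, pmin(max_jump, d))
  trans <- function(s, s2) {
    i <- ((s - 1L) %% I) + 1L
    if (s2 <= I) {
      jp <- jump[as.character(clamp(s2 - i))]
      z <- sum(jump[as.character(clamp(seq_len(I) - i))])
      (1 - p_null) * jp / z
    } else if (s2 == I + i) p_null else 0
  }
  emit <- function(s, j) {
    if (s <= I) t_lookup(src[s], tgt[j]) else t_lookup("<NULL>", tgt[j])
  }
  init <- function(s) if (s <= I) (1 - p_null) / I else p_null / I
  grids <- do.call(expand.grid, rep(list(seq_len(nstate)), J))
  post <- matrix(0, J, I + 1)
  total <- 0
  for (g in seq_len(nrow(grids))) {
    path <- as.integer(grids[g, ])
    p <- init(path[1]) * emit(path[1], 1)
    if (J > 1) for (j in 2:J) {
      p <- p * trans(path[j - 1], path[j]) * emit(path[j], j)
      if (p == 0) break
    }
    if (p == 0) next
    total <- total + p
    for (j in seq_len(J)) {
      col <- if (path[j] <= I) path[j] else I + 1
      post[j, col] <- post[j, col] + p
    }
  }
  post / total
}

# lookup closure over a package translation table
table_lookup <- function(model) {
  function(s, w) {
    row <- if (identical(s, "<NULL>")) length(model$src_vocab) + 1L
           else match(s, model$src_vocab)
    col <- match(w, model$tgt_vocab)
    model$t[row, col]
  }
}

# random small parallel corpus over the given vocabularies
random_toy_corpus <- function(n_pairs, src_vocab, tgt_vocab,
                              max_src = 4, max_tgt = 4) {
  structure(lapply(seq_len(n_pairs), function(i) {
    list(visual = sample(src_vocab, sample.int(max_src, 1), replace = TRUE),
         linguistic = sample(tgt_vocab, sample.int(max_tgt, 1), replace = TRUE),
         observer = "obs", origin = "window", window_start = 0)
  }), class = "parallel_corpus")
}

# hand-built alignment model with random parameters (for oracle comparisons)
random_alignment_model <- function(src_vocab, tgt_vocab, max_jump = 3,
                                   with_hmm = TRUE) {
  tmat <- matrix(stats::rgamma((length(src_vocab) + 1) * length(tgt_vocab),
                               1, 1),
                 nrow = length(src_vocab) + 1)
  tmat <- sweep(tmat, 1, rowSums(tmat), "/")
  jump <- stats::rgamma(2 * max_jump + 1, 1, 1)
  jump <- jump / sum(jump)
  names(jump) <- as.character((-max_jump):max_jump)
  structure(list(t = tmat, src_vocab = src_vocab, tgt_vocab = tgt_vocab,
                 hmm = if (with_hmm) list(jump = jump,
                                          p_null = stats::runif(1, 0.05, 0.4),
                                          max_jump = max_jump)),
            class = "alignment_model")
}
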