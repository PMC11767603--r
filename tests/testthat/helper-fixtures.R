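## Shared fixtures and independent oracles for the test suite.

## A deliberately tiny architecture so forward/backward passes run in
## milliseconds; same topology as the full model.
tiny_model_config <- function(...) {
  defaults <- list(smiles_max_len = 8L, protein_max_len = 12L,
                   bpe_max_tokens = 6L, bpe_merges = 2L, embed_dim = 4L,
                   drug_channels = c(3L, 4L, 5L), drug_kernels = c(2L, 3L, 3L),
                   target_channels = c(3L, 4L, 5L),
                   target_kernels = c(2L, 3L, 4L),
                   d_model = 4L, n_heads = 2L, n_layers = 1L, ffn_dim = 6L,
                   proj_channels = 4L, pool_bins = 3L,
                   head_widths = c(5L, 4L), dropout = 0)
  over <- list(...)
  defaults[names(over)] <- over
  do.call(model_config, defaults)
}

## A compact labelled record set from the synthetic generator.
tiny_records <- function(n = 40L, seed = 17L, label_noise = 0) {
  sp <- synthetic_spec(n_drugs = 25L, n_targets = 20L, seed = seed,
                       label_noise = label_noise,
                       smiles_length_range = c(6L, 10L),
                       protein_length_range = c(8L, 14L))
  generate_pairs(sp, n)$records
}

## O(n^2) Mann-Whitney AUC: explicit pair counting, ties worth one half.
auc_bruteforce <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

## Brute-force ranked average precision with tie-grouped precision: walk
## the ranking, recomputing precision at the end of each tied group from
## scratch.
aupr_bruteforce <- function(labels, scores) {
  ord <- order(-scores)
  lab <- labels[ord]; sc <- scores[ord]
  n <- length(lab)
  total <- 0
  for (i in seq_len(n)) {
    if (lab[i] != 1) next
    last <- i
    while (last < n && sc[last + 1] == sc[i]) last <- last + 1
    first <- i
    while (first > 1 && sc[first - 1] == sc[i]) first <- first - 1
    tp <- sum(lab[seq_len(last)] == 1)
    total <- total + tp / last
  }
  total / sum(labels == 1)
}

## Direct im2col convolution reference, independent of the compiled
## kernel: zero 'same' padding, stride 1, W holds k stacked Cin-row blocks.
conv_reference <- function(X, W, b, k) {
  T <- nrow(X); Cin <- ncol(X); Cout <- length(b)
  left <- (k - 1) %/% 2
  Y <- matrix(0, T, Cout)
  for (t in seq_len(T)) {
    acc <- b
    for (j in seq_len(k)) {
      p <- t - left + (j - 1)
      if (p >= 1 && p <= T)
        acc <- acc + drop(X[p, ] %*% W[((j - 1) * Cin + 1):(j * Cin), ,
                                       drop = FALSE])
    }
    Y[t, ] <- acc
  }
  Y
}

## Small random perturbation of every parameter, used to move pre-ReLU
## activations off the exact-zero kink before finite-difference checks.
jitter_params <- function(params, seed = 99L, amount = 0.05) {
  set.seed(seed)
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk)
    else x + stats::runif(length(x), -amount, amount)
  }
  walk(params)
}

## Character n-gram logistic baseline: hashed 3-gram counts for drug and
## target, main-effects logistic fit.  Certifies that a planted fixture is
## learnable at all before any claim about the network.
ngram_features <- function(strings, n = 3L, top = 150L) {
  grams <- lapply(strings, function(s) {
    ch <- strsplit(s, "")[[1]]
    if (length(ch) < n) return(character(0))
    vapply(seq_len(length(ch) - n + 1L),
           function(i) paste(ch[i:(i + n - 1L)], collapse = ""), character(1))
  })
  vocab <- names(sort(table(unlist(grams)), decreasing = TRUE))
  vocab <- utils::head(vocab, top)
  X <- matrix(0, length(strings), length(vocab))
  for (i in seq_along(grams)) {
    tb <- table(grams[[i]])
    hit <- intersect(names(tb), vocab)
    X[i, match(hit, vocab)] <- as.numeric(tb[hit])
  }
  X
}

ngram_logistic_auc <- function(records, seed = 1L) {
  X <- cbind(ngram_features(records$smiles),
             ngram_features(records$sequence))
  y <- records$label
  set.seed(seed)
  idx <- sample(nrow(X))
  cut <- floor(0.7 * nrow(X))
  tr <- idx[seq_len(cut)]; te <- idx[-seq_len(cut)]
  fit <- suppressWarnings(stats::glm.fit(cbind(1, X[tr, ]), y[tr],
                                         family = stats::binomial()))
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  sc <- drop(cbind(1, X[te, ]) %*% cf)
  auc_score(y[te], sc)
}
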