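## Byte Pair Encoding for protein sequences.
##
## Classic corpus-level BPE: starting from single characters, the most
## frequent adjacent symbol pair is merged into one subword, iteratively.
## Ties on pair frequency are broken lexicographically on (left, right) so
## training is deterministic for a given corpus and merge count.  Merges are
## applied left-to-right without overlap.

BPE_SEP <- "\x1f"  # sequence separator inside the concatenated corpus

pair_keys <- function(sym) {
  n <- length(sym)
  if (n < 2L) return(character(0))
  a <- sym[-n]; b <- sym[-1]
  ok <- a != BPE_SEP & b != BPE_SEP
  paste(a[ok], b[ok], sep = BPE_SEP)
}

## Merge occurrences of pair (a, b) in a symbol vector, left-to-right,
## non-overlapping.  Works on a corpus concatenated with BPE_SEP as well as
## on a single sequence.
merge_pair <- function(sym, a, b) {
  n <- length(sym)
  if (n < 2L) return(sym)
  hit <- which(sym[-n] == a & sym[-1] == b)
  if (length(hit) == 0L) return(sym)
  if (a == b && length(hit) > 1L) {
    ## drop overlapping matches within runs, keeping the leftmost of each
    keep <- logical(length(hit))
    last <- -2L
    for (i in seq_along(hit)) {
      if (hit[i] > last + 1L) { keep[i] <- TRUE; last <- hit[i] }
    }
    hit <- hit[keep]
  }
  sym[hit] <- paste0(a, b)
  sym[-(hit + 1L)]
}

#' Train a byte-pair-encoding model on a protein corpus
#'
#' Splits each sequence into single characters, then repeatedly merges the
#' most frequent adjacent symbol pair.  Equal frequencies are resolved by
#' lexicographic order of the pair, so the merge list is deterministic.
#' The subword vocabulary contains all single characters seen, every merged
#' unit, and the unknown token.  Symbols are taken literally; replacing
#' non-standard amino-acid letters with \code{"?"} is a separate
#' preprocessing step (the model pipeline applies it before training).
#'
#' @param corpus character vector of protein sequences (non-empty).
#' @param num_merges number of merge rules to learn (>= 0).
#' @return An object of class \code{"dti_bpe"}: list with \code{merges}
#'   (list of length-2 character vectors, in training order),
#'   \code{vocab} (a \code{"dti_vocab"} over subwords) and
#'   \code{num_merges}.
#' @examples
#' m <- train_bpe(c("AAAB", "AABA"), num_merges = 1)
#' m$merges[[1]]   # c("A", "A")
#' @export
train_bpe <- function(corpus, num_merges) {
  if (length(corpus) == 0L) stop2("cannot train BPE on an empty corpus")
  if (!is.numeric(num_merges) || num_merges < 0 || num_merges != round(num_merges))
    stop2("num_merges must be a non-negative integer")
  chars <- strsplit(as.character(corpus), "", fixed = TRUE)
  base_symbols <- unique(unlist(chars))
  sym <- unlist(lapply(chars, function(x) c(x, BPE_SEP)))
  merges <- vector("list", num_merges)
  n_done <- 0L
  while (n_done < num_merges) {
    keys <- pair_keys(sym)
    if (length(keys) == 0L) break
    tab <- table(keys)
    top <- names(tab)[tab == max(tab)]
    best <- sort(top, method = "radix")[[1]]
    ab <- strsplit(best, BPE_SEP, fixed = TRUE)[[1]]
    sym <- merge_pair(sym, ab[[1]], ab[[2]])
    n_done <- n_done + 1L
    merges[[n_done]] <- ab
  }
  merges <- merges[seq_len(n_done)]
  merged_units <- vapply(merges, function(p) paste0(p[[1]], p[[2]]), character(1))
  structure(list(merges = merges,
                 vocab = vocabulary(c(base_symbols, merged_units)),
                 num_merges = n_done),
            class = "dti_bpe")
}

#' @export
print.dti_bpe <- function(x, ...) {
  cat("BPE model:", x$num_merges, "merges,",
      x$vocab$size, "subword tokens\n")
  invisible(x)
}

bpe_segment <- function(sequence, model) {
  ch <- strsplit(as.character(sequence), "", fixed = TRUE)[[1]]
  if (length(ch) == 0L) return(character(0))
  for (p in model$merges) ch <- merge_pair(ch, p[[1]], p[[2]])
  ch
}

#' Encode a protein sequence with a trained BPE model
#'
#' Applies the merge rules in training order, maps the resulting subwords to
#' vocabulary indices (unknown subwords map to \code{"?"}), and pads or
#' truncates to \code{max_tokens} with a matching validity mask.  An empty
#' sequence yields an all-padding result with an all-zero mask.
#'
#' @param sequence a single protein string.
#' @param model a \code{"dti_bpe"} from \code{\link{train_bpe}}.
#' @param max_tokens positive integer, fixed output length in subwords.
#' @return A \code{"dti_tokens"} object.
#' @export
encode_bpe <- function(sequence, model, max_tokens) {
  if (!inherits(model, "dti_bpe")) stop2("model must come from train_bpe()")
  if (!is_count(max_tokens)) stop2("max_tokens must be a positive integer")
  toks <- bpe_segment(sequence, model)
  idx <- token_index(model$vocab, toks)
  pad_tokens(idx, as.integer(max_tokens), model$vocab$index[[UNK_TOKEN]])
}

## Batch encoding: applies merges once over the separator-joined corpus so
## per-fold re-encoding of thousands of sequences stays cheap.
encode_bpe_corpus <- function(sequences, model, max_tokens) {
  chars <- strsplit(as.character(sequences), "", fixed = TRUE)
  lens <- lengths(chars)
  sym <- unlist(lapply(chars, function(x) c(x, BPE_SEP)), use.names = FALSE)
  for (p in model$merges) sym <- merge_pair(sym, p[[1]], p[[2]])
  grp <- cumsum(sym == BPE_SEP)
  grp <- c(0L, grp[-length(grp)])
  keep <- sym != BPE_SEP
  pieces <- split(sym[keep], grp[keep])
  out <- vector("list", length(sequences))
  pad <- model$vocab$index[[UNK_TOKEN]]
  nonempty <- lens > 0L
  j <- 0L
  for (i in seq_along(sequences)) {
    if (nonempty[i]) {
      j <- j + 1L
      idx <- token_index(model$vocab, pieces[[j]])
    } else idx <- integer(0)
    out[[i]] <- pad_tokens(idx, as.integer(max_tokens), pad)
  }
  out
}

#' Serialize / restore a BPE model as JSON
#'
#' @param model a \code{"dti_bpe"}.
#' @param path file path.
#' @return \code{write_bpe_json} returns \code{path} invisibly;
#'   \code{read_bpe_json} returns a \code{"dti_bpe"}.
#' @export
write_bpe_json <- function(model, path) {
  jsonlite::write_json(list(merges = lapply(model$merges, as.character),
                            tokens = model$vocab$tokens),
                       path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_bpe_json
#' @export
read_bpe_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  merges <- if (length(x$merges)) {
    if (is.matrix(x$merges)) apply(x$merges, 1L, as.character, simplify = FALSE)
    else lapply(x$merges, as.character)
  } else list()
  structure(list(merges = merges, vocab = vocabulary(x$tokens),
                 num_merges = length(merges)),
            class = "dti_bpe")
}
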