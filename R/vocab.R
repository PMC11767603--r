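## Character vocabularies and fixed-length tokenization.
##
## A vocabulary maps token strings to contiguous 0-based indices.  The
## unknown token '?' doubles as the padding token (index 0); the validity
## mask, not the index value, distinguishes padding from real tokens.

UNK_TOKEN <- "?"

#' Construct a token vocabulary
#'
#' Builds a vocabulary with contiguous 0-based indices.  The unknown/padding
#' token \code{"?"} always occupies index 0; remaining tokens are sorted
#' (C locale) so that index assignment is deterministic for a given token
#' set.
#'
#' @param tokens character vector of distinct tokens (may or may not
#'   include \code{"?"}).
#' @return An object of class \code{"dti_vocab"}: a list with
#'   \code{tokens} (character, in index order), \code{index} (named integer,
#'   0-based), \code{unknown_token}, \code{pad_token} and \code{size}.
#' @examples
#' v <- vocabulary(c("C", "O"))
#' v$size            # 3: '?', 'C', 'O'
#' token_index(v, c("C", "X"))  # unknown 'X' maps to index 0
#' @export
vocabulary <- function(tokens) {
  tokens <- unique(as.character(tokens))
  tokens <- setdiff(tokens, UNK_TOKEN)
  tokens <- sort(tokens, method = "radix")
  toks <- c(UNK_TOKEN, tokens)
  idx <- seq_along(toks) - 1L
  names(idx) <- toks
  structure(list(tokens = toks, index = idx,
                 unknown_token = UNK_TOKEN, pad_token = UNK_TOKEN,
                 size = length(toks)),
            class = "dti_vocab")
}

#' @export
print.dti_vocab <- function(x, ...) {
  cat("Token vocabulary:", x$size, "tokens ('?' = unknown/pad, index 0)\n")
  show <- utils::head(x$tokens, 20L)
  cat("  ", paste(show, collapse = " "),
      if (x$size > 20L) "..." else "", "\n")
  invisible(x)
}

#' Build a character vocabulary from a SMILES corpus
#'
#' Splits every SMILES string into single characters and collects the
#' distinct symbols ('C', 'O', '=', ring digits, ...) plus the unknown
#' token.  Tokenization is strictly per character: two-letter element
#' symbols such as "Cl" become two tokens.
#'
#' @param corpus character vector of SMILES strings (non-empty).
#' @return A \code{"dti_vocab"} object.
#' @export
build_smiles_vocabulary <- function(corpus) {
  if (length(corpus) == 0L) stop2("cannot build a vocabulary from an empty corpus")
  chars <- unique(unlist(strsplit(as.character(corpus), "", fixed = TRUE)))
  vocabulary(chars)
}

#' The fixed 20-letter amino-acid vocabulary
#'
#' Vocabulary over the 20 standard amino-acid one-letter codes plus the
#' unknown token; used for the character-level (convolutional) protein path.
#'
#' @return A \code{"dti_vocab"} object with 21 entries.
#' @export
amino_acid_vocabulary <- function() vocabulary(AA_LETTERS)

#' Look up token indices
#'
#' Total lookup: any token absent from the vocabulary maps to the unknown
#' index, never fails.
#'
#' @param vocab a \code{"dti_vocab"}.
#' @param tokens character vector of tokens.
#' @return integer vector of 0-based indices.
#' @export
token_index <- function(vocab, tokens) {
  i <- vocab$index[tokens]
  i[is.na(i)] <- vocab$index[[vocab$unknown_token]]
  unname(i)
}

new_tokenized <- function(indices, mask, original_length) {
  structure(list(indices = as.integer(indices), mask = as.integer(mask),
                 original_length = as.integer(original_length)),
            class = "dti_tokens")
}

#' @export
print.dti_tokens <- function(x, ...) {
  cat("Tokenized sequence: length", length(x$indices),
      "(", sum(x$mask), "real tokens of", x$original_length, "original )\n")
  invisible(x)
}

pad_tokens <- function(idx, max_len, pad_index) {
  n <- length(idx)
  keep <- min(n, max_len)
  out <- rep.int(pad_index, max_len)
  if (keep > 0L) out[seq_len(keep)] <- idx[seq_len(keep)]
  mask <- c(rep.int(1L, keep), rep.int(0L, max_len - keep))
  new_tokenized(out, mask, n)
}

#' Character tokenization to a fixed length
#'
#' Splits \code{sequence} into single characters, optionally restricts them
#' to an allowed set (characters outside it are replaced by the unknown
#' token before lookup), converts to vocabulary indices, and pads with the
#' pad index or truncates to \code{max_len}.  The returned mask is 1 on the
#' first \code{min(nchar(sequence), max_len)} positions and 0 afterwards.
#'
#' @param sequence a single character string.
#' @param vocab a \code{"dti_vocab"}.
#' @param max_len positive integer, fixed output length.
#' @param allowed optional character vector: the permitted symbols (e.g.
#'   the 20 standard amino-acid letters for proteins).
#' @return A \code{"dti_tokens"} object with \code{indices}, \code{mask}
#'   and \code{original_length}.
#' @examples
#' v <- build_smiles_vocabulary(c("CCO"))
#' tokenize_chars("CCO", v, max_len = 5)
#' @export
tokenize_chars <- function(sequence, vocab, max_len, allowed = NULL) {
  if (!is_count(max_len)) stop2("max_len must be a positive integer")
  stopifnot(length(sequence) == 1L)
  ch <- strsplit(as.character(sequence), "", fixed = TRUE)[[1]]
  if (!is.null(allowed)) ch[!(ch %in% allowed)] <- vocab$unknown_token
  idx <- token_index(vocab, ch)
  pad_tokens(idx, as.integer(max_len), vocab$index[[vocab$pad_token]])
}

#' Read protein sequences from a FASTA file
#'
#' Standard multi-line FASTA ('>' headers); returns a named character
#' vector of sequences keyed by the first whitespace-delimited word of each
#' header.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                          set.attributes = FALSE)
  out <- toupper(unlist(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Read SMILES strings, one per line
#'
#' @param path path to a plain-text file with one SMILES per line; blank
#'   lines are skipped.
#' @return character vector of SMILES strings.
#' @export
read_smiles_lines <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x)]
}

#' Serialize / restore a vocabulary as JSON
#'
#' @param vocab a \code{"dti_vocab"}.
#' @param path file path.
#' @return \code{write_vocab_json} returns \code{path} invisibly;
#'   \code{read_vocab_json} returns a \code{"dti_vocab"}.
#' @export
write_vocab_json <- function(vocab, path) {
  jsonlite::write_json(list(tokens = vocab$tokens), path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_vocab_json
#' @export
read_vocab_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  v <- vocabulary(x$tokens)
  if (!identical(v$tokens, as.character(x$tokens)))
    stop2("vocabulary file is not in canonical order: ", path)
  v
}
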