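test_that("SMILES vocabulary collects distinct characters with '?' first", {
  v <- build_smiles_vocabulary(c("CCO"))
  expect_equal(v$size, 3L)
  expect_setequal(v$tokens, c("?", "C", "O"))
  expect_equal(v$tokens[1], "?")

  v2 <- build_smiles_vocabulary(c("C=O", "CC"))
  expect_equal(v2$size, 4L)
  expect_equal(v2$tokens, c("?", "=", "C", "O"))
  expect_equal(unname(v2$index[v2$tokens]), 0:3)

  expect_error(build_smiles_vocabulary(character(0)), "empty")
})

test_that("unknown lookups always resolve to the '?' index", {
  v <- build_smiles_vocabulary(c("CCO"))
  expect_equal(token_index(v, c("C", "X", "#")), c(1L, 0L, 0L))
  ## arbitrary byte soup stays inside the index range
  junk <- vapply(1:50, function(i) rawToChar(as.raw(sample(32:126, 5))),
                 character(1))
  for (s in junk) {
    tk <- tokenize_chars(s, v, max_len = 8L)
    expect_true(all(tk$indices >= 0L & tk$indices < v$size))
  }
})

test_that("character tokenization pads, truncates and masks correctly", {
  v <- build_smiles_vocabulary(c("CCO"))
  tk <- tokenize_chars("CCO", v, max_len = 5L)
  iC <- unname(v$index[["C"]]); iO <- unname(v$index[["O"]])
  expect_equal(tk$indices, c(iC, iC, iO, 0L, 0L))
  expect_equal(tk$mask, c(1L, 1L, 1L, 0L, 0L))
  expect_equal(tk$original_length, 3L)

  ## '#' absent from the vocabulary maps to the unknown index
  tk2 <- tokenize_chars("C#N", v, max_len = 3L)
  expect_equal(tk2$indices[2], 0L)

  ## non-standard amino acids are rejected before lookup
  vp <- amino_acid_vocabulary()
  tk3 <- tokenize_chars("MALWX", vp, max_len = 5L,
                        allowed = c("A", "C", "D", "E", "F", "G", "H", "I",
                                    "K", "L", "M", "N", "P", "Q", "R", "S",
                                    "T", "V", "W", "Y"))
  expect_equal(tk3$indices[5], 0L)
  expect_equal(tk3$mask, rep(1L, 5))

  ## truncation
  tk4 <- tokenize_chars("CCOCCO", v, max_len = 4L)
  expect_equal(length(tk4$indices), 4L)
  expect_equal(sum(tk4$mask), 4L)
})

test_that("tokenization is deterministic and mask sums are consistent", {
  v <- build_smiles_vocabulary(c("CCO", "C=N", "c1ccccc1"))
  set.seed(4)
  for (i in 1:25) {
    s <- paste(sample(c("C", "O", "N", "=", "(", ")", "z"), sample(0:12, 1),
                      replace = TRUE), collapse = "")
    L <- sample(1:10, 1)
    a <- tokenize_chars(s, v, L)
    b <- tokenize_chars(s, v, L)
    expect_identical(a, b)
    expect_equal(sum(a$mask), min(nchar(s), L))
  }
})

test_that("BPE merges the most frequent pair, ties broken lexicographically", {
  m <- train_bpe(c("AAAB", "AABA"), num_merges = 1L)
  expect_equal(m$merges[[1]], c("A", "A"))

  m0 <- train_bpe(c("AAAB", "AABA"), num_merges = 0L)
  expect_equal(m0$num_merges, 0L)
  expect_setequal(m0$vocab$tokens, c("?", "A", "B"))

  m2 <- train_bpe(c("ABAB", "ABAB"), num_merges = 2L)
  expect_equal(m2$merges[[1]], c("A", "B"))
  expect_equal(m2$merges[[2]], c("AB", "AB"))

  expect_error(train_bpe(character(0), 3L), "empty")
})

test_that("BPE encoding applies merges, pads and masks", {
  m <- train_bpe(c("AAAB", "AABA"), num_merges = 1L)  # merge ("A","A")
  tk <- encode_bpe("AAAB", m, max_tokens = 4L)
  expect_equal(tk$mask, c(1L, 1L, 1L, 0L))
  toks <- m$vocab$tokens[tk$indices[1:3] + 1L]
  expect_equal(toks, c("AA", "A", "B"))

  ## empty sequence: all padding
  tk0 <- encode_bpe("", m, max_tokens = 3L)
  expect_equal(tk0$mask, c(0L, 0L, 0L))

  ## truncation keeps exactly max_tokens
  tk1 <- encode_bpe(strrep("AB", 20), m, max_tokens = 5L)
  expect_equal(length(tk1$indices), 5L)
  expect_equal(tk1$mask, rep(1L, 5))
})

test_that("BPE with zero merges equals character tokenization", {
  corpus <- c("MKLVA", "GGWKL", "MKAAY")
  m0 <- train_bpe(corpus, 0L)
  for (s in c(corpus, "MKXZ")) {
    a <- encode_bpe(s, m0, 8L)
    b <- tokenize_chars(s, m0$vocab, 8L, allowed = mcfdti:::AA_LETTERS)
    expect_identical(a$indices, b$indices)
    expect_identical(a$mask, b$mask)
  }
})

test_that("vocabularies and BPE models round-trip through JSON", {
  v <- build_smiles_vocabulary(c("CC(=O)N", "c1ccccc1"))
  f <- withr::local_tempfile(fileext = ".json")
  write_vocab_json(v, f)
  expect_identical(read_vocab_json(f), v)

  m <- train_bpe(c("MKLVAGG", "MKLWWAG"), 3L)
  f2 <- withr::local_tempfile(fileext = ".json")
  write_bpe_json(m, f2)
  m2 <- read_bpe_json(f2)
  expect_identical(m2$merges, m$merges)
  expect_identical(m2$vocab$tokens, m$vocab$tokens)
  expect_identical(encode_bpe("MKLVAG", m2, 6L), encode_bpe("MKLVAG", m, 6L))
})

test_that("FASTA and SMILES readers parse standard files", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">prot1 description", "MKLV", "AGG", ">prot2", "WWAG"), fa)
  seqs <- read_fasta(fa)
  expect_equal(unname(seqs["prot1"]), "MKLVAGG")
  expect_equal(unname(seqs["prot2"]), "WWAG")

  sm <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO", "", "  c1ccccc1  "), sm)
  expect_equal(read_smiles_lines(sm), c("CCO", "c1ccccc1"))
})
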