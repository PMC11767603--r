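test_that("the Davis loader emits one record per measured cell", {
  lig <- c(d1 = "CCO", d2 = "CCN")
  prot <- c(t1 = "MKLV", t2 = "GGWA", t3 = "MKYY")
  aff <- matrix(c(10, 50, 20, 100, 5, 2000), nrow = 2)
  recs <- load_davis(lig, prot, aff, value_scale = "kd_nM")
  expect_equal(nrow(recs), 6L)
  expect_equal(recs$kd_nM[recs$drug_id == "d1" & recs$target_id == "t1"], 10)

  aff2 <- aff; aff2[2, 3] <- NA
  expect_equal(nrow(load_davis(lig, prot, aff2)), 5L)

  expect_error(load_davis(lig, prot, matrix(1, 3, 3)), "ligands")
  expect_error(load_davis(lig, prot, aff * 0), "non-positive")
})

test_that("pKd inputs convert through kd = 10^(9 - pKd)", {
  recs <- load_davis(c(d = "C"), c(t = "MK"), matrix(7.0),
                     value_scale = "pKd")
  expect_equal(recs$kd_nM, 100.0)
  recs5 <- load_davis(c(d = "C"), c(t = "MK"), matrix(5.0),
                      value_scale = "pKd")
  expect_equal(recs5$kd_nM, 10000.0)
})

test_that("binarization is strict at the Kd threshold", {
  recs <- data.frame(drug_id = "d", smiles = "C", target_id = "t",
                     sequence = "MK", kd_nM = c(29.9, 30.0, 10000))
  lab <- binarize_kd(recs)$label
  expect_equal(lab, c(1L, 0L, 0L))

  ## raising the threshold never loses positives
  thr <- c(5, 30, 100, 5000)
  counts <- vapply(thr, function(t) sum(binarize_kd(recs, t)$label), 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("balancing keeps all positives and samples negatives uniquely", {
  recs <- data.frame(drug_id = paste0("d", c(1:13, 13)),
                     smiles = "C", target_id = "t", sequence = "MK",
                     label = c(rep(1L, 3), rep(0L, 10), 0L))
  ## last row duplicates (d13, t); uniqueness check drops it first
  bal <- suppressMessages(balance_by_downsampling(recs, seed = 5L))
  expect_equal(bal$summary$n_positive, 3L)
  expect_equal(bal$summary$n_negative, 3L)
  expect_equal(bal$summary$n_records, 6L)
  key <- paste(bal$records$drug_id, bal$records$target_id)
  expect_equal(anyDuplicated(key), 0L)

  bal2 <- suppressMessages(balance_by_downsampling(recs, seed = 5L))
  expect_identical(bal$records, bal2$records)
  bal3 <- suppressMessages(balance_by_downsampling(recs, seed = 6L))
  expect_false(identical(bal$records$drug_id, bal3$records$drug_id))

  few_neg <- recs[c(1:3, 4), ]
  expect_error(balance_by_downsampling(few_neg, 1L), "cannot balance")
})

test_that("pair TSV files round-trip losslessly", {
  recs <- tiny_records(5)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_pairs_tsv(recs, f)
  back <- read_pairs_tsv(f)
  expect_equal(back$smiles, recs$smiles)
  expect_equal(back$sequence, recs$sequence)
  expect_equal(back$label, recs$label)

  ## label-only files (no kd_nM) are valid
  expect_false("kd_nM" %in% names(back))

  ## empty SMILES is rejected with its line number
  bad <- recs
  bad$smiles[3] <- ""
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_pairs_tsv(bad, f2)
  expect_error(read_pairs_tsv(f2), "line.*4")

  ## mandatory columns
  f3 <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(recs[c("drug_id", "smiles", "label")], f3, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expect_error(read_pairs_tsv(f3), "target_id")
})

test_that("file-based Davis reading matches the in-memory loader", {
  sp <- synthetic_spec(n_drugs = 6L, n_targets = 5L, seed = 21L,
                       smiles_length_range = c(6L, 10L),
                       protein_length_range = c(8L, 14L))
  davis <- generate_kd_matrix(sp)
  dir <- withr::local_tempdir()
  paths <- write_fixture_bundle(sp, dir)
  from_file <- read_davis(paths[["ligands"]], paths[["proteins"]],
                          paths[["affinity"]])
  in_mem <- load_davis(davis$ligands, davis$proteins, davis$affinity)
  expect_equal(nrow(from_file), 30L)
  expect_equal(from_file$kd_nM, in_mem$kd_nM, tolerance = 1e-8)
  expect_equal(from_file$smiles, in_mem$smiles)
})
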