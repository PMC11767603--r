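## Seeded synthetic DTI fixtures with a plantable conjunctive motif rule.
##
## A pair truly interacts iff the drug string contains the drug motif AND
## the protein contains the target motif; observed labels optionally flip
## with a noise probability.  The conjunctive rule is learnable by both
## convolutional (local motif) and attention (cross-stream pairing)
## components, which is exactly what the architecture claims to capture.

#' Specification for a synthetic DTI fixture
#'
#' Defaults describe a compact but non-trivial benchmark: SMILES-like
#' strings over a 16-symbol chemistry alphabet, protein-like strings over
#' the 20 amino-acid letters, and motifs short enough that chance
#' occurrences are rare but long enough to be unambiguous.  With the
#' default plant probability 0.7 per side, true-positive prevalence is
#' about 0.49, so balanced training sets need little downsampling.
#'
#' @param n_drugs,n_targets library sizes.
#' @param smiles_alphabet character set for drug strings.
#' @param protein_alphabet character set for protein strings (the 20
#'   standard amino-acid letters).
#' @param drug_motif,target_motif planted substrings over the respective
#'   alphabets.
#' @param motif_plant_probability probability, per drug and per target,
#'   that the motif is planted.
#' @param label_noise probability of flipping an observed label.
#' @param smiles_length_range,protein_length_range inclusive length bounds.
#' @param seed master seed; all randomness derives from it.
#' @return list of class \code{"dti_synth_spec"}.
#' @export
synthetic_spec <- function(n_drugs = 80L, n_targets = 60L,
                           smiles_alphabet = c("C", "N", "O", "S", "P", "F",
                                               "I", "c", "n", "o", "=", "#",
                                               "(", ")", "1", "2"),
                           protein_alphabet = AA_LETTERS,
                           drug_motif = "N=CO",
                           target_motif = "GKSW",
                           motif_plant_probability = 0.7,
                           label_noise = 0,
                           smiles_length_range = c(20L, 48L),
                           protein_length_range = c(60L, 160L),
                           seed = 1L) {
  spec <- list(n_drugs = as.integer(n_drugs), n_targets = as.integer(n_targets),
               smiles_alphabet = smiles_alphabet,
               protein_alphabet = protein_alphabet,
               drug_motif = drug_motif, target_motif = target_motif,
               motif_plant_probability = motif_plant_probability,
               label_noise = label_noise,
               smiles_length_range = as.integer(smiles_length_range),
               protein_length_range = as.integer(protein_length_range),
               seed = as.integer(seed))
  dm <- strsplit(drug_motif, "")[[1]]
  tm <- strsplit(target_motif, "")[[1]]
  if (!all(dm %in% smiles_alphabet))
    stop2("drug_motif uses symbols outside smiles_alphabet")
  if (!all(tm %in% protein_alphabet))
    stop2("target_motif uses symbols outside protein_alphabet")
  if (length(dm) > spec$smiles_length_range[1] ||
      length(tm) > spec$protein_length_range[1])
    stop2("motif longer than the minimum sequence length")
  if (motif_plant_probability <= 0 || motif_plant_probability >= 1)
    stop2("motif_plant_probability must lie in (0, 1)")
  if (label_noise < 0 || label_noise >= 1)
    stop2("label_noise must lie in [0, 1)")
  structure(spec, class = "dti_synth_spec")
}

random_strings <- function(n, alphabet, len_range, motif, plant_prob) {
  lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  plant <- stats::runif(n) < plant_prob
  m <- strsplit(motif, "")[[1]]
  out <- character(n)
  for (i in seq_len(n)) {
    s <- sample(alphabet, lens[i], replace = TRUE)
    if (plant[i]) {
      at <- sample.int(lens[i] - length(m) + 1L, 1L)
      s[at:(at + length(m) - 1L)] <- m
    }
    out[i] <- paste(s, collapse = "")
  }
  out
}

synth_libraries <- function(spec) {
  drugs <- with_seed(derive_seed(spec$seed, "drugs"),
                     random_strings(spec$n_drugs, spec$smiles_alphabet,
                                    spec$smiles_length_range, spec$drug_motif,
                                    spec$motif_plant_probability))
  targets <- with_seed(derive_seed(spec$seed, "targets"),
                       random_strings(spec$n_targets, spec$protein_alphabet,
                                      spec$protein_length_range,
                                      spec$target_motif,
                                      spec$motif_plant_probability))
  names(drugs) <- sprintf("D%03d", seq_along(drugs))
  names(targets) <- sprintf("T%03d", seq_along(targets))
  list(drugs = drugs, targets = targets)
}

#' Generate labelled synthetic drug-target pairs
#'
#' Draws \code{n_pairs} distinct (drug, target) pairs.  The true label is 1
#' iff the drug contains the drug motif and the target contains the target
#' motif (by literal substring search, so incidental random occurrences
#' count too); the observed label flips with probability
#' \code{spec$label_noise}.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @param n_pairs number of pairs, at most \code{n_drugs * n_targets}.
#' @return list with \code{records} (data.frame: drug_id, smiles,
#'   target_id, sequence, label, true_label) and \code{rule} (the planted
#'   ground truth: motifs, noise, seed).
#' @export
generate_pairs <- function(spec, n_pairs) {
  stopifnot(inherits(spec, "dti_synth_spec"))
  if (!is_count(n_pairs) || n_pairs > spec$n_drugs * spec$n_targets)
    stop2("n_pairs must be a positive integer <= n_drugs * n_targets")
  lib <- synth_libraries(spec)
  cells <- with_seed(derive_seed(spec$seed, "pairs"),
                     sample.int(spec$n_drugs * spec$n_targets, n_pairs))
  di <- ((cells - 1L) %% spec$n_drugs) + 1L
  ti <- ((cells - 1L) %/% spec$n_drugs) + 1L
  true_lab <- as.integer(grepl(spec$drug_motif, lib$drugs[di], fixed = TRUE) &
                         grepl(spec$target_motif, lib$targets[ti], fixed = TRUE))
  flip <- if (spec$label_noise > 0)
    with_seed(derive_seed(spec$seed, "noise"),
              stats::runif(n_pairs) < spec$label_noise)
  else rep(FALSE, n_pairs)
  records <- data.frame(drug_id = names(lib$drugs)[di],
                        smiles = unname(lib$drugs[di]),
                        target_id = names(lib$targets)[ti],
                        sequence = unname(lib$targets[ti]),
                        label = as.integer(xor(true_lab == 1L, flip)),
                        true_label = true_lab,
                        stringsAsFactors = FALSE)
  class(records) <- c("dti_records", "data.frame")
  list(records = records,
       rule = list(drug_motif = spec$drug_motif,
                   target_motif = spec$target_motif,
                   label_noise = spec$label_noise, seed = spec$seed))
}

#' Generate a Davis-format synthetic affinity matrix
#'
#' Emits a dense drug x target Kd matrix in which truly interacting pairs
#' (conjunctive motif rule) draw log-uniform Kd from the positive range and
#' the rest from the negative range, so the fixture straddles the 30 nM
#' binarization boundary by construction.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @param positive_kd_range,negative_kd_range Kd ranges in nM; the positive
#'   range must lie entirely below 30 nM and the negative range at or
#'   above it.
#' @return list with \code{ligands} (named SMILES), \code{proteins} (named
#'   sequences) and \code{affinity} (dense numeric matrix, nM).
#' @export
generate_kd_matrix <- function(spec, positive_kd_range = c(1, 29),
                               negative_kd_range = c(100, 10000)) {
  stopifnot(inherits(spec, "dti_synth_spec"))
  if (max(positive_kd_range) >= 30 || min(negative_kd_range) < 30)
    stop2("Kd ranges must sit on opposite sides of the 30 nM threshold")
  lib <- synth_libraries(spec)
  has_dm <- grepl(spec$drug_motif, lib$drugs, fixed = TRUE)
  has_tm <- grepl(spec$target_motif, lib$targets, fixed = TRUE)
  truth <- outer(has_dm, has_tm, "&")
  kd <- with_seed(derive_seed(spec$seed, "kd"), {
    n <- length(truth)
    u <- stats::runif(n)
    lo <- ifelse(truth, positive_kd_range[1], negative_kd_range[1])
    hi <- ifelse(truth, positive_kd_range[2], negative_kd_range[2])
    matrix(exp(log(lo) + u * (log(hi) - log(lo))), nrow(truth), ncol(truth))
  })
  dimnames(kd) <- list(names(lib$drugs), names(lib$targets))
  list(ligands = lib$drugs, proteins = lib$targets, affinity = kd)
}

#' Write a complete synthetic fixture bundle
#'
#' Writes the Davis-format files (\code{ligands.json}, \code{proteins.json},
#' \code{affinity.txt}), a FASTA of the proteins, a labelled pair TSV and a
#' JSON ground-truth manifest.  Output is byte-identical across runs with
#' the same spec.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @param out_dir output directory (created if needed).
#' @param n_pairs number of labelled pairs for \code{pairs.tsv}
#'   (default: all cells).
#' @return named character vector of written file paths (the manifest
#'   records counts and the planted rule).
#' @export
write_fixture_bundle <- function(spec, out_dir, n_pairs = NULL) {
  stopifnot(inherits(spec, "dti_synth_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop2("cannot create output directory ", out_dir)
  n_pairs <- n_pairs %||% (spec$n_drugs * spec$n_targets)
  davis <- generate_kd_matrix(spec)
  pairs <- generate_pairs(spec, n_pairs)
  paths <- c(ligands = file.path(out_dir, "ligands.json"),
             proteins = file.path(out_dir, "proteins.json"),
             affinity = file.path(out_dir, "affinity.txt"),
             fasta = file.path(out_dir, "proteins.fasta"),
             pairs = file.path(out_dir, "pairs.tsv"),
             manifest = file.path(out_dir, "manifest.json"))
  jsonlite::write_json(as.list(davis$ligands), paths[["ligands"]],
                       auto_unbox = TRUE, pretty = TRUE)
  jsonlite::write_json(as.list(davis$proteins), paths[["proteins"]],
                       auto_unbox = TRUE, pretty = TRUE)
  writeLines(apply(format(davis$affinity, digits = 10, trim = TRUE,
                          scientific = FALSE), 1L, paste, collapse = " "),
             paths[["affinity"]])
  writeLines(paste0(">", names(davis$proteins), "\n", davis$proteins),
             paths[["fasta"]])
  write_pairs_tsv(pairs$records, paths[["pairs"]])
  manifest <- list(rule = pairs$rule,
                   spec = unclass(spec)[c("n_drugs", "n_targets", "seed",
                                          "motif_plant_probability",
                                          "label_noise")],
                   summary = dataset_summary(pairs$records))
  jsonlite::write_json(manifest, paths[["manifest"]],
                       auto_unbox = TRUE, pretty = TRUE)
  paths
}
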