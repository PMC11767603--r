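## Davis-benchmark-style data handling: keyed ligand/protein collections, a
## dense drug x target affinity matrix (Kd in nM or pKd), Kd-threshold
## binarization, uniqueness checking and balanced negative downsampling.

#' Assemble interaction records from a Davis-style distribution
#'
#' One record is produced per non-missing affinity cell.  Row/column
#' identity follows the key order of the two collections.  When the matrix
#' stores pKd, values are converted to Kd in nM via
#' \code{kd_nM = 10^(9 - pKd)}.
#'
#' @param ligands named character vector of SMILES, one per drug key.
#' @param proteins named character vector of protein sequences, one per
#'   target key.
#' @param affinity numeric matrix, drugs x targets; \code{NA}/\code{NaN}
#'   marks missing measurements.
#' @param value_scale either \code{"kd_nM"} (matrix holds Kd in nM) or
#'   \code{"pKd"}.
#' @return data.frame of class \code{"dti_records"} with columns
#'   \code{drug_id}, \code{smiles}, \code{target_id}, \code{sequence},
#'   \code{kd_nM}.
#' @export
load_davis <- function(ligands, proteins, affinity,
                       value_scale = c("kd_nM", "pKd")) {
  value_scale <- match.arg(value_scale)
  affinity <- as.matrix(affinity)
  if (nrow(affinity) != length(ligands) || ncol(affinity) != length(proteins))
    stop2("affinity matrix is ", nrow(affinity), " x ", ncol(affinity),
          " but there are ", length(ligands), " ligands and ",
          length(proteins), " proteins")
  if (is.null(names(ligands)))
    names(ligands) <- paste0("D", seq_along(ligands))
  if (is.null(names(proteins)))
    names(proteins) <- paste0("T", seq_along(proteins))
  keep <- which(!is.na(affinity))
  if (length(keep) == 0L) stop2("affinity matrix has no measured cells")
  ri <- ((keep - 1L) %% nrow(affinity)) + 1L
  ci <- ((keep - 1L) %/% nrow(affinity)) + 1L
  val <- affinity[keep]
  kd <- if (value_scale == "pKd") 10^(9 - val) else val
  if (any(kd <= 0)) stop2("non-positive Kd values in affinity matrix")
  ord <- order(ri, ci)  # row-major record order
  out <- data.frame(drug_id = names(ligands)[ri],
                    smiles = unname(ligands[ri]),
                    target_id = names(proteins)[ci],
                    sequence = unname(proteins[ci]),
                    kd_nM = kd,
                    stringsAsFactors = FALSE)[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("dti_records", "data.frame")
  out
}

#' Read a Davis-style distribution from files
#'
#' Expects two keyed JSON collections (key -> SMILES, key -> sequence) and a
#' whitespace- or comma-delimited dense matrix with \code{NaN}/\code{NA} for
#' missing entries.
#'
#' @param ligand_file,protein_file JSON files mapping keys to strings.
#' @param affinity_file delimited text matrix, drugs in rows.
#' @inheritParams load_davis
#' @return as \code{\link{load_davis}}.
#' @export
read_davis <- function(ligand_file, protein_file, affinity_file,
                       value_scale = c("kd_nM", "pKd")) {
  lig <- unlist(jsonlite::read_json(ligand_file, simplifyVector = TRUE))
  prot <- unlist(jsonlite::read_json(protein_file, simplifyVector = TRUE))
  if (!is.character(lig) || !is.character(prot))
    stop2("ligand/protein collections must map keys to strings")
  txt <- readLines(affinity_file, warn = FALSE)
  txt <- txt[nzchar(trimws(txt))]
  rows <- lapply(strsplit(trimws(gsub(",", " ", txt, fixed = TRUE)), "\\s+"),
                 function(x) suppressWarnings(as.numeric(x)))
  ncols <- unique(lengths(rows))
  if (length(ncols) != 1L)
    stop2("affinity matrix rows have unequal lengths in ", affinity_file)
  aff <- do.call(rbind, rows)
  load_davis(lig, prot, aff, value_scale = value_scale)
}

#' Binarize binding affinities at a Kd threshold
#'
#' Pairs with \code{kd_nM} strictly below the threshold are labelled
#' positive (interacting); pairs at or above it are negative.
#'
#' @param records a \code{"dti_records"} data.frame with a \code{kd_nM}
#'   column.
#' @param threshold_nM positive Kd threshold in nM (default 30).
#' @return the records with an added integer \code{label} column.
#' @export
binarize_kd <- function(records, threshold_nM = 30) {
  if (is.null(records$kd_nM) || anyNA(records$kd_nM))
    stop2("binarize_kd needs a complete kd_nM column")
  if (!is.numeric(threshold_nM) || threshold_nM <= 0)
    stop2("threshold_nM must be positive")
  records$label <- as.integer(records$kd_nM < threshold_nM)
  records
}

#' Summary counts for a record set
#'
#' @param records a records data.frame.
#' @return list with \code{n_drugs}, \code{n_targets}, \code{n_records},
#'   \code{n_positive}, \code{n_negative} (the last two are \code{NA} when
#'   labels are absent).
#' @export
dataset_summary <- function(records) {
  lab <- records$label
  list(n_drugs = length(unique(records$drug_id)),
       n_targets = length(unique(records$target_id)),
       n_records = nrow(records),
       n_positive = if (is.null(lab)) NA_integer_ else sum(lab == 1L),
       n_negative = if (is.null(lab)) NA_integer_ else sum(lab == 0L))
}

drop_duplicate_pairs <- function(records) {
  key <- paste(records$drug_id, records$target_id, sep = "\x1f")
  dup <- duplicated(key)
  if (any(dup)) {
    message(sum(dup), " duplicate (drug_id, target_id) pairs dropped; ",
            "first occurrence kept")
    records <- records[!dup, , drop = FALSE]
    rownames(records) <- NULL
  }
  records
}

#' Balance a labelled record set by downsampling negatives
#'
#' Enforces (drug_id, target_id) uniqueness (first occurrence wins), keeps
#' every positive, and draws an equal number of negatives uniformly without
#' replacement under the given seed.
#'
#' @param records labelled records data.frame.
#' @param seed integer seed for the negative draw.
#' @return list with \code{records} (balanced, positives first) and
#'   \code{summary} (a \code{\link{dataset_summary}}).
#' @export
balance_by_downsampling <- function(records, seed) {
  if (is.null(records$label)) stop2("records must carry a label column")
  records <- drop_duplicate_pairs(records)
  pos <- which(records$label == 1L)
  neg <- which(records$label == 0L)
  if (length(neg) < length(pos))
    stop2("cannot balance: ", length(neg), " negatives < ",
          length(pos), " positives")
  keep_neg <- with_seed(derive_seed(seed, "sampling"),
                        sort(sample(neg, length(pos))))
  out <- records[c(pos, keep_neg), , drop = FALSE]
  rownames(out) <- NULL
  list(records = out, summary = dataset_summary(out))
}

#' Read / write drug-target pair files (TSV)
#'
#' The TSV must carry a header with columns \code{drug_id}, \code{smiles},
#' \code{target_id}, \code{sequence} and at least one of \code{kd_nM},
#' \code{label}.  Rows with empty SMILES or sequence are rejected with
#' their line numbers.
#'
#' @param path TSV file path.
#' @return \code{read_pairs_tsv}: a \code{"dti_records"} data.frame.
#' @export
read_pairs_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
  need <- c("drug_id", "smiles", "target_id", "sequence")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop2("pair file ", path, " is missing mandatory columns: ",
          paste(miss, collapse = ", "))
  if (!any(c("kd_nM", "label") %in% names(df)))
    stop2("pair file ", path, " needs a kd_nM and/or label column")
  bad <- which(!nzchar(trimws(df$smiles)) | !nzchar(trimws(df$sequence)))
  if (length(bad))
    stop2("pair file ", path, " has empty smiles/sequence on line(s) ",
          paste(bad + 1L, collapse = ", "), " (1 = header)")
  out <- df[need]
  if ("kd_nM" %in% names(df)) {
    kd <- suppressWarnings(as.numeric(df$kd_nM))
    bad <- which(is.na(kd) & nzchar(trimws(df$kd_nM)))
    if (length(bad))
      stop2("pair file ", path, " has unparseable kd_nM on line(s) ",
            paste(bad + 1L, collapse = ", "))
    out$kd_nM <- kd
  }
  if ("label" %in% names(df)) {
    lab <- suppressWarnings(as.integer(df$label))
    if (any(!is.na(lab) & !(lab %in% c(0L, 1L))))
      stop2("pair file ", path, " has non-binary labels")
    out$label <- lab
  }
  class(out) <- c("dti_records", "data.frame")
  out
}

#' @rdname read_pairs_tsv
#' @param records records data.frame to write.
#' @return \code{write_pairs_tsv}: \code{path}, invisibly.
#' @export
write_pairs_tsv <- function(records, path) {
  keep <- intersect(c("drug_id", "smiles", "target_id", "sequence",
                      "kd_nM", "label"), names(records))
  utils::write.table(records[keep], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}
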