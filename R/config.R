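## Model and training configuration with explicit, documented defaults.

MODEL_VARIANTS <- c("mcf_dti", "mscnn_mscnn", "mscnn_transformer",
                    "mscnn2_mscnn2", "mscnn2_mscnn_transformer_s",
                    "cnn_transformer", "mscnn_mscnn_transformer_c")

#' Architecture configuration
#'
#' Every architecture hyperparameter in one place.  The convolutional
#' channel/kernel triples, learning protocol and the '?'-padded fixed-length
#' tokenization follow the reference protocol; quantities the protocol
#' leaves open (embedding width, transformer geometry, fusion widths,
#' maximum lengths, BPE merges) have explicit defaults here and are all
#' overridable.
#'
#' @param smiles_max_len fixed SMILES length in characters.
#' @param protein_max_len fixed protein length in characters (conv path).
#' @param bpe_max_tokens fixed protein length in BPE subwords
#'   (transformer path).
#' @param bpe_merges number of BPE merges learned from the training fold.
#' @param embed_dim embedding width for drug and protein characters.
#' @param drug_channels,drug_kernels output channels and kernel sizes of
#'   the three drug convolution layers (defaults (32, 64, 96) / (4, 6, 8)).
#' @param target_channels,target_kernels the target-side conv triple
#'   (defaults (32, 64, 96) / (4, 8, 12)).
#' @param d_model,n_heads,n_layers,ffn_dim transformer geometry;
#'   \code{d_model} must be divisible by \code{n_heads}.
#' @param proj_channels common channel width C_f to which the local (conv)
#'   and global (transformer) target streams are projected before fusion.
#' @param pool_bins common time length T_f after adaptive mean pooling.
#' @param share_drug_branch_weights tie the two drug conv branches
#'   (the "parallel shared-weight" reading); default untied.
#' @param sfm_on_target_LG apply the selective fusion module to the
#'   (local, global) target streams before interaction instead of to the
#'   two halves of the crossed features.
#' @param bfim_variant \code{"affine"} (concat + elementwise product
#'   through a bias-bearing affine map) or \code{"bilinear"}.
#' @param se_ratio squeeze-and-excitation / SFM reduction ratio r.
#' @param head_widths hidden widths of the fully connected head (a final
#'   1-unit sigmoid layer is implied).
#' @param dropout dropout rate in the head (training only).
#' @return list of class \code{"dti_model_config"}.
#' @export
model_config <- function(smiles_max_len = 100L, protein_max_len = 1000L,
                         bpe_max_tokens = 545L, bpe_merges = 1000L,
                         embed_dim = 128L,
                         drug_channels = c(32L, 64L, 96L),
                         drug_kernels = c(4L, 6L, 8L),
                         target_channels = c(32L, 64L, 96L),
                         target_kernels = c(4L, 8L, 12L),
                         d_model = 128L, n_heads = 8L, n_layers = 2L,
                         ffn_dim = 256L,
                         proj_channels = 96L, pool_bins = 64L,
                         share_drug_branch_weights = FALSE,
                         sfm_on_target_LG = FALSE,
                         bfim_variant = c("affine", "bilinear"),
                         se_ratio = 4L,
                         head_widths = c(512L, 128L),
                         dropout = 0.1) {
  cfg <- list(smiles_max_len = as.integer(smiles_max_len),
              protein_max_len = as.integer(protein_max_len),
              bpe_max_tokens = as.integer(bpe_max_tokens),
              bpe_merges = as.integer(bpe_merges),
              embed_dim = as.integer(embed_dim),
              drug_channels = as.integer(drug_channels),
              drug_kernels = as.integer(drug_kernels),
              target_channels = as.integer(target_channels),
              target_kernels = as.integer(target_kernels),
              d_model = as.integer(d_model), n_heads = as.integer(n_heads),
              n_layers = as.integer(n_layers), ffn_dim = as.integer(ffn_dim),
              proj_channels = as.integer(proj_channels),
              pool_bins = as.integer(pool_bins),
              share_drug_branch_weights = isTRUE(share_drug_branch_weights),
              sfm_on_target_LG = isTRUE(sfm_on_target_LG),
              bfim_variant = match.arg(bfim_variant),
              se_ratio = as.integer(se_ratio),
              head_widths = as.integer(head_widths),
              dropout = dropout)
  stopifnot(length(cfg$drug_channels) == 3L, length(cfg$drug_kernels) == 3L,
            length(cfg$target_channels) == 3L, length(cfg$target_kernels) == 3L)
  if (cfg$d_model %% cfg$n_heads != 0L)
    stop2("d_model (", cfg$d_model, ") must be divisible by n_heads (",
          cfg$n_heads, ")")
  if (cfg$dropout < 0 || cfg$dropout >= 1) stop2("dropout must be in [0, 1)")
  structure(cfg, class = "dti_model_config")
}

#' Compact architecture preset
#'
#' A scaled-down configuration (32-dimensional embeddings, single
#' transformer layer, narrow fusion) for experiments on the synthetic
#' benchmark and for examples; same topology as the full model.
#'
#' @param ... overrides passed on to \code{\link{model_config}}.
#' @return a \code{"dti_model_config"}.
#' @export
small_model_config <- function(...) {
  defaults <- list(smiles_max_len = 48L, protein_max_len = 160L,
                   bpe_max_tokens = 64L, bpe_merges = 50L,
                   embed_dim = 32L,
                   drug_channels = c(16L, 32L, 32L),
                   target_channels = c(16L, 32L, 32L),
                   d_model = 32L, n_heads = 4L, n_layers = 1L, ffn_dim = 64L,
                   proj_channels = 32L, pool_bins = 16L,
                   head_widths = c(64L, 32L))
  over <- list(...)
  defaults[names(over)] <- over
  do.call(model_config, defaults)
}

#' Training configuration
#'
#' Defaults follow the reference protocol: learning rate 0.001, batch size
#' 64, 500 epochs, 5-fold cross-validation.  Loss is binary cross-entropy
#' and the optimizer is Adam.
#'
#' @param learning_rate Adam learning rate (> 0).
#' @param batch_size minibatch size (>= 1).
#' @param epochs training epochs.
#' @param folds cross-validation folds (>= 2).
#' @param seed master seed; drives initialization, shuffling, dropout and
#'   fold assignment through named sub-streams.
#' @param architecture_variant one of \code{"mcf_dti"} (full model) or the
#'   ablation variants \code{"mscnn_mscnn"}, \code{"mscnn_transformer"},
#'   \code{"mscnn2_mscnn2"}, \code{"mscnn2_mscnn_transformer_s"},
#'   \code{"cnn_transformer"}, \code{"mscnn_mscnn_transformer_c"}.
#' @param decision_threshold score threshold for accuracy/precision/recall.
#' @param pooled_metrics report metrics on pooled out-of-fold predictions
#'   instead of fold means.
#' @param early_stopping stop when training loss stops improving for
#'   \code{patience} epochs (off by default: the protocol trains a fixed
#'   number of epochs).
#' @param patience early-stopping patience in epochs.
#' @return list of class \code{"dti_train_config"}.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 64L,
                         epochs = 500L, folds = 5L, seed = 1L,
                         architecture_variant = MODEL_VARIANTS,
                         decision_threshold = 0.5,
                         pooled_metrics = FALSE,
                         early_stopping = FALSE, patience = 20L) {
  architecture_variant <- match.arg(architecture_variant)
  if (!is.numeric(learning_rate) || learning_rate <= 0)
    stop2("learning_rate must be positive")
  if (!is_count(batch_size)) stop2("batch_size must be a positive integer")
  if (!is_count(epochs, min = 0L)) stop2("epochs must be a non-negative integer")
  if (!is_count(folds, min = 2L)) stop2("folds must be an integer >= 2")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), folds = as.integer(folds),
                 seed = as.integer(seed),
                 architecture_variant = architecture_variant,
                 decision_threshold = decision_threshold,
                 pooled_metrics = isTRUE(pooled_metrics),
                 early_stopping = isTRUE(early_stopping),
                 patience = as.integer(patience)),
            class = "dti_train_config")
}

run_config_defaults <- function() {
  c(unclass(model_config()), unclass(train_config()),
    list(pairs = NULL, ligands = NULL, proteins = NULL, affinity = NULL,
         value_scale = "kd_nM", checkpoint = NULL, out_dir = ".",
         n_pairs = 2000L, label_noise = 0, small = FALSE))
}

#' Resolve a run configuration from defaults, a file and overrides
#'
#' Precedence: command-line style overrides > configuration file >
#' defaults.  Unknown keys are rejected with a nearest-match suggestion.
#' The resolved configuration carries a provenance block (content hash,
#' package version) and is serialized next to run outputs so any run can
#' be replayed exactly.
#'
#' @param file optional YAML configuration file.
#' @param overrides named list (or \code{"key=value"} strings) of
#'   overrides.
#' @return list of class \code{"dti_run_config"}.
#' @export
resolve_config <- function(file = NULL, overrides = list()) {
  defaults <- run_config_defaults()
  known <- names(defaults)
  if (is.character(overrides))
    overrides <- parse_key_values(overrides)
  from_file <- if (!is.null(file)) {
    if (!file.exists(file)) stop2("config file not found: ", file)
    yaml::read_yaml(file)
  } else list()
  check_keys <- function(keys, where) {
    bad <- setdiff(keys, known)
    if (length(bad)) {
      hints <- vapply(bad, function(k) {
        d <- utils::adist(k, known)
        known[which.min(d)]
      }, character(1))
      stop2("unknown config key(s) in ", where, ": ",
            paste0(bad, " (did you mean '", hints, "'?)", collapse = ", "))
    }
  }
  check_keys(names(from_file), "file")
  check_keys(names(overrides), "overrides")
  cfg <- defaults
  cfg[names(from_file)] <- from_file
  cfg[names(overrides)] <- overrides
  for (k in known) {
    tmpl <- defaults[[k]]
    if (!is.null(tmpl) && !is.null(cfg[[k]])) {
      if (is.numeric(tmpl) && !is.numeric(cfg[[k]]))
        cfg[[k]] <- suppressWarnings(as.numeric(cfg[[k]]))
      if (is.numeric(tmpl) && anyNA(cfg[[k]]))
        stop2("config key '", k, "' must be numeric")
      if (is.logical(tmpl)) cfg[[k]] <- as.logical(cfg[[k]])
      if (is.integer(tmpl) && is.numeric(cfg[[k]]))
        cfg[[k]] <- as.integer(cfg[[k]])
    }
  }
  if (!(cfg$architecture_variant %in% MODEL_VARIANTS))
    stop2("architecture_variant must be one of: ",
          paste(MODEL_VARIANTS, collapse = ", "))
  cfg$provenance <- list(config_hash = config_hash(cfg),
                         package_version =
                           as.character(utils::packageVersion("mcfdti")))
  structure(cfg, class = "dti_run_config")
}

parse_key_values <- function(kv) {
  kv <- kv[nzchar(kv)]
  parts <- regmatches(kv, regexpr("=", kv), invert = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) stop2("overrides must look like key=value: ",
                      paste(kv[bad], collapse = ", "))
  out <- lapply(parts, function(p) {
    v <- p[[2]]
    if (grepl(",", v, fixed = TRUE)) v <- strsplit(v, ",", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(v))
    if (!anyNA(num)) num
    else if (all(tolower(v) %in% c("true", "false"))) as.logical(v)
    else v
  })
  names(out) <- vapply(parts, `[[`, character(1), 1L)
  out
}

config_hash <- function(cfg) {
  cfg$provenance <- NULL
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                              null = "null"), tf)
  unname(tools::md5sum(tf))
}

split_run_config <- function(cfg) {
  mk <- names(formals(model_config))
  tk <- names(formals(train_config))
  list(model = do.call(model_config, cfg[intersect(names(cfg), mk)]),
       train = do.call(train_config, cfg[intersect(names(cfg), tk)]))
}
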