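#' Extract the lag-zero block of a Wiener-filtered embedded signal
#'
#' The filter output lives in the embedded (multi-lag) space; the rows
#' corresponding to lag zero are the enhanced versions of the original
#' channels and are the ones tensorized downstream.
#'
#' @param filtered output of [apply_mwf()] (embedded-dim x samples).
#' @param emb the [embedded_eeg()] the filter was applied to.
#' @return Im x samples matrix.
#' @export
filtered_channels <- function(filtered, emb) {
  stopifnot(inherits(emb, "embedded_eeg"))
  rows <- emb$tau * emb$im + seq_len(emb$im)
  filtered[rows, , drop = FALSE]
}

#' Run the full sCMTF pipeline
#'
#' Executes all stages end to end: Wiener-filter enhancement of the EEG and
#' extraction of the broadband reference envelope; tensorization (skipped
#' when a precomputed spectrogram tensor is supplied); coupled
#' factorization over a list of candidate ranks; model selection;
#' statistical nonparametric mapping of the selected solution's spatial
#' signatures; and HRF variability metrics with optional zone enrichment.
#' A single `seed` deterministically spawns per-stage seeds, so the whole
#' run is reproducible.
#'
#' @param data a `scmtf_synth` object, or a list with elements `eeg`
#'   (an [eeg_recording()]), `Y` (`bold_matrix`), and optionally `X`
#'   (`spectrogram_tensor`; when absent the tensor is computed from the
#'   enhanced EEG).
#' @param ranks candidate source counts (default `1:3`).
#' @param K,Q HRF basis size and nuisance rank (defaults 2 and 1).
#' @param n_inits restarts per rank (default 3; the study-scale default of
#'   the optimizer itself is 50, see [scmtf_config()]).
#' @param max_iter L-BFGS iteration cap per restart.
#' @param L number of surrogates for inference (default 250).
#' @param alpha familywise error level (default 0.05).
#' @param k_top number of top ROIs inspected per HRF metric (default 20).
#' @param tau Wiener-filter embedding lags (default 4).
#' @param fmax spectrogram upper frequency (default: 40 Hz or what the
#'   sampling rate allows).
#' @param zone_mask optional logical ROI mask for enrichment (taken from
#'   synthetic ground truth when `data` is a `scmtf_synth`).
#' @param seed master seed (default 1).
#' @return object of class `scmtf_report`: selected rank and solution, IED
#'   component, model-selection score table, `snpm_result`,
#'   `hrf_variability_map`, mask summaries and per-stage seeds.
#' @export
run_pipeline <- function(data, ranks = 1:3, K = 2, Q = 1, n_inits = 3,
                         max_iter = 300, L = 250, alpha = 0.05, k_top = 20,
                         tau = 4, fmax = NULL, zone_mask = NULL, seed = 1) {
  stopifnot(is.list(data), !is.null(data$eeg), !is.null(data$Y))
  set.seed(seed)
  stage_seeds <- sample.int(.Machine$integer.max %/% 2L, 4L)
  if (inherits(data, "scmtf_synth") && is.null(zone_mask)) {
    zone_mask <- data$truth$zone_mask
  }
  rec <- data$eeg
  enh <- enhance_eeg(rec, tau = tau)
  s_ref <- enh$envelope
  if (!is.null(data$X)) {
    X <- data$X
  } else {
    if (is.null(fmax)) fmax <- min(40, floor(rec$fs / 2) - 1)
    mt <- multitaper_spectrogram(filtered_channels(enh$filtered, enh$emb),
                                 rec$fs, rec$tr, fmax = fmax)
    X <- normalize_spectrogram(mt)
  }
  Yv <- if (inherits(data$Y, "bold_matrix")) data$Y$values else
    as.matrix(data$Y)
  Is <- min(dim(if (inherits(X, "spectrogram_tensor")) X$values else X)[1L],
            nrow(Yv), length(s_ref))
  Xv <- (if (inherits(X, "spectrogram_tensor")) X$values else
    X)[seq_len(Is), , , drop = FALSE]
  Yv <- Yv[seq_len(Is), , drop = FALSE]
  s_ref <- s_ref[seq_len(Is)]
  tr <- if (inherits(data$Y, "bold_matrix")) data$Y$tr else rec$tr

  fits <- lapply(ranks, function(r) {
    fit_scmtf(Xv, Yv,
              scmtf_config(R = r, K = K, Q = Q, n_inits = n_inits,
                           max_iter = max_iter,
                           seed = (stage_seeds[2L] + r) %%
                             (.Machine$integer.max %/% 2L)),
              tr = tr)
  })
  sel <- select_model(fits, s_ref)
  snpm <- build_snpm(sel$solution, Yv, L = L, alpha = alpha,
                     seed = stage_seeds[3L])
  hrfv <- hrf_variability(roi_hrfs(sel$solution), k = k_top,
                          zone_mask = zone_mask)
  mask_summary <- tibble::tibble(
    source = seq_len(nrow(snpm$t)),
    n_activated = rowSums(snpm$act_mask),
    n_deactivated = rowSums(snpm$deact_mask))
  structure(list(
    selected_R = sel$R, ied = sel$ied, scores = sel$scores,
    solution = sel$solution, snpm = snpm, hrf_variability = hrfv,
    mask_summary = mask_summary, envelope = s_ref,
    zone_mask = zone_mask, seed = seed, stage_seeds = stage_seeds),
    class = "scmtf_report")
}

#' Re-expand per-ROI values to a voxel map
#'
#' Broadcasts a value per atlas label back to the voxel grid. Voxels whose
#' label is absent from `roi_ids` (dropped parcels) and background voxels
#' receive `missing`. When `file` is given and the RNifti package is
#' available, the map is also written as NIfTI (using `reference` for the
#' header/affine when supplied).
#'
#' @param values numeric vector, one value per entry of `roi_ids`.
#' @param atlas 3-D integer label array.
#' @param roi_ids atlas labels corresponding to `values`.
#' @param missing fill value for unlabeled/dropped voxels (default `NA`).
#' @param file optional output path (`.nii`/`.nii.gz`).
#' @param reference optional NIfTI image or header to copy geometry from.
#' @return the voxel array (invisibly when written to file).
#' @export
export_maps <- function(values, atlas, roi_ids, missing = NA_real_,
                        file = NULL, reference = NULL) {
  stopifnot(length(values) == length(roi_ids))
  out <- array(missing, dim(atlas))
  for (i in seq_along(roi_ids)) {
    out[atlas == roi_ids[i]] <- values[i]
  }
  if (!is.null(file)) {
    if (!requireNamespace("RNifti", quietly = TRUE)) {
      stop("writing NIfTI requires the RNifti package")
    }
    img <- if (!is.null(reference)) {
      RNifti::asNifti(out, reference = reference)
    } else {
      RNifti::asNifti(out)
    }
    RNifti::writeNifti(img, file)
    return(invisible(out))
  }
  out
}

#' Integer label map of an SnPM result for one source
#'
#' Encodes, per ROI, 0 = not significant, 1 = activation, 2 = deactivation.
#'
#' @param snpm an `snpm_result`.
#' @param source source index.
#' @return integer vector of length Iv.
#' @export
snpm_label_map <- function(snpm, source = 1) {
  lab <- integer(ncol(snpm$t))
  lab[snpm$act_mask[source, ]] <- 1L
  lab[snpm$deact_mask[source, ]] <- 2L
  lab
}
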