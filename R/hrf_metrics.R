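#' HRF extremity per ROI
#'
#' Extremity of a region's HRF is one minus the mean absolute correlation
#' between its waveform and every other region's waveform: 0 when all HRFs
#' are identical (up to sign and scale), approaching 1 for a waveform
#' orthogonal to all others. Constant waveforms get extremity 1 with a
#' warning.
#'
#' @param hrfs Iv x n_lags matrix of per-ROI HRF waveforms (see
#'   [roi_hrfs()]).
#' @return numeric Iv-vector in `[0, 1]`.
#' @export
hrf_extremity <- function(hrfs) {
  hrfs <- as.matrix(hrfs)
  Iv <- nrow(hrfs)
  if (Iv < 2L) stop("need at least two ROIs")
  sds <- apply(hrfs, 1, stats::sd)
  const <- sds < .Machine$double.eps
  if (any(const)) {
    warning(sum(const), " constant waveform(s): extremity set to 1")
  }
  C <- matrix(0, Iv, Iv)
  ok <- which(!const)
  if (length(ok) >= 2L) {
    C[ok, ok] <- abs(stats::cor(t(hrfs[ok, , drop = FALSE])))
  }
  diag(C) <- 0
  e <- 1 - rowSums(C) / (Iv - 1L)
  e[const] <- 1
  pmin(pmax(e, 0), 1)
}

# canonical per-waveform sign (flip-invariant): main lobe positive, then
# align to the pointwise median of the canonicalized set
align_waveforms <- function(hrfs) {
  W <- as.matrix(hrfs)
  for (i in seq_len(nrow(W))) {
    pk <- W[i, which.max(abs(W[i, ]))]
    if (pk < 0) W[i, ] <- -W[i, ]
  }
  med <- apply(W, 2, stats::median)
  if (sum(med^2) > 0) {
    for (i in seq_len(nrow(W))) {
      if (sum(W[i, ] * med) < 0) W[i, ] <- -W[i, ]
    }
  }
  nrm <- sqrt(rowSums(W^2))
  nrm[nrm < .Machine$double.eps] <- 1
  W / nrm
}

#' HRF entropy per ROI
#'
#' Entropy of a region's HRF is the negative log of its conditional
#' probability given all other regions' HRFs: waveforms are sign-aligned
#' (each flipped so its main lobe is positive, then to agree with the
#' pointwise median -- a convention that makes the metric exactly immune to
#' any input polarity flip) and unit-normed, projected onto the leading
#' `p = min(5, Iv - 2)` principal axes of the whole set, and each ROI's
#' projection is evaluated under a ridge-regularized Gaussian fitted on the
#' other `Iv - 1` projections (leave-one-out mean and covariance). A
#' leave-one-out product-kernel density is available as an alternative
#' density model.
#'
#' @param hrfs Iv x n_lags matrix of per-ROI HRF waveforms.
#' @param n_components dimension of the PCA subspace (default
#'   `min(5, Iv - 2)`).
#' @param ridge ridge added to the leave-one-out covariance, as a fraction
#'   of `trace/p` (default 1e-3).
#' @param density `"gaussian"` (default) or `"kde"`.
#' @return numeric Iv-vector (nonnegative scale not guaranteed; higher =
#'   more deviant).
#' @export
hrf_entropy <- function(hrfs, n_components = NULL, ridge = 1e-3,
                        density = c("gaussian", "kde")) {
  density <- match.arg(density)
  W <- align_waveforms(hrfs)
  Iv <- nrow(W)
  if (is.null(n_components)) n_components <- min(5L, Iv - 2L)
  p <- max(1L, min(n_components, Iv - 2L, ncol(W)))
  if (Iv <= p + 1L) stop("need more ROIs than the reduced dimension + 1")
  Wc <- sweep(W, 2, colMeans(W), "-")
  sv <- svd(Wc, nu = 0, nv = p)
  Tm <- Wc %*% sv$v                                    # Iv x p scores
  ent <- numeric(Iv)
  for (iv in seq_len(Iv)) {
    Zo <- Tm[-iv, , drop = FALSE]
    mu <- colMeans(Zo)
    if (density == "gaussian") {
      S <- stats::cov(Zo)
      lam <- ridge * max(sum(diag(S)) / p, .Machine$double.eps)
      S <- S + diag(lam, p)
      ch <- tryCatch(chol(S), error = function(e) {
        stop("singular covariance despite ridge regularization")
      })
      z <- backsolve(ch, Tm[iv, ] - mu, transpose = TRUE)
      ent[iv] <- 0.5 * sum(z^2) + sum(base::log(diag(ch))) +
        0.5 * p * base::log(2 * pi)
    } else {
      # leave-one-out product-kernel (Gaussian) density, Silverman bandwidth
      n <- nrow(Zo)
      bw <- apply(Zo, 2, stats::sd) * (4 / ((p + 2) * n))^(1 / (p + 4))
      bw <- pmax(bw, 1e-8)
      d2 <- sweep(Zo, 2, Tm[iv, ], "-")
      kern <- exp(-0.5 * rowSums(sweep(d2, 2, bw, "/")^2))
      dens <- mean(kern) / prod(bw * sqrt(2 * pi))
      ent[iv] <- -base::log(max(dens, .Machine$double.xmin))
    }
  }
  ent
}

#' Indices of the k largest values
#'
#' Descending order; ties broken by the lower index (logged via message).
#'
#' @param x numeric vector.
#' @param k number of indices (default 20).
#' @return integer vector of length `k`.
#' @export
top_k_indices <- function(x, k = 20) {
  stopifnot(k >= 1, k <= length(x))
  ord <- order(-x, seq_along(x))
  sel <- ord[seq_len(k)]
  if (k < length(x) && any(duplicated(x[ord][c(k, k + 1L)]))) {
    message("tie at rank ", k, " broken by lower index")
  }
  sel
}

#' Binomial enrichment of top-ranked ROIs in a candidate zone
#'
#' Exact upper-tail binomial probability that at least `k_hits` of
#' `k_total` randomly sampled ROIs fall inside a zone covering
#' `zone_fraction` of the brain:
#' `P(Bin(k_total, zone_fraction) >= k_hits)`.
#'
#' @param k_hits number of top-ranked ROIs inside the zone.
#' @param k_total number of top-ranked ROIs inspected (default 20).
#' @param zone_fraction fraction of ROIs covered by the zone, in (0, 1).
#' @return p-value.
#' @export
binomial_enrichment <- function(k_hits, k_total, zone_fraction) {
  stopifnot(k_hits >= 0, k_hits <= k_total)
  if (!(zone_fraction > 0 && zone_fraction < 1)) {
    stop("zone_fraction must lie strictly between 0 and 1")
  }
  stats::pbinom(k_hits - 1, k_total, zone_fraction, lower.tail = FALSE)
}

#' Per-ROI HRF variability map
#'
#' Computes both deviance metrics ([hrf_extremity()] and [hrf_entropy()])
#' and flags the top-k ROIs under each; optionally scores the enrichment of
#' each top-k set against a candidate (e.g. ictal-onset) zone mask with an
#' exact binomial test, using the mask's ROI fraction as the chance level.
#'
#' @param hrfs Iv x n_lags matrix of per-ROI HRF waveforms.
#' @param k number of top ROIs to flag (default 20, capped at Iv).
#' @param zone_mask optional logical Iv-vector.
#' @param roi_ids optional parcel identifiers.
#' @param ... passed to [hrf_entropy()].
#' @return object of class `hrf_variability_map`: list with `table`
#'   (tibble: roi, extremity, entropy, top-k flags, zone flag), `top_k`
#'   (index lists), `enrichment` (tibble of binomial p-values, when a mask
#'   is given), `k`.
#' @export
hrf_variability <- function(hrfs, k = 20, zone_mask = NULL, roi_ids = NULL,
                            ...) {
  hrfs <- as.matrix(hrfs)
  Iv <- nrow(hrfs)
  k <- min(k, Iv)
  if (is.null(roi_ids)) roi_ids <- seq_len(Iv)
  ext <- hrf_extremity(hrfs)
  ent <- hrf_entropy(hrfs, ...)
  tk <- list(extremity = top_k_indices(ext, k),
             entropy = top_k_indices(ent, k))
  tab <- tibble::tibble(
    roi = roi_ids, extremity = ext, entropy = ent,
    top_extremity = seq_len(Iv) %in% tk$extremity,
    top_entropy = seq_len(Iv) %in% tk$entropy)
  enrich <- NULL
  if (!is.null(zone_mask)) {
    stopifnot(length(zone_mask) == Iv)
    tab$in_zone <- as.logical(zone_mask)
    frac <- mean(zone_mask)
    hits <- c(sum(zone_mask[tk$extremity]), sum(zone_mask[tk$entropy]))
    pvals <- vapply(hits, binomial_enrichment, numeric(1), k_total = k,
                    zone_fraction = frac)
    enrich <- tibble::tibble(
      metric = c("extremity", "entropy"),
      hits = hits, k = k, zone_fraction = frac, p_value = pvals)
  }
  structure(list(table = tab, top_k = tk, enrichment = enrich, k = k),
            class = "hrf_variability_map")
}
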