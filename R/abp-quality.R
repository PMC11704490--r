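#' Normalize an ABP pulse for subspace scoring
#'
#' Spline-resamples the pulse to `P` points and standardizes it to zero mean
#' and unit standard deviation, the same normalization applied to the
#' reference library.
#'
#' @param pulse numeric samples of one pulse (onset to onset).
#' @param P target length (default 100).
#' @return Numeric vector of length `P`.
#' @export
normalizePulse <- function(pulse, P = 100) {
  if (length(pulse) < 3)
    stopWith("autonomiq_input_error", "pulse shorter than 3 samples")
  y <- stats::spline(x = seq_along(pulse), y = pulse, n = P)$y
  s <- stats::sd(y)
  if (s == 0) return(rep(0, P))
  (y - mean(y)) / s
}

#' Fit an SVD signal-subspace model from a reference pulse library
#'
#' All reference pulses are normalized ([normalizePulse()]), stacked into a
#' matrix and decomposed by SVD. The signal subspace is spanned by the leading
#' right-singular directions capturing at least `energyFraction` of the total
#' energy; the noise subspace is its orthogonal complement. The acceptance
#' threshold `tau` is the minimum signal-to-noise energy ratio over the
#' reference pulses themselves, so every library pulse is valid by
#' construction.
#'
#' @param pulses list of numeric pulse vectors (a reference library).
#' @param P resample length (default 100).
#' @param energyFraction energy captured by the signal subspace (default 0.95).
#' @return An [AbpSubspaceModel-class].
#' @seealso [scoreAbpPulse()], [syntheticAbpLibrary()]
#' @export
fitAbpSubspace <- function(pulses, P = 100, energyFraction = 0.95) {
  X <- t(vapply(pulses, normalizePulse, numeric(P), P = P))
  sv <- svd(X)
  energy <- cumsum(sv$d^2) / sum(sv$d^2)
  k <- which(energy >= energyFraction)[1]
  if (k >= P)
    stopWith("autonomiq_input_error", "signal subspace spans the full space")
  basis <- sv$v[, seq_len(k), drop = FALSE]
  model <- methods::new("AbpSubspaceModel", basis = basis, P = P, k = k,
                        tau = 1, energyFraction = energyFraction)
  ratios <- vapply(pulses, function(p) scoreAbpPulse(p, model)$ratio,
                   numeric(1))
  model@tau <- min(ratios)
  methods::validObject(model)
  model
}

#' Score an ABP pulse against the signal-subspace model
#'
#' The pulse is normalized identically to the reference library and projected
#' onto the signal subspace; the score is the ratio of projected-signal energy
#' to residual (noise) energy. The pulse is valid when the ratio reaches the
#' model threshold `tau`. A pulse lying exactly in the signal subspace (zero
#' residual) receives a large sentinel ratio and is valid.
#'
#' @param pulse numeric samples of one pulse.
#' @param model an [AbpSubspaceModel-class].
#' @return List with `ratio` and `valid`.
#' @export
scoreAbpPulse <- function(pulse, model) {
  x <- normalizePulse(pulse, model@P)
  if (all(x == 0))          # flat pulse carries no pulsatile signal
    return(list(ratio = 0, valid = FALSE))
  proj <- model@basis %*% crossprod(model@basis, x)
  eSig <- sum(proj^2)
  eNoise <- sum((x - proj)^2)
  ratio <- if (eNoise < 1e-12 * max(eSig, 1)) 1e12 else eSig / eNoise
  list(ratio = ratio, valid = ratio >= model@tau)
}

setMethod("show", "AbpSubspaceModel", function(object) {
  cat(sprintf(
    "AbpSubspaceModel: P=%d, rank k=%d (%.0f%% energy), tau=%.3g\n",
    object@P, object@k, 100 * object@energyFraction, object@tau))
})

#' Synthetic reference library of arterial pressure pulses
#'
#' Generates expert-shaped synthetic ABP pulses (steep systolic upstroke,
#' exponential diastolic decay, dicrotic notch) with controlled variation in
#' timing, amplitude and heart period. This is a synthetic stand-in reference
#' library for the pulse-validation model; any user-supplied library of pulse
#' vectors can be used in its place through [fitAbpSubspace()].
#'
#' @param n number of pulses (default 120).
#' @param seed RNG seed.
#' @return List of numeric pulse vectors.
#' @export
syntheticAbpLibrary <- function(n = 120, seed = 20, fs = 125) {
  pulses <- list()
  rr0 <- c(700, 850, 1000, 1150)
  for (s in seq_along(rr0)) {
    spec <- subjectSpec(rr0Ms = rr0[s], jitterSdMs = 15, nBeats = 45,
                        sbpProcess = "walk", brsGain = 0,
                        sbp0 = 100 + 15 * s, seed = seed + s)
    tach <- genCoupledSbp(genTachogram(spec), spec)
    wf <- renderWaveforms(tach, fsEcg = fs, nLeads = 1)
    abp <- channelSignal(wf$record, "ABP")
    peaks <- detectSystolicPeaks(abp, fs)
    onsets <- detectPulseOnsets(abp, fs, peaks)
    pulses <- c(pulses, Filter(function(p) length(p) >= 10,
                               splitPulses(abp, fs, onsets)))
  }
  set.seed(seed)
  pulses <- lapply(pulses, function(p) p + stats::rnorm(length(p), sd = 0.15))
  if (length(pulses) > n) pulses <- pulses[sample(length(pulses), n)]
  pulses
}
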