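# Shared fixture builders. Everything is generated in code under fixed seeds;
# waveform fixtures are kept short (tens of seconds to minutes) so the whole
# suite stays fast.

# flat tachogram with k injected PVCs and full pre/post context
pvcTachogram <- function(k, nBeats = 4300, rr0 = 850, jitter = 0, seed = 1,
                         slope = 8, coupling = 0.6) {
  spec <- subjectSpec(rr0Ms = rr0, lfAmpMs = 0, hfAmpMs = 0,
                      jitterSdMs = jitter, nBeats = nBeats, pvcCount = k,
                      couplingFraction = coupling, slopeMsPerBeat = slope,
                      seed = seed)
  injectPvc(genTachogram(spec), spec)
}

# beat series with one PVC and a controlled number of post-compensatory
# sinus intervals (constructed directly, not via the generator)
singlePvcBeats <- function(mPost, rr = 0.8, coupling = 0.6) {
  pre <- cumsum(rep(rr, 4))                       # 3 sinus RR before the PVC
  pvc <- pre[4] + coupling * rr
  comp <- pvc + (2 - coupling) * rr
  post <- comp + cumsum(rep(rr, mPost))           # mPost sinus RR after compI
  beatSeries(c(pre, pvc, comp, post),
             labels = c(rep("N", 4), "V", rep("N", mPost + 1)))
}

# small rendered record with optional PVCs and coupled sBP
renderedFixture <- function(nBeats = 120, pvcCount = 0, seed = 1, fs = 125,
                            nLeads = 2, jitter = 4) {
  spec <- subjectSpec(nBeats = nBeats, pvcCount = pvcCount,
                      jitterSdMs = jitter, seed = seed)
  tach <- genCoupledSbp(genTachogram(spec), spec)
  if (pvcCount > 0) tach <- injectPvc(tach, spec)
  c(renderWaveforms(tach, fsEcg = fs, nLeads = nLeads), list(tach = tach))
}

# quality-gate libraries are expensive enough to share across tests
qualityLibs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- defaultQualityLibraries(seed = 1)
    cache
  }
})
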