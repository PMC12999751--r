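# Shared fixtures, computed lazily and memoized for the session so expensive
# objects (trained models, benchmark runs) are built once.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# a small labeled library and a model trained on it (shared by gnn and
# attribution tests)
small_sar <- function() fixture("small_sar", function() {
  generateSarDataset(sarSimParams(n_compounds = 80, label_noise = 0,
                                  seed = 101))
})

small_model <- function() fixture("small_model", function() {
  sar <- small_sar()
  ds <- suppressWarnings(assembleDataset(sar, augment = FALSE))
  plan <- makeGroupSplits(ds, nRepeats = 1, seed = 102)
  model <- trainGat(buildGatModel(benchmarkConfig(seed = 103)), ds,
                    assignments(plan, 1))
  list(sar = sar, dataset = ds, plan = plan, model = model)
})

# assay table in the near-linear (pre-saturation) regime: inhibitor added at
# the logistic inflection so increments track the rate multiplier closely
linear_regime_assay <- function(f, noise_sd = 0, seed = 1) {
  simulateCulture(cultureSimParams(
    noise_sd = noise_sd, inhibition_fraction = f, addition_time = 114,
    timepoints = seq(0, 126, by = 6), seed = seed))
}

aoi_from_assay <- function(assay, control = "DMSO") {
  computeAoi(assay[assay$treatment != control, ],
             assay[assay$treatment == control, ])
}

# hand-built three-timepoint assay frames for exact AOI identities
tiny_series <- function(values, treatment, addition = 10, reps = 3) {
  do.call(rbind, lapply(seq_len(reps), function(r) {
    data.frame(strain = "AOA_x", treatment = treatment, dose_mg_per_L = 20,
               replicate = r, time_h = c(0, 10, 20), nitrite_uM = values,
               addition_time_h = addition)
  }))
}
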