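# The 200-kb study-condition pipeline is used by several acceptance blocks
# (threshold calibration, detection scoring, and the guanine threshold the
# SNV analysis inherits).  Run it once per session and cache the pieces.
.study_cache <- new.env(parent = emptyenv())

study_run <- function(seed = 20260924) {
  key <- paste0("s", seed)
  if (!is.null(.study_cache[[key]])) return(.study_cache[[key]])
  cfg <- sim_config(seed = seed)
  sim <- sim_genome(cfg)
  sam <- tempfile(fileext = ".sam")
  sim_reads(sim, cfg, sam)
  tracks <- build_tracks(sam)
  pg4 <- predict_pg4(sim$genome)
  regions <- calibration_regions(sim$genome, pg4)
  cal <- calibrate_scanner(tracks, regions)
  mg4 <- call_mg4(tracks, cal, sim$genome)
  out <- list(cfg = cfg, sim = sim, tracks = tracks, pg4 = pg4,
              regions = regions, cal = cal, mg4 = mg4)
  .study_cache[[key]] <- out
  out
}
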