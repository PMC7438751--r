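# Phantom volumes and their segmentations are moderately expensive;
# cache them per (preset, seed) within a test run.

.phantom_cache <- new.env(parent = emptyenv())

cached_phantom <- function(preset = "default", seed = 1L) {
  key <- paste(preset, seed, sep = "_")
  if (is.null(.phantom_cache[[key]]))
    .phantom_cache[[key]] <- generate_phantom(phantom_preset(preset, seed))
  .phantom_cache[[key]]
}

cached_skeleton <- function(preset = "default", seed = 1L) {
  key <- paste("skel", preset, seed, sep = "_")
  if (is.null(.phantom_cache[[key]])) {
    ph <- cached_phantom(preset, seed)
    seg <- segment_arch(ph$volume)
    .phantom_cache[[key]] <- prune_and_order(medial_axis(seg$mask))
  }
  .phantom_cache[[key]]
}
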