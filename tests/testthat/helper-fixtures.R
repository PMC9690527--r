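# Shared in-code fixtures: everything is generated at test time.

# an asymmetric matrix: all 8 dihedral copies are pairwise distinct
asym_matrix <- function(h = 4L, w = 4L) {
  matrix(as.numeric(seq_len(h * w)), h, w)
}

# deterministic tiny phantom batch at 64x64, preprocessed to model size
make_probe_set <- function(n, offset = 0L, seed = 101L, size = 64L,
                           preset = "easy") {
  pp <- phantom_params(image_size = size, seed = seed, preset = preset)
  pcfg <- preprocess_config(target_size = c(size, size))
  lapply(seq_len(n), function(i) {
    ph <- generate_phantom(pp, index = offset + i)
    s <- preprocess_sample(ph$image, ph$mask, pcfg)
    list(image = s$image, mask = s$mask)
  })
}

# a very small network for fast structural tests (16x16 input)
micro_model <- function(seed = 3L) {
  build_acrnet(acrnet_config(input_size = c(16L, 16L),
                             stage_widths = c(4L, 8L),
                             units_per_stage = 1L,
                             condenser_ratio = 2L, seed = seed))
}

random_mask <- function(h, w, p = 0.5) {
  binary_mask(matrix(stats::runif(h * w) < p, h, w))
}
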