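# small in-code fixtures shared across test files

# a raw ATAC dataset from an explicit matrix
make_atac <- function(x, labels = NULL, peaks = NULL) {
  if (is.null(peaks)) {
    peaks <- sprintf("chr1:%d-%d", (seq_len(ncol(x)) - 1L) * 100L,
                     (seq_len(ncol(x)) - 1L) * 100L + 50L)
  }
  raw_dataset(x, peaks, sprintf("c%03d", seq_len(nrow(x))), labels, "atac")
}

# a tiny trained-shape model with reproducible random weights
make_model <- function(m = 12, K = 3, L = 4, widths = c(8L, 5L),
                       modality = "atac", seed = 11) {
  cfg <- model_config(m, K, modality, encoder_widths = widths,
                      embedding_dim = L, labels = paste0("C", seq_len(K)))
  init_model(cfg, seed = seed)
}

# small aligned processed source/target pair for trainer tests
tiny_pair <- function(seed = 5, n = 60, n_peaks = 80, K = 2) {
  cfg <- synth_config(n_source = n, n_target = n, n_peaks = n_peaks,
                      n_known_types = K, n_unknown_types = 1L,
                      marker_peaks_per_type = 10L, seed = seed)
  pair <- generate_atac(cfg)
  pp <- preprocess_pair(pair$source, pair$target, n_features = n_peaks)
  list(pp = pp, pair = pair)
}

expect_matrix_equal <- function(a, b, tol = 1e-12) {
  expect_equal(as.matrix(a), as.matrix(b), tolerance = tol,
               ignore_attr = TRUE)
}
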