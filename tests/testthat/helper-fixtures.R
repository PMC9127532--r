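# small in-code fixtures shared across test files

# cluster from 0-based (row, col) pairs given as a two-column matrix
mk_cluster <- function(image, coords, id = 1L) {
  pixel_cluster(id, matrix(coords, ncol = 2L, byrow = FALSE), image)
}

# flat image of one gray value
flat_image <- function(n, value = 128L) gray_image(matrix(as.integer(value), n, n))

# oracle segmentation of a noiseless two-level phantom: intensity threshold
oracle_mask <- function(image, cut = 125) unclass(image) > cut

# fast engine settings for small CLI/pipeline tests
small_engine <- function(seed = 1L, ...) {
  qwpso_config(qpso = qpso_params(swarm_size = 40L, max_iter = 60L),
               seed = seed, ...)
}
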