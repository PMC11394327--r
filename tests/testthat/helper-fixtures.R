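# Shared fixtures and small independent oracles used across the suite.

# A paired lesion-texture sample degraded with random diagonal lines,
# sized for desk-scale runs.
make_fixture_pair <- function(i, size = c(16L, 16L), n_lines = 6L,
                              length_range = c(3L, 7L), seed_offset = 0L) {
  clean <- make_lesion_texture(seed_offset + i, size)
  hairy <- synth_line_hair(clean, n_lines = n_lines,
                           seed = seed_offset + 1000L + i,
                           length_range = length_range)
  paired_sample(hairy, clean, LESION_CLASSES[(i %% 7L) + 1L], paste0("s", i))
}

# Tiny random paired sample (uniform noise images) for training-path
# tests where image content does not matter.
make_noise_pair <- function(i, H = 8L, W = 8L) {
  set.seed(5000L + i)
  clean <- matrix(runif(H * W), H, W)
  hairy <- matrix(runif(H * W), H, W)
  paired_sample(hairy, clean, "mel", paste0("n", i))
}

tiny_denoiser_cfg <- function() {
  denoiser_config(base_channels = 4L, channel_mults = c(1L, 2L),
                  time_embed_dim = 8L)
}

# Independent connected-component counter (8-connectivity, BFS) for
# binary masks; used as the oracle for the strand-count contract.
count_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  n <- 0L
  for (r0 in seq_len(H)) for (c0 in seq_len(W)) {
    if (mask[r0, c0] == 1 && !seen[r0, c0]) {
      n <- n + 1L
      queue <- list(c(r0, c0)); seen[r0, c0] <- TRUE
      while (length(queue)) {
        p <- queue[[1L]]; queue <- queue[-1L]
        for (dr in -1:1) for (dc in -1:1) {
          r <- p[1L] + dr; c_ <- p[2L] + dc
          if (r >= 1 && r <= H && c_ >= 1 && c_ <= W &&
              mask[r, c_] == 1 && !seen[r, c_]) {
            seen[r, c_] <- TRUE
            queue[[length(queue) + 1L]] <- c(r, c_)
          }
        }
      }
    }
  }
  n
}
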