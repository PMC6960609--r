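# Shared fixtures, built in code at test time.

# Smooth random texture in [0.1, 0.9]: white noise blurred a couple of times.
smooth_texture <- function(size = 64, seed = 7) {
  set.seed(seed)
  tex <- matrix(rnorm(size * size), size, size)
  for (i in 1:2) tex <- cmer:::blur_binomial5(tex)
  0.5 + 0.4 * tex / max(abs(tex))
}

# Circular horizontal shift of a matrix by s columns (integer).
cshift <- function(m, s) {
  n <- ncol(m)
  s <- ((s - 1) %% n) + 1
  m[, c((n - s + 1):n, seq_len(n - s))]
}

# Central crop (drops a border fraction).
central <- function(m, frac = 0.125) {
  h <- nrow(m); w <- ncol(m)
  m[ceiling(h * frac):floor(h * (1 - frac)),
    ceiling(w * frac):floor(w * (1 - frac))]
}

# Frame-difference energy relative to the first frame: the brute-force
# apex oracle.
frame_diff_energy <- function(seq) {
  f1 <- get_frame(seq, 1)
  vapply(seq_len(n_frames(seq)),
         function(t) sum((get_frame(seq, t) - f1)^2), numeric(1))
}

# A sequence of a static face with rendered impulse events at given frames.
impulse_sequence <- function(event_frames, T = 35, amplitude = 1.5, seed = 11) {
  neutral <- render_face(NULL, 0, texture_seed = seed)
  moved <- render_face(au_activation(c(1, 2, 5), amplitude), 1,
                       texture_seed = seed)
  frames <- array(0, c(T, 96, 96, 1))
  for (t in seq_len(T)) {
    frames[t, , , 1] <- if (t %in% event_frames) moved else neutral
  }
  frame_sequence(frames, fps = 30)
}
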