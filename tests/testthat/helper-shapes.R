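# Shared landmark test fixtures: an asymmetric closed outline (no rotational
# symmetry, so Procrustes fits are unique) and a similarity transformer.
ref_shape <- function(k = 14) {
  t <- seq(0, 2 * pi, length.out = k + 1)[seq_len(k)]
  cbind(cos(t) * c(rep(1, k / 2), rep(1.6, k / 2)), sin(t))
}

rand_similarity <- function(x, theta, s, tr) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  sweep(s * (x %*% R), 2, tr, "+")
}
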