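# Frozen coefficient systems relating non-induced to induced quad orbit
# counts (noninduced = C %*% induced). Generated by
# derive_quad_coefficients(); the test suite regenerates them from the
# atlas and asserts equality. Do not edit by hand.

quad_coef_node_frozen <- function() {
  matrix(c(
    1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1,
    0, 1, 0, 1, 1, 2, 0, 2, 0, 1, 2, 3, 1, 1, 2, 3, 2, 2, 3, 3,
    0, 0, 1, 1, 1, 0, 2, 1, 3, 2, 1, 0, 2, 3, 2, 1, 2, 3, 2, 3,
    0, 0, 0, 1, 0, 0, 0, 0, 0, 1, 1, 0, 0, 1, 1, 1, 2, 2, 2, 3,
    0, 0, 0, 0, 1, 0, 0, 2, 0, 1, 1, 0, 2, 2, 3, 2, 2, 4, 4, 6,
    0, 0, 0, 0, 0, 1, 0, 1, 0, 0, 1, 3, 0, 0, 1, 3, 1, 1, 3, 3,
    0, 0, 0, 0, 0, 0, 1, 0, 3, 1, 0, 0, 1, 3, 1, 0, 1, 3, 1, 3,
    0, 0, 0, 0, 0, 0, 0, 1, 0, 0, 0, 0, 0, 0, 1, 1, 0, 1, 2, 3,
    0, 0, 0, 0, 0, 0, 0, 0, 1, 0, 0, 0, 0, 1, 0, 0, 0, 1, 0, 1,
    0, 0, 0, 0, 0, 0, 0, 0, 0, 1, 0, 0, 0, 2, 1, 0, 2, 4, 2, 6,
    0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 1, 0, 0, 0, 1, 2, 2, 2, 4, 6,
    0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 1, 0, 0, 0, 1, 0, 0, 1, 1,
    0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 1, 1, 1, 0, 0, 2, 1, 3,
    0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 1, 0, 0, 0, 2, 0, 3,
    0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 1, 0, 0, 2, 2, 6,
    0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 1, 0, 0, 2, 3,
    0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 1, 1, 1, 3,
    0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 1, 0, 3,
    0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 1, 3,
    0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 1
  ), nrow = 20, byrow = TRUE,
  dimnames = list(paste0("o", 0:19), paste0("o", 0:19)))
}

quad_coef_edge_frozen <- function() {
  matrix(c(
    1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1,
    0, 1, 0, 0, 1, 0, 0, 1, 0, 1, 1, 1, 0, 1,
    0, 0, 1, 2, 1, 2, 2, 2, 3, 2, 2, 3, 4, 4,
    0, 0, 0, 1, 0, 0, 0, 0, 1, 1, 0, 1, 2, 2,
    0, 0, 0, 0, 1, 0, 0, 2, 0, 2, 2, 3, 0, 4,
    0, 0, 0, 0, 0, 1, 0, 0, 1, 0, 1, 1, 2, 2,
    0, 0, 0, 0, 0, 0, 1, 1, 1, 0, 0, 1, 2, 2,
    0, 0, 0, 0, 0, 0, 0, 1, 0, 0, 0, 1, 0, 2,
    0, 0, 0, 0, 0, 0, 0, 0, 1, 0, 0, 1, 4, 4,
    0, 0, 0, 0, 0, 0, 0, 0, 0, 1, 0, 1, 0, 2,
    0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 1, 1, 0, 2,
    0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 1, 0, 4,
    0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 1, 1,
    0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 1
  ), nrow = 14, byrow = TRUE,
  dimnames = list(paste0("o", 0:13), paste0("o", 0:13)))
}

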