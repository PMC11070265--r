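# build a prob_maps object directly from a pixels x species matrix
manual_prob_maps <- function(P, nrow_, ncol_, mask = NULL) {
  if (is.null(colnames(P))) colnames(P) <- sprintf("sp%02d", seq_len(ncol(P)))
  probs <- lapply(seq_len(ncol(P)), function(j)
    matrix(P[, j], nrow_, ncol_, byrow = TRUE))
  names(probs) <- colnames(P)
  structure(list(probs = probs, pixel_size = 30, xll = 0, yll = 0,
                 mask = mask), class = "prob_maps")
}
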