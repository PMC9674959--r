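#' Derive a per-stage seed from a master seed
#'
#' A counter-based expansion of one master seed into independent
#' per-stage/per-iteration seeds, so adding a stage never perturbs the
#' randomness of earlier stages. Deterministic, and kept below 2^31 - 1.
#'
#' @param master master seed (integer).
#' @param stage stage or iteration counter (integer).
#' @return an integer seed.
#' @export
derive_seed <- function(master, stage) {
  m <- 2147483647
  as.integer((as.numeric(master) %% m * 69069 + as.numeric(stage) * 104729 +
                12345) %% m)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
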