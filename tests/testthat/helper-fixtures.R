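# Small in-code fixtures shared across test files.

# Write a generic-dialect peptide table and return its path.
write_generic_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Design TSV with n replicates per condition split over batches.
write_design_fixture <- function(n = 2L, n_batches = 1L,
                                 path = tempfile(fileext = ".tsv")) {
  batch <- paste0("b", rep(seq_len(n_batches), length.out = n))
  df <- data.frame(
    run_id = c(paste0("plus_r", seq_len(n)), paste0("minus_r", seq_len(n))),
    condition = rep(c("+4SU", "-4SU"), each = n),
    replicate = rep(seq_len(n), 2L),
    batch = rep(batch, 2L)
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Tiny 3-peptide / 2-run generic table used by several io tests.
tiny_table_df <- function() {
  data.frame(
    peptide = c("PEPTIDEK", "SEALEDCASEK", "MTAEPK"),
    protein = c("P46100", "P46100", "CON__K1"),
    r1 = c(2, 3, 5),
    r2 = c(1, 4, 5),
    check.names = FALSE
  )
}

# Minimal peptide table object built in memory (bypassing disk).
make_peptides <- function(df, runs) {
  attr(df, "runs") <- runs
  class(df) <- c("rbrid_peptides", "data.frame")
  df
}

# Minimal design object built in memory.
make_design <- function(n = 2L, n_batches = 1L) {
  rbrid::read_design(write_design_fixture(n, n_batches))
}

# Residue profile with a hand-set smoothed track, for segment-calling tests.
make_profile <- function(smoothed, coverage = rep(1, length(smoothed)),
                         raw = smoothed) {
  out <- data.frame(position = seq_along(smoothed), raw_score = raw,
                    coverage = coverage, smoothed_score = smoothed)
  class(out) <- c("rbrid_profile", "data.frame")
  out
}
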