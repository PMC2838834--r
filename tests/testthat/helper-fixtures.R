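# Shared fixture builders. Everything is generated in code; nothing binary.

spot_df <- function(array_id, spot_id, probe_id, gene_symbol, spot_kind,
                    sample_signal, reference_signal) {
  data.frame(array_id = array_id, spot_id = spot_id, probe_id = probe_id,
             gene_symbol = gene_symbol, spot_kind = spot_kind,
             sample_signal = sample_signal,
             reference_signal = reference_signal,
             stringsAsFactors = FALSE)
}

# minimal 1-array table: 3 regular spots + 1 negative control
tiny_spot_df <- function(array_id = "a1") {
  spot_df(array_id, paste0("s", 1:4), paste0("p", 1:4),
          c("GeneA", "GeneA", "GeneB", ""),
          c("regular", "regular", "regular", "negative_control"),
          c(10, 12, 100, 1.5), c(9, 11, 90, 1.4))
}

write_tiny_spot_file <- function(path, df = tiny_spot_df()) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

tiny_design <- function(n_per_group = 5L) {
  groups <- rep(c("SHAM", "LPS_PMN", "LPS_NOPMN"), each = n_per_group)
  as_study_design(data.frame(
    sample_id = paste(groups, rep(seq_len(n_per_group), 3L), sep = "_"),
    group = groups))
}

# small but non-pathological simulation (DE genes stay a minority so that
# normalization sees a mostly-null distribution, as on a real array)
small_config <- function(seed = 1L, ...) {
  default_config(n_genes = 800L, seed = seed, ...)
}

noise_free_config <- function(seed = 1L, n_genes = 2000L) {
  default_config(n_genes = n_genes, seed = seed,
                 spot_noise_sd = 0, array_shift_sd = 0,
                 reference_noise_sd = 0, animal_heterogeneity_sd = 0)
}

# independent permutation generator for the Spearman oracle: filters the
# full n^n grid down to permutations (fine for n <= 5), unlike the
# package's recursive constructor
all_perms_bruteforce <- function(n) {
  grid <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  grid[apply(grid, 1L, function(r) length(unique(r)) == n), , drop = FALSE]
}

fc_of <- function(ct, gene, contrast) {
  ct$fold_change[ct$gene_symbol == gene & ct$contrast == contrast]
}
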