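# Small in-code fixtures shared across test files.

make_counts <- function(n_otu = 3L, n_sample = 2L, seed = 42L,
                        max_count = 500L) {
  set.seed(seed)
  m <- matrix(sample.int(max_count, n_otu * n_sample, replace = TRUE),
              n_otu, n_sample,
              dimnames = list(sprintf("OTU%d", seq_len(n_otu)),
                              sprintf("S%d", seq_len(n_sample))))
  m
}

make_table <- function(n_otu = 3L, n_sample = 2L, seed = 42L) {
  otu_table(make_counts(n_otu, n_sample, seed),
            taxonomy = paste0("Bacteria; Phylum", seq_len(n_otu)))
}

# rel_abundance built straight from fractions (columns must sum to 1)
rel_from <- function(p, taxonomy = NULL) {
  p <- as.matrix(p)
  if (is.null(rownames(p))) rownames(p) <- sprintf("OTU%d", seq_len(nrow(p)))
  if (is.null(colnames(p))) colnames(p) <- sprintf("S%d", seq_len(ncol(p)))
  rel_abundance(p, taxonomy)
}

expI_cfg <- function(Cc = 10) reactor_config(150, 3, 2, Cf = 6.2, Cc = Cc)
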