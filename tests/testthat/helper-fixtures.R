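# shared builders and brute-force oracles

# all length-k count vectors summing to n (columns of the result)
compositions <- function(n, k) {
  if (k == 1) return(matrix(n, 1))
  out <- NULL
  for (x in 0:n) {
    sub <- compositions(n - x, k - 1)
    out <- cbind(out, rbind(x, sub))
  }
  unname(out)
}

toy_table <- function(counts, tag, cats = NULL, samples = NULL) {
  counts <- as.matrix(counts)
  cats <- cats %||% paste0("t", seq_len(nrow(counts)))
  samples <- samples %||% paste0("s", seq_len(ncol(counts)))
  count_table(counts, cats, samples, tag)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# small dataset with only MT-SC counts: theta posterior is conjugate Dirichlet
sc_only_dataset <- function(ysc = c(5L, 9L, 2L)) {
  tcr_dataset(mt_sc = toy_table(matrix(ysc), "MT-SC"))
}

# one-sample MT-MC-only dataset (single category unless given)
mc_only_dataset <- function(ymc, s, f) {
  ymc <- as.matrix(ymc)
  tcr_dataset(mt_mc = toy_table(ymc, "MT-MC"),
              meta = sample_meta(paste0("s", seq_len(ncol(ymc))), s, f))
}

# complete two-category toy dataset with every table present
tiny_full_dataset <- function() {
  tcr_dataset(
    wt_mc = toy_table(matrix(c(6L, 4L), 2), "WT-MC"),
    mt_mc = toy_table(matrix(c(3L, 2L), 2), "MT-MC"),
    wt_sc = toy_table(matrix(c(2L, 3L), 2), "WT-SC"),
    mt_sc = toy_table(matrix(c(1L, 4L), 2), "MT-SC"),
    meta = sample_meta("s1", s = 100, f = 0.05))
}
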