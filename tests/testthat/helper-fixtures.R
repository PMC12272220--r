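# shared fixtures, built in code at test time

toy_atlas <- function(np = 2, zones = c("primary", "limbic")) {
  make_synthetic_atlas(np, zones)
}

write_tmp_tsv <- function(df) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# z-scale FC matrix built entry-wise for hand-constructed cases
toy_z_matrix <- function(atlas, fill = 0) {
  p <- n_regions(atlas)
  labels <- names(sort(atlas$region_index))
  m <- matrix(fill, p, p, dimnames = list(labels, labels))
  diag(m) <- NaN
  m
}

as_z <- function(m) as_fc_matrix(m, "z")

# independent brute-force ICC(2,1) from two-way ANOVA fitted by aov()
icc21_aov <- function(m) {
  n <- nrow(m); k <- ncol(m)
  d <- data.frame(y = as.vector(m),
                  subj = factor(rep(seq_len(n), k)),
                  sess = factor(rep(seq_len(k), each = n)))
  tab <- summary(stats::aov(y ~ subj + sess, data = d))[[1]]
  msr <- tab["subj", "Mean Sq"]
  msc <- tab["sess", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}
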