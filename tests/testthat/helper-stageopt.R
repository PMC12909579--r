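# shared fixtures and independent oracles for the test suite

# a deliberately small L1 genotype so CNN-training tests stay fast
small_cnn_genotype <- function(epochs = 10, lr = 0.003) {
  c(learning_rate = lr, dropout = 0.05, epochs = epochs,
    n_conv_layers = 1, n_dense_layers = 1,
    conv1_width = 32, conv2_width = 32, dense1_width = 32, dense2_width = 32)
}

# a capable genotype for learnability floors
capable_cnn_genotype <- function(epochs = 12) {
  c(learning_rate = 0.003, dropout = 0.05, epochs = epochs,
    n_conv_layers = 2, n_dense_layers = 1,
    conv1_width = 48, conv2_width = 48, dense1_width = 64, dense2_width = 32)
}

tiny_image_set <- function(n_per_class = 30L, separability = 2, seed = 7L) {
  generate_images(synthetic_image_spec(n_per_class = rep(n_per_class, 4L),
                                       separability = separability,
                                       seed = seed))
}

# exact two-sided signed-rank p-value by enumeration of all 2^n sign vectors
# (no zeros/ties assumed); independent oracle for the Wilcoxon wrapper
wilcoxon_exact_enum <- function(x, y) {
  d <- x - y
  stopifnot(all(d != 0), !anyDuplicated(abs(d)))
  n <- length(d)
  rk <- rank(abs(d))
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vdist <- as.vector(signs %*% rk)          # V+ under H0 for every sign vector
  v <- sum(rk[d > 0])
  p_le <- mean(vdist <= v)
  p_ge <- mean(vdist >= v)
  min(1, 2 * min(p_le, p_ge))
}

# published per-class reference tables shipped with the package
reported_tables <- function() {
  path <- system.file("extdata", "reported_per_class_metrics.csv",
                      package = "stageopt")
  utils::read.csv(path, check.names = FALSE)
}

reported_row <- function(tbl, model, metric) {
  r <- tbl[tbl$model == model & tbl$metric == metric, ]
  as.numeric(r[1, c("class0", "class1", "class2", "class3")])
}
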