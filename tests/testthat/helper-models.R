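# Builders shared across test files; everything is generated in code.

# A PS+PI+DS model: means on the {0, d} grid, unit variances, zero
# correlations, orthogonal bounds through d/2.
ps_pi_ds_model <- function(d = 2, var = c(1, 1), rho = rep(0, 4)) {
  grt_model(list(gaussian2d(c(0, 0), var, rho[1]),
                 gaussian2d(c(d, 0), var, rho[2]),
                 gaussian2d(c(0, d), var, rho[3]),
                 gaussian2d(c(d, d), var, rho[4])),
            linear_bound(0, d / 2, "A"), linear_bound(0, d / 2, "B"))
}

face_example_csv <- function() {
  paste(
    "Stimulus,Happy/Male,Sad/Male,Happy/Female,Sad/Female",
    "Happy/Male,140,36,34,40",
    "Sad/Male,89,91,4,66",
    "Happy/Female,85,5,90,70",
    "Sad/Female,20,59,8,163",
    sep = "\n")
}

# Swap the roles of dimensions A and B in a confusion matrix: stimulus and
# response A_iB_j become A_jB_i, i.e. permute rows and columns by (1,3,2,4).
swap_dimensions <- function(cm) {
  p <- c(1, 3, 2, 4)
  grt_confusion_matrix(unclass(cm)[p, p])
}

# Brute-force two-sample KS statistic: max over all pooled points of the
# absolute ECDF difference.
brute_force_ks_d <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(t) mean(x <= t) - mean(y <= t), numeric(1))))
}
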