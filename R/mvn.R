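# multivariate-normal draws with a reusable covariance factor

# Factor A with A %*% z ~ MVN(0, V) for z ~ N(0, I).  Cholesky when V is
# numerically PD, otherwise an eigendecomposition with negative eigenvalues
# clamped to zero (kinship matrices are PSD up to rounding).
mvn_factor <- function(V) {
  V <- (V + t(V)) / 2
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (!is.null(ch)) return(t(ch))
  e <- eigen(V, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(V))
}

mvn_draw_factor <- function(A) as.vector(A %*% stats::rnorm(ncol(A)))
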