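# Shared fixtures: the 3 x 5 worked example and random instance generators.

table1_genotypes <- function() {
  genotype_matrix(rbind(c(1, 2, 1, 2, 2),
                        c(2, 1, 0, 1, 1),
                        c(0, 0, 2, 1, 2)),
                  individual_ids = c("1", "2", "3"),
                  marker_ids = paste0("M", 1:5))
}

table1_phenotypes <- function() c(`1` = 1.97, `2` = 2.12, `3` = -0.62)

table1_vc <- function() variance_components(sigma2_beta = 0.1, sigma2_e = 1,
                                            sigma2_L = 1000)

# Random dosage matrix with no missingness; not guaranteed full rank.
rand_genotypes <- function(n, p) {
  genotype_matrix(matrix(sample(0:2, n * p, replace = TRUE), n, p))
}

rand_instance <- function(n, p) {
  g <- rand_genotypes(n, p)
  list(g = g, y = stats::rnorm(n), n = n, p = p)
}

# Independent reference: dense generic solve of the MEM normal equations,
# no Cholesky, no shared code with the package internals.
ref_mem_solution <- function(X, y, lambda) {
  Xs <- cbind(1, X)
  D <- diag(c(0, rep(1, ncol(X))))
  unname(drop(solve(crossprod(Xs) + D * lambda, crossprod(Xs, y))))
}
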